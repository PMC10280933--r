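test_that("GMT parsing: structure, duplicate collapse, errors, round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tfirst\tg1\tg2\tg3\tg2",
               "SET_B\tsecond\tg4\tg5"), path)
  sets <- read_gmt(path)
  expect_length(sets, 2)
  expect_identical(sets$SET_A, c("g1", "g2", "g3"))  # duplicate member collapsed
  expect_identical(unname(attr(sets, "descriptions")["SET_B"]), "second")

  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, out)
  expect_identical(read_gmt(out), sets)

  writeLines(c("SET_A\td\tg1", "SET_A\td\tg2"), path)
  expect_error(read_gmt(path), "duplicate set name")
  writeLines("ONLY_TWO\tfields", path)
  expect_error(read_gmt(path), "line 1")
})

test_that("hypergeometric ORA matches exhaustive enumeration on small universes", {
  # worked value: N=10, K=5, n=4, k=4 -> 5/210
  universe <- paste0("g", 1:10)
  collection <- list(S = universe[1:5])
  res <- ora(universe[1:4], universe, collection, min_size = 1)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)
  expect_equal(res$k, 4)
  expect_equal(res$fold_enrichment, (4 / 4) / (5 / 10))

  # k = 0 tail is 1
  res0 <- ora(universe[6:9], universe, list(S = universe[1:5]), min_size = 1)
  expect_equal(res0$p, 1)

  # random small configurations against the enumeration oracle
  set.seed(4)
  for (i in 1:12) {
    N <- sample(6:12, 1); K <- sample(2:(N - 1), 1); n <- sample(1:N, 1)
    uni <- paste0("g", 1:N)
    query <- sample(uni, n)
    k <- sum(query %in% uni[1:K])
    res <- ora(query, uni, list(S = uni[1:K]), min_size = 1)
    expect_equal(res$p, enum_hyper_tail(N, K, n, k), tolerance = 1e-12)
  }

  # query = universe forces full overlap with every set
  resq <- ora(universe, universe, list(S = universe[1:5]), min_size = 1)
  expect_equal(resq$k, 5)
  expect_equal(resq$p, 1)
  expect_error(ora("g1", character(0), list(S = "g1")), "universe")
  expect_warning(ora(c("g1", "zz"), universe, list(S = universe[1:5]),
                     min_size = 1), "outside")
})

test_that("BH adjustment: hand-stepped example, idempotence, bounds", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  q <- bh_adjust(c(0.001, 0.04, 0.9, 0.2))
  expect_true(all(q >= c(0.001, 0.04, 0.9, 0.2)))        # q never below p
  expect_identical(order(q), order(c(0.001, 0.04, 0.9, 0.2)))  # order-preserving
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("enrichment score: worked cases and explicit running-sum oracle", {
  N <- 12
  genes <- sprintf("g%02d", 1:N)
  metric <- stats::setNames(seq(3, -3, length.out = N), genes)
  # single top-ranked gene, unweighted -> ES = 1
  expect_equal(gsea_es(genes, metric, genes[1], exponent = 0), 1)
  # single bottom-ranked gene, unweighted: walk reaches -1 just before the hit
  expect_equal(gsea_es(genes, metric, genes[N], exponent = 0), -1)
  # random sets against the trace oracle, weighted and unweighted
  set.seed(9)
  for (i in 1:20) {
    set <- sample(genes, sample(2:6, 1))
    for (ex in c(0, 1)) {
      expect_equal(gsea_es(genes, metric, set, exponent = ex),
                   trace_gsea_es(genes, metric, set, exponent = ex),
                   tolerance = 1e-12)
    }
  }
  # reversing the ranking flips which tail holds the extreme
  top_set <- genes[1:3]
  es_fwd <- gsea_es(genes, metric, top_set, exponent = 0)
  es_rev <- gsea_es(rev(genes), metric[rev(genes)], top_set, exponent = 0)
  expect_gt(es_fwd, 0)
  expect_lt(es_rev, 0)
  # positive rescaling of the metric leaves the weighted ES unchanged
  expect_equal(gsea_es(genes, metric * 7.3, genes[c(2, 5)], exponent = 1),
               gsea_es(genes, metric, genes[c(2, 5)], exponent = 1),
               tolerance = 1e-12)
  expect_error(gsea_es(genes, metric, "absent"), "intersect")
})

test_that("enrichment score agrees with the independent fgsea implementation", {
  skip_if_not_installed("fgsea")
  set.seed(11)
  N <- 60
  genes <- sprintf("g%02d", 1:N)
  metric <- stats::setNames(sort(rnorm(N), decreasing = TRUE), genes)
  for (i in 1:8) {
    set <- sample(genes, 8)
    ours <- gsea_es(genes, metric, set, exponent = 1)
    theirs <- fgsea::calcGseaStat(metric, selectedStats = which(genes %in% set),
                                  gseaParam = 1, scoreType = "std")
    expect_equal(ours, theirs, tolerance = 1e-8)
  }
})

test_that("permutation p is seeded, deterministic and powerful on planted sets", {
  N <- 300
  genes <- sprintf("g%03d", 1:N)
  set.seed(3)
  metric <- stats::setNames(sort(rnorm(N, 0, 1), decreasing = TRUE), genes)
  planted <- genes[1:15]  # top-concentrated
  g1 <- gsea_permutation_p(genes, metric, planted, n_perm = 500, seed = 77)
  g2 <- gsea_permutation_p(genes, metric, planted, n_perm = 500, seed = 77)
  expect_identical(g1$p, g2$p)
  expect_lt(g1$p, 0.05)
  g3 <- gsea_permutation_p(genes, metric, planted, n_perm = 500, seed = 78)
  expect_lt(g3$p, 0.05)  # small under any seed for a top-concentrated set
  expect_error(gsea_permutation_p(genes, metric, planted, n_perm = 10),
               "n_perm")
})
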