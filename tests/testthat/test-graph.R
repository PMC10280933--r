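test_that("PPI loading: inclusive score boundary, duplicate merge, validation", {
  rows <- data.frame(gene_a = c("A", "A", "B", "B", "C"),
                     gene_b = c("B", "B", "C", "A", "D"),
                     combined_score = c(0.8, 0.9, 0.70, 0.69, 0.69),
                     stringsAsFactors = FALSE)
  g <- load_ppi(rows, min_score = 0.7)
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 2)                    # A-B merged, B-C kept, rest dropped
  ab <- el[el$from == "A" | el$to == "A", ]
  expect_equal(ab$score, 0.9)                  # max wins on duplicates
  expect_true(any(el$score == 0.70))           # >= is inclusive
  bad <- rows; bad$combined_score[3] <- 1.2
  expect_error(load_ppi(bad), "row")
  loops <- data.frame(gene_a = "A", gene_b = "A", combined_score = 0.9)
  expect_equal(igraph::ecount(load_ppi(loops)), 0)
})

test_that("degree hubs rank deterministically under both comparators", {
  star <- igraph::make_star(6, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:5))
  hs <- degree_hubs(star, 4, ">=")
  expect_identical(hs$node_id, "hub")
  expect_equal(hs$degree, 5)
  expect_equal(nrow(degree_hubs(star, 5, ">")), 0)
})

test_that("k-core matches closed forms and the brute-force deletion oracle", {
  tri <- graph_from_pairs("a", "b", "b", "c", "a", "c")
  expect_true(all(k_core(tri) == 2))
  p4 <- graph_from_pairs("a", "b", "b", "c", "c", "d")
  expect_true(all(k_core(p4) == 1))
  g <- random_named_gnp(12, 0.4, 7)
  expect_equal(as.integer(k_core(g)[igraph::V(g)$name]),
               as.integer(brute_kcore(g)[igraph::V(g)$name]))
})

test_that("vertex weights equal k x density of the closed-neighborhood core", {
  w <- mcode_weights(fixture_k4_pendant())
  wt <- stats::setNames(w$weight, w$node_id)
  expect_equal(unname(wt[c("a", "b", "c", "d")]), rep(3, 4))  # K4 interior
  expect_equal(unname(wt["p"]), 1)                            # pendant: an edge
  lone <- igraph::make_empty_graph(1, directed = FALSE)
  igraph::V(lone)$name <- "z"
  expect_equal(mcode_weights(lone)$weight, 0)
  # pendant on a triangle: closed neighborhood is a single edge
  tri_p <- graph_from_pairs("a", "b", "b", "c", "a", "c", "c", "p")
  wtp <- mcode_weights(tri_p)
  expect_equal(wtp$weight[wtp$node_id == "p"], 1)
  expect_equal(wtp$k[wtp$node_id == "a"], 2)
})

test_that("module detection reproduces the hand-verified fixtures", {
  m1 <- mcode_modules(fixture_k4_pendant())
  expect_length(m1, 1)
  expect_identical(m1[[1]]$members, c("a", "b", "c", "d"))  # haircut drops p
  expect_equal(m1[[1]]$score, 4)                            # density 1 x size 4

  expect_length(mcode_modules(fixture_p6()), 0)             # no 2-core

  m3 <- mcode_modules(fixture_double_k4_bridge())
  expect_length(m3, 2)
  expect_identical(lapply(m3, `[[`, "members"),
                   list(c("a", "b", "c", "d"), c("e", "f", "g", "h")))
})

test_that("module output is deterministic under node insertion order", {
  g1 <- fixture_double_k4_bridge()
  perm <- igraph::permute(g1, match(igraph::V(g1)$name,
                                    rev(sort(igraph::V(g1)$name))))
  m1 <- mcode_modules(g1)
  m2 <- mcode_modules(perm)
  expect_identical(lapply(m1, `[[`, "members"), lapply(m2, `[[`, "members"))
  expect_identical(vapply(m1, `[[`, numeric(1), "score"),
                   vapply(m2, `[[`, numeric(1), "score"))
})

test_that("reported modules contain the required core and a density in (0,1]", {
  for (seed in 1:6) {
    g <- random_named_gnp(30, 0.18, seed)
    mods <- mcode_modules(g)
    for (m in mods) {
      sub <- igraph::induced_subgraph(g, m$members)
      expect_gte(max(igraph::coreness(sub)), 2)
      expect_gt(m$density, 0)
      expect_lte(m$density, 1)
      expect_true(igraph::is_connected(sub))
    }
    # node-disjointness of modules
    all_members <- unlist(lapply(mods, `[[`, "members"))
    expect_equal(anyDuplicated(all_members), 0)
  }
})

test_that("the planted PPI clique dominates the top module", {
  d <- generate_dataset(small_sim(seed = 19))
  g <- load_ppi(d$ppi, 0.7)
  mods <- mcode_modules(g)
  expect_gte(length(mods), 1)
  expect_gte(mean(d$truth$clique_members %in% mods[[1]]$members), 0.9)
  hubs <- degree_hubs(g, 10, ">")
  expect_true(all(hubs$node_id %in% d$truth$clique_members))
})
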