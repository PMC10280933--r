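test_that("identical config and seed give identical datasets and files", {
  d1 <- generate_dataset(small_sim(seed = 42))
  d2 <- generate_dataset(small_sim(seed = 42))
  expect_identical(d1$expr$values, d2$expr$values)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$lnc_mir, d2$lnc_mir)

  t1 <- withr::local_tempdir()
  t2 <- withr::local_tempdir()
  write_dataset(d1, t1)
  write_dataset(d2, t2)
  for (f in setdiff(list.files(t1), "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(t1, f))),
                     unname(tools::md5sum(file.path(t2, f))),
                     info = f)
  }
})

test_that("a different seed changes the data", {
  d1 <- generate_dataset(small_sim(seed = 1))
  d2 <- generate_dataset(small_sim(seed = 2))
  expect_false(identical(d1$expr$values, d2$expr$values))
})

test_that("null configuration yields empty ground truth and ~alpha-level raw calls", {
  cfg <- sim_config(n_mrna = 800, n_lncrna = 200, n_de_mrna = 0,
                    n_de_lncrna = 0, n_triples = 0, hub_lnc_mirna_fanout = 0,
                    seed = 5)
  d <- generate_dataset(cfg)
  expect_length(d$truth$de_genes_up, 0)
  expect_length(d$truth$de_genes_down, 0)
  expect_equal(nrow(d$truth$planted_triples), 0)
  de <- differential_expression(d$expr)
  # raw p < 0.05 near the nominal level; FC gate removes essentially all
  expect_lt(abs(mean(de$p < 0.05) - 0.05), 0.02)
  expect_lt(mean(de$direction != "ns"), 0.01)
})

test_that("planted pairs exceed the r > 0.97 gate by direct recomputation", {
  d <- generate_dataset(sim_config(seed = 7))
  pr <- d$truth$planted_pairs
  r <- vapply(seq_len(nrow(pr)), function(i)
    stats::cor(d$expr$values[pr$lncrna_id[i], ],
               d$expr$values[pr$mrna_id[i], ]), numeric(1))
  expect_gte(mean(r > 0.97), 0.95)
})

test_that("ground-truth invariants hold: triples back pairs, hub fan-out met", {
  d <- generate_dataset(small_sim(seed = 3))
  tr <- d$truth
  tk <- unique(paste(tr$planted_triples$lncrna_id, tr$planted_triples$mrna_id))
  pk <- paste(tr$planted_pairs$lncrna_id, tr$planted_pairs$mrna_id)
  expect_setequal(tk, pk)
  hub_triples <- tr$planted_triples[tr$planted_triples$lncrna_id == tr$hub_lncrna, ]
  expect_gte(nrow(hub_triples), 10)  # small_sim fan-out
  expect_gte(length(unique(hub_triples$mirna_id)), 10)
  # every planted triple is wired into both interaction tables
  lm <- paste(d$lnc_mir$source_id, d$lnc_mir$target_id)
  mm <- paste(d$mir_mrna$source_id, d$mir_mrna$target_id)
  expect_true(all(paste(tr$planted_triples$lncrna_id,
                        tr$planted_triples$mirna_id) %in% lm))
  expect_true(all(paste(tr$planted_triples$mirna_id,
                        tr$planted_triples$mrna_id) %in% mm))
})

test_that("inconsistent configurations are rejected with a clear error", {
  expect_error(sim_config(n_triples = 300, n_de_mrna = 20, n_mirna = 500),
               "DE mRNAs")
  expect_error(sim_config(n_triples = 10, hub_lnc_mirna_fanout = 20),
               "hub_lnc_mirna_fanout")
  expect_error(sim_config(coexpr_noise_sd = 0.5, noise_sd = 0.25),
               "coexpr_noise_sd")
  expect_error(sim_config(n_de_mrna = 5000), "exceed")
})

test_that("write_dataset emits 7 data files plus a checksummed manifest and round-trips", {
  d <- generate_dataset(small_sim(seed = 9))
  out <- withr::local_tempdir()
  manifest <- write_dataset(d, out)
  expect_length(manifest$checksums, 7)
  expect_setequal(list.files(out),
                  c("expression.tsv", "samples.tsv", "lncrna_mirna.tsv",
                    "mirna_mrna.tsv", "ppi.tsv", "gene_sets.gmt",
                    "ground_truth.tsv", "manifest.json"))
  em <- read_expression(file.path(out, "expression.tsv"),
                        file.path(out, "samples.tsv"))
  expect_equal(em$values, d$expr$values, tolerance = 1e-12)
  expect_identical(em$biotype, d$expr$biotype)
  expect_identical(em$groups, d$expr$groups)
  tr <- read_ground_truth(file.path(out, "ground_truth.tsv"))
  expect_identical(tr$hub_lncrna, d$truth$hub_lncrna)
  expect_identical(tr$planted_triples, d$truth$planted_triples)

  expect_error(write_dataset(d, ""), "non-empty")
})
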