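make_pairs <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(lncrna_id = m[, 1], mrna_id = m[, 2], stringsAsFactors = FALSE)
}
make_tab <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  data.frame(source_id = m[, 1], target_id = m[, 2], stringsAsFactors = FALSE)
}

test_that("triple assembly is the definition-forced set intersection", {
  net <- assemble_cerna(make_pairs("L1", "G1"),
                        make_tab("L1", "m1", "L1", "m2"),
                        make_tab("m1", "G1", "m3", "G1"))
  expect_equal(nrow(net$triples), 1)
  expect_identical(unlist(net$triples[1, ], use.names = FALSE),
                   c("L1", "m1", "G1"))
  expect_equal(nrow(net$edges), 2)
  expect_setequal(c(net$lncrna_nodes, net$mirna_nodes, net$mrna_nodes),
                  c("L1", "m1", "G1"))
  # no lncRNA-mRNA edge ever
  expect_false(any(net$edges$from %in% net$lncrna_nodes &
                   net$edges$to %in% net$mrna_nodes))

  # no shared miRNA -> empty network
  empty <- assemble_cerna(make_pairs("L1", "G1"),
                          make_tab("L1", "m1"), make_tab("m2", "G1"))
  expect_equal(nrow(empty$triples), 0)
  expect_length(empty$lncrna_nodes, 0)

  # empty co-expression input warns, does not error
  expect_warning(assemble_cerna(make_pairs("L1", "G1")[0, ], make_tab("L1", "m1"),
                                make_tab("m1", "G1")), "empty")
})

test_that("assembly is order-independent and monotone in interaction rows", {
  pairs <- make_pairs("L1", "G1", "L2", "G2", "L1", "G2")
  lm <- make_tab("L1", "m1", "L2", "m2", "L1", "m3", "L2", "m1")
  mm <- make_tab("m1", "G1", "m2", "G2", "m3", "G2", "m1", "G2")
  net1 <- assemble_cerna(pairs, lm, mm)
  net2 <- assemble_cerna(pairs[sample(nrow(pairs)), ],
                         lm[rev(seq_len(nrow(lm))), ],
                         mm[sample(nrow(mm)), ])
  expect_identical(net1$triples, net2$triples)
  expect_identical(net1$edges, net2$edges)
  # adding rows never removes triples
  net3 <- assemble_cerna(pairs, rbind(lm, make_tab("L1", "m9")),
                         rbind(mm, make_tab("m9", "G1")))
  old <- do.call(paste, net1$triples)
  new <- do.call(paste, net3$triples)
  expect_true(all(old %in% new))
  expect_true(length(new) > length(old))
})

test_that("degrees count incident edges and satisfy the handshake lemma", {
  net <- assemble_cerna(make_pairs("L1", "G1"),
                        make_tab("L1", "m1", "L1", "m2"),
                        make_tab("m1", "G1", "m2", "G1"))
  deg <- node_degrees(net)
  expect_equal(unname(deg["L1"]), 2)   # distinct miRNA partners
  expect_equal(unname(deg["G1"]), 2)
  expect_equal(unname(deg["m1"]), 2)
  expect_equal(sum(deg), 2 * nrow(net$edges))

  # lncRNA in k triples via k distinct miRNAs, one mRNA -> degree k
  k <- 5
  netk <- assemble_cerna(make_pairs("L1", "G1"),
                         do.call(make_tab, as.list(rbind("L1", paste0("m", 1:k)))),
                         do.call(make_tab, as.list(rbind(paste0("m", 1:k), "G1"))))
  expect_equal(unname(node_degrees(netk)["L1"]), k)
})

test_that("hub extraction applies strict/inclusive thresholds with stable ties", {
  degs <- c(L1 = 21, L2 = 20, L3 = 36)
  hs <- cernascope:::hub_set(degs, 20, ">")
  expect_identical(hs$node_id, c("L3", "L1"))
  hs2 <- cernascope:::hub_set(degs, 20, ">=")
  expect_identical(hs2$node_id, c("L3", "L1", "L2"))
  # tie-break by id at equal degree
  hs3 <- cernascope:::hub_set(c(B = 5, A = 5, C = 9), 4, ">")
  expect_identical(hs3$node_id, c("C", "A", "B"))
})

test_that("the planted hub lncRNA ranks first by degree", {
  d <- generate_dataset(small_sim(seed = 23))
  de <- differential_expression(d$expr)
  pairs <- coexpression_pairs(de, d$expr)
  net <- assemble_cerna(pairs, d$lnc_mir, d$mir_mrna, de)
  deg <- node_degrees(net)
  lnc_deg <- deg[names(deg) %in% net$lncrna_nodes]
  expect_identical(names(which.max(lnc_deg)), d$truth$hub_lncrna)
})

test_that("subnetwork extraction restricts triples and preserves invariants", {
  pairs <- make_pairs("L1", "G1", "L2", "G2")
  lm <- make_tab("L1", "m1", "L2", "m2", "L2", "m1")
  mm <- make_tab("m1", "G1", "m2", "G2", "m1", "G2")
  net <- assemble_cerna(pairs, lm, mm)
  all_sub <- extract_subnetwork(net, net$lncrna_nodes)
  expect_identical(all_sub$triples, net$triples)
  none <- extract_subnetwork(net, character(0))
  expect_equal(nrow(none$triples), 0)
  one <- extract_subnetwork(net, "L2")
  # recount: exactly the triples whose lncRNA is L2
  expect_identical(one$triples,
                   local({t <- net$triples[net$triples$lncrna_id == "L2", ]
                          rownames(t) <- NULL; t}))
  # every node in the restriction is in >= 1 triple, edges re-derive
  expect_setequal(one$mirna_nodes, unique(one$triples$mirna_id))
  expect_equal(nrow(one$edges),
               nrow(unique(one$triples[, c("lncrna_id", "mirna_id")])) +
               nrow(unique(one$triples[, c("mirna_id", "mrna_id")])))
  expect_error(extract_subnetwork(net, "L9"), "L9")
})

test_that("core-gene merge is an exact n-way intersection with membership export", {
  core <- core_mrnas(list(a = c("A", "B", "C"), b = c("B", "C", "D"),
                          c = c("C", "B")))
  expect_identical(as.character(core), c("B", "C"))
  mem <- attr(core, "membership")
  expect_setequal(mem$gene_id, c("A", "B", "C", "D"))
  expect_identical(mem$b[mem$gene_id == "A"], FALSE)
  expect_identical(core_mrnas(list(x = "A", y = "B")), character(0),
                   ignore_attr = TRUE)
  expect_error(core_mrnas(list(only = "A")), ">= 2")
  expect_error(core_mrnas(list(c("A"), c("B"))), "named")
})

test_that("network export/import round-trips triples, edges and attributes", {
  d <- generate_dataset(small_sim(seed = 31))
  de <- differential_expression(d$expr)
  pairs <- coexpression_pairs(de, d$expr)
  net <- assemble_cerna(pairs, d$lnc_mir, d$mir_mrna, de)
  dir <- withr::local_tempdir()
  files <- export_cerna(net, dir)
  expect_true(all(file.exists(files)))
  back <- import_cerna(dir)
  expect_identical(back$triples, net$triples)
  expect_identical(back$edges, net$edges)
  expect_identical(back$node_attrs, net$node_attrs)
  # the GraphML carries the same topology
  g <- igraph::read_graph(files[["graphml"]], format = "graphml")
  expect_equal(igraph::ecount(g), nrow(net$edges))
  expect_setequal(igraph::V(g)$name,
                  c(net$lncrna_nodes, net$mirna_nodes, net$mrna_nodes))
})
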