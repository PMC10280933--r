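#' Configuration for the synthetic ceRNA dataset generator
#'
#' Defaults emulate a two-group expression-array study design: 4 case vs 4
#' control samples, a few thousand mRNAs and a few hundred lncRNAs on log2
#' scale, several dozen genes shifted by +/- 2 log2 units in the case group,
#' planted lncRNA-mRNA co-expressed pairs tight enough to clear an r > 0.97
#' gate at n = 8, planted lncRNA-miRNA-mRNA triples, one hub lncRNA fanned out
#' through many miRNAs, and a dense clique planted in the PPI edge list.
#'
#' @param n_case,n_control samples per group.
#' @param n_mrna,n_lncrna,n_mirna numbers of genes of each species.
#' @param n_de_mrna,n_de_lncrna numbers of genes shifted between groups.
#' @param planted_log2fc magnitude of the case-group shift, log2 units.
#' @param noise_sd per-sample baseline noise, log2 units.
#' @param coexpr_noise_sd noise added when an mRNA copies its partner
#'   lncRNA's profile; must be smaller than \code{noise_sd} so planted pairs
#'   can exceed the correlation gate.
#' @param n_triples planted lncRNA-miRNA-mRNA triples (includes the hub's).
#' @param hub_lnc_mirna_fanout distinct miRNAs wired to the designated hub
#'   lncRNA; the hub's triples are spread over up to 5 partner mRNAs.
#' @param background_pair_rate probability of a background interaction row
#'   (also the background PPI edge rate).
#' @param ppi_hub_extra_degree extra high-confidence partners attached to each
#'   planted-clique member, mimicking high-degree hub proteins.
#' @param seed integer RNG seed.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_case = 4, n_control = 4,
                       n_mrna = 2000, n_lncrna = 500, n_mirna = 300,
                       n_de_mrna = 60, n_de_lncrna = 30,
                       planted_log2fc = 2.0, noise_sd = 0.25,
                       coexpr_noise_sd = 0.02,
                       n_triples = 40, hub_lnc_mirna_fanout = 30,
                       background_pair_rate = 0.002,
                       ppi_hub_extra_degree = 25,
                       seed = 1L) {
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_mrna = as.integer(n_mrna), n_lncrna = as.integer(n_lncrna),
              n_mirna = as.integer(n_mirna),
              n_de_mrna = as.integer(n_de_mrna),
              n_de_lncrna = as.integer(n_de_lncrna),
              planted_log2fc = as.numeric(planted_log2fc),
              noise_sd = as.numeric(noise_sd),
              coexpr_noise_sd = as.numeric(coexpr_noise_sd),
              n_triples = as.integer(n_triples),
              hub_lnc_mirna_fanout = as.integer(hub_lnc_mirna_fanout),
              background_pair_rate = as.numeric(background_pair_rate),
              ppi_hub_extra_degree = as.integer(ppi_hub_extra_degree),
              seed = as.integer(seed))
  with(cfg, {
    if (n_case < 2 || n_control < 2)
      stop("sim_config: need at least 2 samples per group")
    if (n_mrna < 1 || n_lncrna < 1 || n_mirna < 1)
      stop("sim_config: gene counts must be positive")
    if (n_de_mrna < 0 || n_de_lncrna < 0 || n_triples < 0 ||
        hub_lnc_mirna_fanout < 0 || ppi_hub_extra_degree < 0)
      stop("sim_config: counts must be non-negative")
    if (n_de_mrna > n_mrna || n_de_lncrna > n_lncrna)
      stop("sim_config: differential gene counts exceed gene totals")
    if (background_pair_rate < 0 || background_pair_rate > 1)
      stop("sim_config: background_pair_rate must be a probability")
    if (noise_sd <= 0 || coexpr_noise_sd <= 0)
      stop("sim_config: noise standard deviations must be positive")
    if (coexpr_noise_sd >= noise_sd)
      stop("sim_config: coexpr_noise_sd must be < noise_sd so planted pairs can pass the correlation gate")
    if (n_triples > 0) {
      if (n_triples < hub_lnc_mirna_fanout)
        stop("sim_config: n_triples must be >= hub_lnc_mirna_fanout (the hub's triples are part of n_triples)")
      if (n_triples > n_mirna)
        stop("sim_config: n_triples exceeds the number of miRNAs")
      n_hub_mrna <- min(5L, hub_lnc_mirna_fanout)
      need_mrna <- n_hub_mrna + (n_triples - hub_lnc_mirna_fanout)
      if (need_mrna > n_de_mrna)
        stop(sprintf("sim_config: n_triples=%d needs %d distinct DE mRNAs but n_de_mrna=%d",
                     n_triples, need_mrna, n_de_mrna))
      if (n_de_lncrna < 1)
        stop("sim_config: planted triples need at least one DE lncRNA")
    }
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_case, "case vs", x$n_control, "control;",
      x$n_mrna, "mRNA /", x$n_lncrna, "lncRNA /", x$n_mirna, "miRNA;",
      x$n_de_mrna + x$n_de_lncrna, "DE genes;", x$n_triples,
      "planted triples; seed", x$seed, "\n")
  invisible(x)
}

#' Generate a synthetic ceRNA study dataset with known ground truth
#'
#' Draws per-gene baseline log2 intensities uniform on [6, 12] with Gaussian
#' per-sample noise, shifts differential genes by \code{planted_log2fc} in the
#' case group, plants co-expressed lncRNA-mRNA pairs by profile sharing (the
#' mRNA copies its partner lncRNA's profile plus tiny noise, inheriting its
#' direction), wires planted triples into the two interaction tables, attaches
#' a dense high-score clique (size 8 where the configuration permits) plus
#' hub-protein spokes to the PPI edge list, and emits one gene set enriched
#' for up-regulated planted mRNAs among random sets. miRNAs get no expression
#' values: they enter the analysis only through the interaction tables.
#'
#' Identical \code{config} (including seed) gives byte-identical outputs.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list of class \code{cerna_dataset} with elements
#'   \code{expr} (an \code{\link{expression_matrix}}),
#'   \code{lnc_mir} and \code{mir_mrna} (interaction data.frames with columns
#'   \code{source_id}, \code{target_id}, \code{source_type},
#'   \code{target_type}), \code{ppi} (data.frame \code{gene_a}, \code{gene_b},
#'   \code{combined_score}), \code{gene_sets} (a named list as returned by
#'   \code{\link{read_gmt}}), \code{truth} (the ground truth, see Details) and
#'   \code{config}.
#'
#' @details \code{truth} is a list with \code{de_genes_up}, \code{de_genes_down}
#'   (character vectors over both biotypes), \code{planted_pairs} (data.frame
#'   \code{lncrna_id}, \code{mrna_id}), \code{planted_triples} (data.frame
#'   \code{lncrna_id}, \code{mirna_id}, \code{mrna_id}), \code{hub_lncrna}
#'   (id or \code{NA}), and \code{clique_members}.
#' @examples
#' d <- generate_dataset(sim_config(n_mrna = 200, n_lncrna = 50,
#'                                  n_mirna = 60, n_de_mrna = 20,
#'                                  n_de_lncrna = 10, n_triples = 12,
#'                                  hub_lnc_mirna_fanout = 8, seed = 3))
#' d$truth$hub_lncrna
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_samp <- config$n_case + config$n_control
  groups <- rep(c("case", "control"), c(config$n_case, config$n_control))
  sample_ids <- sprintf("S%02d_%s", seq_len(n_samp), groups)

  mrna_ids <- sprintf("MRNA%05d", seq_len(config$n_mrna))
  lnc_ids <- sprintf("LNC%05d", seq_len(config$n_lncrna))
  mir_ids <- sprintf("miR-%04d", seq_len(config$n_mirna))
  gene_ids <- c(mrna_ids, lnc_ids)
  biotype <- rep(c("mRNA", "lncRNA"), c(config$n_mrna, config$n_lncrna))
  n_gene <- length(gene_ids)

  mu <- stats::runif(n_gene, 6, 12)
  vals <- matrix(stats::rnorm(n_gene * n_samp, mean = mu, sd = config$noise_sd),
                 nrow = n_gene, ncol = n_samp,
                 dimnames = list(gene_ids, sample_ids))

  # differential genes and their directions
  de_mrna <- if (config$n_de_mrna > 0) sample(mrna_ids, config$n_de_mrna) else character()
  de_lnc <- if (config$n_de_lncrna > 0) sample(lnc_ids, config$n_de_lncrna) else character()
  dir_mrna <- rep_len(c("up", "down"), length(de_mrna))
  dir_lnc <- rep_len(c("up", "down"), length(de_lnc))
  names(dir_mrna) <- de_mrna
  names(dir_lnc) <- de_lnc

  # planted triples: the hub lncRNA takes the first fanout triples over up to
  # 5 partner mRNAs; remaining triples use one lncRNA/miRNA/mRNA each
  triples <- data.frame(lncrna_id = character(), mirna_id = character(),
                        mrna_id = character(), stringsAsFactors = FALSE)
  hub_lnc <- NA_character_
  if (config$n_triples > 0) {
    fan <- config$hub_lnc_mirna_fanout
    n_hub_mrna <- min(5L, fan)
    n_extra <- config$n_triples - fan
    hub_lnc <- de_lnc[1]
    trip_mirs <- mir_ids[seq_len(config$n_triples)]
    hub_mrnas <- de_mrna[seq_len(n_hub_mrna)]
    extra_mrnas <- if (n_extra > 0) de_mrna[n_hub_mrna + seq_len(n_extra)] else character()
    extra_lncs <- if (n_extra > 0) {
      pool <- setdiff(de_lnc, hub_lnc)
      if (length(pool) == 0) rep(hub_lnc, n_extra) else rep_len(pool, n_extra)
    } else character()
    triples <- rbind(
      if (fan > 0) data.frame(lncrna_id = hub_lnc,
                              mirna_id = trip_mirs[seq_len(fan)],
                              mrna_id = rep_len(hub_mrnas, fan),
                              stringsAsFactors = FALSE),
      if (n_extra > 0) data.frame(lncrna_id = extra_lncs,
                                  mirna_id = trip_mirs[fan + seq_len(n_extra)],
                                  mrna_id = extra_mrnas,
                                  stringsAsFactors = FALSE))
  }
  pairs <- unique(triples[, c("lncrna_id", "mrna_id")])

  # apply DE shifts to lncRNAs and to unpaired mRNAs; paired mRNAs then copy
  # their partner lncRNA's finished profile (inheriting shift + direction)
  case_cols <- which(groups == "case")
  shift <- function(id, dir) {
    s <- if (dir == "up") config$planted_log2fc else -config$planted_log2fc
    vals[id, case_cols] <<- vals[id, case_cols] + s
  }
  for (id in de_lnc) shift(id, dir_lnc[[id]])
  paired_mrna <- pairs$mrna_id
  for (id in setdiff(de_mrna, paired_mrna)) shift(id, dir_mrna[[id]])
  if (nrow(pairs) > 0) {
    for (i in seq_len(nrow(pairs))) {
      g <- pairs$mrna_id[i]; l <- pairs$lncrna_id[i]
      vals[g, ] <- vals[l, ] + stats::rnorm(n_samp, 0, config$coexpr_noise_sd)
      dir_mrna[[g]] <- dir_lnc[[l]]
    }
  }

  expr <- expression_matrix(vals, biotype, groups)

  # interaction tables: planted triple edges + background rows
  bern_pairs <- function(src, tgt, rate) {
    hits <- which(stats::runif(length(src) * length(tgt)) < rate)
    if (length(hits) == 0)
      return(data.frame(source_id = character(), target_id = character(),
                        stringsAsFactors = FALSE))
    data.frame(source_id = src[(hits - 1) %% length(src) + 1],
               target_id = tgt[(hits - 1) %/% length(src) + 1],
               stringsAsFactors = FALSE)
  }
  lm_bg <- bern_pairs(lnc_ids, mir_ids, config$background_pair_rate)
  mm_bg <- bern_pairs(mir_ids, mrna_ids, config$background_pair_rate)
  lnc_mir <- unique(rbind(
    data.frame(source_id = triples$lncrna_id, target_id = triples$mirna_id,
               stringsAsFactors = FALSE), lm_bg))
  mir_mrna <- unique(rbind(
    data.frame(source_id = triples$mirna_id, target_id = triples$mrna_id,
               stringsAsFactors = FALSE), mm_bg))
  lnc_mir$source_type <- "lncRNA"; lnc_mir$target_type <- "miRNA"
  mir_mrna$source_type <- "miRNA"; mir_mrna$target_type <- "mRNA"
  rownames(lnc_mir) <- rownames(mir_mrna) <- NULL

  # PPI: dense clique over triple-partner mRNAs (falling back to any DE
  # mRNAs), hub-protein spokes, and sparse background edges
  clique_size <- 8L
  clique_pool <- unique(c(paired_mrna, de_mrna))
  clique <- sort(clique_pool[seq_len(min(clique_size, length(clique_pool)))])
  ppi <- NULL
  if (length(clique) >= 2) {
    cmb <- utils::combn(clique, 2)
    ppi <- data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
                      combined_score = round(stats::runif(ncol(cmb), 0.90, 0.999), 3),
                      stringsAsFactors = FALSE)
    if (config$ppi_hub_extra_degree > 0) {
      spokes <- do.call(rbind, lapply(clique, function(g) {
        partners <- sample(setdiff(mrna_ids, clique), config$ppi_hub_extra_degree)
        data.frame(gene_a = g, gene_b = partners,
                   combined_score = round(stats::runif(length(partners), 0.70, 0.90), 3),
                   stringsAsFactors = FALSE)
      }))
      ppi <- rbind(ppi, spokes)
    }
  }
  n_bg_edges <- round(config$background_pair_rate * config$n_mrna * (config$n_mrna - 1) / 2)
  if (n_bg_edges > 0) {
    a <- sample(mrna_ids, n_bg_edges, replace = TRUE)
    b <- sample(mrna_ids, n_bg_edges, replace = TRUE)
    keep <- a != b
    bg <- data.frame(gene_a = pmin(a[keep], b[keep]),
                     gene_b = pmax(a[keep], b[keep]),
                     combined_score = round(stats::runif(sum(keep), 0.20, 0.80), 3),
                     stringsAsFactors = FALSE)
    ppi <- rbind(ppi, bg)
  }
  if (is.null(ppi))
    ppi <- data.frame(gene_a = character(), gene_b = character(),
                      combined_score = numeric(), stringsAsFactors = FALSE)
  ppi <- ppi[!duplicated(ppi[, c("gene_a", "gene_b")]), ]
  rownames(ppi) <- NULL

  # gene sets: one set enriched for up-regulated planted mRNAs, rest random
  de_up_mrna <- names(dir_mrna)[dir_mrna == "up"]
  gene_sets <- list()
  if (length(de_up_mrna) >= 10) {
    gene_sets$PLANTED_DE_SET <- sort(unique(c(
      de_up_mrna[seq_len(min(40, length(de_up_mrna)))],
      sample(setdiff(mrna_ids, de_mrna), 10))))
  }
  for (i in seq_len(19)) {
    gene_sets[[sprintf("RANDOM_SET_%02d", i)]] <- sort(sample(mrna_ids, 50))
  }
  attr(gene_sets, "descriptions") <-
    stats::setNames(rep("synthetic", length(gene_sets)), names(gene_sets))

  truth <- list(
    de_genes_up = sort(c(names(dir_mrna)[dir_mrna == "up"],
                         names(dir_lnc)[dir_lnc == "up"])),
    de_genes_down = sort(c(names(dir_mrna)[dir_mrna == "down"],
                           names(dir_lnc)[dir_lnc == "down"])),
    planted_pairs = pairs[order(pairs$lncrna_id, pairs$mrna_id), , drop = FALSE],
    planted_triples = triples[order(triples$lncrna_id, triples$mirna_id,
                                    triples$mrna_id), , drop = FALSE],
    hub_lncrna = hub_lnc,
    clique_members = clique)
  rownames(truth$planted_pairs) <- rownames(truth$planted_triples) <- NULL

  structure(list(expr = expr, lnc_mir = lnc_mir, mir_mrna = mir_mrna,
                 ppi = ppi, gene_sets = gene_sets, truth = truth,
                 config = config),
            class = "cerna_dataset")
}

#' @export
print.cerna_dataset <- function(x, ...) {
  cat("cerna_dataset (seed", x$config$seed, ")\n")
  print(x$expr)
  cat(sprintf("  %d lncRNA-miRNA rows, %d miRNA-mRNA rows, %d PPI edges, %d gene sets\n",
              nrow(x$lnc_mir), nrow(x$mir_mrna), nrow(x$ppi),
              length(x$gene_sets)))
  cat(sprintf("  truth: %d up / %d down, %d pairs, %d triples, hub %s\n",
              length(x$truth$de_genes_up), length(x$truth$de_genes_down),
              nrow(x$truth$planted_pairs), nrow(x$truth$planted_triples),
              x$truth$hub_lncrna))
  invisible(x)
}

#' Write a synthetic dataset to a directory of plain-text files
#'
#' Emits the expression matrix and sample sheet, the two interaction tables,
#' the PPI edge list, the gene-set GMT and the ground truth, plus a JSON
#' manifest holding the generating configuration, the seed, an md5 checksum
#' per file, and a note that all distributional choices are synthetic
#' stand-ins.
#'
#' @param dataset a \code{cerna_dataset} from \code{\link{generate_dataset}}.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the manifest as a list.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "cerna_dataset"))
  if (!is.character(out_dir) || length(out_dir) != 1 || !nzchar(out_dir))
    stop("write_dataset: 'out_dir' must be a non-empty path")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("write_dataset: cannot create directory ", out_dir)

  p <- function(f) file.path(out_dir, f)
  wt <- function(df, f) utils::write.table(df, p(f), sep = "\t", quote = FALSE,
                                           row.names = FALSE)
  write_expression(dataset$expr, p("expression.tsv"), p("samples.tsv"))
  wt(dataset$lnc_mir, "lncrna_mirna.tsv")
  wt(dataset$mir_mrna, "mirna_mrna.tsv")
  wt(dataset$ppi, "ppi.tsv")
  write_gmt(dataset$gene_sets, p("gene_sets.gmt"))

  tr <- dataset$truth
  truth_tab <- rbind(
    if (length(tr$de_genes_up)) data.frame(category = "de_up", id1 = tr$de_genes_up, id2 = "", id3 = ""),
    if (length(tr$de_genes_down)) data.frame(category = "de_down", id1 = tr$de_genes_down, id2 = "", id3 = ""),
    if (nrow(tr$planted_pairs)) data.frame(category = "pair", id1 = tr$planted_pairs$lncrna_id,
                                           id2 = tr$planted_pairs$mrna_id, id3 = ""),
    if (nrow(tr$planted_triples)) data.frame(category = "triple", id1 = tr$planted_triples$lncrna_id,
                                             id2 = tr$planted_triples$mirna_id,
                                             id3 = tr$planted_triples$mrna_id),
    if (!is.na(tr$hub_lncrna)) data.frame(category = "hub", id1 = tr$hub_lncrna, id2 = "", id3 = ""),
    if (length(tr$clique_members)) data.frame(category = "clique", id1 = tr$clique_members, id2 = "", id3 = ""))
  if (is.null(truth_tab))
    truth_tab <- data.frame(category = character(), id1 = character(),
                            id2 = character(), id3 = character())
  wt(truth_tab, "ground_truth.tsv")

  files <- c("expression.tsv", "samples.tsv", "lncrna_mirna.tsv",
             "mirna_mrna.tsv", "ppi.tsv", "gene_sets.gmt", "ground_truth.tsv")
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- list(config = unclass(dataset$config),
                   seed = dataset$config$seed,
                   note = "synthetic stand-in data; distributional choices are not fitted to any real platform",
                   checksums = as.list(stats::setNames(unname(sums), files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Read ground truth written by \code{\link{write_dataset}}
#'
#' @param path path to \code{ground_truth.tsv}.
#' @return A truth list in the same shape as \code{generate_dataset()$truth}
#'   (without \code{clique_members} ordering guarantees beyond sortedness).
#' @export
read_ground_truth <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  pick <- function(cat) tab[tab$category == cat, , drop = FALSE]
  pr <- pick("pair"); tp <- pick("triple"); hb <- pick("hub")
  list(de_genes_up = pick("de_up")$id1,
       de_genes_down = pick("de_down")$id1,
       planted_pairs = data.frame(lncrna_id = pr$id1, mrna_id = pr$id2,
                                  stringsAsFactors = FALSE),
       planted_triples = data.frame(lncrna_id = tp$id1, mirna_id = tp$id2,
                                    mrna_id = tp$id3, stringsAsFactors = FALSE),
       hub_lncrna = if (nrow(hb)) hb$id1 else NA_character_,
       clique_members = pick("clique")$id1)
}
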