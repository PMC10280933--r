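#' Pipeline configuration
#'
#' Collects every stage threshold of the co-dysregulation analysis with its
#' default gate: fold change >= 2.0 / <= 0.5 at raw p < 0.05 for differential
#' expression; Pearson r > 0.97 at p < 0.01 for co-expression; combined score
#' >= 0.7 for PPI edges; degree > 20 for whole-PPI hub genes and hub lncRNAs;
#' degree >= 4 for hub mRNAs in the ceRNA-restricted PPI; MCODE with degree
#' cutoff 2, node score cutoff 0.2, k-core 2, max depth 100.
#'
#' @param out_dir output directory for stage files and the report.
#' @param seed integer seed driving simulation and GSEA permutations.
#' @param input_dir optional directory of input files as written by
#'   \code{\link{write_dataset}}; when NULL a dataset is simulated from
#'   \code{sim}.
#' @param sim a \code{\link{sim_config}} used when \code{input_dir} is NULL
#'   (its seed is overridden by \code{seed}).
#' @param fc_up,fc_down,alpha differential-expression gates.
#' @param r_min,p_max,use_absolute co-expression gates.
#' @param ppi_min_score PPI combined-score cutoff (inclusive).
#' @param ppi_hub_degree whole-PPI hub degree threshold (strict >).
#' @param cerna_ppi_hub_degree ceRNA-PPI hub degree threshold (inclusive >=).
#' @param lnc_hub_degree hub-lncRNA degree threshold (strict >).
#' @param mcode list of MCODE parameters passed to
#'   \code{\link{mcode_modules}}.
#' @param gsea_n_perm gene permutations per GSEA set.
#' @param cache reuse cached stage results when inputs are unchanged.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(out_dir, seed = 1L, input_dir = NULL,
                            sim = sim_config(),
                            fc_up = 2.0, fc_down = 0.5, alpha = 0.05,
                            r_min = 0.97, p_max = 0.01, use_absolute = FALSE,
                            ppi_min_score = 0.7, ppi_hub_degree = 20,
                            cerna_ppi_hub_degree = 4, lnc_hub_degree = 20,
                            mcode = list(degree_cutoff = 2,
                                         node_score_cutoff = 0.2, k_core = 2,
                                         max_depth = 100, haircut = TRUE,
                                         fluff = FALSE),
                            gsea_n_perm = 1000, cache = TRUE) {
  if (missing(out_dir) || !nzchar(out_dir))
    stop("pipeline_config: 'out_dir' is required")
  stopifnot(alpha >= 0, alpha <= 1, r_min >= -1, r_min <= 1,
            p_max >= 0, p_max <= 1, ppi_min_score >= 0, ppi_min_score <= 1,
            fc_up > 0, fc_down > 0)
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 input_dir = input_dir, sim = sim,
                 fc_up = fc_up, fc_down = fc_down, alpha = alpha,
                 r_min = r_min, p_max = p_max, use_absolute = use_absolute,
                 ppi_min_score = ppi_min_score,
                 ppi_hub_degree = ppi_hub_degree,
                 cerna_ppi_hub_degree = cerna_ppi_hub_degree,
                 lnc_hub_degree = lnc_hub_degree, mcode = mcode,
                 gsea_n_perm = gsea_n_perm, cache = isTRUE(cache)),
            class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

obj_md5 <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

# checksum-keyed stage cache: recompute only when the stage inputs changed
stage_cached <- function(env, stage, inputs, fun) {
  if (!env$config$cache) {
    stage_log(stage, "computing")
    return(fun())
  }
  key <- obj_md5(list(stage, inputs))
  path <- file.path(env$cache_dir, paste0(stage, "-", key, ".rds"))
  if (file.exists(path)) {
    stage_log(stage, "cache hit")
    env$cache_hits <- env$cache_hits + 1L
    return(readRDS(path))
  }
  stage_log(stage, "computing")
  val <- fun()
  saveRDS(val, path, version = 2)
  val
}

#' Run the full co-dysregulation ceRNA pipeline
#'
#' Executes, in dependency order: data acquisition (simulation or reading the
#' \code{input_dir}), differential expression, lncRNA-mRNA co-expression,
#' ceRNA triple assembly, hub-lncRNA and core-subnetwork extraction, PPI
#' loading with degree hubs and MCODE modules (whole and ceRNA-restricted),
#' ORA and GSEA enrichment, and the core-gene intersection. Stage results are
#' written as TSVs under \code{out_dir}, cached by input checksum, and
#' summarized in a JSON report; a fixed seed and config give a byte-identical
#' bundle.
#'
#' A stage failure stops with the stage name; an empty differential or
#' co-expression result is not a failure — downstream stages produce valid
#' empty outputs.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return A list of class \code{result_bundle} holding every stage result
#'   plus \code{summary} (named counts), \code{files} (written paths) and
#'   \code{cache_hits}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir) &&
      !dir.create(config$out_dir, recursive = TRUE))
    stop("run_pipeline: cannot create ", config$out_dir)
  env <- new.env()
  env$config <- config
  env$cache_dir <- file.path(config$out_dir, "cache")
  if (config$cache && !dir.exists(env$cache_dir))
    dir.create(env$cache_dir, recursive = TRUE)
  env$cache_hits <- 0L

  run_stage <- function(stage, inputs, fun) {
    tryCatch(stage_cached(env, stage, inputs, fun),
             error = function(e)
               stop("pipeline stage '", stage, "' failed: ",
                    conditionMessage(e), call. = FALSE))
  }

  # -- data -----------------------------------------------------------------
  dataset <- if (is.null(config$input_dir)) {
    run_stage("simulate", config$sim, function() generate_dataset(config$sim))
  } else {
    run_stage("load", config$input_dir, function() {
      d <- config$input_dir
      list(expr = read_expression(file.path(d, "expression.tsv"),
                                  file.path(d, "samples.tsv")),
           lnc_mir = utils::read.delim(file.path(d, "lncrna_mirna.tsv"),
                                       stringsAsFactors = FALSE),
           mir_mrna = utils::read.delim(file.path(d, "mirna_mrna.tsv"),
                                        stringsAsFactors = FALSE),
           ppi = utils::read.delim(file.path(d, "ppi.tsv"),
                                   stringsAsFactors = FALSE),
           gene_sets = read_gmt(file.path(d, "gene_sets.gmt")),
           truth = NULL, config = NULL)
    })
  }

  # -- differential expression ---------------------------------------------
  stage_log("de", sprintf("gates: fc >= %g or <= %g, p < %g",
                          config$fc_up, config$fc_down, config$alpha))
  de <- run_stage("de", list(dataset$expr, config$fc_up, config$fc_down,
                             config$alpha),
                  function() differential_expression(dataset$expr,
                                                     config$fc_up,
                                                     config$fc_down,
                                                     config$alpha))
  dif <- de[de$direction != "ns", ]
  have_dif <- sum(dif$biotype == "lncRNA") > 0 && sum(dif$biotype == "mRNA") > 0

  # -- co-expression --------------------------------------------------------
  stage_log("coexpr", sprintf("gates: r > %g, p < %g%s", config$r_min,
                              config$p_max,
                              if (config$use_absolute) " (absolute)" else ""))
  pairs <- if (have_dif) {
    run_stage("coexpr", list(de, dataset$expr, config$r_min, config$p_max,
                             config$use_absolute),
              function() coexpression_pairs(de, dataset$expr, config$r_min,
                                            config$p_max,
                                            config$use_absolute))
  } else {
    stage_log("coexpr", "no differential lncRNA/mRNA pair; empty result")
    empty_coexpr()
  }

  # -- ceRNA assembly and hubs ---------------------------------------------
  net <- run_stage("cerna", list(pairs, dataset$lnc_mir, dataset$mir_mrna, de),
                   function() suppressWarnings(
                     assemble_cerna(pairs, dataset$lnc_mir, dataset$mir_mrna,
                                    de)))
  stage_log("hubs", "lncRNA hub gate: degree > ", config$lnc_hub_degree)
  lnc_hubs <- hub_lncrnas(net, config$lnc_hub_degree, ">")
  core_net <- if (nrow(lnc_hubs) > 0) {
    extract_subnetwork(net, lnc_hubs$node_id[1])
  } else NULL

  # -- PPI: whole-network hubs and modules ---------------------------------
  stage_log("ppi", "combined score cutoff >= ", config$ppi_min_score)
  ppi <- run_stage("ppi", list(dataset$ppi, config$ppi_min_score),
                   function() load_ppi(dataset$ppi, config$ppi_min_score))
  ppi_hubs <- degree_hubs(ppi, config$ppi_hub_degree, ">")
  stage_log("mcode", sprintf("degree cutoff %d, k-core %d, max depth %d",
                             config$mcode$degree_cutoff, config$mcode$k_core,
                             config$mcode$max_depth))
  modules <- run_stage("mcode", list(dataset$ppi, config$ppi_min_score,
                                     config$mcode),
                       function() do.call(mcode_modules,
                                          c(list(ppi), config$mcode)))

  # -- ceRNA-restricted PPI hubs -------------------------------------------
  cerna_genes <- intersect(net$mrna_nodes, igraph::V(ppi)$name)
  cerna_ppi_hubs <- if (length(cerna_genes) >= 2) {
    sub <- igraph::induced_subgraph(ppi, cerna_genes)
    degree_hubs(sub, config$cerna_ppi_hub_degree, ">=")
  } else hub_set(stats::setNames(integer(0), character(0)),
                 config$cerna_ppi_hub_degree, ">=")

  # -- enrichment -----------------------------------------------------------
  mrna_ids <- rownames(dataset$expr$values)[dataset$expr$biotype == "mRNA"]
  dif_mrna <- dif$gene_id[dif$biotype == "mRNA"]
  ora_res <- if (length(dif_mrna) > 0 && length(dataset$gene_sets) > 0) {
    run_stage("ora", list(dif_mrna, mrna_ids, dataset$gene_sets),
              function() ora(dif_mrna, mrna_ids, dataset$gene_sets))
  } else NULL
  gsea_res <- if (length(dataset$gene_sets) > 0) {
    run_stage("gsea", list(de, dataset$gene_sets, config$gsea_n_perm,
                           config$seed),
              function() {
        de_mrna <- de[de$biotype == "mRNA", ]
        ranked <- de_mrna$gene_id[order(-de_mrna$log2fc, de_mrna$gene_id)]
        metric <- stats::setNames(de_mrna$log2fc, de_mrna$gene_id)[ranked]
        rows <- lapply(names(dataset$gene_sets), function(nm) {
          set <- dataset$gene_sets[[nm]]
          if (length(intersect(set, ranked)) == 0) return(NULL)
          g <- gsea_permutation_p(ranked, metric, set,
                                  n_perm = config$gsea_n_perm,
                                  seed = config$seed)
          data.frame(set_name = nm, size = g$set_size, es = g$es, p = g$p,
                     n_perm = g$n_perm, stringsAsFactors = FALSE)
        })
        rows <- rows[!vapply(rows, is.null, logical(1))]
        if (length(rows) == 0) NULL else do.call(rbind, rows)
      })
  } else NULL

  # -- core-gene intersection ----------------------------------------------
  core_sets <- list(
    cerna_core_mrnas = if (!is.null(core_net)) core_net$mrna_nodes else character(),
    cerna_ppi_hubs = cerna_ppi_hubs$node_id,
    whole_ppi_hubs = ppi_hubs$node_id)
  core_sets <- core_sets[lengths(core_sets) > 0]
  core <- if (length(core_sets) >= 2) core_mrnas(core_sets) else character()

  # -- write stage files ----------------------------------------------------
  out <- config$out_dir
  wt <- function(df, f) {
    p <- file.path(out, f)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- c(
    de = wt(format_floats(de), "de.tsv"),
    coexpr = wt(format_floats(as.data.frame(pairs)), "coexpr_pairs.tsv"),
    lnc_hubs = wt(as.data.frame(lnc_hubs), "hub_lncrnas.tsv"),
    ppi_hubs = wt(as.data.frame(ppi_hubs), "ppi_hubs.tsv"),
    cerna_ppi_hubs = wt(as.data.frame(cerna_ppi_hubs), "cerna_ppi_hubs.tsv"),
    core = wt(data.frame(gene_id = core), "core_genes.tsv"))
  files <- c(files, export_cerna(net, out))
  mcode_path <- file.path(out, "mcode_modules.tsv")
  write_mcode(modules, mcode_path)
  files <- c(files, mcode = mcode_path)
  if (!is.null(ora_res)) files <- c(files, ora = wt(format_floats(ora_res), "ora.tsv"))
  if (!is.null(gsea_res)) files <- c(files, gsea = wt(format_floats(gsea_res), "gsea.tsv"))

  summary <- list(
    seed = config$seed,
    n_genes = nrow(dataset$expr$values),
    n_samples = ncol(dataset$expr$values),
    de = de_summary(de),
    n_coexpr_pairs = nrow(pairs),
    network = list(n_lncrna = length(net$lncrna_nodes),
                   n_mirna = length(net$mirna_nodes),
                   n_mrna = length(net$mrna_nodes),
                   n_edges = nrow(net$edges),
                   n_triples = nrow(net$triples)),
    hub_lncrnas = lnc_hubs$node_id,
    n_ppi_hubs = nrow(ppi_hubs),
    cerna_ppi_hubs = cerna_ppi_hubs$node_id,
    module_sizes = vapply(modules, `[[`, numeric(1), "size"),
    core_genes = as.character(core))

  bundle <- structure(list(dataset = dataset, de = de, pairs = pairs,
                           network = net, lnc_hubs = lnc_hubs,
                           core_network = core_net, ppi = ppi,
                           ppi_hubs = ppi_hubs,
                           cerna_ppi_hubs = cerna_ppi_hubs,
                           modules = modules, ora = ora_res, gsea = gsea_res,
                           core_genes = core, summary = summary,
                           files = files, cache_hits = env$cache_hits,
                           config = config),
                      class = "result_bundle")
  write_report(bundle, file.path(out, "report.json"))
  bundle
}

# 6-significant-digit float formatting for deterministic table output
format_floats <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  df
}

#' Write the machine- and human-readable pipeline report
#'
#' Writes the JSON summary (stable key order) to \code{path} and a plain-text
#' digest alongside it (same path with a \code{.txt} extension).
#'
#' @param bundle a \code{result_bundle} from \code{\link{run_pipeline}}.
#' @param path output JSON path.
#' @return Invisibly, the JSON path.
#' @export
write_report <- function(bundle, path) {
  stopifnot(inherits(bundle, "result_bundle"))
  s <- bundle$summary
  jsonlite::write_json(s, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  txt <- sub("\\.json$", ".txt", path)
  if (identical(txt, path)) txt <- paste0(path, ".txt")
  des <- s$de
  lines <- c(
    "ceRNA co-dysregulation pipeline report",
    sprintf("seed: %d; %d genes x %d samples", s$seed, s$n_genes, s$n_samples),
    sprintf("differential: lncRNA %d up / %d down; mRNA %d up / %d down",
            des$up[des$biotype == "lncRNA"], des$down[des$biotype == "lncRNA"],
            des$up[des$biotype == "mRNA"], des$down[des$biotype == "mRNA"]),
    sprintf("co-expression pairs retained: %d", s$n_coexpr_pairs),
    sprintf("ceRNA network: %d lncRNA / %d miRNA / %d mRNA, %d edges, %d triples",
            s$network$n_lncrna, s$network$n_mirna, s$network$n_mrna,
            s$network$n_edges, s$network$n_triples),
    sprintf("hub lncRNAs (degree > %g): %s", bundle$config$lnc_hub_degree,
            if (length(s$hub_lncrnas)) paste(s$hub_lncrnas, collapse = ", ") else "none"),
    sprintf("whole-PPI hubs (degree > %g): %d", bundle$config$ppi_hub_degree,
            s$n_ppi_hubs),
    sprintf("MCODE module sizes: %s",
            if (length(s$module_sizes)) paste(s$module_sizes, collapse = ", ") else "none"),
    sprintf("core genes: %s",
            if (length(s$core_genes)) paste(s$core_genes, collapse = ", ") else "none"))
  writeLines(lines, txt)
  invisible(path)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("result_bundle (seed ", x$config$seed, ")\n", sep = "")
  print(x$network)
  cat(sprintf("  %d hub lncRNA(s), %d core gene(s), %d MCODE module(s), %d cache hit(s)\n",
              nrow(x$lnc_hubs), length(x$core_genes), length(x$modules),
              x$cache_hits))
  invisible(x)
}
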