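#' Pipeline run configuration
#'
#' Paths and parameters for a full two-population comparison run. The two
#' populations are labelled `"GFP"` (mature) and `"RFP"` (young) by
#' default; labels must be distinct.
#'
#' @param quant_a,quant_b Paths to the two populations' Salmon-style
#'   quantification tables (A = mature/GFP, B = young/RFP by default
#'   labelling).
#' @param tx2gene Path to the transcript-to-gene map.
#' @param ortholog_map Optional path to the source-to-human ortholog map.
#' @param megakaryocyte,platelet Optional paths to external gene lists.
#' @param thresholds A [threshold_config()].
#' @param labels Character length-2, population labels (default
#'   `c("GFP", "RFP")`).
#' @param seed Integer recorded in provenance (the comparison itself is
#'   deterministic).
#' @param out_dir Output directory for intermediates and the report.
#' @param unmapped Unmapped-transcript policy for gene aggregation
#'   (`"lenient"` or `"strict"`).
#' @param verbose Log stage progress to standard error.
#' @return A `run_config` list.
#' @export
run_config <- function(quant_a, quant_b, tx2gene,
                       ortholog_map = NULL,
                       megakaryocyte = NULL, platelet = NULL,
                       thresholds = threshold_config(),
                       labels = c("GFP", "RFP"),
                       seed = 1L, out_dir = tempfile("thrombocompare_run_"),
                       unmapped = c("lenient", "strict"),
                       verbose = FALSE) {
  unmapped <- match.arg(unmapped)
  stopifnot(length(labels) == 2L, labels[1L] != labels[2L],
            inherits(thresholds, "threshold_config"))
  for (p in c(quant_a, quant_b, tx2gene, ortholog_map, megakaryocyte,
              platelet)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path not resolvable: ", p, call. = FALSE)
    }
  }
  structure(list(quant_a = quant_a, quant_b = quant_b, tx2gene = tx2gene,
                 ortholog_map = ortholog_map,
                 megakaryocyte = megakaryocyte, platelet = platelet,
                 thresholds = thresholds, labels = labels,
                 seed = as.integer(seed), out_dir = out_dir,
                 unmapped = unmapped, verbose = isTRUE(verbose)),
            class = "run_config")
}

stage_log <- function(cfg, stage, msg) {
  if (cfg$verbose) {
    message(sprintf("[stage:%s] %s", stage, msg))
  }
}

run_stage <- function(cfg, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    marker <- file.path(cfg$out_dir, "FAILED")
    writeLines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
               marker)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  stage_log(cfg, stage, sprintf("done in %.2fs",
                                proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full two-population comparison pipeline
#'
#' Stages, in order: transcript TPM recomputation and gene-level
#' aggregation for both populations; expressed / highly-expressed
#' classification and five-interval binning; two-way expressed-set
#' comparison; decile partition and cross-population overlap matrix;
#' ortholog projection of the cumulative expressed set; three-way
#' comparison with the external megakaryocyte and platelet lists (with
#' the population-unique sets as designated subsets). Every intermediate
#' is materialised under `cfg$out_dir`, and the report is written as both
#' JSON and flat TSV. Re-running with identical config and inputs
#' produces byte-identical reports (no timestamps enter the outputs;
#' timing goes to standard error only).
#'
#' @param cfg A [run_config()].
#' @return The comparison report, an object of class `comparison_report`
#'   (named list; see the `report.json` it writes), invisibly returned
#'   components included.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  lab <- cfg$labels

  tx2gene <- run_stage(cfg, "read", read_tx2gene(cfg$tx2gene))
  pops <- run_stage(cfg, "quantify", {
    lapply(stats::setNames(c(cfg$quant_a, cfg$quant_b), lab), function(p) {
      q <- compute_transcript_tpm(read_quant_table(p))
      aggregate_gene_tpm(q, tx2gene, unmapped = cfg$unmapped)
    })
  })

  pops <- run_stage(cfg, "classify", {
    lapply(pops, classify_population, cfg = cfg$thresholds)
  })
  bins <- lapply(pops, bin_tpm_intervals)
  for (l in lab) {
    utils::write.table(pops[[l]], file.path(cfg$out_dir,
                                            paste0("genes_", l, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(bins[[l]], file.path(cfg$out_dir,
                                            paste0("intervals_", l, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_gene_list(expressed_genes(pops[[l]]),
                    file.path(cfg$out_dir, paste0("expressed_", l, ".txt")))
    write_gene_list(highly_expressed_genes(pops[[l]]),
                    file.path(cfg$out_dir, paste0("highly_expressed_", l,
                                                  ".txt")))
  }

  comparison <- run_stage(cfg, "compare", {
    compare_two(expressed_genes(pops[[lab[1L]]]),
                expressed_genes(pops[[lab[2L]]]))
  })
  write_gene_list(comparison$common_genes,
                  file.path(cfg$out_dir, "expressed_common.txt"))
  write_gene_list(comparison$unique_a,
                  file.path(cfg$out_dir,
                            paste0("expressed_unique_", lab[1L], ".txt")))
  write_gene_list(comparison$unique_b,
                  file.path(cfg$out_dir,
                            paste0("expressed_unique_", lab[2L], ".txt")))

  qmat <- run_stage(cfg, "quantile_map", {
    qa <- partition_quantiles(pops[[lab[1L]]][pops[[lab[1L]]]$expressed, ])
    qb <- partition_quantiles(pops[[lab[2L]]][pops[[lab[2L]]]$expressed, ])
    overlap_matrix(qa, qb, labels = lab)
  })
  write_overlap_matrix(qmat, file.path(cfg$out_dir, "quantile_matrix.csv"))

  projection <- NULL
  if (!is.null(cfg$ortholog_map)) {
    projection <- run_stage(cfg, "orthologs", {
      map_to_orthologs(comparison$union_genes,
                       read_ortholog_map(cfg$ortholog_map))
    })
    write_gene_list(projection$distinct_orthologs,
                    file.path(cfg$out_dir, "orthologs_distinct.txt"))
  }

  mk <- if (is.null(cfg$megakaryocyte)) character(0L) else
    read_gene_list(cfg$megakaryocyte)
  pl <- if (is.null(cfg$platelet)) character(0L) else
    read_gene_list(cfg$platelet)
  triset <- run_stage(cfg, "compare3", {
    compare_three(comparison$union_genes, mk, pl,
                  designated_subsets = stats::setNames(
                    list(comparison$unique_a, comparison$unique_b),
                    paste0("unique_", lab)))
  })

  highly_common <- intersect(highly_expressed_genes(pops[[lab[1L]]]),
                             highly_expressed_genes(pops[[lab[2L]]]))

  report <- list(
    populations = stats::setNames(lapply(lab, function(l) {
      list(total_genes = nrow(pops[[l]]),
           expressed = sum(pops[[l]]$expressed),
           highly_expressed = sum(pops[[l]]$highly_expressed),
           intervals = bins[[l]])
    }), lab),
    comparison = list(
      n_union = comparison$n_union, n_common = comparison$n_common,
      n_unique_a = comparison$n_unique_a,
      n_unique_b = comparison$n_unique_b
    ),
    highly_expressed_common = length(highly_common),
    orthologs = if (is.null(projection)) NULL else list(
      raw_hits = projection$n_raw,
      redundant = projection$redundant_count,
      distinct = projection$n_distinct,
      unmapped_sources = projection$n_unmapped,
      percent_of_union = percent_of(projection$n_distinct,
                                    comparison$n_union)
    ),
    quantile_matrix = unclass(qmat)[1:10, 1:10, drop = FALSE],
    quantile_mean_tpm = list(a = attr(qmat, "mean_tpm_a"),
                             b = attr(qmat, "mean_tpm_b")),
    tri_set = list(
      n_m = triset$n_m, n_p = triset$n_p,
      n_tm = triset$n_tm, n_tp = triset$n_tp, n_tmp = triset$n_tmp,
      percent_tm = if (triset$n_t > 0)
        percent_of(triset$n_tm, triset$n_t) else 0L,
      percent_tp = if (triset$n_t > 0)
        percent_of(triset$n_tp, triset$n_t) else 0L,
      subsets = lapply(triset$subsets, function(s)
        list(with_m = s$n_with_m, with_p = s$n_with_p))
    ),
    provenance = list(
      seed = cfg$seed,
      labels = lab,
      thresholds = unclass(cfg$thresholds),
      config_hash = rlang::hash(cfg[setdiff(names(cfg), "verbose")]),
      package_version = as.character(utils::packageVersion("thrombocompare"))
    )
  )
  class(report) <- "comparison_report"
  write_report(unclass(report), file.path(cfg$out_dir, "report.json"),
               format = "json")
  report_flat <- unclass(report)
  report_flat$quantile_matrix <- as.data.frame(report$quantile_matrix)
  write_report(report_flat, file.path(cfg$out_dir, "report.tsv"),
               format = "tsv")
  invisible(report)
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Two-population comparison report\n")
  for (l in names(x$populations)) {
    p <- x$populations[[l]]
    cat(sprintf("  %s: %d genes, %d expressed, %d highly expressed\n",
                l, p$total_genes, p$expressed, p$highly_expressed))
  }
  cat(sprintf("  union %d, common %d, unique %d / %d\n",
              x$comparison$n_union, x$comparison$n_common,
              x$comparison$n_unique_a, x$comparison$n_unique_b))
  if (!is.null(x$orthologs)) {
    cat(sprintf("  orthologs: %d distinct (%d%% of union)\n",
                x$orthologs$distinct, x$orthologs$percent_of_union))
  }
  invisible(x)
}
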