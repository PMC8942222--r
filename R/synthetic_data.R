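#' Configuration for the synthetic thrombocyte data generator
#'
#' The generator emulates, at desk scale, the statistical structure of the
#' two sorted thrombocyte populations and their companion resources: a
#' zero-inflated gene-level TPM mixture per population, a transcript table
#' that inverts to the gene TPM under the TPM formula, a many-to-one
#' ortholog map with paralog collapse, and external megakaryocyte/platelet
#' gene lists with configurable overlaps.
#'
#' Per-population TPM mixture: a gene has zero TPM with probability
#' `zero_fraction`, TPM uniform in (0, 1) with probability
#' `sub1_fraction`, and otherwise TPM = 1 + a lognormal draw
#' (`lognormal_meanlog`, `lognormal_sdlog`). The default mixture weights
#' are the observed mature (GFP) and young (RFP) population fractions
#' (zero: 40.09% / 49.12%; sub-1: 20.19% / 34.55%), and the default
#' lognormal parameters are solved so the three expressed intervals
#' approximate the observed proportions (GFP 15.94 / 15.01 / 8.71,
#' RFP 9.57 / 4.68 / 2.05, percent of all genes); the mature population
#' has the heavier right tail.
#'
#' @param seed Integer seed; all generators derive their streams from it.
#' @param n_genes Number of genes per population (default 10000).
#' @param transcripts_per_gene Integer range (length-2 vector) of
#'   transcripts per gene, default `c(1, 3)`.
#' @param zero_fraction,sub1_fraction Named numeric, probability per
#'   population (`GFP`, `RFP`) of the zero / sub-1 TPM components.
#' @param lognormal_meanlog,lognormal_sdlog Named numeric per population,
#'   parameters of the expressed-magnitude lognormal (natural-log scale).
#' @param ortholog_coverage Probability a source gene has any human
#'   ortholog (default 0.72).
#' @param paralog_fraction Probability a human gene is shared by 2-3
#'   source paralogs (default 0.1).
#' @param mk_overlap,pl_overlap,three_way_overlap Target |T&M|/|T|,
#'   |T&P|/|T| and |T&M&P|/|T| fractions for the external megakaryocyte
#'   and platelet lists (defaults 0.46, 0.17, 0.146).
#' @param mk_size_factor,pl_size_factor External list sizes as fractions
#'   of |T| (defaults 0.843 and 0.308, the megakaryocyte/platelet to
#'   thrombocyte transcriptome size ratios).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L,
                             n_genes = 10000L,
                             transcripts_per_gene = c(1L, 3L),
                             zero_fraction = c(GFP = 0.4009, RFP = 0.4912),
                             sub1_fraction = c(GFP = 0.2019, RFP = 0.3455),
                             lognormal_meanlog = c(GFP = 1.868, RFP = 0.921),
                             lognormal_sdlog = c(GFP = 1.942, RFP = 2.144),
                             ortholog_coverage = 0.72,
                             paralog_fraction = 0.10,
                             mk_overlap = 0.46,
                             pl_overlap = 0.17,
                             three_way_overlap = 0.146,
                             mk_size_factor = 0.843,
                             pl_size_factor = 0.308) {
  probs <- c(zero_fraction, sub1_fraction, ortholog_coverage,
             paralog_fraction, mk_overlap, pl_overlap, three_way_overlap)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(n_genes > 0L, length(transcripts_per_gene) == 2L,
            transcripts_per_gene[1L] >= 1L,
            transcripts_per_gene[2L] >= transcripts_per_gene[1L])
  for (pop in c("GFP", "RFP")) {
    if (zero_fraction[[pop]] + sub1_fraction[[pop]] > 1) {
      stop("zero_fraction + sub1_fraction exceeds 1 for population ", pop,
           call. = FALSE)
    }
  }
  if (three_way_overlap > min(mk_overlap, pl_overlap)) {
    stop("three-way overlap fraction cannot exceed either pairwise ",
         "overlap fraction", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    transcripts_per_gene = as.integer(transcripts_per_gene),
    zero_fraction = zero_fraction, sub1_fraction = sub1_fraction,
    lognormal_meanlog = lognormal_meanlog,
    lognormal_sdlog = lognormal_sdlog,
    ortholog_coverage = ortholog_coverage,
    paralog_fraction = paralog_fraction,
    mk_overlap = mk_overlap, pl_overlap = pl_overlap,
    three_way_overlap = three_way_overlap,
    mk_size_factor = mk_size_factor, pl_size_factor = pl_size_factor
  ), class = "synthetic_config")
}

# fixed offsets keep the per-generator streams independent of call order
pop_seed <- function(cfg, population) {
  cfg$seed + c(GFP = 101L, RFP = 202L)[[population]]
}

#' Generate one population's expression data
#'
#' Draws gene-level TPM from the configured zero-inflated mixture, splits
#' each gene's abundance over 1-3 transcripts, and emits a Salmon-style
#' transcript quantification table whose read counts invert to the gene
#' TPM under the TPM formula (counts are proportional to TPM times
#' effective length, so recomputing TPM from counts reproduces the
#' generated values up to the global per-million normalisation; the
#' quantification table's own TPM column carries the normalised values).
#'
#' @param cfg A [synthetic_config()].
#' @param population `"GFP"` (mature) or `"RFP"` (young).
#' @return List with `genes` (`data.frame`: `gene_id`, `tpm`, `category`
#'   — the true mixture component, one of `ZERO`, `SUB1`, `EXPR`),
#'   `quant` (quantification `data.frame` in [read_quant_table()] layout),
#'   and `tx2gene` (`data.frame`). Deterministic given `cfg$seed`.
#' @export
gen_population_expression <- function(cfg, population = c("GFP", "RFP")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  population <- match.arg(population)
  set.seed(pop_seed(cfg, population))
  n <- cfg$n_genes
  gene_id <- sprintf("zg%06d", seq_len(n))

  z <- cfg$zero_fraction[[population]]
  s <- cfg$sub1_fraction[[population]]
  u <- stats::runif(n)
  category <- ifelse(u < z, "ZERO", ifelse(u < z + s, "SUB1", "EXPR"))
  tpm <- numeric(n)
  n_sub1 <- sum(category == "SUB1")
  n_expr <- sum(category == "EXPR")
  tpm[category == "SUB1"] <- stats::runif(n_sub1, min = 1e-6, max = 1)
  tpm[category == "EXPR"] <- 1 + stats::rlnorm(
    n_expr,
    meanlog = cfg$lognormal_meanlog[[population]],
    sdlog = cfg$lognormal_sdlog[[population]]
  )
  genes <- data.frame(gene_id = gene_id, tpm = tpm, category = category,
                      stringsAsFactors = FALSE)

  # transcript structure: split gene abundance over 1-3 isoforms
  n_tx <- sample(seq(cfg$transcripts_per_gene[1L],
                     cfg$transcripts_per_gene[2L]), n, replace = TRUE)
  tx_gene_idx <- rep.int(seq_len(n), n_tx)
  tx_rank <- sequence(n_tx)
  transcript_id <- sprintf("%s.t%d", gene_id[tx_gene_idx], tx_rank)
  w <- stats::runif(length(tx_gene_idx), min = 0.1, max = 1)
  w <- w / rep.int(vapply(split(w, tx_gene_idx), sum, numeric(1L)), n_tx)
  tx_tpm_raw <- tpm[tx_gene_idx] * w

  length_nt <- sample(400:10000, length(transcript_id), replace = TRUE)
  eff_len <- length_nt - 150
  # normalise so the table is a valid TPM vector (sums to 1e6)
  tx_tpm <- if (sum(tx_tpm_raw) > 0) 1e6 * tx_tpm_raw / sum(tx_tpm_raw)
            else tx_tpm_raw
  depth <- 2e6
  reads_unscaled <- tx_tpm * eff_len
  num_reads <- if (sum(reads_unscaled) > 0)
    depth * reads_unscaled / sum(reads_unscaled) else reads_unscaled

  quant <- data.frame(transcript_id = transcript_id,
                      length = as.integer(length_nt),
                      effective_length = as.numeric(eff_len),
                      tpm = tx_tpm, num_reads = num_reads,
                      stringsAsFactors = FALSE)
  tx2gene <- data.frame(transcript_id = transcript_id,
                        gene_id = gene_id[tx_gene_idx],
                        stringsAsFactors = FALSE)
  list(genes = genes, quant = quant, tx2gene = tx2gene)
}

#' Generate a synthetic ortholog map with paralog structure
#'
#' A configurable fraction of source genes receives a human ortholog;
#' human targets are shared by groups of 2-3 source paralogs with
#' probability `paralog_fraction`, so projecting the mapped sources yields
#' duplicate hits that collapse at the human level.
#'
#' @param cfg A [synthetic_config()].
#' @param source_genes Character vector of source-species gene
#'   identifiers (non-empty).
#' @return `data.frame` with columns `source_gene`, `human_gene` and
#'   attributes `n_mapped`, `n_human`, `redundant_count` (generator-side
#'   bookkeeping: `n_mapped - n_human`).
#' @export
gen_ortholog_map <- function(cfg, source_genes) {
  stopifnot(inherits(cfg, "synthetic_config"), length(source_genes) > 0L)
  set.seed(cfg$seed + 303L)
  mapped <- source_genes[stats::runif(length(source_genes)) <
                           cfg$ortholog_coverage]
  n_mapped <- length(mapped)
  if (n_mapped == 0L) {
    out <- data.frame(source_gene = character(0L),
                      human_gene = character(0L),
                      stringsAsFactors = FALSE)
    attr(out, "n_mapped") <- 0L
    attr(out, "n_human") <- 0L
    attr(out, "redundant_count") <- 0L
    return(out)
  }
  # draw paralog-group sizes until every mapped source is consumed
  sizes <- integer(0L)
  total <- 0L
  while (total < n_mapped) {
    share <- stats::runif(1L) < cfg$paralog_fraction
    sz <- if (share) sample(2:3, 1L) else 1L
    sz <- min(sz, n_mapped - total)
    sizes <- c(sizes, sz)
    total <- total + sz
  }
  human <- sprintf("HG%06d", seq_along(sizes))
  out <- data.frame(source_gene = mapped,
                    human_gene = rep.int(human, sizes),
                    stringsAsFactors = FALSE)
  attr(out, "n_mapped") <- n_mapped
  attr(out, "n_human") <- length(sizes)
  attr(out, "redundant_count") <- n_mapped - length(sizes)
  out
}

#' Generate external megakaryocyte and platelet gene lists
#'
#' Constructs two gene lists whose overlaps with the thrombocyte set (and
#' with each other, within the thrombocyte set) hit the configured
#' fractions exactly up to integer rounding, padded with non-thrombocyte
#' identifiers (`EXT...`) to the configured sizes. The pads of the two
#' lists are disjoint, so the three-way overlap equals the
#' megakaryocyte-platelet overlap within the thrombocyte set.
#'
#' @param cfg A [synthetic_config()].
#' @param thrombo_genes Character vector of thrombocyte gene identifiers
#'   (non-empty, deduplicated internally).
#' @return List with `megakaryocyte` and `platelet` character vectors.
#' @export
gen_external_sets <- function(cfg, thrombo_genes) {
  stopifnot(inherits(cfg, "synthetic_config"), length(thrombo_genes) > 0L)
  set.seed(cfg$seed + 404L)
  t_genes <- unique(as.character(thrombo_genes))
  n_t <- length(t_genes)
  n_tm <- round(cfg$mk_overlap * n_t)
  n_tp <- round(cfg$pl_overlap * n_t)
  n_tmp <- round(cfg$three_way_overlap * n_t)
  if (n_tmp > min(n_tm, n_tp)) {
    stop("infeasible overlap configuration: three-way overlap exceeds a ",
         "pairwise overlap", call. = FALSE)
  }
  if (n_tm + n_tp - n_tmp > n_t) {
    stop("infeasible overlap configuration: requested overlaps exceed the ",
         "thrombocyte set size", call. = FALSE)
  }
  perm <- sample(t_genes)
  in_both <- perm[seq_len(n_tmp)]
  mk_only <- perm[seq_len(n_tm)][-seq_len(n_tmp)]
  rest <- perm[-seq_len(n_tm)]
  pl_only <- rest[seq_len(n_tp - n_tmp)]

  mk_size <- max(round(cfg$mk_size_factor * n_t), n_tm)
  pl_size <- max(round(cfg$pl_size_factor * n_t), n_tp)
  mk_pad <- sprintf("EXTM%06d", seq_len(mk_size - n_tm))
  pl_pad <- sprintf("EXTP%06d", seq_len(pl_size - n_tp))
  list(megakaryocyte = c(in_both, mk_only, mk_pad),
       platelet = c(in_both, pl_only, pl_pad))
}

#' Write a full synthetic input bundle to disk
#'
#' Materialises both populations' quantification tables and tx2gene maps,
#' the ortholog map, and the external gene lists in the package's tabular
#' formats, ready for [run_pipeline()].
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if missing).
#' @return Named list of the written file paths, invisibly.
#' @export
write_synthetic_bundle <- function(cfg, dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gfp <- gen_population_expression(cfg, "GFP")
  rfp <- gen_population_expression(cfg, "RFP")
  tx2gene <- rbind(gfp$tx2gene, rfp$tx2gene)
  tx2gene <- tx2gene[!duplicated(tx2gene$transcript_id), , drop = FALSE]
  # expressed status on the per-million-normalised scale, as the pipeline
  # recomputes it from the quantification tables
  cfg_strict <- threshold_config()
  norm_tpm <- function(pop) pop$genes$tpm * 1e6 / sum(pop$genes$tpm)
  all_expressed <- union(
    gfp$genes$gene_id[norm_tpm(gfp) > cfg_strict$expressed_tpm_min],
    rfp$genes$gene_id[norm_tpm(rfp) > cfg_strict$expressed_tpm_min])
  omap <- gen_ortholog_map(cfg, union(gfp$genes$gene_id,
                                      rfp$genes$gene_id))
  ext <- gen_external_sets(cfg, all_expressed)
  paths <- list(
    quant_gfp = file.path(dir, "quant_gfp.sf"),
    quant_rfp = file.path(dir, "quant_rfp.sf"),
    tx2gene = file.path(dir, "tx2gene.tsv"),
    ortholog_map = file.path(dir, "ortholog_map.tsv"),
    megakaryocyte = file.path(dir, "megakaryocyte_genes.txt"),
    platelet = file.path(dir, "platelet_genes.txt")
  )
  write_quant_table(gfp$quant, paths$quant_gfp)
  write_quant_table(rfp$quant, paths$quant_rfp)
  write_mapping_table(tx2gene, paths$tx2gene)
  write_mapping_table(omap, paths$ortholog_map)
  write_gene_list(ext$megakaryocyte, paths$megakaryocyte)
  write_gene_list(ext$platelet, paths$platelet)
  invisible(paths)
}
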