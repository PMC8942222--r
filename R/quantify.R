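#' Recompute transcript TPM from read counts
#'
#' Transcripts per million for transcript i is the length-normalised read
#' rate rescaled to sum to one million over the sample:
#' \deqn{TPM_i = 10^6 \frac{c_i / \ell_i}{\sum_j c_j / \ell_j}}
#' where \eqn{c_i} is `num_reads` and \eqn{\ell_i} the effective length.
#'
#' @param quant Quantification `data.frame` (see [read_quant_table()]);
#'   the existing `tpm` column, if any, is overwritten.
#' @return The table with `tpm` recomputed; `sum(tpm)` equals 1e6 to within
#'   1e-6 relative tolerance.
#' @export
compute_transcript_tpm <- function(quant) {
  stopifnot(all(c("num_reads", "effective_length") %in% names(quant)))
  if (nrow(quant) == 0L || all(quant$num_reads == 0)) {
    stop("degenerate input: no transcript has a positive read count",
         call. = FALSE)
  }
  if (any(quant$effective_length <= 0)) {
    stop("effective lengths must be strictly positive", call. = FALSE)
  }
  rate <- quant$num_reads / quant$effective_length
  quant$tpm <- 1e6 * rate / sum(rate)
  quant
}

#' Aggregate transcript TPM to gene level
#'
#' Gene abundance is the sum of the member transcripts' TPM (the simple
#' abundance semantics of tximport-style aggregation). Total TPM is
#' conserved over mapped transcripts.
#'
#' @param quant Quantification table with a `tpm` column.
#' @param tx2gene Transcript-to-gene map (see [read_tx2gene()]).
#' @param unmapped Policy for transcripts absent from the map:
#'   `"lenient"` (default) promotes each to its own gene, flagged in the
#'   `unmapped` column; `"strict"` raises an error listing the offenders.
#' @return `data.frame` with columns `gene_id`, `tpm`, `unmapped`
#'   (logical), one row per gene, in first-occurrence order of the genes.
#' @export
aggregate_gene_tpm <- function(quant, tx2gene,
                               unmapped = c("lenient", "strict")) {
  unmapped <- match.arg(unmapped)
  stopifnot(all(c("transcript_id", "tpm") %in% names(quant)))
  idx <- match(quant$transcript_id, tx2gene$transcript_id)
  miss <- is.na(idx)
  if (any(miss) && unmapped == "strict") {
    stop("unmapped transcript(s) under strict policy: ",
         paste(utils::head(quant$transcript_id[miss], 10L), collapse = ", "),
         if (sum(miss) > 10L) ", ..." else "",
         call. = FALSE)
  }
  gene <- ifelse(miss, quant$transcript_id, tx2gene$gene_id[idx])
  gene_order <- unique(gene)
  tpm <- vapply(split(quant$tpm, factor(gene, levels = gene_order)), sum,
                numeric(1L))
  flag <- vapply(split(miss, factor(gene, levels = gene_order)), any,
                 logical(1L))
  data.frame(gene_id = gene_order, tpm = as.numeric(tpm),
             unmapped = as.logical(flag), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' TPM interval labels
#'
#' The five-interval partition of the TPM axis used throughout the package:
#' `ZERO` = \{0\}, `SUB1` = (0, 1), `LOW_1_5` = \[1, 5), `MID_5_30` =
#' \[5, 30), `HIGH_30_PLUS` = \[30, Inf). Left-closed upper bins match the
#' "30 and higher" reading; a gene at exactly 1 TPM falls in `LOW_1_5` but
#' is still not "expressed" under the strict TPM > 1 rule.
#'
#' @param tpm Numeric vector of non-negative TPM values.
#' @return Factor with levels `ZERO`, `SUB1`, `LOW_1_5`, `MID_5_30`,
#'   `HIGH_30_PLUS`.
#' @export
tpm_interval <- function(tpm) {
  stopifnot(is.numeric(tpm))
  if (any(tpm < 0, na.rm = TRUE)) {
    stop("TPM values must be non-negative", call. = FALSE)
  }
  lv <- tpm_interval_levels()
  out <- character(length(tpm))
  out[tpm == 0] <- "ZERO"
  out[tpm > 0 & tpm < 1] <- "SUB1"
  out[tpm >= 1 & tpm < 5] <- "LOW_1_5"
  out[tpm >= 5 & tpm < 30] <- "MID_5_30"
  out[tpm >= 30] <- "HIGH_30_PLUS"
  factor(out, levels = lv)
}

tpm_interval_levels <- function() {
  c("ZERO", "SUB1", "LOW_1_5", "MID_5_30", "HIGH_30_PLUS")
}

#' Bin genes into the five TPM intervals
#'
#' Every gene falls in exactly one interval; counts sum to the table size
#' and percentages to 100 (up to rounding of the individual entries).
#'
#' @param table Gene expression `data.frame` with a `tpm` column.
#' @return `data.frame` with columns `interval`, `count`, `percent`. For an
#'   empty input all counts are 0, percentages are reported as 0, and the
#'   attribute `empty` is set to `TRUE`.
#' @export
bin_tpm_intervals <- function(table) {
  stopifnot("tpm" %in% names(table))
  iv <- tpm_interval(table$tpm)
  counts <- as.integer(table(iv))
  n <- nrow(table)
  out <- data.frame(interval = tpm_interval_levels(),
                    count = counts,
                    percent = if (n > 0L) 100 * counts / n else rep(0, 5L),
                    stringsAsFactors = FALSE)
  attr(out, "empty") <- n == 0L
  out
}
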