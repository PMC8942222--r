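#' Classification thresholds
#'
#' Both thresholds are strict: a gene is expressed when its TPM is strictly
#' greater than `expressed_tpm_min`, and highly expressed when additionally
#' its z-score of log TPM (computed over expressed genes only) is strictly
#' greater than `highly_expressed_z_min`.
#'
#' @param expressed_tpm_min TPM threshold for "expressed" (default 1).
#' @param highly_expressed_z_min z threshold for "highly expressed"
#'   (default 1.5).
#' @return A `threshold_config` list.
#' @export
threshold_config <- function(expressed_tpm_min = 1,
                             highly_expressed_z_min = 1.5) {
  stopifnot(is.numeric(expressed_tpm_min), length(expressed_tpm_min) == 1L,
            is.finite(expressed_tpm_min), expressed_tpm_min >= 0,
            is.numeric(highly_expressed_z_min),
            length(highly_expressed_z_min) == 1L,
            is.finite(highly_expressed_z_min))
  structure(list(expressed_tpm_min = expressed_tpm_min,
                 highly_expressed_z_min = highly_expressed_z_min),
            class = "threshold_config")
}

#' Flag expressed genes
#'
#' @param table Gene expression `data.frame` with a `tpm` column.
#' @param cfg A [threshold_config()].
#' @return The table with a logical `expressed` column:
#'   `tpm > expressed_tpm_min`, strictly. A gene at exactly the threshold
#'   is not expressed.
#' @export
classify_expressed <- function(table, cfg = threshold_config()) {
  stopifnot("tpm" %in% names(table), inherits(cfg, "threshold_config"))
  table$expressed <- table$tpm > cfg$expressed_tpm_min
  table
}

#' z-score of log TPM over expressed genes
#'
#' For expressed genes only, `log_tpm` is the natural log of TPM and `z`
#' its standardisation, \eqn{z = (\log TPM - \bar{m}) / s}, with mean and
#' sample (n-1) standard deviation taken over the expressed genes. Genes
#' not expressed get `NA` in both columns and take no part in the
#' normalisation. The classification downstream is invariant to the log
#' base, since changing base rescales numerator and denominator alike.
#'
#' @param table Gene expression `data.frame` with `tpm` and `expressed`
#'   columns (see [classify_expressed()]).
#' @return The table with `log_tpm` and `z` columns added.
#' @export
zscore_log_tpm <- function(table) {
  stopifnot(all(c("tpm", "expressed") %in% names(table)))
  ex <- table$expressed
  if (sum(ex) < 2L) {
    stop("degenerate input: need at least 2 expressed genes to standardise",
         call. = FALSE)
  }
  lt <- log(table$tpm[ex])
  s <- stats::sd(lt)
  if (s == 0) {
    stop("degenerate input: expressed genes have zero log-TPM variance",
         call. = FALSE)
  }
  table$log_tpm <- NA_real_
  table$z <- NA_real_
  table$log_tpm[ex] <- lt
  table$z[ex] <- (lt - mean(lt)) / s
  table
}

#' Flag highly expressed genes
#'
#' @param table Gene expression `data.frame` with `expressed` and `z`
#'   columns (see [zscore_log_tpm()]).
#' @param cfg A [threshold_config()].
#' @return The table with a logical `highly_expressed` column:
#'   expressed and `z > highly_expressed_z_min`, strictly (`z` exactly at
#'   the threshold does not qualify).
#' @export
classify_highly_expressed <- function(table, cfg = threshold_config()) {
  stopifnot(all(c("expressed", "z") %in% names(table)),
            inherits(cfg, "threshold_config"))
  table$highly_expressed <- table$expressed &
    !is.na(table$z) & table$z > cfg$highly_expressed_z_min
  table
}

#' Extract gene id lists by class
#'
#' @param table A classified gene expression table.
#' @return Character vector of gene identifiers, in table order.
#' @export
expressed_genes <- function(table) {
  stopifnot(all(c("gene_id", "expressed") %in% names(table)))
  table$gene_id[table$expressed]
}

#' @rdname expressed_genes
#' @export
highly_expressed_genes <- function(table) {
  stopifnot(all(c("gene_id", "highly_expressed") %in% names(table)))
  table$gene_id[table$highly_expressed]
}

#' Full per-population classification
#'
#' Convenience composition: expressed flags, log-TPM z-scores, highly
#' expressed flags, and interval labels in one call.
#'
#' @param table Gene expression `data.frame` with `gene_id` and `tpm`.
#' @param cfg A [threshold_config()].
#' @return The table with `expressed`, `log_tpm`, `z`, `highly_expressed`,
#'   and `interval` columns.
#' @export
classify_population <- function(table, cfg = threshold_config()) {
  table <- classify_expressed(table, cfg)
  table <- zscore_log_tpm(table)
  table <- classify_highly_expressed(table, cfg)
  table$interval <- tpm_interval(table$tpm)
  table
}
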