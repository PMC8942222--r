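#' Partition expressed genes into expression deciles
#'
#' Genes are sorted by decreasing TPM (quantile 1 holds the most highly
#' expressed ~10%), ties broken by ascending gene identifier so the
#' assignment is deterministic and independent of input order. Quantile i
#' spans ranks `(ceiling((i-1) * n / 10), ceiling(i * n / 10)]`, which
#' makes sizes as even as possible (differing by at most 1).
#'
#' @param expressed Gene expression `data.frame` with `gene_id` and `tpm`
#'   columns, containing only the expressed genes (at least 10 of them).
#' @return Object of class `quantile_assignment`: list with `assignment`
#'   (`data.frame` of `gene_id`, `quantile`, `tpm`, in rank order) and
#'   `mean_tpm` (numeric length 10, per-quantile mean TPM).
#' @export
partition_quantiles <- function(expressed) {
  stopifnot(all(c("gene_id", "tpm") %in% names(expressed)))
  n <- nrow(expressed)
  if (n < 10L) {
    stop("need at least 10 expressed genes for 10 quantiles; fewer bins ",
         "are not supported", call. = FALSE)
  }
  if (anyDuplicated(expressed$gene_id)) {
    stop("gene identifiers must be unique", call. = FALSE)
  }
  ord <- order(-expressed$tpm, expressed$gene_id, method = "radix")
  gene_id <- expressed$gene_id[ord]
  tpm <- expressed$tpm[ord]
  upper <- ceiling(seq_len(10L) * n / 10)
  sizes <- diff(c(0L, upper))
  q <- rep.int(seq_len(10L), sizes)
  assignment <- data.frame(gene_id = gene_id, quantile = q, tpm = tpm,
                           stringsAsFactors = FALSE)
  mean_tpm <- vapply(split(tpm, q), mean, numeric(1L))
  structure(list(assignment = assignment,
                 mean_tpm = as.numeric(mean_tpm)),
            class = "quantile_assignment")
}

#' Cross-population decile overlap matrix
#'
#' Cell (i, j) counts the genes in quantile i of population A that fall in
#' quantile j of population B. The grand total equals the number of genes
#' expressed in both populations; row i sums to the number of A's
#' quantile-i genes that are also expressed in B.
#'
#' @param a,b `quantile_assignment` objects (see [partition_quantiles()]).
#' @param labels Character vector of length 2 used for the dimnames, e.g.
#'   `c("GFP", "RFP")` produces labels `GFP_1..GFP_10` (rows, population
#'   A) and `RFP_1..RFP_10` (columns, population B).
#' @return Integer 10 x 10 matrix with attributes `mean_tpm_a` and
#'   `mean_tpm_b` (the per-quantile mean TPM of each population).
#' @export
overlap_matrix <- function(a, b, labels = c("GFP", "RFP")) {
  stopifnot(inherits(a, "quantile_assignment"),
            inherits(b, "quantile_assignment"),
            length(labels) == 2L, labels[1L] != labels[2L])
  qa <- a$assignment
  qb <- b$assignment
  j <- match(qa$gene_id, qb$gene_id)
  keep <- !is.na(j)
  m <- matrix(0L, nrow = 10L, ncol = 10L,
              dimnames = list(paste(labels[1L], 1:10, sep = "_"),
                              paste(labels[2L], 1:10, sep = "_")))
  if (any(keep)) {
    tab <- table(factor(qa$quantile[keep], levels = 1:10),
                 factor(qb$quantile[j[keep]], levels = 1:10))
    m[] <- as.integer(tab)
  }
  attr(m, "mean_tpm_a") <- a$mean_tpm
  attr(m, "mean_tpm_b") <- b$mean_tpm
  m
}

#' Write a decile overlap matrix as labelled CSV
#'
#' @param m Matrix from [overlap_matrix()].
#' @param path Output path; row and column labels are preserved.
#' @return `path`, invisibly.
#' @export
write_overlap_matrix <- function(m, path) {
  utils::write.csv(as.data.frame(unclass(m)[1:10, 1:10, drop = FALSE]),
                   path, row.names = TRUE, quote = FALSE)
  invisible(path)
}
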