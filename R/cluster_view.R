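#' Cluster cells by k-means over a range of k
#'
#' Runs k-means (multiple restarts, fixed seed) for each candidate k and
#' picks the k maximising the mean silhouette width, unless `fixed_k` pins
#' the choice. Cluster number selection by eye against a t-SNE embedding
#' is replaced here by the silhouette criterion so the choice is
#' reproducible; `fixed_k` reproduces an externally chosen clustering
#' (e.g. 4 clusters).
#'
#' @param matrix Numeric cells x genes count matrix.
#' @param k_range Integer vector of candidate cluster numbers
#'   (default `2:10`).
#' @param seed Integer seed; the model is reproducible given the seed.
#' @param fixed_k Optional single integer overriding model selection
#'   (must lie in `k_range`).
#' @param nstart Restarts per k (default 10).
#' @return Object of class `cluster_model`: list with `chosen_k`,
#'   `cluster` (named integer vector, cell to cluster), `centers`,
#'   `silhouette` (named numeric, mean silhouette width per candidate k),
#'   `k_range`, `seed`.
#' @export
cluster_cells <- function(matrix, k_range = 2:10, seed = 1L,
                          fixed_k = NULL, nstart = 10L) {
  matrix <- as.matrix(matrix)
  stopifnot(is.numeric(matrix), length(k_range) >= 1L, all(k_range >= 2L))
  if (nrow(matrix) < max(k_range)) {
    stop("fewer cells (", nrow(matrix), ") than the largest candidate k (",
         max(k_range), ")", call. = FALSE)
  }
  if (all(apply(matrix, 2L, stats::var) == 0)) {
    stop("degenerate input: all cells are identical (zero variance)",
         call. = FALSE)
  }
  if (!is.null(fixed_k)) {
    stopifnot(length(fixed_k) == 1L, fixed_k %in% k_range)
  }
  d <- stats::dist(matrix)
  sil <- stats::setNames(rep(NA_real_, length(k_range)),
                         as.character(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed + k)   # per-k stream: adding a k does not shift the others
    fits[[i]] <- stats::kmeans(matrix, centers = k, nstart = nstart,
                               iter.max = 100L)
    sw <- cluster::silhouette(fits[[i]]$cluster, d)
    sil[i] <- mean(sw[, "sil_width"])
  }
  chosen_k <- if (is.null(fixed_k)) k_range[which.max(sil)] else fixed_k
  fit <- fits[[match(chosen_k, k_range)]]
  cl <- fit$cluster
  if (!is.null(rownames(matrix))) names(cl) <- rownames(matrix)
  structure(list(chosen_k = as.integer(chosen_k),
                 cluster = cl,
                 centers = fit$centers,
                 silhouette = sil,
                 k_range = as.integer(k_range),
                 seed = as.integer(seed)),
            class = "cluster_model")
}

#' Per-cluster mean counts
#'
#' Entry (c, g) is the arithmetic mean count of gene g over the cells
#' assigned to cluster c — the matrix displayed in a cluster heat map.
#'
#' @param model A `cluster_model` fitted on `matrix`.
#' @param matrix The cells x genes matrix the model was fitted on.
#' @return Numeric clusters x genes matrix; an empty cluster yields a row
#'   of `NaN` and is recorded in the `empty_clusters` attribute.
#' @export
cluster_mean_counts <- function(model, matrix) {
  stopifnot(inherits(model, "cluster_model"))
  matrix <- as.matrix(matrix)
  if (nrow(matrix) != length(model$cluster)) {
    stop("matrix has ", nrow(matrix), " cells but the model assigns ",
         length(model$cluster), call. = FALSE)
  }
  ks <- seq_len(model$chosen_k)
  out <- matrix(NaN, nrow = length(ks), ncol = ncol(matrix),
                dimnames = list(paste0("cluster_", ks), colnames(matrix)))
  sizes <- tabulate(model$cluster, nbins = model$chosen_k)
  for (k in ks) {
    if (sizes[k] > 0L) {
      out[k, ] <- colMeans(matrix[model$cluster == k, , drop = FALSE])
    }
  }
  attr(out, "empty_clusters") <- which(sizes == 0L)
  out
}

#' Row-wise standardisation for heat-map display
#'
#' Each row is centred and divided by its sample (n-1) standard deviation,
#' which places typical values roughly in \[-2, 2\]; that range is a
#' consequence of standardisation, not a clamp — no truncation is applied.
#' Constant rows (zero variance) are mapped to all zeros and listed in the
#' `constant_rows` attribute.
#'
#' @param matrix Numeric matrix; rows are scaled independently.
#' @return Matrix of the same shape with attribute `constant_rows`
#'   (integer indices of flagged rows).
#' @export
row_scale <- function(matrix) {
  matrix <- as.matrix(matrix)
  ctr <- matrix - rowMeans(matrix)
  s <- apply(matrix, 1L, stats::sd)
  const <- which(s == 0)
  s[s == 0] <- 1   # constant rows: centred values are already all zero
  out <- ctr / s
  attr(out, "constant_rows") <- const
  out
}
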