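#' Deduplicate a gene list, counting duplicates
#'
#' Reproduces the spreadsheet "remove duplicates" step as an explicit,
#' audited operation: the result keeps the first occurrence of each
#' identifier in input order, and the number of removed entries is
#' reported. Matching is case-sensitive exact match (zebrafish symbols are
#' lower-case, human symbols upper-case; the distinction is meaningful).
#'
#' @param list Character vector of gene identifiers, duplicates permitted.
#' @return List with `genes` (unique identifiers, first-occurrence order)
#'   and `duplicate_count` (`length(list) - length(genes)`).
#' @export
dedupe <- function(list) {
  list <- as.character(list)
  genes <- unique(list)
  list(genes = genes, duplicate_count = length(list) - length(genes))
}

#' Two-way gene-list comparison
#'
#' Inputs are deduplicated internally. All four membership sets are
#' returned alongside their cardinalities; the inclusion-exclusion
#' identity `|union| = |A| + |B| - |common|` holds by construction.
#'
#' @param a,b Character vectors of gene identifiers.
#' @return Object of class `set_comparison`: a list with `union_genes`,
#'   `common_genes`, `unique_a`, `unique_b` (all in first-occurrence
#'   order) and the counts `n_a`, `n_b`, `n_union`, `n_common`,
#'   `n_unique_a`, `n_unique_b`.
#' @export
compare_two <- function(a, b) {
  a <- dedupe(a)$genes
  b <- dedupe(b)$genes
  common <- a[a %in% b]
  structure(list(
    union_genes = union(a, b),
    common_genes = common,
    unique_a = setdiff(a, b),
    unique_b = setdiff(b, a),
    n_a = length(a), n_b = length(b),
    n_union = length(union(a, b)), n_common = length(common),
    n_unique_a = length(setdiff(a, b)),
    n_unique_b = length(setdiff(b, a))
  ), class = "set_comparison")
}

#' @export
print.set_comparison <- function(x, ...) {
  cat("Two-way gene set comparison\n")
  cat(sprintf("  A: %d  B: %d  union: %d  common: %d  A-only: %d  B-only: %d\n",
              x$n_a, x$n_b, x$n_union, x$n_common, x$n_unique_a,
              x$n_unique_b))
  invisible(x)
}

#' Project a gene set onto human orthologs, collapsing paralogs
#'
#' Every (source, human) pairing of a query gene contributes its human
#' side to the raw hit multiset — a source gene with several human
#' orthologs contributes all of them, and zebrafish paralog pairs mapping
#' to one human gene produce duplicate (or triplicate) hits. Collapsing
#' happens only at the human-identifier level: `distinct_orthologs` is the
#' deduplicated multiset and `redundant_count` the number of entries
#' removed.
#'
#' @param genes Character vector of source-species gene identifiers
#'   (deduplicated internally).
#' @param map Ortholog map `data.frame` with `source_gene` and
#'   `human_gene` columns (see [read_ortholog_map()]).
#' @return Object of class `ortholog_projection`: list with `raw_hits`
#'   (character, with duplicates, in map-driven order), `redundant_count`,
#'   `distinct_orthologs`, `unmapped_sources`, and the counts `n_raw`,
#'   `n_distinct`, `n_unmapped`.
#' @export
map_to_orthologs <- function(genes, map) {
  stopifnot(all(c("source_gene", "human_gene") %in% names(map)))
  genes <- dedupe(genes)$genes
  hit_rows <- map[map$source_gene %in% genes, , drop = FALSE]
  raw_hits <- hit_rows$human_gene
  distinct <- unique(raw_hits)
  unmapped <- setdiff(genes, map$source_gene)
  structure(list(
    raw_hits = raw_hits,
    redundant_count = length(raw_hits) - length(distinct),
    distinct_orthologs = distinct,
    unmapped_sources = unmapped,
    n_raw = length(raw_hits),
    n_distinct = length(distinct),
    n_unmapped = length(unmapped)
  ), class = "ortholog_projection")
}

#' @export
print.ortholog_projection <- function(x, ...) {
  cat("Ortholog projection\n")
  cat(sprintf("  raw hits: %d  redundant: %d  distinct: %d  unmapped sources: %d\n",
              x$n_raw, x$redundant_count, x$n_distinct, x$n_unmapped))
  invisible(x)
}

#' Integer percentage, truncated toward zero
#'
#' `100 * part / whole` truncated to an integer. Truncation (not rounding)
#' is the convention for every printed percentage in the package's
#' reports: e.g. 1603 of 9143 is 17.53..., reported as 17.
#'
#' @param part Non-negative integer, at most `whole`.
#' @param whole Positive integer.
#' @return Integer percent in `[0, 100]`.
#' @export
percent_of <- function(part, whole) {
  stopifnot(length(part) == length(whole) || length(whole) == 1L)
  if (any(whole == 0)) {
    stop("whole must be positive", call. = FALSE)
  }
  if (any(part < 0 | part > whole)) {
    stop("part must satisfy 0 <= part <= whole", call. = FALSE)
  }
  as.integer(trunc(100 * part / whole))
}

#' Three-way gene-set comparison
#'
#' Typically thrombocyte (t) vs megakaryocyte (m) vs platelet (p) sets.
#' All pairwise overlaps and the three-way overlap are returned; the
#' three-way overlap is a subset of every pairwise one by construction.
#' Designated subsets (e.g. genes unique to the mature population) are
#' additionally intersected with each external set.
#'
#' @param t,m,p Character vectors of gene identifiers (deduplicated
#'   internally).
#' @param designated_subsets Optional named list of character vectors;
#'   each is intersected with `m` and `p`.
#' @return Object of class `tri_set_comparison`: list with membership
#'   vectors `tm`, `tp`, `mp`, `tmp`, counts `n_t`, `n_m`, `n_p`, `n_tm`,
#'   `n_tp`, `n_mp`, `n_tmp`, and `subsets` — per designated subset, the
#'   overlap memberships and counts with `m` and `p`.
#' @export
compare_three <- function(t, m, p, designated_subsets = NULL) {
  t <- dedupe(t)$genes
  m <- dedupe(m)$genes
  p <- dedupe(p)$genes
  tm <- t[t %in% m]
  tp <- t[t %in% p]
  mp <- m[m %in% p]
  tmp <- tm[tm %in% p]
  subsets <- list()
  if (!is.null(designated_subsets)) {
    stopifnot(is.list(designated_subsets),
              !is.null(names(designated_subsets)))
    for (nm in names(designated_subsets)) {
      s <- dedupe(designated_subsets[[nm]])$genes
      subsets[[nm]] <- list(
        with_m = s[s %in% m], with_p = s[s %in% p],
        n_with_m = sum(s %in% m), n_with_p = sum(s %in% p)
      )
    }
  }
  structure(list(
    tm = tm, tp = tp, mp = mp, tmp = tmp,
    n_t = length(t), n_m = length(m), n_p = length(p),
    n_tm = length(tm), n_tp = length(tp), n_mp = length(mp),
    n_tmp = length(tmp),
    subsets = subsets
  ), class = "tri_set_comparison")
}

#' @export
print.tri_set_comparison <- function(x, ...) {
  cat("Three-way gene set comparison\n")
  cat(sprintf("  |T|=%d |M|=%d |P|=%d  T&M=%d T&P=%d M&P=%d  T&M&P=%d\n",
              x$n_t, x$n_m, x$n_p, x$n_tm, x$n_tp, x$n_mp, x$n_tmp))
  for (nm in names(x$subsets)) {
    cat(sprintf("  subset %s: &M=%d &P=%d\n", nm,
                x$subsets[[nm]]$n_with_m, x$subsets[[nm]]$n_with_p))
  }
  invisible(x)
}
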