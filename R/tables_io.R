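#' Read a Salmon-style transcript quantification table
#'
#' Parses a tab-delimited quantification file in the five-column Salmon
#' `quant.sf` layout (`Name`, `Length`, `EffectiveLength`, `TPM`,
#' `NumReads`, header row required). Extra columns are ignored. Numbers are
#' parsed with a decimal point regardless of locale.
#'
#' @param path Path to a tab-delimited quantification file.
#' @return A `data.frame` with columns `transcript_id` (character),
#'   `length` (integer, nt), `effective_length` (double, nt), `tpm`
#'   (double), `num_reads` (double), one row per transcript.
#' @details Validation enforced on read: transcript identifiers unique,
#'   effective lengths strictly positive, no negative TPM or read counts.
#'   Violations raise an error naming the offending line (line numbers count
#'   the header as line 1).
#' @examples
#' tf <- tempfile(fileext = ".sf")
#' writeLines(c("Name\tLength\tEffectiveLength\tTPM\tNumReads",
#'              "tx1\t1000\t950\t500000\t10"), tf)
#' read_quant_table(tf)
#' @export
read_quant_table <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) {
    stop("quantification file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  required <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("quantification table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tab <- data.frame(
    transcript_id    = trimws(raw[["Name"]]),
    length           = as.integer(raw[["Length"]]),
    effective_length = as.numeric(raw[["EffectiveLength"]]),
    tpm              = as.numeric(raw[["TPM"]]),
    num_reads        = as.numeric(raw[["NumReads"]]),
    stringsAsFactors = FALSE
  )
  validate_quant_table(tab, line_offset = 1L)
  tab
}

validate_quant_table <- function(tab, line_offset = 0L) {
  line <- function(i) i + line_offset
  for (col in c("tpm", "num_reads")) {
    bad <- which(!is.na(tab[[col]]) & tab[[col]] < 0)
    if (length(bad) > 0L) {
      stop("negative ", col, " at line ", line(bad[1L]), call. = FALSE)
    }
  }
  bad_el <- which(!is.na(tab$effective_length) & tab$effective_length <= 0)
  if (length(bad_el) > 0L) {
    stop("non-positive effective length at line ", line(bad_el[1L]),
         call. = FALSE)
  }
  dup <- which(duplicated(tab$transcript_id))
  if (length(dup) > 0L) {
    stop("duplicate transcript identifier '", tab$transcript_id[dup[1L]],
         "' at line ", line(dup[1L]), call. = FALSE)
  }
  invisible(tab)
}

#' Write a transcript quantification table
#'
#' Inverse of [read_quant_table()]: writes the five-column Salmon-style
#' layout with a header row, tab-delimited.
#'
#' @param quant A quantification `data.frame` as returned by
#'   [read_quant_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(quant, path) {
  out <- data.frame(
    Name = quant$transcript_id,
    Length = quant$length,
    EffectiveLength = quant$effective_length,
    TPM = quant$tpm,
    NumReads = quant$num_reads
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a gene-identifier list
#'
#' Reads gene identifiers from newline-delimited text or a single-column
#' CSV. Order is preserved and duplicates are kept (deduplication is an
#' explicit, counted step; see [dedupe()]). Surrounding whitespace is
#' trimmed and blank lines dropped.
#'
#' Identifiers beginning with `"LOC"` denote genes without a curated
#' annotation; they are accepted, never dropped, and flagged via
#' [is_unannotated()].
#'
#' @param path Path to the list file.
#' @param header Logical; if `TRUE` the first non-blank line is treated as
#'   a column header and skipped.
#' @return Character vector of identifiers. Warns (does not error) if the
#'   result is empty.
#' @export
read_gene_list <- function(path, header = FALSE) {
  if (!file.exists(path)) {
    stop("gene list file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  # single-column CSV: strip one trailing comma-separated empty field if any,
  # otherwise take the first field
  vals <- vapply(lines, function(x) strsplit(x, ",", fixed = TRUE)[[1L]][1L],
                 character(1L), USE.NAMES = FALSE)
  vals <- trimws(vals)
  vals <- vals[!is.na(vals) & nzchar(vals)]
  if (header && length(vals) > 0L) {
    vals <- vals[-1L]
  }
  if (length(vals) == 0L) {
    warning("gene list is empty: ", path, call. = FALSE)
  }
  vals
}

#' Flag unannotated gene identifiers
#'
#' Gene identifiers beginning with `"LOC"` come from expression files with
#' no curated database entry. They are carried through all analyses.
#'
#' @param ids Character vector of gene identifiers.
#' @return Logical vector, `TRUE` where the identifier starts with `LOC`.
#' @export
is_unannotated <- function(ids) {
  startsWith(as.character(ids), "LOC")
}

#' Write a gene-identifier list
#'
#' @param genes Character vector of identifiers.
#' @param path Output path; one identifier per line.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read a transcript-to-gene mapping table
#'
#' Two-column tab-delimited file with a header row; first column transcript
#' identifiers, second column gene identifiers. Every transcript must map
#' to exactly one gene; a transcript appearing with two different genes is
#' a validation error. Exact duplicate rows are collapsed.
#'
#' @param path Path to the mapping file.
#' @return `data.frame` with columns `transcript_id`, `gene_id`.
#' @export
read_tx2gene <- function(path) {
  tab <- read_two_column_tsv(path, c("transcript_id", "gene_id"))
  tab <- unique(tab)
  dup <- which(duplicated(tab$transcript_id))
  if (length(dup) > 0L) {
    stop("transcript '", tab$transcript_id[dup[1L]],
         "' maps to more than one gene", call. = FALSE)
  }
  rownames(tab) <- NULL
  tab
}

#' Read an ortholog mapping table
#'
#' Two-column (optionally three-column, with a free-text annotation carried
#' through unmodified) tab-delimited file with a header row mapping source-
#' species gene identifiers to human gene identifiers. Duplicate pairs are
#' collapsed; many-to-one and one-to-many pairings are both legal (paralogs
#' and split orthologs).
#'
#' @param path Path to the mapping file.
#' @return `data.frame` with columns `source_gene`, `human_gene`, and
#'   `annotation` if a third column is present.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) {
    stop("ortholog map file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) {
    stop("ortholog map must have at least two tab-delimited columns",
         call. = FALSE)
  }
  tab <- data.frame(source_gene = trimws(raw[[1L]]),
                    human_gene = trimws(raw[[2L]]),
                    stringsAsFactors = FALSE)
  if (ncol(raw) >= 3L) {
    tab$annotation <- raw[[3L]]
  }
  tab <- tab[!duplicated(tab[c("source_gene", "human_gene")]), , drop = FALSE]
  tab <- tab[nzchar(tab$source_gene) & nzchar(tab$human_gene), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write a two-column mapping table (tx2gene or ortholog map)
#'
#' @param map `data.frame` whose columns are written tab-delimited with a
#'   header row.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_two_column_tsv <- function(path, col_names) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) {
    stop("expected a two-column tab-delimited file with header: ", path,
         call. = FALSE)
  }
  out <- data.frame(trimws(raw[[1L]]), trimws(raw[[2L]]),
                    stringsAsFactors = FALSE)
  names(out) <- col_names
  out[nzchar(out[[1L]]) & nzchar(out[[2L]]), , drop = FALSE]
}

#' Serialize a report
#'
#' Writes a named report (possibly nested lists of scalars, vectors, and
#' data frames) as JSON or, for flat reports, as a two-column TSV with
#' stable key order. `read_report()` reads the JSON form back.
#'
#' @param report Named list.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    flat <- flatten_report(report)
    out <- data.frame(key = names(flat),
                      value = vapply(flat, function(v)
                        paste(format(v, scientific = FALSE, trim = TRUE),
                              collapse = ","), character(1L)),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

flatten_report <- function(x, prefix = NULL) {
  if (is.list(x) && !is.data.frame(x)) {
    out <- list()
    for (nm in names(x)) {
      key <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
      out <- c(out, flatten_report(x[[nm]], key))
    }
    out
  } else if (is.data.frame(x)) {
    out <- list()
    for (nm in names(x)) {
      out[[paste(prefix, nm, sep = ".")]] <- x[[nm]]
    }
    out
  } else {
    stats::setNames(list(x), prefix)
  }
}
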