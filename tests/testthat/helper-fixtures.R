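# Shared fixture builders and brute-force oracles. Oracles deliberately use
# naive loops so they stay independent of the implementation they check.

make_quant <- function(ids, eff_len, reads, len = round(eff_len) + 150L,
                       tpm = 0) {
  data.frame(transcript_id = ids, length = as.integer(len),
             effective_length = as.numeric(eff_len), tpm = tpm,
             num_reads = as.numeric(reads), stringsAsFactors = FALSE)
}

write_quant_file <- function(quant, path = tempfile(fileext = ".sf")) {
  write_quant_table(quant, path)
  path
}

random_gene_pool <- function(n) sprintf("g%04d", seq_len(n))

# first-occurrence dedup by explicit scan
brute_dedupe <- function(x) {
  out <- character(0L)
  dups <- 0L
  for (v in x) {
    if (v %in% out) dups <- dups + 1L else out <- c(out, v)
  }
  list(genes = out, duplicate_count = dups)
}

# membership counting by exhaustive double loop
brute_overlap_count <- function(a, b) {
  n <- 0L
  for (x in unique(a)) {
    for (y in unique(b)) {
      if (identical(x, y)) n <- n + 1L
    }
  }
  n
}

# gene-level TPM sums by nested loops
brute_gene_sums <- function(quant, tx2gene) {
  genes <- unique(tx2gene$gene_id)
  sums <- numeric(length(genes))
  for (i in seq_along(genes)) {
    for (j in seq_len(nrow(quant))) {
      g <- tx2gene$gene_id[tx2gene$transcript_id == quant$transcript_id[j]]
      if (length(g) == 1L && g == genes[i]) {
        sums[i] <- sums[i] + quant$tpm[j]
      }
    }
  }
  stats::setNames(sums, genes)
}

# two well-separated Gaussian blobs in gene-expression space
make_blobs <- function(n_per = 15L, n_genes = 5L, sep = 50, sd = 1,
                       seed = 42L) {
  set.seed(seed)
  a <- matrix(stats::rnorm(n_per * n_genes, 0, sd), nrow = n_per)
  b <- matrix(stats::rnorm(n_per * n_genes, sep, sd), nrow = n_per)
  m <- rbind(a, b)
  rownames(m) <- sprintf("cell%02d", seq_len(2L * n_per))
  colnames(m) <- sprintf("gene%d", seq_len(n_genes))
  list(matrix = m, labels = rep(1:2, each = n_per))
}
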