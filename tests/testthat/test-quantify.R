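test_that("TPM formula normalises length-adjusted read rates to one million", {
  # single transcript: normalisation forces 1e6 whatever the count
  q1 <- make_quant("tx1", eff_len = 500, reads = 3)
  expect_equal(compute_transcript_tpm(q1)$tpm, 1e6)

  # equal rates: counts (10,20,30) over effective lengths (100,200,300)
  q3 <- make_quant(c("a", "b", "c"), eff_len = c(100, 200, 300),
                   reads = c(10, 20, 30))
  expect_equal(compute_transcript_tpm(q3)$tpm, rep(1e6 / 3, 3L))

  # all-zero counts are degenerate
  q0 <- make_quant(c("a", "b"), eff_len = c(100, 200), reads = c(0, 0))
  expect_error(compute_transcript_tpm(q0), "degenerate")

  # property: randomized tables always sum to 1e6
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:100, 1L)
    q <- make_quant(sprintf("t%03d", 1:n),
                    eff_len = stats::runif(n, 30, 5000),
                    reads = c(stats::runif(n - 1L, 0, 200),
                              stats::runif(1L, 1, 200)))
    expect_equal(sum(compute_transcript_tpm(q)$tpm), 1e6,
                 tolerance = 1e-6)
  }
})

test_that("gene aggregation sums member transcripts and conserves mass", {
  q <- make_quant(c("t1", "t2"), eff_len = c(100, 100), reads = c(1, 1),
                  tpm = c(2e5, 3e5))
  t2g <- data.frame(transcript_id = c("t1", "t2"),
                    gene_id = c("g1", "g1"), stringsAsFactors = FALSE)
  agg <- aggregate_gene_tpm(q, t2g)
  expect_equal(agg$tpm, 5e5)

  # bijective map: gene table equals transcript table
  t2g_id <- data.frame(transcript_id = c("t1", "t2"),
                       gene_id = c("ga", "gb"), stringsAsFactors = FALSE)
  agg_id <- aggregate_gene_tpm(q, t2g_id)
  expect_equal(agg_id$tpm, q$tpm)

  # 5 transcripts over 3 genes vs brute-force nested-loop accumulation
  set.seed(3)
  q5 <- make_quant(sprintf("t%d", 1:5), eff_len = rep(100, 5),
                   reads = rep(1, 5), tpm = round(stats::runif(5, 0, 9), 2))
  t2g5 <- data.frame(transcript_id = sprintf("t%d", 1:5),
                     gene_id = c("g1", "g2", "g1", "g3", "g2"),
                     stringsAsFactors = FALSE)
  agg5 <- aggregate_gene_tpm(q5, t2g5)
  oracle <- brute_gene_sums(q5, t2g5)
  expect_equal(stats::setNames(agg5$tpm, agg5$gene_id),
               oracle[agg5$gene_id])

  # mass conservation on randomized inputs
  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:50, 1L)
    qq <- make_quant(sprintf("t%03d", 1:n), eff_len = rep(100, n),
                     reads = rep(1, n), tpm = stats::runif(n, 0, 100))
    map <- data.frame(transcript_id = sprintf("t%03d", 1:n),
                      gene_id = sample(sprintf("g%02d", 1:10), n,
                                       replace = TRUE),
                      stringsAsFactors = FALSE)
    expect_equal(sum(aggregate_gene_tpm(qq, map)$tpm), sum(qq$tpm))
  }
})

test_that("unmapped transcripts follow the lenient/strict policy", {
  q <- make_quant(c("t1", "LOCtx"), eff_len = c(100, 100), reads = c(1, 1),
                  tpm = c(10, 20))
  t2g <- data.frame(transcript_id = "t1", gene_id = "g1",
                    stringsAsFactors = FALSE)
  lenient <- aggregate_gene_tpm(q, t2g, unmapped = "lenient")
  expect_equal(nrow(lenient), 2L)
  expect_true(lenient$unmapped[lenient$gene_id == "LOCtx"])
  expect_false(lenient$unmapped[lenient$gene_id == "g1"])
  expect_error(aggregate_gene_tpm(q, t2g, unmapped = "strict"), "LOCtx")
})

test_that("five-interval binning partitions genes with the stated boundaries", {
  tab <- data.frame(gene_id = letters[1:5], tpm = c(0, 0.5, 3, 10, 50))
  bins <- bin_tpm_intervals(tab)
  expect_equal(bins$count, rep(1L, 5L))
  expect_equal(sum(bins$percent), 100)

  # boundary convention: 1 falls in LOW_1_5, 5 in MID_5_30, 30 in the top bin
  expect_equal(as.character(tpm_interval(c(0, 1e-9, 1, 5, 30))),
               c("ZERO", "SUB1", "LOW_1_5", "MID_5_30", "HIGH_30_PLUS"))

  # empty table: zero counts, flagged
  empty <- bin_tpm_intervals(data.frame(gene_id = character(0),
                                        tpm = numeric(0)))
  expect_equal(empty$count, rep(0L, 5L))
  expect_equal(empty$percent, rep(0, 5L))
  expect_true(attr(empty, "empty"))

  # partition property on randomized tables
  set.seed(5)
  for (i in 1:20) {
    n <- sample(1:200, 1L)
    tt <- data.frame(gene_id = sprintf("g%03d", 1:n),
                     tpm = stats::rexp(n, rate = 0.05) *
                       stats::rbinom(n, 1, 0.6))
    b <- bin_tpm_intervals(tt)
    expect_equal(sum(b$count), n)
    expect_equal(sum(b$percent), 100, tolerance = 1e-9)
  }
})
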