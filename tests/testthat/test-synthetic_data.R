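test_that("config validation rejects inconsistent parameters", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(zero_fraction = c(GFP = 0.8, RFP = 0.5),
                                sub1_fraction = c(GFP = 0.3, RFP = 0.2)),
               "exceeds 1")
  expect_error(synthetic_config(ortholog_coverage = 1.2), "\\[0, 1\\]")
  expect_error(synthetic_config(three_way_overlap = 0.5, mk_overlap = 0.4,
                                pl_overlap = 0.6), "three-way")
})

test_that("population generator is deterministic and respects the mixture", {
  cfg <- synthetic_config(seed = 9L, n_genes = 2000L)
  a <- gen_population_expression(cfg, "GFP")
  b <- gen_population_expression(cfg, "GFP")
  expect_identical(a, b)
  # populations draw from distinct streams
  r <- gen_population_expression(cfg, "RFP")
  expect_false(identical(a$genes$tpm, r$genes$tpm))

  # all-zero population
  cfg0 <- synthetic_config(seed = 2L, n_genes = 100L,
                           zero_fraction = c(GFP = 1, RFP = 1),
                           sub1_fraction = c(GFP = 0, RFP = 0))
  z <- gen_population_expression(cfg0, "GFP")
  expect_true(all(z$genes$tpm == 0))

  # mixture categories agree with the TPM values
  expect_true(all(a$genes$tpm[a$genes$category == "ZERO"] == 0))
  expect_true(all(a$genes$tpm[a$genes$category == "SUB1"] > 0 &
                    a$genes$tpm[a$genes$category == "SUB1"] < 1))
  expect_true(all(a$genes$tpm[a$genes$category == "EXPR"] > 1))

  # empirical zero fraction within the binomial 99% CI of p = 0.4009:
  # at n = 10000, p +/- 2.576 * sqrt(p(1-p)/n) = (0.3883, 0.4135)
  cfg10k <- synthetic_config(seed = 5L, n_genes = 10000L)
  g <- gen_population_expression(cfg10k, "GFP")
  frac <- mean(g$genes$tpm == 0)
  expect_gt(frac, 0.3883)
  expect_lt(frac, 0.4135)
})

test_that("transcript tables invert to gene TPM under the TPM formula", {
  cfg <- synthetic_config(seed = 17L, n_genes = 800L)
  pop <- gen_population_expression(cfg, "RFP")
  # quant table is a valid TPM vector and consistent with its counts
  expect_equal(sum(pop$quant$tpm), 1e6, tolerance = 1e-6)
  recomputed <- compute_transcript_tpm(pop$quant)
  expect_equal(recomputed$tpm, pop$quant$tpm, tolerance = 1e-9)
  # aggregation recovers gene TPM up to the per-million normalisation
  agg <- aggregate_gene_tpm(recomputed, pop$tx2gene)
  expected <- pop$genes$tpm * 1e6 / sum(pop$genes$tpm)
  expect_equal(agg$tpm[match(pop$genes$gene_id, agg$gene_id)], expected,
               tolerance = 1e-9)
})

test_that("ortholog map generator keeps paralog bookkeeping consistent", {
  genes <- sprintf("zg%06d", 1:5000)
  cfg <- synthetic_config(seed = 23L)
  map <- gen_ortholog_map(cfg, genes)

  # projecting the full source set recovers the generator's bookkeeping
  pr <- map_to_orthologs(genes, map)
  expect_equal(pr$n_raw, attr(map, "n_mapped"))
  expect_equal(pr$n_distinct, attr(map, "n_human"))
  expect_equal(pr$redundant_count, attr(map, "redundant_count"))
  expect_gt(pr$redundant_count, 0L)
  expect_lt(pr$n_distinct, attr(map, "n_mapped"))
  # shared humans come in groups of 2-3
  sizes <- table(map$human_gene)
  expect_true(all(sizes %in% 1:3))

  # no paralogs: injective map
  cfg_inj <- synthetic_config(seed = 23L, paralog_fraction = 0)
  map_inj <- gen_ortholog_map(cfg_inj, genes)
  expect_equal(anyDuplicated(map_inj$human_gene), 0L)
  expect_equal(attr(map_inj, "redundant_count"), 0L)

  # no coverage: empty map
  cfg_none <- synthetic_config(seed = 23L, ortholog_coverage = 0)
  expect_equal(nrow(gen_ortholog_map(cfg_none, genes)), 0L)
})

test_that("external set generator hits configured overlaps exactly", {
  t_genes <- sprintf("zg%06d", 1:1000)

  cfg <- synthetic_config(seed = 3L, mk_overlap = 0.46, pl_overlap = 0.17,
                          three_way_overlap = 0.15)
  ext <- gen_external_sets(cfg, t_genes)
  tri <- compare_three(t_genes, ext$megakaryocyte, ext$platelet)
  expect_equal(tri$n_tm, 460L)
  expect_equal(tri$n_tp, 170L)
  expect_equal(tri$n_tmp, 150L)
  # padded sizes follow the size factors
  expect_equal(length(ext$megakaryocyte), 843L)
  expect_equal(length(ext$platelet), 308L)

  # full containment
  cfg_all <- synthetic_config(seed = 3L, mk_overlap = 1, pl_overlap = 1,
                              three_way_overlap = 1)
  ext_all <- gen_external_sets(cfg_all, t_genes)
  expect_true(all(t_genes %in% ext_all$megakaryocyte))
  expect_true(all(t_genes %in% ext_all$platelet))

  # disjoint
  cfg_no <- synthetic_config(seed = 3L, mk_overlap = 0, pl_overlap = 0,
                             three_way_overlap = 0)
  ext_no <- gen_external_sets(cfg_no, t_genes)
  expect_length(intersect(t_genes, ext_no$megakaryocyte), 0L)
  expect_length(intersect(t_genes, ext_no$platelet), 0L)
})

test_that("bundle writer materialises a consistent, readable input set", {
  cfg <- synthetic_config(seed = 8L, n_genes = 300L)
  d <- tempfile("bundle_")
  paths <- write_synthetic_bundle(cfg, d)
  expect_true(all(vapply(paths, file.exists, logical(1L))))
  q <- read_quant_table(paths$quant_gfp)
  t2g <- read_tx2gene(paths$tx2gene)
  expect_true(all(q$transcript_id %in% t2g$transcript_id))
  om <- read_ortholog_map(paths$ortholog_map)
  expect_true(all(startsWith(om$human_gene, "HG")))
})
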