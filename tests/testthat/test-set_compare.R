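test_that("dedupe keeps first occurrences and counts removals", {
  d <- dedupe(c("a", "b", "a", "c", "a"))
  expect_equal(d$genes, c("a", "b", "c"))
  expect_equal(d$duplicate_count, 2L)
  expect_equal(dedupe(c("x", "y"))$duplicate_count, 0L)

  # random lists vs nested-loop first-occurrence scan
  set.seed(31)
  for (i in 1:30) {
    x <- sample(random_gene_pool(15), sample(1:40, 1L), replace = TRUE)
    expect_equal(dedupe(x), brute_dedupe(x))
  }
})

test_that("two-way comparison satisfies the set identities", {
  # identical lists
  cmp <- compare_two(c("a", "b"), c("b", "a"))
  expect_equal(sort(cmp$union_genes), c("a", "b"))
  expect_length(cmp$unique_a, 0L)
  expect_length(cmp$unique_b, 0L)

  # disjoint lists
  cmp <- compare_two(c("a", "b"), c("c", "d"))
  expect_equal(cmp$n_common, 0L)
  expect_equal(cmp$n_union, 4L)

  # symmetry up to swapping the unique sets, and inclusion-exclusion
  set.seed(32)
  for (i in 1:30) {
    a <- sample(random_gene_pool(30), sample(5:25, 1L))
    b <- sample(random_gene_pool(30), sample(5:25, 1L))
    ab <- compare_two(a, b)
    ba <- compare_two(b, a)
    expect_equal(ab$n_union, ab$n_a + ab$n_b - ab$n_common)
    expect_equal(sort(ab$unique_a), sort(ba$unique_b))
    expect_equal(sort(ab$common_genes), sort(ba$common_genes))
    expect_equal(ab$n_common, brute_overlap_count(a, b))
  }
})

test_that("ortholog projection collapses paralog hits at the human level", {
  map <- data.frame(source_gene = c("zga", "zgb", "zgc"),
                    human_gene = c("H1", "H1", "H2"),
                    stringsAsFactors = FALSE)
  pr <- map_to_orthologs(c("zga", "zgb", "zgd"), map)
  expect_equal(sort(pr$raw_hits), c("H1", "H1"))
  expect_equal(pr$distinct_orthologs, "H1")
  expect_equal(pr$redundant_count, 1L)
  expect_equal(pr$unmapped_sources, "zgd")
  expect_equal(pr$n_distinct, pr$n_raw - pr$redundant_count)

  # empty map: everything unmapped
  empty <- map_to_orthologs(c("a", "b"),
                            data.frame(source_gene = character(0),
                                       human_gene = character(0)))
  expect_length(empty$raw_hits, 0L)
  expect_equal(sort(empty$unmapped_sources), c("a", "b"))

  # one source with two human orthologs contributes both hits
  multi <- map_to_orthologs("zga",
                            data.frame(source_gene = c("zga", "zga"),
                                       human_gene = c("H1", "H2")))
  expect_equal(sort(multi$raw_hits), c("H1", "H2"))
  expect_equal(multi$redundant_count, 0L)

  # idempotence at the human level: identity map changes nothing
  idmap <- data.frame(source_gene = pr$distinct_orthologs,
                      human_gene = pr$distinct_orthologs)
  again <- map_to_orthologs(pr$distinct_orthologs, idmap)
  expect_equal(again$distinct_orthologs, pr$distinct_orthologs)
  expect_equal(again$redundant_count, 0L)
})

test_that("integer percentages truncate toward zero", {
  expect_equal(percent_of(6621, 9143), 72L)
  expect_equal(percent_of(1603, 9143), 17L)
  expect_equal(percent_of(0, 50), 0L)
  expect_equal(percent_of(50, 50), 100L)
  # 17.53... truncates, does not round
  expect_equal(percent_of(1753, 10000), 17L)
  expect_error(percent_of(1, 0), "positive")
  expect_error(percent_of(5, 3), "part")
})

test_that("three-way comparison matches exhaustive membership checking", {
  s <- c("a", "b", "c")
  all_same <- compare_three(s, s, s)
  expect_equal(all_same$n_tmp, 3L)
  expect_equal(sort(all_same$tmp), s)

  disj <- compare_three(c("a"), c("b"), c("c"))
  expect_equal(disj$n_tm + disj$n_tp + disj$n_mp + disj$n_tmp, 0L)

  set.seed(33)
  for (i in 1:25) {
    t <- sample(random_gene_pool(20), sample(3:15, 1L))
    m <- sample(random_gene_pool(20), sample(3:15, 1L))
    p <- sample(random_gene_pool(20), sample(3:15, 1L))
    tri <- compare_three(t, m, p, designated_subsets = list(sub = t[1:2]))
    expect_equal(tri$n_tm, brute_overlap_count(t, m))
    expect_equal(tri$n_tp, brute_overlap_count(t, p))
    expect_equal(tri$n_mp, brute_overlap_count(m, p))
    expect_equal(tri$n_tmp, length(intersect(intersect(t, m), p)))
    # three-way overlap is inside every pairwise overlap
    expect_true(all(tri$tmp %in% tri$tm))
    expect_true(all(tri$tmp %in% tri$tp))
    expect_true(all(tri$tmp %in% tri$mp))
    expect_equal(tri$subsets$sub$n_with_m, brute_overlap_count(t[1:2], m))
  }
})
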