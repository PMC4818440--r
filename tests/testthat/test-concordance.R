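test_that("profile_correlation handles exact, anti- and hand-derived cases", {
  first <- cbind(c(1, 2, 3, 4, 5))
  em <- make_paired_em(first, cbind(c(0, 0, 0, 0, 1)))   # second=(1,2,3,4,6)
  sheet <- make_pair_sheet(1)
  pc <- profile_correlation(em, sheet)
  # textbook covariance/sd oracle, computed from first principles
  x <- c(1, 2, 3, 4, 5); y <- c(1, 2, 3, 4, 6)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pc$r_pearson, r_oracle)
  expect_identical(pc$n_probes, 5L)

  em1 <- make_paired_em(first, cbind(rep(0, 5)))
  expect_equal(profile_correlation(em1, sheet)$r_pearson, 1)

  # negated profile around its centre: r = -1
  neg <- cbind(2 * mean(x) - x) - first
  em2 <- make_paired_em(first, neg)
  expect_equal(profile_correlation(em2, sheet)$r_pearson, -1)
})

test_that("profile_correlation drops probe pairs with missing values", {
  vals <- cbind(c(1, 2, 3, NA), c(1.1, 2.2, 2.9, 5))
  rownames(vals) <- sprintf("p%d", 1:4)
  colnames(vals) <- c("T01_1", "T01_2")
  det <- !is.na(vals)
  em <- expression_matrix(vals, det)
  pc <- profile_correlation(em, make_pair_sheet(1))
  expect_identical(pc$n_probes, 3L)
})

test_that("zero-variance profiles yield NaN with a warning", {
  em <- make_paired_em(cbind(rep(4, 3)), cbind(rep(0.5, 3)))
  expect_warning(pc <- profile_correlation(em, make_pair_sheet(1)),
                 "zero-variance")
  expect_true(is.nan(pc$r_pearson))
})

test_that("profile correlations are invariant to affine/monotone rescaling", {
  set.seed(21)
  first <- matrix(rnorm(50, 8), 50, 1)
  em <- make_paired_em(first, matrix(rnorm(50, 0, 0.3)))
  sheet <- make_pair_sheet(1)
  base <- profile_correlation(em, sheet)
  resc <- expression_matrix(2.5 * em$values + 3, em$detected)
  expect_equal(profile_correlation(resc, sheet)$r_pearson, base$r_pearson)
  mono <- expression_matrix(em$values^3, em$detected)
  expect_equal(profile_correlation(mono, sheet)$r_spearman, base$r_spearman)
})

test_that("gene_pair_correlation: exact r, guard rails, permutation null", {
  set.seed(22)
  n <- 12
  first <- matrix(rnorm(5 * n, 8), 5)
  em <- make_paired_em(first, matrix(0, 5, n))    # second == first
  sheet <- make_pair_sheet(n)
  gc <- gene_pair_correlation(em, sheet)
  expect_true(all(gc$r > 1 - 1e-12))
  expect_true(all(gc$p < 1e-8))
  expect_identical(gc$n_pairs, rep(12L, 5))
  expect_error(gene_pair_correlation(em, make_pair_sheet(2)), "4 complete")

  # label permutation: r centred on zero over replicates
  set.seed(23)
  rs <- replicate(300, {
    x <- rnorm(10, 8); y <- x[sample(10)]
    cor(x, y)
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("gene pair correlation estimates the intraclass correlation", {
  # variance-components closed form: E[r] ~ sb^2 / (sb^2 + sw^2)
  set.seed(24)
  n <- 1000
  for (case in list(c(sb = 1, sw = 1), c(sb = 2, sw = 1))) {
    tum <- rnorm(n, 0, case["sb"])
    x <- tum + rnorm(n, 0, case["sw"])
    y <- tum + rnorm(n, 0, case["sw"])
    icc <- case[["sb"]]^2 / (case[["sb"]]^2 + case[["sw"]]^2)
    expect_lt(abs(cor(x, y) - icc), 0.04)
  }
})

test_that("wider dynamic range means better paired reproducibility", {
  # constant within-pair noise, spreading between-tumour sd per gene:
  # empirical per-gene pair correlation must track the range multipliers
  set.seed(25)
  co <- generate_cohort(simulation_config(
    n_tumours = 300, n_genes = 100, n_centroid_genes = 0,
    sigma_between = 0.6, sigma_within = 0.3,
    dynamic_range_profile = seq(0.5, 4, length.out = 100),
    time_model = NULL, seed = 251))
  gc <- gene_pair_correlation(co$matrix, co$sheet)
  expect_gt(cor(gc$r, gc$dynamic_range_log2, method = "spearman"), 0.9)
  # and the measured range itself grows with the multiplier
  expect_gt(cor(gc$dynamic_range_log2, seq(0.5, 4, length.out = 100),
                method = "spearman"), 0.9)
})

test_that("average-linkage clustering follows the hand-evaluated merges", {
  em <- make_em(matrix(c(0, 1, 10), 1))
  hc <- hierarchical_cluster(em)
  expect_equal(hc$height, c(1, 9.5))     # mean(10, 9) after merging {0,1}
  # two samples: a single merge at their distance
  hc2 <- hierarchical_cluster(make_em(matrix(c(3, 7), 1)))
  expect_equal(hc2$height, 4)
  # duplicated sample merges first at distance zero
  hc3 <- hierarchical_cluster(make_em(matrix(c(5, 5, 9), 1)))
  expect_equal(hc3$height[1], 0)
  expect_setequal(-hc3$merge[1, ], c(1, 2))
})

test_that("pair adjacency counts sibling leaves only", {
  # exact duplicate pairs: all adjacent
  set.seed(26)
  first <- matrix(rnorm(20 * 5, 8, 2), 20)
  em <- make_paired_em(first, matrix(0, 20, 5))
  sheet <- make_pair_sheet(5)
  cc <- pair_adjacency_concordance(hierarchical_cluster(em), sheet)
  expect_identical(cc$n_pairs_adjacent, 5L)
  expect_equal(cc$fraction, 1)

  # constructed counterexample: T01's members each duplicate a different
  # tumour, so T01 is never a sibling pair
  base <- matrix(rnorm(20 * 3, 8, 3), 20)
  vals <- cbind(base[, 2] + 0.01, base[, 2], base[, 3] + 0.01, base[, 3],
                base[, 1], base[, 1] + 5)
  rownames(vals) <- sprintf("p%d", 1:20)
  colnames(vals) <- c("T01_1", "T02_1", "T01_2", "T03_1", "T02_2", "T03_2")
  em2 <- expression_matrix(vals)
  cc2 <- pair_adjacency_concordance(hierarchical_cluster(em2),
                                    make_pair_sheet(3))
  expect_false("T01" %in% cc2$adjacent_tumours)

  # missing sample from the tree is an error
  em3 <- em_subset(em, samples = setdiff(sample_ids(em), "T02_2"))
  expect_error(
    pair_adjacency_concordance(hierarchical_cluster(em3), sheet),
    "missing from tree.*T02")
})

test_that("pair adjacency is invariant to sample input order", {
  set.seed(27)
  first <- matrix(rnorm(30 * 8, 8, 1), 30)
  em <- make_paired_em(first, matrix(rnorm(30 * 8, 0, 0.8), 30))
  sheet <- make_pair_sheet(8)
  cc1 <- pair_adjacency_concordance(hierarchical_cluster(em), sheet)
  perm <- sample(ncol(em$values))
  em2 <- em_subset(em, samples = perm)
  cc2 <- pair_adjacency_concordance(hierarchical_cluster(em2), sheet)
  expect_identical(cc1$n_pairs_adjacent, cc2$n_pairs_adjacent)
})

test_that("heavy within-pair noise drives adjacency to the random-pair rate", {
  # Monte-Carlo null: with exchangeable samples the chance a given pair is
  # sibling is small; estimate it empirically and compare
  set.seed(28)
  n <- 10
  frac <- replicate(60, {
    em <- make_em(matrix(rnorm(5 * 2 * n, 8, 1), 5)) # no pair structure at all
    colnames(em$values) <- c(sprintf("T%02d_1", 1:n), sprintf("T%02d_2", 1:n))
    colnames(em$detected) <- colnames(em$values)
    pair_adjacency_concordance(hierarchical_cluster(em),
                               make_pair_sheet(n))$fraction
  })
  # null adjacency is far from 1; well below 0.3 for 10 pairs
  expect_lt(mean(frac), 0.3)
})

test_that("dendrograms export as Newick", {
  em <- make_em(matrix(c(0, 1, 10), 1))
  nwk <- dendrogram_newick(hierarchical_cluster(em))
  expect_match(nwk, "^\\(.*s3.*;$")
  path <- withr::local_tempfile(fileext = ".nwk")
  dendrogram_newick(hierarchical_cluster(em), path)
  expect_identical(ape::read.tree(path)$tip.label %in% c("s1", "s2", "s3"),
                   rep(TRUE, 3))
})
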