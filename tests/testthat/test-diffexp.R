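test_that("paired t matches hand arithmetic and handles degeneracy", {
  # d = (1, 2, 3): t = 2 / (1/sqrt(3)) = 3.4641, p from t(2)
  first <- matrix(8, 1, 3)
  em <- make_paired_em(first, matrix(c(1, 2, 3), 1))
  sheet <- make_pair_sheet(3)
  tt <- paired_t(em, sheet)
  expect_equal(tt$t_stat, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(tt$p_parametric, 0.0741799, tolerance = 1e-4) # frozen t(2) CDF
  expect_equal(tt$mean_log2_diff, 2)

  # all differences zero: t = 0, p = 1
  em0 <- make_paired_em(matrix(8, 1, 4), matrix(0, 1, 4))
  tt0 <- paired_t(em0, make_pair_sheet(4))
  expect_equal(tt0$t_stat, 0)
  expect_equal(tt0$p_parametric, 1)

  # constant nonzero differences: degenerate, p -> 0
  em1 <- make_paired_em(matrix(8, 1, 4), matrix(1, 1, 4))
  tt1 <- paired_t(em1, make_pair_sheet(4))
  expect_true(tt1$degenerate)
  expect_equal(tt1$p_parametric, 0)

  expect_error(paired_t(make_paired_em(matrix(8, 1, 2), matrix(0, 1, 2)),
                        make_pair_sheet(2)), ">= 3")
})

test_that("exhaustive sign-flip enumeration is exact", {
  # constant shift in every one of 8 pairs: only the two all-same-sign
  # patterns reach |t| = Inf, so p = 2 / 2^8
  n <- 8
  em <- make_paired_em(matrix(8, 1, n), matrix(0.7, 1, n))
  sheet <- make_pair_sheet(n)
  pp <- signflip_permutation(em, sheet, seed = 1, exhaustive = TRUE)
  expect_equal(pp$p_permutation, 2 / 2^n)
  expect_match(attr(pp, "method"), "exhaustive")

  # exhaustive agrees with a large random run
  set.seed(31)
  em2 <- make_paired_em(matrix(8, 2, n), matrix(rnorm(2 * n, 0.4, 0.5), 2))
  pe <- signflip_permutation(em2, sheet, seed = 5, exhaustive = TRUE)
  pr <- signflip_permutation(em2, sheet, n_perm = 20000, seed = 5,
                             exhaustive = FALSE)
  expect_equal(pe$p_permutation, pr$p_permutation, tolerance = 0.02)
})

test_that("sign-flip permutation is deterministic in the seed", {
  set.seed(32)
  em <- make_paired_em(matrix(8, 5, 12), matrix(rnorm(60, 0, 1), 5))
  sheet <- make_pair_sheet(12)
  a <- signflip_permutation(em, sheet, n_perm = 500, seed = 99,
                            exhaustive = FALSE)
  b <- signflip_permutation(em, sheet, n_perm = 500, seed = 99,
                            exhaustive = FALSE)
  expect_identical(a$p_permutation, b$p_permutation)
  expect_error(signflip_permutation(em, sheet), "seed is mandatory")
})

test_that("permutation and parametric p agree for normal differences", {
  set.seed(33)
  n <- 56
  em <- make_paired_em(matrix(8, 30, n), matrix(rnorm(30 * n, 0, 0.5), 30))
  sheet <- make_pair_sheet(n)
  tt <- paired_t(em, sheet)
  pp <- signflip_permutation(em, sheet, n_perm = 10000, seed = 7,
                             exhaustive = FALSE)
  expect_lt(max(abs(tt$p_parametric - pp$p_permutation)), 0.02)
})

test_that("bh_fdr implements the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.2, 0.2, 0.2)), rep(0.2, 3))
  expect_equal(bh_fdr(0.037), 0.037)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # order preservation and brute-force agreement on random vectors
  set.seed(34)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, bh_brute(p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("geometric-mean ratio and CI back-transform the t interval", {
  # d all zero: ratio 1, degenerate CI at 1
  em0 <- make_paired_em(matrix(8, 1, 4), matrix(0, 1, 4))
  gm0 <- geometric_mean_ratio(em0, make_pair_sheet(4))
  expect_equal(gm0$gm_ratio, 1)
  expect_equal(gm0$gm_ci_low, 1)
  expect_true(gm0$degenerate)

  # d = (1,1,1): ratio 2, CI collapses to (2,2)
  em1 <- make_paired_em(matrix(8, 1, 3), matrix(1, 1, 3))
  gm1 <- geometric_mean_ratio(em1, make_pair_sheet(3))
  expect_equal(gm1$gm_ratio, 2)
  expect_equal(c(gm1$gm_ci_low, gm1$gm_ci_high), c(2, 2))
  expect_true(gm1$degenerate)

  # hand-computed interval for d = (0.2, 0.6, 0.4, 0.8)
  d <- c(0.2, 0.6, 0.4, 0.8)
  em2 <- make_paired_em(matrix(8, 1, 4), matrix(d, 1))
  gm2 <- geometric_mean_ratio(em2, make_pair_sheet(4))
  half <- qt(0.975, 3) * sd(d) / 2
  expect_equal(gm2$gm_ratio, 2^0.5)
  expect_equal(gm2$gm_ci_low, 2^(0.5 - half))
  expect_equal(gm2$gm_ci_high, 2^(0.5 + half))
})

test_that("geometric-mean CI attains nominal coverage for an injected ratio", {
  # true second/first ratio 1.44 (log2 shift 0.526) at n = 56
  set.seed(35)
  n <- 56
  delta <- log2(1.44)
  hits <- replicate(200, {
    d <- delta + rnorm(n, 0, 0.5)
    m <- mean(d); half <- qt(0.975, n - 1) * sd(d) / sqrt(n)
    2^(m - half) <= 1.44 && 1.44 <= 2^(m + half)
  })
  em <- make_paired_em(matrix(8, 1, n),
                       matrix(delta + rnorm(n, 0, 0.5), 1))
  gm <- geometric_mean_ratio(em, make_pair_sheet(n))
  expect_true(gm$gm_ci_low <= gm$gm_ratio && gm$gm_ratio <= gm$gm_ci_high)
  expect_gt(mean(hits), 0.90)   # 95% nominal, MC tolerance
})

test_that("select_de applies FDR and reciprocal fold-change rules", {
  res <- data.frame(probe_id = c("a", "b", "c", "d"),
                    q_fdr = c(0.04, 0.04, 0.06, 0.04),
                    p_parametric = c(0.001, 0.001, 0.01, 0.2),
                    gm_ratio = c(1.30, 0.70, 1.30, 1.10))
  expect_setequal(select_de(res), c("a", "b"))       # 1/0.70 > 1.25
  expect_identical(select_de(res, fdr_max = 0.03), character(0))
  expect_setequal(select_de(res, fdr_max = 1, fc_min = 1),
                  c("a", "b", "c", "d"))             # thresholds disabled
  expect_setequal(select_de(res, criterion = "p_screen"), c("a", "b"))
})

test_that("time correlation recovers exact and drifting signals", {
  n <- 6
  minutes <- c(20, 25, 30, 40, 50, 60)
  # gene 1 drifts exactly 0.01 log2/minute; gene 2 is flat noise-free
  diffs <- rbind(0.01 * minutes, rep(0.3, n))
  em <- make_paired_em(matrix(8, 2, n), diffs)
  sheet <- make_pair_sheet(n, minutes = minutes)
  tc <- time_correlation(em, sheet)
  expect_equal(tc$r_time[1], 1)
  expect_lt(tc$p[1], 1e-10)

  # missing elapsed time is a hard error pointing at the sheet
  expect_error(time_correlation(em, make_pair_sheet(n)), "elapsed_minutes")
})

test_that("slope recovery: regression estimate within 2 SE at n = 23", {
  set.seed(36)
  n <- 23
  minutes <- runif(n, 20, 60)
  slope <- 0.015
  d <- slope * minutes + rnorm(n, 0, 0.2)
  fit <- lm(d ~ minutes)
  est <- coef(fit)["minutes"]
  se <- summary(fit)$coefficients["minutes", "Std. Error"]
  expect_lt(abs(est - slope), 2 * se)
  # and the package's correlation screen flags the drifting gene
  em <- make_paired_em(matrix(8, 1, n), matrix(d, 1))
  tc <- time_correlation(em, make_pair_sheet(n, minutes = minutes))
  expect_lt(tc$p[1], 0.05)
})

test_that("larger cohorts give more power at matched effect size", {
  # a 1.25-fold shift with 0.5 log2 within-pair sd is found at FDR 5%
  # far more often with 56 pairs than with 23
  set.seed(37)
  delta <- log2(1.25)
  power_at <- function(n, reps = 200) {
    mean(replicate(reps, {
      p_shift <- 2 * pt(-abs(mean(delta + rnorm(n, 0, 0.5)) /
                             (0.5 / sqrt(n))), n - 1)
      p_null <- runif(40)          # 40 null genes alongside
      q <- bh_fdr(c(p_shift, p_null))
      q[1] < 0.05
    }))
  }
  p23 <- power_at(23)
  p56 <- power_at(56)
  expect_gt(p56, p23)
  expect_gt(p56 - p23, 0.1)
})

test_that("paired_diffexp assembles a coherent results table", {
  set.seed(38)
  n <- 10
  em <- make_paired_em(matrix(rnorm(6 * n, 8), 6),
                       matrix(rnorm(6 * n, 0, 0.4), 6))
  sheet <- make_pair_sheet(n)
  de <- paired_diffexp(em, sheet, n_perm = 200, seed = 3)
  expect_identical(de$probe_id, probe_ids(em))
  expect_equal(de$gm_ratio, 2^de$mean_log2_diff)
  expect_true(all(de$gm_ci_low <= de$gm_ratio + 1e-12 &
                  de$gm_ratio <= de$gm_ci_high + 1e-12))
  expect_true(all(de$q_fdr >= de$p_parametric - 1e-12))
  expect_equal(de$fc_signed,
               ifelse(de$gm_ratio >= 1, de$gm_ratio, -1 / de$gm_ratio))
})
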