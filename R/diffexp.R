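# Paired differential expression: per-gene paired t statistics, sign-flip
# permutation p-values, Benjamini-Hochberg FDR, geometric-mean fold ratios
# with 95% CIs, and correlation of paired change with elapsed time.

pair_diff_matrix <- function(em, sheet) {
  pairs <- complete_pairs(sheet, sample_ids(em))
  if (!nrow(pairs)) stop("no complete pairs among matrix samples",
                         call. = FALSE)
  d <- em$values[, pairs$second, drop = FALSE] -
       em$values[, pairs$first, drop = FALSE]
  colnames(d) <- pairs$tumour_id
  list(d = d, pairs = pairs)
}

paired_t_from_diffs <- function(d) {
  n <- ncol(d)
  m <- rowMeans(d)
  s <- apply(d, 1, stats::sd)
  degenerate <- s == 0
  t_stat <- ifelse(degenerate, ifelse(m == 0, 0, sign(m) * Inf),
                   m / (s / sqrt(n)))
  p <- ifelse(degenerate, ifelse(m == 0, 1, 0),
              2 * stats::pt(-abs(t_stat), df = n - 1))
  data.frame(mean_log2_diff = m, t_stat = t_stat, p_parametric = p,
             degenerate = degenerate, n_pairs = n)
}

#' Per-gene paired t test between first and second biopsies
#'
#' Differences are second minus first on the log2 scale; `t =
#' mean(d)/(sd(d)/sqrt(n))`, two-sided p on `n - 1` df. Genes whose
#' differences have zero variance are flagged degenerate (p = 1 when the mean
#' difference is also 0, p = 0 otherwise).
#'
#' @param em An `ExpressionMatrix` (log2 scale).
#' @param sheet A `SampleSheet`.
#' @return data.frame keyed by `probe_id` with `mean_log2_diff`, `t_stat`,
#'   `p_parametric`, `degenerate`, `n_pairs`.
#' @export
paired_t <- function(em, sheet) {
  pd <- pair_diff_matrix(em, sheet)
  if (ncol(pd$d) < 3) stop("paired t needs >= 3 complete pairs", call. = FALSE)
  res <- paired_t_from_diffs(pd$d)
  cbind(data.frame(probe_id = probe_ids(em), stringsAsFactors = FALSE), res)
}

# |t| for every row of D under a matrix S of sign patterns (rows = patterns).
# var(s*d) shares the raw sum of squares with d, only the mean moves, so the
# whole permutation set is two matrix products.
signflip_t_abs <- function(d, S) {
  n <- ncol(d)
  ss <- rowSums(d^2)
  M <- tcrossprod(d, S) / n                   # genes x patterns mean
  V <- (ss - n * M^2) / (n - 1)
  Tm <- abs(M / sqrt(pmax(V, 0) / n))
  Tm[is.nan(Tm)] <- 0      # all-zero difference row: t defined as 0
  Tm
}

#' Sign-flip permutation p-values for the paired design
#'
#' Under the paired null each tumour's difference is symmetric around zero,
#' so the reference distribution is obtained by independently flipping the
#' sign of every pair's difference and recomputing the t statistic. With
#' `exhaustive = TRUE` (allowed for `n <= 20` pairs, automatic default for
#' `n <= 10`) all `2^n` sign patterns are enumerated and the p-value is the
#' exact fraction `#{|t*| >= |t|} / 2^n`; otherwise `n_perm` random patterns
#' give `p = (1 + #{|t*| >= |t|}) / (1 + n_perm)`.
#'
#' @param em An `ExpressionMatrix`.
#' @param sheet A `SampleSheet`.
#' @param n_perm Number of random sign patterns (>= 1000 advised).
#' @param seed Integer seed; mandatory so runs are reproducible.
#' @param exhaustive `NULL` (auto), `TRUE` or `FALSE`.
#' @return data.frame `probe_id`, `p_permutation`, plus attributes `seed`
#'   and `method`.
#' @export
signflip_permutation <- function(em, sheet, n_perm = 10000, seed,
                                 exhaustive = NULL) {
  if (missing(seed)) stop("a permutation seed is mandatory", call. = FALSE)
  pd <- pair_diff_matrix(em, sheet)
  d <- pd$d
  n <- ncol(d)
  if (is.null(exhaustive)) exhaustive <- n <= 10
  t_obs <- signflip_t_abs(d, matrix(1, 1, n))[, 1]
  if (exhaustive) {
    if (n > 20) stop("exhaustive enumeration limited to n <= 20 pairs",
                     call. = FALSE)
    S <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    Tperm <- signflip_t_abs(d, S)
    p <- rowMeans(Tperm >= t_obs - 1e-12)
    method <- sprintf("exhaustive_2^%d", n)
  } else {
    set.seed(seed)
    S <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    Tperm <- signflip_t_abs(d, S)
    p <- (1 + rowSums(Tperm >= t_obs - 1e-12)) / (1 + n_perm)
    method <- sprintf("random_%d", n_perm)
  }
  out <- data.frame(probe_id = probe_ids(em), p_permutation = p,
                    stringsAsFactors = FALSE)
  attr(out, "seed") <- seed
  attr(out, "method") <- method
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j`, clipped at 1;
#' the adjustment preserves the ordering of the p-values.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  m <- length(p)
  o <- order(p)
  q <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- q
  out[is.na(p)] <- NA_real_
  out
}

#' Geometric-mean ratio of second to first biopsy with 95% CI
#'
#' On the log2 scale the mean within-pair difference `mean(d)` back-transforms
#' to the geometric mean of the per-tumour ratios; the CI is the
#' back-transformed t interval `2^(mean(d) +/- t_{0.975, n-1} * sd(d)/sqrt(n))`.
#'
#' @param em An `ExpressionMatrix`.
#' @param sheet A `SampleSheet`.
#' @param probes Optional probe subset.
#' @param conf Confidence level (default 0.95).
#' @return data.frame `probe_id`, `gm_ratio`, `gm_ci_low`, `gm_ci_high`,
#'   `n_pairs`, `degenerate`.
#' @export
geometric_mean_ratio <- function(em, sheet, probes = NULL, conf = 0.95) {
  pd <- pair_diff_matrix(em, sheet)
  d <- pd$d
  if (!is.null(probes)) d <- d[probes, , drop = FALSE]
  res <- lapply(seq_len(nrow(d)), function(i) {
    di <- d[i, ]
    di <- di[is.finite(di)]
    n <- length(di)
    if (n < 3) stop("geometric_mean_ratio needs >= 3 usable pairs for probe ",
                    rownames(d)[i], call. = FALSE)
    m <- mean(di)
    s <- stats::sd(di)
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * s / sqrt(n)
    data.frame(probe_id = rownames(d)[i], gm_ratio = 2^m,
               gm_ci_low = 2^(m - half), gm_ci_high = 2^(m + half),
               n_pairs = n, degenerate = s == 0, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Full paired differential-expression analysis
#'
#' Combines [paired_t()], [signflip_permutation()], [bh_fdr()] (on the
#' parametric p by default) and [geometric_mean_ratio()] into one per-gene
#' results table.
#'
#' @param em An `ExpressionMatrix`.
#' @param sheet A `SampleSheet`.
#' @param n_perm Permutations for the sign-flip test; 0 skips it.
#' @param seed Permutation seed (default 20160401).
#' @param fdr_on `"parametric"` or `"permutation"`: which p-value feeds BH.
#' @return data.frame of class `PairedDEResult` with one row per probe:
#'   `probe_id`, `mean_log2_diff`, `t_stat`, `p_parametric`,
#'   `p_permutation`, `q_fdr`, `gm_ratio`, `gm_ci_low`, `gm_ci_high`,
#'   `fc_signed` (signed fold-change convention: negative = down, magnitude =
#'   reciprocal ratio), `n_pairs`.
#' @export
paired_diffexp <- function(em, sheet, n_perm = 10000, seed = 20160401,
                           fdr_on = c("parametric", "permutation")) {
  fdr_on <- match.arg(fdr_on)
  tt <- paired_t(em, sheet)
  gm <- geometric_mean_ratio(em, sheet)
  res <- merge(tt, gm, by = "probe_id", sort = FALSE)
  res$n_pairs <- res$n_pairs.x
  res$n_pairs.x <- res$n_pairs.y <- NULL
  if (n_perm > 0) {
    pp <- signflip_permutation(em, sheet, n_perm = n_perm, seed = seed)
    res$p_permutation <- pp$p_permutation[match(res$probe_id, pp$probe_id)]
  } else {
    res$p_permutation <- NA_real_
  }
  res$q_fdr <- bh_fdr(if (fdr_on == "parametric") res$p_parametric
                      else res$p_permutation)
  res$fc_signed <- ifelse(res$gm_ratio >= 1, res$gm_ratio, -1 / res$gm_ratio)
  res <- res[match(probe_ids(em), res$probe_id), ]
  rownames(res) <- NULL
  class(res) <- c("PairedDEResult", "data.frame")
  res
}

#' Select differentially expressed genes
#'
#' Default rule: FDR q below `fdr_max` and fold change above `fc_min` in
#' either direction (`max(gm_ratio, 1/gm_ratio) > fc_min`, strict). The
#' `criterion = "p_screen"` variant instead screens on the unadjusted
#' parametric p (`p < p_max` and fold change `>= fc_min`), the convention for
#' an exploratory ranking in a small cohort.
#'
#' @param results A `PairedDEResult` data.frame.
#' @param fdr_max FDR ceiling (default 0.05); `fdr_max >= 1` disables the
#'   FDR filter (every tested gene passes it).
#' @param fc_min Fold-change floor (default 1.25); `fc_min <= 1` disables it.
#' @param criterion `"fdr"` (default) or `"p_screen"`.
#' @param p_max Unadjusted-p ceiling for the screen (default 0.005).
#' @return Character vector of selected probe ids.
#' @export
select_de <- function(results, fdr_max = 0.05, fc_min = 1.25,
                      criterion = c("fdr", "p_screen"), p_max = 0.005) {
  criterion <- match.arg(criterion)
  fc <- pmax(results$gm_ratio, 1 / results$gm_ratio)
  pass_fc <- if (fc_min <= 1) rep(TRUE, nrow(results)) else fc > fc_min
  keep <- if (criterion == "fdr")
    (if (fdr_max >= 1) TRUE else results$q_fdr < fdr_max) & pass_fc
  else
    results$p_parametric < p_max & fc >= fc_min
  results$probe_id[keep & !is.na(keep)]
}

#' Correlation of paired expression change with elapsed time
#'
#' Per gene, the Pearson correlation across tumours between the within-pair
#' log2 difference and the minutes elapsed between the two biopsies, with
#' parametric p and BH q.
#'
#' @param em An `ExpressionMatrix`.
#' @param sheet A `SampleSheet` whose pairs all carry `elapsed_minutes`.
#' @return data.frame `probe_id`, `r_time`, `p`, `q_adjusted`, `n_pairs`.
#' @export
time_correlation <- function(em, sheet) {
  pd <- pair_diff_matrix(em, sheet)
  mins <- pd$pairs$elapsed_minutes
  if (any(is.na(mins)))
    stop("elapsed_minutes missing for tumour(s): ",
         paste(pd$pairs$tumour_id[is.na(mins)], collapse = ", "),
         "; the elapsed-time analysis needs a sheet recording the delay ",
         "between paired biopsies", call. = FALSE)
  n <- length(mins)
  r <- apply(pd$d, 1, function(di) suppressWarnings(stats::cor(di, mins)))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  data.frame(probe_id = probe_ids(em), r_time = r, p = p,
             q_adjusted = bh_fdr(p), n_pairs = n, stringsAsFactors = FALSE)
}
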