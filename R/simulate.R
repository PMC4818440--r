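# Synthetic paired-biopsy cohort generator with known ground truth.
#
# Model, per tumour t of subtype s and gene g (all on the log2 scale):
#   tumour profile   mu_gt = centroid_gs + N(0, sigma_b * range_mult_g)
#   first biopsy     x1 = mu_gt + N(0, sigma_w_g)                + batch
#   second biopsy    x2 = mu_gt + N(0, sigma_w_g) + delta_g
#                         + slope_g * minutes_t                  + batch
# Detection is a logistic function of expression, so dim genes drop out of
# detection the way bead-array probes do.

#' Build a simulation configuration
#'
#' Defaults describe a cohort of the size and noise scale seen in
#' peri-surgical paired-biopsy studies: 56 tumour pairs, mostly-luminal
#' subtype mix, between-tumour spread of 1 log2 unit around subtype
#' centroids, within-pair (biopsy) noise of 0.25 log2, biopsies 20-60
#' minutes apart.
#'
#' @param n_tumours Number of tumours (each contributes a pair).
#' @param n_genes Number of genes/probes.
#' @param subtype_proportions Named proportions summing to 1.
#' @param n_centroid_genes How many genes carry subtype-centroid structure
#'   (these form the returned `CentroidSet`).
#' @param centroid_separation SD (log2) of the subtype-specific centroid
#'   offsets on centroid genes.
#' @param luminal_correlation Correlation imposed between the LumA and LumB
#'   centroid offsets (default 0.8): the two luminal subtypes are molecular
#'   neighbours, which is what makes their assignments confusable at small
#'   correlation margins. Ignored unless both labels are present.
#' @param sigma_between Between-tumour SD (log2), scaled per gene by
#'   `dynamic_range_profile`.
#' @param sigma_within Within-pair biopsy SD (log2); scalar or per-gene.
#' @param dynamic_range_profile Per-gene multipliers of `sigma_between`
#'   (length `n_genes`), or `NULL` for all 1.
#' @param shift_genes Named numeric: systematic log2 shift added to the
#'   second biopsy of the named genes (names are probe ids `g0001`, ...).
#' @param time_model `NULL` (no elapsed-time covariate) or a list with
#'   `minutes_range` (default `c(20, 60)`) and optional named `slope_genes`
#'   (log2 change per minute applied to the second biopsy).
#' @param batch_structure list with `n_batches` (default 1) and `sd`
#'   (per-gene batch-effect SD, default 0).
#' @param dropout list with `midpoint` and `scale` of the logistic detection
#'   model; defaults are calibrated so an ordinary cohort passes the 30%
#'   detection QC comfortably.
#' @param n_degraded Number of second-timepoint samples rendered mostly
#'   undetected, to exercise the QC filter.
#' @param baseline_range Range of per-gene baseline means (log2).
#' @param study_id Study label written into the sample sheet.
#' @param seed Mandatory integer seed.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_tumours = 56,
                              n_genes = 1000,
                              subtype_proportions = c(LumA = 0.50, LumB = 0.25,
                                                      Her2 = 0.10, Basal = 0.10,
                                                      Normal = 0.05),
                              n_centroid_genes = 50,
                              centroid_separation = 2,
                              luminal_correlation = 0.8,
                              sigma_between = 1,
                              sigma_within = 0.25,
                              dynamic_range_profile = NULL,
                              shift_genes = numeric(),
                              time_model = list(minutes_range = c(20, 60)),
                              batch_structure = list(n_batches = 1, sd = 0),
                              dropout = list(midpoint = 4, scale = 0.5),
                              n_degraded = 0,
                              baseline_range = c(6, 12),
                              study_id = "S1",
                              seed) {
  if (missing(seed)) stop("a simulation seed is mandatory", call. = FALSE)
  if (abs(sum(subtype_proportions) - 1) > 1e-8)
    stop("subtype_proportions must sum to 1", call. = FALSE)
  if (is.null(names(subtype_proportions)))
    stop("subtype_proportions must be named", call. = FALSE)
  if (sigma_between < 0 || any(sigma_within < 0))
    stop("standard deviations must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "SimulationConfig")
}

#' Generate a paired-biopsy cohort
#'
#' @param config A [simulation_config()].
#' @return list: `matrix` (an `ExpressionMatrix`), `sheet` (a `SampleSheet`),
#'   `centroids` (a `CentroidSet` over the centroid genes), `truth` (list:
#'   `subtype` per tumour, `delta`, `sigma_b`, `sigma_w`, `slope` per gene,
#'   `minutes` per tumour, `batch` per sample), `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  ng <- config$n_genes
  nt <- config$n_tumours
  genes <- sprintf("g%04d", seq_len(ng))
  tumours <- sprintf("T%03d", seq_len(nt))
  props <- config$subtype_proportions
  subtypes <- sample(names(props), nt, replace = TRUE, prob = props)

  baseline <- stats::runif(ng, config$baseline_range[1], config$baseline_range[2])
  range_mult <- config$dynamic_range_profile
  if (is.null(range_mult)) range_mult <- rep(1, ng)
  if (length(range_mult) != ng)
    stop("dynamic_range_profile must have length n_genes", call. = FALSE)
  sigma_b <- config$sigma_between * range_mult
  sigma_w <- rep_len(config$sigma_within, ng)

  ncg <- min(config$n_centroid_genes, ng)
  cen <- matrix(baseline, ng, length(props),
                dimnames = list(genes, names(props)))
  if (ncg > 0) {
    off <- matrix(stats::rnorm(ncg * length(props), 0,
                               config$centroid_separation),
                  ncg, dimnames = list(NULL, names(props)))
    rho <- config$luminal_correlation %||% 0
    if (rho != 0 && all(c("LumA", "LumB") %in% names(props)))
      off[, "LumB"] <- rho * off[, "LumA"] +
        sqrt(1 - rho^2) * off[, "LumB"]
    cen[seq_len(ncg), ] <- cen[seq_len(ncg), ] + off
  }

  delta <- stats::setNames(rep(0, ng), genes)
  if (length(config$shift_genes)) {
    unknown <- setdiff(names(config$shift_genes), genes)
    if (length(unknown)) stop("unknown shift gene(s): ",
                              paste(unknown, collapse = ", "), call. = FALSE)
    delta[names(config$shift_genes)] <- config$shift_genes
  }
  slope <- stats::setNames(rep(0, ng), genes)
  minutes <- rep(NA_real_, nt)
  if (!is.null(config$time_model)) {
    mr <- config$time_model$minutes_range %||% c(20, 60)
    minutes <- stats::runif(nt, mr[1], mr[2])
    sg <- config$time_model$slope_genes
    if (length(sg)) slope[names(sg)] <- sg
  }

  mu <- cen[, subtypes, drop = FALSE] +
    matrix(stats::rnorm(ng * nt, 0, sigma_b), ng, nt)
  x1 <- mu + matrix(stats::rnorm(ng * nt, 0, sigma_w), ng, nt)
  x2 <- mu + matrix(stats::rnorm(ng * nt, 0, sigma_w), ng, nt) + delta
  if (any(slope != 0))
    x2 <- x2 + outer(slope, ifelse(is.na(minutes), 0, minutes))

  nb <- config$batch_structure$n_batches %||% 1
  bsd <- config$batch_structure$sd %||% 0
  sample_idx <- seq_len(2 * nt)
  batch <- sprintf("B%d", ((sample_idx - 1) %% nb) + 1)
  vals <- cbind(x1, x2)
  s_ids <- c(paste0(tumours, "_1"), paste0(tumours, "_2"))
  colnames(vals) <- s_ids
  rownames(vals) <- genes
  if (bsd > 0) {
    beff <- matrix(stats::rnorm(ng * nb, 0, bsd), ng, nb,
                   dimnames = list(genes, sprintf("B%d", seq_len(nb))))
    vals <- vals + beff[, batch]
  }

  pdet <- stats::plogis((vals - config$dropout$midpoint) / config$dropout$scale)
  if (config$n_degraded > 0) {
    deg <- nt + seq_len(min(config$n_degraded, nt))   # second-timepoint cols
    pdet[, deg] <- stats::plogis(
      (vals[, deg] - (max(vals) + 2)) / config$dropout$scale)
  }
  detected <- matrix(stats::runif(length(pdet)) < pdet, ng,
                     dimnames = dimnames(vals))

  em <- expression_matrix(vals, detected)
  sheet <- sample_sheet(data.frame(
    sample_id = s_ids,
    tumour_id = rep(tumours, 2),
    timepoint = rep(c("first", "second"), each = nt),
    study_id = config$study_id,
    batch_id = batch,
    elapsed_minutes = c(rep(NA_real_, nt), minutes),
    stringsAsFactors = FALSE))
  centroids <- if (ncg > 0) centroid_set(cen[seq_len(ncg), , drop = FALSE])
               else NULL
  truth <- list(subtype = stats::setNames(subtypes, tumours),
                delta = delta, sigma_b = stats::setNames(sigma_b, genes),
                sigma_w = stats::setNames(sigma_w, genes),
                slope = slope,
                minutes = stats::setNames(minutes, tumours),
                batch = stats::setNames(batch, s_ids))
  list(matrix = em, sheet = sheet, centroids = centroids, truth = truth,
       config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Compare analysis outputs against simulation ground truth
#'
#' @param truth The `truth` component of [generate_cohort()] output.
#' @param de_selected Optional character vector of probes called DE.
#' @param calls Optional `SubtypeCalls` for the generated samples.
#' @param sheet Required with `calls`: the generated `SampleSheet`.
#' @param gene_corr Optional output of [gene_pair_correlation()].
#' @return list of class `TruthRecovery` with whichever metrics the supplied
#'   outputs allow: `de_sensitivity`, `de_fdp`, `subtype_accuracy`,
#'   `icc_mean_abs_error`.
#' @export
truth_recovery_report <- function(truth, de_selected = NULL, calls = NULL,
                                  sheet = NULL, gene_corr = NULL) {
  out <- list()
  if (!is.null(de_selected)) {
    shifted <- names(truth$delta)[truth$delta != 0]
    unknown <- setdiff(de_selected, names(truth$delta))
    if (length(unknown))
      stop("DE call(s) not present in truth: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    out$de_sensitivity <- if (length(shifted))
      length(intersect(de_selected, shifted)) / length(shifted) else NA_real_
    out$de_fdp <- if (length(de_selected))
      length(setdiff(de_selected, shifted)) / length(de_selected) else 0
  }
  if (!is.null(calls)) {
    if (is.null(sheet)) stop("subtype accuracy needs the sample sheet",
                             call. = FALSE)
    tum <- sheet$tumour_id[match(calls$sample_id, sheet$sample_id)]
    if (any(is.na(tum))) stop("calls contain samples absent from the sheet",
                              call. = FALSE)
    out$subtype_accuracy <- mean(calls$subtype == truth$subtype[tum])
  }
  if (!is.null(gene_corr)) {
    icc <- truth$sigma_b^2 / (truth$sigma_b^2 + truth$sigma_w^2)
    idx <- match(gene_corr$probe_id, names(icc))
    if (any(is.na(idx))) stop("gene_corr probes not aligned to truth",
                              call. = FALSE)
    out$icc_mean_abs_error <- mean(abs(gene_corr$r - icc[idx]))
  }
  structure(out, class = "TruthRecovery")
}
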