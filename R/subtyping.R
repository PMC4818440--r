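# Nearest-centroid intrinsic subtyping with correlation-margin diagnostics.
#
# A sample is assigned to the subtype whose reference centroid its profile
# correlates with most strongly (PAM50-style). The margin between the two
# luminal centroids is carried along because small margins are where paired
# subtype calls flip.

#' Classify samples by nearest centroid correlation
#'
#' Centroid gene ids are matched to matrix probes directly, or through an
#' annotation (Entrez ids; multiple probes per gene averaged). At least half
#' the centroid genes must be matched. By default expression is gene-wise
#' median-centered across the cohort before correlating, as centroid
#' classifiers expect.
#'
#' @param em An `ExpressionMatrix` (log2 scale).
#' @param centroids A `CentroidSet`.
#' @param annotation Optional `ProbeAnnotation` if centroid gene ids are
#'   Entrez ids rather than probe ids.
#' @param method Correlation: `"spearman"` (default, classical centroid
#'   practice) or `"pearson"`.
#' @param median_center Gene-wise median-center across samples first
#'   (default `TRUE`).
#' @return data.frame of class `SubtypeCalls`: `sample_id`, `subtype`,
#'   one `r_<label>` column per centroid, `margin_lumA_lumB` (when both
#'   luminal centroids exist; signed, LumA minus LumB), `top_margin`
#'   (best minus second-best correlation) and `tie` flag.
#' @export
classify_subtypes <- function(em, centroids, annotation = NULL,
                              method = c("spearman", "pearson"),
                              median_center = TRUE) {
  method <- match.arg(method)
  cen <- centroids$values
  if (is.null(annotation)) {
    shared <- intersect(rownames(cen), probe_ids(em))
    expr <- em$values[shared, , drop = FALSE]
  } else {
    ann <- annotation[annotation$probe_id %in% probe_ids(em), ]
    shared <- intersect(rownames(cen), unique(ann$entrez_id))
    expr <- t(vapply(shared, function(g) {
      pr <- ann$probe_id[ann$entrez_id == g]
      colMeans(em$values[pr, , drop = FALSE])
    }, numeric(ncol(em$values))))
  }
  if (length(shared) < nrow(cen) / 2)
    stop("only ", length(shared), " of ", nrow(cen),
         " centroid genes matched (need >= 50%); missing: ",
         paste(utils::head(setdiff(rownames(cen), shared), 10), collapse = ", "),
         call. = FALSE)
  cen <- cen[shared, , drop = FALSE]
  if (median_center)
    expr <- expr - apply(expr, 1, stats::median)
  R <- suppressWarnings(stats::cor(expr, cen, method = method))
  labels <- colnames(cen)
  if (anyNA(R))
    warning("zero-variance profile(s) after centering; NA calls for: ",
            paste(rownames(R)[apply(is.na(R), 1, any)], collapse = ", "),
            call. = FALSE)
  calls <- lapply(seq_len(nrow(R)), function(i) {
    r <- R[i, ]
    if (anyNA(r)) {
      row <- data.frame(sample_id = rownames(R)[i], subtype = NA_character_,
                        stringsAsFactors = FALSE)
      for (lab in labels) row[[paste0("r_", lab)]] <- r[[lab]]
      row$margin_lumA_lumB <- NA_real_
      row$top_margin <- NA_real_
      row$tie <- NA
      return(row)
    }
    best <- max(r)
    top <- labels[r == best]
    tie <- length(top) > 1
    assigned <- sort(top)[1L]                 # alphabetical tie-break
    second <- max(r[labels != assigned])
    row <- data.frame(sample_id = rownames(R)[i], subtype = assigned,
                      stringsAsFactors = FALSE)
    for (lab in labels) row[[paste0("r_", lab)]] <- r[[lab]]
    row$margin_lumA_lumB <-
      if (all(c("LumA", "LumB") %in% labels)) r[["LumA"]] - r[["LumB"]]
      else NA_real_
    row$top_margin <- best - second
    row$tie <- tie
    row
  })
  out <- do.call(rbind, calls)
  class(out) <- c("SubtypeCalls", "data.frame")
  out
}

#' Paired subtype concordance
#'
#' Cross-tabulates the subtype calls of the first and second biopsy of every
#' complete pair. Systematic drift (more flips in one direction than the
#' other) is tested by an exact binomial test comparing the off-diagonal
#' counts above versus below the diagonal of the contingency table.
#'
#' @param calls A `SubtypeCalls` data.frame covering both timepoints.
#' @param sheet A `SampleSheet`.
#' @return list of class `PairedSubtypeConcordance`: `pairs` (per-tumour
#'   calls + concordant flag), `table` (contingency, first in rows),
#'   `n_pairs`, `n_discordant`, `discordance_rate`, `asymmetry_p`.
#' @export
paired_subtype_concordance <- function(calls, sheet) {
  pairs <- complete_pairs(sheet, calls$sample_id)
  c1 <- calls$subtype[match(pairs$first, calls$sample_id)]
  c2 <- calls$subtype[match(pairs$second, calls$sample_id)]
  levs <- sort(unique(c(c1, c2)))
  tab <- table(factor(c1, levs), factor(c2, levs), dnn = c("first", "second"))
  up <- sum(tab[upper.tri(tab)])
  dn <- sum(tab[lower.tri(tab)])
  asym_p <- if (up + dn == 0) 1 else
    stats::binom.test(up, up + dn, 0.5)$p.value
  pr <- data.frame(tumour_id = pairs$tumour_id, call_first = c1,
                   call_second = c2, concordant = c1 == c2,
                   stringsAsFactors = FALSE)
  structure(list(pairs = pr, table = tab, n_pairs = nrow(pr),
                 n_discordant = sum(!pr$concordant),
                 discordance_rate = mean(!pr$concordant),
                 asymmetry_p = asym_p),
            class = "PairedSubtypeConcordance")
}

#' @export
print.PairedSubtypeConcordance <- function(x, ...) {
  cat(sprintf(
    "PairedSubtypeConcordance: %d/%d discordant (%.1f%%), asymmetry p = %.3g\n",
    x$n_discordant, x$n_pairs, 100 * x$discordance_rate, x$asymmetry_p))
  print(x$table)
  invisible(x)
}

#' Distribution-free confidence interval for a median
#'
#' Order-statistic (binomial) interval: the tightest symmetric pair of order
#' statistics whose binomial(n, 1/2) coverage reaches `conf`. Below n = 6 the
#' construction cannot reach 95% coverage, so a bootstrap percentile interval
#' of the median is used instead (degenerate for constant data).
#'
#' @param x Numeric vector.
#' @param conf Coverage (default 0.95).
#' @param n_boot Bootstrap resamples for the small-n fallback.
#' @return Numeric `c(lower, upper)`.
#' @export
median_ci <- function(x, conf = 0.95, n_boot = 2000) {
  x <- sort(x)
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_))
  if (n == 1) return(c(x, x))
  if (n < 6) {
    meds <- vapply(seq_len(n_boot), function(i)
      stats::median(sample(x, n, replace = TRUE)), numeric(1))
    return(unname(stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2))))
  }
  alpha <- 1 - conf
  l <- stats::qbinom(alpha / 2, n, 0.5)
  # widen until the order-statistic interval attains the nominal coverage
  while (l > 0 &&
         (stats::pbinom(n - l, n, 0.5) - stats::pbinom(l - 1, n, 0.5)) < conf)
    l <- l - 1
  c(x[max(l, 1)], x[min(n + 1 - l, n)])
}

#' Centroid-correlation margins of concordant vs discordant pairs
#'
#' Summarizes the absolute LumA-minus-LumB correlation margin separately for
#' pairs whose subtype calls agree and pairs whose calls flip, at each
#' timepoint: discordant calls are expected to sit at small margins
#' (uncertain assignments), concordant calls at large ones.
#'
#' @param calls A `SubtypeCalls` data.frame.
#' @param sheet A `SampleSheet`.
#' @return data.frame: `group` (concordant/discordant), `timepoint`, `n`,
#'   `median_abs_margin`, `ci_low`, `ci_high`. Empty groups are omitted with
#'   a note attribute.
#' @export
margin_summary <- function(calls, sheet) {
  conc <- paired_subtype_concordance(calls, sheet)
  pr <- conc$pairs
  pairs <- complete_pairs(sheet, calls$sample_id)
  m1 <- abs(calls$margin_lumA_lumB[match(pairs$first, calls$sample_id)])
  m2 <- abs(calls$margin_lumA_lumB[match(pairs$second, calls$sample_id)])
  rows <- list()
  notes <- character()
  for (grp in c("concordant", "discordant")) {
    sel <- if (grp == "concordant") pr$concordant else !pr$concordant
    for (tp in c("first", "second")) {
      m <- (if (tp == "first") m1 else m2)[sel]
      m <- m[!is.na(m)]
      if (!length(m)) {
        notes <- c(notes, paste0("group '", grp, "'/", tp, " empty; omitted"))
        next
      }
      ci <- median_ci(m)
      rows[[length(rows) + 1L]] <- data.frame(
        group = grp, timepoint = tp, n = length(m),
        median_abs_margin = stats::median(m),
        ci_low = ci[1], ci_high = ci[2], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "notes") <- notes
  out
}
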