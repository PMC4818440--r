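# QC and normalization for bead-array style expression matrices.
#
# Default recipe: log2(x + 1) -> detection-fraction sample filter (paired
# exclusion) -> undetected-probe filter -> quantile normalization -> per-batch
# gene-mean centering. Every stage is independently switchable and the
# PreprocessReport records what was done.

new_preprocess_report <- function(excluded_samples = data.frame(
                                    sample_id = character(),
                                    reason = character(),
                                    detection_fraction = numeric(),
                                    stringsAsFactors = FALSE),
                                  removed_probes = 0L,
                                  normalization = "none",
                                  batches_centered = character()) {
  structure(list(excluded_samples = excluded_samples,
                 removed_probes = as.integer(removed_probes),
                 normalization = normalization,
                 batches_centered = batches_centered),
            class = "PreprocessReport")
}

#' @export
print.PreprocessReport <- function(x, ...) {
  cat("PreprocessReport:\n",
      "  excluded samples: ", nrow(x$excluded_samples), "\n",
      "  removed probes:   ", x$removed_probes, "\n",
      "  normalization:    ", x$normalization, "\n", sep = "")
  invisible(x)
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param em An `ExpressionMatrix` on the linear scale.
#' @param offset Non-negative value added before taking logs (default 1).
#' @param already_log2 If `TRUE` the matrix is passed through unchanged.
#' @return An `ExpressionMatrix` on the log2 scale; detection flags unchanged.
#' @export
log2_transform <- function(em, offset = 1, already_log2 = FALSE) {
  if (already_log2) return(em)
  if (offset < 0) stop("offset must be >= 0", call. = FALSE)
  shifted <- em$values + offset
  if (any(shifted <= 0))
    stop("log2 transform undefined: value + offset <= 0 encountered",
         call. = FALSE)
  expression_matrix(log2(shifted), em$detected)
}

#' Exclude sample pairs failing the detection-fraction QC
#'
#' A sample whose fraction of detected probes falls below `min_fraction`
#' (strictly) is removed, and because every downstream statistic is paired,
#' its partner sample is removed with it. Both appear in the report with
#' their reason.
#'
#' @param em An `ExpressionMatrix` with meaningful detection flags.
#' @param sheet A `SampleSheet` covering the matrix samples.
#' @param min_fraction QC threshold on the detected fraction (default 0.30).
#' @return `list(matrix = ExpressionMatrix, report = PreprocessReport)`.
#' @export
filter_samples_by_detection <- function(em, sheet, min_fraction = 0.30) {
  frac <- detection_fraction(em)
  failing <- names(frac)[frac < min_fraction]
  partner_of <- function(sid) {
    row <- sheet[sheet$sample_id == sid, ]
    if (!nrow(row)) return(character())
    other <- sheet$sample_id[sheet$tumour_id == row$tumour_id &
                             sheet$sample_id != sid]
    intersect(other, sample_ids(em))
  }
  partners <- setdiff(unique(unlist(lapply(failing, partner_of))), failing)
  drop <- c(failing, partners)
  report <- new_preprocess_report(excluded_samples = data.frame(
    sample_id = drop,
    reason = c(rep("detection_fraction_below_threshold", length(failing)),
               rep("partner_of_excluded_sample", length(partners))),
    detection_fraction = unname(frac[drop]),
    stringsAsFactors = FALSE))
  keep <- setdiff(sample_ids(em), drop)
  list(matrix = em_subset(em, samples = keep), report = report)
}

#' Remove probes not detected in any sample
#'
#' @param em An `ExpressionMatrix`.
#' @return `list(matrix = ExpressionMatrix, report = PreprocessReport)`.
#' @export
filter_undetected_probes <- function(em) {
  keep <- rowSums(em$detected) > 0
  list(matrix = em_subset(em, probes = which(keep)),
       report = new_preprocess_report(removed_probes = sum(!keep)))
}

#' Quantile-normalize samples to a common distribution
#'
#' Every sample's sorted value vector is replaced by the across-sample mean
#' of sorted vectors; within-sample ranks are preserved and tied values
#' receive the average of the target values over the tied block.
#'
#' @param em An `ExpressionMatrix` with at least two samples.
#' @return An `ExpressionMatrix`.
#' @export
quantile_normalize <- function(em) {
  v <- em$values
  if (ncol(v) < 2) stop("quantile normalization needs >= 2 samples",
                        call. = FALSE)
  target <- rowMeans(apply(v, 2, sort))
  out <- apply(v, 2, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- target
    # ties share the mean of the target values over their whole block
    stats::ave(res, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(v)
  expression_matrix(out, em$detected)
}

#' Remove batch main effects by gene-wise batch-mean centering
#'
#' Per gene and per batch, the batch mean is subtracted and the global gene
#' mean added back, so per-batch gene means coincide afterwards while the
#' global gene mean is untouched. A batch of size one is centered to the
#' global mean with a warning (nothing can be learned from it).
#'
#' @param em An `ExpressionMatrix`.
#' @param sheet A `SampleSheet` supplying `batch_id` for every sample.
#' @return An `ExpressionMatrix`.
#' @export
batch_center <- function(em, sheet) {
  sids <- sample_ids(em)
  batch <- sheet$batch_id[match(sids, sheet$sample_id)]
  if (any(is.na(batch)))
    stop("batch_id missing for sample(s): ",
         paste(sids[is.na(batch)], collapse = ", "), call. = FALSE)
  sizes <- table(batch)
  if (any(sizes == 1))
    warning("batch(es) of size 1 centered to the global mean: ",
            paste(names(sizes)[sizes == 1], collapse = ", "), call. = FALSE)
  v <- em$values
  global <- rowMeans(v)
  out <- v
  for (b in unique(batch)) {
    cols <- which(batch == b)
    bm <- rowMeans(v[, cols, drop = FALSE])
    out[, cols] <- v[, cols, drop = FALSE] - bm + global
  }
  expression_matrix(out, em$detected)
}

#' Run the default preprocessing recipe
#'
#' @param em Raw `ExpressionMatrix`.
#' @param sheet A `SampleSheet`.
#' @param log2_offset Offset for [log2_transform()]; `NULL` skips it
#'   (matrix already on log2 scale).
#' @param min_detect_frac Sample QC threshold; `NULL` skips the sample filter.
#' @param drop_undetected Remove never-detected probes (default `TRUE`).
#' @param normalize `"quantile"` or `"none"`.
#' @param center_batches Apply [batch_center()] (default `TRUE`).
#' @return `list(matrix, report)` where the report aggregates all stages.
#' @export
preprocess_pipeline <- function(em, sheet, log2_offset = NULL,
                                min_detect_frac = 0.30,
                                drop_undetected = TRUE,
                                normalize = c("quantile", "none"),
                                center_batches = TRUE) {
  normalize <- match.arg(normalize)
  report <- new_preprocess_report()
  if (!is.null(log2_offset)) em <- log2_transform(em, log2_offset)
  if (!is.null(min_detect_frac)) {
    step <- filter_samples_by_detection(em, sheet, min_detect_frac)
    em <- step$matrix
    report$excluded_samples <- step$report$excluded_samples
  }
  if (drop_undetected) {
    step <- filter_undetected_probes(em)
    em <- step$matrix
    report$removed_probes <- step$report$removed_probes
  }
  if (normalize == "quantile") {
    em <- quantile_normalize(em)
    report$normalization <- "quantile"
  }
  if (center_batches) {
    em <- batch_center(em, sheet)
    batch <- sheet$batch_id[match(sample_ids(em), sheet$sample_id)]
    report$batches_centered <- unique(batch)
  }
  list(matrix = em, report = report)
}
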