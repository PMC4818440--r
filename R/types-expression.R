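#' Construct an ExpressionMatrix
#'
#' The central container of the package: a probe-by-sample matrix of log2
#' expression values together with a parallel logical matrix of detection
#' calls (probe detected above background in that sample). Probe and sample
#' identifiers are carried as the dimnames and must be unique.
#'
#' @param values Numeric matrix, probes in rows, samples in columns, with
#'   rownames (probe ids) and colnames (sample ids).
#' @param detected Logical matrix of the same shape, or `NULL` for
#'   all-detected.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(values, detected = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry probe ids as rownames and sample ids as colnames",
         call. = FALSE)
  if (is.null(detected)) {
    detected <- matrix(TRUE, nrow(values), ncol(values),
                       dimnames = dimnames(values))
  }
  if (!is.logical(detected) || !identical(dim(detected), dim(values)))
    stop("`detected` must be a logical matrix with the same shape as `values`",
         call. = FALSE)
  dimnames(detected) <- dimnames(values)
  em <- structure(list(values = values, detected = detected),
                  class = "ExpressionMatrix")
  validate_expression_matrix(em)
}

validate_expression_matrix <- function(em) {
  v <- em$values
  if (anyDuplicated(rownames(v)))
    stop("duplicate probe id: ",
         rownames(v)[duplicated(rownames(v))][1L], call. = FALSE)
  if (anyDuplicated(colnames(v)))
    stop("duplicate sample id: ",
         colnames(v)[duplicated(colnames(v))][1L], call. = FALSE)
  bad <- em$detected & !is.finite(v)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-finite value flagged as detected at probe '",
         rownames(v)[idx[1L]], "', sample '", colnames(v)[idx[2L]], "'",
         call. = FALSE)
  }
  em
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (%.1f%% detected)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$detected)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Probe and sample identifiers
#' @param em An `ExpressionMatrix`.
#' @return Character vector of identifiers.
#' @export
probe_ids <- function(em) rownames(em$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(em) colnames(em$values)

#' Subset an ExpressionMatrix by probe and/or sample
#'
#' @param em An `ExpressionMatrix`.
#' @param probes,samples Character, integer or logical index; `NULL` keeps all.
#' @return An `ExpressionMatrix`.
#' @export
em_subset <- function(em, probes = NULL, samples = NULL) {
  if (is.null(probes)) probes <- seq_len(nrow(em$values))
  if (is.null(samples)) samples <- seq_len(ncol(em$values))
  expression_matrix(em$values[probes, samples, drop = FALSE],
                    em$detected[probes, samples, drop = FALSE])
}

#' Fraction of detected probes per sample
#' @param em An `ExpressionMatrix`.
#' @return Named numeric vector in `[0, 1]`.
#' @export
detection_fraction <- function(em) colMeans(em$detected)
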