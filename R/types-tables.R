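#' Construct a SampleSheet
#'
#' Pairing metadata for a peri-surgical paired-biopsy design: each sample
#' belongs to a tumour and a timepoint (`"first"` for the baseline biopsy,
#' `"second"` for the later one), with a study label, a processing batch and
#' an optional elapsed time between the two biopsies in minutes (recorded per
#' tumour on the second sample in designs where samples were delayed by, for
#' example, specimen X-ray).
#'
#' @param df data.frame with columns `sample_id`, `tumour_id`, `timepoint`
#'   (`"first"`/`"second"`), `study_id`, `batch_id` and optionally
#'   `elapsed_minutes` (non-negative or `NA`).
#' @return A `SampleSheet` (a validated data.frame).
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "tumour_id", "timepoint", "study_id", "batch_id")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample sheet is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"elapsed_minutes" %in% names(df)) df$elapsed_minutes <- NA_real_
  df <- df[c(req, "elapsed_minutes")]
  for (col in req) df[[col]] <- as.character(df[[col]])
  df$elapsed_minutes <- as.numeric(df$elapsed_minutes)
  if (!all(df$timepoint %in% c("first", "second")))
    stop("timepoint must be 'first' or 'second'", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id: ", df$sample_id[duplicated(df$sample_id)][1L],
         call. = FALSE)
  if (any(!is.na(df$elapsed_minutes) & df$elapsed_minutes < 0))
    stop("elapsed_minutes must be non-negative", call. = FALSE)
  key <- paste(df$tumour_id, df$timepoint)
  if (anyDuplicated(key))
    stop("tumour '", df$tumour_id[duplicated(key)][1L],
         "' has more than one sample at the same timepoint", call. = FALSE)
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' Tumours with both timepoints present
#'
#' @param sheet A `SampleSheet`.
#' @param samples Optional character vector restricting to samples actually
#'   present (e.g. after QC); a pair must have both members in it.
#' @return data.frame with columns `tumour_id`, `first`, `second`,
#'   `elapsed_minutes` (taken from whichever row records it).
#' @export
complete_pairs <- function(sheet, samples = NULL) {
  if (!is.null(samples)) sheet <- sheet[sheet$sample_id %in% samples, ]
  f <- sheet[sheet$timepoint == "first", ]
  s <- sheet[sheet$timepoint == "second", ]
  common <- intersect(f$tumour_id, s$tumour_id)
  f <- f[match(common, f$tumour_id), ]
  s <- s[match(common, s$tumour_id), ]
  el <- ifelse(is.na(s$elapsed_minutes), f$elapsed_minutes, s$elapsed_minutes)
  data.frame(tumour_id = common, first = f$sample_id, second = s$sample_id,
             elapsed_minutes = el, stringsAsFactors = FALSE)
}

#' Construct a ProbeAnnotation table
#'
#' Maps platform probe ids to Entrez gene ids (the gene identifier used for
#' all gene-level matching) and a display symbol. A gene may be measured by
#' several probes; probe ids are unique.
#'
#' @param df data.frame with columns `probe_id`, `entrez_id`, `symbol`.
#' @return A `ProbeAnnotation` data.frame.
#' @export
probe_annotation <- function(df) {
  req <- c("probe_id", "entrez_id", "symbol")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("annotation is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[req]
  for (col in req) df[[col]] <- as.character(df[[col]])
  if (anyDuplicated(df$probe_id))
    stop("duplicate probe_id in annotation: ",
         df$probe_id[duplicated(df$probe_id)][1L], call. = FALSE)
  class(df) <- c("ProbeAnnotation", "data.frame")
  df
}

#' Construct a GeneSignature
#'
#' A named gene set with per-gene weights; the signature score of a sample is
#' the weighted average of its member genes' log2 expression.
#'
#' @param name Signature name.
#' @param entrez_id Character vector of Entrez gene ids.
#' @param weight Numeric weights, recycled from 1 if omitted.
#' @return A `GeneSignature`.
#' @export
gene_signature <- function(name, entrez_id, weight = rep(1, length(entrez_id))) {
  entrez_id <- as.character(entrez_id)
  if (!length(entrez_id)) stop("signature '", name, "' has no entries",
                               call. = FALSE)
  if (length(weight) != length(entrez_id))
    stop("weights and entrez ids differ in length", call. = FALSE)
  if (!all(is.finite(weight))) stop("signature weights must be finite",
                                    call. = FALSE)
  structure(list(name = name, entrez_id = entrez_id, weight = as.numeric(weight)),
            class = "GeneSignature")
}

#' @export
print.GeneSignature <- function(x, ...) {
  cat(sprintf("GeneSignature '%s': %d genes\n", x$name, length(x$entrez_id)))
  invisible(x)
}

#' Construct a CentroidSet
#'
#' Reference expression profiles (one per intrinsic subtype) used for
#' nearest-centroid classification: each sample is assigned to the subtype
#' whose centroid its profile correlates with most strongly.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids), one
#'   column per subtype (colnames = subtype labels). No missing values.
#' @return A `CentroidSet`.
#' @export
centroid_set <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("centroids must be a numeric matrix", call. = FALSE)
  if (ncol(values) < 2) stop("need at least 2 subtype centroids", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("centroid matrix needs gene ids (rownames) and subtype labels (colnames)",
         call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("duplicate gene id or subtype label in centroid set", call. = FALSE)
  if (any(!is.finite(values))) stop("centroid values must all be present and finite",
                                    call. = FALSE)
  structure(list(values = values), class = "CentroidSet")
}

#' @export
print.CentroidSet <- function(x, ...) {
  cat(sprintf("CentroidSet: %d genes x %d subtypes (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(colnames(x$values), collapse = ", ")))
  invisible(x)
}
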