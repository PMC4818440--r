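# Tab-delimited readers/writers for every table the pipeline touches.
# All formats round-trip losslessly: read_*(write_*(x)) reproduces x.

read_tsv_table <- function(path, skip_bang = FALSE) {
  df <- tryCatch(
    utils::read.delim(path, header = TRUE, sep = "\t", fill = FALSE,
                      comment.char = if (skip_bang) "!" else "",
                      check.names = FALSE, stringsAsFactors = FALSE,
                      colClasses = "character"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e),
                             call. = FALSE))
  if (!nrow(df) && !ncol(df)) stop("empty table: ", path, call. = FALSE)
  df
}

numeric_cells <- function(df, id_col, path) {
  ids <- df[[id_col]]
  m <- as.matrix(df[setdiff(names(df), id_col)])
  suppressWarnings(storage <- matrix(as.numeric(m), nrow(m), ncol(m),
                                     dimnames = list(ids, colnames(m))))
  bad <- is.na(storage) & !(is.na(m) | m %in% c("NA", ""))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at row '", ids[idx[1L]], "', column '",
         colnames(m)[idx[2L]], "' in ", path, call. = FALSE)
  }
  storage
}

#' Read an expression matrix from a tab-delimited file
#'
#' Expects probes as rows and samples as columns with the first column named
#' `probe_id`. GEO series-matrix-style files are supported through
#' `dialect = "geo"`, which skips `!`-prefixed header lines and accepts
#' `ID_REF` as the id column. Detection p-values may be supplied as a
#' companion file of identical layout; cells with p below `detection_alpha`
#' are flagged detected.
#'
#' @param path Path to the expression TSV.
#' @param dialect `"tsv"` (default) or `"geo"`.
#' @param detection_path Optional companion detection p-value TSV.
#' @param detection_alpha Detection call threshold on the p-value
#'   (default 0.05, the usual bead-array convention).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "geo"),
                                   detection_path = NULL,
                                   detection_alpha = 0.05) {
  dialect <- match.arg(dialect)
  df <- read_tsv_table(path, skip_bang = dialect == "geo")
  id_col <- if (names(df)[1L] %in% c("probe_id", "ID_REF")) names(df)[1L] else
    stop("first column must be 'probe_id' (or 'ID_REF' for dialect='geo'), got '",
         names(df)[1L], "' in ", path, call. = FALSE)
  vals <- numeric_cells(df, id_col, path)
  detected <- NULL
  if (!is.null(detection_path)) {
    ddf <- read_tsv_table(detection_path, skip_bang = dialect == "geo")
    dp <- numeric_cells(ddf, names(ddf)[1L], detection_path)
    if (!identical(dim(dp), dim(vals)))
      stop("detection file shape does not match expression file", call. = FALSE)
    dp <- dp[rownames(vals), colnames(vals), drop = FALSE]
    detected <- dp < detection_alpha
  }
  expression_matrix(vals, detected)
}

#' Write an expression matrix (and optionally its detection flags)
#'
#' @param em An `ExpressionMatrix`.
#' @param path Output TSV path.
#' @param detection_path If non-`NULL`, the detection flags are written there
#'   as pseudo p-values (0 for detected, 1 for not) so that re-reading with
#'   any alpha in (0, 1] restores the flags.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(em, path, detection_path = NULL) {
  df <- data.frame(probe_id = probe_ids(em), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(detection_path)) {
    dp <- ifelse(em$detected, 0, 1)
    ddf <- data.frame(probe_id = probe_ids(em), dp,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(ddf, detection_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a sample sheet
#'
#' Columns: `sample_id`, `tumour_id`, `timepoint` (first/second), `study_id`,
#' `batch_id`, `elapsed_minutes` (optional, minutes between the paired
#' biopsies).
#'
#' @param path TSV path.
#' @return A [sample_sheet()].
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet A `SampleSheet`.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a probe annotation table
#'
#' Columns: `probe_id`, `entrez_id`, `symbol`.
#' @param path TSV path.
#' @return A [probe_annotation()].
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  probe_annotation(df)
}

#' @rdname read_annotation
#' @param ann A `ProbeAnnotation`.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a gene signature
#'
#' Columns: `entrez_id` and optionally `weight`; absent weights default
#' to 1.
#'
#' @param path TSV path.
#' @param name Signature name; defaults to the file stem.
#' @return A [gene_signature()].
#' @export
read_signature <- function(path, name = NULL) {
  if (is.null(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (!"entrez_id" %in% names(df))
    stop("signature file must have an 'entrez_id' column: ", path,
         call. = FALSE)
  w <- if ("weight" %in% names(df)) as.numeric(df$weight) else
    rep(1, nrow(df))
  gene_signature(name, df$entrez_id, w)
}

#' @rdname read_signature
#' @param sig A `GeneSignature`.
#' @export
write_signature <- function(sig, path) {
  df <- data.frame(entrez_id = sig$entrez_id, weight = sig$weight,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a centroid table
#'
#' First column `gene_id`, then one numeric column per subtype.
#'
#' @param path TSV path.
#' @return A [centroid_set()].
#' @export
read_centroids <- function(path) {
  df <- read_tsv_table(path)
  if (names(df)[1L] != "gene_id")
    stop("centroid file must start with a 'gene_id' column: ", path,
         call. = FALSE)
  centroid_set(numeric_cells(df, "gene_id", path))
}

#' @rdname read_centroids
#' @param cen A `CentroidSet`.
#' @export
write_centroids <- function(cen, path) {
  df <- data.frame(gene_id = rownames(cen$values), cen$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
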