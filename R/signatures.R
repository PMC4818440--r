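# Gene-signature (metagene) scoring and paired tests of signature change.

#' Score a gene signature in every sample
#'
#' The score of sample s is the weighted average
#' `sum_g w_g * x_gs / sum_g |w_g|` over the signature genes matched in the
#' matrix. Entrez ids are mapped to probes through the annotation; when a
#' gene is measured by several probes, the probes are averaged first so that
#' probe multiplicity does not tilt the weighting. Unmatched ids (genes not
#' represented on the platform) are reported, not silently dropped.
#'
#' @param em An `ExpressionMatrix` (log2 scale).
#' @param annotation A `ProbeAnnotation`.
#' @param signature A `GeneSignature`.
#' @param probe_level If `TRUE`, weight at the probe level instead of
#'   averaging probes per gene first.
#' @return list of class `SignatureScore`: `name`, `scores` (named numeric
#'   per sample), `n_genes_matched`, `unmatched` (entrez ids).
#' @export
score_signature <- function(em, annotation, signature, probe_level = FALSE) {
  ann <- annotation[annotation$probe_id %in% probe_ids(em), ]
  gene_rows <- lapply(signature$entrez_id, function(g)
    ann$probe_id[ann$entrez_id == g])
  matched <- lengths(gene_rows) > 0
  if (!any(matched))
    stop("no gene of signature '", signature$name,
         "' matched a probe in the matrix", call. = FALSE)
  w <- signature$weight[matched]
  rows <- gene_rows[matched]
  if (probe_level) {
    w <- rep(w, lengths(rows))
    gx <- em$values[unlist(rows), , drop = FALSE]
  } else {
    gx <- t(vapply(rows, function(pr)
      colMeans(em$values[pr, , drop = FALSE]), numeric(ncol(em$values))))
  }
  scores <- colSums(gx * w) / sum(abs(w))
  structure(list(name = signature$name, scores = scores,
                 n_genes_matched = sum(matched),
                 unmatched = signature$entrez_id[!matched]),
            class = "SignatureScore")
}

#' @export
print.SignatureScore <- function(x, ...) {
  cat(sprintf("SignatureScore '%s': %d genes matched, %d unmatched\n",
              x$name, x$n_genes_matched, length(x$unmatched)))
  invisible(x)
}

#' Score several signatures into one sample-by-signature table
#'
#' @param em,annotation As in [score_signature()].
#' @param signatures A list of `GeneSignature` objects.
#' @return data.frame: `sample_id` plus one column per signature.
#' @export
score_signatures <- function(em, annotation, signatures) {
  out <- data.frame(sample_id = sample_ids(em), stringsAsFactors = FALSE)
  for (sig in signatures)
    out[[sig$name]] <- unname(score_signature(em, annotation, sig)$scores)
  out
}

#' Paired test of signature-score change between timepoints
#'
#' @param scores Named numeric vector of per-sample scores (e.g.
#'   `score_signature(...)$scores`).
#' @param sheet A `SampleSheet`.
#' @param method `"wilcoxon"` (matched-pairs signed rank, default) or
#'   `"paired_t"`.
#' @return list: `statistic`, `p`, `n_pairs`, `method`, `mean_diff`.
#' @export
paired_signature_test <- function(scores, sheet,
                                  method = c("wilcoxon", "paired_t")) {
  method <- match.arg(method)
  pairs <- complete_pairs(sheet, names(scores))
  x <- scores[pairs$first]
  y <- scores[pairs$second]
  d <- y - x
  if (method == "wilcoxon" && length(d) < 5)
    stop("Wilcoxon signed-rank test needs >= 5 pairs", call. = FALSE)
  if (all(d == 0))
    return(list(statistic = NA_real_, p = 1, n_pairs = length(d),
                method = method, mean_diff = 0))
  ht <- if (method == "wilcoxon")
    stats::wilcox.test(y, x, paired = TRUE, exact = length(d) < 50)
  else
    stats::t.test(y, x, paired = TRUE)
  list(statistic = unname(ht$statistic), p = ht$p.value,
       n_pairs = length(d), method = method, mean_diff = mean(d))
}

# Entrez ids for the bundled panels (standard human Entrez Gene ids).
.jeselsohn13 <- c(IGFBP2 = "3485", IL6 = "3569", CD68 = "968", CD14 = "929",
                  CD52 = "1043", CD44 = "960", PPARG = "5468", ADM = "133",
                  VEGFA = "7422", CENPF = "1063", MYC = "4609", CCNB1 = "891",
                  MAP1LC3B = "81631")
# Breast-cancer panel members whose identities are public; the remaining
# members of the 18-gene panel are not printed in any open source, so the
# bundled set is deliberately partial (see the methods vignette).
.breast_panel <- c(BAG1 = "573", MKI67 = "4288", MAPT = "4137", PGR = "5241",
                   SNAI2 = "6591", GPR160 = "26996", TFF1 = "7031",
                   ERBB2 = "2064")

#' Built-in gene sets
#'
#' Bundles the gene sets for which full memberships are public:
#' `"jeselsohn13"` — the 13 genes (of 14; SNAI1 has no probe on the Illumina
#' HT-12 platform) reported to change between diagnostic core-cut and
#' surgical excision in an earlier paired-biopsy study — and
#' `"breast_panel"` — commonly studied breast-cancer genes (partial panel;
#' see Details). The wound-healing and immune-response metagenes are *not*
#' bundled: their memberships and weights live in their source publications
#' and must be supplied as signature files.
#'
#' @details All weights are 1 (equal weighting); supply your own file via
#'   [read_signature()] for weighted metagenes.
#' @param which `NULL` for all bundled sets, or a character vector of names.
#' @return Named list of `GeneSignature` objects.
#' @export
builtin_gene_sets <- function(which = NULL) {
  sets <- list(
    jeselsohn13 = gene_signature("jeselsohn13", unname(.jeselsohn13)),
    breast_panel = gene_signature("breast_panel", unname(.breast_panel))
  )
  attr(sets$jeselsohn13, "symbols") <- names(.jeselsohn13)
  attr(sets$breast_panel, "symbols") <- names(.breast_panel)
  if (is.null(which)) return(sets)
  not_bundled <- setdiff(which, names(sets))
  if (length(not_bundled))
    stop("gene set(s) not bundled: ", paste(not_bundled, collapse = ", "),
         ". Wound-healing and immune metagenes must be supplied as ",
         "signature files (their memberships are published elsewhere).",
         call. = FALSE)
  sets[which]
}
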