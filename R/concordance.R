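# Within-pair concordance: whole-profile correlations, per-gene cross-pair
# correlations, and dendrogram pair-adjacency.

#' Whole-profile correlation between the two biopsies of each tumour
#'
#' For every complete pair the Pearson and Spearman correlations are computed
#' across probes between the first- and second-timepoint profiles. Probes
#' with a missing value in either member are dropped from that pair's
#' computation and the number actually used recorded.
#'
#' @param em An `ExpressionMatrix` (log2 scale).
#' @param sheet A `SampleSheet`.
#' @return data.frame: `tumour_id`, `r_pearson`, `r_spearman`, `n_probes`.
#' @export
profile_correlation <- function(em, sheet) {
  pairs <- complete_pairs(sheet, sample_ids(em))
  if (!nrow(pairs)) stop("no complete pairs among matrix samples",
                         call. = FALSE)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- em$values[, pairs$first[i]]
    y <- em$values[, pairs$second[i]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 2) stop("fewer than 2 usable probes for tumour ",
                            pairs$tumour_id[i], call. = FALSE)
    rp <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      warning("zero-variance profile for tumour ", pairs$tumour_id[i],
              "; correlation undefined", call. = FALSE)
      NaN
    } else stats::cor(x, y)
    rs <- suppressWarnings(stats::cor(x, y, method = "spearman"))
    data.frame(tumour_id = pairs$tumour_id[i], r_pearson = rp,
               r_spearman = rs, n_probes = length(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Per-gene correlation between first- and second-biopsy expression
#'
#' For each probe, the Pearson correlation across tumours between the
#' first-sample and second-sample values, with a two-sided p-value from the
#' exact t transform (`t = r * sqrt((n-2)/(1-r^2))` on `n - 2` df). Also
#' reports the probe's dynamic range (max - min of log2 expression over all
#' samples), the quantity that in practice governs how reproducible a gene's
#' paired measurement is.
#'
#' @param em An `ExpressionMatrix`.
#' @param sheet A `SampleSheet`.
#' @param probes Optional subset of probe ids (default: all).
#' @return data.frame: `probe_id`, `r`, `p`, `n_pairs`, `dynamic_range_log2`.
#' @export
gene_pair_correlation <- function(em, sheet, probes = NULL) {
  pairs <- complete_pairs(sheet, sample_ids(em))
  if (nrow(pairs) < 4)
    stop("gene_pair_correlation needs >= 4 complete pairs, got ",
         nrow(pairs), call. = FALSE)
  if (is.null(probes)) probes <- probe_ids(em)
  X <- em$values[probes, pairs$first, drop = FALSE]
  Y <- em$values[probes, pairs$second, drop = FALSE]
  n <- nrow(pairs)
  r <- vapply(seq_along(probes), function(i) {
    suppressWarnings(stats::cor(X[i, ], Y[i, ]))
  }, numeric(1))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  rng <- apply(em$values[probes, , drop = FALSE], 1, function(v)
    diff(range(v[is.finite(v)])))
  data.frame(probe_id = probes, r = r, p = p, n_pairs = n,
             dynamic_range_log2 = unname(rng), stringsAsFactors = FALSE)
}

#' Hierarchically cluster samples
#'
#' Agglomerative clustering of the sample profiles, by default with
#' Euclidean distance and average linkage (UPGMA). `stats::hclust` resolves
#' distance ties by the lowest merged-cluster index, so the tree is
#' deterministic given the input sample order.
#'
#' @param em An `ExpressionMatrix` with >= 2 samples.
#' @param metric Distance metric passed to [stats::dist()].
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `hclust` over the samples.
#' @export
hierarchical_cluster <- function(em, metric = "euclidean",
                                 linkage = "average") {
  if (ncol(em$values) < 2) stop("clustering needs >= 2 samples",
                                call. = FALSE)
  d <- stats::dist(t(em$values), method = metric)
  stats::hclust(d, method = linkage)
}

#' Export a sample dendrogram as a Newick string
#'
#' @param hc An `hclust` tree from [hierarchical_cluster()].
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  phy <- ape::as.phylo(hc)
  if (is.null(path)) return(ape::write.tree(phy))
  ape::write.tree(phy, file = path)
  invisible(ape::write.tree(phy))
}

#' Fraction of biopsy pairs that cluster together
#'
#' A pair counts as "clustered together" iff its two samples are sibling
#' leaves of the dendrogram — their first merge joins exactly those two
#' leaves. This is the strictest reading of pair adjacency and is invariant
#' to sample input order.
#'
#' @param hc An `hclust` tree over the samples.
#' @param sheet A `SampleSheet`.
#' @return list of class `ClusterConcordance`: `n_pairs_total`,
#'   `n_pairs_adjacent`, `fraction`, and the adjacent tumour ids.
#' @export
pair_adjacency_concordance <- function(hc, sheet) {
  labels <- hc$labels
  all_pairs <- complete_pairs(sheet)
  in_tree <- cbind(all_pairs$first %in% labels, all_pairs$second %in% labels)
  half <- xor(in_tree[, 1], in_tree[, 2])
  if (any(half))
    stop("sample missing from tree for tumour(s): ",
         paste(all_pairs$tumour_id[half], collapse = ", "), call. = FALSE)
  pairs <- all_pairs[in_tree[, 1] & in_tree[, 2], , drop = FALSE]
  # sibling leaves: merge rows joining two negative (leaf) entries
  leaf_merges <- hc$merge[hc$merge[, 1] < 0 & hc$merge[, 2] < 0, , drop = FALSE]
  sib_keys <- apply(leaf_merges, 1, function(m) {
    paste(sort(labels[-m]), collapse = "\r")
  })
  pair_keys <- vapply(seq_len(nrow(pairs)), function(i)
    paste(sort(c(pairs$first[i], pairs$second[i])), collapse = "\r"),
    character(1))
  adjacent <- pair_keys %in% sib_keys
  structure(list(n_pairs_total = nrow(pairs),
                 n_pairs_adjacent = sum(adjacent),
                 fraction = if (nrow(pairs)) sum(adjacent) / nrow(pairs)
                            else NaN,
                 adjacent_tumours = pairs$tumour_id[adjacent]),
            class = "ClusterConcordance")
}

#' @export
print.ClusterConcordance <- function(x, ...) {
  cat(sprintf("ClusterConcordance: %d/%d pairs adjacent (%.1f%%)\n",
              x$n_pairs_adjacent, x$n_pairs_total, 100 * x$fraction))
  invisible(x)
}
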