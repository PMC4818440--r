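# Fisher r-to-z comparison of a gene's pair correlation between two
# independent studies.

#' Compare two correlation coefficients via the Fisher r-to-z transform
#'
#' `z_i = atanh(r_i)`; the test statistic is
#' `Z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))` with a two-tailed standard
#' normal p. Values are reported raw and rounded to the conventional table
#' precision (Z to 2 d.p., p to 4 d.p.); `p_from_rounded_z` is the two-tail p
#' recomputed from the rounded Z, which is what printed tables typically
#' carry.
#'
#' @param r1,n1 Correlation and sample size in study 1.
#' @param r2,n2 Correlation and sample size in study 2.
#' @return list of class `CorrelationComparison`: `z1`, `z2`, `z_stat`,
#'   `p_two_tail`, `z_rounded`, `p_rounded`, `p_from_rounded_z`.
#' @export
fisher_r_to_z_compare <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3)
    stop("Fisher r-to-z comparison undefined for n <= 3", call. = FALSE)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 (atanh diverges at |r| = 1)", call. = FALSE)
  z1 <- atanh(r1)
  z2 <- atanh(r2)
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (z1 - z2) / se
  p <- 2 * stats::pnorm(-abs(z))
  zr <- round(z, 2)
  structure(list(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
                 z1 = z1, z2 = z2, z_stat = z, p_two_tail = p,
                 z_rounded = zr, p_rounded = round(p, 4),
                 p_from_rounded_z = 2 * stats::pnorm(-abs(zr))),
            class = "CorrelationComparison")
}

#' @export
print.CorrelationComparison <- function(x, ...) {
  cat(sprintf("Fisher r-to-z: r1=%.3f (n=%d) vs r2=%.3f (n=%d): Z = %.2f, p = %.4f\n",
              x$r1, x$n1, x$r2, x$n2, x$z_stat, x$p_two_tail))
  invisible(x)
}

#' Per-gene cross-study comparison table
#'
#' Joins two per-gene correlation tables (as produced by
#' [gene_pair_correlation()], with a `gene` or `probe_id` key column plus `r`
#' and `n_pairs`) and applies [fisher_r_to_z_compare()] to every gene present
#' in both. Genes missing from either study — e.g. not detected on one
#' platform — are kept as `ND` rows with `NA` statistics rather than dropped.
#'
#' @param study1,study2 data.frames with columns `gene` (or `probe_id`),
#'   `r`, `n_pairs`.
#' @param genes Optional character vector ordering/limiting the output rows;
#'   default: union of both studies' genes.
#' @return data.frame: `gene`, `r1`, `n1`, `r2`, `n2`, `z_stat`,
#'   `p_two_tail`, `status` (`"ok"` or `"ND"`).
#' @export
compare_gene_table <- function(study1, study2, genes = NULL) {
  key <- function(df) if ("gene" %in% names(df)) df$gene else df$probe_id
  k1 <- key(study1); k2 <- key(study2)
  if (is.null(genes)) genes <- union(k1, k2)
  if (!length(genes))
    return(data.frame(gene = character(), r1 = numeric(), n1 = integer(),
                      r2 = numeric(), n2 = integer(), z_stat = numeric(),
                      p_two_tail = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(genes, function(g) {
    i1 <- match(g, k1); i2 <- match(g, k2)
    if (is.na(i1) || is.na(i2)) {
      return(data.frame(gene = g,
                        r1 = if (is.na(i1)) NA_real_ else study1$r[i1],
                        n1 = if (is.na(i1)) NA_integer_ else study1$n_pairs[i1],
                        r2 = if (is.na(i2)) NA_real_ else study2$r[i2],
                        n2 = if (is.na(i2)) NA_integer_ else study2$n_pairs[i2],
                        z_stat = NA_real_, p_two_tail = NA_real_,
                        status = "ND", stringsAsFactors = FALSE))
    }
    cmp <- fisher_r_to_z_compare(study1$r[i1], study1$n_pairs[i1],
                                 study2$r[i2], study2$n_pairs[i2])
    data.frame(gene = g, r1 = cmp$r1, n1 = cmp$n1, r2 = cmp$r2, n2 = cmp$n2,
               z_stat = cmp$z_stat, p_two_tail = cmp$p_two_tail,
               status = "ok", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
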