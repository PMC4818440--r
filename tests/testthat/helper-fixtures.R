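# Fixture builders shared across the suite. Everything is constructed in
# code; no binary fixtures.

# probe-by-sample matrix with ids p1..pn / s1..sm
make_em <- function(values, detected = NULL) {
  values <- as.matrix(values)
  rownames(values) <- sprintf("p%d", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%d", seq_len(ncol(values)))
  if (!is.null(detected)) {
    detected <- as.matrix(detected)
    dimnames(detected) <- dimnames(values)
  }
  expression_matrix(values, detected)
}

# a paired design: n tumours, samples <Txx>_1 / <Txx>_2
make_pair_sheet <- function(n, study = "S", batch = "B1", minutes = NULL) {
  tum <- sprintf("T%02d", seq_len(n))
  sample_sheet(data.frame(
    sample_id = c(paste0(tum, "_1"), paste0(tum, "_2")),
    tumour_id = rep(tum, 2),
    timepoint = rep(c("first", "second"), each = n),
    study_id = study,
    batch_id = batch,
    elapsed_minutes = c(rep(NA_real_, n),
                        if (is.null(minutes)) rep(NA_real_, n) else minutes),
    stringsAsFactors = FALSE))
}

# build an ExpressionMatrix from a genes x pairs matrix of first-biopsy
# values and a matrix of within-pair differences (second = first + d)
make_paired_em <- function(first_vals, diffs) {
  n <- ncol(first_vals)
  vals <- cbind(first_vals, first_vals + diffs)
  rownames(vals) <- sprintf("p%d", seq_len(nrow(vals)))
  colnames(vals) <- c(sprintf("T%02d_1", seq_len(n)),
                      sprintf("T%02d_2", seq_len(n)))
  expression_matrix(vals)
}

# brute-force BH step-up straight from the definition:
# q_i = min over j with p_(j) >= p_(i) of p_(j) * m / j
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- vapply(seq_len(m), function(i) {
    js <- which(ps >= ps[i])
    min(1, min(ps[js] * m / js))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q
  out
}
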