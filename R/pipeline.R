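# End-to-end driver: simulate two studies, preprocess, run every analysis,
# and compare the studies' per-gene correlations — writing all artifacts and
# a manifest so a run is regenerable from config + seed alone.

#' Build a pipeline run configuration
#'
#' @param seed Integer seed driving both simulated studies (study II uses
#'   `seed + 1`).
#' @param n_tumours1,n_tumours2 Pair counts of the two simulated studies
#'   (defaults 23 and 56; study I carries the elapsed-time covariate).
#' @param n_genes Genes per simulated study.
#' @param min_detect_frac,fdr_max,fc_min,p_screen Analysis thresholds.
#' @param n_perm Sign-flip permutations.
#' @param subtype_method Correlation used for subtyping.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(seed, n_tumours1 = 23, n_tumours2 = 56,
                       n_genes = 500, min_detect_frac = 0.30,
                       fdr_max = 0.05, fc_min = 1.25, p_screen = 0.005,
                       n_perm = 1000,
                       subtype_method = c("spearman", "pearson")) {
  if (missing(seed)) stop("a run seed is mandatory", call. = FALSE)
  subtype_method <- match.arg(subtype_method)
  stopifnot(min_detect_frac >= 0, min_detect_frac <= 1,
            fdr_max > 0, fdr_max <= 1, fc_min >= 1, p_screen > 0)
  structure(as.list(environment()), class = "RunConfig")
}

write_df <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# probe ids g0001... -> a synthetic Entrez-style annotation
synthetic_annotation <- function(em) {
  probe_annotation(data.frame(
    probe_id = probe_ids(em),
    entrez_id = sub("^g0*", "", probe_ids(em)),
    symbol = toupper(probe_ids(em)),
    stringsAsFactors = FALSE))
}

#' Run the full simulated-cohort pipeline
#'
#' Chains simulate (two studies) -> preprocess -> concordance -> diffexp
#' (+ elapsed-time analysis for study I) -> signatures -> subtype ->
#' cross-study correlation comparison, writing every stage's outputs under
#' `out_dir` plus `manifest.json` recording the package version, seed, the
#' effective configuration and an md5 checksum per artifact.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character()
  artifacts <- character()
  keep <- function(stage, paths) {
    stages <<- unique(c(stages, stage))
    artifacts <<- c(artifacts, paths)
  }

  shift <- stats::setNames(c(1, -0.6), c("g0001", "g0002"))
  cohorts <- list(
    I = generate_cohort(simulation_config(
      n_tumours = config$n_tumours1, n_genes = config$n_genes,
      shift_genes = shift,
      time_model = list(minutes_range = c(20, 60),
                        slope_genes = c(g0003 = 0.01)),
      study_id = "I", seed = config$seed)),
    II = generate_cohort(simulation_config(
      n_tumours = config$n_tumours2, n_genes = config$n_genes,
      shift_genes = shift, time_model = NULL,
      study_id = "II", seed = config$seed + 1)))

  gene_tabs <- list()
  for (nm in names(cohorts)) {
    co <- cohorts[[nm]]
    sd_ <- file.path(out_dir, paste0("study", nm))
    dir.create(sd_, showWarnings = FALSE)
    keep("simulate", c(
      write_expression_matrix(co$matrix, file.path(sd_, "expr.tsv"),
                              file.path(sd_, "expr.detection.tsv")),
      file.path(sd_, "expr.detection.tsv"),
      write_sample_sheet(co$sheet, file.path(sd_, "sheet.tsv")),
      write_centroids(co$centroids, file.path(sd_, "centroids.tsv"))))

    pp <- preprocess_pipeline(co$matrix, co$sheet,
                              min_detect_frac = config$min_detect_frac)
    em <- pp$matrix
    keep("preprocess", c(
      write_expression_matrix(em, file.path(sd_, "expr.norm.tsv")),
      local({
        p <- file.path(sd_, "preprocess_report.json")
        jsonlite::write_json(unclass(pp$report), p, auto_unbox = TRUE,
                             digits = NA)
        p
      })))

    pc <- profile_correlation(em, co$sheet)
    gc <- gene_pair_correlation(em, co$sheet)
    hc <- hierarchical_cluster(em)
    cc <- pair_adjacency_concordance(hc, co$sheet)
    keep("concordance", c(
      write_df(pc, file.path(sd_, "pair_correlations.tsv")),
      write_df(gc, file.path(sd_, "gene_correlations.tsv")),
      local({
        p <- file.path(sd_, "cluster_concordance.json")
        jsonlite::write_json(unclass(cc), p, auto_unbox = TRUE, digits = NA)
        p
      }),
      local({
        p <- file.path(sd_, "dendrogram.nwk")
        dendrogram_newick(hc, p)
        p
      })))
    gene_tabs[[nm]] <- gc

    de <- paired_diffexp(em, co$sheet, n_perm = config$n_perm,
                         seed = config$seed)
    sel <- select_de(de, fdr_max = config$fdr_max, fc_min = config$fc_min)
    de$selected <- de$probe_id %in% sel
    de_paths <- write_df(de, file.path(sd_, "de.tsv"))
    if (nm == "I") {
      tc <- time_correlation(em, co$sheet)
      de_paths <- c(de_paths, write_df(tc, file.path(sd_, "time_correlation.tsv")))
    }
    keep("diffexp", de_paths)

    ann <- synthetic_annotation(em)
    sig <- gene_signature("shifted_panel", ann$entrez_id[
      match(names(shift), ann$probe_id)])
    sc <- score_signatures(em, ann, list(sig))
    tst <- paired_signature_test(
      stats::setNames(sc$shifted_panel, sc$sample_id), co$sheet)
    sc_path <- write_df(sc, file.path(sd_, "signature_scores.tsv"))
    tst_path <- file.path(sd_, "signature_test.json")
    jsonlite::write_json(tst, tst_path, auto_unbox = TRUE, digits = NA)
    keep("signatures", c(sc_path, tst_path))

    calls <- classify_subtypes(em, co$centroids, method = config$subtype_method)
    conc <- paired_subtype_concordance(calls, co$sheet)
    ms <- margin_summary(calls, co$sheet)
    keep("subtype", c(
      write_df(as.data.frame(calls), file.path(sd_, "subtype_calls.tsv")),
      local({
        p <- file.path(sd_, "subtype_concordance.json")
        jsonlite::write_json(list(
          n_pairs = conc$n_pairs, n_discordant = conc$n_discordant,
          discordance_rate = conc$discordance_rate,
          asymmetry_p = conc$asymmetry_p,
          table = as.data.frame(conc$table)), p, auto_unbox = TRUE,
          digits = NA)
        p
      }),
      write_df(ms, file.path(sd_, "margin_summary.tsv"))))
  }

  cmp <- compare_gene_table(gene_tabs$I, gene_tabs$II)
  keep("compare-correlations",
       write_df(cmp, file.path(out_dir, "cross_study_comparison.tsv")))

  manifest <- list(
    package = "pairedconcord",
    version = as.character(utils::packageVersion("pairedconcord")),
    seed = config$seed,
    config = unclass(config),
    stages = stages,
    checksums = as.list(tools::md5sum(sort(unique(artifacts)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarize a locally supplied cohort against published reference figures
#'
#' For users who have downloaded the deposited paired-biopsy series
#' themselves: given an expression matrix and sheet already preprocessed with
#' the default recipe, recomputes the dendrogram pair-adjacency count and,
#' if an annotation is given, the MYC geometric-mean ratio, and *reports*
#' the deviation from supplied reference values rather than asserting —
#' the deposited data's exact supplementary normalization is not public, so
#' exact agreement is not guaranteed.
#'
#' @param em,sheet Preprocessed matrix and sheet.
#' @param annotation Optional `ProbeAnnotation` (to locate MYC, Entrez 4609).
#' @param reference Optional list with any of `n_pairs_adjacent`,
#'   `myc_gm_ratio` to diff against.
#' @return list: `n_pairs_total`, `n_pairs_adjacent`, `fraction`,
#'   `myc_gm_ratio` (or `NA`), and `deviations` (named numeric).
#' @export
geo_reproduction_summary <- function(em, sheet, annotation = NULL,
                                     reference = list()) {
  cc <- pair_adjacency_concordance(hierarchical_cluster(em), sheet)
  myc <- NA_real_
  if (!is.null(annotation)) {
    pr <- annotation$probe_id[annotation$entrez_id == "4609"]
    pr <- intersect(pr, probe_ids(em))
    if (length(pr))
      myc <- mean(geometric_mean_ratio(em, sheet, probes = pr)$gm_ratio)
  }
  dev <- c()
  if (!is.null(reference$n_pairs_adjacent))
    dev["n_pairs_adjacent"] <- cc$n_pairs_adjacent - reference$n_pairs_adjacent
  if (!is.null(reference$myc_gm_ratio) && is.finite(myc))
    dev["myc_gm_ratio"] <- myc - reference$myc_gm_ratio
  list(n_pairs_total = cc$n_pairs_total,
       n_pairs_adjacent = cc$n_pairs_adjacent,
       fraction = cc$fraction, myc_gm_ratio = myc,
       deviations = as.list(dev))
}
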