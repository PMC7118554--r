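#' Write a cohort to plain-text files
#'
#' One tab-delimited time-series file per subject (T rows x N regions,
#' header = region ids), a phenotype CSV (subject_id, group, gender,
#' education, hamd, hama; clinical columns empty for controls), an atlas
#' TSV (region_id, region_name, network_name) and a ground-truth JSON.
#'
#' @param cohort a `dfc_cohort`.
#' @param dir output directory (created if needed).
#' @param atlas optional atlas table; defaults to [make_atlas()] over the
#'   cohort's regions.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, atlas = NULL) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in cohort$subjects) {
    utils::write.table(
      s$timeseries,
      file.path(dir, "timeseries", paste0(s$subject_id, ".tsv")),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  pheno <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    group = cohort_labels(cohort),
    cohort_covariates(cohort), cohort_clinical(cohort))
  utils::write.csv(pheno, file.path(dir, "phenotype.csv"), row.names = FALSE,
                   na = "")
  if (is.null(atlas)) atlas <- make_atlas(cohort$spec$n_regions)
  utils::write.table(atlas, file.path(dir, "atlas.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  gt <- cohort$ground_truth
  jsonlite::write_json(
    list(effect_edges = gt$effect_edges,
         clinical_couplings = gt$clinical_couplings,
         window_width = gt$window_width, window_step = gt$window_step),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding `timeseries/`, `phenotype.csv` and
#'   (optionally) `ground_truth.json`.
#' @return a `dfc_cohort` (spec fields limited to what the files record).
#' @export
read_cohort <- function(dir) {
  pheno <- utils::read.csv(file.path(dir, "phenotype.csv"))
  subjects <- lapply(seq_len(nrow(pheno)), function(k) {
    ts <- as.matrix(utils::read.delim(
      file.path(dir, "timeseries", paste0(pheno$subject_id[k], ".tsv")),
      check.names = FALSE))
    structure(list(subject_id = pheno$subject_id[k], timeseries = ts,
                   group = as.integer(pheno$group[k]),
                   gender = pheno$gender[k], education = pheno$education[k],
                   hamd = if (is.null(pheno$hamd)) NA_real_ else
                     as.numeric(pheno$hamd[k]),
                   hama = if (is.null(pheno$hama)) NA_real_ else
                     as.numeric(pheno$hama[k])),
              class = "subject_record")
  })
  gt_path <- file.path(dir, "ground_truth.json")
  gt <- NULL
  ww <- ws <- NULL
  if (file.exists(gt_path)) {
    g <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    ww <- g$window_width; ws <- g$window_step
    gt <- structure(list(
      effect_edges = as.data.frame(g$effect_edges),
      clinical_couplings = if (is.null(g$clinical_couplings)) NULL else
        as.data.frame(g$clinical_couplings),
      window_width = ww, window_step = ws), class = "ground_truth")
  }
  Tn <- nrow(subjects[[1L]]$timeseries)
  spec <- list(n_regions = ncol(subjects[[1L]]$timeseries),
               n_timepoints = Tn,
               window_width = if (is.null(ww)) min(50L, Tn) else ww,
               window_step = if (is.null(ws)) 2L else ws)
  structure(list(subjects = subjects, ground_truth = gt, spec = spec),
            class = "dfc_cohort")
}
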