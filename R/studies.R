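# Study drivers shared by the analysis scripts, the test suite and the
# acceptance script. Problem sizes default to the desk scale the package's
# simulation studies use: 30 regions, 40+40 subjects, T = 200 at TR = 2 s.

#' Coarse desk-scale hyperparameter grids
#'
#' A thinned power-of-two grid used by the simulation studies: C over
#' 2^{0,2,4,6}, gamma over 2^{-9,-7,-5,-3} (gamma centered near 1/p for
#' screened feature counts in the tens to hundreds).
#' @export
study_grids <- function() {
  list(cost = 2^c(0, 2, 4, 6), gamma = 2^c(-9, -7, -5, -3))
}

# distinct region pairs of a set of feature columns
selected_edges <- function(columns, index) {
  if (!length(columns)) return(character(0))
  d <- decode_features(index, columns)
  unique(paste(d$i, d$j, sep = "-"))
}

#' Parameter-recovery study: planted transient edges vs the selected subset
#'
#' For each seed, generates a transient-effect cohort, runs the DFC pipeline
#' (residualization, screening, grid search, RFE, AUC-optimal subset) on the
#' whole cohort, and scores recovery. Recovery is measured on region-pair
#' identity — the Jaccard overlap between the distinct edges of the selected
#' subset and the planted edges — because at width 50 / step 2 adjacent
#' windows overlap 96% and window-exact attribution is not identifiable;
#' window localization is scored separately as the fraction of selected
#' true-edge features whose window lies inside the planted epoch.
#'
#' @param n_seeds number of independent cohorts (default 10).
#' @param base_seed offset added to each cohort index to form its seed.
#' @param n_patients,n_controls,n_regions cohort shape.
#' @param alpha screening threshold.
#' @param n_max subset-selection scan limit.
#' @return data.frame, one row per seed: `jaccard_edges`, `window_in_epoch`
#'   (fraction), `n_selected`, `n_screened`, `optimal_auc`.
#' @export
study_recovery <- function(n_seeds = 10L, base_seed = 1L,
                           n_patients = 40L, n_controls = 40L,
                           n_regions = 30L, alpha = 0.001, n_max = 60L) {
  res <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    seed <- base_seed + s - 1L
    cohort <- generate_cohort(demo_cohort_spec(
      n_patients = n_patients, n_controls = n_controls,
      n_regions = n_regions, seed = seed))
    fm <- build_features(cohort, "dfc")
    y <- cohort_labels(cohort)
    fit <- dfc_pipeline(fm, y, cohort_covariates(cohort), alpha = alpha,
                        grids = study_grids(), n_max = n_max, seed = seed,
                        eval_rounds = 2L)
    true_cols <- true_feature_columns(cohort, fm$index, fm$scheme)
    true_edges <- unique(paste(cohort$spec$effect_edges$i,
                               cohort$spec$effect_edges$j, sep = "-"))
    sel_edges <- selected_edges(fit$selected_columns, fm$index)
    jac <- length(intersect(sel_edges, true_edges)) /
      length(union(sel_edges, true_edges))
    dec <- decode_features(fm$index, fit$selected_columns)
    on_true <- paste(dec$i, dec$j, sep = "-") %in% true_edges
    # a selected window is "localized" if it overlaps the planted epoch
    win_ok <- if (any(on_true)) {
      b <- enumerate_windows(fm$scheme)
      ee <- cohort$spec$effect_edges
      mean(vapply(which(on_true), function(k) {
        ek <- ee[ee$i == dec$i[k] & ee$j == dec$j[k], ]
        b[dec$window[k], 2] > ek$start && b[dec$window[k], 1] < ek$end
      }, logical(1)))
    } else NA_real_
    res[[s]] <- data.frame(seed = seed, jaccard_edges = jac,
                           window_in_epoch = win_ok,
                           n_selected = length(fit$selected_columns),
                           n_screened = length(fit$screen$retained),
                           optimal_auc = if (is.null(fit$rfe)) NA_real_ else
                             max(fit$rfe$auc_curve$auc))
  }
  do.call(rbind, res)
}

#' Dynamic-vs-static headline study
#'
#' For each seed, generates a transient-effect cohort and runs the full
#' pipeline twice — once on sliding-window (DFC) features and once on
#' whole-series (SFC) features — reporting the repeated-CV AUC of each.
#' Transient group differences are diluted over the full series, so the DFC
#' pipeline is expected to dominate.
#'
#' @inheritParams study_recovery
#' @param eval_rounds repeated-CV rounds per pipeline (default 5).
#' @return data.frame per seed: `dfc_auc`, `sfc_auc`, `dfc_minus_sfc`.
#' @export
study_dfc_vs_sfc <- function(n_seeds = 10L, base_seed = 101L,
                             n_patients = 40L, n_controls = 40L,
                             n_regions = 30L, alpha = 0.001,
                             eval_rounds = 5L) {
  res <- vector("list", n_seeds)
  for (s in seq_len(n_seeds)) {
    seed <- base_seed + s - 1L
    cohort <- generate_cohort(demo_cohort_spec(
      n_patients = n_patients, n_controls = n_controls,
      n_regions = n_regions, seed = seed))
    y <- cohort_labels(cohort)
    cov <- cohort_covariates(cohort)
    auc <- sapply(c("dfc", "sfc"), function(mode) {
      fm <- build_features(cohort, mode)
      fit <- dfc_pipeline(fm, y, cov, alpha = alpha, grids = study_grids(),
                          n_max = 40L, eval_rounds = eval_rounds,
                          seed = seed)
      fit$auc
    })
    res[[s]] <- data.frame(seed = seed, dfc_auc = auc[["dfc"]],
                           sfc_auc = auc[["sfc"]],
                           dfc_minus_sfc = auc[["dfc"]] - auc[["sfc"]])
  }
  do.call(rbind, res)
}

#' Null-calibration study
#'
#' On an effect-free cohort: (a) the fraction of DFC features retained by
#' screening at `alpha`; (b) the mean repeated 10-fold CV AUC under label
#' permutation, averaged over `n_perms` independent permutation draws (a
#' single draw has cohort-level sd about 0.06 at n = 80, so the average is
#' the calibrated quantity); (c) the selection-before-CV optimism — the
#' repeated-CV AUC after whole-cohort screening — next to the honest
#' hold-out test AUC from a train-only pipeline.
#'
#' @param seed cohort seed.
#' @param n_perms permutation draws for (b).
#' @param rounds CV rounds per permutation draw.
#' @return list with `screen_fraction`, `permuted_mean_auc`,
#'   `inflated_cv_auc`, `holdout_test_auc`, `n_features`.
#' @export
study_null_calibration <- function(seed = 1L, n_perms = 5L, rounds = 4L,
                                   n_patients = 40L, n_controls = 40L,
                                   n_regions = 30L) {
  spec <- cohort_spec(n_patients = n_patients, n_controls = n_controls,
                      n_regions = n_regions, seed = seed,
                      covariate_model = default_covariate_model())
  cohort <- generate_cohort(spec)
  fm <- build_features(cohort, "dfc")
  y <- cohort_labels(cohort)
  xr <- regress_covariates(fm$x, cohort_covariates(cohort))
  screen <- ttest_screen(xr, y, alpha = 0.001)
  screen_fraction <- length(screen$retained) / ncol(xr)

  # (b) chance calibration of the evaluator on a fixed random feature subset
  set.seed(seed + 1000L)
  cols <- sample(ncol(xr), 30L)
  params <- kernel_params(1, 1 / 30)
  perm_auc <- vapply(seq_len(n_perms), function(p) {
    yp <- sample(y)
    repeated_kfold(xr[, cols, drop = FALSE], yp, params, k = 10L,
                   rounds = rounds, seed = seed + p)$auc
  }, numeric(1))

  # (c) optimism of selection-before-CV vs the honest hold-out
  inflated <- if (length(screen$retained)) {
    repeated_kfold(xr[, screen$retained, drop = FALSE], y,
                   kernel_params(1, 1 / max(1, length(screen$retained))),
                   k = 10L, rounds = rounds, seed = seed + 1L)$auc
  } else 0.5
  ho <- holdout_protocol(fm$x, y, cohort_covariates(cohort),
                         grids = study_grids(), n_max = 30L,
                         eval_rounds = 2L, seed = seed + 2L)
  list(screen_fraction = screen_fraction,
       permuted_mean_auc = mean(perm_auc),
       inflated_cv_auc = inflated,
       holdout_test_auc = ho$test_auc,
       n_features = ncol(xr))
}

#' Clinical-coupling recovery study
#'
#' Generates a cohort shaped like the emulated one (43 patients, 56
#' controls) and correlates the HAMD-coupled DFC feature (the mean windowed
#' correlation of the coupled edge over its coupled window range) with the
#' HAMD score across patients, adjusting gender and education.
#'
#' @param seed cohort seed.
#' @param n_regions region count (default 30).
#' @return list with `r` (observed), `ci` (95% Fisher interval), `n`.
#' @export
study_clinical_recovery <- function(seed = 1L, n_regions = 30L) {
  cohort <- generate_cohort(demo_cohort_spec(
    n_patients = 43L, n_controls = 56L, n_regions = n_regions, seed = seed))
  feat <- clinical_feature(cohort, "hamd")
  pat <- cohort_labels(cohort) == 1L
  cc <- clinical_correlation(matrix(feat[pat], ncol = 1),
                             data.frame(hamd = cohort_clinical(cohort)$hamd[pat]),
                             cohort_covariates(cohort)[pat, ])
  n <- sum(pat)
  z <- atanh(cc$r) + c(-1, 1) * stats::qnorm(0.975) / sqrt(n - 3)
  list(r = cc$r, p = cc$p, ci = tanh(z), n = n)
}

#' The coupled clinical predictor
#'
#' The subject-level mean windowed correlation of the edge a clinical scale
#' is coupled to, over its coupled window range — the exact feature the
#' generator linked the score to.
#'
#' @param cohort a `dfc_cohort` whose spec has a clinical model.
#' @param scale `"hamd"` or `"hama"`.
#' @return numeric vector, one value per subject.
#' @export
clinical_feature <- function(cohort, scale = "hamd") {
  cm <- cohort$spec$clinical_model
  row <- cm[cm$scale == scale, ][1L, ]
  scheme <- window_scheme(cohort$spec$window_width, cohort$spec$window_step,
                          cohort$spec$n_timepoints)
  vapply(cohort$subjects, function(s) {
    edge_windowed_cor(s$timeseries, row$i, row$j, scheme,
                      row$win_start:row$win_end)
  }, numeric(1))
}

#' End-to-end study run with manifest
#'
#' Orchestrates simulate, extract, screen, select, evaluate and characterize
#' on one cohort, writing plain-text artifacts and a manifest (config, stage
#' seeds, content hashes) to `out_dir`. Deterministic: rerunning with the
#' same config and seed reproduces the hashes.
#'
#' @param out_dir output directory.
#' @param seed master seed (stage seeds derive from it and are recorded).
#' @param spec a [cohort_spec()] (default [demo_cohort_spec()] at the seed).
#' @param mode feature set to analyse ("dfc" or "sfc").
#' @param ... passed to [dfc_pipeline()].
#' @return the manifest, invisibly.
#' @export
run_study <- function(out_dir, seed = 1L, spec = NULL, mode = "dfc", ...) {
  if (is.null(spec)) spec <- demo_cohort_spec(seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  cohort <- stage("simulate", function() generate_cohort(spec))
  atlas <- make_atlas(spec$n_regions)
  write_cohort(cohort, file.path(out_dir, "cohort"), atlas)
  fm <- stage("extract", function() build_features(cohort, mode))
  y <- cohort_labels(cohort)
  fit <- stage("screen+select+evaluate", function() {
    dfc_pipeline(fm, y, cohort_covariates(cohort), grids = study_grids(),
                 seed = seed, ...)
  })
  conn <- stage("characterize", function() {
    if (!length(fit$selected_columns)) return(NULL)
    map_connections(fit$selected_columns, fm$index, atlas, fm$scheme,
                    tr = spec$tr_seconds,
                    weights = if (is.null(fit$rfe)) NULL else fit$rfe$weights)
  })
  jsonlite::write_json(list(
    screen = list(alpha = fit$screen$alpha,
                  n_retained = length(fit$screen$retained)),
    params = unclass(fit$params)[c("cost", "gamma")],
    optimal_n = length(fit$selected_columns),
    selected_columns = fit$selected_columns,
    report = if (is.null(fit$report)) NULL else list(
      sensitivity = fit$report$sensitivity,
      specificity = fit$report$specificity,
      accuracy = fit$report$accuracy, auc = fit$report$auc,
      protocol = fit$report$protocol)),
    file.path(out_dir, "result.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  if (!is.null(conn)) {
    utils::write.table(conn, file.path(out_dir, "connections.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = seed, mode = mode,
    config = list(n_patients = spec$n_patients, n_controls = spec$n_controls,
                  n_regions = spec$n_regions,
                  n_timepoints = spec$n_timepoints,
                  window_width = spec$window_width,
                  window_step = spec$window_step),
    hashes = as.list(stats::setNames(unname(tools::md5sum(files)),
                                     sub(paste0("^", out_dir, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
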