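#' Cohort specification for the synthetic generator
#'
#' Describes a two-group resting-state cohort: patients (+1) and controls
#' (-1), band-limited regional time series, and group differences in
#' connectivity that are confined to time epochs ("transient" effects, the
#' regime where dynamic connectivity outperforms static connectivity).
#'
#' The signal model is piecewise-stationary Gaussian: within each epoch
#' segment, innovations are transformed by the Cholesky square root of a
#' target correlation matrix (baseline for controls, baseline + delta on the
#' planted edges for patients during their epochs), then the whole series is
#' band-limited to `band` by an exact Fourier mask. Clinical scores are
#' linear in the subject's mean windowed correlation of a designated edge
#' over a designated window range, plus Gaussian noise; controls carry no
#' clinical scores.
#'
#' @param n_patients,n_controls group sizes (defaults mirror a 43/56 cohort).
#' @param n_regions number of regions N (default 273, the Brainnetome-derived
#'   count after dropping one unidentifiable region from 274).
#' @param n_timepoints series length T after dummy-scan discard (default 200).
#' @param tr_seconds repetition time in seconds (default 2).
#' @param band retained frequency band in Hz (default 0.01-0.1); `NULL`
#'   disables filtering (exact epochwise correlations, used by unit tests).
#' @param effect_edges data.frame with columns `i`, `j`, `start`, `end`
#'   (half-open 0-based timepoint epoch), `delta`, and optional `baseline`
#'   (default 0): patients' target correlation on edge (i,j) is
#'   baseline + delta inside the epoch and baseline outside; controls get
#'   baseline throughout.
#' @param covariate_model per-group gender rates (probability of male = 1)
#'   and education mean/sd in years.
#' @param clinical_model data.frame with columns `scale` ("hamd"/"hama"),
#'   `i`, `j`, `win_start`, `win_end` (1-based inclusive window range),
#'   `intercept`, `coef`, `noise_sd`: score = intercept + coef * mean
#'   windowed r of edge (i,j) over the range + N(0, noise_sd), rounded to an
#'   integer (scores are integer sums of rating items).
#' @param window_width,window_step the window scheme the clinical couplings
#'   refer to (defaults 50 and 2).
#' @param seed integer seed; the same spec and seed reproduce the cohort
#'   bit-identically.
#' @return a validated `cohort_spec`.
#' @seealso [generate_cohort()], [demo_cohort_spec()]
#' @export
cohort_spec <- function(n_patients = 43L, n_controls = 56L,
                        n_regions = 273L, n_timepoints = 200L,
                        tr_seconds = 2, band = c(0.01, 0.1),
                        effect_edges = NULL,
                        covariate_model = default_covariate_model(),
                        clinical_model = NULL,
                        window_width = 50L, window_step = 2L,
                        seed = 1L) {
  if (is.null(effect_edges)) {
    effect_edges <- data.frame(i = integer(), j = integer(),
                               start = integer(), end = integer(),
                               delta = numeric())
  }
  if (is.null(effect_edges$baseline)) {
    effect_edges$baseline <- rep(0, nrow(effect_edges))
  }
  spec <- structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_regions = as.integer(n_regions), n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds, band = band,
    effect_edges = effect_edges, covariate_model = covariate_model,
    clinical_model = clinical_model,
    window_width = as.integer(window_width),
    window_step = as.integer(window_step),
    seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (spec$n_regions < 2L) stop("n_regions must be >= 2")
  if (spec$n_patients < 1L || spec$n_controls < 1L) {
    stop("both groups must be non-empty")
  }
  ee <- spec$effect_edges
  if (nrow(ee)) {
    if (any(ee$i >= ee$j)) stop("effect edges must satisfy i < j")
    if (any(ee$j > spec$n_regions)) stop("effect edge region out of range")
    if (any(ee$start < 0L | ee$end > spec$n_timepoints | ee$start >= ee$end)) {
      stop("effect epochs must satisfy 0 <= start < end <= n_timepoints")
    }
    bad <- abs(ee$baseline + ee$delta) >= 1
    if (any(bad)) {
      stop(sprintf("|baseline + delta| must be < 1; violated by edge(s) %s",
                   paste(sprintf("(%d,%d)", ee$i[bad], ee$j[bad]),
                         collapse = ", ")))
    }
  }
  if (!is.null(spec$band)) {
    if (length(spec$band) != 2L || spec$band[1] <= 0 ||
        spec$band[1] >= spec$band[2]) {
      stop("band must be (low, high) with 0 < low < high")
    }
    if (spec$band[2] > 1 / (2 * spec$tr_seconds)) {
      stop("band upper edge exceeds the Nyquist frequency")
    }
  }
  invisible(spec)
}

#' @rdname cohort_spec
#' @export
default_covariate_model <- function() {
  # rates and moments of the emulated cohort's demographics
  list(gender_rate = c(patient = 13 / 43, control = 30 / 56),
       education = list(patient = c(mean = 11.44, sd = 3.33),
                        control = c(mean = 15.78, sd = 4.33)))
}

#' Default planted effects and clinical couplings
#'
#' Three transient edges of magnitude 0.5 whose epochs each span 11 fully
#' contained sliding windows at width 50 / step 2, plus clinical couplings:
#' HAMD linearly coupled to the first edge's within-epoch windowed
#' correlation and HAMA (negatively signed predictor) to the second.
#' Intercepts are set so score means land near 23.4 (HAMD) and 18.0 (HAMA),
#' coefficients and noise so the population feature-score correlation is
#' about 0.6 in magnitude.
#'
#' @name default_effects
#' @export
default_effect_edges <- function() {
  data.frame(i = c(1L, 3L, 5L), j = c(2L, 4L, 6L),
             start = c(40L, 90L, 20L), end = c(110L, 160L, 90L),
             delta = c(0.5, -0.5, 0.5))
}

#' @rdname default_effects
#' @export
default_clinical_model <- function() {
  data.frame(scale = c("hamd", "hama"),
             i = c(1L, 3L), j = c(2L, 4L),
             win_start = c(21L, 46L), win_end = c(31L, 56L),
             intercept = c(18.9, 14.4), coef = c(10, -8),
             noise_sd = c(2.3, 1.84))
}

#' Desk-scale demonstration cohort specification
#'
#' The default study conditions used throughout the tests and analyses:
#' 30 regions, 200 timepoints at TR = 2 s, 0.01-0.1 Hz band, the three
#' default transient edges and both clinical couplings.
#'
#' @param n_patients,n_controls group sizes (default 40/40 for recovery
#'   studies; pass 43/56 for a cohort shaped like the emulated one).
#' @param n_regions region count (default 30).
#' @param seed integer seed.
#' @param ... passed through to [cohort_spec()].
#' @export
demo_cohort_spec <- function(n_patients = 40L, n_controls = 40L,
                             n_regions = 30L, seed = 1L, ...) {
  cohort_spec(n_patients = n_patients, n_controls = n_controls,
              n_regions = n_regions,
              effect_edges = default_effect_edges(),
              clinical_model = default_clinical_model(),
              seed = seed, ...)
}

#' Exact Fourier band-pass mask
#'
#' Zeroes every Fourier coefficient (including DC) whose frequency lies
#' outside `[band[1], band[2]]` Hz and inverts the transform. Linear and
#' exactly band-confining, so in-band cross-correlations are preserved in
#' expectation.
#'
#' @param x timepoints x regions matrix.
#' @param tr sampling interval in seconds.
#' @param band (low, high) in Hz.
#' @return filtered matrix of the same shape.
#' @export
bandpass_fft <- function(x, tr, band) {
  x <- as.matrix(x)
  Tn <- nrow(x)
  freqs <- (seq_len(Tn) - 1) / (Tn * tr)
  folded <- pmin(freqs, 1 / tr - freqs)
  keep <- folded >= band[1] & folded <= band[2]
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  Re(stats::mvfft(xf, inverse = TRUE)) / Tn
}

# Target correlation matrix for one epoch segment of one group.
# active: logical vector over effect_edges rows.
segment_correlation <- function(spec, active) {
  R <- diag(spec$n_regions)
  ee <- spec$effect_edges
  for (k in seq_len(nrow(ee))) {
    r <- ee$baseline[k] + if (active[k]) ee$delta[k] else 0
    R[ee$i[k], ee$j[k]] <- R[ee$j[k], ee$i[k]] <- r
  }
  R
}

# mean windowed Pearson r of one edge over a 1-based inclusive window range
edge_windowed_cor <- function(ts, i, j, scheme, win_range) {
  bounds <- enumerate_windows(scheme)
  r <- vapply(win_range, function(w) {
    rows <- (bounds[w, 1] + 1L):bounds[w, 2]
    stats::cor(ts[rows, i], ts[rows, j])
  }, numeric(1))
  mean(r)
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws every subject's band-limited regional time series under the
#' piecewise-stationary correlation model of the spec, plus covariates and
#' (patients only) clinical scores. Deterministic: the same spec and seed
#' reproduce the cohort bit-identically.
#'
#' @param spec a [cohort_spec()].
#' @return a `dfc_cohort`: list with `subjects` (each a `subject_record`
#'   holding `subject_id`, `timeseries`, `group` in {+1, -1}, `gender`,
#'   `education`, `hamd`, `hama`), `ground_truth` (planted edges and
#'   clinical couplings), and the `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  ee <- spec$effect_edges
  Tn <- spec$n_timepoints

  # epoch segmentation (patients only; controls are globally stationary)
  breaks <- sort(unique(c(0L, ee$start, ee$end, Tn)))
  seg_rows <- lapply(seq_len(length(breaks) - 1L), function(s) {
    (breaks[s] + 1L):breaks[s + 1L]
  })
  chol_for <- function(active_by_seg) {
    lapply(active_by_seg, function(active) {
      R <- segment_correlation(spec, active)
      tryCatch(chol(R), error = function(e) {
        bad <- which(active | ee$baseline != 0)
        stop(sprintf(paste0("target correlation is not positive definite ",
                            "in a segment; offending edge set: %s"),
                     paste(sprintf("(%d,%d)", ee$i[bad], ee$j[bad]),
                           collapse = ", ")), call. = FALSE)
      })
    })
  }
  active_pat <- lapply(seq_len(length(breaks) - 1L), function(s) {
    if (!nrow(ee)) return(logical(0))
    ee$start <= breaks[s] & ee$end >= breaks[s + 1L]
  })
  chol_pat <- chol_for(active_pat)
  chol_ctl <- chol_for(lapply(active_pat, function(a) a & FALSE))

  scheme <- window_scheme(spec$window_width, spec$window_step, Tn)
  cm <- spec$covariate_model
  n_total <- spec$n_patients + spec$n_controls

  subjects <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    patient <- s <= spec$n_patients
    grp <- if (patient) "patient" else "control"
    z <- matrix(stats::rnorm(Tn * spec$n_regions), Tn, spec$n_regions)
    L <- if (patient) chol_pat else chol_ctl
    x <- z
    for (k in seq_along(seg_rows)) {
      x[seg_rows[[k]], ] <- z[seg_rows[[k]], , drop = FALSE] %*% L[[k]]
    }
    if (!is.null(spec$band)) x <- bandpass_fft(x, spec$tr_seconds, spec$band)
    colnames(x) <- sprintf("R%03d", seq_len(spec$n_regions))

    gender <- stats::rbinom(1L, 1L, cm$gender_rate[[grp]])
    edu <- round(stats::rnorm(1L, cm$education[[grp]]["mean"],
                              cm$education[[grp]]["sd"]), 1)
    edu <- min(max(edu, 6), 25)

    hamd <- hama <- NA_real_
    if (patient && !is.null(spec$clinical_model)) {
      for (k in seq_len(nrow(spec$clinical_model))) {
        row <- spec$clinical_model[k, ]
        xc <- edge_windowed_cor(x, row$i, row$j, scheme,
                                row$win_start:row$win_end)
        score <- round(row$intercept + row$coef * xc +
                         stats::rnorm(1L, 0, row$noise_sd))
        if (row$scale == "hamd") hamd <- score else hama <- score
      }
    }
    subjects[[s]] <- structure(list(
      subject_id = sprintf("sub%03d", s), timeseries = x,
      group = if (patient) 1L else -1L,
      gender = gender, education = edu, hamd = hamd, hama = hama),
      class = "subject_record")
  }
  structure(list(subjects = subjects,
                 ground_truth = structure(list(
                   effect_edges = ee,
                   clinical_couplings = spec$clinical_model,
                   window_width = spec$window_width,
                   window_step = spec$window_step), class = "ground_truth"),
                 spec = spec),
            class = "dfc_cohort")
}

#' @export
print.dfc_cohort <- function(x, ...) {
  n <- length(x$subjects)
  np <- sum(cohort_labels(x) == 1L)
  cat(sprintf("dfc_cohort: %d subjects (%d patients / %d controls), %d regions x %d timepoints, %d planted edge(s)\n",
              n, np, n - np, x$spec$n_regions, x$spec$n_timepoints,
              nrow(x$spec$effect_edges)))
  invisible(x)
}

#' Cohort accessors
#'
#' @param cohort a `dfc_cohort`.
#' @return `cohort_labels()`: integer vector in {+1 patient, -1 control};
#'   `cohort_covariates()`: data.frame (gender, education);
#'   `cohort_clinical()`: data.frame (hamd, hama; NA for controls).
#' @name cohort_accessors
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort$subjects, `[[`, integer(1), "group")
}

#' @rdname cohort_accessors
#' @export
cohort_covariates <- function(cohort) {
  data.frame(gender = vapply(cohort$subjects, `[[`, numeric(1), "gender"),
             education = vapply(cohort$subjects, `[[`, numeric(1), "education"))
}

#' @rdname cohort_accessors
#' @export
cohort_clinical <- function(cohort) {
  data.frame(hamd = vapply(cohort$subjects, `[[`, numeric(1), "hamd"),
             hama = vapply(cohort$subjects, `[[`, numeric(1), "hama"))
}

#' Ground-truth feature columns of the planted effects
#'
#' Maps each planted edge's timepoint epoch to the sliding windows fully
#' contained in it and returns the corresponding feature columns (and
#' triples). Windows only partially overlapping an epoch carry a diluted
#' effect and are not counted as ground truth.
#'
#' @param cohort a `dfc_cohort`.
#' @param index the [feature_index()] of the DFC feature matrix.
#' @param scheme the [window_scheme()] used to build it.
#' @return data.frame with `column`, `window`, `i`, `j`, `delta`.
#' @export
true_feature_columns <- function(cohort, index, scheme) {
  ee <- cohort$ground_truth$effect_edges
  bounds <- enumerate_windows(scheme)
  out <- lapply(seq_len(nrow(ee)), function(k) {
    win <- which(bounds[, 1] >= ee$start[k] & bounds[, 2] <= ee$end[k])
    if (!length(win)) return(NULL)
    data.frame(column = encode_features(index, win, ee$i[k], ee$j[k]),
               window = win, i = ee$i[k], j = ee$j[k], delta = ee$delta[k])
  })
  do.call(rbind, out)
}

#' Synthetic atlas label table
#'
#' Region ids, names, and a cyclic assignment to the seven canonical
#' resting-state networks (VN, SMN, DAN, VAN, LN, FPN, DMN). Optionally
#' drops region ids (emulating parcels excluded from an atlas).
#'
#' @param n_regions number of regions before exclusion.
#' @param drop integer region ids to exclude (default none).
#' @return data.frame: `region_id`, `region_name`, `network_name`.
#' @export
make_atlas <- function(n_regions, drop = integer()) {
  nets <- c("VN", "SMN", "DAN", "VAN", "LN", "FPN", "DMN")
  atlas <- data.frame(
    region_id = seq_len(n_regions),
    region_name = sprintf("ROI_%03d", seq_len(n_regions)),
    network_name = rep_len(nets, n_regions))
  atlas[!atlas$region_id %in% drop, , drop = FALSE]
}
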