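#' Sliding-window scheme
#'
#' Defines the rectangular sliding-window scheme used for dynamic functional
#' connectivity: windows of `width` timepoints advanced by `step` timepoints
#' over a series of `n_timepoints`. Intervals are half-open and 0-based:
#' window k (k = 0 ... W-1) covers timepoints `[k*step, k*step + width)`.
#'
#' @param width window width in timepoints. The conventional lower bound is
#'   `1 / f_min` seconds (see [min_window_width()]); at TR = 2 s and
#'   f_min = 0.01 Hz this gives the default of 50 timepoints.
#' @param step step length in timepoints (default 2).
#' @param n_timepoints length of the series the scheme will be applied to.
#' @return an object of class `window_scheme` with fields `width`, `step`,
#'   `n_timepoints` and the window count `n_windows`.
#' @seealso [enumerate_windows()], [windowed_connectivity()]
#' @export
window_scheme <- function(width, step = 2L, n_timepoints) {
  width <- as.integer(width); step <- as.integer(step)
  n_timepoints <- as.integer(n_timepoints)
  if (width < 1L) stop("window width must be >= 1")
  if (step < 1L) stop("step must be >= 1")
  if (width > n_timepoints) {
    stop(sprintf("window width (%d) exceeds series length (%d)",
                 width, n_timepoints))
  }
  W <- (n_timepoints - width) %/% step + 1L
  structure(list(width = width, step = step,
                 n_timepoints = n_timepoints, n_windows = W),
            class = "window_scheme")
}

#' Minimum admissible window width
#'
#' The sliding-window literature recommends a window no shorter than
#' `1 / f_min`, the period of the slowest frequency retained by band-pass
#' filtering. Converted to timepoints at repetition time `tr`.
#'
#' @param f_min lowest retained frequency in Hz.
#' @param tr repetition time (sampling interval) in seconds.
#' @return width in timepoints (ceiling).
#' @export
min_window_width <- function(f_min, tr) {
  as.integer(ceiling(1 / (f_min * tr)))
}

#' Enumerate sliding-window intervals
#'
#' @param scheme a [window_scheme()].
#' @return a two-column integer matrix (`start`, `end`) of half-open, 0-based
#'   intervals, one row per window.
#' @export
enumerate_windows <- function(scheme) {
  stopifnot(inherits(scheme, "window_scheme"))
  starts <- seq.int(0L, by = scheme$step, length.out = scheme$n_windows)
  cbind(start = starts, end = starts + scheme$width)
}

#' Windowed (dynamic) functional connectivity
#'
#' Computes the Pearson correlation matrix of the regional time series inside
#' each sliding window, yielding a W x N x N connectivity tensor.
#'
#' @param ts numeric matrix, timepoints x regions.
#' @param scheme a [window_scheme()]; its `n_timepoints` must equal `nrow(ts)`.
#' @return a `connectivity_tensor`: list with `values` (W x N x N array),
#'   `window_bounds` (half-open intervals) and the `scheme`.
#' @export
windowed_connectivity <- function(ts, scheme) {
  ts <- as.matrix(ts)
  stopifnot(inherits(scheme, "window_scheme"))
  if (scheme$n_timepoints != nrow(ts)) {
    stop(sprintf("scheme expects %d timepoints, series has %d",
                 scheme$n_timepoints, nrow(ts)))
  }
  bounds <- enumerate_windows(scheme)
  N <- ncol(ts); W <- nrow(bounds)
  vals <- array(NA_real_, dim = c(W, N, N))
  for (w in seq_len(W)) {
    block <- ts[(bounds[w, 1] + 1L):bounds[w, 2], , drop = FALSE]
    sds <- apply(block, 2L, stats::sd)
    if (any(sds == 0)) {
      stop(sprintf("zero-variance region(s) %s in window %d [%d,%d)",
                   paste(which(sds == 0), collapse = ", "),
                   w, bounds[w, 1], bounds[w, 2]))
    }
    vals[w, , ] <- stats::cor(block)
  }
  structure(list(values = vals, window_bounds = bounds, scheme = scheme),
            class = "connectivity_tensor")
}

#' Static functional connectivity
#'
#' The single whole-series Pearson correlation matrix, i.e. windowed
#' connectivity with the window width equal to the series length (W = 1).
#'
#' @inheritParams windowed_connectivity
#' @return a `connectivity_tensor` with one slice.
#' @export
static_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  windowed_connectivity(ts, window_scheme(width = nrow(ts), step = nrow(ts),
                                          n_timepoints = nrow(ts)))
}

#' Feature index: column <-> (window, region i, region j) bijection
#'
#' Enumerates the upper-triangle elements of each windowed connectivity
#' matrix in window-major order; within a window, pairs are row-major:
#' (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N). Column c of a vectorized
#' feature row therefore decodes uniquely to a (window, i, j) triple with
#' i < j, and every triple encodes back to its column.
#'
#' @param n_windows number of windows W.
#' @param n_regions number of regions N (>= 2).
#' @return a `feature_index` with `n_windows`, `n_regions`, `pairs`
#'   (the N(N-1)/2 x 2 row-major pair table) and `n_features` = W*N*(N-1)/2.
#' @export
feature_index <- function(n_windows, n_regions) {
  n_windows <- as.integer(n_windows); n_regions <- as.integer(n_regions)
  stopifnot(n_windows >= 1L, n_regions >= 2L)
  i <- rep.int(seq_len(n_regions - 1L), times = (n_regions - 1L):1L)
  j <- sequence((n_regions - 1L):1L) + i
  pairs <- cbind(i = i, j = j)
  structure(list(n_windows = n_windows, n_regions = n_regions, pairs = pairs,
                 n_pairs = nrow(pairs),
                 n_features = n_windows * nrow(pairs)),
            class = "feature_index")
}

#' Decode feature columns to (window, i, j) triples
#'
#' @param index a [feature_index()].
#' @param cols integer vector of 1-based feature columns.
#' @return data.frame with `column`, `window` (1-based), `i`, `j`.
#' @export
decode_features <- function(index, cols) {
  stopifnot(inherits(index, "feature_index"))
  cols <- as.integer(cols)
  if (any(cols < 1L | cols > index$n_features)) {
    stop("feature column out of range")
  }
  w <- (cols - 1L) %/% index$n_pairs + 1L
  p <- (cols - 1L) %% index$n_pairs + 1L
  data.frame(column = cols, window = w,
             i = unname(index$pairs[p, 1L]), j = unname(index$pairs[p, 2L]),
             row.names = NULL)
}

#' Encode (window, i, j) triples to feature columns
#'
#' @param index a [feature_index()].
#' @param window 1-based window indices.
#' @param i,j region indices with i < j.
#' @return integer vector of 1-based columns.
#' @export
encode_features <- function(index, window, i, j) {
  stopifnot(inherits(index, "feature_index"))
  if (any(i >= j)) stop("region pairs must satisfy i < j")
  if (any(window < 1L | window > index$n_windows)) stop("window out of range")
  if (any(j > index$n_regions)) stop("region index out of range")
  N <- index$n_regions
  # row-major upper-triangle position of (i, j)
  p <- (i - 1L) * N - (i * (i - 1L)) %/% 2L + (j - i)
  as.integer((window - 1L) * index$n_pairs + p)
}

#' Vectorize a connectivity tensor into one feature row
#'
#' @param tensor a `connectivity_tensor`.
#' @return list with `row` (numeric vector of length W*N*(N-1)/2) and
#'   `index` (the matching [feature_index()]).
#' @export
vectorize_tensor <- function(tensor) {
  stopifnot(inherits(tensor, "connectivity_tensor"))
  W <- dim(tensor$values)[1L]; N <- dim(tensor$values)[2L]
  idx <- feature_index(W, N)
  row <- numeric(idx$n_features)
  sel <- idx$pairs
  for (w in seq_len(W)) {
    m <- tensor$values[w, , ]
    row[((w - 1L) * idx$n_pairs + 1L):(w * idx$n_pairs)] <- m[sel]
  }
  list(row = row, index = idx)
}

#' Build a subjects-by-features matrix from a cohort
#'
#' Applies windowed (or static) connectivity to every subject and stacks the
#' vectorized upper-triangle features.
#'
#' @param cohort a `dfc_cohort` from [generate_cohort()] or [read_cohort()].
#' @param mode `"dfc"` (sliding windows), `"sfc"` (whole-series), or
#'   `"both"` (column-wise concatenation DFC then SFC).
#' @param scheme window scheme for DFC; defaults to the scheme recorded in the
#'   cohort's spec (width/step at the cohort's length).
#' @return a `feature_matrix`: list with `x` (subjects x features), `index`,
#'   `subject_ids`, `feature_set` tag, and for `"both"` the DFC/SFC column
#'   split `n_dfc`.
#' @export
build_features <- function(cohort, mode = c("dfc", "sfc", "both"),
                           scheme = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(cohort, "dfc_cohort"))
  Tn <- nrow(cohort$subjects[[1L]]$timeseries)
  if (mode == "both") {
    d <- build_features(cohort, "dfc", scheme)
    s <- build_features(cohort, "sfc")
    return(structure(list(x = cbind(d$x, s$x), index = d$index,
                          sfc_index = s$index, n_dfc = ncol(d$x),
                          subject_ids = d$subject_ids,
                          feature_set = "DFC+SFC"),
                     class = "feature_matrix"))
  }
  if (mode == "sfc") {
    scheme <- window_scheme(width = Tn, step = Tn, n_timepoints = Tn)
  } else if (is.null(scheme)) {
    scheme <- window_scheme(width = cohort$spec$window_width,
                            step = cohort$spec$window_step,
                            n_timepoints = Tn)
  }
  idx <- feature_index(scheme$n_windows, ncol(cohort$subjects[[1L]]$timeseries))
  x <- matrix(NA_real_, nrow = length(cohort$subjects), ncol = idx$n_features)
  for (s in seq_along(cohort$subjects)) {
    tens <- windowed_connectivity(cohort$subjects[[s]]$timeseries, scheme)
    x[s, ] <- vectorize_tensor(tens)$row
  }
  structure(list(x = x, index = idx,
                 subject_ids = vapply(cohort$subjects, `[[`, "", "subject_id"),
                 feature_set = toupper(mode), scheme = scheme),
            class = "feature_matrix")
}
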