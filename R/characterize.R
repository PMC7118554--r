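#' Map selected feature columns to anatomy and time
#'
#' Decodes each selected column to its (window, region i, region j) triple,
#' joins region names and network labels from the atlas table, and converts
#' window indices to scan time. Windows are 1-based in all reports (internal
#' indices are 0-based half-open intervals); window w spans
#' `[(w-1)*step*TR, ((w-1)*step + width)*TR)` seconds.
#'
#' @param columns integer feature columns (e.g. `selected_columns` of a
#'   pipeline result).
#' @param index the [feature_index()] the columns refer to.
#' @param atlas data.frame with `region_id`, `region_name`, `network_name`
#'   covering every decoded region.
#' @param scheme the [window_scheme()] used for the features.
#' @param tr repetition time in seconds.
#' @param weights optional named weight scores (from an `rfe_result`).
#' @return a `connection_table`: data.frame of `discriminative connections`
#'   (column, window, window start/end s, region ids/names, network pair,
#'   weight), with a `summary` attribute holding distinct-region,
#'   distinct-network and distinct-window counts.
#' @export
map_connections <- function(columns, index, atlas, scheme, tr = 2,
                            weights = NULL) {
  dec <- decode_features(index, columns)
  missing <- setdiff(unique(c(dec$i, dec$j)), atlas$region_id)
  if (length(missing)) {
    stop(sprintf("region id(s) %s missing from the atlas table",
                 paste(missing, collapse = ", ")))
  }
  look <- function(ids, what) atlas[[what]][match(ids, atlas$region_id)]
  out <- data.frame(
    column = dec$column, window = dec$window,
    window_start_s = (dec$window - 1) * scheme$step * tr,
    window_end_s = ((dec$window - 1) * scheme$step + scheme$width) * tr,
    region_i = dec$i, region_j = dec$j,
    name_i = look(dec$i, "region_name"), name_j = look(dec$j, "region_name"),
    network_i = look(dec$i, "network_name"),
    network_j = look(dec$j, "network_name"))
  out$weight <- if (is.null(weights)) NA_real_ else
    unname(weights[as.character(columns)])
  attr(out, "summary") <- list(
    n_connections = nrow(out),
    n_distinct_regions = length(unique(c(out$region_i, out$region_j))),
    n_distinct_networks = length(unique(c(out$network_i, out$network_j))),
    n_distinct_windows = length(unique(out$window)))
  class(out) <- c("connection_table", "data.frame")
  out
}

#' Node degree of the selected connections
#'
#' Counts, per region, the selected connections incident to it. Degrees sum
#' to twice the number of connections (handshake identity).
#'
#' @param connections a `connection_table` from [map_connections()].
#' @param atlas atlas table (for network labels).
#' @return data.frame `region_id`, `degree`, `region_name`, `network_name`,
#'   sorted by decreasing degree.
#' @export
node_degrees <- function(connections, atlas) {
  tab <- table(c(connections$region_i, connections$region_j))
  out <- data.frame(region_id = as.integer(names(tab)),
                    degree = as.integer(tab))
  out$region_name <- atlas$region_name[match(out$region_id, atlas$region_id)]
  out$network_name <- atlas$network_name[match(out$region_id, atlas$region_id)]
  out[order(-out$degree, out$region_id), , drop = FALSE]
}

#' Clinical correlations of selected features (patients only)
#'
#' Regresses gender and education out of the selected feature columns, then
#' computes the Pearson correlation (with a two-sided t-test p value) of each
#' residualized feature with each clinical scale. Signs are reported as-is;
#' no multiple-testing correction is applied (flagged in the output).
#'
#' @param x patients x features matrix of the selected columns.
#' @param clinical data.frame of scores (e.g. hamd, hama), complete, with
#'   positive variance per scale.
#' @param covariates patients' covariate data.frame; `NULL` skips adjustment.
#' @return data.frame `feature`, `scale`, `r`, `p`, `n`, with attribute
#'   `multiple_testing = "uncorrected"`.
#' @export
clinical_correlation <- function(x, clinical, covariates = NULL) {
  x <- as.matrix(x)
  if (anyNA(clinical)) stop("clinical scores must be complete (patients only)")
  zero <- vapply(clinical, function(v) stats::sd(v) == 0, logical(1))
  if (any(zero)) {
    stop(sprintf("zero-variance clinical scale(s): %s",
                 paste(names(clinical)[zero], collapse = ", ")))
  }
  if (!is.null(covariates)) x <- regress_covariates(x, covariates)
  n <- nrow(x)
  out <- expand.grid(feature = seq_len(ncol(x)), scale = names(clinical),
                     stringsAsFactors = FALSE)
  out$r <- mapply(function(f, s) stats::cor(x[, f], clinical[[s]]),
                  out$feature, out$scale)
  tt <- out$r * sqrt((n - 2) / pmax(1 - out$r^2, .Machine$double.eps))
  out$p <- 2 * stats::pt(-abs(tt), n - 2)
  out$n <- n
  attr(out, "multiple_testing") <- "uncorrected"
  out
}
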