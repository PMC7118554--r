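# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles (explicit loops, normal
# equations, pair counting) so they share no code with the implementation.

# per-window Pearson correlation by explicit loops over region pairs
brute_windowed_cor <- function(ts, width, step) {
  Tn <- nrow(ts); N <- ncol(ts)
  starts <- seq(0, Tn - width, by = step)
  out <- array(NA_real_, c(length(starts), N, N))
  for (w in seq_along(starts)) {
    rows <- (starts[w] + 1):(starts[w] + width)
    for (i in 1:N) for (j in 1:N) {
      xi <- ts[rows, i] - mean(ts[rows, i])
      xj <- ts[rows, j] - mean(ts[rows, j])
      out[w, i, j] <- sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2))
    }
  }
  out
}

# pooled-variance two-sample t by the textbook formula, one column
brute_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# residuals through the normal equations
brute_residuals <- function(x, Z) {
  D <- cbind(1, as.matrix(Z))
  x - D %*% solve(t(D) %*% D, t(D) %*% x)
}

# AUC by counting ordered pairs, ties one half
brute_auc <- function(scores, labels) {
  sp <- scores[labels == 1]; sn <- scores[labels == -1]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# Guyon kernel criterion by direct double loops over support vectors,
# recomputing the RBF kernel with and without each feature
brute_delta_j <- function(model, gamma) {
  SV <- as.matrix(model$SV); a <- as.numeric(model$coefs)
  m <- nrow(SV)
  quad <- function(cols) {
    tot <- 0
    for (u in 1:m) for (v in 1:m) {
      d2 <- sum((SV[u, cols] - SV[v, cols])^2)
      tot <- tot + a[u] * a[v] * exp(-gamma * d2)
    }
    tot
  }
  Jall <- quad(seq_len(ncol(SV)))
  vapply(seq_len(ncol(SV)),
         function(f) 0.5 * (Jall - quad(setdiff(seq_len(ncol(SV)), f))),
         numeric(1))
}

# trapezoidal area under an ROC polygon
trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  fpr <- c(roc$fpr[o], 1); tpr <- c(roc$tpr[o], 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# small transient-effect cohort for protocol tests
small_effect_spec <- function(seed, n_patients = 20L, n_controls = 20L,
                              n_regions = 10L) {
  cohort_spec(n_patients = n_patients, n_controls = n_controls,
              n_regions = n_regions, n_timepoints = 200L,
              effect_edges = data.frame(i = 1L, j = 2L, start = 40L,
                                        end = 110L, delta = 0.6),
              seed = seed)
}
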