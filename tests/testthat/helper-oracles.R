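# Independent brute-force oracles used to validate the hand-written
# operators, plus small fixture builders.

# Exhaustive-scan peak detector: for every strict local maximum (leftmost
# point of a flat top), walk outward point by point to find each base (the
# minimum before the nearest strictly higher point, or the signal end),
# the prominence, and the interpolated width at half prominence.
oracle_peaks <- function(y) {
  n <- length(y)
  rows <- list()
  for (i in seq_len(n)) {
    if (i < 2L || i > n - 1L) next
    if (!(y[i] > y[i - 1L])) next
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L
    if (j >= n || y[j + 1L] >= y[i]) next
    lmin <- Inf; k <- i - 1L
    while (k >= 1L && y[k] <= y[i]) { lmin <- min(lmin, y[k]); k <- k - 1L }
    rmin <- Inf; k <- j + 1L
    while (k <= n && y[k] <= y[i]) { rmin <- min(rmin, y[k]); k <- k + 1L }
    prom <- y[i] - max(lmin, rmin)
    ref <- y[i] - prom / 2
    k <- i - 1L
    while (y[k] > ref) k <- k - 1L
    xl <- k + (ref - y[k]) / (y[k + 1L] - y[k])
    k <- i + 1L
    while (y[k] > ref) k <- k + 1L
    xr <- k - (ref - y[k]) / (y[k - 1L] - y[k])
    rows[[length(rows) + 1L]] <- data.frame(bin_index = i, prominence = prom,
                                            width = xr - xl)
  }
  do.call(rbind, rows)
}

# Direct evaluation of the multi-rater kappa formulas from an
# items x categories count matrix.
oracle_fleiss <- function(counts) {
  n <- rowSums(counts)[1]
  p_i <- apply(counts, 1, function(r) (sum(r^2) - n) / (n * (n - 1)))
  p_j <- colSums(counts) / sum(counts)
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  (p_bar - p_e) / (1 - p_e)
}

# Covariance eigendecomposition route to PCA.
oracle_pca <- function(x) {
  xc <- scale(x, center = TRUE, scale = FALSE)
  eg <- eigen(stats::cov(xc), symmetric = TRUE)
  list(fractions = eg$values / sum(eg$values),
       scores = xc %*% eg$vectors)
}

# Wrap a bare dB vector as a band-selected binned spectrum.
make_binned <- function(y, centers = seq_along(y)) {
  structure(list(bin_centers = centers, bin_power_db = as.numeric(y),
                 bin_size = 80L, n_bins_total = length(y),
                 band = c(1L, length(y))),
            class = "binned_spectrum")
}

# A small, fast simulation config for unit tests.
tiny_config <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(psv = 140, edv = 35, heart_rate = 150, duration = 3.3, seed = seed),
    list(...))
  do.call(simulation_config, args)
}

# A peak feature matrix built directly from numbers (bypasses audio).
fake_pfm <- function(id, prominence, height, width, location,
                     subject = "unknown") {
  extract_peak_features(
    data.frame(prominence = prominence, height = height, width = width,
               location = location),
    recording_id = id, subject_id = subject, n_peaks = length(prominence))
}
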