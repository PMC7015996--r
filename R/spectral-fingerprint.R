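#' One-sided periodogram of an audio signal
#'
#' Power spectral density estimate over the full recording: rectangular
#' window, no detrending, DFT zero-padded (or truncated) so that exactly
#' `n_freq` equally spaced frequencies from 0 to Nyquist are returned.
#' Power is expressed in dB relative to `db_reference`; the default of
#' 1e-12 follows the acoustic intensity-level convention and keeps the dB
#' values of any realistic recording positive, which the downstream
#' max-normalization of peak heights relies on. Bins with zero power are
#' floored at -300 dB.
#'
#' @param signal An [audio_signal()].
#' @param n_freq Number of frequency values returned (default 100000).
#' @param db_reference Reference PSD for the dB scale.
#' @return A `power_spectrum`: list with `frequencies` (Hz, ascending) and
#'   `power_db`, both of length `n_freq`.
#' @export
#' @examples
#' sig <- audio_signal(sin(2 * pi * 1000 * (0:44099) / 44100), 44100)
#' ps <- compute_periodogram(sig, n_freq = 5000)
#' ps$frequencies[which.max(ps$power_db)]  # ~1000 Hz
compute_periodogram <- function(signal, n_freq = 100000L, db_reference = 1e-12) {
  stopifnot(inherits(signal, "audio_signal"))
  n_freq <- check_count(n_freq, "n_freq", lower = 2L)
  check_number(db_reference, "db_reference", lower = 0, strict_lower = TRUE,
               class = "validation_error")
  x <- signal$samples
  fs <- signal$sampling_rate
  n <- length(x)
  nfft <- 2L * (n_freq - 1L)
  xp <- if (n >= nfft) x[seq_len(nfft)] else c(x, numeric(nfft - n))
  X <- stats::fft(xp)[seq_len(n_freq)]
  psd <- Mod(X)^2 / (fs * min(n, nfft))
  psd[2:(n_freq - 1L)] <- 2 * psd[2:(n_freq - 1L)]  # one-sided scaling
  if (all(psd == 0))
    warning("all-zero signal: periodogram floored at -300 dB")
  power_db <- ifelse(psd > 0, 10 * log10(psd / db_reference), -300)
  power_db <- pmax(power_db, -300)
  structure(list(frequencies = (seq_len(n_freq) - 1) * fs / nfft,
                 power_db = power_db),
            class = "power_spectrum")
}

#' Bin a power spectrum into fixed-width frequency bins
#'
#' Bin `k` (1-based) aggregates frequency points `(k-1)*bin_size + 1` through
#' `k*bin_size`; its power is the arithmetic mean of the dB values and its
#' centre the mean of the frequencies. A trailing remainder shorter than
#' `bin_size` is discarded. 100000 points binned by 80 give 1250 bins.
#'
#' @param spectrum A `power_spectrum` from [compute_periodogram()].
#' @param bin_size Frequency points per bin (default 80).
#' @return A `binned_spectrum`: `bin_centers` (Hz), `bin_power_db`,
#'   `bin_size`, `n_bins_total`, and `band` (set by [select_band()]).
#' @export
bin_spectrum <- function(spectrum, bin_size = 80L) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  bin_size <- check_count(bin_size, "bin_size")
  n <- length(spectrum$power_db)
  if (n < bin_size)
    stop_("spectrum has %d points, fewer than bin_size %d", n, bin_size,
          class = "validation_error")
  n_bins <- n %/% bin_size
  keep <- seq_len(n_bins * bin_size)
  pw <- matrix(spectrum$power_db[keep], nrow = bin_size)
  fr <- matrix(spectrum$frequencies[keep], nrow = bin_size)
  structure(list(bin_centers = colMeans(fr), bin_power_db = colMeans(pw),
                 bin_size = bin_size, n_bins_total = n_bins, band = NULL),
            class = "binned_spectrum")
}

#' Restrict a binned spectrum to an analysis band
#'
#' Keeps bins `first_bin` through `last_bin` (1-based, both inclusive),
#' discarding the low-frequency vessel-wall signal and high-frequency
#' instrumentation noise outside the band. The defaults (10, 200) retain
#' 191 bins.
#'
#' @param binned A `binned_spectrum`.
#' @param first_bin,last_bin 1-based inclusive bin range.
#' @return A `binned_spectrum` covering the selected band.
#' @export
select_band <- function(binned, first_bin = 10L, last_bin = 200L) {
  stopifnot(inherits(binned, "binned_spectrum"))
  first_bin <- check_count(first_bin, "first_bin")
  last_bin <- check_count(last_bin, "last_bin")
  n <- length(binned$bin_power_db)
  if (first_bin > last_bin || last_bin > n)
    stop_("band [%d, %d] out of range for %d bins", first_bin, last_bin, n,
          class = "validation_error")
  idx <- first_bin:last_bin
  structure(list(bin_centers = binned$bin_centers[idx],
                 bin_power_db = binned$bin_power_db[idx],
                 bin_size = binned$bin_size,
                 n_bins_total = binned$n_bins_total,
                 band = c(first_bin, last_bin)),
            class = "binned_spectrum")
}

# Local maxima: strictly greater than both immediate neighbours; a flat top
# is represented by its leftmost point. Endpoints are never peaks.
local_maxima <- function(y) {
  n <- length(y)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (y[i] > y[i - 1L]) {
      j <- i
      while (j < n && y[j + 1L] == y[i]) j <- j + 1L
      if (j < n && y[j + 1L] < y[i]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# Prominence and base positions of the peak at index i.
peak_prominence <- function(y, i) {
  h <- y[i]
  n <- length(y)
  higher_left <- which(y[seq_len(i - 1L)] > h)
  lo <- if (length(higher_left)) max(higher_left) + 1L else 1L
  left_seg <- y[lo:(i - 1L)]
  left_base <- min(left_seg)
  left_pos <- lo - 1L + max(which(left_seg == left_base))  # nearest to peak
  higher_right <- which(y[(i + 1L):n] > h)
  hi <- if (length(higher_right)) i + min(higher_right) - 1L else n
  right_seg <- y[(i + 1L):hi]
  right_base <- min(right_seg)
  right_pos <- i + min(which(right_seg == right_base))
  list(prominence = h - max(left_base, right_base),
       left_pos = left_pos, right_pos = right_pos)
}

# Interpolated crossings of the half-prominence reference level, searched no
# farther than the prominence bases; width in (fractional) bins.
peak_width <- function(y, i, prominence, left_pos, right_pos) {
  ref <- y[i] - prominence / 2
  xl <- left_pos
  for (j in (i - 1L):left_pos) {
    if (y[j] <= ref) {
      xl <- j + (ref - y[j]) / (y[j + 1L] - y[j])
      break
    }
  }
  xr <- right_pos
  for (j in (i + 1L):right_pos) {
    if (y[j] <= ref) {
      xr <- j - (ref - y[j]) / (y[j - 1L] - y[j])
      break
    }
  }
  xr - xl
}

#' Detect the most prominent spectral peaks
#'
#' Finds local maxima of the band-limited spectrum and, for each, its
#' prominence (height above the higher of the two bases, where each base is
#' the minimum between the peak and the nearest higher point on that side,
#' or the spectrum end) and its width at half prominence (linear-interpolated
#' crossings of the level `height - prominence/2`, searched no farther than
#' the bases). The `n_peaks` peaks of largest prominence are returned,
#' ordered by ascending location; prominence ties for the last slot are
#' broken in favour of the lower bin index.
#'
#' @param binned A band-selected `binned_spectrum`.
#' @param n_peaks Number of peaks to keep (default 10).
#' @return Data frame with columns `bin_index` (1-based within the band),
#'   `location` (Hz, the peak bin's centre), `height` (dB), `prominence`
#'   (dB) and `width` (bins, fractional).
#' @export
find_prominent_peaks <- function(binned, n_peaks = 10L) {
  stopifnot(inherits(binned, "binned_spectrum"))
  n_peaks <- check_count(n_peaks, "n_peaks")
  y <- binned$bin_power_db
  idx <- local_maxima(y)
  if (length(idx) < n_peaks)
    stop_("only %d local maxima found; %d peaks required (recording rejected)",
          length(idx), n_peaks, class = "insufficient_peaks")
  pr <- lapply(idx, function(i) peak_prominence(y, i))
  prom <- vapply(pr, `[[`, numeric(1), "prominence")
  width <- vapply(seq_along(idx), function(k)
    peak_width(y, idx[k], prom[k], pr[[k]]$left_pos, pr[[k]]$right_pos),
    numeric(1))
  keep <- order(-prom, idx)[seq_len(n_peaks)]
  keep <- keep[order(idx[keep])]  # ascending location
  data.frame(bin_index = idx[keep],
             location = binned$bin_centers[idx[keep]],
             height = y[idx[keep]],
             prominence = prom[keep],
             width = width[keep])
}

#' Assemble the per-recording peak feature matrix
#'
#' Validates and orders the peak table of one recording: exactly `n_peaks`
#' peaks, rows by ascending location (ties broken by descending prominence),
#' four parameters per peak — 40 values for the default 10 peaks.
#'
#' @param peaks Data frame as returned by [find_prominent_peaks()].
#' @param recording_id Label for the recording.
#' @param subject_id Label for the individual (used later to constrain
#'   similar/dissimilar pairs to different subjects).
#' @param n_peaks Required number of peaks.
#' @return A `peak_feature_matrix`: list with `recording_id`, `subject_id`
#'   and `features`, a `n_peaks x 4` data frame with columns `prominence`,
#'   `height`, `width`, `location`.
#' @export
extract_peak_features <- function(peaks, recording_id, subject_id = "unknown",
                                  n_peaks = 10L) {
  n_peaks <- check_count(n_peaks, "n_peaks")
  need <- c("prominence", "height", "width", "location")
  if (!is.data.frame(peaks) || !all(need %in% names(peaks)))
    stop_("'peaks' must be a data frame with columns %s",
          paste(need, collapse = ", "), class = "validation_error")
  if (nrow(peaks) != n_peaks)
    stop_("expected %d peaks, got %d", n_peaks, nrow(peaks),
          class = "validation_error")
  ord <- order(peaks$location, -peaks$prominence)
  structure(list(recording_id = as.character(recording_id),
                 subject_id = as.character(subject_id),
                 features = peaks[ord, need, drop = FALSE]),
            class = "peak_feature_matrix")
}

fingerprint_names <- c("sum_prominence", "sum_height", "sum_width",
                       "mean_location", "var_location")

reduce_features <- function(features, stage1_max) {
  norm <- sweep(as.matrix(features[, names(stage1_max)]), 2, stage1_max, "/")
  c(sum_prominence = sum(norm[, "prominence"]),
    sum_height = sum(norm[, "height"]),
    sum_width = sum(norm[, "width"]),
    mean_location = mean(norm[, "location"]),
    var_location = stats::var(norm[, "location"]))
}

#' Build the fingerprint collection from peak feature matrices
#'
#' Three-stage reduction of the 40 peak parameters per recording to a
#' 5-element fingerprint: (1) each of the four peak parameters is divided by
#' its maximum pooled over all peaks of all recordings; (2) per recording,
#' the normalized values are reduced to the sum of prominences, sum of
#' heights, sum of widths, mean of locations and sample variance (n-1
#' denominator) of locations; (3) each of the five resulting columns is
#' divided by its maximum over recordings, so every column of the collection
#' has maximum one. All nine normalization constants are stored so new
#' recordings can be projected with [apply_fingerprint()].
#'
#' @param matrices List of [extract_peak_features()] results (>= 2).
#' @return A `fingerprint_collection`: `fingerprints` (n x 5 matrix, rows
#'   named by recording id), `stage1_max` (4 constants), `stage2_max`
#'   (5 constants), `recording_ids`, `subject_ids`.
#' @export
build_fingerprints <- function(matrices) {
  if (!is.list(matrices) || length(matrices) < 2L ||
      !all(vapply(matrices, inherits, logical(1), "peak_feature_matrix")))
    stop_("'matrices' must be a list of >= 2 peak_feature_matrix objects",
          class = "validation_error")
  pooled <- do.call(rbind, lapply(matrices, `[[`, "features"))
  stage1_max <- vapply(c("prominence", "height", "width", "location"),
                       function(p) max(pooled[[p]]), numeric(1))
  if (any(stage1_max <= 0))
    stop_("pooled maximum of '%s' is not positive; features degenerate",
          names(stage1_max)[which(stage1_max <= 0)[1]],
          class = "degenerate_feature")
  reduced <- t(vapply(matrices, function(m) reduce_features(m$features, stage1_max),
                      numeric(5)))
  colnames(reduced) <- fingerprint_names
  stage2_max <- apply(reduced, 2, max)
  if (any(stage2_max <= 0))
    stop_("maximum of reduced feature '%s' is not positive; features degenerate",
          names(stage2_max)[which(stage2_max <= 0)[1]],
          class = "degenerate_feature")
  fp <- sweep(reduced, 2, stage2_max, "/")
  rownames(fp) <- vapply(matrices, `[[`, character(1), "recording_id")
  structure(list(fingerprints = fp,
                 stage1_max = stage1_max, stage2_max = stage2_max,
                 recording_ids = rownames(fp),
                 subject_ids = vapply(matrices, `[[`, character(1), "subject_id")),
            class = "fingerprint_collection")
}

#' @export
print.fingerprint_collection <- function(x, ...) {
  cat(sprintf("fingerprint_collection: %d recordings x %d features\n",
              nrow(x$fingerprints), ncol(x$fingerprints)))
  invisible(x)
}

#' Project a recording with frozen normalization constants
#'
#' Applies the same three-stage reduction as [build_fingerprints()] but with
#' the constants stored in an existing collection, so a new recording can be
#' fingerprinted against an established index. Values may exceed one if the
#' new recording is more extreme than anything indexed.
#'
#' @param matrix A `peak_feature_matrix`.
#' @param collection A `fingerprint_collection` holding the constants.
#' @return Named numeric vector of the five fingerprint features.
#' @export
apply_fingerprint <- function(matrix, collection) {
  stopifnot(inherits(matrix, "peak_feature_matrix"))
  if (!inherits(collection, "fingerprint_collection") ||
      is.null(collection$stage1_max) || is.null(collection$stage2_max))
    stop_("collection does not carry normalization constants",
          class = "state_error")
  reduce_features(matrix$features, collection$stage1_max) / collection$stage2_max
}

#' Fingerprint one audio recording (periodogram through peak features)
#'
#' Convenience wrapper chaining [compute_periodogram()], [bin_spectrum()],
#' [select_band()], [find_prominent_peaks()] and [extract_peak_features()].
#'
#' @param signal An [audio_signal()].
#' @param n_freq,bin_size,first_bin,last_bin,n_peaks Pipeline parameters; see
#'   the individual stages.
#' @return A `peak_feature_matrix` for the recording.
#' @export
fingerprint_audio <- function(signal, n_freq = 100000L, bin_size = 80L,
                              first_bin = 10L, last_bin = 200L, n_peaks = 10L) {
  spec <- compute_periodogram(signal, n_freq = n_freq)
  band <- select_band(bin_spectrum(spec, bin_size = bin_size),
                      first_bin = first_bin, last_bin = last_bin)
  peaks <- find_prominent_peaks(band, n_peaks = n_peaks)
  extract_peak_features(peaks, recording_id = signal$recording_id,
                        subject_id = signal$subject_id, n_peaks = n_peaks)
}

#' @export
as.data.frame.fingerprint_collection <- function(x, ...) {
  data.frame(recording_id = x$recording_ids, subject_id = x$subject_ids,
             as.data.frame(x$fingerprints), row.names = NULL)
}

#' Write a fingerprint collection to CSV and JSON
#'
#' The CSV holds one row per recording (ids plus the five features); the
#' JSON additionally stores the nine normalization constants so the index
#' can be reloaded for [apply_fingerprint()].
#'
#' @param collection A `fingerprint_collection`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return `collection`, invisibly.
#' @export
write_fingerprints <- function(collection, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(collection, "fingerprint_collection"))
  if (!is.null(csv_path))
    utils::write.csv(as.data.frame(collection), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(
      fingerprints = as.data.frame(collection),
      stage1_max = as.list(collection$stage1_max),
      stage2_max = as.list(collection$stage2_max)),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(collection)
}
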