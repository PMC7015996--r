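#' Construct an audio signal object
#'
#' Container for one mono Doppler audio recording: an amplitude vector in
#' `[-1, 1]`, its sampling rate, and identity metadata. Recordings shorter
#' than one second are rejected; a usable Doppler recording spans at least
#' eight cardiac cycles and is always far longer than that.
#'
#' @param samples Numeric amplitude vector, finite, in `[-1, 1]`.
#' @param sampling_rate Sampling rate, Hz.
#' @param recording_id,subject_id Labels identifying the recording and the
#'   individual it came from.
#' @param vessel_side `"left"`, `"right"` or `"unknown"`.
#' @return An object of class `"audio_signal"`.
#' @export
audio_signal <- function(samples, sampling_rate, recording_id = "rec",
                         subject_id = "unknown", vessel_side = "unknown") {
  check_number(sampling_rate, "sampling_rate", lower = 0, strict_lower = TRUE,
               class = "validation_error")
  if (length(samples) == 0L)
    stop_("audio signal has no samples", class = "validation_error")
  if (length(samples) < sampling_rate)
    stop_("audio signal shorter than 1 s (%d samples at %g Hz)",
          length(samples), sampling_rate, class = "validation_error")
  if (!all(is.finite(samples)))
    stop_("audio samples must be finite", class = "validation_error")
  vessel_side <- match.arg(vessel_side, c("left", "right", "unknown"))
  structure(list(samples = as.numeric(samples),
                 sampling_rate = as.numeric(sampling_rate),
                 recording_id = as.character(recording_id),
                 subject_id = as.character(subject_id),
                 vessel_side = vessel_side),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("audio_signal '%s' (subject %s, %s): %.2f s @ %g Hz\n",
              x$recording_id, x$subject_id, x$vessel_side,
              length(x$samples) / x$sampling_rate, x$sampling_rate))
  invisible(x)
}

# ---- raw-vector integer helpers -------------------------------------------

raw_int <- function(bytes, size, endian, signed = TRUE) {
  n <- length(bytes) %/% size
  m <- matrix(as.integer(bytes[seq_len(n * size)]), nrow = size)
  if (endian == "big") m <- m[rev(seq_len(size)), , drop = FALSE]
  weights <- 256^(seq_len(size) - 1)
  v <- as.numeric(weights %*% m)
  if (signed) {
    lim <- 256^size
    v <- ifelse(v >= lim / 2, v - lim, v)
  }
  v
}

int_raw <- function(values, size, endian) {
  lim <- 256^size
  v <- values %% lim
  out <- raw(length(v) * size)
  for (b in seq_len(size)) {
    byte <- v %% 256
    idx <- if (endian == "little") b else size + 1L - b
    out[seq(idx, by = size, length.out = length(v))] <- as.raw(byte)
    v <- (v - byte) / 256
  }
  out
}

# IEEE 754 80-bit extended float (AIFF sample-rate field)
ext80_decode <- function(bytes) {
  se <- raw_int(bytes[1:2], 2, "big", signed = FALSE)
  sign <- if (se >= 32768) -1 else 1
  expo <- se %% 32768
  hi <- raw_int(bytes[3:6], 4, "big", signed = FALSE)
  lo <- raw_int(bytes[7:10], 4, "big", signed = FALSE)
  mant <- hi * 2^32 + lo
  if (expo == 0 && mant == 0) return(0)
  sign * mant * 2^(expo - 16383 - 63)
}

ext80_encode <- function(x) {
  if (x <= 0) stop_("sample rate must be positive", class = "io_error")
  expo <- floor(log2(x))
  mant <- round(x / 2^(expo - 63))
  if (mant >= 2^64) { mant <- mant / 2; expo <- expo + 1 }
  hi <- floor(mant / 2^32)
  lo <- mant - hi * 2^32
  c(int_raw(expo + 16383, 2, "big"),
    int_raw(hi, 4, "big"), int_raw(lo, 4, "big"))
}

# ---- WAV -------------------------------------------------------------------

read_wav_raw <- function(bytes) {
  if (length(bytes) < 44 || rawToChar(bytes[1:4]) != "RIFF" ||
      rawToChar(bytes[9:12]) != "WAVE")
    stop_("not a RIFF/WAVE file", class = "format_error")
  pos <- 13L
  fmt <- NULL; dat <- NULL
  while (pos + 8 <= length(bytes) + 1) {
    id <- rawToChar(bytes[pos:(pos + 3L)])
    sz <- raw_int(bytes[(pos + 4L):(pos + 7L)], 4, "little", signed = FALSE)
    body <- bytes[(pos + 8L):min(length(bytes), pos + 7L + sz)]
    if (id == "fmt ") fmt <- body
    if (id == "data") dat <- body
    pos <- pos + 8L + sz + (sz %% 2L)  # chunks are word-aligned
  }
  if (is.null(fmt) || is.null(dat))
    stop_("WAV file missing fmt/data chunk", class = "format_error")
  audio_format <- raw_int(fmt[1:2], 2, "little", signed = FALSE)
  n_channels <- raw_int(fmt[3:4], 2, "little", signed = FALSE)
  fs <- raw_int(fmt[5:8], 4, "little", signed = FALSE)
  bits <- raw_int(fmt[15:16], 2, "little", signed = FALSE)
  if (audio_format == 65534 && length(fmt) >= 26)  # WAVE_FORMAT_EXTENSIBLE
    audio_format <- raw_int(fmt[25:26], 2, "little", signed = FALSE)
  x <- if (audio_format == 1 && bits == 16) {
    raw_int(dat, 2, "little") / 32768
  } else if (audio_format == 1 && bits == 24) {
    raw_int(dat, 3, "little") / 8388608
  } else if (audio_format == 3 && bits == 32) {
    readBin(dat, numeric(), n = length(dat) %/% 4L, size = 4, endian = "little")
  } else {
    stop_("unsupported WAV encoding (format %d, %d bit)", audio_format, bits,
          class = "format_error")
  }
  list(samples = x, sampling_rate = fs, n_channels = n_channels)
}

write_wav_raw <- function(samples, fs, path) {
  q <- round(samples * 32768)
  q <- pmin(pmax(q, -32768), 32767)
  dat <- int_raw(q, 2, "little")
  fmt <- c(int_raw(1, 2, "little"), int_raw(1, 2, "little"),
           int_raw(fs, 4, "little"), int_raw(fs * 2, 4, "little"),
           int_raw(2, 2, "little"), int_raw(16, 2, "little"))
  body <- c(charToRaw("WAVE"),
            charToRaw("fmt "), int_raw(length(fmt), 4, "little"), fmt,
            charToRaw("data"), int_raw(length(dat), 4, "little"), dat)
  writeBin(c(charToRaw("RIFF"), int_raw(length(body), 4, "little"), body),
           path)
}

# ---- AIFF ------------------------------------------------------------------

read_aiff_raw <- function(bytes) {
  if (length(bytes) < 12 || rawToChar(bytes[1:4]) != "FORM" ||
      rawToChar(bytes[9:12]) != "AIFF")
    stop_("not a FORM/AIFF file", class = "format_error")
  pos <- 13L
  comm <- NULL; ssnd <- NULL
  while (pos + 8 <= length(bytes) + 1) {
    id <- rawToChar(bytes[pos:(pos + 3L)])
    sz <- raw_int(bytes[(pos + 4L):(pos + 7L)], 4, "big", signed = FALSE)
    body <- bytes[(pos + 8L):min(length(bytes), pos + 7L + sz)]
    if (id == "COMM") comm <- body
    if (id == "SSND") ssnd <- body
    pos <- pos + 8L + sz + (sz %% 2L)
  }
  if (is.null(comm) || is.null(ssnd))
    stop_("AIFF file missing COMM/SSND chunk", class = "format_error")
  n_channels <- raw_int(comm[1:2], 2, "big", signed = FALSE)
  bits <- raw_int(comm[7:8], 2, "big", signed = FALSE)
  fs <- ext80_decode(comm[9:18])
  offset <- raw_int(ssnd[1:4], 4, "big", signed = FALSE)
  dat <- ssnd[(9L + offset):length(ssnd)]
  x <- if (bits == 16) {
    raw_int(dat, 2, "big") / 32768
  } else if (bits == 24) {
    raw_int(dat, 3, "big") / 8388608
  } else {
    stop_("unsupported AIFF sample size (%d bit)", bits, class = "format_error")
  }
  list(samples = x, sampling_rate = fs, n_channels = n_channels)
}

write_aiff_raw <- function(samples, fs, path) {
  q <- round(samples * 32768)
  q <- pmin(pmax(q, -32768), 32767)
  dat <- int_raw(q, 2, "big")
  comm <- c(int_raw(1, 2, "big"),                   # channels
            int_raw(length(samples), 4, "big"),     # sample frames
            int_raw(16, 2, "big"),                  # bits
            ext80_encode(fs))
  ssnd <- c(int_raw(0, 4, "big"), int_raw(0, 4, "big"), dat)
  body <- c(charToRaw("AIFF"),
            charToRaw("COMM"), int_raw(length(comm), 4, "big"), comm,
            charToRaw("SSND"), int_raw(length(ssnd), 4, "big"), ssnd)
  writeBin(c(charToRaw("FORM"), int_raw(length(body), 4, "big"), body),
           path)
}

# ---- public API ------------------------------------------------------------

#' Read a WAV or AIFF audio file
#'
#' Supports RIFF WAV (16/24-bit PCM and 32-bit float) and AIFF (16/24-bit
#' PCM). Multi-channel input is downmixed to mono by the per-frame channel
#' mean; integer PCM is scaled by `2^(bits-1)` into `[-1, 1]`.
#'
#' @param path Path to a `.wav`/`.aif`/`.aiff` file.
#' @param recording_id,subject_id,vessel_side Optional identity metadata;
#'   `recording_id` defaults to the file name without extension.
#' @return An [audio_signal()].
#' @export
#' @examples
#' f <- tempfile(fileext = ".wav")
#' write_audio(audio_signal(sin(2 * pi * 440 * (0:44099) / 44100), 44100), f)
#' sig <- read_audio(f)
#' sig$sampling_rate
read_audio <- function(path, recording_id = NULL, subject_id = "unknown",
                       vessel_side = "unknown") {
  if (!file.exists(path))
    stop_("audio file not found: %s", path, class = "io_error")
  bytes <- readBin(path, raw(), n = file.size(path))
  magic <- rawToChar(bytes[1:4])
  raw_audio <- switch(magic,
    RIFF = read_wav_raw(bytes),
    FORM = read_aiff_raw(bytes),
    stop_("unrecognized audio container in %s", path, class = "format_error"))
  x <- raw_audio$samples
  if (raw_audio$n_channels > 1) {
    n_frames <- length(x) %/% raw_audio$n_channels
    x <- colMeans(matrix(x[seq_len(n_frames * raw_audio$n_channels)],
                         nrow = raw_audio$n_channels))
  }
  if (length(x) == 0L)
    stop_("audio file %s contains no samples", path, class = "validation_error")
  audio_signal(x, raw_audio$sampling_rate,
               recording_id = recording_id %||%
                 sub("\\.[^.]+$", "", basename(path)),
               subject_id = subject_id, vessel_side = vessel_side)
}

#' Write an audio signal to WAV or AIFF
#'
#' Writes 16-bit PCM; the container is chosen by the file extension
#' (`.aif`/`.aiff` for AIFF, anything else for RIFF WAV). Samples outside
#' `[-1, 1]` are clamped with a warning. A written file read back with
#' [read_audio()] reproduces the samples within one 16-bit quantization step.
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_audio <- function(signal, path) {
  stopifnot(inherits(signal, "audio_signal"))
  x <- signal$samples
  if (any(abs(x) > 1)) {
    warning("samples outside [-1, 1] clamped on write")
    x <- pmin(pmax(x, -1), 1)
  }
  aiff <- grepl("\\.aiff?$", path, ignore.case = TRUE)
  if (aiff) write_aiff_raw(x, signal$sampling_rate, path)
  else write_wav_raw(x, signal$sampling_rate, path)
  invisible(path)
}

#' Read a recording metadata sidecar table
#'
#' @param path CSV with columns `recording_id`, `subject_id`, `vessel_side`,
#'   `path` (audio file path, relative to the CSV's directory unless
#'   absolute).
#' @return A data frame with those columns, paths resolved.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("recording_id", "subject_id", "vessel_side", "path")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols))
    stop_("metadata CSV missing column(s): %s",
          paste(missing_cols, collapse = ", "), class = "format_error")
  rel <- !grepl("^(/|[A-Za-z]:)", meta$path)
  meta$path[rel] <- file.path(dirname(path), meta$path[rel])
  meta
}
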