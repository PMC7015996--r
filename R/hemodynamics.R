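#' Time-domain hemodynamic indices from a velocity waveform
#'
#' Computes the conventional pulsed-wave Doppler indices. PSV is the maximum
#' velocity and Vmin the minimum over the waveform; the mean velocity is the
#' trapezoidal time-average over complete cardiac cycles only (a trailing
#' partial cycle is discarded); EDV is the velocity at the end of each
#' complete cycle (sample nearest the cycle boundary), averaged over cycles.
#' The pulsatility index is `(PSV - Vmin) / Vmean` and the resistive index
#' `(PSV - EDV) / PSV`.
#'
#' @param waveform A [velocity_waveform()] spanning at least one full cycle.
#' @param heart_rate Heart rate in beats/min, defining the cycle period.
#' @param subject_id,vessel_side Identity labels carried into the output.
#' @return One-row data frame: `subject_id`, `vessel_side`, `psv`, `edv`,
#'   `vmin`, `vmean` (cm/s), `pi`, `ri` (dimensionless).
#' @export
#' @examples
#' # triangular pulse: rises 50 -> 100 -> back to 50 over one 1 s cycle
#' tt <- seq(0, 1, by = 0.001)
#' wf <- velocity_waveform(tt, 50 + 50 * (1 - abs(2 * tt - 1)))
#' compute_indices(wf, heart_rate = 60)  # pi = 2/3, ri = 0.5
compute_indices <- function(waveform, heart_rate, subject_id = "unknown",
                            vessel_side = "unknown") {
  stopifnot(inherits(waveform, "velocity_waveform"))
  check_number(heart_rate, "heart_rate", lower = 0, strict_lower = TRUE,
               class = "validation_error")
  tt <- waveform$times
  v <- waveform$velocities
  period <- 60 / heart_rate
  span <- tt[length(tt)] - tt[1]
  n_complete <- floor(span / period + 1e-9)
  if (n_complete < 1)
    stop_("waveform spans %.3f s, less than one %.3f s cycle", span, period,
          class = "validation_error")
  psv <- max(v)
  vmin <- min(v)
  t_end <- tt[1] + n_complete * period
  in_win <- tt <= t_end + 1e-12
  ti <- tt[in_win]; vi <- v[in_win]
  vmean <- sum(diff(ti) * (utils::head(vi, -1) + utils::tail(vi, -1)) / 2) /
    (ti[length(ti)] - ti[1])
  boundaries <- tt[1] + period * seq_len(n_complete)
  edv <- mean(vapply(boundaries, function(b) v[which.min(abs(tt - b))],
                     numeric(1)))
  if (vmean == 0)
    stop_("mean velocity is zero; pulsatility index undefined",
          class = "undefined_pi")
  if (psv == 0)
    stop_("peak-systolic velocity is zero; resistive index undefined",
          class = "undefined_ri")
  data.frame(subject_id = as.character(subject_id),
             vessel_side = as.character(vessel_side),
             psv = psv, edv = edv, vmin = vmin, vmean = vmean,
             pi = (psv - vmin) / vmean, ri = (psv - edv) / psv,
             stringsAsFactors = FALSE)
}

#' Average hemodynamic indices per vessel
#'
#' Arithmetic mean of PSV, EDV, PI and RI over repeated samples of the same
#' vessel, grouped by subject and vessel side.
#'
#' @param per_sample Data frame of [compute_indices()] rows.
#' @return Data frame with one row per (subject_id, vessel_side) group and
#'   the group means of `psv`, `edv`, `pi`, `ri`.
#' @export
average_indices <- function(per_sample) {
  need <- c("subject_id", "vessel_side", "psv", "edv", "pi", "ri")
  if (!is.data.frame(per_sample) || !all(need %in% names(per_sample)))
    stop_("'per_sample' must contain columns %s", paste(need, collapse = ", "),
          class = "validation_error")
  if (nrow(per_sample) == 0L) {
    warning("no records to average")
    return(per_sample[, need])
  }
  out <- stats::aggregate(per_sample[, c("psv", "edv", "pi", "ri")],
                          by = per_sample[, c("subject_id", "vessel_side")],
                          FUN = mean)
  out[order(out$subject_id, out$vessel_side), , drop = FALSE]
}

#' Read a velocity waveform from CSV
#'
#' @param path CSV with columns `time_s` and `velocity_cm_s`.
#' @return A [velocity_waveform()].
#' @export
read_waveform <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "velocity_cm_s") %in% names(d)))
    stop_("waveform CSV needs columns time_s, velocity_cm_s",
          class = "format_error")
  velocity_waveform(d$time_s, d$velocity_cm_s)
}

#' Write a velocity waveform to CSV
#'
#' @param waveform A [velocity_waveform()].
#' @param path Output CSV path (columns `time_s`, `velocity_cm_s`).
#' @return `path`, invisibly.
#' @export
write_waveform <- function(waveform, path) {
  stopifnot(inherits(waveform, "velocity_waveform"))
  utils::write.csv(data.frame(time_s = waveform$times,
                              velocity_cm_s = waveform$velocities),
                   path, row.names = FALSE)
  invisible(path)
}
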