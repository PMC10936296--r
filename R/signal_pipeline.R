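# EMG/force processing: band-pass, sliding RMS, MVIC normalization (nRMS),
# phase segmentation, peak device-to-body force extraction and the
# reducer/co-contractor phenotype rule.

#' Zero-phase Butterworth band-pass filter
#'
#' 4th-order Butterworth applied forward-backward ([signal::filtfilt()]),
#' giving zero phase distortion and doubling the effective attenuation.
#'
#' @param x numeric series, or a matrix filtered column-wise.
#' @param rate sampling rate (Hz).
#' @param low,high band edges (Hz); defaults 20-400 Hz.
#' @param order Butterworth design order.
#' @return Filtered series, same shape as `x`.
#' @export
emg_bandpass <- function(x, rate, low = 20, high = 400, order = 4) {
  if (!(low < high && high < rate / 2)) {
    stop("need low < high < rate/2 (Nyquist)")
  }
  filt <- signal::butter(order, c(low, high) / (rate / 2), type = "pass")
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- signal::filtfilt(filt, x[, j])
    out
  } else {
    signal::filtfilt(filt, x)
  }
}

#' Centered sliding-window RMS envelope
#'
#' Single-sample hop, centered window; windows are shrunk at the series
#' edges so the envelope has the same length as the input.
#'
#' @param x numeric series, or a matrix processed column-wise.
#' @param rate sampling rate (Hz).
#' @param window window length in seconds (default 125 ms).
#' @return Non-negative envelope, same shape as `x`.
#' @export
sliding_rms <- function(x, rate, window = 0.125) {
  if (is.matrix(x)) {
    out <- x
    for (j in seq_len(ncol(x))) out[, j] <- sliding_rms(x[, j], rate, window)
    return(out)
  }
  n <- length(x)
  L <- round(window * rate)
  if (L < 2) stop("window must span at least 2 samples")
  if (L > n) stop("window longer than the series")
  h1 <- (L - 1L) %/% 2L
  h2 <- L - 1L - h1
  i <- seq_len(n)
  lo <- pmax(1L, i - h1)
  hi <- pmin(n, i + h2)
  cs <- c(0, cumsum(x^2))
  sqrt((cs[hi + 1L] - cs[lo]) / (hi - lo + 1L))
}

#' Segment a recording into lift / hold / lower windows
#'
#' Half-open windows `[0, lift)`, `[lift, lift+hold)`, `[lift+hold, end)`
#' expressed as inclusive 1-based R index ranges.
#'
#' @param lift_s,hold_s,lower_s phase durations (s).
#' @param rate sampling rate (Hz).
#' @param n_samples actual series length, checked against the durations
#'   (must agree within one sample).
#' @return Object of class `phase_windows`: list of `c(from, to)` index
#'   pairs for `lift`, `hold`, `lower`.
#' @export
segment_phases <- function(lift_s, hold_s, lower_s, rate, n_samples) {
  n_lift <- round(lift_s * rate)
  n_hold <- round(hold_s * rate)
  n_lower <- round(lower_s * rate)
  if (abs(n_lift + n_hold + n_lower - n_samples) > 1) {
    stop(sprintf("series length %d inconsistent with durations (expect %d samples)",
                 n_samples, n_lift + n_hold + n_lower))
  }
  structure(list(
    lift = c(from = 1L, to = n_lift),
    hold = c(from = n_lift + 1L, to = n_lift + n_hold),
    lower = c(from = n_lift + n_hold + 1L, to = n_samples)
  ), class = "phase_windows")
}

phase_slice <- function(x, win) x[win[["from"]]:win[["to"]]]

#' Per-channel normalization set for MVIC-based nRMS
#'
#' Band-passes the MVIC and rest recordings, computes their sliding-RMS
#' envelopes, and stores per channel the maximum MVIC envelope (`rms_max`)
#' and the mean rest envelope (`rms_rest`).
#'
#' @param mvic,rest EMG matrices (samples x channels) in mV.
#' @param rate sampling rate (Hz).
#' @param window RMS window (s).
#' @return List of class `normalization_set` with named vectors `rms_max`
#'   and `rms_rest`.  Errors if any channel has `rms_max <= rms_rest`.
#' @export
normalization_set <- function(mvic, rest, rate, window = 0.125) {
  env_m <- sliding_rms(emg_bandpass(mvic, rate), rate, window)
  env_r <- sliding_rms(emg_bandpass(rest, rate), rate, window)
  rms_max <- apply(env_m, 2L, max)
  rms_rest <- apply(env_r, 2L, mean)
  bad <- rms_max <= rms_rest
  if (any(bad)) {
    stop("MVIC RMS does not exceed rest RMS for channel(s): ",
         paste(names(rms_max)[bad], collapse = ", "))
  }
  structure(list(rms_max = rms_max, rms_rest = rms_rest), class = "normalization_set")
}

#' Maximum sliding-RMS amplitude of an MVIC recording
#'
#' @param mvic EMG matrix or vector (mV).
#' @param rate sampling rate (Hz).
#' @param window RMS window (s).
#' @return Per-channel maximum of the sliding-RMS envelope (mV).
#' @export
mvic_max <- function(mvic, rate, window = 0.125) {
  env <- sliding_rms(mvic, rate, window)
  if (is.matrix(env)) apply(env, 2L, max) else max(env)
}

#' MVIC-normalized task EMG (nRMS, percent)
#'
#' `nRMS = 100 * (RMS_task - RMS_rest) / (RMS_max - RMS_rest)` where
#' `RMS_task` is the mean of the RMS envelope over the task phase.  Values
#' are not clipped: task activity below resting level yields a negative
#' nRMS and is carried through (clipping would bias group means).
#'
#' @param task_rms mean task-phase RMS (mV), scalar or named vector.
#' @param norms a [normalization_set()], or `rms_rest`/`rms_max` directly.
#' @param rms_rest,rms_max alternative to `norms`.
#' @return nRMS in percent.
#' @export
nrms <- function(task_rms, norms = NULL, rms_rest = NULL, rms_max = NULL) {
  if (!is.null(norms)) {
    rms_rest <- norms$rms_rest
    rms_max <- norms$rms_max
  }
  if (any(rms_max <= rms_rest)) stop("rms_max must exceed rms_rest")
  100 * (task_rms - rms_rest) / (rms_max - rms_rest)
}

#' Peak force within a phase window
#'
#' @param force numeric force series (N).
#' @param win a `c(from, to)` index pair (e.g. one entry of
#'   [segment_phases()]).
#' @return Maximum sample value within the window.
#' @export
peak_force <- function(force, win) {
  if (win[["from"]] > win[["to"]] || win[["to"]] > length(force)) {
    stop("phase window outside the series")
  }
  max(phase_slice(force, win))
}

#' Process a full study into the tidy outcomes table
#'
#' For every trial: band-pass the 8 EMG channels (20-400 Hz), compute the
#' 125 ms sliding-RMS envelope, average it over the lift and lower phases,
#' normalize with the participant's MVIC/rest set, and extract the peak
#' `F_S` and `F_W` within the same phases.  The 10 s hold is segmented but
#' not reported, matching the study analysis.
#'
#' @param dataset a `study_dataset` from [generate_study()].
#' @param window RMS window (s).
#' @return Data frame with one row per trial x phase (`lift`, `lower`):
#'   `pid`, `condition`, `repetition`, `phase`, `peak_FS_N`, `peak_FW_N`,
#'   and `nRMS_<channel>_pct` for the 8 channels.
#' @export
process_study <- function(dataset, window = 0.125) {
  stopifnot(inherits(dataset, "study_dataset"))
  cfg <- dataset$config
  ch <- emg_channel_names()
  norms <- lapply(dataset$mvic, function(x) NULL)
  for (pid in names(dataset$mvic)) {
    norms[[pid]] <- normalization_set(dataset$mvic[[pid]], dataset$rest[[pid]],
                                      cfg$emg_rate, window)
  }
  rows <- vector("list", 2L * length(dataset$trials))
  k <- 0L
  for (tr in dataset$trials) {
    ph_emg <- segment_phases(cfg$lift_s, cfg$hold_s, cfg$lower_s,
                             tr$emg_rate, nrow(tr$emg))
    ph_force <- segment_phases(cfg$lift_s, cfg$hold_s, cfg$lower_s,
                               tr$force_rate, nrow(tr$forces))
    env <- sliding_rms(emg_bandpass(tr$emg, tr$emg_rate), tr$emg_rate, window)
    nm <- norms[[tr$pid]]
    for (phase in c("lift", "lower")) {
      task_rms <- colMeans(env[ph_emg[[phase]][["from"]]:ph_emg[[phase]][["to"]], , drop = FALSE])
      vals <- nrms(task_rms, nm)
      row <- data.frame(pid = tr$pid, condition = tr$condition,
                        repetition = tr$repetition, phase = phase,
                        peak_FS_N = peak_force(tr$forces[, "F_S"], ph_force[[phase]]),
                        peak_FW_N = peak_force(tr$forces[, "F_W"], ph_force[[phase]]),
                        stringsAsFactors = FALSE)
      for (cn in ch) row[[paste0("nRMS_", cn, "_pct")]] <- vals[[cn]]
      k <- k + 1L
      rows[[k]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify participants as EMG reducers or co-contractors
#'
#' A participant is a co-contractor when a strict majority of the 8
#' channels shows a higher mean task nRMS in exosuit conditions than in
#' NoExo (averaged over exo conditions, repetitions and the lift/lower
#' phases); otherwise a reducer.
#'
#' @param outcomes outcomes table from [process_study()].
#' @return Data frame `pid`, `n_channels_higher`, `phenotype`.
#' @export
phenotype_classify <- function(outcomes) {
  need <- c("pid", "condition", grep("^nRMS_.*_pct$", names(outcomes), value = TRUE))
  miss <- setdiff(need, names(outcomes))
  if (length(miss)) stop("outcomes table missing columns: ", paste(miss, collapse = ", "))
  nrms_cols <- grep("^nRMS_.*_pct$", names(outcomes), value = TRUE)
  if (!any(outcomes$condition == "NoExo")) stop("no NoExo trials to compare against")
  res <- lapply(split(outcomes, outcomes$pid), function(d) {
    noexo <- d$condition == "NoExo"
    if (!any(noexo) || all(noexo)) stop("participant lacks NoExo or exo trials")
    higher <- vapply(nrms_cols, function(cn) {
      mean(d[[cn]][!noexo]) > mean(d[[cn]][noexo])
    }, logical(1L))
    data.frame(pid = d$pid[1L], n_channels_higher = sum(higher),
               phenotype = if (sum(higher) > length(nrms_cols) / 2) "cocontractor" else "reducer",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
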