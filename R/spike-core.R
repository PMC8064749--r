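#' Construct a spike train
#'
#' A spike train holds the occurrence times of action potentials (APs)
#' recorded from one afferent fiber, in seconds relative to a reference
#' event (stimulus onset or injection onset). Timestamps must be strictly
#' increasing; an empty train is allowed.
#'
#' @param timestamps Numeric vector of AP times in seconds, strictly
#'   increasing. Recorded times include the conduction delay from the
#'   receptive field to the electrode.
#' @param fiber_id Identifier of the fiber (character or numeric).
#' @param metadata Optional [fiber_metadata()] object.
#' @return An object of class `spike_train`.
#' @examples
#' spike_train(c(0.31, 0.35, 0.41, 0.80), fiber_id = "u17")
#' @export
spike_train <- function(timestamps, fiber_id = NA_character_, metadata = NULL) {
  timestamps <- as.numeric(timestamps)
  if (anyNA(timestamps)) stop("spike timestamps must not contain NA")
  if (length(timestamps) > 1 && any(diff(timestamps) <= 0)) {
    stop("spike timestamps must be strictly increasing (duplicate or ",
         "out-of-order timestamps found)")
  }
  if (!is.null(metadata) && !inherits(metadata, "fiber_metadata")) {
    stop("`metadata` must be a fiber_metadata object")
  }
  structure(
    list(timestamps = timestamps, fiber_id = fiber_id, metadata = metadata),
    class = "spike_train"
  )
}

#' @export
print.spike_train <- function(x, ...) {
  cat("<spike_train> fiber", x$fiber_id, "-", length(x$timestamps), "APs")
  if (length(x$timestamps)) {
    cat(sprintf(" in [%.3f, %.3f] s", min(x$timestamps), max(x$timestamps)))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.spike_train <- function(x) length(x$timestamps)

#' Fiber metadata
#'
#' Electrophysiological characterization of one afferent: the minimal AP
#' conduction latency measured by transcutaneous electrical stimulation at
#' the proximal edge of the receptive field, the conduction velocity
#' measured at the nerve trunk, and the von Frey mechanical threshold.
#'
#' @param conduction_latency_skin Minimal conduction latency from skin in
#'   seconds (must be > 0). This latency enters the line of equality used to
#'   separate QC from SC heat responses.
#' @param conduction_velocity Conduction velocity in m/s (> 0), or `NULL`.
#' @param conduction_distance Conduction distance in cm, or `NULL`.
#' @param mech_threshold von Frey threshold in bar, `Inf` when no filament
#'   evoked a response, or `NULL` when untested.
#' @return An object of class `fiber_metadata`.
#' @export
fiber_metadata <- function(conduction_latency_skin,
                           conduction_velocity = NULL,
                           conduction_distance = NULL,
                           mech_threshold = NULL) {
  if (!is.null(conduction_latency_skin)) {
    conduction_latency_skin <- as.numeric(conduction_latency_skin)
    stopifnot(length(conduction_latency_skin) == 1)
    if (!is.na(conduction_latency_skin) && conduction_latency_skin <= 0) {
      stop("conduction latency must be positive")
    }
  }
  if (!is.null(conduction_velocity) && !is.na(conduction_velocity) &&
      conduction_velocity <= 0) {
    stop("conduction velocity must be positive")
  }
  structure(
    list(conduction_latency_skin = conduction_latency_skin,
         conduction_velocity = conduction_velocity,
         conduction_distance = conduction_distance,
         mech_threshold = mech_threshold),
    class = "fiber_metadata"
  )
}

#' Stepped heat stimulus
#'
#' Parametric description of the laser heat stimulus: skin pre-heated to a
#' baseline temperature, then rapidly raised to a target temperature and
#' held for a plateau. The default is the 38 to 49 degree C step with a
#' 3 s baseline, 0.2 s rise and 3 s plateau.
#'
#' @param baseline_temp,target_temp Temperatures in degrees C;
#'   `target_temp` must exceed `baseline_temp`.
#' @param baseline_duration Baseline (pre-step) duration in seconds.
#' @param rise_time Temperature rise time in seconds (> 0).
#' @param plateau_duration Plateau duration in seconds (> 0).
#' @return An object of class `heat_stimulus`.
#' @export
heat_stimulus <- function(baseline_temp = 38, target_temp = 49,
                          baseline_duration = 3, rise_time = 0.2,
                          plateau_duration = 3) {
  if (target_temp <= baseline_temp) stop("target_temp must exceed baseline_temp")
  if (rise_time <= 0) stop("rise_time must be positive")
  if (plateau_duration <= 0) stop("plateau_duration must be positive")
  structure(
    list(baseline_temp = baseline_temp, target_temp = target_temp,
         baseline_duration = baseline_duration, rise_time = rise_time,
         plateau_duration = plateau_duration),
    class = "heat_stimulus"
  )
}

new_if_series <- function(time, freq) {
  structure(data.frame(time = time, freq = freq),
            class = c("if_series", "data.frame"))
}

#' Instantaneous discharge frequency
#'
#' For each consecutive spike pair the instantaneous frequency is the
#' reciprocal of the interspike interval, assigned to the time of the later
#' spike (the frequency is only known once the second spike has arrived).
#' A train with fewer than two spikes yields an empty series.
#'
#' @param train A [spike_train()] or a sorted numeric vector of spike times.
#' @return An `if_series` data frame with columns `time` (s) and `freq` (Hz).
#' @examples
#' instantaneous_frequency(spike_train(c(1, 1.5, 2)))
#' @export
instantaneous_frequency <- function(train) {
  ts <- if (inherits(train, "spike_train")) train$timestamps else as.numeric(train)
  if (length(ts) > 1 && any(diff(ts) <= 0)) {
    stop("zero or negative interspike interval: timestamps must be strictly increasing")
  }
  if (length(ts) < 2) return(new_if_series(numeric(0), numeric(0)))
  isi <- diff(ts)
  new_if_series(ts[-1], 1 / isi)
}

#' Three-point median smoothing of an instantaneous-frequency series
#'
#' Each interior frequency is replaced by the median of itself and its two
#' neighbours; the first and last points pass through unchanged. Times and
#' series length are preserved. Series shorter than three points are
#' returned unchanged.
#'
#' @param series An `if_series` (see [instantaneous_frequency()]).
#' @return The smoothed `if_series`.
#' @export
median_smooth3 <- function(series) {
  f <- series$freq
  if (length(f) < 3) return(series)
  series$freq <- as.numeric(stats::runmed(f, 3, endrule = "keep"))
  series
}

#' Time of peak discharge
#'
#' The time at which the (smoothed) instantaneous frequency attains its
#' maximum; ties are broken by the earliest occurrence, which is
#' conservative toward a rising-phase (QC-like) peak.
#'
#' @param series An `if_series`.
#' @return Time in seconds, relative to the same origin as the series.
#' @export
time_of_peak_discharge <- function(series) {
  if (nrow(series) == 0) stop("no discharge: empty instantaneous-frequency series")
  series$time[which.max(series$freq)]
}

#' Burst-rule parameters
#'
#' The onset-burst criterion used by [classify_heat_response()]: a burst is
#' present when at least `min_spikes` smoothed instantaneous-frequency
#' points of at least `min_freq` Hz fall inside the onset window (the
#' temperature rise plus `window` seconds, shifted by the conduction
#' latency), and the discharge adapts, i.e. the mean smoothed frequency in
#' the final half of the plateau is below `adaptation_ratio` times the peak
#' frequency.
#'
#' @param min_spikes Minimum number of qualifying points in the onset window.
#' @param window Extension of the onset window past the end of the rise, s.
#' @param min_freq Minimum instantaneous frequency, Hz.
#' @param adaptation_ratio Upper bound on (late-plateau mean)/(peak), unitless.
#' @return A list of class `burst_params`.
#' @export
burst_params <- function(min_spikes = 3, window = 0.2, min_freq = 20,
                         adaptation_ratio = 0.5) {
  stopifnot(min_spikes >= 1, window >= 0, min_freq > 0,
            adaptation_ratio > 0, adaptation_ratio <= 1)
  structure(list(min_spikes = min_spikes, window = window,
                 min_freq = min_freq, adaptation_ratio = adaptation_ratio),
            class = "burst_params")
}

#' Detect a burst of discharge at stimulus onset
#'
#' @param series A smoothed `if_series` in recorded time (stimulus onset at 0).
#' @param stimulus A [heat_stimulus()].
#' @param params A [burst_params()] object.
#' @param latency Conduction latency from skin in seconds; the onset window
#'   is shifted by this amount because recorded spike times lag the stimulus
#'   by the conduction delay.
#' @return `TRUE` if the onset-burst criterion is met, else `FALSE`.
#' @export
detect_onset_burst <- function(series, stimulus, params = burst_params(),
                               latency = 0) {
  if (nrow(series) == 0) return(FALSE)
  onset_end <- latency + stimulus$rise_time + params$window
  in_onset <- series$time >= 0 & series$time <= onset_end
  n_burst <- sum(in_onset & series$freq >= params$min_freq)
  if (n_burst < params$min_spikes) return(FALSE)
  # adaptation: discharge in the final half of the plateau has died down
  plateau_end <- latency + stimulus$rise_time + stimulus$plateau_duration
  late_start <- plateau_end - stimulus$plateau_duration / 2
  late <- series$freq[series$time >= late_start & series$time <= plateau_end]
  late_mean <- if (length(late)) mean(late) else 0
  late_mean < params$adaptation_ratio * max(series$freq)
}

#' Classify a CMH heat response as QC, SC or unclassified
#'
#' CMH nociceptors fall into two subtypes by their response to a stepped
#' heat stimulus. QCs fire a burst of discharge at stimulus onset and then
#' adapt; SCs respond slowly, without an onset burst, and reach their peak
#' discharge during the stimulus plateau. The formal separation plots the
#' time of peak discharge `P` (from the three-point median-smoothed
#' instantaneous frequency) against the line of equality
#' `E = rise_time + conduction_latency_skin`:
#' a peak above the line (`P > E + tolerance`) means the peak fell in the
#' plateau phase (SC); a peak below it means the peak fell in the rising
#' phase (QC). Fibers with an onset burst are QC even when their peak lies
#' above the line; fibers close to the line (`|P - E| <= tolerance`) with
#' no burst are left unclassified.
#'
#' @param train A [spike_train()] in seconds relative to stimulus onset.
#' @param stimulus A [heat_stimulus()].
#' @param meta A [fiber_metadata()] carrying `conduction_latency_skin`.
#' @param tolerance Half-width of the "close to the line of equality" band,
#'   seconds. Default 0.1 s, the same order as the 0.2 s temperature rise.
#' @param burst A [burst_params()] object.
#' @return A list of class `heat_classification` with elements `label`
#'   (`"QC"`, `"SC"` or `"UNCLASSIFIED"`), `peak_time`,
#'   `equality_line_value`, `burst_at_onset`, `diagnostics` (the smoothed
#'   `if_series`) and `fiber_id`.
#' @export
classify_heat_response <- function(train, stimulus, meta, tolerance = 0.1,
                                   burst = burst_params()) {
  if (is.null(meta) || is.null(meta$conduction_latency_skin) ||
      is.na(meta$conduction_latency_skin)) {
    stop("missing conduction latency: cannot place the line of equality")
  }
  lat <- meta$conduction_latency_skin
  window_end <- lat + stimulus$rise_time + stimulus$plateau_duration
  ts <- train$timestamps[train$timestamps >= 0 & train$timestamps <= window_end]
  out <- list(label = "UNCLASSIFIED", peak_time = NA_real_,
              equality_line_value = stimulus$rise_time + lat,
              burst_at_onset = FALSE,
              diagnostics = new_if_series(numeric(0), numeric(0)),
              fiber_id = train$fiber_id)
  class(out) <- "heat_classification"
  if (length(ts) < 2) return(out)

  sm <- median_smooth3(instantaneous_frequency(ts))
  p <- time_of_peak_discharge(sm)
  e <- out$equality_line_value
  has_burst <- detect_onset_burst(sm, stimulus, burst, latency = lat)

  label <-
    if (has_burst) "QC"
    else if (p > e + tolerance) "SC"
    else if (abs(p - e) <= tolerance) "UNCLASSIFIED"
    else "QC"

  out$label <- label
  out$peak_time <- p
  out$burst_at_onset <- has_burst
  out$diagnostics <- sm
  out
}

#' @export
print.heat_classification <- function(x, ...) {
  cat(sprintf("<heat_classification> %s: peak %.3f s vs line of equality %.3f s, burst %s\n",
              x$label, x$peak_time, x$equality_line_value,
              if (x$burst_at_onset) "yes" else "no"))
  invisible(x)
}

#' Classify a fiber by conduction velocity
#'
#' Fibers conducting below 2 m/s are C-fibers; those between 2 and 20 m/s
#' (inclusive) are A-delta fibers; faster fibers are outside the
#' nociceptor range considered here.
#'
#' @param cv Conduction velocity in m/s (> 0).
#' @return `"C"`, `"A_DELTA"`, or `"OUT_OF_RANGE"`.
#' @export
classify_by_cv <- function(cv) {
  if (!is.numeric(cv) || length(cv) != 1 || is.na(cv) || cv <= 0) {
    stop("conduction velocity must be a single positive number")
  }
  if (cv < 2) "C" else if (cv <= 20) "A_DELTA" else "OUT_OF_RANGE"
}

#' von Frey mechanical threshold
#'
#' The smallest von Frey filament that evokes a response in at least two
#' out of four applications is the mechanical threshold.
#'
#' @param filaments Numeric vector of filament strengths in bar, ascending.
#' @param positives Integer vector, same length: number of applications (out
#'   of four) that evoked a response.
#' @return Threshold in bar, or `Inf` when no filament reached criterion
#'   (threshold not reached).
#' @examples
#' von_frey_threshold(c(4, 6, 8.9), c(1, 2, 4))  # 6 bar
#' @export
von_frey_threshold <- function(filaments, positives) {
  stopifnot(length(filaments) == length(positives), length(filaments) >= 1)
  if (is.unsorted(filaments, strictly = TRUE)) {
    stop("filaments must be in strictly ascending stiffness order")
  }
  if (any(positives < 0 | positives > 4 | positives != round(positives))) {
    stop("positives must be integer counts in 0..4")
  }
  hit <- which(positives >= 2)
  if (length(hit) == 0) return(Inf)
  filaments[hit[1]]
}

#' Mechanosensitivity class from von Frey threshold
#'
#' Fibers responsive to filaments of at most 6 bar are mechano-sensitive
#' afferents (MSA); fibers with a higher threshold, or with no threshold
#' reached, are mechano-insensitive afferents (MIA). The 6 bar boundary is
#' counted as MSA.
#'
#' @param threshold Threshold in bar, or `Inf` for not reached.
#' @return `"MSA"` or `"MIA"`.
#' @export
classify_mechanosensitivity <- function(threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1, !is.na(threshold))
  if (threshold <= 6) "MSA" else "MIA"
}
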