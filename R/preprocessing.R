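# Cleaning and epoching rules for wearable EDA and HR.
#
# All artifact handling is mask-only: sample values are never altered except
# by smoothing and tonic/phasic decomposition, which are signal transforms.

#' Savitzky-Golay smoothing of an EDA recording
#'
#' Applies a Savitzky-Golay filter (polynomial order 2) with a window of
#' \code{window_s} seconds (odd number of samples nearest to
#' \code{window_s * rate}), the standard remedy for quantization noise in
#' wearable skin-conductance output. Length is preserved.
#'
#' @param recording an EDA \linkS4class{PhysioRecording}.
#' @param window_s smoothing window in seconds (default 3).
#' @return the recording with smoothed values.
#' @export
smoothEda <- function(recording, window_s = 3) {
  stopifnot(is(recording, "PhysioRecording"))
  if (!recording@modality %in% c("EDA_RAW", "EDA_PHASIC"))
    stop("smoothEda expects an EDA recording", call. = FALSE)
  n_win <- round(window_s * recording@sampling_rate_hz)
  if (n_win %% 2 == 0) n_win <- n_win + 1
  if (n_win < 3)
    stop("smoothing window must span at least 3 samples", call. = FALSE)
  if (length(recording@values) < n_win)
    stop("recording shorter than the smoothing window", call. = FALSE)
  recording@values <- as.numeric(
    signal::sgolayfilt(recording@values, p = 2, n = n_win))
  recording
}

#' Mark EDA signal loss from loose electrodes
#'
#' Runs where the conductance stays below \code{low_threshold_uS} for at
#' least \code{min_duration_s} seconds are flagged unusable: a detached or
#' drying electrode reads (near) zero for an extended period, whereas brief
#' dips are physiologically plausible.
#'
#' @param recording an EDA \linkS4class{PhysioRecording}.
#' @param low_threshold_uS conductance floor in microsiemens (default 0.01).
#' @param min_duration_s minimum run length in seconds (default 5).
#' @return logical quality mask (TRUE = usable), same length as the values.
#' @export
markEdaSignalLoss <- function(recording, low_threshold_uS = 0.01,
                              min_duration_s = 5) {
  stopifnot(is(recording, "PhysioRecording"))
  low <- recording@values < low_threshold_uS
  mask <- rep(TRUE, length(low))
  if (any(low)) {
    r <- rle(low)
    min_n <- min_duration_s * recording@sampling_rate_hz
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (i in which(r$values & r$lengths >= min_n))
      mask[starts[i]:ends[i]] <- FALSE
  }
  mask
}

#' Split smoothed EDA into tonic and phasic components
#'
#' A deliberately simple, deterministic decomposition: the tonic (slow)
#' level is estimated as a running minimum over \code{tonic_window_s}
#' seconds, smoothed with a moving average of the same width; the phasic
#' component is the remainder, clipped at 0. This captures the fast
#' stimulus-locked fluctuations that inter-subject correlation needs while
#' removing baseline drift; it does not estimate SCR shape parameters the
#' way full nonnegative-deconvolution decompositions do.
#'
#' @param recording a smoothed \code{EDA_RAW} \linkS4class{PhysioRecording}.
#' @param tonic_window_s running-minimum window in seconds (default 10).
#' @return a \linkS4class{PhysioRecording} of modality \code{"EDA_PHASIC"}.
#' @export
extractPhasic <- function(recording, tonic_window_s = 10) {
  stopifnot(is(recording, "PhysioRecording"))
  if (recording@modality != "EDA_RAW")
    stop("extractPhasic expects an EDA_RAW recording", call. = FALSE)
  w <- round(tonic_window_s * recording@sampling_rate_hz)
  if (length(recording@values) < w)
    stop("recording shorter than the tonic window", call. = FALSE)
  tonic <- movingAverage(runningMin(recording@values, w), w)
  physioRecording(recording@participant_id, "EDA_PHASIC",
                  recording@sampling_rate_hz,
                  pmax(recording@values - tonic, 0),
                  quality_mask = recording@quality_mask,
                  t0_s = recording@t0_s,
                  provenance = recording@provenance)
}

#' Clean a 1 Hz HR recording
#'
#' Two mask-only rules for wearable HR: (1) samples above
#' \code{max_bpm} or below \code{min_bpm} are physiologically implausible;
#' (2) samples differing by more than \code{max_jump} (fractional) from the
#' most recent usable sample are implausible beat-to-second jumps. Using the
#' most recent usable sample as the reference stops one bad sample from
#' cascading down the series.
#'
#' @param recording an HR \linkS4class{PhysioRecording}.
#' @param min_bpm,max_bpm plausible range (defaults 30, 200).
#' @param max_jump maximum fractional change per second (default 0.25).
#' @return list with \code{recording} (quality mask updated) and
#'   \code{report}, a one-row data.frame (participant_id, modality, n,
#'   n_range, n_jump, n_removed, fraction_removed).
#' @export
cleanHr <- function(recording, min_bpm = 30, max_bpm = 200, max_jump = 0.25) {
  stopifnot(is(recording, "PhysioRecording"))
  if (recording@modality != "HR")
    stop("cleanHr expects an HR recording", call. = FALSE)
  v <- recording@values
  n <- length(v)
  if (n == 0L) stop("empty recording", call. = FALSE)
  mask <- recording@quality_mask
  range_bad <- v > max_bpm | v < min_bpm
  mask[range_bad] <- FALSE
  jump_bad <- rep(FALSE, n)
  ref <- NA_real_
  for (i in seq_len(n)) {
    if (!mask[i]) next
    if (!is.na(ref) && abs(v[i] - ref) / ref > max_jump) {
      jump_bad[i] <- TRUE
      mask[i] <- FALSE
    } else {
      ref <- v[i]
    }
  }
  recording@quality_mask <- mask
  report <- data.frame(
    participant_id = recording@participant_id,
    modality = "HR",
    n = n,
    n_range = sum(range_bad),
    n_jump = sum(jump_bad),
    n_removed = sum(!mask),
    fraction_removed = sum(!mask) / n,
    stringsAsFactors = FALSE)
  list(recording = recording, report = report)
}

#' Detect a stuck (malfunctioning) HR sensor
#'
#' Computes the ratio of consecutive-sample repeats to consecutive-sample
#' changes. A healthy 1 Hz HR stream changes often; a sensor that lost its
#' strap connection repeats its last value. The recording is flagged when
#' repeats are more than \code{max_ratio} times as prevalent as changes
#' (all-equal series: ratio +Inf, flagged).
#'
#' @param recording an HR \linkS4class{PhysioRecording} with >= 2 samples.
#' @param max_ratio flag threshold (default 50).
#' @return list with \code{flagged} (logical) and \code{stuck_ratio}.
#' @export
detectStuckHr <- function(recording, max_ratio = 50) {
  stopifnot(is(recording, "PhysioRecording"))
  v <- recording@values
  if (length(v) < 2L) stop("need at least 2 samples", call. = FALSE)
  same <- sum(diff(v) == 0)
  diff_n <- length(v) - 1L - same
  ratio <- if (diff_n == 0L) Inf else same / diff_n
  list(flagged = ratio > max_ratio, stuck_ratio = ratio)
}

#' Apply the whole-recording exclusion rule
#'
#' A recording is excluded when strictly more than \code{threshold} of its
#' samples are marked unusable ("more than 30 percent": exactly 30 percent
#' is retained), or when the stuck-sensor rule fired.
#'
#' @param report cleaning report (any object with \code{fraction_removed}),
#'   or NULL to compute the fraction from the recording's mask.
#' @param recording the \linkS4class{PhysioRecording}.
#' @param threshold exclusion threshold (default 0.30, strict).
#' @param stuck_flagged logical from \code{\link{detectStuckHr}} (default FALSE).
#' @return logical: TRUE if the recording must be excluded.
#' @export
applyExclusion <- function(report, recording, threshold = 0.30,
                           stuck_flagged = FALSE) {
  frac <- if (!is.null(report) && !is.null(report$fraction_removed))
    report$fraction_removed
  else
    mean(!recording@quality_mask)
  isTRUE(frac > threshold) || isTRUE(stuck_flagged)
}

#' Epoch a continuous recording and time-lock it to movie onsets
#'
#' Cuts half-open windows \code{[onset, onset + duration)} on the shared
#' clock out of a continuous recording and re-indexes each segment to t = 0
#' at its movie onset. Sample i (1-based) of a rate-f recording starting at
#' \code{t0_s} lies at \code{t0_s + (i - 1) / f}.
#'
#' @param recording a continuous \linkS4class{PhysioRecording}.
#' @param movie_catalogue data.frame (movie_id, onset_s, duration_s).
#' @return named list (by movie_id) of epoched \linkS4class{PhysioRecording}s.
#' @export
epochTimelock <- function(recording, movie_catalogue) {
  stopifnot(is(recording, "PhysioRecording"))
  fs <- recording@sampling_rate_hz
  n <- length(recording@values)
  out <- list()
  for (r in seq_len(nrow(movie_catalogue))) {
    mv <- movie_catalogue[r, ]
    i0 <- round((mv$onset_s - recording@t0_s) * fs) + 1
    len <- round(mv$duration_s * fs)
    if (i0 < 1 || i0 + len - 1 > n)
      stop(sprintf("movie '%s' window [%g, %g) outside recording extent",
                   mv$movie_id, mv$onset_s, mv$onset_s + mv$duration_s),
           call. = FALSE)
    idx <- seq.int(i0, i0 + len - 1)
    out[[as.character(mv$movie_id)]] <- physioRecording(
      recording@participant_id, recording@modality, fs,
      recording@values[idx],
      quality_mask = recording@quality_mask[idx],
      t0_s = 0,
      provenance = recording@provenance)
  }
  out
}
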