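# Synthetic cohort generator: shared stimulus drive + idiosyncratic events +
# onset transient + noise, with known coupling gains and linked quiz scores.

#' Generate a homogeneous Poisson event train
#'
#' Stimulus-driven arousal events are modeled as a homogeneous Poisson
#' process. Event times are sorted and lie strictly within
#' \code{[0, duration_s)}.
#'
#' @param rate_per_min nonnegative event rate (events per minute).
#' @param duration_s positive duration in seconds.
#' @param seed integer seed.
#' @return numeric vector of event times in seconds, sorted ascending.
#' @export
generateEventTrain <- function(rate_per_min, duration_s, seed) {
  stopifnot_scalar(rate_per_min, "rate_per_min", nonneg = TRUE)
  stopifnot_scalar(duration_s, "duration_s", positive = TRUE)
  if (rate_per_min == 0) return(numeric(0))
  withSeed(seed, {
    n <- stats::rpois(1, rate_per_min / 60 * duration_s)
    sort(stats::runif(n, 0, duration_s))
  })
}

#' Two-exponential (Bateman-form) skin-conductance response kernel
#'
#' \code{k(t) = exp(-t / tau_decay) - exp(-t / tau_rise)}, sampled at
#' \code{sampling_rate_hz} over \code{[0, length_s)} and normalized to unit
#' peak. \code{k(0) = 0}; the analytic peak lies at
#' \code{t* = log(tau_decay / tau_rise) / (1 / tau_rise - 1 / tau_decay)}.
#'
#' @param tau_rise_s rise time constant (s); must be < \code{tau_decay_s}.
#' @param tau_decay_s decay time constant (s).
#' @param sampling_rate_hz sampling rate.
#' @param length_s kernel support in seconds (default 15, by which the
#'   default kernel has decayed to well under 0.1 percent of peak).
#' @return numeric vector of kernel samples, nonnegative, max 1.
#' @export
scrKernel <- function(tau_rise_s = 0.75, tau_decay_s = 2,
                      sampling_rate_hz = 32, length_s = 15) {
  stopifnot_scalar(tau_rise_s, "tau_rise_s", positive = TRUE)
  stopifnot_scalar(tau_decay_s, "tau_decay_s", positive = TRUE)
  if (tau_rise_s >= tau_decay_s)
    stop("tau_rise_s must be strictly smaller than tau_decay_s", call. = FALSE)
  t <- seq(0, length_s, by = 1 / sampling_rate_hz)
  t <- t[t < length_s]
  k <- exp(-t / tau_decay_s) - exp(-t / tau_rise_s)
  k / max(k)
}

# linear convolution of x with kernel k, truncated to length(x)
.convTrunc <- function(x, k) {
  if (!length(x)) return(x)
  stats::convolve(x, rev(k), type = "open")[seq_along(x)]
}

# impulse train at the sample grid: unit mass at floor(t * fs) + 1
.impulses <- function(times, n, fs) {
  z <- numeric(n)
  if (length(times)) {
    idx <- pmin(floor(times * fs) + 1, n)
    for (i in idx) z[i] <- z[i] + 1
  }
  z
}

#' Generate one participant's phasic EDA epoch
#'
#' Signal model: coupling gain times the shared event train convolved with
#' the SCR kernel, plus an idiosyncratic event train convolved with the same
#' kernel, plus a large SCR-shaped onset transient at t = 0 (the
#' start-of-movie arousal burst followed by a sharp drop), plus Gaussian
#' noise smoothed with the SCR kernel, clipped at 0.
#'
#' @param shared_events shared event times (s) for this movie.
#' @param config a \linkS4class{CohortConfig}.
#' @param participant_index,movie_index 1-based indices.
#' @param seed substream seed (defaults to a documented derivation from
#'   \code{config@seed}).
#' @return a \linkS4class{PhysioRecording} of modality \code{"EDA_PHASIC"}.
#' @export
generateEdaPhasic <- function(shared_events, config, participant_index,
                              movie_index,
                              seed = mixSeed(config@seed, "eda",
                                             participant_index, movie_index)) {
  validObject(config)
  if (participant_index < 1 || participant_index > config@n_participants)
    stop("participant_index out of range", call. = FALSE)
  if (movie_index < 1 || movie_index > config@n_movies)
    stop("movie_index out of range", call. = FALSE)
  fs <- config@eda_rate_hz
  n <- round(config@movie_duration_s * fs)
  k <- scrKernel(config@tau_rise_s, config@tau_decay_s, fs)
  gain <- config@coupling_gains[participant_index]

  sig <- gain * .convTrunc(.impulses(shared_events, n, fs), k)
  withSeed(seed, {
    idio <- generateEventTrain(config@idio_event_rate_per_min,
                               config@movie_duration_s,
                               seed = mixSeed(seed, "idio"))
    if (length(idio)) sig <- sig + .convTrunc(.impulses(idio, n, fs), k)
    if (config@onset_amplitude > 0) {
      m <- min(length(k), n)
      sig[seq_len(m)] <- sig[seq_len(m)] + config@onset_amplitude * k[seq_len(m)]
    }
    if (config@noise_sd > 0) {
      w <- stats::rnorm(n)
      sig <- sig + config@noise_sd * .convTrunc(w, k) / sqrt(sum(k^2))
    }
  })
  physioRecording(sprintf("P%02d", participant_index), "EDA_PHASIC", fs,
                  pmax(sig, 0))
}

# shared HR drive: 1 Hz event counts smoothed with a moving average so HR
# synchrony lives at slower timescales than EDA
.hrDrive <- function(shared_events, config) {
  n <- round(config@movie_duration_s * config@hr_rate_hz)
  counts <- .impulses(shared_events, n, config@hr_rate_hz)
  movingAverage(counts, round(config@hr_drive_window_s * config@hr_rate_hz))
}

#' Generate one participant's HR epoch
#'
#' HR = round(baseline + gain * hr_gain_bpm * shared drive + AR(1) noise),
#' at the HR rate (default 1 Hz) with 1 bpm integer resolution, matching
#' wearable chest-strap output. The shared drive is the low-pass-filtered
#' (10 s moving average) shared event train, identical across participants.
#'
#' @inheritParams generateEdaPhasic
#' @return a \linkS4class{PhysioRecording} of modality \code{"HR"}.
#' @export
generateHr <- function(shared_events, config, participant_index, movie_index,
                       seed = mixSeed(config@seed, "hr",
                                      participant_index, movie_index)) {
  validObject(config)
  if (participant_index < 1 || participant_index > config@n_participants)
    stop("participant_index out of range", call. = FALSE)
  n <- round(config@movie_duration_s * config@hr_rate_hz)
  drive <- .hrDrive(shared_events, config)
  gain <- config@coupling_gains[participant_index]
  base <- config@hr_baselines_bpm[participant_index]
  sig <- base + gain * config@hr_gain_bpm * drive
  if (config@hr_noise_sd_bpm > 0) {
    phi <- config@hr_ar_coef
    innov_sd <- config@hr_noise_sd_bpm * sqrt(1 - phi^2)
    noise <- withSeed(seed, {
      e <- stats::rnorm(n, 0, innov_sd)
      as.numeric(stats::filter(e, phi, method = "recursive"))
    })
    sig <- sig + noise
  }
  physioRecording(sprintf("P%02d", participant_index), "HR",
                  config@hr_rate_hz, round(sig))
}

#' Inject wearable-sensor artifacts into a recording
#'
#' Writes artifact segments into a copy of the recording's values; the
#' quality mask is left untouched (detecting artifacts is preprocessing's
#' job). Supported types: \code{"eda_signal_loss"} (values set to 0,
#' electrode detached), \code{"hr_out_of_range"} (constant implausible
#' value), \code{"hr_jump"} (step offset added), \code{"hr_stuck"} (all
#' samples frozen at the segment's first value). Injected segments are
#' recorded in the returned recording's provenance.
#'
#' @param recording a \linkS4class{PhysioRecording}.
#' @param artifact_spec list of specs, each a list with \code{type},
#'   \code{start_s}, \code{end_s} (half-open, seconds from the first sample)
#'   and optionally \code{value} (for \code{hr_out_of_range}, default 250)
#'   or \code{offset} (for \code{hr_jump}, default +40 bpm).
#' @param seed unused by the deterministic artifact types; kept so callers
#'   can thread a substream seed uniformly.
#' @return a modified copy of \code{recording}.
#' @export
injectArtifacts <- function(recording, artifact_spec, seed = NULL) {
  stopifnot(is(recording, "PhysioRecording"))
  if (!length(artifact_spec)) return(recording)
  fs <- recording@sampling_rate_hz
  n <- length(recording@values)
  v <- recording@values
  for (a in artifact_spec) {
    if (is.null(a$type) || is.null(a$start_s) || is.null(a$end_s))
      stop("each artifact spec needs type, start_s, end_s", call. = FALSE)
    i0 <- floor(a$start_s * fs) + 1
    i1 <- ceiling(a$end_s * fs)  # half-open [start_s, end_s)
    if (i0 < 1 || i1 > n || i0 > i1)
      stop(sprintf("artifact segment [%g, %g) outside recording extent",
                   a$start_s, a$end_s), call. = FALSE)
    idx <- i0:i1
    v[idx] <- switch(a$type,
      eda_signal_loss = 0,
      hr_out_of_range = if (is.null(a$value)) 250 else a$value,
      hr_jump = v[idx] + if (is.null(a$offset)) 40 else a$offset,
      hr_stuck = v[i0],
      stop(sprintf("unknown artifact type '%s'", a$type), call. = FALSE))
  }
  recording@values <- v
  recording@provenance$artifacts <- c(recording@provenance$artifacts,
                                      artifact_spec)
  recording
}

#' Generate a full synthetic cohort
#'
#' Produces an \linkS4class{EpochedCohort} of HR and/or phasic-EDA epochs for
#' \code{n_participants x n_movies}, plus a \linkS4class{GroundTruth} with
#' the coupling gains, the shared event times per movie, and quiz scores
#' linked to the gains via
#' \code{round(quiz_intercept + quiz_slope * gain + noise)} clipped to
#' [0, 10]. Fully reproducible from \code{config@seed}: every random draw
#' uses a documented per-(participant, movie, purpose) substream derived by
#' \code{\link{mixSeed}}.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param modalities which modalities to generate (subset of
#'   \code{c("HR", "EDA_PHASIC")}).
#' @return list with elements \code{cohort} (\linkS4class{EpochedCohort}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @export
generateCohort <- function(config, modalities = c("HR", "EDA_PHASIC")) {
  validObject(config)
  modalities <- match.arg(modalities, c("HR", "EDA_PHASIC"), several.ok = TRUE)
  np <- config@n_participants
  nm <- config@n_movies
  pid <- sprintf("P%02d", seq_len(np))
  mid <- sprintf("M%d", seq_len(nm))

  shared <- lapply(seq_len(nm), function(m)
    generateEventTrain(config@shared_event_rate_per_min,
                       config@movie_duration_s,
                       seed = mixSeed(config@seed, "shared", m)))
  names(shared) <- mid

  recs <- list()
  for (m in seq_len(nm)) {
    for (p in seq_len(np)) {
      if ("HR" %in% modalities)
        recs[[.rec_key(pid[p], mid[m], "HR")]] <-
          generateHr(shared[[m]], config, p, m)
      if ("EDA_PHASIC" %in% modalities)
        recs[[.rec_key(pid[p], mid[m], "EDA_PHASIC")]] <-
          generateEdaPhasic(shared[[m]], config, p, m)
    }
  }
  cat <- data.frame(movie_id = mid,
                    onset_s = (seq_len(nm) - 1) * config@movie_duration_s,
                    duration_s = config@movie_duration_s,
                    stringsAsFactors = FALSE)

  quiz <- withSeed(mixSeed(config@seed, "quiz"), {
    g <- rep(config@coupling_gains, times = nm)
    raw <- config@quiz_intercept + config@quiz_slope * g +
      stats::rnorm(np * nm, 0, config@quiz_noise_sd)
    data.frame(participant_id = rep(pid, times = nm),
               movie_id = rep(mid, each = np),
               quiz_score = as.integer(pmin(10, pmax(0, round(raw)))),
               stringsAsFactors = FALSE)
  })

  gains <- stats::setNames(config@coupling_gains, pid)
  list(cohort = epochedCohort(recs, cat),
       truth = new("GroundTruth", coupling_gains = gains,
                   quiz_scores = quiz, shared_event_times = shared))
}
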