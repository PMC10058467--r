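# S4 classes for the synchrony pipeline.

#' @import methods
NULL

.MODALITIES <- c("HR", "EDA_RAW", "EDA_PHASIC")

#' PhysioRecording: one participant x modality time series
#'
#' A regularly sampled physiological time series with a per-sample quality
#' mask. HR is in beats per minute (1 Hz, integer resolution on wearable
#' chest straps); EDA is skin conductance in microsiemens (32 Hz on the
#' wearable used as reference). \code{t0_s} places the first sample on the
#' shared experiment clock; sample \code{i} (1-based) lies at
#' \code{t0_s + (i - 1) / sampling_rate_hz}.
#'
#' Cleaning never alters sample values: artifact handling is mask-only, with
#' \code{quality_mask[i] == TRUE} meaning sample \code{i} is usable.
#'
#' @slot participant_id character scalar.
#' @slot modality one of \code{"HR"}, \code{"EDA_RAW"}, \code{"EDA_PHASIC"}.
#' @slot sampling_rate_hz positive number.
#' @slot t0_s numeric scalar, seconds on the shared clock.
#' @slot values numeric vector (bpm for HR, microsiemens for EDA).
#' @slot quality_mask logical vector, same length as \code{values}.
#' @slot provenance list of free-form provenance records (e.g. injected
#'   artifact segments).
#' @export
setClass("PhysioRecording",
  representation(
    participant_id = "character",
    modality = "character",
    sampling_rate_hz = "numeric",
    t0_s = "numeric",
    values = "numeric",
    quality_mask = "logical",
    provenance = "list"
  ),
  prototype(t0_s = 0, provenance = list())
)

setValidity("PhysioRecording", function(object) {
  msg <- character(0)
  if (length(object@participant_id) != 1L)
    msg <- c(msg, "participant_id must be a single id")
  if (length(object@modality) != 1L || !object@modality %in% .MODALITIES)
    msg <- c(msg, sprintf("modality must be one of %s",
                          paste(.MODALITIES, collapse = ", ")))
  if (length(object@sampling_rate_hz) != 1L || object@sampling_rate_hz <= 0)
    msg <- c(msg, "sampling_rate_hz must be a positive scalar")
  if (length(object@values) != length(object@quality_mask))
    msg <- c(msg, "values and quality_mask must have equal length")
  if (length(object@modality) == 1L && object@modality == "HR") {
    usable <- object@values[object@quality_mask]
    if (any(is.finite(usable) & usable <= 0))
      msg <- c(msg, "usable HR values must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PhysioRecording
#'
#' @param participant_id participant identifier.
#' @param modality \code{"HR"}, \code{"EDA_RAW"} or \code{"EDA_PHASIC"}.
#' @param sampling_rate_hz sampling rate in Hz.
#' @param values sample values.
#' @param quality_mask logical usability mask; defaults to all usable.
#' @param t0_s time of the first sample on the shared clock (s).
#' @param provenance optional list of provenance records.
#' @return a \linkS4class{PhysioRecording}.
#' @export
physioRecording <- function(participant_id, modality, sampling_rate_hz,
                            values, quality_mask = rep(TRUE, length(values)),
                            t0_s = 0, provenance = list()) {
  new("PhysioRecording",
      participant_id = as.character(participant_id),
      modality = modality,
      sampling_rate_hz = as.numeric(sampling_rate_hz),
      t0_s = as.numeric(t0_s),
      values = as.numeric(values),
      quality_mask = as.logical(quality_mask),
      provenance = provenance)
}

#' CohortConfig: parameters of the synthetic cohort generator
#'
#' Houses the stimulus and recording parameters the generator emulates:
#' movie-clip duration (default 600 s, i.e. six clips of about 10 min),
#' EDA sampled at 32 Hz, HR at 1 Hz with 1 bpm resolution, a shared
#' stimulus-driven event train with participant-specific coupling gains, a
#' large onset transient at the start of every movie, and idiosyncratic
#' events plus noise. Quiz scores (0-10 correct answers per movie) are linked
#' to the coupling gain through
#' \code{round(quiz_intercept + quiz_slope * gain + noise)}.
#'
#' @slot n_participants,n_movies positive integers.
#' @slot movie_duration_s movie length in seconds (default 600).
#' @slot eda_rate_hz,hr_rate_hz sampling rates (defaults 32 and 1).
#' @slot shared_event_rate_per_min rate of stimulus-driven arousal events
#'   shared by all participants (Poisson, events/min).
#' @slot coupling_gains one nonnegative gain per participant scaling the
#'   shared component; gain 0 means no stimulus coupling.
#' @slot idio_event_rate_per_min rate of participant-specific events.
#' @slot onset_amplitude amplitude (microsiemens) of the start-of-movie
#'   SCR-shaped transient.
#' @slot noise_sd EDA noise standard deviation (microsiemens) after SCR
#'   smoothing.
#' @slot hr_baselines_bpm one baseline per participant in [40, 100].
#' @slot hr_gain_bpm bpm swing per unit coupling gain per unit of shared
#'   drive (the 10 s moving average of the 1 Hz event-count train).
#' @slot hr_noise_sd_bpm stationary SD of the AR(1) HR noise.
#' @slot hr_ar_coef AR(1) coefficient of the HR noise (default 0.9).
#' @slot hr_drive_window_s moving-average window (s) applied to the shared
#'   event train before it drives HR (default 10), so HR synchrony lives at
#'   slower timescales than EDA.
#' @slot tau_rise_s,tau_decay_s SCR kernel time constants (defaults 0.75, 2).
#' @slot quiz_intercept,quiz_slope,quiz_noise_sd quiz-score linkage.
#' @slot seed integer root seed.
#' @export
setClass("CohortConfig",
  representation(
    n_participants = "integer",
    n_movies = "integer",
    movie_duration_s = "numeric",
    eda_rate_hz = "numeric",
    hr_rate_hz = "numeric",
    shared_event_rate_per_min = "numeric",
    coupling_gains = "numeric",
    idio_event_rate_per_min = "numeric",
    onset_amplitude = "numeric",
    noise_sd = "numeric",
    hr_baselines_bpm = "numeric",
    hr_gain_bpm = "numeric",
    hr_noise_sd_bpm = "numeric",
    hr_ar_coef = "numeric",
    hr_drive_window_s = "numeric",
    tau_rise_s = "numeric",
    tau_decay_s = "numeric",
    quiz_intercept = "numeric",
    quiz_slope = "numeric",
    quiz_noise_sd = "numeric",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character(0)
  np <- object@n_participants
  if (length(np) != 1L || np < 1L) msg <- c(msg, "n_participants must be >= 1")
  if (length(object@n_movies) != 1L || object@n_movies < 1L)
    msg <- c(msg, "n_movies must be >= 1")
  if (object@movie_duration_s <= 0) msg <- c(msg, "movie_duration_s must be > 0")
  if (object@eda_rate_hz <= 0 || object@hr_rate_hz <= 0)
    msg <- c(msg, "sampling rates must be > 0")
  if (length(object@coupling_gains) != np)
    msg <- c(msg, "coupling_gains must have one entry per participant")
  if (any(object@coupling_gains < 0))
    msg <- c(msg, "coupling_gains must be nonnegative")
  if (length(object@hr_baselines_bpm) != np)
    msg <- c(msg, "hr_baselines_bpm must have one entry per participant")
  if (any(object@hr_baselines_bpm < 40 | object@hr_baselines_bpm > 100))
    msg <- c(msg, "hr_baselines_bpm must lie in [40, 100]")
  if (object@shared_event_rate_per_min < 0 || object@idio_event_rate_per_min < 0)
    msg <- c(msg, "event rates must be nonnegative")
  if (object@onset_amplitude < 0) msg <- c(msg, "onset_amplitude must be >= 0")
  if (object@noise_sd < 0 || object@hr_noise_sd_bpm < 0)
    msg <- c(msg, "noise SDs must be nonnegative")
  if (object@tau_rise_s >= object@tau_decay_s)
    msg <- c(msg, "tau_rise_s must be < tau_decay_s")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' Defaults describe a moderately coupled cohort: 20 participants, six
#' 10 min movies, shared arousal events at 6/min with unit coupling gains,
#' idiosyncratic events at 3/min, a 2 microsiemens onset transient, and HR
#' parameters calibrated so that dyadic HR ISC sits in the moderate-synchrony
#' regime (mean dyadic ISC around 0.2 for 10 min epochs). Set
#' \code{coupling_gains = rep(0, n)} for a null (uncoupled) cohort.
#'
#' @param n_participants,n_movies cohort dimensions.
#' @param movie_duration_s movie duration in seconds.
#' @param eda_rate_hz,hr_rate_hz sampling rates.
#' @param shared_event_rate_per_min,idio_event_rate_per_min event rates.
#' @param coupling_gains per-participant gains (recycled scalar allowed).
#' @param onset_amplitude,noise_sd EDA transient amplitude and noise SD.
#' @param hr_baselines_bpm per-participant baselines in [40, 100].
#' @param hr_gain_bpm,hr_noise_sd_bpm,hr_ar_coef,hr_drive_window_s HR model.
#' @param tau_rise_s,tau_decay_s SCR kernel time constants.
#' @param quiz_intercept,quiz_slope,quiz_noise_sd quiz linkage parameters.
#' @param seed root seed (mandatory for any generation).
#' @return a \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(n_participants = 20L, n_movies = 6L,
                         movie_duration_s = 600, eda_rate_hz = 32,
                         hr_rate_hz = 1,
                         shared_event_rate_per_min = 6,
                         coupling_gains = 1,
                         idio_event_rate_per_min = 3,
                         onset_amplitude = 2,
                         noise_sd = 0.05,
                         hr_baselines_bpm = NULL,
                         hr_gain_bpm = 10,
                         hr_noise_sd_bpm = 2,
                         hr_ar_coef = 0.9,
                         hr_drive_window_s = 10,
                         tau_rise_s = 0.75,
                         tau_decay_s = 2,
                         quiz_intercept = 3,
                         quiz_slope = 3,
                         quiz_noise_sd = 1.5,
                         seed = 1L) {
  n <- as.integer(n_participants)
  if (length(coupling_gains) == 1L) coupling_gains <- rep(coupling_gains, n)
  if (is.null(hr_baselines_bpm)) {
    # deterministic spread of resting baselines across the physiological range
    hr_baselines_bpm <- 55 + 30 * (seq_len(n) - 1) / max(1, n - 1)
    if (n == 1L) hr_baselines_bpm <- 70
  }
  new("CohortConfig",
      n_participants = n, n_movies = as.integer(n_movies),
      movie_duration_s = as.numeric(movie_duration_s),
      eda_rate_hz = as.numeric(eda_rate_hz),
      hr_rate_hz = as.numeric(hr_rate_hz),
      shared_event_rate_per_min = as.numeric(shared_event_rate_per_min),
      coupling_gains = as.numeric(coupling_gains),
      idio_event_rate_per_min = as.numeric(idio_event_rate_per_min),
      onset_amplitude = as.numeric(onset_amplitude),
      noise_sd = as.numeric(noise_sd),
      hr_baselines_bpm = as.numeric(hr_baselines_bpm),
      hr_gain_bpm = as.numeric(hr_gain_bpm),
      hr_noise_sd_bpm = as.numeric(hr_noise_sd_bpm),
      hr_ar_coef = as.numeric(hr_ar_coef),
      hr_drive_window_s = as.numeric(hr_drive_window_s),
      tau_rise_s = as.numeric(tau_rise_s),
      tau_decay_s = as.numeric(tau_decay_s),
      quiz_intercept = as.numeric(quiz_intercept),
      quiz_slope = as.numeric(quiz_slope),
      quiz_noise_sd = as.numeric(quiz_noise_sd),
      seed = as.integer(seed))
}

#' EpochedCohort: recordings time-locked to movie onsets
#'
#' Holds per-(participant, movie, modality) \linkS4class{PhysioRecording}
#' segments, each re-indexed so that t = 0 at the movie onset, plus the movie
#' catalogue (onsets and durations on the shared clock).
#'
#' @slot recordings named list; names are \code{"<participant>|<movie>|<modality>"}.
#' @slot catalogue data.frame with columns movie_id, onset_s, duration_s.
#' @export
setClass("EpochedCohort",
  representation(recordings = "list", catalogue = "data.frame")
)

setValidity("EpochedCohort", function(object) {
  msg <- character(0)
  cat <- object@catalogue
  need <- c("movie_id", "onset_s", "duration_s")
  if (!all(need %in% names(cat)))
    msg <- c(msg, "catalogue must have columns movie_id, onset_s, duration_s")
  if (length(object@recordings) &&
      !all(vapply(object@recordings, is, logical(1), "PhysioRecording")))
    msg <- c(msg, "recordings must all be PhysioRecording objects")
  if (length(msg)) msg else TRUE
})

.rec_key <- function(participant, movie, modality)
  paste(participant, movie, modality, sep = "|")

#' Construct an EpochedCohort
#' @param recordings named list of \linkS4class{PhysioRecording} segments,
#'   keyed \code{"<participant>|<movie>|<modality>"} (see \code{\link{getRecording}}).
#' @param catalogue movie catalogue data.frame (movie_id, onset_s, duration_s).
#' @return an \linkS4class{EpochedCohort}.
#' @export
epochedCohort <- function(recordings = list(),
                          catalogue = data.frame(movie_id = character(0),
                                                 onset_s = numeric(0),
                                                 duration_s = numeric(0))) {
  new("EpochedCohort", recordings = recordings, catalogue = catalogue)
}

#' ISCMatrix: dyadic inter-subject correlations for one epoch
#'
#' Symmetric N x N matrix of dyadic ISC values in [-1, 1] (NA on the diagonal
#' and for dyads without enough valid windows), with participant ids as
#' dimnames and the epoch identifier attached.
#'
#' @slot values numeric matrix.
#' @slot epoch_id character scalar.
#' @export
setClass("ISCMatrix",
  representation(values = "matrix", epoch_id = "character")
)

setValidity("ISCMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v) || nrow(v) < 2L)
    msg <- c(msg, "values must be a square matrix with N >= 2")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "values must carry identical participant ids as dimnames")
  offd <- v[row(v) != col(v)]
  if (any(is.finite(offd) & (offd < -1 - 1e-12 | offd > 1 + 1e-12)))
    msg <- c(msg, "ISC values must lie in [-1, 1]")
  if (!all(is.na(diag(v))))
    msg <- c(msg, "diagonal must be NA (self-correlation excluded)")
  if (!isTRUE(all.equal(v, t(v))) && !identical(v, t(v))) {
    d <- v - t(v)
    if (any(abs(d[is.finite(d)]) > 1e-12)) msg <- c(msg, "matrix must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' GroundTruth of a synthetic cohort
#'
#' @slot coupling_gains named per-participant gains.
#' @slot quiz_scores data.frame (participant_id, movie_id, quiz_score in 0..10).
#' @slot shared_event_times named list (by movie) of shared event times (s).
#' @export
setClass("GroundTruth",
  representation(coupling_gains = "numeric",
                 quiz_scores = "data.frame",
                 shared_event_times = "list")
)

setValidity("GroundTruth", function(object) {
  msg <- character(0)
  qs <- object@quiz_scores
  if (nrow(qs) && (any(qs$quiz_score < 0) || any(qs$quiz_score > 10)))
    msg <- c(msg, "quiz scores must lie in [0, 10]")
  if (length(msg)) msg else TRUE
})
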