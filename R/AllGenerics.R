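# Generics and accessor/show methods.

#' @rdname PhysioRecording-class
#' @param object,x a \linkS4class{PhysioRecording}.
#' @export
setGeneric("participantId", function(x) standardGeneric("participantId"))
#' @rdname PhysioRecording-class
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))
#' @rdname PhysioRecording-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname PhysioRecording-class
#' @export
setGeneric("sampleValues", function(x) standardGeneric("sampleValues"))
#' @rdname PhysioRecording-class
#' @export
setGeneric("qualityMask", function(x) standardGeneric("qualityMask"))
#' Replace the quality mask of a recording
#' @param x a \linkS4class{PhysioRecording}.
#' @param value logical vector, same length as the values.
#' @export
setGeneric("qualityMask<-", function(x, value) standardGeneric("qualityMask<-"))
#' @rdname PhysioRecording-class
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))

#' @export
setMethod("participantId", "PhysioRecording", function(x) x@participant_id)
#' @export
setMethod("modality", "PhysioRecording", function(x) x@modality)
#' @export
setMethod("samplingRate", "PhysioRecording", function(x) x@sampling_rate_hz)
#' @export
setMethod("sampleValues", "PhysioRecording", function(x) x@values)
#' @export
setMethod("qualityMask", "PhysioRecording", function(x) x@quality_mask)
#' @export
setReplaceMethod("qualityMask", "PhysioRecording", function(x, value) {
  x@quality_mask <- as.logical(value)
  validObject(x)
  x
})
#' @export
setMethod("sampleTimes", "PhysioRecording", function(x)
  x@t0_s + (seq_along(x@values) - 1) / x@sampling_rate_hz)

setMethod("show", "PhysioRecording", function(object) {
  n <- length(object@values)
  cat(sprintf("PhysioRecording %s [%s] %g Hz, %d samples (%.1f s), %.1f%% usable\n",
              object@participant_id, object@modality, object@sampling_rate_hz,
              n, n / object@sampling_rate_hz,
              if (n) 100 * mean(object@quality_mask) else 100))
})

setMethod("show", "CohortConfig", function(object) {
  cat(sprintf(paste0(
    "CohortConfig: %d participants x %d movies of %g s\n",
    "  EDA %g Hz (noise SD %g uS, onset %g uS), HR %g Hz (noise SD %g bpm)\n",
    "  shared events %g/min, idiosyncratic %g/min, gains in [%g, %g], seed %d\n"),
    object@n_participants, object@n_movies, object@movie_duration_s,
    object@eda_rate_hz, object@noise_sd, object@onset_amplitude,
    object@hr_rate_hz, object@hr_noise_sd_bpm,
    object@shared_event_rate_per_min, object@idio_event_rate_per_min,
    min(object@coupling_gains), max(object@coupling_gains), object@seed))
})

#' @rdname EpochedCohort-class
#' @param x an \linkS4class{EpochedCohort}.
#' @export
setGeneric("participants", function(x) standardGeneric("participants"))
#' @rdname EpochedCohort-class
#' @export
setGeneric("movies", function(x) standardGeneric("movies"))
#' @rdname EpochedCohort-class
#' @export
setGeneric("catalogue", function(x) standardGeneric("catalogue"))

.key_parts <- function(x, i)
  unique(vapply(strsplit(names(x@recordings), "|", fixed = TRUE),
                `[`, character(1), i))

#' @export
setMethod("participants", "EpochedCohort", function(x)
  if (length(x@recordings)) .key_parts(x, 1L) else character(0))
#' @export
setMethod("movies", "EpochedCohort", function(x) as.character(x@catalogue$movie_id))
#' @export
setMethod("catalogue", "EpochedCohort", function(x) x@catalogue)

#' Retrieve one epoched recording
#'
#' @param cohort an \linkS4class{EpochedCohort}.
#' @param participant,movie,modality key of the segment.
#' @return the \linkS4class{PhysioRecording}, or NULL if absent.
#' @export
getRecording <- function(cohort, participant, movie, modality) {
  cohort@recordings[[.rec_key(participant, movie, modality)]]
}

setMethod("show", "EpochedCohort", function(object) {
  cat(sprintf("EpochedCohort: %d participants, %d movies, %d recordings\n",
              length(participants(object)), nrow(object@catalogue),
              length(object@recordings)))
  mods <- if (length(object@recordings)) .key_parts(object, 3L) else character(0)
  if (length(mods)) cat("  modalities:", paste(mods, collapse = ", "), "\n")
})

#' @rdname ISCMatrix-class
#' @param x an \linkS4class{ISCMatrix}.
#' @export
setGeneric("iscValues", function(x) standardGeneric("iscValues"))
#' @rdname ISCMatrix-class
#' @export
setGeneric("epochId", function(x) standardGeneric("epochId"))
#' @export
setMethod("iscValues", "ISCMatrix", function(x) x@values)
#' @export
setMethod("epochId", "ISCMatrix", function(x) x@epoch_id)
#' @export
setMethod("participants", "ISCMatrix", function(x) rownames(x@values))

setMethod("show", "ISCMatrix", function(object) {
  v <- object@values
  offd <- v[row(v) != col(v)]
  cat(sprintf("ISCMatrix '%s': %d participants, mean dyadic ISC %.3f (%d/%d dyads valid)\n",
              object@epoch_id, nrow(v), mean(offd, na.rm = TRUE),
              sum(is.finite(offd)) / 2, nrow(v) * (nrow(v) - 1) / 2))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d participants, %d quiz rows, %d movies with shared events\n",
              length(object@coupling_gains), nrow(object@quiz_scores),
              length(object@shared_event_times)))
})

#' @rdname GroundTruth-class
#' @param x a \linkS4class{GroundTruth}.
#' @export
setGeneric("couplingGains", function(x) standardGeneric("couplingGains"))
#' @rdname GroundTruth-class
#' @export
setGeneric("quizScores", function(x) standardGeneric("quizScores"))
#' @rdname GroundTruth-class
#' @export
setGeneric("sharedEventTimes", function(x) standardGeneric("sharedEventTimes"))
#' @export
setMethod("couplingGains", "GroundTruth", function(x) x@coupling_gains)
#' @export
setMethod("quizScores", "GroundTruth", function(x) x@quiz_scores)
#' @export
setMethod("sharedEventTimes", "GroundTruth", function(x) x@shared_event_times)
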