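# Circular-shuffle significance test for participant-to-group ISC.
#
# The null preserves each signal's amplitude distribution and
# autocorrelation while destroying stimulus alignment: every participant's
# series is circularly shifted by an independent random offset, and the full
# dyadic ISC matrix is recomputed. Each participant's null sample pools
# their N - 1 dyadic values across all shuffles.

#' Shuffle-test parameters
#'
#' @param n_shuffles number of circular shuffles (default 50).
#' @param alpha one-sided significance threshold (default 0.05).
#' @param seed integer seed for the shift draws.
#' @return an object of class \code{ShuffleParams}.
#' @export
shuffleParams <- function(n_shuffles = 50, alpha = 0.05, seed = 1L) {
  stopifnot_scalar(n_shuffles, "n_shuffles", positive = TRUE)
  if (n_shuffles < 2) stop("n_shuffles must be >= 2", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(n_shuffles = as.integer(n_shuffles), alpha = alpha,
                 seed = as.integer(seed)),
            class = "ShuffleParams")
}

#' Circularly shift a series
#'
#' \code{out[i] = in[(i - shift - 1) mod L + 1]}: the series is rotated so
#' its tail wraps to the front. The multiset of values is preserved exactly,
#' as are mean, variance and autocorrelation structure.
#'
#' @param values numeric vector.
#' @param shift integer in \code{[0, length(values))}.
#' @return the shifted vector.
#' @export
circularShift <- function(values, shift) {
  L <- length(values)
  if (shift < 0 || shift >= L)
    stop("shift must lie in [0, length)", call. = FALSE)
  if (shift == 0) return(values)
  c(values[(L - shift + 1):L], values[1:(L - shift)])
}

#' Build the circular-shuffle null distribution
#'
#' For each of \code{n_shuffles} shuffles, every participant's series is
#' shifted by an independent offset drawn uniformly from {1, ..., L-1}
#' (the identity shift is excluded so true synchrony cannot leak into the
#' null) and the full dyadic ISC matrix is recomputed. Participant i's null
#' values pool their N - 1 dyadic entries across all shuffles.
#'
#' @param mat L x N series matrix at the analysis rate (NA = unusable).
#' @param isc_params an \code{\link{iscParams}} object.
#' @param shuffle_params a \code{\link{shuffleParams}} object.
#' @param analysis_rate_hz analysis rate of \code{mat} (default 1).
#' @return named list, one numeric vector of pooled null dyadic ISC values
#'   per participant (length n_shuffles * (N - 1) minus missing dyads).
#' @export
buildNull <- function(mat, isc_params = iscParams(),
                      shuffle_params = shuffleParams(),
                      analysis_rate_hz = 1) {
  L <- nrow(mat)
  N <- ncol(mat)
  if (L < 2L) stop("epoch must contain at least 2 samples", call. = FALSE)
  ids <- colnames(mat)
  acc <- matrix(NA_real_, shuffle_params$n_shuffles * (N - 1), N,
                dimnames = list(NULL, ids))
  withSeed(shuffle_params$seed, {
    for (k in seq_len(shuffle_params$n_shuffles)) {
      shifts <- sample.int(L - 1L, N, replace = TRUE)  # 1 .. L-1
      sm <- mat
      for (j in seq_len(N)) sm[, j] <- circularShift(mat[, j], shifts[j])
      v <- .iscMatrixValues(sm, isc_params, analysis_rate_hz)
      rows <- seq.int((k - 1) * (N - 1) + 1, k * (N - 1))
      for (j in seq_len(N)) acc[rows, j] <- v[-j, j]
    }
  })
  lapply(stats::setNames(ids, ids), function(id) {
    x <- acc[, id]
    x[is.finite(x)]
  })
}

#' Test one participant's ISC against their shuffle null
#'
#' One-sided Welch two-sample t-test of the participant's actual dyadic ISC
#' values (N - 1 of them) against their pooled null values, alternative
#' mean(actual) > mean(null). Welch (unequal variance) is used because the
#' two samples differ greatly in size.
#'
#' @param actual_values the participant's dyadic ISC values.
#' @param null_values their pooled shuffled dyadic ISC values.
#' @param alpha significance threshold (default 0.05).
#' @param participant_id optional id carried into the result.
#' @return one-row data.frame: participant_id, n_actual, n_null,
#'   mean_actual, mean_null, t_stat, df, p_value, significant, testable,
#'   reason (empty when testable).
#' @export
testParticipant <- function(actual_values, null_values, alpha = 0.05,
                            participant_id = NA_character_) {
  a <- actual_values[is.finite(actual_values)]
  b <- null_values[is.finite(null_values)]
  base <- data.frame(participant_id = participant_id,
                     n_actual = length(a), n_null = length(b),
                     mean_actual = if (length(a)) mean(a) else NA_real_,
                     mean_null = if (length(b)) mean(b) else NA_real_,
                     t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
                     significant = NA, testable = FALSE, reason = "",
                     stringsAsFactors = FALSE)
  if (length(a) < 2 || length(b) < 2) {
    base$reason <- "fewer than 2 usable values in a sample"
    return(base)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    base$reason <- "zero variance in both samples"
    return(base)
  }
  tt <- stats::t.test(a, b, alternative = "greater", var.equal = FALSE)
  base$t_stat <- unname(tt$statistic)
  base$df <- unname(tt$parameter)
  base$p_value <- tt$p.value
  base$significant <- tt$p.value < alpha
  base$testable <- TRUE
  base
}

#' Run the full significance test for one epoch
#'
#' Computes the actual dyadic ISC matrix, builds the circular-shuffle null,
#' and applies \code{\link{testParticipant}} to every participant.
#'
#' @inheritParams buildNull
#' @param epoch_id label for the epoch.
#' @return data.frame with one row per participant (see
#'   \code{\link{testParticipant}}) plus a \code{p2g_isc} column; the actual
#'   \linkS4class{ISCMatrix} and the null list are attached as attributes
#'   \code{"isc"} and \code{"null"}.
#' @export
cohortSignificance <- function(mat, isc_params = iscParams(),
                               shuffle_params = shuffleParams(),
                               analysis_rate_hz = 1, epoch_id = "epoch") {
  isc <- iscMatrix(mat, isc_params, analysis_rate_hz = analysis_rate_hz,
                   epoch_id = epoch_id)
  v <- iscValues(isc)
  mat <- mat[, rownames(v), drop = FALSE]  # participants omitted by iscMatrix
  nulls <- buildNull(mat, isc_params, shuffle_params, analysis_rate_hz)
  rows <- lapply(rownames(v), function(id) {
    res <- testParticipant(v[id, colnames(v) != id], nulls[[id]],
                           alpha = shuffle_params$alpha, participant_id = id)
    res$p2g_isc <- if (any(is.finite(v[id, colnames(v) != id])))
      mean(v[id, colnames(v) != id], na.rm = TRUE) else NA_real_
    res
  })
  out <- do.call(rbind, rows)
  attr(out, "isc") <- isc
  attr(out, "null") <- nulls
  out
}

#' Fraction of participants with significant ISC
#'
#' 100 x (number significant) / (number testable). Untestable participants
#' (too few usable dyads) are excluded from the denominator.
#'
#' @param results data.frame from \code{\link{cohortSignificance}} or rows
#'   from \code{\link{testParticipant}}.
#' @return percentage in [0, 100], or NA if no participant was testable.
#' @export
fractionSignificant <- function(results) {
  testable <- results$testable %in% TRUE
  if (!any(testable)) return(NA_real_)
  100 * sum(results$significant[testable]) / sum(testable)
}
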