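# Windowed dyadic inter-subject correlations (ISC).
#
# ISC between two participants is the plain mean of Pearson correlations
# computed in short sliding windows (default 15 s sliding at 1 s increments)
# over the epoch. Rolling-sum vectorization makes the N x N matrix and the
# 50-shuffle null affordable at cohort scale.

#' ISC parameters
#'
#' @param window_s window length in seconds (default 15).
#' @param step_s window increment in seconds (default 1).
#' @param min_valid_fraction minimum fraction of a window's sample pairs
#'   that must be usable for the window to count (default 0.8); windows
#'   below it, and zero-variance windows, are treated as missing.
#' @param min_windows minimum number of valid windows for the epoch-level
#'   ISC to be reported (default 10).
#' @param fisher average window correlations on the Fisher-z scale instead
#'   of raw (default FALSE: plain mean).
#' @return an object of class \code{ISCParams} (a validated list).
#' @export
iscParams <- function(window_s = 15, step_s = 1, min_valid_fraction = 0.8,
                      min_windows = 10, fisher = FALSE) {
  stopifnot_scalar(window_s, "window_s", positive = TRUE)
  stopifnot_scalar(step_s, "step_s", positive = TRUE)
  if (window_s < step_s) stop("window_s must be >= step_s", call. = FALSE)
  if (min_valid_fraction <= 0 || min_valid_fraction > 1)
    stop("min_valid_fraction must lie in (0, 1]", call. = FALSE)
  stopifnot_scalar(min_windows, "min_windows", positive = TRUE)
  structure(list(window_s = window_s, step_s = step_s,
                 min_valid_fraction = min_valid_fraction,
                 min_windows = min_windows, fisher = isTRUE(fisher)),
            class = "ISCParams")
}

# window-wise Pearson r for one pair, rolling-sum implementation.
# x, y numeric with NA at unusable samples. Returns r per window (NA where
# the window is incomplete or degenerate).
.pairWindowCors <- function(x, y, w, step, min_valid_fraction) {
  L <- length(x)
  if (length(y) != L) stop("series lengths differ", call. = FALSE)
  if (L < w) stop("series shorter than one window", call. = FALSE)
  starts <- seq.int(1L, L - w + 1L, by = step)
  ok <- is.finite(x) & is.finite(y)
  if (all(ok)) {
    n <- w
    Sx <- rollingWindowSums(x, w, starts)
    Sy <- rollingWindowSums(y, w, starts)
    Sxx <- rollingWindowSums(x * x, w, starts)
    Syy <- rollingWindowSums(y * y, w, starts)
    Sxy <- rollingWindowSums(x * y, w, starts)
  } else {
    x0 <- ifelse(ok, x, 0)
    y0 <- ifelse(ok, y, 0)
    n <- rollingWindowSums(as.numeric(ok), w, starts)
    Sx <- rollingWindowSums(x0, w, starts)
    Sy <- rollingWindowSums(y0, w, starts)
    Sxx <- rollingWindowSums(x0 * x0, w, starts)
    Syy <- rollingWindowSums(y0 * y0, w, starts)
    Sxy <- rollingWindowSums(x0 * y0, w, starts)
  }
  dx <- n * Sxx - Sx^2
  dy <- n * Syy - Sy^2
  r <- (n * Sxy - Sx * Sy) / sqrt(dx * dy)
  # degenerate: too few usable pairs, or (numerically) zero variance
  bad <- n < pmax(3, ceiling(min_valid_fraction * w)) |
    dx <= 1e-9 * n * Sxx | dy <= 1e-9 * n * Syy
  r[bad] <- NA_real_
  pmin(pmax(r, -1), 1)
}

.meanWindowCors <- function(r, params) {
  ok <- is.finite(r)
  if (sum(ok) < params$min_windows) return(NA_real_)
  if (params$fisher) tanh(mean(atanh(pmin(pmax(r[ok], -1 + 1e-12),
                                          1 - 1e-12))))
  else mean(r[ok])
}

#' Pearson correlation of one window
#'
#' Correlates the pairwise-usable samples of two equal-length windows.
#' Returns NA when fewer than \code{min_valid_fraction} of the pairs are
#' usable, fewer than 3 pairs remain, or either series has zero variance
#' (a constant window carries no synchrony evidence).
#'
#' @param x,y numeric vectors of equal length; NA marks unusable samples.
#' @param min_valid_fraction minimum usable fraction (default 0.8).
#' @return Pearson r, or NA.
#' @export
windowCorrelation <- function(x, y, min_valid_fraction = 0.8) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  .pairWindowCors(x, y, w = length(x), step = 1L,
                  min_valid_fraction = min_valid_fraction)[1]
}

#' Sliding-window ISC of one dyad
#'
#' Pearson correlations in windows of \code{window_s} seconds starting at
#' 0, step_s, 2 step_s, ... (trailing partial window dropped), averaged
#' over all windows that are valid; missing windows are excluded from the
#' mean. Returns NA if fewer than \code{min_windows} windows are valid.
#'
#' @param x,y equal-length numeric series at \code{sampling_rate_hz}; NA
#'   marks unusable samples.
#' @param params an \code{\link{iscParams}} object.
#' @param sampling_rate_hz common sampling rate of both series.
#' @return mean windowed correlation in [-1, 1], or NA.
#' @export
slidingISC <- function(x, y, params = iscParams(), sampling_rate_hz = 1) {
  w <- round(params$window_s * sampling_rate_hz)
  step <- max(1L, round(params$step_s * sampling_rate_hz))
  r <- .pairWindowCors(x, y, w, step, params$min_valid_fraction)
  .meanWindowCors(r, params)
}

#' Assemble an epoch's series matrix at the analysis rate
#'
#' Collects one movie x modality slice of an \linkS4class{EpochedCohort}
#' into an L x N matrix (time x participant) at \code{analysis_rate_hz}
#' (default 1 Hz, so HR and EDA use identical 15-sample windows). Higher-rate
#' recordings are mean-decimated block-wise; masked samples become NA, and a
#' decimated sample is NA when fewer than half of its block is usable.
#'
#' @param cohort an \linkS4class{EpochedCohort}.
#' @param movie movie id.
#' @param modality modality to extract.
#' @param analysis_rate_hz target rate (default 1).
#' @return numeric matrix with participant ids as column names.
#' @export
epochSeriesMatrix <- function(cohort, movie, modality, analysis_rate_hz = 1) {
  keys <- names(cohort@recordings)
  sel <- endsWith(keys, paste0("|", movie, "|", modality))
  if (!any(sel))
    stop(sprintf("no %s recordings for movie '%s'", modality, movie),
         call. = FALSE)
  recs <- cohort@recordings[sel]
  cols <- lapply(recs, function(rec) {
    v <- rec@values
    v[!rec@quality_mask] <- NA_real_
    fac <- rec@sampling_rate_hz / analysis_rate_hz
    if (abs(fac - round(fac)) > 1e-8)
      stop("sampling rate must be an integer multiple of the analysis rate",
           call. = FALSE)
    fac <- round(fac)
    if (fac > 1L) {
      nb <- floor(length(v) / fac)
      m <- matrix(v[seq_len(nb * fac)], nrow = fac)
      ok <- colSums(!is.na(m)) >= fac / 2
      out <- colMeans(m, na.rm = TRUE)
      out[!ok] <- NA_real_
      out[is.nan(out)] <- NA_real_
      out
    } else v
  })
  len <- unique(vapply(cols, length, integer(1)))
  if (length(len) != 1L)
    stop("epoch segments have inconsistent lengths", call. = FALSE)
  mat <- do.call(cbind, cols)
  colnames(mat) <- vapply(recs, function(r) r@participant_id, character(1))
  mat[, order(colnames(mat)), drop = FALSE]
}

# dyadic ISC values for an L x N series matrix; returns plain matrix
.iscMatrixValues <- function(mat, params, rate_hz = 1) {
  N <- ncol(mat)
  L <- nrow(mat)
  w <- round(params$window_s * rate_hz)
  step <- max(1L, round(params$step_s * rate_hz))
  if (L < w) stop("epoch shorter than one window", call. = FALSE)
  ids <- colnames(mat)
  vals <- matrix(NA_real_, N, N, dimnames = list(ids, ids))
  starts <- seq.int(1L, L - w + 1L, by = step)
  if (!anyNA(mat)) {
    # fast path: per-column window sums precomputed, per-dyad cross term only
    cs <- apply(mat, 2, cumsum)
    cs2 <- apply(mat * mat, 2, cumsum)
    Sx <- rbind(0, cs)[starts + w, , drop = FALSE] -
      rbind(0, cs)[starts, , drop = FALSE]
    Sxx <- rbind(0, cs2)[starts + w, , drop = FALSE] -
      rbind(0, cs2)[starts, , drop = FALSE]
    dx <- w * Sxx - Sx^2
    badcol <- dx <= 1e-9 * w * Sxx
    for (i in seq_len(N - 1)) {
      xi <- mat[, i]
      for (j in seq.int(i + 1, N)) {
        cxy <- c(0, cumsum(xi * mat[, j]))
        Sxy <- cxy[starts + w] - cxy[starts]
        r <- (w * Sxy - Sx[, i] * Sx[, j]) / sqrt(dx[, i] * dx[, j])
        r[badcol[, i] | badcol[, j]] <- NA_real_
        r <- pmin(pmax(r, -1), 1)
        vals[i, j] <- vals[j, i] <- .meanWindowCors(r, params)
      }
    }
  } else {
    for (i in seq_len(N - 1)) {
      for (j in seq.int(i + 1, N)) {
        r <- .pairWindowCors(mat[, i], mat[, j], w, step,
                             params$min_valid_fraction)
        vals[i, j] <- vals[j, i] <- .meanWindowCors(r, params)
      }
    }
  }
  vals
}

#' Dyadic ISC matrix for one epoch
#'
#' Computes \code{\link{slidingISC}} for all N(N-1)/2 unique dyads of an
#' epoch and mirrors them into a symmetric \linkS4class{ISCMatrix}
#' (diagonal NA). Accepts either an L x N series matrix (time x participant,
#' already at the analysis rate, NA = unusable) or an
#' \linkS4class{EpochedCohort} plus \code{movie}/\code{modality}.
#'
#' @param x series matrix or \linkS4class{EpochedCohort}.
#' @param params an \code{\link{iscParams}} object.
#' @param movie,modality epoch selector when \code{x} is a cohort.
#' @param analysis_rate_hz analysis rate for cohort extraction (default 1).
#' @param epoch_id label stored in the result.
#' @return an \linkS4class{ISCMatrix}.
#' @export
iscMatrix <- function(x, params = iscParams(), movie = NULL, modality = NULL,
                      analysis_rate_hz = 1, epoch_id = NULL) {
  if (is(x, "EpochedCohort")) {
    if (is.null(movie) || is.null(modality))
      stop("movie and modality are required with an EpochedCohort",
           call. = FALSE)
    if (is.null(epoch_id)) epoch_id <- paste(movie, modality, sep = "/")
    x <- epochSeriesMatrix(x, movie, modality, analysis_rate_hz)
  }
  if (ncol(x) < 2L)
    stop("need at least 2 participants with data for the epoch",
         call. = FALSE)
  all_na <- colSums(is.finite(x)) == 0L
  if (any(all_na)) {
    warning(sprintf("omitting participants without usable data: %s",
                    paste(colnames(x)[all_na], collapse = ", ")))
    x <- x[, !all_na, drop = FALSE]
    if (ncol(x) < 2L)
      stop("fewer than 2 participants with usable data", call. = FALSE)
  }
  if (is.null(epoch_id)) epoch_id <- "epoch"
  new("ISCMatrix", values = .iscMatrixValues(x, params, analysis_rate_hz),
      epoch_id = as.character(epoch_id))
}

#' Participant-to-group ISC
#'
#' For each participant, the mean of their dyadic ISC values with all other
#' participants (row mean excluding the diagonal, missing dyads dropped;
#' NA if a row has no valid dyad).
#'
#' @param matrix an \linkS4class{ISCMatrix}.
#' @return named numeric vector, one value per participant.
#' @export
participantToGroup <- function(matrix) {
  stopifnot(is(matrix, "ISCMatrix"))
  v <- matrix@values
  out <- vapply(seq_len(nrow(v)), function(i) {
    row <- v[i, -i]
    if (any(is.finite(row))) mean(row, na.rm = TRUE) else NA_real_
  }, numeric(1))
  stats::setNames(out, rownames(v))
}
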