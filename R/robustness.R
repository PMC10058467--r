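# Robustness of ISC significance under varying stimulus duration and group
# size: movie-order concatenation, duration truncation, random participant
# subsets, and the resulting fraction-significant surface.

#' Default stimulus-duration grid (minutes)
#'
#' 30 s, 1 min, then 2 min increments up to 19 min, then from 24 min in
#' 4 min increments up to 60 min (the gap between 19 and 24 is part of the
#' design).
#'
#' @return strictly increasing numeric vector of durations in minutes.
#' @export
durationGrid <- function() {
  c(0.5, 1, seq(3, 19, by = 2), seq(24, 60, by = 4))
}

#' The six counterbalanced movie orders (Latin square)
#'
#' Six of the 720 possible orders of six movie clips, arranged as a Latin
#' square: each movie appears once per row (order) and once per column
#' (position). Validated on construction.
#'
#' @return 6 x 6 integer matrix, one order per row.
#' @export
latinSquareOrders <- function() {
  m <- rbind(c(1, 2, 3, 4, 5, 6),
             c(2, 5, 4, 6, 1, 3),
             c(5, 1, 6, 3, 2, 4),
             c(3, 4, 5, 1, 6, 2),
             c(6, 3, 2, 5, 4, 1),
             c(4, 6, 1, 2, 3, 5))
  storage.mode(m) <- "integer"
  for (i in seq_len(6)) {
    if (!setequal(m[i, ], 1:6))
      stop("order row is not a permutation of 1..6", call. = FALSE)
    if (!setequal(m[, i], 1:6))
      stop("order column is not a permutation of 1..6", call. = FALSE)
  }
  m
}

#' Enumerate all orderings of n movie clips
#'
#' Full-factorial alternative to the Latin-square subset: every permutation
#' of \code{1..n}, one per row.
#'
#' @param n number of movie clips (default 6).
#' @return n! x n integer matrix of permutations.
#' @export
allMovieOrders <- function(n = 6) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allMovieOrders(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], n,
                   sub[, seq.int(pos, n - 1)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Number of distinct movie-clip orderings
#'
#' Counted by enumerating the permutations (six clips: 720).
#'
#' @param n number of movie clips (default 6).
#' @return integer count.
#' @export
countMovieOrders <- function(n = 6) {
  nrow(allMovieOrders(n))
}

#' Total minutes of data in an analysis cell
#'
#' The total duration of included data for a group of
#' \code{group_size} participants each contributing \code{duration_min}
#' minutes: their product. Used to compare growing the data via more
#' participants against growing it via longer stimuli.
#'
#' @param group_size number of participants.
#' @param duration_min stimulus duration per participant (minutes).
#' @return total minutes.
#' @export
totalMinutes <- function(group_size, duration_min) {
  group_size * duration_min
}

#' Concatenate a cohort's movie epochs in a given order
#'
#' Stacks the per-movie series matrices (at the analysis rate) in the given
#' movie order into one continuous series per participant. Participants
#' missing any movie in the order are dropped with a warning, keeping the
#' concatenation well-defined.
#'
#' @param cohort an \linkS4class{EpochedCohort}.
#' @param order integer vector of movie indices (into \code{movies(cohort)}).
#' @param modality modality to concatenate.
#' @param analysis_rate_hz analysis rate (default 1).
#' @return L x N numeric matrix, L = total concatenated length.
#' @export
concatenateEpochs <- function(cohort, order, modality = "HR",
                              analysis_rate_hz = 1) {
  if (!length(order)) stop("empty movie order", call. = FALSE)
  mids <- movies(cohort)
  if (any(order < 1 | order > length(mids)))
    stop("order indexes a movie outside the catalogue", call. = FALSE)
  mats <- lapply(mids[order], function(m)
    epochSeriesMatrix(cohort, m, modality, analysis_rate_hz))
  common <- Reduce(intersect, lapply(mats, colnames))
  dropped <- setdiff(unique(unlist(lapply(mats, colnames))), common)
  if (length(dropped))
    warning(sprintf("dropping participants missing a movie in this order: %s",
                    paste(dropped, collapse = ", ")))
  if (length(common) < 1L)
    stop("no participant has data for every movie in the order",
         call. = FALSE)
  do.call(rbind, lapply(mats, function(m) m[, common, drop = FALSE]))
}

#' Truncate a concatenated series to its first minutes
#'
#' @param series numeric vector or matrix (time in rows).
#' @param duration_min duration to keep, in minutes.
#' @param rate_hz sampling rate (default 1).
#' @return the first \code{round(duration_min * 60 * rate_hz)} samples/rows.
#' @export
truncateSeries <- function(series, duration_min, rate_hz = 1) {
  n <- round(duration_min * 60 * rate_hz)
  len <- if (is.matrix(series)) nrow(series) else length(series)
  if (n > len)
    stop("requested duration exceeds the series length", call. = FALSE)
  if (is.matrix(series)) series[seq_len(n), , drop = FALSE]
  else series[seq_len(n)]
}

#' Draw random participant subsets of a given size
#'
#' \code{n_subsets} subsets of \code{group_size} distinct participants,
#' reproducible from the seed. When fewer than \code{n_subsets} distinct
#' subsets exist, all distinct subsets are enumerated instead.
#'
#' @param participant_ids vector of ids.
#' @param group_size subset size, between 2 and the number of ids.
#' @param n_subsets number of subsets (default 50).
#' @param seed integer seed.
#' @return list of character vectors.
#' @export
sampleSubsets <- function(participant_ids, group_size, n_subsets = 50,
                          seed = 1L) {
  N <- length(participant_ids)
  if (group_size < 2 || group_size > N)
    stop("group_size must lie in [2, number of participants]", call. = FALSE)
  if (choose(N, group_size) < n_subsets) {
    cmb <- utils::combn(participant_ids, group_size, simplify = FALSE)
    return(cmb)
  }
  withSeed(seed, {
    lapply(seq_len(n_subsets), function(s)
      sample(participant_ids, group_size))
  })
}

#' Fraction-significant surface over duration and group size
#'
#' For every cell (movie order x stimulus duration x group size x
#' participant subset): concatenate the movie epochs in the order, keep the
#' first \code{duration} minutes, restrict to the subset, run the
#' circular-shuffle significance test, and record the percentage of
#' participants with significant ISC. Shuffle seeds vary per cell by a
#' documented derivation from \code{seed}, so cells are independent but
#' individually reproducible.
#'
#' @param cohort an \linkS4class{EpochedCohort}.
#' @param modality modality to analyze (default "HR").
#' @param orders matrix of movie orders, one per row (default the Latin
#'   square rows).
#' @param durations_min duration grid in minutes (default
#'   \code{\link{durationGrid}()}).
#' @param group_sizes group sizes (default 2 .. N).
#' @param isc_params an \code{\link{iscParams}} object.
#' @param n_shuffles,alpha shuffle-test settings.
#' @param n_subsets subsets per group size (default 50).
#' @param seed root seed for subsets and shuffles.
#' @param analysis_rate_hz analysis rate (default 1).
#' @return data.frame of cells: order_id, duration_min, group_size,
#'   subset_id, n_testable, fraction_significant, total_minutes.
#' @export
robustnessSurface <- function(cohort, modality = "HR",
                              orders = latinSquareOrders(),
                              durations_min = durationGrid(),
                              group_sizes = NULL,
                              isc_params = iscParams(),
                              n_shuffles = 50, alpha = 0.05,
                              n_subsets = 50, seed = 1L,
                              analysis_rate_hz = 1) {
  if (is.vector(orders)) orders <- matrix(orders, nrow = 1)
  rows <- list()
  for (o in seq_len(nrow(orders))) {
    full <- concatenateEpochs(cohort, orders[o, ], modality,
                              analysis_rate_hz)
    ids <- colnames(full)
    if (is.null(group_sizes)) group_sizes <- seq.int(2L, length(ids))
    for (m in group_sizes) {
      subsets <- sampleSubsets(ids, m, n_subsets,
                               seed = mixSeed(seed, "subsets", o, m))
      for (di in seq_along(durations_min)) {
        d <- durations_min[di]
        trunc <- truncateSeries(full, d, analysis_rate_hz * 1)
        for (si in seq_along(subsets)) {
          sub <- trunc[, subsets[[si]], drop = FALSE]
          sp <- shuffleParams(n_shuffles, alpha,
                              seed = mixSeed(seed, "shuffle", o, di, m, si))
          res <- tryCatch(
            cohortSignificance(sub, isc_params, sp, analysis_rate_hz,
                               epoch_id = sprintf("o%d/d%g/m%d/s%d",
                                                  o, d, m, si)),
            error = function(e)
              stop(sprintf("cell order=%d duration=%g size=%d subset=%d: %s",
                           o, d, m, si, conditionMessage(e)), call. = FALSE))
          rows[[length(rows) + 1L]] <- data.frame(
            order_id = o, duration_min = d, group_size = m, subset_id = si,
            n_testable = sum(res$testable),
            fraction_significant = fractionSignificant(res),
            total_minutes = totalMinutes(m, d))
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a robustness surface
#'
#' Per (duration, group size) cell: the mean fraction of significant
#' participants over orders and subsets, the SD across movie orders (of
#' order means, the duration-axis dispersion) and the SD across subsets (of
#' subset means, the group-size-axis dispersion), plus the cell's total
#' minutes of included data.
#'
#' @param points data.frame from \code{\link{robustnessSurface}}.
#' @return data.frame: duration_min, group_size, total_minutes, n_points,
#'   mean_fraction, sd_across_orders, sd_across_subsets.
#' @export
summarizeRobustness <- function(points) {
  key <- interaction(points$duration_min, points$group_size, drop = TRUE)
  out <- lapply(split(points, key), function(p) {
    om <- tapply(p$fraction_significant, p$order_id, mean, na.rm = TRUE)
    sm <- tapply(p$fraction_significant, p$subset_id, mean, na.rm = TRUE)
    data.frame(duration_min = p$duration_min[1],
               group_size = p$group_size[1],
               total_minutes = p$total_minutes[1],
               n_points = nrow(p),
               mean_fraction = mean(p$fraction_significant, na.rm = TRUE),
               sd_across_orders = if (length(om) > 1) stats::sd(om) else 0,
               sd_across_subsets = if (length(sm) > 1) stats::sd(sm) else 0)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$duration_min, out$group_size), ]
}

#' Association between ISC and quiz performance
#'
#' Spearman rank correlation (tie-corrected, asymptotic p) between
#' participant-to-group ISC and the number of correctly answered questions
#' about each movie, per movie and pooled over all (participant, movie)
#' pairs ("overall").
#'
#' @param p2g data.frame with columns participant_id, movie_id, p2g_isc.
#' @param quiz data.frame with columns participant_id, movie_id, quiz_score.
#' @return data.frame: movie_id ("overall" for the pooled row), n, rho,
#'   p_value, reason (non-empty when the cell was untestable).
#' @export
iscPerformanceAssociation <- function(p2g, quiz) {
  d <- merge(p2g, quiz, by = c("participant_id", "movie_id"))
  d <- d[is.finite(d$p2g_isc) & is.finite(d$quiz_score), ]
  one <- function(dd, label) {
    if (nrow(dd) < 5)
      return(data.frame(movie_id = label, n = nrow(dd), rho = NA_real_,
                        p_value = NA_real_, reason = "fewer than 5 pairs"))
    if (length(unique(dd$quiz_score)) < 2)
      return(data.frame(movie_id = label, n = nrow(dd), rho = NA_real_,
                        p_value = NA_real_, reason = "all scores tied"))
    ct <- suppressWarnings(
      stats::cor.test(dd$p2g_isc, dd$quiz_score, method = "spearman",
                      exact = FALSE))
    data.frame(movie_id = label, n = nrow(dd), rho = unname(ct$estimate),
               p_value = ct$p.value, reason = "")
  }
  per_movie <- lapply(split(d, d$movie_id), function(dd)
    one(dd, dd$movie_id[1]))
  out <- rbind(do.call(rbind, per_movie), one(d, "overall"))
  rownames(out) <- NULL
  out
}
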