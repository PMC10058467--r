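# CSV readers/writers for cohorts, catalogues and ground truth.
#
# Long format: participant_id, movie_id, modality, t_s, value, quality —
# one row per sample, RFC 4180 via utils::write.csv.

#' Write an epoched cohort as long-format CSV
#'
#' @param cohort an \linkS4class{EpochedCohort}.
#' @param path output file (combined), or a directory when
#'   \code{split_by_modality = TRUE} (one \code{<modality>.csv} per
#'   modality).
#' @param split_by_modality write one file per modality (default FALSE).
#' @return invisibly, the paths written.
#' @export
writeCohortCsv <- function(cohort, path, split_by_modality = FALSE) {
  stopifnot(is(cohort, "EpochedCohort"))
  df <- do.call(rbind, lapply(names(cohort@recordings), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    rec <- cohort@recordings[[key]]
    data.frame(participant_id = parts[1], movie_id = parts[2],
               modality = parts[3],
               t_s = (seq_along(rec@values) - 1) / rec@sampling_rate_hz,
               value = rec@values, quality = rec@quality_mask,
               stringsAsFactors = FALSE)
  }))
  if (split_by_modality) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(unique(df$modality), function(m) {
      f <- file.path(path, paste0(m, ".csv"))
      utils::write.csv(df[df$modality == m, ], f, row.names = FALSE)
      f
    }, character(1))
  } else {
    utils::write.csv(df, path, row.names = FALSE)
    paths <- path
  }
  invisible(paths)
}

#' Write the movie catalogue as CSV
#' @param catalogue data.frame (movie_id, onset_s, duration_s).
#' @param path output file.
#' @export
writeCatalogueCsv <- function(catalogue, path) {
  utils::write.csv(catalogue, path, row.names = FALSE)
  invisible(path)
}

#' Write ground truth (gains and quiz scores) as CSV
#' @param truth a \linkS4class{GroundTruth}.
#' @param dir output directory; writes \code{gains.csv} and
#'   \code{quiz_scores.csv}.
#' @export
writeGroundTruthCsv <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(participant_id = names(truth@coupling_gains),
                              gain = unname(truth@coupling_gains)),
                   file.path(dir, "gains.csv"), row.names = FALSE)
  utils::write.csv(truth@quiz_scores, file.path(dir, "quiz_scores.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read recordings from long-format CSV
#'
#' Validates the documented long format (participant_id, movie_id,
#' modality, t_s, value, quality): unknown modalities, non-monotone or
#' rate-inconsistent time stamps and malformed values are reported with the
#' offending data line numbers.
#'
#' @param path CSV file written by \code{\link{writeCohortCsv}} (combined
#'   form) or equivalent.
#' @param catalogue optional movie catalogue to attach (data.frame or path
#'   to its CSV).
#' @return an \linkS4class{EpochedCohort}.
#' @export
readRecordings <- function(path, catalogue = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "movie_id", "modality", "t_s", "value",
            "quality")
  if (!all(need %in% names(df)))
    stop(sprintf("missing columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", ")),
         call. = FALSE)
  if (nrow(df) == 0L)
    stop("empty input: file contains no samples", call. = FALSE)
  line_no <- seq_len(nrow(df)) + 1L  # header is line 1
  bad_mod <- !df$modality %in% .MODALITIES
  if (any(bad_mod))
    stop(sprintf("unknown modality at line(s) %s",
                 paste(utils::head(line_no[bad_mod], 5), collapse = ", ")),
         call. = FALSE)
  bad_val <- !is.finite(suppressWarnings(as.numeric(df$value)))
  if (any(bad_val))
    stop(sprintf("malformed value at line(s) %s",
                 paste(utils::head(line_no[bad_val], 5), collapse = ", ")),
         call. = FALSE)
  recs <- list()
  key <- paste(df$participant_id, df$movie_id, df$modality, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    g <- df[idx, ]
    dt <- diff(g$t_s)
    if (any(dt <= 0))
      stop(sprintf("non-monotone time in group '%s' at line %d",
                   k, line_no[idx][which(dt <= 0)[1] + 1L]), call. = FALSE)
    if (max(dt) - min(dt) > 1e-6 * max(dt))
      stop(sprintf("inconsistent sampling rate in group '%s' (line %d)",
                   k, line_no[idx][which.max(dt) + 1L]), call. = FALSE)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    recs[[k]] <- physioRecording(parts[1], parts[3],
                                 sampling_rate_hz = 1 / dt[1],
                                 values = as.numeric(g$value),
                                 quality_mask = as.logical(g$quality),
                                 t0_s = 0)
  }
  if (is.character(catalogue)) catalogue <- readCatalogue(catalogue)
  if (is.null(catalogue)) {
    mids <- unique(df$movie_id)
    catalogue <- data.frame(movie_id = mids, onset_s = NA_real_,
                            duration_s = vapply(mids, function(m) {
                              r <- recs[[grep(paste0("|", m, "|"),
                                              names(recs), fixed = TRUE)[1]]]
                              length(r@values) / r@sampling_rate_hz
                            }, numeric(1)),
                            stringsAsFactors = FALSE)
  }
  epochedCohort(recs, catalogue)
}

#' Read a movie catalogue CSV
#' @param path CSV with columns movie_id, onset_s, duration_s.
#' @return data.frame.
#' @export
readCatalogue <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("movie_id", "onset_s", "duration_s")
  if (!all(need %in% names(df)))
    stop("catalogue must have columns movie_id, onset_s, duration_s",
         call. = FALSE)
  df
}

#' Reference movie-clip catalogue
#'
#' The six roughly 10 min movie clips of the reference study design, with
#' their durations (mm:ss) parsed into minutes. Shipped as package data;
#' used e.g. to compute the design's mean clip duration.
#'
#' @return data.frame: name, duration_mm_ss, duration_min.
#' @export
movieCatalogue <- function() {
  f <- system.file("extdata", "movie_catalogue.csv", package = "physync",
                   mustWork = TRUE)
  df <- utils::read.csv(f, stringsAsFactors = FALSE)
  parts <- strsplit(df$duration_mm_ss, ":", fixed = TRUE)
  df$duration_min <- vapply(parts, function(p)
    as.numeric(p[1]) + as.numeric(p[2]) / 60, numeric(1))
  df
}
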