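# End-to-end pipeline: simulate -> preprocess -> ISC -> significance ->
# (optional) robustness, with a machine-readable run manifest.

#' Run the full synchrony pipeline
#'
#' Chains the pipeline stages on a synthetic cohort described by a run
#' configuration (a YAML file or an equivalent named list) and writes all
#' stage outputs plus a manifest to \code{out_dir}. Identical configurations
#' produce byte-identical result CSVs. A root seed is mandatory: the run is
#' refused before any computation without one.
#'
#' Config fields (all optional except \code{seed}): \code{cohort} (arguments
#' to \code{\link{cohortConfig}}), \code{isc} (arguments to
#' \code{\link{iscParams}}), \code{shuffle} (\code{n_shuffles},
#' \code{alpha}), \code{modalities}, and \code{robustness}
#' (\code{enabled}, \code{durations_min}, \code{group_sizes},
#' \code{n_orders}, \code{n_subsets}).
#'
#' @param config path to a YAML file, or a named list.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$seed))
    stop("config must specify a root seed", call. = FALSE)
  seed <- as.integer(config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cc_args <- config$cohort
  cc_args$seed <- seed
  cc <- do.call(cohortConfig, cc_args)
  ip <- do.call(iscParams, if (is.null(config$isc)) list() else config$isc)
  n_shuffles <- if (is.null(config$shuffle$n_shuffles)) 50
    else config$shuffle$n_shuffles
  alpha <- if (is.null(config$shuffle$alpha)) 0.05 else config$shuffle$alpha
  modalities <- if (is.null(config$modalities)) c("HR", "EDA_PHASIC")
    else config$modalities

  # stage: simulate
  gen <- generateCohort(cc, modalities = modalities)
  writeCohortCsv(gen$cohort, file.path(out_dir, "cohort.csv"))
  writeCatalogueCsv(catalogue(gen$cohort), file.path(out_dir, "catalogue.csv"))
  writeGroundTruthCsv(gen$truth, out_dir)

  # stage: preprocess (HR cleaning + stuck detection + exclusion accounting)
  reports <- list()
  cohort <- gen$cohort
  for (key in names(cohort@recordings)) {
    rec <- cohort@recordings[[key]]
    if (rec@modality == "HR") {
      cl <- cleanHr(rec)
      stuck <- detectStuckHr(rec)
      rep <- cl$report
      rep$stuck_ratio <- stuck$stuck_ratio
      rep$excluded <- applyExclusion(rep, cl$recording,
                                     stuck_flagged = stuck$flagged)
      rep$movie_id <- strsplit(key, "|", fixed = TRUE)[[1]][2]
      reports[[key]] <- rep
      if (!rep$excluded) cohort@recordings[[key]] <- cl$recording
      else cohort@recordings[[key]] <- NULL
    } else if (rec@modality == "EDA_PHASIC") {
      qualityMask(cohort@recordings[[key]]) <-
        rec@quality_mask & markEdaSignalLoss(rec)
    }
  }
  report_df <- do.call(rbind, reports)
  if (!is.null(report_df)) {
    rownames(report_df) <- NULL
    utils::write.csv(report_df, file.path(out_dir, "cleaning_report.csv"),
                     row.names = FALSE)
  }

  # stage: ISC + significance per movie x modality
  sig_rows <- list()
  for (m in movies(cohort)) {
    for (mod in modalities) {
      keys <- names(cohort@recordings)
      if (!any(endsWith(keys, paste0("|", m, "|", mod)))) next
      mat <- epochSeriesMatrix(cohort, m, mod)
      if (ncol(mat) < 2L) next
      sp <- shuffleParams(n_shuffles, alpha,
                          seed = mixSeed(seed, "significance", m, mod))
      res <- cohortSignificance(mat, ip, sp,
                                epoch_id = paste(m, mod, sep = "/"))
      utils::write.csv(iscValues(attr(res, "isc")),
                       file.path(out_dir, sprintf("isc_%s_%s.csv", m, mod)))
      res$movie_id <- m
      res$modality <- mod
      attr(res, "isc") <- NULL
      attr(res, "null") <- NULL
      sig_rows[[paste(m, mod)]] <- res
    }
  }
  sig <- do.call(rbind, sig_rows)
  rownames(sig) <- NULL
  utils::write.csv(sig, file.path(out_dir, "significance.csv"),
                   row.names = FALSE)

  # stage: robustness (optional, off by default)
  rb <- config$robustness
  if (isTRUE(rb$enabled)) {
    orders <- latinSquareOrders()
    if (!is.null(rb$n_orders))
      orders <- orders[seq_len(rb$n_orders), , drop = FALSE]
    orders <- orders[, seq_len(min(ncol(orders), cc@n_movies)), drop = FALSE]
    orders[orders > cc@n_movies] <- NA
    orders <- orders[stats::complete.cases(orders), , drop = FALSE]
    pts <- robustnessSurface(
      cohort, modality = "HR", orders = orders,
      durations_min = if (is.null(rb$durations_min)) durationGrid()
        else rb$durations_min,
      group_sizes = rb$group_sizes, isc_params = ip,
      n_shuffles = n_shuffles, alpha = alpha,
      n_subsets = if (is.null(rb$n_subsets)) 50 else rb$n_subsets,
      seed = mixSeed(seed, "robustness"))
    utils::write.csv(pts, file.path(out_dir, "robustness_points.csv"),
                     row.names = FALSE)
    utils::write.csv(summarizeRobustness(pts),
                     file.path(out_dir, "robustness_summary.csv"),
                     row.names = FALSE)
  }

  manifest <- list(package_version = as.character(utils::packageVersion("physync")),
                   r_version = as.character(getRversion()),
                   seed = seed,
                   config = config,
                   outputs = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
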