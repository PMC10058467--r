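# Shared fixtures and independent oracles, built in code.

# Naive double-loop sliding ISC: the independent reference the fast
# rolling-sum implementation is checked against.
naiveSlidingISC <- function(x, y, window, step = 1, min_valid_fraction = 0.8,
                            min_windows = 10) {
  L <- length(x)
  rs <- c()
  for (s in seq(1, L - window + 1, by = step)) {
    xs <- x[s:(s + window - 1)]
    ys <- y[s:(s + window - 1)]
    ok <- is.finite(xs) & is.finite(ys)
    r <- NA_real_
    if (sum(ok) >= max(3, ceiling(min_valid_fraction * window)) &&
        stats::sd(xs[ok]) > 0 && stats::sd(ys[ok]) > 0) {
      r <- stats::cor(xs[ok], ys[ok])
    }
    rs <- c(rs, r)
  }
  ok <- is.finite(rs)
  if (sum(ok) < min_windows) NA_real_ else mean(rs[ok])
}

# small coupled/null configs reused across tests
tinyCoupledConfig <- function(n = 6, n_movies = 1, duration = 120, seed = 1,
                              ...) {
  cohortConfig(n_participants = n, n_movies = n_movies,
               movie_duration_s = duration, seed = seed, ...)
}

tinyNullConfig <- function(n = 6, n_movies = 1, duration = 120, seed = 1,
                           ...) {
  cohortConfig(n_participants = n, n_movies = n_movies,
               movie_duration_s = duration, coupling_gains = 0,
               seed = seed, ...)
}

# HR series matrix of movie 1 for a config
hrMatrix <- function(config) {
  gen <- generateCohort(config, modalities = "HR")
  epochSeriesMatrix(gen$cohort, "M1", "HR")
}

flatRecording <- function(values, modality = "HR", rate = 1, id = "P01",
                          mask = rep(TRUE, length(values)))
  physioRecording(id, modality, rate, values, quality_mask = mask)
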