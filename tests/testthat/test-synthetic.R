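# Synthetic cohort generator: event trains, SCR kernel, EDA/HR models,
# artifact injection, cohort assembly.

test_that("event trains are valid Poisson realizations", {
  expect_identical(generateEventTrain(0, 600, seed = 1), numeric(0))
  expect_error(generateEventTrain(-1, 600, seed = 1), "rate")
  expect_error(generateEventTrain(6, 0, seed = 1), "duration")

  # contract: sorted, strictly inside [0, duration)
  for (s in 1:20) {
    ev <- generateEventTrain(6, 600, seed = s)
    expect_true(all(ev >= 0 & ev < 600))
    expect_identical(ev, sort(ev))
  }
  # Poisson mean: rate * duration = 60; 500 seeds, within 3 standard errors
  counts <- vapply(1:500, function(s)
    length(generateEventTrain(6, 600, seed = 1000 + s)), numeric(1))
  se <- sqrt(60 / 500)  # var of Poisson(60) mean over 500 draws
  expect_lt(abs(mean(counts) - 60), 3 * se)
  # determinism
  expect_identical(generateEventTrain(6, 600, seed = 5),
                   generateEventTrain(6, 600, seed = 5))
})

test_that("SCR kernel has Bateman shape with analytic peak", {
  k <- scrKernel(0.75, 2, sampling_rate_hz = 32)
  expect_equal(k[1], 0)
  expect_equal(max(k), 1)
  expect_true(all(k >= 0))
  t_star <- log(2 / 0.75) / (1 / 0.75 - 1 / 2)
  expect_lt(abs((which.max(k) - 1) / 32 - t_star), 1 / 32)
  expect_error(scrKernel(2, 0.75), "tau_rise")
  expect_error(scrKernel(2, 2), "tau_rise")
})

test_that("phasic EDA follows the linear shared-drive model", {
  base <- list(n_participants = 2, n_movies = 1, movie_duration_s = 60)

  # gain 0, no idio/noise/onset -> all-zero signal
  cc0 <- cohortConfig(n_participants = 2, n_movies = 1, movie_duration_s = 60,
                      coupling_gains = 0, idio_event_rate_per_min = 0,
                      noise_sd = 0, onset_amplitude = 0, seed = 1)
  ev <- generateEventTrain(6, 60, seed = 9)
  r0 <- generateEdaPhasic(ev, cc0, 1, 1)
  expect_true(all(sampleValues(r0) == 0))

  # linearity: gains 1 and 2, same shared events, no noise/idio/onset
  cc <- cohortConfig(n_participants = 2, n_movies = 1, movie_duration_s = 60,
                     coupling_gains = c(1, 2), idio_event_rate_per_min = 0,
                     noise_sd = 0, onset_amplitude = 0, seed = 1)
  r1 <- generateEdaPhasic(ev, cc, 1, 1)
  r2 <- generateEdaPhasic(ev, cc, 2, 1)
  expect_equal(sampleValues(r2), 2 * sampleValues(r1), tolerance = 1e-12)

  # onset transient dominates the start of the noise-free signal
  cc_on <- cohortConfig(n_participants = 1, n_movies = 1,
                        movie_duration_s = 60, coupling_gains = 1,
                        idio_event_rate_per_min = 0, noise_sd = 0,
                        onset_amplitude = 5, seed = 1)
  ron <- generateEdaPhasic(ev, cc_on, 1, 1)
  t_star <- log(2 / 0.75) / (1 / 0.75 - 1 / 2)
  peak_t <- (which.max(sampleValues(ron)) - 1) / samplingRate(ron)
  # an early shared event can delay the combined peak by at most ~t_star
  expect_lte(peak_t, 2 * t_star + 1 / 32)
  # with no shared coupling the onset peak is exactly the kernel peak
  cc_pure <- cohortConfig(n_participants = 1, n_movies = 1,
                          movie_duration_s = 60, coupling_gains = 0,
                          idio_event_rate_per_min = 0, noise_sd = 0,
                          onset_amplitude = 5, seed = 1)
  rp <- generateEdaPhasic(ev, cc_pure, 1, 1)
  expect_lt(abs((which.max(sampleValues(rp)) - 1) / 32 - t_star), 1 / 32)

  expect_error(generateEdaPhasic(ev, cc, 3, 1), "participant_index")
})

test_that("HR is integer bpm driven by the shared low-pass drive", {
  ev <- generateEventTrain(6, 120, seed = 4)
  cc <- cohortConfig(n_participants = 3, n_movies = 1, movie_duration_s = 120,
                     coupling_gains = c(0, 1, 1), hr_noise_sd_bpm = 0,
                     hr_baselines_bpm = c(60, 70, 70), seed = 1)
  h1 <- generateHr(ev, cc, 1, 1)
  h2 <- generateHr(ev, cc, 2, 1)
  h3 <- generateHr(ev, cc, 3, 1)
  # gain 0, noise 0 -> constant rounded baseline
  expect_true(all(sampleValues(h1) == 60))
  # integer resolution always
  cc_n <- cohortConfig(n_participants = 1, n_movies = 1,
                       movie_duration_s = 120, seed = 2)
  hn <- generateHr(ev, cc_n, 1, 1)
  expect_true(all(sampleValues(hn) == round(sampleValues(hn))))
  # equal gains + baselines, no noise -> identical series (shared drive)
  expect_identical(sampleValues(h2), sampleValues(h3))
  expect_equal(samplingRate(h2), 1)
})

test_that("artifact injection writes values but never touches the mask", {
  hr <- flatRecording(rep(c(60, 62, 64), length.out = 500))
  expect_identical(injectArtifacts(hr, list()), hr)

  out <- injectArtifacts(hr, list(
    list(type = "hr_stuck", start_s = 100, end_s = 400)))
  v <- sampleValues(out)
  expect_true(all(v[101:400] == sampleValues(hr)[101]))
  expect_identical(qualityMask(out), qualityMask(hr))
  expect_length(out@provenance$artifacts, 1)

  out2 <- injectArtifacts(hr, list(
    list(type = "hr_out_of_range", start_s = 10, end_s = 11, value = 250)))
  expect_equal(sampleValues(out2)[11], 250)
  expect_equal(sampleValues(out2)[-11], sampleValues(hr)[-11])

  expect_error(injectArtifacts(hr, list(
    list(type = "hr_stuck", start_s = 400, end_s = 600))), "extent")
  expect_error(injectArtifacts(hr, list(
    list(type = "nope", start_s = 0, end_s = 10))), "unknown artifact")
})

test_that("cohort generation is deterministic with correct cardinality", {
  cc <- tinyCoupledConfig(n = 5, n_movies = 3, duration = 60, seed = 11)
  g1 <- generateCohort(cc)
  g2 <- generateCohort(cc)
  expect_identical(g1, g2)
  expect_length(g1$cohort@recordings, 5 * 3 * 2)  # HR + EDA_PHASIC
  expect_identical(movies(g1$cohort), c("M1", "M2", "M3"))
  expect_length(participants(g1$cohort), 5)
  qs <- quizScores(g1$truth)
  expect_true(all(qs$quiz_score >= 0 & qs$quiz_score <= 10))
  expect_equal(nrow(qs), 15)
})

test_that("quiz scores increase with coupling gain", {
  cc <- cohortConfig(n_participants = 20, n_movies = 6, movie_duration_s = 10,
                     coupling_gains = seq(0.2, 2, length.out = 20),
                     seed = 21)
  truth <- generateCohort(cc, modalities = "HR")$truth
  qs <- quizScores(truth)
  mean_q <- tapply(qs$quiz_score, qs$participant_id, mean)
  rho <- cor(couplingGains(truth)[names(mean_q)], mean_q,
             method = "spearman")
  expect_gt(rho, 0)
})

test_that("uncoupled participants are statistically independent", {
  # mean dyadic ISC over 100 null cohorts within 3 standard errors of 0
  means <- vapply(1:100, function(s) {
    v <- iscValues(iscMatrix(hrMatrix(tinyNullConfig(n = 4, duration = 120,
                                                     seed = 3000 + s))))
    mean(v[row(v) != col(v)], na.rm = TRUE)
  }, numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 3 * se)
})

test_that("strong identical coupling with vanishing noise drives ISC to 1", {
  isc_at_noise <- function(nsd) {
    cc <- cohortConfig(n_participants = 4, n_movies = 1,
                       movie_duration_s = 300, coupling_gains = 3,
                       hr_noise_sd_bpm = nsd, seed = 5)
    v <- iscValues(iscMatrix(hrMatrix(cc),
                             iscParams(min_valid_fraction = 0.8)))
    mean(v[row(v) != col(v)], na.rm = TRUE)
  }
  # integer HR quantization puts a ceiling below 1; drop quantization by
  # checking the trend: ISC rises steeply as noise shrinks
  expect_gt(isc_at_noise(0.3), isc_at_noise(2))
  expect_gt(isc_at_noise(0.1), 0.9)
})
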