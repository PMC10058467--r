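# Cleaning and epoching rules: Savitzky-Golay smoothing, signal-loss
# marking, phasic extraction, HR range/jump/stuck rules, exclusion, epoching.

test_that("Savitzky-Golay smoothing reproduces low-order polynomials", {
  rate <- 32
  const <- flatRecording(rep(1.5, 320), "EDA_RAW", rate)
  expect_equal(sampleValues(smoothEda(const)), rep(1.5, 320),
               tolerance = 1e-10)

  ramp <- flatRecording(seq(0, 2, length.out = 320), "EDA_RAW", rate)
  expect_equal(sampleValues(smoothEda(ramp)), seq(0, 2, length.out = 320),
               tolerance = 1e-8)

  # sinusoid + one-sample spike: smoothing pulls the spike toward the curve
  t <- seq(0, 10, by = 1 / rate)
  clean <- 2 + sin(2 * pi * 0.05 * t)
  spiked <- clean
  i_spike <- 160
  spiked[i_spike] <- spiked[i_spike] + 1
  sm <- sampleValues(smoothEda(flatRecording(spiked, "EDA_RAW", rate)))
  expect_lt(abs(sm[i_spike] - clean[i_spike]), abs(spiked[i_spike] - clean[i_spike]))

  expect_error(smoothEda(flatRecording(rep(1, 10), "EDA_RAW", rate)),
               "shorter")
  expect_error(smoothEda(flatRecording(rep(60, 320), "HR", 1)), "EDA")
})

test_that("signal-loss marking flags only long low-conductance runs", {
  rate <- 32
  good <- flatRecording(rep(2, 30 * rate), "EDA_RAW", rate)
  expect_true(all(markEdaSignalLoss(good)))

  # 10 s of zeros inside good signal -> exactly that run masked
  v <- rep(2, 30 * rate)
  drop_idx <- (10 * rate + 1):(20 * rate)
  v[drop_idx] <- 0
  mask <- markEdaSignalLoss(flatRecording(v, "EDA_RAW", rate))
  expect_true(all(!mask[drop_idx]))
  expect_true(all(mask[-drop_idx]))

  # 2 s run of zeros is below the minimum duration -> untouched
  v2 <- rep(2, 30 * rate)
  v2[(10 * rate + 1):(12 * rate)] <- 0
  expect_true(all(markEdaSignalLoss(flatRecording(v2, "EDA_RAW", rate))))
})

test_that("phasic extraction removes tonic level and keeps fast bumps", {
  rate <- 32
  const <- flatRecording(rep(3, 60 * rate), "EDA_RAW", rate)
  expect_true(all(sampleValues(extractPhasic(const)) == 0))

  # constant + single SCR bump: peak recovered within 10%
  k <- scrKernel(0.75, 2, rate)
  v <- rep(2, 60 * rate)
  at <- 30 * rate
  amp <- 0.8
  v[at + seq_along(k)] <- v[at + seq_along(k)] + amp * k
  ph <- sampleValues(extractPhasic(flatRecording(v, "EDA_RAW", rate)))
  expect_lt(abs(max(ph) - amp) / amp, 0.10)

  # slow drift (period >> tonic window), no events: phasic < 5% of amplitude
  t <- seq(0, 600 - 1 / rate, by = 1 / rate)
  drift <- 2 + 1 * sin(2 * pi * t / 1000)
  phd <- sampleValues(extractPhasic(flatRecording(drift, "EDA_RAW", rate)))
  expect_lt(max(phd), 0.05 * 1)

  expect_error(extractPhasic(flatRecording(rep(2, 32), "EDA_RAW", rate)),
               "shorter")
  expect_error(extractPhasic(flatRecording(rep(60, 600), "HR", 1)),
               "EDA_RAW")
})

test_that("HR range and jump rules mask exactly the implausible samples", {
  r1 <- cleanHr(flatRecording(c(60, 61, 62, 250, 61)))
  expect_identical(which(!qualityMask(r1$recording)), 4L)
  expect_equal(r1$report$n_range, 1)
  expect_equal(r1$report$n_jump, 0)

  # 60 -> 80 is a 33% jump
  r2 <- cleanHr(flatRecording(c(60, 80, 62, 63)))
  expect_identical(which(!qualityMask(r2$recording)), 2L)
  expect_equal(r2$report$n_jump, 1)

  r3 <- cleanHr(flatRecording(c(60, 61, 60, 62)))
  expect_true(all(qualityMask(r3$recording)))
  expect_equal(r3$report$n_removed, 0)

  # jump reference is the most recent usable sample, so one out-of-range
  # sample does not cascade: 250 is range-masked, 61 is compared to 62
  r4 <- cleanHr(flatRecording(c(60, 61, 62, 250, 61, 60)))
  expect_identical(which(!qualityMask(r4$recording)), 4L)

  # report fraction matches the mask exactly
  expect_equal(r4$report$fraction_removed,
               mean(!qualityMask(r4$recording)))
  expect_error(cleanHr(flatRecording(numeric(0))), "empty")
})

test_that("stuck-sensor detection uses the repeat/change ratio", {
  all_same <- detectStuckHr(flatRecording(rep(70, 50)))
  expect_true(all_same$flagged)
  expect_identical(all_same$stuck_ratio, Inf)

  alt <- detectStuckHr(flatRecording(rep(c(60, 61), 25)))
  expect_false(alt$flagged)
  expect_equal(alt$stuck_ratio, 0)

  # 102 samples: 100 repeat transitions, 1 change -> ratio 100 > 50
  v <- c(rep(70, 51), rep(71, 51))
  st <- detectStuckHr(flatRecording(v))
  expect_equal(st$stuck_ratio, 100)
  expect_true(st$flagged)

  expect_error(detectStuckHr(flatRecording(70)), "2 samples")
})

test_that("exclusion threshold is strict (more than 30%)", {
  mk <- function(frac) {
    n <- 100
    mask <- rep(TRUE, n)
    if (frac > 0) mask[seq_len(round(frac * n))] <- FALSE
    flatRecording(rep(60, n), mask = mask)
  }
  expect_false(applyExclusion(NULL, mk(0.29)))
  expect_false(applyExclusion(NULL, mk(0.30)))  # exactly 30%: retained
  expect_true(applyExclusion(NULL, mk(0.31)))
  # stuck flag forces exclusion regardless of the fraction
  expect_true(applyExclusion(NULL, mk(0), stuck_flagged = TRUE))
  # report-based route
  expect_true(applyExclusion(list(fraction_removed = 0.5), mk(0)))
})

test_that("epoching cuts half-open windows time-locked to onsets", {
  rec <- flatRecording(101:200, "HR", 1)  # value 101 + t, sample i at t = i-1

  full <- epochTimelock(rec, data.frame(movie_id = "M1", onset_s = 0,
                                        duration_s = 100))
  expect_equal(sampleValues(full$M1), 101:200)

  # onset 10, duration 5 at 1 Hz -> original times 10..14
  seg <- epochTimelock(rec, data.frame(movie_id = "M1", onset_s = 10,
                                       duration_s = 5))
  expect_equal(sampleValues(seg$M1), 101 + (10:14))
  expect_equal(seg$M1@t0_s, 0)

  # six 600 s movies on a 3700 s recording -> six 600-sample segments
  long <- flatRecording(seq_len(3700), "HR", 1)
  cat6 <- data.frame(movie_id = paste0("M", 1:6),
                     onset_s = 50 + (0:5) * 600, duration_s = 600)
  segs <- epochTimelock(long, cat6)
  expect_length(segs, 6)
  expect_true(all(vapply(segs, function(s) length(sampleValues(s)),
                         numeric(1)) == 600))

  expect_error(
    epochTimelock(rec, data.frame(movie_id = "M9", onset_s = 50,
                                  duration_s = 100)),
    "M9")
})

test_that("preprocessing recovers injected artifacts without false alarms", {
  # EDA: inject signal loss, detect with the loss rule
  cc <- tinyCoupledConfig(n = 3, duration = 300, seed = 8)
  gen <- generateCohort(cc, modalities = "EDA_PHASIC")
  rec <- getRecording(gen$cohort, "P01", "M1", "EDA_PHASIC")
  rec@values <- rec@values + 0.5  # keep clean signal off the floor
  segs <- list(list(type = "eda_signal_loss", start_s = 60, end_s = 90),
               list(type = "eda_signal_loss", start_s = 200, end_s = 230))
  bad <- injectArtifacts(rec, segs)
  mask <- markEdaSignalLoss(bad)
  injected <- rep(FALSE, length(mask))
  fs <- samplingRate(rec)
  for (s in segs) injected[(s$start_s * fs + 1):(s$end_s * fs)] <- TRUE
  sens <- sum(!mask & injected) / sum(injected)
  false_rate <- sum(!mask & !injected) / sum(!injected)
  expect_gte(sens, 0.95)
  expect_lt(false_rate, 0.01)

  # HR: out-of-range and stuck artifacts
  hr <- getRecording(generateCohort(tinyCoupledConfig(n = 2, duration = 300,
                                                      seed = 9),
                                    modalities = "HR")$cohort,
                     "P01", "M1", "HR")
  bad_hr <- injectArtifacts(hr, list(
    list(type = "hr_out_of_range", start_s = 50, end_s = 55, value = 250),
    list(type = "hr_out_of_range", start_s = 150, end_s = 152, value = 20)))
  cl <- cleanHr(bad_hr)
  inj <- rep(FALSE, 300)
  inj[c(51:55, 151:152)] <- TRUE
  expect_gte(sum(!qualityMask(cl$recording) & inj) / sum(inj), 0.95)
  expect_lt(sum(!qualityMask(cl$recording) & !inj) / sum(!inj), 0.01)

  stuck <- injectArtifacts(hr, list(
    list(type = "hr_stuck", start_s = 0, end_s = 298)))
  expect_true(detectStuckHr(stuck)$flagged)
})
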