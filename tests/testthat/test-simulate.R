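test_that("stimulus trains respect the ISI range and duration", {
  set.seed(7)
  st <- generateStimulusTrain(c(2, 15), 1800)
  gaps <- diff(c(0, st))
  expect_true(all(gaps >= 2 & gaps <= 15))
  expect_true(all(st < 1800))
  expect_error(generateStimulusTrain(c(5, 2), 100), "interval range")
  expect_error(generateStimulusTrain(c(-1, 5), 100), "interval range")
})

test_that("a degenerate constant ISI gives the arithmetic train", {
  set.seed(1)
  expect_equal(generateStimulusTrain(c(5, 5), 20), c(5, 10, 15))
})

test_that("mean stimulus count matches the renewal-process rate", {
  # Monte-Carlo oracle: E[count] ~ duration / mean(ISI) = 1800 / 8.5
  set.seed(123)
  counts <- replicate(300, length(generateStimulusTrain(c(2, 15), 1800)))
  expect_equal(mean(counts), 1800 / 8.5, tolerance = 0.02)
})

test_that("recordings have the configured geometry and sample count", {
  cfg <- smallConfig()
  rec <- simulateSubject(cfg, 1)
  expect_equal(ncol(rec@o2hb), (120 + 1200) * 10)
  expect_equal(nrow(rec@o2hb), 7)
  expect_equal(dim(rec@hhb), dim(rec@o2hb))
  # full-length protocol: 19200 samples
  cfg30 <- simConfig(nSubjects = 2, seed = 1)
  expect_equal(round((cfg30@baselineDuration + cfg30@taskDuration) *
                       cfg30@fs), 19200)
  ev <- rec@events
  expect_equal(sum(ev$label == "stimulus"), nrow(rec@trials))
  expect_false(is.unsorted(ev$time_s))
})

test_that("the null generator leaves early and late thirds identical", {
  cfg <- simConfig(nSubjects = 2, taskDuration = 1200, seed = 9,
                   noiseSd = 0, artifactRate = 0, attentionEffect = 0,
                   hrfPeakAmplitudeO2hb = 0, cardiacAmp = 0, respAmp = 0,
                   driftSd = 0)
  rec <- simulateSubject(cfg, 1)
  n <- ncol(rec@o2hb)
  third <- floor(n / 3)
  early <- rowMeans(rec@o2hb[, 1:third])
  late <- rowMeans(rec@o2hb[, (n - third + 1):n])
  expect_equal(early, late, tolerance = 1e-12)
})

test_that("the programmed parietal shift appears where injected", {
  # Monte-Carlo: late-minus-early third O2Hb difference ~ effect on
  # parietal channels, ~0 on PFC channels. Full 30-min task so the
  # ramp saturates within the final third.
  diffs <- sapply(1:4, function(s) {
    cfg <- simConfig(nSubjects = 2, seed = s, artifactRate = 0,
                     attentionEffect = c(lPFC = 0, mPFC = 0, rPFC = 0,
                                         rParietal = 0.5))
    rec <- simulateSubject(cfg, 1)
    n <- ncol(rec@o2hb)
    i0 <- 120 * 10
    thirds <- floor((n - i0) / 3)
    late <- rowMeans(rec@o2hb[, (n - thirds + 1):n])
    early <- rowMeans(rec@o2hb[, (i0 + 1):(i0 + thirds)])
    late - early
  })
  parietal <- mean(diffs[4:7, ])
  pfc <- mean(diffs[1:3, ])
  expect_equal(parietal, 0.5, tolerance = 0.15)
  expect_lt(abs(pfc), 0.1)
})

test_that("effect recovery is monotone in the programmed effect size", {
  recover <- function(effect) {
    mean(sapply(1:3, function(s) {
      cfg <- simConfig(nSubjects = 2, seed = s, artifactRate = 0,
                       attentionEffect = c(lPFC = 0, mPFC = 0, rPFC = 0,
                                           rParietal = effect))
      rec <- simulateSubject(cfg, 1)
      n <- ncol(rec@o2hb)
      i0 <- 120 * 10
      thirds <- floor((n - i0) / 3)
      mean(rowMeans(rec@o2hb[4:7, (n - thirds + 1):n]) -
             rowMeans(rec@o2hb[4:7, (i0 + 1):(i0 + thirds)]))
    }))
  }
  d <- vapply(c(0, 0.25, 0.5, 1), recover, numeric(1))
  expect_true(all(diff(d) > 0))
})

test_that("cohorts are deterministic and extensible in the seed", {
  cfg <- quietConfig(seed = 31)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(recordings(c1)[[2]]@o2hb, recordings(c2)[[2]]@o2hb)
  expect_identical(recordings(c1)[[1]]@trials, recordings(c2)[[1]]@trials)
  expect_equal(length(c1), 3)
  expect_equal(anyDuplicated(subjectIds(c1)), 0)
  # adding a subject must not reshuffle existing ones
  cfg4 <- quietConfig(seed = 31); cfg4@nSubjects <- 4L
  c4 <- simulateCohort(cfg4)
  expect_identical(recordings(c4)[[3]]@o2hb, recordings(c1)[[3]]@o2hb)
  expect_error(simConfig(nSubjects = 1), ">= 2")
})

test_that("artifact truth masks match the injected excursions", {
  cfg <- smallConfig(seed = 4, artifactRate = 1)
  rec <- simulateSubject(cfg, 1)
  art <- rec@truth$artifacts
  expect_gt(nrow(art), 0)
  expect_true(all(art$kind %in% c("spike", "shift")))
  # the contaminated series differs from the clean series inside spikes
  sp <- art[art$kind == "spike", ][1, ]
  idx <- (floor(sp$start_s * 10) + 1):ceiling(sp$end_s * 10)
  ch <- sp$channel_id
  expect_gt(max(abs(rec@o2hb[ch, idx] - rec@truth$clean_o2hb[ch, idx])), 0)
})

test_that("reaction times follow the programmed late-task slowing", {
  # sign of the within-subject slowing component recovered in nearly
  # all seeds (between-subject slowing variability switched off here;
  # the cohort-level test covers the full model)
  signs <- vapply(1:20, function(s) {
    cfg <- simConfig(nSubjects = 2, taskDuration = 1200, seed = s,
                     rtSlowingSdBetween = 0)
    rec <- simulateSubject(cfg, 1)
    bm <- blockMeans(validateTrials(rec@trials), 120, 1320)
    sign(bm[["late"]] - bm[["early"]])
  }, numeric(1))
  expect_gte(mean(signs > 0), 0.95)
  # RTs are nonnegative under both distributions
  cfg <- smallConfig(rtDistribution = "truncnormal", rtMeanEarly = 30,
                     rtSd = 100)
  rec <- simulateSubject(cfg, 1)
  rt <- (rec@trials$response_onset_time_s - rec@trials$stimulus_time_s)
  expect_true(all(rt[!is.na(rt)] >= 0))
})
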