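#' Draw a psychomotor-vigilance stimulus train
#'
#' Successive inter-stimulus intervals are i.i.d. uniform on
#' \code{isiRange}; stimuli accumulate from time 0 (task start) and the
#' train stops before \code{taskDuration}. Uses the current RNG state,
#' so wrap in \code{set.seed()} for reproducibility.
#'
#' @param isiRange two-element range (s), \code{0 <= low <= high},
#'   \code{high > 0}. Equal bounds give a constant ISI.
#' @param taskDuration task length in seconds.
#' @return numeric vector of stimulus times (s, relative to task
#'   start), all strictly less than \code{taskDuration}.
#' @export
#' @examples
#' set.seed(1)
#' head(generateStimulusTrain(c(2, 15), 1800))
generateStimulusTrain <- function(isiRange, taskDuration) {
  if (length(isiRange) != 2L || !all(is.finite(isiRange)) ||
      isiRange[1] < 0 || isiRange[1] > isiRange[2] || isiRange[2] <= 0)
    stop("invalid inter-stimulus interval range: need 0 <= low <= high, high > 0")
  if (!is.finite(taskDuration) || taskDuration <= 0)
    stop("taskDuration must be positive")
  times <- numeric(0)
  t <- 0
  repeat {
    gaps <- stats::runif(256L, isiRange[1], isiRange[2])
    tt <- t + cumsum(gaps)
    times <- c(times, tt[tt < taskDuration])
    t <- tt[length(tt)]
    if (t >= taskDuration) break
  }
  times
}

#' Canonical double-gamma hemodynamic response kernel
#'
#' Positive lobe peaking near 5 s with a late undershoot near 15 s
#' (gamma shape/rate 6/1 minus 1/6 of shape/rate 16/1), sampled at
#' \code{fs} over \code{lengthS} seconds and scaled to unit peak.
#'
#' @param fs sampling rate, Hz.
#' @param lengthS kernel support, s.
#' @return numeric kernel with \code{max(kernel) == 1}.
#' @export
hrfDoubleGamma <- function(fs, lengthS = 32) {
  t <- seq(0, lengthS, by = 1 / fs)
  h <- stats::dgamma(t, shape = 6, rate = 1) -
    stats::dgamma(t, shape = 16, rate = 1) / 6
  h / max(h)
}

# Target mean RT (ms) as a function of time within the task: flat at
# rtMeanEarly over the first third, flat at rtMeanLate over the last
# third, linear in between.
rtTargetMean <- function(tTask, taskDuration, rtMeanEarly, rtMeanLate) {
  third <- taskDuration / 3
  frac <- pmin(pmax((tTask - third) / third, 0), 1)
  rtMeanEarly + frac * (rtMeanLate - rtMeanEarly)
}

# Draw one RT (ms) per stimulus given per-trial target means. Lognormal
# moment matching: sdlog^2 = log(1 + (s/m)^2), meanlog = log(m) - sdlog^2/2.
drawReactionTimes <- function(means, sd, distribution) {
  n <- length(means)
  if (distribution == "lognormal") {
    s2 <- log(1 + (sd / means)^2)
    stats::rlnorm(n, meanlog = log(means) - s2 / 2, sdlog = sqrt(s2))
  } else {
    pmax(stats::rnorm(n, means, sd), 0)
  }
}

# Stimulus-locked trial table for one subject. The subject's own mean
# slowing is drawn around the configured population slowing with SD
# rtSlowingSdBetween (individual differences in vigilance decrement).
# Lapse trials (programmed fraction) are half omissions (no response)
# and half slow responses beyond the 600 ms validity bound.
simulateTrials <- function(stimTimesTask, config) {
  slowing <- stats::rnorm(1, config@rtMeanLate - config@rtMeanEarly,
                          config@rtSlowingSdBetween)
  lateMean <- max(config@rtMeanEarly + slowing, 0.5 * config@rtMeanEarly)
  m <- rtTargetMean(stimTimesTask, config@taskDuration,
                    config@rtMeanEarly, lateMean)
  rt <- drawReactionTimes(m, config@rtSd, config@rtDistribution)
  lapse <- stats::runif(length(rt)) < config@rtLapseRate
  omit <- lapse & (stats::runif(length(rt)) < 0.5)
  slow <- lapse & !omit
  rt[slow] <- stats::runif(sum(slow), 620, 1000)
  rt[omit] <- NA_real_
  rt
}

#' Simulate one subject's recording
#'
#' Each channel's O2Hb series is the sum of a stimulus-locked
#' double-gamma response train, a region-specific attention shift that
#' ramps linearly from task minute 10 to minute 20 and then holds (so
#' the first and last task thirds differ by the configured amount),
#' cardiac and respiratory sinusoids (random phase per channel), a slow
#' random-walk drift, white noise, and injected spike/shift movement
#' artifacts. The HHb series scales the functional components by
#' \code{hhbToO2hbRatio} and carries its own (smaller) oscillations,
#' drift and noise; artifacts are common-mode across chromophores.
#' Reaction times follow the configured distribution with the late-task
#' slowing. The ground truth (artifact segments, artifact-free series,
#' programmed effects) is kept in \code{truth}.
#'
#' @param config a [SimConfig-class].
#' @param subjectIndex 1-based index into the cohort; fixes the
#'   derived per-subject seed.
#' @param subjectId identifier (default \code{"S<index>"}).
#' @return a [SubjectRecording-class].
#' @export
simulateSubject <- function(config, subjectIndex,
                            subjectId = sprintf("S%02d", subjectIndex)) {
  validObject(config)
  set.seed(subjectSeed(config@seed, subjectIndex))
  layout <- defaultChannelLayout()
  fs <- config@fs
  n <- round((config@baselineDuration + config@taskDuration) * fs)
  tAbs <- (seq_len(n) - 1) / fs
  taskStart <- config@baselineDuration
  taskEnd <- taskStart + config@taskDuration

  age <- round(stats::runif(1, config@ageRange[1], config@ageRange[2]), 1)

  stimTask <- generateStimulusTrain(config@isiRange, config@taskDuration)
  stimAbs <- taskStart + stimTask

  # per-channel neural impulse trains convolved with the HRF kernel;
  # trial amplitudes carry lognormal trial-to-trial variability drawn
  # independently per channel, so channels share stimulus timing but
  # not the exact evoked fluctuation
  kernel <- hrfDoubleGamma(fs)
  idx <- pmin(round(stimAbs * fs) + 1L, n)
  cv <- config@hrfTrialCv
  s2 <- log(1 + cv^2)
  channelResponse <- function() {
    imp <- numeric(n)
    amp <- if (cv > 0)
      stats::rlnorm(length(idx), -s2 / 2, sqrt(s2)) else rep(1, length(idx))
    imp[idx] <- imp[idx] + amp
    stats::convolve(imp, rev(kernel), type = "open")[seq_len(n)] *
      config@hrfPeakAmplitudeO2hb
  }

  # attention-shift time course: 0 -> 1 ramp over task minutes 10-20
  ramp <- pmin(pmax((tAbs - (taskStart + 600)) / 600, 0), 1)

  effHhb <- if (all(is.na(config@attentionEffectHhb)))
    config@hhbToO2hbRatio * config@attentionEffect
  else config@attentionEffectHhb

  nch <- nChannels(layout)
  chIds <- layout@channels$channel_id
  o2hb <- hhb <- cleanO <- cleanH <- matrix(0, nch, n,
                                            dimnames = list(chIds, NULL))
  artifacts <- list()
  minutes <- (config@baselineDuration + config@taskDuration) / 60

  for (c_i in seq_len(nch)) {
    region <- layout@channels$region[c_i]
    gain <- stats::runif(1, 0.8, 1.2)
    resp <- channelResponse()
    oClean <- gain * resp + config@attentionEffect[[region]] * ramp +
      config@cardiacAmp * sin(2 * pi * config@cardiacFreq * tAbs +
                              stats::runif(1, 0, 2 * pi)) +
      config@respAmp * sin(2 * pi * config@respFreq * tAbs +
                           stats::runif(1, 0, 2 * pi)) +
      slowDrift(n, config@driftSd) +
      stats::rnorm(n, 0, config@noiseSd)
    hClean <- config@hhbToO2hbRatio * gain * resp +
      effHhb[[region]] * ramp +
      0.3 * config@cardiacAmp * sin(2 * pi * config@cardiacFreq * tAbs +
                                    stats::runif(1, 0, 2 * pi)) +
      0.5 * config@respAmp * sin(2 * pi * config@respFreq * tAbs +
                                 stats::runif(1, 0, 2 * pi)) +
      slowDrift(n, 0.5 * config@driftSd) +
      stats::rnorm(n, 0, 0.5 * config@noiseSd)

    art <- injectArtifacts(n, fs, config@artifactRate * minutes,
                           config@artifactKinds, config@noiseSd)
    cleanO[c_i, ] <- oClean
    cleanH[c_i, ] <- hClean
    o2hb[c_i, ] <- oClean + art$signal
    hhb[c_i, ] <- hClean + art$signal
    if (nrow(art$segments))
      artifacts[[length(artifacts) + 1L]] <-
        cbind(channel_id = chIds[c_i], art$segments)
  }

  artifacts <- if (length(artifacts)) do.call(rbind, artifacts)
  else data.frame(channel_id = character(), start_s = numeric(),
                  end_s = numeric(), kind = character())

  rt <- simulateTrials(stimTask, config)
  trials <- data.frame(stimulus_time_s = stimAbs,
                       response_onset_time_s = stimAbs + rt / 1000)

  events <- rbind(
    data.frame(label = "baseline_start", time_s = 0),
    data.frame(label = "task_start", time_s = taskStart),
    data.frame(label = "stimulus", time_s = stimAbs),
    data.frame(label = "task_end", time_s = taskEnd))
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL

  new("SubjectRecording", subjectId = subjectId, age = age,
      layout = layout, fs = fs, o2hb = o2hb, hhb = hhb,
      events = events, trials = trials,
      truth = list(artifacts = artifacts,
                   effect = list(
                     attention_effect = config@attentionEffect,
                     attention_effect_hhb = effHhb,
                     rt_mean_early = config@rtMeanEarly,
                     rt_mean_late = config@rtMeanLate),
                   clean_o2hb = cleanO, clean_hhb = cleanH),
      preprocessed = FALSE)
}

# Zero-mean slow baseline wander: standardized Gaussian random walk
# rescaled to the requested overall SD.
slowDrift <- function(n, sd) {
  if (sd <= 0) return(numeric(n))
  d <- cumsum(stats::rnorm(n))
  d <- d - mean(d)
  s <- stats::sd(d)
  if (s == 0) numeric(n) else d / s * sd
}

# Spike (1-10 samples, windowed excursion) and shift (persistent
# baseline step) artifacts; amplitudes 5-20x the white-noise SD, or an
# absolute floor when the noise is zeroed. Returns the additive
# artifact signal and the truth segment table.
injectArtifacts <- function(n, fs, expectedCount, kinds, noiseSd) {
  segs <- data.frame(start_s = numeric(), end_s = numeric(),
                     kind = character())
  sig <- numeric(n)
  if (expectedCount <= 0 || !length(kinds))
    return(list(signal = sig, segments = segs))
  k <- stats::rpois(1, expectedCount)
  if (k == 0) return(list(signal = sig, segments = segs))
  scale <- if (noiseSd > 0) noiseSd else 0.05
  for (i in seq_len(k)) {
    pos <- sample.int(n - round(2 * fs), 1)
    kind <- kinds[sample.int(length(kinds), 1)]
    amp <- sample(c(-1, 1), 1) * stats::runif(1, 5, 20) * scale
    if (kind == "spike") {
      len <- sample.int(10L, 1)
      j <- pos:min(pos + len - 1L, n)
      sig[j] <- sig[j] + amp * sin(pi * seq_along(j) / (length(j) + 1))
      segs <- rbind(segs, data.frame(start_s = (pos - 1) / fs,
                                     end_s = (pos - 1 + len) / fs,
                                     kind = "spike"))
    } else {
      sig[pos:n] <- sig[pos:n] + amp
      segs <- rbind(segs, data.frame(start_s = (pos - 1) / fs,
                                     end_s = (pos - 1) / fs + 1,
                                     kind = "shift"))
    }
  }
  list(signal = sig, segments = segs[order(segs$start_s), , drop = FALSE])
}

#' Simulate a multi-subject cohort
#'
#' Generates \code{nSubjects} independent [SubjectRecording-class]
#' objects with per-subject seeds derived deterministically from
#' \code{config@seed}, so the same configuration always reproduces the
#' same cohort bit for bit and extending the cohort does not reshuffle
#' existing subjects.
#'
#' @param config a [SimConfig-class]; \code{nSubjects >= 2}.
#' @return a [VigilanceCohort-class].
#' @export
#' @examples
#' cohort <- simulateCohort(simConfig(nSubjects = 2, taskDuration = 1200,
#'                                    seed = 3))
#' cohort
simulateCohort <- function(config) {
  validObject(config)
  recs <- lapply(seq_len(config@nSubjects),
                 function(i) simulateSubject(config, i))
  new("VigilanceCohort", recordings = recs, config = config)
}

#' @describeIn simulateCohort recordings list of a cohort.
#' @param cohort a [VigilanceCohort-class].
#' @export
recordings <- function(cohort) cohort@recordings

#' @describeIn simulateCohort configuration a cohort was generated with.
#' @export
cohortConfig <- function(cohort) cohort@config

#' @describeIn simulateCohort subject identifiers.
#' @export
subjectIds <- function(cohort)
  vapply(cohort@recordings, function(r) r@subjectId, character(1))

setMethod("length", "VigilanceCohort", function(x) length(x@recordings))

setMethod("show", "VigilanceCohort", function(object) {
  cat("VigilanceCohort of", length(object@recordings), "subjects",
      sprintf("(config %s)\n", configHash(object@config)))
  for (r in object@recordings)
    cat(" ", r@subjectId, ": age", r@age, "-", ncol(r@o2hb), "samples x",
        nrow(r@o2hb), "channels",
        if (r@preprocessed) "[preprocessed]" else "[raw]", "\n")
})

setMethod("show", "SubjectRecording", function(object) {
  cat("SubjectRecording", object@subjectId, "- age", object@age, "\n")
  cat(" ", nrow(object@o2hb), "channels x", ncol(object@o2hb),
      "samples @", object@fs, "Hz;", nrow(object@trials), "trials;",
      if (object@preprocessed) "preprocessed" else "raw", "\n")
})
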