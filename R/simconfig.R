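#' Build a simulation configuration
#'
#' Returns a [SimConfig-class] populated with the study defaults: seven
#' subjects, 10 Hz sampling, a two-minute baseline followed by a
#' thirty-minute psychomotor-vigilance task with 150 ms flashes at
#' uniform 2-15 s inter-stimulus intervals, a canonical double-gamma
#' hemodynamic response to each flash, cardiac (1.1 Hz) and respiratory
#' (0.3 Hz) oscillations, slow baseline wander, white measurement
#' noise, spike/shift movement artifacts, a slowly ramping time-on-task
#' attention effect expressed as an O2Hb mean shift between the first
#' and last task thirds (larger over the right parietal area than the
#' PFC), and reaction times that lengthen late in the task.
#'
#' @param nSubjects cohort size (default 7).
#' @param fs sampling rate, Hz.
#' @param baselineDuration,taskDuration protocol durations, s.
#' @param isiRange uniform inter-stimulus interval range, s.
#' @param stimulusDuration flash duration, s.
#' @param hrfPeakAmplitudeO2hb evoked O2Hb response peak, micromolar.
#' @param hrfTrialCv coefficient of variation of the per-trial,
#'   per-channel evoked-response amplitude.
#' @param hhbToO2hbRatio signed HHb/O2Hb scaling of functional
#'   components (negative).
#' @param attentionEffect named O2Hb shift per region, micromolar.
#' @param attentionEffectHhb HHb shift per region; \code{NA} derives it
#'   from \code{hhbToO2hbRatio}.
#' @param cardiacFreq,cardiacAmp,respFreq,respAmp physiological
#'   oscillation parameters (Hz, micromolar).
#' @param driftSd,noiseSd slow-drift and white-noise SD, micromolar.
#' @param artifactRate movement artifacts per minute per channel.
#' @param artifactKinds which artifact kinds to inject.
#' @param rtMeanEarly,rtMeanLate,rtSd reaction-time model, ms.
#' @param rtSlowingSdBetween between-subject SD (ms) of the late-task
#'   slowing: each subject's own mean slowing is drawn around
#'   \code{rtMeanLate - rtMeanEarly} with this SD, reflecting the wide
#'   individual differences in vigilance decrement.
#' @param rtLapseRate fraction of lapse trials.
#' @param rtDistribution \code{"lognormal"} or \code{"truncnormal"}.
#' @param ageRange subject age range, years.
#' @param seed integer master seed.
#' @return a validated [SimConfig-class].
#' @export
#' @examples
#' cfg <- simConfig(nSubjects = 3, seed = 11)
#' cfg
simConfig <- function(nSubjects = 7L, fs = 10, baselineDuration = 120,
                      taskDuration = 1800, isiRange = c(2, 15),
                      stimulusDuration = 0.15,
                      hrfPeakAmplitudeO2hb = 0.3, hrfTrialCv = 0.3,
                      hhbToO2hbRatio = -0.3,
                      attentionEffect = c(lPFC = 0.2, mPFC = 0.2,
                                          rPFC = 0.2, rParietal = 0.4),
                      attentionEffectHhb = NA_real_,
                      cardiacFreq = 1.1, cardiacAmp = 0.15,
                      respFreq = 0.3, respAmp = 0.1,
                      driftSd = 0.05, noiseSd = 0.15,
                      artifactRate = 0.2,
                      artifactKinds = c("spike", "shift"),
                      rtMeanEarly = 300, rtMeanLate = 340, rtSd = 50,
                      rtSlowingSdBetween = 35, rtLapseRate = 0.05,
                      rtDistribution = c("lognormal", "truncnormal"),
                      ageRange = c(20, 40), seed = 1L) {
  rtDistribution <- match.arg(rtDistribution)
  if (length(attentionEffect) == 1L && is.null(names(attentionEffect)))
    attentionEffect <- stats::setNames(rep(attentionEffect, 4L), VALID_REGIONS)
  attentionEffect <- attentionEffect[VALID_REGIONS]
  names(attentionEffect) <- VALID_REGIONS
  if (!all(is.na(attentionEffectHhb))) {
    if (length(attentionEffectHhb) == 1L && is.null(names(attentionEffectHhb)))
      attentionEffectHhb <- stats::setNames(rep(attentionEffectHhb, 4L),
                                            VALID_REGIONS)
    attentionEffectHhb <- attentionEffectHhb[VALID_REGIONS]
    names(attentionEffectHhb) <- VALID_REGIONS
  }
  new("SimConfig", nSubjects = as.integer(nSubjects), fs = fs,
      baselineDuration = baselineDuration, taskDuration = taskDuration,
      isiRange = as.numeric(isiRange), stimulusDuration = stimulusDuration,
      hrfPeakAmplitudeO2hb = hrfPeakAmplitudeO2hb,
      hrfTrialCv = hrfTrialCv,
      hhbToO2hbRatio = hhbToO2hbRatio,
      attentionEffect = attentionEffect,
      attentionEffectHhb = attentionEffectHhb,
      cardiacFreq = cardiacFreq, cardiacAmp = cardiacAmp,
      respFreq = respFreq, respAmp = respAmp,
      driftSd = driftSd, noiseSd = noiseSd,
      artifactRate = artifactRate, artifactKinds = artifactKinds,
      rtMeanEarly = rtMeanEarly, rtMeanLate = rtMeanLate, rtSd = rtSd,
      rtSlowingSdBetween = rtSlowingSdBetween,
      rtLapseRate = rtLapseRate, rtDistribution = rtDistribution,
      ageRange = as.numeric(ageRange), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSubjects, "subjects @", object@fs, "Hz;",
      object@baselineDuration, "s baseline +", object@taskDuration,
      "s task\n")
  cat("  ISI U(", object@isiRange[1], ",", object@isiRange[2],
      ") s; HRF peak ", object@hrfPeakAmplitudeO2hb, " uM; noise sd ",
      object@noiseSd, " uM; artifacts ", object@artifactRate, "/min\n",
      sep = "")
  cat("  attention effect (uM O2Hb):",
      paste(names(object@attentionEffect), object@attentionEffect,
            sep = "=", collapse = " "), "\n")
  cat("  RT", object@rtMeanEarly, "->", object@rtMeanLate, "ms (sd",
      object@rtSd, "); seed", object@seed, "\n")
})

# Serializable plain-list view of a config (used for YAML round-trips
# and config hashing).
configToList <- function(config) {
  list(
    n_subjects = config@nSubjects, fs = config@fs,
    baseline_duration = config@baselineDuration,
    task_duration = config@taskDuration,
    isi_range = config@isiRange,
    stimulus_duration = config@stimulusDuration,
    hrf_peak_amplitude_o2hb = config@hrfPeakAmplitudeO2hb,
    hrf_trial_cv = config@hrfTrialCv,
    hhb_to_o2hb_ratio = config@hhbToO2hbRatio,
    attention_effect = as.list(config@attentionEffect),
    attention_effect_hhb = if (all(is.na(config@attentionEffectHhb)))
      NULL else as.list(config@attentionEffectHhb),
    cardiac_freq = config@cardiacFreq, cardiac_amp = config@cardiacAmp,
    resp_freq = config@respFreq, resp_amp = config@respAmp,
    drift_sd = config@driftSd, noise_sd = config@noiseSd,
    artifact_rate = config@artifactRate,
    artifact_kinds = config@artifactKinds,
    rt_mean_early = config@rtMeanEarly, rt_mean_late = config@rtMeanLate,
    rt_sd = config@rtSd,
    rt_slowing_sd_between = config@rtSlowingSdBetween,
    rt_lapse_rate = config@rtLapseRate,
    rt_distribution = config@rtDistribution,
    age_range = config@ageRange, seed = config@seed)
}

configFromList <- function(x) {
  simConfig(
    nSubjects = x$n_subjects, fs = x$fs,
    baselineDuration = x$baseline_duration, taskDuration = x$task_duration,
    isiRange = unlist(x$isi_range), stimulusDuration = x$stimulus_duration,
    hrfPeakAmplitudeO2hb = x$hrf_peak_amplitude_o2hb,
    hrfTrialCv = if (is.null(x$hrf_trial_cv)) 0.3 else x$hrf_trial_cv,
    hhbToO2hbRatio = x$hhb_to_o2hb_ratio,
    attentionEffect = unlist(x$attention_effect),
    attentionEffectHhb = if (is.null(x$attention_effect_hhb)) NA_real_
      else unlist(x$attention_effect_hhb),
    cardiacFreq = x$cardiac_freq, cardiacAmp = x$cardiac_amp,
    respFreq = x$resp_freq, respAmp = x$resp_amp,
    driftSd = x$drift_sd, noiseSd = x$noise_sd,
    artifactRate = x$artifact_rate, artifactKinds = unlist(x$artifact_kinds),
    rtMeanEarly = x$rt_mean_early, rtMeanLate = x$rt_mean_late,
    rtSd = x$rt_sd,
    rtSlowingSdBetween = if (is.null(x$rt_slowing_sd_between)) 35
      else x$rt_slowing_sd_between,
    rtLapseRate = x$rt_lapse_rate,
    rtDistribution = x$rt_distribution,
    ageRange = unlist(x$age_range), seed = x$seed)
}

#' Short deterministic fingerprint of a configuration
#'
#' Polynomial byte hash (FNV-style) of the YAML serialization, used to
#' stamp every output file of a run so mismatched intermediates can be
#' refused.
#'
#' @param config a [SimConfig-class] (or any serializable list).
#' @return 8-hex-digit character scalar.
#' @export
configHash <- function(config) {
  x <- if (is(config, "SimConfig")) configToList(config) else config
  bytes <- utf8ToInt(yaml::as.yaml(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor64(h, b)
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# 32-bit xor on doubles (values may exceed .Machine$integer.max)
bitwXor64 <- function(a, b) {
  ahi <- as.integer(a %/% 65536); alo <- as.integer(a %% 65536)
  bhi <- as.integer(b %/% 65536); blo <- as.integer(b %% 65536)
  as.double(bitwXor(ahi, bhi)) * 65536 + as.double(bitwXor(alo, blo))
}

# Deterministic per-subject seed derived from the master seed, so a
# cohort can be extended without reshuffling existing subjects.
subjectSeed <- function(seed, idx) {
  as.integer((as.double(seed) * 48271 + as.double(idx) * 9973 + 12345) %%
               2147483647)
}
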