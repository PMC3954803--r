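#' @useDynLib nirsvigilance, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

VALID_REGIONS <- c("lPFC", "mPFC", "rPFC", "rParietal")
PFC_REGIONS <- c("lPFC", "mPFC", "rPFC")
CHROMOPHORES <- c("O2Hb", "HHb")
CLASS_LABELS <- c("full_attention", "attention_decrement")

#' Probe geometry of a multichannel fNIRS montage
#'
#' Describes where each measurement channel sits on the scalp (10-10
#' system label), which cortical region it samples, and the
#' emitter-detector separation shared by all channels.
#'
#' @slot channels \code{data.frame} with columns \code{channel_id},
#'   \code{region} (one of \code{lPFC}, \code{mPFC}, \code{rPFC},
#'   \code{rParietal}) and \code{label} (10-10 system position).
#' @slot separationCm emitter-detector distance in cm (single positive
#'   number).
#' @export
setClass("ChannelLayout",
  representation(channels = "data.frame", separationCm = "numeric"))

setValidity("ChannelLayout", function(object) {
  ch <- object@channels
  msgs <- character()
  need <- c("channel_id", "region", "label")
  if (!all(need %in% names(ch)))
    msgs <- c(msgs, paste("channels must have columns",
                          paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(ch$channel_id))
      msgs <- c(msgs, "channel_id values must be unique")
    if (!all(ch$region %in% VALID_REGIONS))
      msgs <- c(msgs, paste("region must be one of",
                            paste(VALID_REGIONS, collapse = ", ")))
  }
  if (length(object@separationCm) != 1L || !is.finite(object@separationCm) ||
      object@separationCm <= 0)
    msgs <- c(msgs, "separationCm must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' Simulation configuration for a synthetic vigilance cohort
#'
#' Holds every parameter of the synthetic sustained-attention experiment:
#' timing of the protocol, hemodynamic response and physiological noise
#' model, the programmed time-on-task attention effect, the movement
#' artifact process, and the reaction-time model.
#'
#' Construct with [simConfig()], which supplies the study defaults.
#'
#' @slot nSubjects number of subjects in the cohort (>= 2).
#' @slot fs sampling rate in Hz.
#' @slot baselineDuration pre-task rest duration, seconds.
#' @slot taskDuration sustained-attention task duration, seconds.
#' @slot isiRange two-element range (s) of the uniform inter-stimulus
#'   interval.
#' @slot stimulusDuration flash duration, seconds.
#' @slot hrfPeakAmplitudeO2hb peak amplitude of the per-stimulus
#'   oxyhemoglobin response, micromolar.
#' @slot hrfTrialCv coefficient of variation of the per-trial,
#'   per-channel response amplitude (trial-to-trial variability of the
#'   evoked response; decorrelates channels beyond their shared
#'   stimulus timing).
#' @slot hhbToO2hbRatio signed scaling from the O2Hb functional
#'   components (evoked response, attention shift) to their HHb
#'   counterparts; negative, reflecting washout.
#' @slot attentionEffect named numeric vector over regions: O2Hb mean
#'   shift (micromolar) between the first and last task thirds.
#' @slot attentionEffectHhb HHb counterpart of \code{attentionEffect};
#'   \code{NA} means derive it as \code{hhbToO2hbRatio * attentionEffect}.
#' @slot cardiacFreq,cardiacAmp cardiac oscillation frequency (Hz) and
#'   amplitude (micromolar).
#' @slot respFreq,respAmp respiratory oscillation frequency (Hz) and
#'   amplitude (micromolar).
#' @slot driftSd standard deviation (micromolar) of the slow baseline
#'   wander over the recording.
#' @slot noiseSd standard deviation (micromolar) of white measurement
#'   noise.
#' @slot artifactRate movement-artifact events per minute per channel.
#' @slot artifactKinds subset of \code{c("spike", "shift")}.
#' @slot rtMeanEarly,rtMeanLate target mean reaction time (ms) in the
#'   first and last task thirds.
#' @slot rtSd reaction-time standard deviation, ms.
#' @slot rtSlowingSdBetween between-subject SD of the mean late-task
#'   slowing, ms.
#' @slot rtLapseRate fraction of trials programmed to fall outside the
#'   150-600 ms validity window.
#' @slot rtDistribution \code{"lognormal"} (default) or
#'   \code{"truncnormal"}.
#' @slot ageRange two-element range (years) for uniform subject ages.
#' @slot seed integer master seed; per-subject seeds derive from it.
#' @export
setClass("SimConfig",
  representation(
    nSubjects = "integer", fs = "numeric",
    baselineDuration = "numeric", taskDuration = "numeric",
    isiRange = "numeric", stimulusDuration = "numeric",
    hrfPeakAmplitudeO2hb = "numeric", hrfTrialCv = "numeric",
    hhbToO2hbRatio = "numeric",
    attentionEffect = "numeric", attentionEffectHhb = "numeric",
    cardiacFreq = "numeric", cardiacAmp = "numeric",
    respFreq = "numeric", respAmp = "numeric",
    driftSd = "numeric", noiseSd = "numeric",
    artifactRate = "numeric", artifactKinds = "character",
    rtMeanEarly = "numeric", rtMeanLate = "numeric", rtSd = "numeric",
    rtSlowingSdBetween = "numeric",
    rtLapseRate = "numeric", rtDistribution = "character",
    ageRange = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nSubjects < 2L)
    msgs <- c(msgs, "nSubjects must be >= 2 (leave-one-subject-out undefined otherwise)")
  if (object@fs <= 0) msgs <- c(msgs, "fs must be positive")
  if (object@baselineDuration <= 0 || object@taskDuration <= 0)
    msgs <- c(msgs, "durations must be positive")
  if (length(object@isiRange) != 2L || object@isiRange[1] < 0 ||
      object@isiRange[1] >= object@isiRange[2])
    msgs <- c(msgs, "isiRange must satisfy 0 <= low < high")
  if (!setequal(names(object@attentionEffect), VALID_REGIONS))
    msgs <- c(msgs, "attentionEffect must be named over all four regions")
  if (!all(is.na(object@attentionEffectHhb)) &&
      !setequal(names(object@attentionEffectHhb), VALID_REGIONS))
    msgs <- c(msgs, "attentionEffectHhb must be NA or named over all four regions")
  if (!all(object@artifactKinds %in% c("spike", "shift")))
    msgs <- c(msgs, "artifactKinds must be a subset of spike, shift")
  if (object@rtMeanEarly <= 0 || object@rtMeanLate <= 0 || object@rtSd <= 0)
    msgs <- c(msgs, "reaction-time parameters must be positive")
  if (object@rtSlowingSdBetween < 0)
    msgs <- c(msgs, "rtSlowingSdBetween must be nonnegative")
  if (object@hrfTrialCv < 0)
    msgs <- c(msgs, "hrfTrialCv must be nonnegative")
  if (object@rtLapseRate < 0 || object@rtLapseRate >= 1)
    msgs <- c(msgs, "rtLapseRate must be in [0, 1)")
  if (!object@rtDistribution %in% c("lognormal", "truncnormal"))
    msgs <- c(msgs, "rtDistribution must be lognormal or truncnormal")
  if (length(object@ageRange) != 2L || object@ageRange[1] <= 0 ||
      object@ageRange[1] > object@ageRange[2])
    msgs <- c(msgs, "ageRange must satisfy 0 < low <= high")
  if (length(msgs)) msgs else TRUE
})

#' One subject's recording from the synthetic vigilance experiment
#'
#' Aligned oxy-/deoxy-hemoglobin concentration-change series for every
#' channel, protocol event markers, per-trial stimulus/response times,
#' and the simulation ground truth used to score artifact correction
#' and effect recovery.
#'
#' @slot subjectId character identifier.
#' @slot age subject age in years (drives the differential pathlength
#'   factor).
#' @slot layout a [ChannelLayout-class].
#' @slot fs sampling rate, Hz.
#' @slot o2hb,hhb numeric matrices, channels x samples, micromolar;
#'   rownames are channel ids.
#' @slot events \code{data.frame(label, time_s)}, time-ordered, with one
#'   \code{baseline_start}, one \code{task_start}, one \code{task_end}
#'   and one \code{stimulus} row per trial.
#' @slot trials \code{data.frame(stimulus_time_s, response_onset_time_s)};
#'   \code{NA} response time means no response was produced.
#' @slot truth list: \code{artifacts} (data.frame channel_id, start_s,
#'   end_s, kind), \code{effect} (the programmed attention-shift
#'   parameters), and — in memory only — \code{clean_o2hb}/\code{clean_hhb}
#'   artifact-free matrices.
#' @slot preprocessed logical; TRUE once the conditioning chain has run.
#' @export
setClass("SubjectRecording",
  representation(
    subjectId = "character", age = "numeric", layout = "ChannelLayout",
    fs = "numeric", o2hb = "matrix", hhb = "matrix",
    events = "data.frame", trials = "data.frame", truth = "list",
    preprocessed = "logical"))

setValidity("SubjectRecording", function(object) {
  msgs <- character()
  nch <- nrow(object@layout@channels)
  if (nrow(object@o2hb) != nch || nrow(object@hhb) != nch)
    msgs <- c(msgs, "o2hb/hhb must have one row per layout channel")
  if (ncol(object@o2hb) != ncol(object@hhb))
    msgs <- c(msgs, "o2hb and hhb must be sample-aligned")
  ev <- object@events
  if (!all(c("label", "time_s") %in% names(ev)))
    msgs <- c(msgs, "events needs columns label, time_s")
  else {
    if (is.unsorted(ev$time_s))
      msgs <- c(msgs, "events must be time-ordered")
    for (lab in c("baseline_start", "task_start", "task_end"))
      if (sum(ev$label == lab) != 1L)
        msgs <- c(msgs, paste("events must contain exactly one", lab))
    if (all(c("task_start", "task_end") %in% ev$label) &&
        nrow(object@trials)) {
      t0 <- ev$time_s[ev$label == "task_start"]
      t1 <- ev$time_s[ev$label == "task_end"]
      st <- object@trials$stimulus_time_s
      if (any(st < t0 | st > t1))
        msgs <- c(msgs, "every trial stimulus must lie within the task window")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' A cohort of subject recordings plus the configuration that produced it
#'
#' @slot recordings list of [SubjectRecording-class] with unique
#'   subject ids.
#' @slot config the [SimConfig-class] used (carried for provenance and
#'   config-hash stamping of outputs).
#' @export
setClass("VigilanceCohort",
  representation(recordings = "list", config = "SimConfig"))

setValidity("VigilanceCohort", function(object) {
  msgs <- character()
  if (length(object@recordings) < 2L)
    msgs <- c(msgs, "a cohort needs at least 2 subjects")
  if (!all(vapply(object@recordings, is, logical(1), "SubjectRecording")))
    msgs <- c(msgs, "recordings must all be SubjectRecording objects")
  else {
    ids <- vapply(object@recordings, function(r) r@subjectId, character(1))
    if (anyDuplicated(ids)) msgs <- c(msgs, "subject ids must be unique")
  }
  if (length(msgs)) msgs else TRUE
})

#' Epoch-level feature table for one region-by-chromophore design cell
#'
#' Rows are one-second epochs labelled \code{full_attention} (first ten
#' task minutes) or \code{attention_decrement} (last ten); columns are
#' epoch-mean concentration values for each selected
#' (channel, chromophore) pair.
#'
#' @slot features numeric matrix, epochs x features.
#' @slot info \code{data.frame(subject_id, epoch_index, class)} aligned
#'   with the feature rows.
#' @slot featureNames "channel.chromophore" column identifiers.
#' @slot regionSet one of \code{"PFC"}, \code{"parietal"}, \code{"both"}.
#' @slot chromophoreSet one of \code{"O2Hb"}, \code{"HHb"}, \code{"both"}.
#' @export
setClass("EpochFeatureTable",
  representation(features = "matrix", info = "data.frame",
                 featureNames = "character", regionSet = "character",
                 chromophoreSet = "character"))

setValidity("EpochFeatureTable", function(object) {
  msgs <- character()
  if (nrow(object@features) != nrow(object@info))
    msgs <- c(msgs, "features and info must have equal row counts")
  if (ncol(object@features) != length(object@featureNames))
    msgs <- c(msgs, "featureNames must match the feature dimension")
  if (!all(object@info$class %in% CLASS_LABELS))
    msgs <- c(msgs, "class labels must be full_attention/attention_decrement")
  if (length(msgs)) msgs else TRUE
})

#' Trained linear soft-margin support vector machine
#'
#' The separating hyperplane sign(w.x + b) fitted by sequential minimal
#' optimization on the hinge-loss dual. Ties (w.x + b == 0) are
#' assigned to the positive class (\code{attention_decrement}).
#'
#' @slot weights numeric weight vector aligned with \code{featureNames}.
#' @slot bias intercept.
#' @slot C soft-margin regularization parameter.
#' @slot featureNames feature identifiers the model was trained on.
#' @slot iterations solver iterations used.
#' @slot converged logical, duality-gap stopping rule satisfied.
#' @slot dualObjective value of the dual objective at the solution.
#' @export
setClass("LinearSVM",
  representation(weights = "numeric", bias = "numeric", C = "numeric",
                 featureNames = "character", iterations = "integer",
                 converged = "logical", dualObjective = "numeric"),
  prototype(C = 1, bias = 0, converged = FALSE, iterations = 0L))

setValidity("LinearSVM", function(object) {
  msgs <- character()
  if (length(object@weights) != length(object@featureNames))
    msgs <- c(msgs, "weights must align with featureNames")
  if (object@C <= 0) msgs <- c(msgs, "C must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Leave-one-subject-out cross-validation result
#'
#' @slot perFold \code{data.frame(held_out_subject, acc_overall,
#'   acc_full_attention, acc_attention_decrement)}, accuracies in
#'   percent of correctly classified epochs.
#' @slot meanAccuracy unweighted mean of the per-fold overall
#'   accuracies, percent.
#' @slot nTrainPerClass training epochs per class in each fold.
#' @slot regionSet,chromophoreSet the design cell evaluated.
#' @slot C regularization parameter used.
#' @export
setClass("CVResult",
  representation(perFold = "data.frame", meanAccuracy = "numeric",
                 nTrainPerClass = "integer", regionSet = "character",
                 chromophoreSet = "character", C = "numeric"),
  prototype(C = 1))

setValidity("CVResult", function(object) {
  acc <- unlist(object@perFold[, c("acc_overall", "acc_full_attention",
                                   "acc_attention_decrement")])
  if (any(acc < 0 | acc > 100)) "accuracies must lie in [0, 100]" else TRUE
})

#' Reaction-time block analysis result
#'
#' First-versus-last ten task minutes block means of valid reaction
#' times, the paired Student t-test on the change scores, and Cohen's d
#' of change (mean change divided by the SD of change, so t = d * sqrt(n)).
#'
#' @slot perSubject \code{data.frame(subject_id, mean_rt_early_ms,
#'   mean_rt_late_ms, change_ms)}.
#' @slot tStatistic paired t statistic.
#' @slot df degrees of freedom (n - 1).
#' @slot pValue two-sided p-value.
#' @slot cohensD Cohen's d of change.
#' @slot normality skewness/kurtosis diagnostics of the change scores
#'   (reported, never used as a gate).
#' @export
setClass("BehaviorStats",
  representation(perSubject = "data.frame", tStatistic = "numeric",
                 df = "integer", pValue = "numeric", cohensD = "numeric",
                 normality = "numeric"))

#' Accuracy grid over the region-by-chromophore design space
#'
#' @slot results named list of [CVResult-class], keys
#'   \code{"<region>_<chromophore>"} over \{PFC, parietal, both\} x
#'   \{O2Hb, HHb, both\}.
#' @slot summary \code{data.frame(region_set, chromophore_set,
#'   n_features, mean_accuracy)} with one row per grid cell.
#' @export
setClass("DesignSpaceResult",
  representation(results = "list", summary = "data.frame"))
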