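#' Extract a response onset from a force series
#'
#' The onset is the first sample after the stimulus at which the force
#' crosses a threshold above the pre-stimulus baseline. By default the
#' threshold is the baseline mean plus five baseline SDs, with the
#' baseline taken over the 500 ms preceding the stimulus.
#'
#' @param force numeric force series.
#' @param fs sampling rate, Hz.
#' @param stimulusTime stimulus onset, s; the series must cover
#'   \code{[stimulusTime, stimulusTime + searchS]}.
#' @param threshold absolute threshold override; \code{NULL} derives it
#'   from the baseline.
#' @param searchS response search window after the stimulus, s.
#' @param baselineS pre-stimulus baseline window, s.
#' @return onset time in seconds, or \code{NA} if the force never
#'   crosses the threshold.
#' @export
extractResponseOnset <- function(force, fs, stimulusTime, threshold = NULL,
                                 searchS = 1.5, baselineS = 0.5) {
  n <- length(force)
  if (stimulusTime < 0 || stimulusTime + searchS > n / fs + 1e-9)
    stop("stimulus outside the recorded force series")
  iStim <- floor(stimulusTime * fs) + 1L
  if (is.null(threshold)) {
    iBase <- max(1L, iStim - round(baselineS * fs)):max(1L, iStim - 1L)
    threshold <- mean(force[iBase]) +
      5 * (if (length(iBase) > 1) stats::sd(force[iBase]) else 0)
  }
  iEnd <- min(n, iStim + round(searchS * fs))
  win <- force[iStim:iEnd]
  hit <- which(win > threshold)
  if (!length(hit)) return(NA_real_)
  (iStim + hit[1] - 2L) / fs
}

#' Flag trial validity by the 150-600 ms response window
#'
#' Computes each trial's reaction time from its stimulus and response
#' onset times and flags it valid exactly when the response falls
#' between 150 and 600 ms after stimulus onset; trials with no
#' response are invalid. Idempotent and order-independent.
#'
#' @param trials \code{data.frame(stimulus_time_s,
#'   response_onset_time_s)} (\code{NA} response = omission).
#' @return the trials with added \code{rt_ms} and \code{valid} columns.
#' @export
#' @examples
#' validateTrials(data.frame(stimulus_time_s = c(1, 10),
#'                           response_onset_time_s = c(1.4, 10.1)))
validateTrials <- function(trials) {
  rt <- (trials$response_onset_time_s - trials$stimulus_time_s) * 1000
  trials$rt_ms <- rt
  # tiny tolerance so responses exactly at a window edge are not lost
  # to floating-point subtraction of the two onset times
  eps <- 1e-6
  trials$valid <- !is.na(rt) & rt >= 150 - eps & rt <= 600 + eps
  trials
}

#' Block-mean reaction times over the first and last ten task minutes
#'
#' Means of valid reaction times whose stimulus fell in
#' \code{[taskStart, taskStart + 600)} and
#' \code{[taskEnd - 600, taskEnd)} respectively.
#'
#' @param trials a validated trial table (see [validateTrials()];
#'   validation is applied if the \code{valid} column is absent).
#' @param taskStart,taskEnd task window bounds, s.
#' @param subjectId used only in error messages.
#' @return named numeric vector \code{c(early = ..., late = ...)}, ms.
#' @export
blockMeans <- function(trials, taskStart, taskEnd, subjectId = "?") {
  if (is.null(trials$valid)) trials <- validateTrials(trials)
  st <- trials$stimulus_time_s
  early <- trials$valid & st >= taskStart & st < taskStart + 600
  late <- trials$valid & st >= taskEnd - 600 & st < taskEnd
  if (!any(early))
    stop("subject ", subjectId, ": no valid trials in the early block")
  if (!any(late))
    stop("subject ", subjectId, ": no valid trials in the late block")
  c(early = mean(trials$rt_ms[early]), late = mean(trials$rt_ms[late]))
}

# Moment diagnostics of the change scores (reported only, never a gate).
momentDiagnostics <- function(x) {
  n <- length(x)
  m <- mean(x); s <- stats::sd(x)
  c(skewness = mean((x - m)^3) / (sum((x - m)^2) / n)^1.5,
    kurtosis = n * sum((x - m)^4) / sum((x - m)^2)^2 - 3)
}

#' Paired t-test and Cohen's d of change on block means
#'
#' Change scores are late minus early block means per subject. The
#' paired Student t-test is two-sided with df = n - 1; Cohen's d is
#' the mean change divided by the SD of the changes, so the algebraic
#' identity t = d * sqrt(n) holds exactly.
#'
#' @param perSubject \code{data.frame(subject_id, mean_rt_early_ms,
#'   mean_rt_late_ms)} (a \code{change_ms} column is added).
#' @return a [BehaviorStats-class].
#' @export
#' @examples
#' df <- data.frame(subject_id = paste0("S", 1:7),
#'                  mean_rt_early_ms = rep(300, 7),
#'                  mean_rt_late_ms = 300 + seq(10, 70, 10))
#' pairedTStats(df)
pairedTStats <- function(perSubject) {
  n <- nrow(perSubject)
  if (n < 2) stop("need at least two subjects")
  change <- perSubject$mean_rt_late_ms - perSubject$mean_rt_early_ms
  s <- stats::sd(change)
  if (!is.finite(s) || s == 0)
    stop("zero-variance change scores: t and d undefined")
  tt <- stats::t.test(change)
  perSubject$change_ms <- change
  new("BehaviorStats", perSubject = perSubject,
      tStatistic = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
      pValue = tt$p.value, cohensD = mean(change) / s,
      normality = momentDiagnostics(change))
}

#' Reaction-time analysis of a cohort
#'
#' Applies the validity window, computes per-subject first/last
#' ten-minute block means, and runs the paired t-test with Cohen's d
#' of change.
#'
#' @param cohort a [VigilanceCohort-class].
#' @return a [BehaviorStats-class].
#' @export
behaviorAnalysis <- function(cohort) {
  rows <- lapply(cohort@recordings, function(rec) {
    ev <- rec@events
    bm <- blockMeans(validateTrials(rec@trials),
                     ev$time_s[ev$label == "task_start"],
                     ev$time_s[ev$label == "task_end"],
                     subjectId = rec@subjectId)
    data.frame(subject_id = rec@subjectId,
               mean_rt_early_ms = bm[["early"]],
               mean_rt_late_ms = bm[["late"]],
               stringsAsFactors = FALSE)
  })
  pairedTStats(do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

setMethod("show", "BehaviorStats", function(object) {
  ps <- object@perSubject
  cat("BehaviorStats over", nrow(ps), "subjects\n")
  cat(sprintf("  RT %0.1f -> %0.1f ms (mean change %+0.1f ms)\n",
              mean(ps$mean_rt_early_ms), mean(ps$mean_rt_late_ms),
              mean(ps$change_ms)))
  cat(sprintf("  t(%d) = %0.3f, p = %0.4f, Cohen's d = %0.3f\n",
              object@df, object@tStatistic, object@pValue, object@cohensD))
})
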