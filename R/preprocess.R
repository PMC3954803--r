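#' Age-specific differential pathlength factor
#'
#' Continuous-wave NIRS measures optical-density changes along a photon
#' path longer than the emitter-detector separation; the differential
#' pathlength factor (DPF) corrects for this. The age dependence used
#' here is the general formula DPF = 4.99 + 0.067 * age^0.814.
#'
#' @param ageYears subject age in years (> 0).
#' @return DPF (unitless, > 4.99, increasing in age).
#' @export
#' @examples
#' dpfFromAge(29) # ~6.03
dpfFromAge <- function(ageYears) {
  if (any(!is.finite(ageYears)) || any(ageYears <= 0))
    stop("age must be positive")
  4.99 + 0.067 * ageYears^0.814
}

#' Default extinction coefficients at 763 and 855 nm
#'
#' Specific extinction coefficients of oxy- and deoxy-hemoglobin in
#' mM^-1 cm^-1, interpolated to the instrument's nominal wavelengths
#' from the standard compiled hemoglobin absorption spectra. Rows are
#' wavelengths, columns the chromophores. The matrix is configuration:
#' substitute your own table for a different instrument.
#'
#' @return 2 x 2 numeric matrix, dimnames wavelengths x
#'   \code{c("O2Hb", "HHb")}.
#' @export
defaultExtinctionCoefficients <- function() {
  matrix(c(0.610, 1.450,
           1.066, 0.680),
         nrow = 2, byrow = TRUE,
         dimnames = list(c("763", "855"), c("O2Hb", "HHb")))
}

#' Construct the modified Beer-Lambert conversion model
#'
#' @param age subject age in years (sets the DPF) or \code{NULL} if
#'   \code{dpf} is given directly.
#' @param separationCm emitter-detector distance, cm.
#' @param extinction 2 x 2 extinction matrix (wavelengths x
#'   chromophores), mM^-1 cm^-1.
#' @param dpf differential pathlength factor override.
#' @return list with elements \code{extinction}, \code{separationCm},
#'   \code{dpf}.
#' @export
opticalModel <- function(age = NULL, separationCm = 3.5,
                         extinction = defaultExtinctionCoefficients(),
                         dpf = NULL) {
  if (is.null(dpf)) {
    if (is.null(age)) stop("provide either age or dpf")
    dpf <- dpfFromAge(age)
  }
  if (separationCm <= 0) stop("separation must be positive")
  if (dpf <= 0) stop("dpf must be positive")
  if (!all(dim(extinction) == c(2L, 2L)) ||
      abs(det(extinction)) < 1e-12 * prod(apply(abs(extinction), 1, max)))
    stop("extinction matrix must be 2 x 2 and invertible")
  list(extinction = extinction, separationCm = separationCm, dpf = dpf)
}

#' Forward modified Beer-Lambert model
#'
#' Maps chromophore concentration changes (micromolar) to
#' optical-density changes at the two wavelengths:
#' dOD(lambda) = (eps_O2Hb(lambda) dC_O2Hb + eps_HHb(lambda) dC_HHb)
#' * separation * DPF, concentrations converted to mM to match the
#' extinction units.
#'
#' @param o2hbUm,hhbUm concentration changes, micromolar (vectors of
#'   equal length).
#' @param model an [opticalModel()].
#' @return 2 x n matrix of optical-density changes (rows: wavelengths).
#' @export
mbllForward <- function(o2hbUm, hhbUm, model) {
  conc <- rbind(o2hbUm, hhbUm) / 1000  # uM -> mM
  (model$extinction %*% conc) * model$separationCm * model$dpf
}

#' Invert the modified Beer-Lambert model
#'
#' Solves the 2 x 2 linear system of [mbllForward()] for the
#' concentration changes; exact linear inverse, so the round trip is
#' identity to numerical precision.
#'
#' @param deltaOd 2 x n matrix (or length-2 vector) of optical-density
#'   changes, rows ordered as the model's wavelengths.
#' @param model an [opticalModel()].
#' @return list with numeric vectors \code{o2hb} and \code{hhb},
#'   micromolar.
#' @export
mbllConvert <- function(deltaOd, model) {
  if (is.null(dim(deltaOd))) deltaOd <- matrix(deltaOd, nrow = 2)
  conc <- solve(model$extinction,
                deltaOd / (model$separationCm * model$dpf)) * 1000
  list(o2hb = unname(conc[1, ]), hhb = unname(conc[2, ]))
}

#' Low-pass filter specification
#'
#' @param order filter order (default 4).
#' @param cutoffHz cutoff frequency in Hz (default 0.1, which removes
#'   cardiac and respiratory oscillations at a 10 Hz sampling rate).
#' @param mode \code{"zero_phase"} (forward-backward, offline analysis)
#'   or \code{"causal"} (single pass).
#' @return validated list.
#' @export
filterSpec <- function(order = 4L, cutoffHz = 0.1,
                       mode = c("zero_phase", "causal")) {
  mode <- match.arg(mode)
  if (order < 1) stop("filter order must be >= 1")
  if (cutoffHz <= 0) stop("cutoff must be positive")
  list(order = as.integer(order), cutoffHz = cutoffHz, mode = mode)
}

#' Butterworth low-pass filter with controlled edges
#'
#' Coefficients from \code{signal::butter}; the zero-phase mode applies
#' the filter forward and backward over an odd-reflection extension of
#' the demeaned series, long enough that start-up transients decay
#' below numerical noise, so DC gain is exactly 1 on constants and the
#' pass is linear. Causal mode pads the front with the first sample.
#'
#' @param series numeric vector.
#' @param fs sampling rate, Hz.
#' @param spec a [filterSpec()].
#' @return filtered series, same length.
#' @export
lowpassFilter <- function(series, fs, spec = filterSpec()) {
  n <- length(series)
  if (spec$cutoffHz >= fs / 2) stop("cutoff must be below the Nyquist frequency")
  if (n <= 3 * (spec$order + 1)) stop("series too short for edge handling")
  bf <- signal::butter(spec$order, spec$cutoffHz / (fs / 2), type = "low")
  L <- min(n - 1L, ceiling(6 * fs / spec$cutoffHz))
  if (spec$mode == "zero_phase") {
    m <- mean(series)
    z <- series - m
    front <- 2 * z[1] - z[(L + 1):2]
    back <- 2 * z[n] - z[(n - 1):(n - L)]
    ext <- c(front, z, back)
    y <- signal::filter(bf, ext)
    y <- rev(signal::filter(bf, rev(y)))
    as.numeric(y[(L + 1):(L + n)]) + m
  } else {
    # causal mode can only reference the past: settle the filter on
    # the first sample's level
    z <- series - series[1]
    y <- signal::filter(bf, c(rep(0, L), z))
    as.numeric(y[(L + 1):(L + n)]) + series[1]
  }
}

#' Movement-artifact detection specification
#'
#' @param windowS moving-SD window length, s.
#' @param thresholdK threshold as a multiple of the median moving SD.
#' @param splineSmoothing smoothing parameter in [0, 1]; values near 1
#'   let the correction spline follow the artifact closely.
#' @param minGapS segments closer than this are merged, s.
#' @param dilateS seconds added to both ends of each segment before
#'   correction. Detection runs on the unfiltered series (where an
#'   abrupt artifact stands out sharply against the white measurement
#'   noise), while correction is applied to the low-pass-filtered
#'   trace, over which the zero-phase filter has smeared the artifact
#'   symmetrically; the default (one cutoff period of the 0.1 Hz
#'   low-pass) covers that smear.
#' @return validated list.
#' @export
maraSpec <- function(windowS = 1, thresholdK = 3, splineSmoothing = 0.99,
                     minGapS = 0.5, dilateS = 10) {
  if (windowS <= 0 || thresholdK <= 0) stop("windowS and thresholdK must be positive")
  if (splineSmoothing < 0 || splineSmoothing > 1)
    stop("splineSmoothing must be in [0, 1]")
  if (dilateS < 0) stop("dilateS must be nonnegative")
  list(windowS = windowS, thresholdK = thresholdK,
       splineSmoothing = splineSmoothing, minGapS = minGapS,
       dilateS = dilateS)
}

# Centered moving standard deviation; edges carry the nearest interior
# value so threshold crossings are defined everywhere.
movingSd <- function(x, w) {
  n <- length(x)
  w <- max(2L, min(w, n))
  kern <- rep(1 / w, w)
  m1 <- stats::filter(x, kern, sides = 2)
  m2 <- stats::filter(x^2, kern, sides = 2)
  v <- pmax((m2 - m1^2) * w / (w - 1), 0)
  s <- sqrt(as.numeric(v))
  ok <- which(!is.na(s))
  if (!length(ok)) return(rep(0, n))
  s[seq_len(ok[1] - 1)] <- s[ok[1]]
  s[seq((ok[length(ok)] + 1), length.out = n - ok[length(ok)])] <-
    s[ok[length(ok)]]
  s
}

#' Detect movement-artifact segments by moving standard deviation
#'
#' Samples where the moving SD exceeds \code{thresholdK} times its
#' median are flagged; runs of flagged samples become segments, and
#' segments closer than \code{minGapS} are merged. A constant series
#' (median moving SD zero) yields no segments.
#'
#' @param series numeric vector.
#' @param fs sampling rate, Hz.
#' @param spec a [maraSpec()].
#' @return \code{data.frame(start_s, end_s)}; zero rows when the series
#'   is clean.
#' @export
detectArtifacts <- function(series, fs, spec = maraSpec()) {
  n <- length(series)
  w <- round(spec$windowS * fs)
  if (n < w) stop("series shorter than the moving-SD window")
  msd <- movingSd(series, w)
  med <- stats::median(msd)
  thr <- max(spec$thresholdK * med, 1e-10)
  flags <- msd > thr
  if (!any(flags))
    return(data.frame(start_s = numeric(), end_s = numeric()))
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # a flagged sample indicts its whole centered window: extend each
  # run by half a window so e.g. the two transition edges of a
  # sustained excursion coalesce into one segment
  half <- w %/% 2
  seg <- data.frame(start = pmax(1L, starts[r$values] - half),
                    end = pmin(n, ends[r$values] + half))
  # merge neighbours closer than minGapS
  gap <- round(spec$minGapS * fs)
  merged <- seg[1, , drop = FALSE]
  for (i in seq_len(nrow(seg) - 1L) + 1L) {
    if (seg$start[i] - merged$end[nrow(merged)] <= gap)
      merged$end[nrow(merged)] <- seg$end[i]
    else merged <- rbind(merged, seg[i, ])
  }
  data.frame(start_s = (merged$start - 1) / fs, end_s = merged$end / fs)
}

#' Correct artifact segments by spline subtraction and re-leveling
#'
#' For each detected segment a smoothing spline is fitted to the
#' segment samples and subtracted, removing the artifact's shape; the
#' residual is then re-seated on a linear extrapolation of the local
#' trend fitted just before the segment (so a trend across the
#' segment is carried through rather than flattened), and everything
#' after the segment is shifted by the constant offset between that
#' extrapolated trend and the data that follows — which removes
#' baseline steps while leaving samples outside segments changed only
#' by constant offsets. Overlapping segments are merged silently.
#'
#' @param series numeric vector.
#' @param segments \code{data.frame(start_s, end_s)} as returned by
#'   [detectArtifacts()].
#' @param fs sampling rate, Hz.
#' @param spec a [maraSpec()].
#' @return corrected series, same length.
#' @export
correctArtifacts <- function(series, segments, fs, spec = maraSpec()) {
  n <- length(series)
  if (is.null(segments) || nrow(segments) == 0) return(series)
  if (any(segments$start_s < 0) || any(segments$end_s > n / fs + 1e-9))
    stop("artifact segments outside series bounds")
  seg <- segments[order(segments$start_s), , drop = FALSE]
  a <- pmax(1L, floor((seg$start_s - spec$dilateS) * fs) + 1L)
  b <- pmin(n, ceiling((seg$end_s + spec$dilateS) * fs))
  # merge overlaps
  ka <- a[1]; kb <- b[1]; ma <- integer(); mb <- integer()
  for (i in seq_along(a)[-1]) {
    if (a[i] <= kb + 1L) kb <- max(kb, b[i])
    else { ma <- c(ma, ka); mb <- c(mb, kb); ka <- a[i]; kb <- b[i] }
  }
  ma <- c(ma, ka); mb <- c(mb, kb)

  w <- max(2L, round(spec$windowS * fs))
  # linear trend fitted on y[win], evaluated at positions `at`
  trendAt <- function(win, at) {
    if (length(win) < 2L) return(rep(y[win[1]], length(at)))
    co <- stats::lm.fit(cbind(1, win), y[win])$coefficients
    as.numeric(cbind(1, at) %*% co)
  }
  y <- series
  for (i in seq_along(ma)) {
    idx <- ma[i]:mb[i]
    len <- length(idx)
    # flanking-trend window: well beyond the segment length, so slow
    # evoked fluctuations average out of the slope estimate and the
    # extrapolation horizon stays small relative to the fit support
    wl <- max(10L * w, 2L * len)
    if (len >= 8L) {
      # smoothing parameter in [0,1] mapped onto smooth.spline's spar
      # scale: 1 (follow the artifact tightly) -> spar -1.5,
      # 0 (maximal smoothing) -> spar 1.5
      spar <- 1.5 - 3 * spec$splineSmoothing
      fit <- try(stats::smooth.spline(idx, y[idx], spar = spar), silent = TRUE)
      trend <- if (inherits(fit, "try-error"))
        stats::fitted(stats::lm(y[idx] ~ idx)) else stats::fitted(fit)
    } else {
      trend <- stats::fitted(stats::lm(y[idx] ~ idx))
    }
    resid <- y[idx] - trend
    hasPre <- ma[i] > 1L
    hasPost <- mb[i] < n
    # flanking windows stop at neighbouring artifact segments
    preLo <- if (i > 1L) mb[i - 1L] + 1L else 1L
    postHi <- if (i < length(ma)) ma[i + 1L] - 1L else n
    preWin <- if (hasPre) max(preLo, ma[i] - wl):(ma[i] - 1L)
    postWin <- if (hasPost) (mb[i] + 1L):min(postHi, mb[i] + wl)
    if (hasPre) {
      base <- trendAt(preWin, idx)
      y[idx] <- resid + base
      if (hasPost) {
        off <- mean(trendAt(preWin, postWin) - y[postWin])
        y[(mb[i] + 1L):n] <- y[(mb[i] + 1L):n] + off
      }
    } else if (hasPost) {
      # segment starts the series: seat it on the following trend
      y[idx] <- resid + trendAt(postWin, idx)
    } else {
      y[idx] <- resid + mean(trend)
    }
  }
  y
}

#' z-normalize a series
#'
#' Centers to mean 0 and scales to (sample) SD 1. Applied per subject,
#' channel and chromophore over the full recording, so signals from
#' different regions and subjects share a common scale before
#' classification.
#'
#' @param series numeric vector, non-constant.
#' @return standardized series.
#' @export
znormalize <- function(series) {
  s <- stats::sd(series)
  if (!is.finite(s) || s == 0)
    stop("cannot z-normalize a constant series (zero variance)")
  (series - mean(series)) / s
}

#' Run the full signal-conditioning chain on one recording
#'
#' Per channel and chromophore: low-pass filter, movement-artifact
#' reduction, then z-normalization — in that order. The moving-SD
#' detector runs on the unfiltered series, where abrupt artifacts
#' stand out sharply against the white measurement noise; the spline
#' correction is applied to the filtered trace over the detected
#' segments dilated by \code{mara$dilateS} to cover the filter's
#' smearing. Detected segments are recorded in
#' \code{truth$provenance}.
#'
#' @param recording a [SubjectRecording-class].
#' @param filter a [filterSpec()].
#' @param mara a [maraSpec()].
#' @return the preprocessed [SubjectRecording-class]
#'   (\code{preprocessed = TRUE}).
#' @export
preprocessRecording <- function(recording, filter = filterSpec(),
                                mara = maraSpec()) {
  fs <- recording@fs
  segsAll <- list()
  for (chrom in CHROMOPHORES) {
    mat <- slot(recording, tolower(chrom))
    for (c_i in seq_len(nrow(mat))) {
      segs <- detectArtifacts(mat[c_i, ], fs, mara)
      y <- lowpassFilter(mat[c_i, ], fs, filter)
      y <- correctArtifacts(y, segs, fs, mara)
      mat[c_i, ] <- znormalize(y)
      if (nrow(segs))
        segsAll[[length(segsAll) + 1L]] <- cbind(
          channel_id = rownames(mat)[c_i], chromophore = chrom, segs)
    }
    slot(recording, tolower(chrom)) <- mat
  }
  recording@truth$provenance <- list(
    filter = filter, mara = mara,
    segments = if (length(segsAll)) do.call(rbind, segsAll)
    else data.frame(channel_id = character(), chromophore = character(),
                    start_s = numeric(), end_s = numeric()))
  recording@preprocessed <- TRUE
  recording
}

#' @describeIn preprocessRecording apply the chain to every recording
#'   in a cohort.
#' @param cohort a [VigilanceCohort-class].
#' @export
preprocessCohort <- function(cohort, filter = filterSpec(),
                             mara = maraSpec()) {
  cohort@recordings <- lapply(cohort@recordings, preprocessRecording,
                              filter = filter, mara = mara)
  cohort
}
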