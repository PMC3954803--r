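#' Segment a series into consecutive fixed-length epoch means
#'
#' Epochs are half-open intervals \code{[t, t + epochS)} anchored at
#' \code{windowStartS}; a trailing incomplete epoch is dropped. Each
#' value is the arithmetic mean of the samples in its interval (sample
#' i covers time (i-1)/fs).
#'
#' @param series numeric vector.
#' @param fs sampling rate, Hz.
#' @param windowStartS,windowEndS window bounds, s; must lie within the
#'   recording.
#' @param epochS epoch duration, s (default 1).
#' @return numeric vector of \code{floor((end - start)/epochS)} epoch
#'   means.
#' @export
#' @examples
#' segmentEpochs(rep(2, 50), fs = 10, 0, 5) # five epochs, all 2
segmentEpochs <- function(series, fs, windowStartS, windowEndS, epochS = 1) {
  n <- length(series)
  if (epochS <= 0) stop("epochS must be positive")
  if (windowEndS <= windowStartS) stop("empty epoch window")
  if (windowStartS < 0 || windowEndS > n / fs + 1e-9)
    stop("epoch window outside the recording")
  nEp <- floor((windowEndS - windowStartS) / epochS + 1e-9)
  if (nEp < 1) stop("window shorter than one epoch")
  i0 <- round(windowStartS * fs)
  bounds <- i0 + round((0:nEp) * epochS * fs)
  bounds <- pmin(bounds, n)
  cs <- c(0, cumsum(series))
  (cs[bounds[-1] + 1] - cs[bounds[-(nEp + 1)] + 1]) /
    (bounds[-1] - bounds[-(nEp + 1)])
}

#' Class windows from the protocol events
#'
#' The first ten task minutes define the \code{full_attention} class,
#' the last ten the \code{attention_decrement} class; the middle of the
#' task is discarded.
#'
#' @param events \code{data.frame(label, time_s)} containing
#'   \code{task_start} and \code{task_end}; the task must last at least
#'   twenty minutes so the windows do not overlap.
#' @return list with two-element numeric vectors \code{early} and
#'   \code{late} (half-open windows, s).
#' @export
labelWindows <- function(events) {
  t0 <- events$time_s[events$label == "task_start"]
  t1 <- events$time_s[events$label == "task_end"]
  if (length(t0) != 1L || length(t1) != 1L)
    stop("events must contain exactly one task_start and one task_end")
  if (t1 - t0 < 1200)
    stop("task shorter than twenty minutes: class windows undefined")
  list(early = c(t0, t0 + 600), late = c(t1 - 600, t1))
}

# Channel x chromophore selection for a design cell, in deterministic
# (layout order, O2Hb before HHb) column order.
designColumns <- function(layout, regionSet, chromophoreSet) {
  chans <- regionChannels(layout, regionSet)
  chroms <- if (chromophoreSet == "both") CHROMOPHORES else chromophoreSet
  expand.grid(channel_id = chans, chromophore = chroms,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Assemble the epoch feature table for one design cell
#'
#' For every subject, one-second epoch means are computed over the
#' early (\code{full_attention}) and late (\code{attention_decrement})
#' windows for each selected (channel, chromophore) pair. Feature
#' dimension is n_channels x n_chromophores: 3 or 4 for a single
#' chromophore over one region, up to 14 for both chromophores over
#' all seven channels. Row order is deterministic: subject, then
#' class (early before late), then epoch index.
#'
#' @param cohort a preprocessed [VigilanceCohort-class].
#' @param regionSet \code{"PFC"}, \code{"parietal"} or \code{"both"}.
#' @param chromophoreSet \code{"O2Hb"}, \code{"HHb"} or \code{"both"}.
#' @param epochS epoch duration, s.
#' @return an [EpochFeatureTable-class].
#' @export
buildFeatureTable <- function(cohort,
                              regionSet = c("PFC", "parietal", "both"),
                              chromophoreSet = c("O2Hb", "HHb", "both"),
                              epochS = 1) {
  regionSet <- match.arg(regionSet)
  chromophoreSet <- match.arg(chromophoreSet)
  blocks <- list()
  infos <- list()
  for (rec in cohort@recordings) {
    win <- labelWindows(rec@events)
    cols <- designColumns(rec@layout, regionSet, chromophoreSet)
    feat <- NULL
    for (k in seq_len(nrow(cols))) {
      series <- slot(rec, tolower(cols$chromophore[k]))[cols$channel_id[k], ]
      early <- segmentEpochs(series, rec@fs, win$early[1], win$early[2], epochS)
      late <- segmentEpochs(series, rec@fs, win$late[1], win$late[2], epochS)
      col <- c(early, late)
      if (is.null(feat))
        feat <- matrix(NA_real_, length(col), nrow(cols))
      feat[, k] <- col
    }
    nE <- length(feat[, 1]) / 2
    infos[[rec@subjectId]] <- data.frame(
      subject_id = rec@subjectId,
      epoch_index = c(seq_len(nE), seq_len(nE)),
      class = rep(CLASS_LABELS, each = nE),
      stringsAsFactors = FALSE)
    blocks[[rec@subjectId]] <- feat
  }
  cols <- designColumns(cohort@recordings[[1]]@layout, regionSet,
                        chromophoreSet)
  new("EpochFeatureTable",
      features = do.call(rbind, blocks),
      info = do.call(rbind, c(infos, list(make.row.names = FALSE))),
      featureNames = paste(cols$channel_id, cols$chromophore, sep = "."),
      regionSet = regionSet, chromophoreSet = chromophoreSet)
}

#' @describeIn buildFeatureTable number of feature columns.
#' @param table an \code{EpochFeatureTable}.
#' @export
nFeatures <- function(table) ncol(table@features)

#' @describeIn buildFeatureTable feature matrix accessor.
#' @export
featureMatrix <- function(table) {
  m <- table@features
  colnames(m) <- table@featureNames
  m
}

#' @describeIn buildFeatureTable epoch metadata accessor
#'   (\code{subject_id}, \code{epoch_index}, \code{class}).
#' @export
epochInfo <- function(table) table@info

setMethod("show", "EpochFeatureTable", function(object) {
  cat("EpochFeatureTable:", nrow(object@features), "epochs x",
      ncol(object@features), "features",
      sprintf("(%s, %s)\n", object@regionSet, object@chromophoreSet))
  tab <- table(object@info$class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "over", length(unique(object@info$subject_id)), "subjects\n")
})

#' Write / read a feature table as CSV
#'
#' Columns: \code{subject_id}, \code{epoch_index}, \code{class}, then
#' one column per (channel, chromophore) feature; header mandatory.
#'
#' @param table an [EpochFeatureTable-class].
#' @param path output CSV path.
#' @export
writeFeatureTable <- function(table, path) {
  df <- cbind(table@info, as.data.frame(featureMatrix(table)))
  data.table::fwrite(df, path)
  invisible(path)
}

#' @describeIn writeFeatureTable read back; region/chromophore sets are
#'   inferred from the feature columns.
#' @export
readFeatureTable <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  meta <- c("subject_id", "epoch_index", "class")
  if (!all(meta %in% names(df)))
    stop("feature CSV must contain subject_id, epoch_index, class")
  featCols <- setdiff(names(df), meta)
  parts <- strsplit(featCols, ".", fixed = TRUE)
  chroms <- unique(vapply(parts, `[`, character(1), 2))
  layout <- defaultChannelLayout()
  chans <- vapply(parts, `[`, character(1), 1)
  regions <- unique(layout@channels$region[match(unique(chans),
                                                 layout@channels$channel_id)])
  regionSet <- if (all(regions %in% PFC_REGIONS)) "PFC"
  else if (all(regions == "rParietal")) "parietal" else "both"
  new("EpochFeatureTable",
      features = as.matrix(df[, featCols, drop = FALSE]),
      info = df[, meta],
      featureNames = featCols,
      regionSet = regionSet,
      chromophoreSet = if (length(chroms) == 2L) "both" else chroms)
}
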