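#' Write a cohort to plain-text files
#'
#' Serializes a cohort into the on-disk exchange layout:
#' \itemize{
#'   \item \code{signals.csv} — long format: \code{subject_id},
#'     \code{channel_id}, \code{chromophore}, \code{time_s} (3
#'     decimals), \code{value_uM};
#'   \item \code{events.tsv} — \code{subject_id}, \code{label},
#'     \code{time_s};
#'   \item \code{trials.tsv} — \code{subject_id},
#'     \code{stimulus_time_s}, \code{response_onset_time_s} (empty for
#'     omissions);
#'   \item \code{truth_artifacts.tsv} — \code{subject_id},
#'     \code{channel_id}, \code{start_s}, \code{end_s}, \code{kind};
#'   \item \code{cohort.yaml} — the simulation configuration, its
#'     hash, the channel layout, and per-subject metadata.
#' }
#' The in-memory ground-truth clean series are deliberately not
#' serialized; [readCohort()] restores every on-disk field.
#'
#' @param cohort a [VigilanceCohort-class].
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- list(); ev <- list(); tr <- list(); art <- list()
  for (rec in cohort@recordings) {
    tS <- round((seq_len(ncol(rec@o2hb)) - 1) / rec@fs, 3)
    for (chrom in CHROMOPHORES) {
      mat <- slot(rec, tolower(chrom))
      sig[[paste(rec@subjectId, chrom)]] <- data.table::data.table(
        subject_id = rec@subjectId,
        channel_id = rep(rownames(mat), each = ncol(mat)),
        chromophore = chrom,
        time_s = rep(tS, nrow(mat)),
        value_uM = as.vector(t(mat)))
    }
    ev[[rec@subjectId]] <- data.table::data.table(
      subject_id = rec@subjectId, rec@events)
    tr[[rec@subjectId]] <- data.table::data.table(
      subject_id = rec@subjectId, rec@trials)
    if (nrow(rec@truth$artifacts))
      art[[rec@subjectId]] <- data.table::data.table(
        subject_id = rec@subjectId, rec@truth$artifacts)
  }
  data.table::fwrite(data.table::rbindlist(sig), file.path(dir, "signals.csv"))
  data.table::fwrite(data.table::rbindlist(ev), file.path(dir, "events.tsv"),
                     sep = "\t")
  data.table::fwrite(data.table::rbindlist(tr), file.path(dir, "trials.tsv"),
                     sep = "\t")
  artDt <- if (length(art)) data.table::rbindlist(art)
  else data.table::data.table(subject_id = character(),
                              channel_id = character(),
                              start_s = numeric(), end_s = numeric(),
                              kind = character())
  data.table::fwrite(artDt, file.path(dir, "truth_artifacts.tsv"), sep = "\t")
  meta <- list(
    config = configToList(cohort@config),
    config_hash = configHash(cohort@config),
    layout = list(
      separation_cm = cohort@recordings[[1]]@layout@separationCm,
      channels = cohort@recordings[[1]]@layout@channels),
    subjects = lapply(cohort@recordings, function(r)
      list(subject_id = r@subjectId, age = r@age,
           preprocessed = r@preprocessed)))
  yaml::write_yaml(meta, file.path(dir, "cohort.yaml"))
  invisible(dir)
}

requireFile <- function(dir, name) {
  p <- file.path(dir, name)
  if (!file.exists(p)) stop("missing cohort file: ", p)
  p
}

# Tolerant reader: known columns are required, unknown extra columns
# are dropped with a warning.
readTable <- function(path, required, sep = "auto") {
  dt <- data.table::fread(path, sep = sep)
  miss <- setdiff(required, names(dt))
  if (length(miss))
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "))
  extra <- setdiff(names(dt), required)
  if (length(extra)) {
    warning(basename(path), ": ignoring unknown column(s) ",
            paste(extra, collapse = ", "))
    dt <- dt[, required, with = FALSE]
  }
  dt
}

#' Read a cohort written by [writeCohort()]
#'
#' Unknown extra columns in the tables are ignored with a warning;
#' missing files or columns raise an error naming the file. When
#' \code{expectHash} is given, a cohort whose stored configuration
#' hash differs is refused — this is how pipeline stages detect
#' mismatched intermediates.
#'
#' @param dir directory produced by [writeCohort()].
#' @param expectHash optional configuration hash to enforce.
#' @return a [VigilanceCohort-class] (ground-truth clean series are
#'   not restored; artifact segments and effect parameters are).
#' @export
readCohort <- function(dir, expectHash = NULL) {
  meta <- yaml::read_yaml(requireFile(dir, "cohort.yaml"))
  if (!is.null(expectHash) && !identical(meta$config_hash, expectHash))
    stop("cohort in ", dir, " was produced by a different configuration (",
         meta$config_hash, " != ", expectHash, ")")
  config <- configFromList(meta$config)
  layout <- channelLayout(
    data.frame(channel_id = unlist(meta$layout$channels$channel_id),
               region = unlist(meta$layout$channels$region),
               label = unlist(meta$layout$channels$label),
               stringsAsFactors = FALSE),
    separationCm = meta$layout$separation_cm)

  sig <- readTable(requireFile(dir, "signals.csv"),
                   c("subject_id", "channel_id", "chromophore", "time_s",
                     "value_uM"))
  ev <- readTable(requireFile(dir, "events.tsv"),
                  c("subject_id", "label", "time_s"), sep = "\t")
  tr <- readTable(requireFile(dir, "trials.tsv"),
                  c("subject_id", "stimulus_time_s",
                    "response_onset_time_s"), sep = "\t")
  art <- readTable(requireFile(dir, "truth_artifacts.tsv"),
                   c("subject_id", "channel_id", "start_s", "end_s",
                     "kind"), sep = "\t")

  chIds <- layout@channels$channel_id
  recs <- lapply(meta$subjects, function(sub) {
    sid <- sub$subject_id
    s <- sig[sig$subject_id == sid, ]
    mats <- lapply(CHROMOPHORES, function(chrom) {
      sc <- s[s$chromophore == chrom, ]
      m <- do.call(rbind, lapply(chIds, function(ci) {
        rows <- sc[sc$channel_id == ci, ]
        rows$value_uM[order(rows$time_s)]
      }))
      rownames(m) <- chIds
      m
    })
    evS <- as.data.frame(ev[ev$subject_id == sid, c("label", "time_s")])
    trS <- as.data.frame(tr[tr$subject_id == sid,
                            c("stimulus_time_s", "response_onset_time_s")])
    artS <- as.data.frame(art[art$subject_id == sid,
                              c("channel_id", "start_s", "end_s", "kind")])
    rownames(evS) <- rownames(trS) <- rownames(artS) <- NULL
    new("SubjectRecording", subjectId = sid, age = sub$age,
        layout = layout, fs = config@fs,
        o2hb = mats[[1]], hhb = mats[[2]],
        events = evS, trials = trS,
        truth = list(artifacts = artS,
                     effect = list(
                       attention_effect = config@attentionEffect,
                       attention_effect_hhb =
                         if (all(is.na(config@attentionEffectHhb)))
                           config@hhbToO2hbRatio * config@attentionEffect
                         else config@attentionEffectHhb,
                       rt_mean_early = config@rtMeanEarly,
                       rt_mean_late = config@rtMeanLate)),
        preprocessed = isTRUE(sub$preprocessed))
  })
  new("VigilanceCohort", recordings = recs, config = config)
}
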