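#' Train a linear soft-margin support vector machine
#'
#' Minimizes 1/2 ||w||^2 + C * sum_i max(0, 1 - y_i (w.x_i + b)) via
#' sequential minimal optimization of the dual (see the package
#' vignette for the solver details). The bias is unregularized. Class
#' labels are encoded \code{full_attention = -1},
#' \code{attention_decrement = +1}; a numeric -1/+1 vector is also
#' accepted.
#'
#' @param x numeric feature matrix (rows = epochs) or an
#'   [EpochFeatureTable-class] (labels then come from its epoch info).
#' @param y class labels (ignored when \code{x} is a feature table).
#' @param C soft-margin regularization (default 1).
#' @param tol duality-gap stopping tolerance (default 1e-8).
#' @param maxIter iteration cap; a warning is raised if reached.
#' @return a [LinearSVM-class].
#' @export
#' @examples
#' x <- rbind(c(-1, 0), c(1, 0))
#' m <- trainLinearSVM(x, c(-1, 1))
#' predict(m, x)
trainLinearSVM <- function(x, y = NULL, C = 1, tol = 1e-8,
                           maxIter = 500000L) {
  if (is(x, "EpochFeatureTable")) {
    y <- x@info$class
    featNames <- x@featureNames
    x <- x@features
  } else {
    x <- as.matrix(x)
    featNames <- colnames(x)
    if (is.null(featNames)) featNames <- paste0("f", seq_len(ncol(x)))
  }
  if (C <= 0) stop("C must be positive")
  yNum <- encodeLabels(y)
  if (length(unique(yNum)) < 2L)
    stop("training data must contain both classes")
  fit <- smoLinearSvm(x, yNum, C, tol, as.integer(maxIter))
  if (!fit$converged)
    warning("SMO solver hit the iteration cap before reaching tolerance")
  # the C slot is assigned after construction: a named `C` argument to
  # new() would partially match its Class parameter
  model <- new("LinearSVM", weights = as.numeric(fit$w), bias = fit$b,
               featureNames = featNames,
               iterations = as.integer(fit$iterations),
               converged = fit$converged,
               dualObjective = fit$dual_objective)
  model@C <- C
  validObject(model)
  model
}

encodeLabels <- function(y) {
  if (is.numeric(y)) {
    if (!all(y %in% c(-1, 1))) stop("numeric labels must be -1/+1")
    return(as.numeric(y))
  }
  y <- as.character(y)
  if (!all(y %in% CLASS_LABELS))
    stop("labels must be full_attention/attention_decrement or -1/+1")
  ifelse(y == "attention_decrement", 1, -1)
}

#' @describeIn trainLinearSVM decision values w.x + b.
#' @param object a trained \code{LinearSVM}.
#' @param newdata feature matrix aligned with the training features.
#' @export
decisionValues <- function(object, newdata)
  as.numeric(as.matrix(newdata) %*% object@weights + object@bias)

#' Predict classes from a linear SVM
#'
#' Returns the sign of the decision value; ties (decision value
#' exactly zero) go to the positive class (\code{attention_decrement}).
#'
#' @param object a [LinearSVM-class].
#' @param newdata feature matrix.
#' @param type \code{"numeric"} for -1/+1, \code{"class"} for labels.
#' @return predictions, one per row of \code{newdata}.
#' @export
setMethod("predict", "LinearSVM",
  function(object, newdata, type = c("numeric", "class")) {
    type <- match.arg(type)
    p <- ifelse(decisionValues(object, newdata) >= 0, 1, -1)
    if (type == "class") CLASS_LABELS[(p + 3) / 2] else p
  })

#' Primal objective of a linear SVM on a dataset
#'
#' 1/2 ||w||^2 + C * sum of hinge losses; used to certify solver
#' optimality against independent quadratic-programming solutions.
#'
#' @param model a [LinearSVM-class].
#' @param x feature matrix.
#' @param y labels (-1/+1 or class labels).
#' @return numeric scalar.
#' @export
svmObjective <- function(model, x, y) {
  yNum <- encodeLabels(y)
  f <- decisionValues(model, x)
  0.5 * sum(model@weights^2) + model@C * sum(pmax(0, 1 - yNum * f))
}

setMethod("show", "LinearSVM", function(object) {
  cat("LinearSVM:", length(object@weights), "features, C =", object@C,
      "\n  |w| =", round(sqrt(sum(object@weights^2)), 4),
      " b =", round(object@bias, 4),
      " (", object@iterations, "SMO iterations,",
      if (object@converged) "converged" else "NOT converged", ")\n")
})

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject: the model trains on every other subject's
#' epochs and is scored on the held-out subject's, reporting the
#' percentage of correctly classified epochs overall and within each
#' class period. Train/test subject sets are asserted disjoint on
#' every fold.
#'
#' @param table an [EpochFeatureTable-class] covering >= 2 subjects,
#'   each with both classes.
#' @param C soft-margin regularization.
#' @param tol solver tolerance.
#' @return a [CVResult-class].
#' @export
losoCrossValidate <- function(table, C = 1, tol = 1e-8) {
  info <- table@info
  x <- table@features
  subjects <- unique(info$subject_id)
  if (length(subjects) < 2L) stop("leave-one-subject-out needs >= 2 subjects")
  for (s in subjects)
    if (length(unique(info$class[info$subject_id == s])) < 2L)
      stop("subject ", s, " is missing a class")
  y <- encodeLabels(info$class)
  perFold <- vector("list", length(subjects))
  nTrain <- NA_integer_
  for (i in seq_along(subjects)) {
    test <- info$subject_id == subjects[i]
    stopifnot(length(intersect(unique(info$subject_id[!test]),
                               unique(info$subject_id[test]))) == 0L)
    model <- trainLinearSVM(x[!test, , drop = FALSE], y[!test], C = C,
                            tol = tol)
    nTrain <- as.integer(sum(y[!test] == 1))
    pred <- predict(model, x[test, , drop = FALSE])
    yt <- y[test]
    perFold[[i]] <- data.frame(
      held_out_subject = subjects[i],
      acc_overall = 100 * mean(pred == yt),
      acc_full_attention = 100 * mean(pred[yt == -1] == -1),
      acc_attention_decrement = 100 * mean(pred[yt == 1] == 1),
      stringsAsFactors = FALSE)
  }
  perFold <- do.call(rbind, perFold)
  cv <- new("CVResult", perFold = perFold,
            meanAccuracy = mean(perFold$acc_overall),
            nTrainPerClass = nTrain,
            regionSet = table@regionSet,
            chromophoreSet = table@chromophoreSet)
  cv@C <- C
  cv
}

#' @describeIn losoCrossValidate per-fold accuracy table accessor.
#' @param result a \code{CVResult}.
#' @export
foldAccuracies <- function(result) result@perFold

#' @describeIn losoCrossValidate mean overall accuracy (percent).
#' @export
meanAccuracy <- function(result) result@meanAccuracy

setMethod("show", "CVResult", function(object) {
  cat("CVResult (", object@regionSet, ", ", object@chromophoreSet,
      "): mean accuracy ", round(object@meanAccuracy, 1), "% over ",
      nrow(object@perFold), " folds (", object@nTrainPerClass,
      " train epochs/class, C = ", object@C, ")\n", sep = "")
})

#' Evaluate the full region-by-chromophore design space
#'
#' Runs [losoCrossValidate()] for each of the nine cells of
#' \{PFC, parietal, both\} x \{O2Hb, HHb, both\}.
#'
#' @param cohort a preprocessed [VigilanceCohort-class].
#' @param C soft-margin regularization.
#' @param tol solver tolerance.
#' @param epochS epoch duration, s.
#' @return a [DesignSpaceResult-class].
#' @export
evaluateDesignSpace <- function(cohort, C = 1, tol = 1e-8, epochS = 1) {
  regionSets <- c("PFC", "parietal", "both")
  chromSets <- c("O2Hb", "HHb", "both")
  results <- list()
  rows <- list()
  for (r in regionSets) for (ch in chromSets) {
    tab <- buildFeatureTable(cohort, r, ch, epochS)
    cv <- losoCrossValidate(tab, C = C, tol = tol)
    key <- paste(r, ch, sep = "_")
    results[[key]] <- cv
    rows[[key]] <- data.frame(region_set = r, chromophore_set = ch,
                              n_features = nFeatures(tab),
                              mean_accuracy = cv@meanAccuracy,
                              stringsAsFactors = FALSE)
  }
  new("DesignSpaceResult", results = results,
      summary = do.call(rbind, c(rows, list(make.row.names = FALSE))))
}

#' @describeIn evaluateDesignSpace grid summary accessor (one row per
#'   cell: region, chromophore, feature count, mean accuracy).
#' @param grid a \code{DesignSpaceResult}.
#' @export
gridSummary <- function(grid) grid@summary

#' @describeIn evaluateDesignSpace single-cell [CVResult-class]
#'   accessor.
#' @param regionSet,chromophoreSet cell key.
#' @export
gridCell <- function(grid, regionSet, chromophoreSet)
  grid@results[[paste(regionSet, chromophoreSet, sep = "_")]]

setMethod("show", "DesignSpaceResult", function(object) {
  cat("DesignSpaceResult: mean LOSO accuracy (%) by design cell\n")
  s <- object@summary
  wide <- stats::reshape(s[, c("region_set", "chromophore_set",
                               "mean_accuracy")],
                         idvar = "region_set", timevar = "chromophore_set",
                         direction = "wide")
  print(format(wide, digits = 3), row.names = FALSE)
})
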