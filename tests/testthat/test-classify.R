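test_that("a symmetric two-point problem yields the midline hyperplane", {
  x <- rbind(c(-1, 0), c(1, 0))
  m <- trainLinearSVM(x, c(-1, 1))
  expect_equal(m@weights, c(1, 0), tolerance = 1e-8)
  expect_equal(m@bias, 0, tolerance = 1e-8)
  expect_equal(predict(m, x), c(-1, 1))
  expect_error(trainLinearSVM(x, c(1, 1)), "both classes")
  expect_error(trainLinearSVM(x, c(-1, 1), C = 0), "positive")
})

test_that("a hand-solvable three-point margin is recovered", {
  # Points: A(0,0) class -1; B(2,0), C(0,2) class +1. The max-margin
  # hyperplane is x + y = 1 (margin sqrt(2)/2): w = (1, 1), b = -1,
  # found by solving the hard-margin geometry by hand. C large enough
  # that the soft margin reproduces it.
  x <- rbind(c(0, 0), c(2, 0), c(0, 2))
  y <- c(-1, 1, 1)
  m <- trainLinearSVM(x, y, C = 100)
  expect_equal(m@weights, c(1, 1), tolerance = 1e-6)
  expect_equal(m@bias, -1, tolerance = 1e-6)
})

test_that("the non-separable XOR layout matches its analytic objective", {
  # XOR corners at (+-1, +-1), C = 1: by symmetry the optimum is
  # w = 0, b = 0 with all four hinge losses equal to 1, objective 4
  # (any w with |w| > 0 raises 0.5|w|^2 faster than it lowers the
  # symmetric hinge sum). Checked against the QP oracle too.
  x <- rbind(c(1, 1), c(-1, -1), c(1, -1), c(-1, 1))
  y <- c(1, 1, -1, -1)
  m <- trainLinearSVM(x, y, C = 1)
  expect_equal(svmObjective(m, x, y), 4, tolerance = 1e-6)
  oracle <- bruteForceSvmOracle(x, y, C = 1)
  expect_equal(svmObjective(m, x, y), oracle$primal, tolerance = 1e-6)
})

test_that("SMO matches a brute-force QP oracle on small random instances", {
  set.seed(99)
  worst <- 0
  for (rep in 1:15) {
    n <- sample(4:9, 1)
    d <- sample(1:2, 1)
    sep <- runif(1) < 0.5
    y <- c(rep(-1, ceiling(n / 2)), rep(1, floor(n / 2)))
    x <- matrix(rnorm(n * d), n, d)
    if (sep) x[y == 1, 1] <- x[y == 1, 1] + 4
    C <- sample(c(0.1, 1, 10), 1)
    m <- trainLinearSVM(x, y, C = C, tol = 1e-10)
    oracle <- bruteForceSvmOracle(x, y, C)
    obj <- svmObjective(m, x, y)
    # two-sided equivalence: neither solution beats the other
    expect_lt(abs(obj - oracle$primal), 1e-6)
    worst <- max(worst, abs(obj - oracle$primal))
  }
  # one larger instance at the enumeration limit
  n <- 12
  y <- rep(c(-1, 1), each = 6)
  x <- matrix(rnorm(n * 2), n, 2)
  m <- trainLinearSVM(x, y, C = 1, tol = 1e-10)
  oracle <- bruteForceSvmOracle(x, y, 1)
  expect_lt(abs(svmObjective(m, x, y) - oracle$primal), 1e-6)
  expect_lt(worst, 1e-4)
})

test_that("an independent SVM implementation agrees on a realistic instance", {
  skip_if_not_installed("e1071")
  set.seed(21)
  n <- 200
  x <- rbind(matrix(rnorm(n, -0.4), n / 2, 2), matrix(rnorm(n, 0.4), n / 2, 2))
  y <- rep(c(-1, 1), each = n / 2)
  m <- trainLinearSVM(x, y, C = 1)
  ref <- e1071::svm(x, factor(y), kernel = "linear", cost = 1,
                    scale = FALSE, tolerance = 1e-6)
  wRef <- as.numeric(t(ref$coefs) %*% ref$SV) * (-ref$labels[1])
  bRef <- -ref$rho * (-ref$labels[1])
  expect_equal(svmObjective(m, x, y),
               primalObjective(wRef, bRef, x, y, 1), tolerance = 1e-4)
})

test_that("increasing C converges to the hard-margin solution", {
  # separable instance: margin monotone in C; the hard-margin limit
  # satisfies |w| = 2 / (distance between the class convex hulls),
  # which a dense grid search over the hull segments provides as an
  # independent geometric oracle
  x <- rbind(c(-1, 0.3), c(-1.5, -0.2), c(1, -0.4), c(1.2, 0.5))
  y <- c(-1, -1, 1, 1)
  norms <- vapply(c(0.01, 0.1, 1, 1e6), function(C)
    sqrt(sum(trainLinearSVM(x, y, C = C)@weights^2)), numeric(1))
  expect_true(all(diff(norms) >= -1e-9))
  tt <- seq(0, 1, by = 1e-3)
  grid <- expand.grid(t = tt, s = tt)
  p <- cbind(-1 - 0.5 * grid$t, 0.3 - 0.5 * grid$t)
  q <- cbind(1 + 0.2 * grid$s, -0.4 + 0.9 * grid$s)
  hullDist <- sqrt(min(rowSums((p - q)^2)))
  m <- trainLinearSVM(x, y, C = 1e6)
  expect_equal(sqrt(sum(m@weights^2)), 2 / hullDist, tolerance = 1e-4)
})

test_that("ties go to the attention-decrement class", {
  m <- trainLinearSVM(rbind(c(-1, 0), c(1, 0)), c(-1, 1))
  expect_equal(predict(m, rbind(c(0, 0))), 1)
  expect_equal(predict(m, rbind(c(0, 0)), type = "class"),
               "attention_decrement")
})

test_that("LOSO folds are leakage-free with the expected bookkeeping", {
  cohort <- cachedQuietCohort(2)
  tab <- buildFeatureTable(cohort, "PFC", "O2Hb")
  cv <- losoCrossValidate(tab)
  pf <- foldAccuracies(cv)
  expect_equal(nrow(pf), 3)
  expect_setequal(pf$held_out_subject, subjectIds(cohort))
  # 3 subjects, 600 epochs per class: each fold trains on 1200/class
  expect_equal(cv@nTrainPerClass, 1200L)
  expect_true(all(pf$acc_overall >= 0 & pf$acc_overall <= 100))
  # per-class accuracies average to the overall (balanced classes)
  expect_equal(pf$acc_overall,
               (pf$acc_full_attention + pf$acc_attention_decrement) / 2,
               tolerance = 1e-9)
})

test_that("LOSO rejects degenerate subject sets", {
  cohort <- cachedQuietCohort(2)
  tab <- buildFeatureTable(cohort, "PFC", "O2Hb")
  one <- tab@info$subject_id == subjectIds(cohort)[1]
  sub <- new("EpochFeatureTable",
             features = tab@features[one, , drop = FALSE],
             info = tab@info[one, ], featureNames = tab@featureNames,
             regionSet = tab@regionSet, chromophoreSet = tab@chromophoreSet)
  expect_error(losoCrossValidate(sub), ">= 2 subjects")
  mut <- tab
  drop <- mut@info$subject_id == subjectIds(cohort)[1] &
    mut@info$class == "full_attention"
  mut@features <- mut@features[!drop, , drop = FALSE]
  mut@info <- mut@info[!drop, ]
  expect_error(losoCrossValidate(mut), "missing a class")
})

test_that("the design-space grid enumerates 3 x 3 cells deterministically", {
  cohort <- cachedQuietCohort(2)
  g1 <- evaluateDesignSpace(cohort)
  expect_equal(nrow(gridSummary(g1)), 9)
  expect_setequal(gridSummary(g1)$n_features, c(3, 3, 6, 4, 4, 8, 7, 7, 14))
  g2 <- evaluateDesignSpace(cohort)
  expect_identical(gridSummary(g1), gridSummary(g2))
  expect_s4_class(gridCell(g1, "parietal", "O2Hb"), "CVResult")
})

test_that("classification accuracy tracks the injected effect ordering", {
  # strong parietal O2Hb effect (>= 5x noise sd), none elsewhere, no
  # HHb counterpart: the parietal-O2Hb cell must beat the PFC-HHb cell.
  # Full-length task (the effect ramp saturates before the late
  # window); artifacts off so the classifier check is not confounded
  # by correction residue, which the preprocessing tests score
  accs <- vapply(1:3, function(s) {
    cfg <- simConfig(nSubjects = 3, seed = 100 + s, artifactRate = 0,
                     attentionEffect = c(lPFC = 0, mPFC = 0, rPFC = 0,
                                         rParietal = 0.75),
                     attentionEffectHhb = 0)
    cohort <- preprocessCohort(simulateCohort(cfg))
    c(meanAccuracy(losoCrossValidate(
        buildFeatureTable(cohort, "parietal", "O2Hb"))),
      meanAccuracy(losoCrossValidate(
        buildFeatureTable(cohort, "PFC", "HHb"))))
  }, numeric(2))
  expect_gt(mean(accs[1, ]), mean(accs[2, ]))
})
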