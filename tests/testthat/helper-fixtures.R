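# Shared fixtures: small cohorts built in code at test time.

# Compact cohort: 3 subjects, 20-minute task (the shortest for which
# the class windows are defined), default physiology.
smallConfig <- function(seed = 42, ...) {
  simConfig(nSubjects = 3, taskDuration = 1200, seed = seed, ...)
}

# Quiet generator: no artifacts, no attention effect, reduced noise.
# Overrides in ... take precedence over the quiet defaults.
quietConfig <- function(seed = 42, ...) {
  args <- utils::modifyList(
    list(nSubjects = 3, taskDuration = 1200, seed = seed,
         artifactRate = 0, attentionEffect = 0, driftSd = 0.02),
    list(...))
  do.call(simConfig, args)
}

# Cached preprocessed cohorts, keyed by seed, so several test files can
# share one simulation without recomputing it.
.fixtureCache <- new.env(parent = emptyenv())
cachedQuietCohort <- function(seed = 2) {
  key <- paste0("quiet", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <-
      preprocessCohort(simulateCohort(quietConfig(seed = seed)))
  .fixtureCache[[key]]
}

# Brute-force QP oracle for the linear soft-margin SVM, fully
# independent of the package's SMO path. Enumerates every partition of
# the points into {alpha = 0, free, alpha = C}; for each candidate free
# set solves the KKT equalities
#   y_i (w.x_i + b) = 1  (i free),   sum_i y_i alpha_i = 0
# for (alpha_free, b), checks box feasibility and the KKT inequalities
# on the remaining points, and keeps the feasible solution with the
# smallest primal objective. Exact for any instance; cost 3^n, so keep
# n <= 12.
bruteForceSvmOracle <- function(x, y, C, tol = 1e-7) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n <= 12)
  K <- x %*% t(x)
  best <- list(primal = Inf)
  code <- integer(n)
  repeat {
    F <- which(code == 1L)
    B <- which(code == 2L)
    alpha <- numeric(n)
    alpha[B] <- C
    feasible <- TRUE
    b <- NA_real_
    if (length(F)) {
      M <- rbind(cbind(sweep(K[F, F, drop = FALSE], 2, y[F], `*`), 1),
                 c(y[F], 0))
      offs <- if (length(B))
        as.numeric(K[F, B, drop = FALSE] %*% (C * y[B])) else 0
      rhs <- c(y[F] - offs, -C * sum(y[B]))
      sol <- try(solve(M, rhs), silent = TRUE)
      if (inherits(sol, "try-error") || any(!is.finite(sol))) {
        feasible <- FALSE
      } else {
        aF <- sol[seq_along(F)]
        b <- sol[length(sol)]
        if (any(aF < -tol | aF > C + tol)) feasible <- FALSE
        else alpha[F] <- pmin(pmax(aF, 0), C)
      }
    } else if (length(B) && abs(sum(y[B])) > tol) {
      feasible <- FALSE     # equality constraint violated
    }
    if (feasible) {
      w <- as.numeric(t(x) %*% (alpha * y))
      f0 <- as.numeric(x %*% w)
      if (is.na(b)) {
        # no free SVs: b sits at a hinge kink minimizing the loss
        cand <- y - f0
        hl <- vapply(cand, function(bb) sum(pmax(0, 1 - y * (f0 + bb))),
                     numeric(1))
        b <- cand[which.min(hl)]
      }
      marg <- y * (f0 + b)
      if (all(marg[code == 0L] >= 1 - 1e-6) &&
          all(marg[code == 2L] <= 1 + 1e-6)) {
        primal <- 0.5 * sum(w^2) + C * sum(pmax(0, 1 - marg))
        if (primal < best$primal)
          best <- list(w = w, b = b, alpha = alpha, primal = primal)
      }
    }
    # next base-3 code
    k <- 1L
    while (k <= n) {
      code[k] <- code[k] + 1L
      if (code[k] < 3L) break
      code[k] <- 0L
      k <- k + 1L
    }
    if (k > n) break
  }
  stopifnot(is.finite(best$primal))
  best
}

# Primal objective for arbitrary (w, b) on a dataset.
primalObjective <- function(w, b, x, y, C)
  0.5 * sum(w^2) + C * sum(pmax(0, 1 - y * (as.matrix(x) %*% w + b)))

# Amplitude of a sinusoid at frequency f in a series, by least-squares
# regression on sin/cos at that frequency.
sineAmplitude <- function(series, fs, f) {
  t <- (seq_along(series) - 1) / fs
  co <- stats::coef(stats::lm(series ~ sin(2 * pi * f * t) +
                                cos(2 * pi * f * t)))
  sqrt(co[2]^2 + co[3]^2)
}
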