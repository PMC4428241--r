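#' Classify genes as core, accessory or unobserved
#'
#' Over one cohort (one column per individual), a gene detected in every
#' individual is core; a gene detected in none is unobserved (specific to
#' the reference genome, never seen in the cohort); the remainder are
#' accessory.
#'
#' @param pm a [PresenceMatrix-class] with one column per individual
#'   (duplicate individual ids are an error; subset to primary samples
#'   first).
#' @return named factor over the reference genes with levels core,
#'   accessory, unobserved, plus a \code{summary} attribute with the three
#'   counts.
#' @export
classifyGenes <- function(pm) {
  p <- presence(pm)
  if (ncol(p) < 2L)
    stop("gene classification needs at least 2 individuals")
  if (anyDuplicated(individualIds(pm)))
    stop("columns must be one sample per individual; subset to primary ",
         "samples before classifying")
  k <- rowSums(p)
  lab <- factor(ifelse(k == ncol(p), "core",
                       ifelse(k == 0L, "unobserved", "accessory")),
                levels = c("core", "accessory", "unobserved"))
  names(lab) <- rownames(p)
  attr(lab, "summary") <- table(lab)
  lab
}

# distinct random k-subsets of 1..n by rejection
.sampleCombinations <- function(n, k, m, maxTries = 50L) {
  seen <- new.env(hash = TRUE)
  out <- vector("list", m)
  got <- 0L; tries <- 0L
  while (got < m && tries < maxTries * m) {
    tries <- tries + 1L
    s <- sort(sample.int(n, k))
    key <- paste(s, collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      got <- got + 1L
      out[[got]] <- s
    }
  }
  if (got < m)
    stop("failed to draw ", m, " distinct combinations of ", k, " from ", n)
  out
}

#' Subsample-based accessory fractions (rarefaction)
#'
#' For each subsample size k, draws subsets of individuals and computes the
#' fraction of genes missing in at least one subset member. The denominator
#' is fixed to the universe of genes observed in at least one of \emph{all}
#' cohort individuals, which makes the mean fraction provably non-decreasing
#' in k and lets k = n recover the cohort accessory fraction exactly. All
#' C(n, k) combinations are used when \code{maxCombinations} is NULL;
#' otherwise min(C(n, k), maxCombinations) distinct random combinations are
#' drawn under \code{seed}.
#'
#' @param pm a [PresenceMatrix-class], one column per individual.
#' @param sizes subsample sizes (default 2..n).
#' @param maxCombinations cap on combinations per size (NULL = exhaustive;
#'   500 mirrors the usual cap for larger cohorts).
#' @param seed seed used when combinations are subsampled.
#' @return data.frame with columns size, n_combinations, mean_fraction,
#'   median_fraction and a list-column fractions of the per-combination
#'   values.
#' @export
subsampleFractions <- function(pm, sizes = NULL, maxCombinations = NULL,
                               seed = 1L) {
  p <- presence(pm)
  n <- ncol(p)
  if (is.null(sizes)) sizes <- 2:n
  if (any(sizes > n)) stop("subsample size exceeds the number of individuals")
  if (any(sizes < 1L)) stop("subsample sizes must be >= 1")
  universe <- rowSums(p) > 0L
  U <- p[universe, , drop = FALSE]
  nu <- nrow(U)
  if (nu == 0L) stop("no gene is observed in any individual")
  if (!is.null(maxCombinations)) set.seed(seed)
  res <- lapply(sizes, function(k) {
    total <- choose(n, k)
    exhaustive <- is.null(maxCombinations) || total <= maxCombinations
    combos <- if (exhaustive) {
      asplit(utils::combn(n, k), 2L)
    } else {
      .sampleCombinations(n, k, maxCombinations)
    }
    fr <- vapply(combos, function(cc)
      sum(rowSums(U[, cc, drop = FALSE]) < k) / nu, numeric(1))
    list(size = k, n_combinations = length(combos), exhaustive = exhaustive,
         mean_fraction = mean(fr), median_fraction = stats::median(fr),
         fractions = fr)
  })
  out <- data.frame(size = vapply(res, `[[`, numeric(1), "size"),
                    n_combinations = vapply(res, `[[`, numeric(1),
                                            "n_combinations"),
                    mean_fraction = vapply(res, `[[`, numeric(1),
                                           "mean_fraction"),
                    median_fraction = vapply(res, `[[`, numeric(1),
                                             "median_fraction"))
  out$fractions <- I(lapply(res, `[[`, "fractions"))
  exh <- vapply(res, `[[`, logical(1), "exhaustive")
  ok <- order(out$size)
  d <- diff(out$mean_fraction[ok])
  if (all(exh)) {
    # provable under the fixed-universe denominator; a violation means a bug
    stopifnot("mean rarefaction fraction must be non-decreasing in k" =
                all(d >= -1e-12))
  } else if (any(d < -5e-3)) {
    # under combination subsampling monotonicity only holds in expectation;
    # warn when a drop is too large to be sampling noise
    warning("mean fraction decreases materially between sizes under ",
            "combination subsampling; consider raising maxCombinations")
  }
  out
}

.fitNls <- function(formula, data, starts, lower, upper, restarts = 20L) {
  best <- NULL
  err <- NULL
  for (r in seq_len(restarts + 1L)) {
    st <- if (r == 1L) starts else
      lapply(starts, function(v) v * stats::runif(1, 0.5, 2))
    fit <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) { err <- fit; next }
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop("nonlinear fit failed to converge after ", restarts, " restarts: ",
         conditionMessage(err))
  best
}

#' Fit a rarefaction model to subsample-based accessory fractions
#'
#' Least-squares fit of the per-size mean (or median) fraction versus
#' subsample size k under one of four model families:
#' \describe{
#'   \item{exponential}{f(k) = a - b exp(-k / c), b, c > 0; a is the finite
#'     asymptote.}
#'   \item{power_law}{f(k) = a k^b; unbounded for b > 0, so no asymptote —
#'     the value at the extrapolation \code{horizon} is reported instead.}
#'   \item{negative_exponential}{f(k) = a (1 - exp(-b k)); asymptote a.}
#'   \item{spline}{monotone cubic interpolant through the means; no
#'     asymptote, horizon value reported and flagged non-asymptotic.}
#' }
#' A constant table is handled as the degenerate exponential limit (b = 0,
#' asymptote equal to the constant). Nonlinear fits use analytic-start
#' Levenberg–Marquardt with up to 20 jittered restarts.
#'
#' @param table a data.frame from [subsampleFractions()] (columns size and
#'   mean_fraction / median_fraction).
#' @param model model family.
#' @param stat fit the per-size \code{"mean"} (default) or \code{"median"}.
#' @param horizon sample size at which non-asymptotic models are evaluated.
#' @return an [AccessoryModelFit-class].
#' @export
fitAccessoryModel <- function(table,
    model = c("exponential", "power_law", "negative_exponential", "spline"),
    stat = c("mean", "median"), horizon = 100) {
  model <- match.arg(model)
  stat <- match.arg(stat)
  ycol <- paste0(stat, "_fraction")
  k <- as.numeric(table$size)
  y <- as.numeric(table[[ycol]])
  keep <- is.finite(k) & is.finite(y)
  k <- k[keep]; y <- y[keep]
  if (length(k) < 3L)
    stop("model fitting needs at least 3 sizes with finite fractions")
  o <- order(k); k <- k[o]; y <- y[o]
  dat <- data.frame(k = k, y = y)

  if (model == "exponential") {
    if (diff(range(y)) < 1e-10) {
      a <- mean(y)
      pred <- local({ a0 <- a; function(kk) rep(a0, length(kk)) })
      return(new("AccessoryModelFit", modelName = model,
                 parameters = c(a = a, b = 0, c = 1), asymptote = a,
                 rss = sum((y - a)^2), horizon = horizon, horizonValue = a,
                 fittedSizes = k, fittedValues = y, predictor = pred))
    }
    a0 <- max(y) + 0.05
    resid <- pmax(a0 - y, 1e-8)
    ll <- stats::lm(log(resid) ~ k)
    c0 <- -1 / stats::coef(ll)[[2L]]
    if (!is.finite(c0) || c0 <= 0) c0 <- diff(range(k)) / 2
    b0 <- exp(stats::coef(ll)[[1L]])
    best <- .fitNls(y ~ a - b * exp(-k / c), dat,
                    starts = list(a = a0, b = b0, c = c0),
                    lower = c(a = 0, b = 1e-10, c = 1e-6),
                    upper = c(a = 2, b = 10, c = 1e4))
    cf <- stats::coef(best$fit)
    pred <- local({ p <- cf
      function(kk) p[["a"]] - p[["b"]] * exp(-kk / p[["c"]]) })
    new("AccessoryModelFit", modelName = model, parameters = cf,
        asymptote = unname(cf[["a"]]), rss = best$rss, horizon = horizon,
        horizonValue = pred(horizon), fittedSizes = k, fittedValues = y,
        predictor = pred)
  } else if (model == "power_law") {
    pos <- y > 0
    if (sum(pos) >= 2L) {
      ll <- stats::lm(log(y[pos]) ~ log(k[pos]))
      a0 <- exp(stats::coef(ll)[[1L]]); b0 <- stats::coef(ll)[[2L]]
    } else { a0 <- max(y, 1e-4); b0 <- 0.5 }
    best <- .fitNls(y ~ a * k^b, dat, starts = list(a = a0, b = b0),
                    lower = c(a = 1e-10, b = -5), upper = c(a = 2, b = 5))
    cf <- stats::coef(best$fit)
    pred <- local({ p <- cf; function(kk) p[["a"]] * kk^p[["b"]] })
    new("AccessoryModelFit", modelName = model, parameters = cf,
        asymptote = NA_real_, rss = best$rss, horizon = horizon,
        horizonValue = pred(horizon), fittedSizes = k, fittedValues = y,
        predictor = pred)
  } else if (model == "negative_exponential") {
    if (diff(range(y)) < 1e-10) {
      a <- mean(y)
      pred <- local({ a0 <- a; function(kk) rep(a0, length(kk)) })
      return(new("AccessoryModelFit", modelName = model,
                 parameters = c(a = a, b = Inf), asymptote = a,
                 rss = sum((y - a)^2), horizon = horizon, horizonValue = a,
                 fittedSizes = k, fittedValues = y, predictor = pred))
    }
    best <- .fitNls(y ~ a * (1 - exp(-b * k)), dat,
                    starts = list(a = max(y) * 1.1, b = 0.5),
                    lower = c(a = 1e-10, b = 1e-6), upper = c(a = 2, b = 100))
    cf <- stats::coef(best$fit)
    pred <- local({ p <- cf
      function(kk) p[["a"]] * (1 - exp(-p[["b"]] * kk)) })
    new("AccessoryModelFit", modelName = model, parameters = cf,
        asymptote = unname(cf[["a"]]), rss = best$rss, horizon = horizon,
        horizonValue = pred(horizon), fittedSizes = k, fittedValues = y,
        predictor = pred)
  } else { # spline
    f <- stats::splinefun(k, y, method = "monoH.FC")
    new("AccessoryModelFit", modelName = model, parameters = numeric(0),
        asymptote = NA_real_, rss = 0, horizon = horizon,
        horizonValue = f(horizon), fittedSizes = k, fittedValues = y,
        predictor = f)
  }
}

#' Accessory-gene percentage from a fitted rarefaction model
#'
#' Converts the fitted asymptote to a percentage (100 a). Because gene
#' insertions relative to the reference are invisible to a
#' reference-mapping approach, and the exponential family tends to
#' underestimate, the value is a lower bound on the true accessory
#' percentage. Power-law fits have no finite asymptote: the value at the
#' configured horizon is returned with a warning. Spline fits carry no
#' asymptote at all and raise an error pointing at the horizon value.
#'
#' @param fit an [AccessoryModelFit-class].
#' @return percentage of accessory genes (0--100 scale).
#' @export
estimateAccessoryPercent <- function(fit) {
  if (fit@modelName == "spline")
    stop("spline fits have no asymptote; use predict() or the horizon ",
         "value (fit@horizonValue) instead")
  if (fit@modelName == "power_law") {
    warning("power-law fits have no finite asymptote; returning the value ",
            "at the extrapolation horizon k = ", fit@horizon)
    return(100 * fit@horizonValue)
  }
  100 * fit@asymptote
}

#' Mean absolute deviation of a fitted model from expected fractions
#'
#' Scores an extrapolation model against the expected fractions — the same
#' subsample statistic computed on all available individuals (beyond the
#' analysis cohort). Returns the mean of |model(k) - expected mean(k)| over
#' the expected table's sizes, in percentage points.
#'
#' @param fit an [AccessoryModelFit-class].
#' @param expectedTable data.frame from [subsampleFractions()] computed on
#'   the full set of available individuals.
#' @param stat compare against the per-size \code{"mean"} (default) or
#'   \code{"median"}.
#' @return mean absolute deviation in percentage points.
#' @export
modelDeviation <- function(fit, expectedTable, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  if (nrow(expectedTable) == 0L)
    stop("expected table has no sizes to compare against")
  kk <- as.numeric(expectedTable$size)
  expv <- as.numeric(expectedTable[[paste0(stat, "_fraction")]])
  100 * mean(abs(predict(fit, kk) - expv))
}
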