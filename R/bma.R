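#' Standardize columns of a table
#'
#' Mean 0, SD 1 per column (sample SD, n - 1 denominator). Idempotent up
#' to floating point; a constant column is an error.
#'
#' @param table data.frame.
#' @param columns character vector of column names to standardize.
#' @return the table with the named columns standardized.
#' @export
standardizeColumns <- function(table, columns) {
  for (cn in columns) {
    x <- table[[cn]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) stop("cannot standardize constant column '", cn, "'")
    table[[cn]] <- (x - mean(x, na.rm = TRUE)) / s
  }
  table
}

# Log of the inverse-gamma(1/2, b) density at g (the Cauchy mixing law).
logInvGamma <- function(g, b) 0.5 * log(b) - lgamma(0.5) - 1.5 * log(g) - b / g

#' Zellner-Siow Bayes factor of a model against the null
#'
#' Computes the Bayes factor of a linear model with `p` predictors and
#' coefficient of determination `r2` against the intercept-only null,
#' under the JZS prior: a multivariate Cauchy on the standardized
#' coefficients, represented as a normal g-prior mixed over an
#' inverse-gamma(1/2, n r^2 / 2) distribution on g. The one-dimensional
#' g-integral
#' \deqn{BF = \int_0^\infty (1+g)^{(n-p-1)/2} (1 + g(1-R^2))^{-(n-1)/2} \pi(g)\, dg}
#' is evaluated by adaptive quadrature. `fixedG` replaces the mixture by
#' a point mass (closed-form check).
#'
#' @param r2 coefficient of determination in `[0, 1)`.
#' @param n number of observations (> p + 1).
#' @param p number of predictors in the model.
#' @param r JZS scale: 0.354 (medium, default), 0.5 (wide), 0.707
#'   (ultrawide).
#' @param fixedG optional fixed g, bypassing the mixture.
#' @return the Bayes factor versus the null model.
#' @export
#' @examples
#' zsModelBF(r2 = 0.3, n = 44, p = 2)
zsModelBF <- function(r2, n, p, r = 0.354, fixedG = NULL) {
  stopifnot(r2 >= 0, r2 < 1, n > p + 1, r > 0)
  if (p == 0L) return(1)
  logIntegrand0 <- function(g) {
    (n - p - 1) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2))
  }
  if (!is.null(fixedG)) return(exp(logIntegrand0(fixedG)))
  b <- n * r^2 / 2
  # substitute t = log(g): the integrand becomes smooth and light-tailed
  # on the whole real line, which keeps the quadrature stable even for
  # very small prior scales
  f <- function(t) {
    g <- exp(t)
    lv <- logIntegrand0(g) + logInvGamma(g, b) + t
    out <- exp(lv)
    out[!is.finite(g) | !is.finite(lv)] <- 0  # tails vanish; avoid Inf - Inf
    out
  }
  out <- stats::integrate(f, -Inf, Inf, rel.tol = 1e-8, stop.on.error = FALSE)
  if (!is.finite(out$value) || out$value <= 0) {
    stop("non-convergent quadrature in zsModelBF")
  }
  out$value
}

#' Enumerate the predictor-subset model space
#'
#' All 2^p predictor subsets with their prior probabilities: uniform
#' (each model 2^-p, per-predictor prior inclusion 0.5) or
#' beta-binomial(1, 1), where P(model with k predictors) =
#' 1 / ((p + 1) choose(p, k)), favouring no model size over another.
#'
#' @param predictors character vector of predictor names (p <= 20).
#' @param modelPrior "uniform" or "betabinomial".
#' @return data.frame with columns `model` (label), `k` (size),
#'   `prior_prob`, and a `members` list-column.
#' @export
enumerateModels <- function(predictors,
                            modelPrior = c("uniform", "betabinomial")) {
  modelPrior <- match.arg(modelPrior)
  p <- length(predictors)
  stopifnot(p <= 20)
  idx <- seq_len(2^p) - 1L
  members <- lapply(idx, function(m) predictors[bitwAnd(m, 2^(seq_len(p) - 1L)) > 0])
  k <- lengths(members)
  prior <- if (modelPrior == "uniform") {
    rep(1 / 2^p, length(idx))
  } else {
    1 / ((p + 1) * choose(p, k))
  }
  label <- vapply(members, function(m) {
    if (length(m) == 0L) "null" else paste(m, collapse = " + ")
  }, character(1))
  out <- data.frame(model = label, k = k, prior_prob = prior,
                    stringsAsFactors = FALSE)
  out$members <- members
  out
}

# Posterior weights over g for one model, on a shrinkage grid u = g/(1+g).
# Returns u grid and normalized weights.
gPosteriorGrid <- function(r2, n, p, r, nGrid = 400) {
  u <- (seq_len(nGrid) - 0.5) / nGrid
  g <- u / (1 - u)
  b <- n * r^2 / 2
  lw <- (n - p - 1) / 2 * log1p(g) - (n - 1) / 2 * log1p(g * (1 - r2)) +
    logInvGamma(g, b) - 2 * log(1 - u)  # Jacobian dg/du = 1/(1-u)^2
  w <- exp(lw - max(lw))
  list(u = u, w = w / sum(w))
}

#' Bayesian model averaging with the JZS prior
#'
#' Runs the full model-averaged regression: complete cases are taken, the
#' outcome is optionally log-transformed (before centring) and centred,
#' predictors are standardized, every predictor subset is fit by ordinary
#' least squares, its Bayes factor against the null is computed with
#' [zsModelBF()], and posterior model probabilities (prior times BF,
#' normalized) yield per-predictor inclusion statistics and model-averaged
#' coefficient moments. Models excluding a predictor contribute a point
#' mass at zero; the model-averaged SD follows from the law of total
#' variance and the central 95% credible interval from the posterior
#' mixture. Conditional on g, each model's coefficient posterior is the
#' shrunk least-squares solution (shrinkage g/(1+g)), integrated over the
#' posterior of g by quadrature, so the whole procedure is deterministic.
#'
#' @param table data.frame holding outcome and predictors.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor column names.
#' @param jzsScale JZS scale r (0.354 medium, 0.5 wide, 0.707 ultrawide).
#' @param modelPrior "uniform" or "betabinomial".
#' @param outcomeTransform "none" or "log" (log taken before centring).
#' @return a [BMAResult-class].
#' @export
modelAverage <- function(table, outcome, predictors,
                         jzsScale = 0.354,
                         modelPrior = c("uniform", "betabinomial"),
                         outcomeTransform = c("none", "log")) {
  modelPrior <- match.arg(modelPrior)
  outcomeTransform <- match.arg(outcomeTransform)
  dat <- table[, c(outcome, predictors), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  n <- nrow(dat)
  p <- length(predictors)
  if (n <= p + 2) stop("too few complete cases for the model space")
  y <- dat[[outcome]]
  if (outcomeTransform == "log") {
    if (any(y <= 0)) stop("log transform requires a positive outcome")
    y <- log(y)
  }
  yMean <- mean(y)
  yc <- y - yMean
  dat <- standardizeColumns(dat, predictors)
  X <- as.matrix(dat[, predictors, drop = FALSE])
  if (p > 0L && qr(X)$rank < p) {
    cc <- stats::cor(X)
    diag(cc) <- 0
    bad <- which(abs(cc) > 1 - 1e-8, arr.ind = TRUE)
    stop("singular design (perfect collinearity): ",
         paste(unique(predictors[bad[, 1L]]), collapse = ", "))
  }
  TSS <- sum(yc^2)

  models <- enumerateModels(predictors, modelPrior)
  nm <- nrow(models)
  models$r2 <- 0
  models$bf_vs_null <- 1
  fitList <- vector("list", nm)
  for (i in seq_len(nm)) {
    mem <- models$members[[i]]
    k <- length(mem)
    if (k == 0L) { fitList[[i]] <- list(beta = numeric(0)); next }
    Xi <- X[, mem, drop = FALSE]
    fit <- stats::lm.fit(Xi, yc)
    beta <- fit$coefficients
    ess <- TSS - sum(fit$residuals^2)
    r2 <- max(0, min(1 - 1e-12, ess / TSS))
    models$r2[i] <- r2
    models$bf_vs_null[i] <- zsModelBF(r2, n, k, jzsScale)
    fitList[[i]] <- list(beta = beta, XtXinv = solve(crossprod(Xi)), r2 = r2)
  }
  post <- models$prior_prob * models$bf_vs_null
  models$post_prob <- post / sum(post)

  # per-model posterior moments of each included coefficient
  meanM <- matrix(0, nrow = nm, ncol = p, dimnames = list(NULL, predictors))
  varM <- matrix(0, nrow = nm, ncol = p, dimnames = list(NULL, predictors))
  dfT <- n - 1
  for (i in seq_len(nm)) {
    mem <- models$members[[i]]
    k <- length(mem)
    if (k == 0L) next
    fi <- fitList[[i]]
    gq <- gPosteriorGrid(fi$r2, n, k, jzsScale)
    for (j in seq_along(mem)) {
      bj <- fi$beta[j]
      cjj <- fi$XtXinv[j, j]
      condMean <- gq$u * bj
      condVar <- gq$u * (TSS * (1 - gq$u * fi$r2) / dfT) * cjj * dfT / (dfT - 2)
      m1 <- sum(gq$w * condMean)
      m2 <- sum(gq$w * (condVar + condMean^2))
      meanM[i, mem[j]] <- m1
      varM[i, mem[j]] <- m2 - m1^2
    }
  }

  priorIncl <- vapply(predictors, function(pr) {
    sum(models$prior_prob[vapply(models$members, function(m) pr %in% m, logical(1))])
  }, numeric(1))
  postIncl <- vapply(predictors, function(pr) {
    sum(models$post_prob[vapply(models$members, function(m) pr %in% m, logical(1))])
  }, numeric(1))
  bfIncl <- inclusionBF(priorIncl, postIncl)

  wAvg <- models$post_prob
  coefMean <- colSums(wAvg * meanM)
  coefM2 <- colSums(wAvg * (varM + meanM^2))
  coefSd <- sqrt(pmax(0, coefM2 - coefMean^2))

  # central 95% CI from the posterior mixture (point mass at 0 for
  # excluding models, normal approximation within each including model)
  ciFor <- function(j) {
    pr <- predictors[j]
    inM <- vapply(models$members, function(m) pr %in% m, logical(1))
    lo <- min(-1e-3, meanM[, j] - 8 * sqrt(varM[, j]))
    hi <- max(1e-3, meanM[, j] + 8 * sqrt(varM[, j]))
    grid <- seq(lo, hi, length.out = 4001)
    Fm <- rep(0, length(grid))
    for (i in which(inM)) {
      Fm <- Fm + wAvg[i] * stats::pnorm(grid, meanM[i, j],
                                        sqrt(max(varM[i, j], 1e-300)))
    }
    Fm <- Fm + sum(wAvg[!inM]) * as.numeric(grid >= 0)
    c(grid[which.max(Fm >= 0.025)], grid[which.max(Fm >= 0.975)])
  }
  cis <- if (p > 0L) vapply(seq_len(p), ciFor, numeric(2)) else
    matrix(numeric(0), nrow = 2)

  seInt <- stats::sd(y) / sqrt(n)
  predTable <- data.frame(
    predictor = c("Intercept", predictors),
    p_incl = c(1, priorIncl),
    p_incl_data = c(1, postIncl),
    bf_inclusion = c(1, bfIncl),
    mean = c(yMean, coefMean),
    sd = c(seInt, coefSd),
    ci_lower = c(yMean + stats::qt(0.025, dfT) * seInt, cis[1L, ]),
    ci_upper = c(yMean + stats::qt(0.975, dfT) * seInt, cis[2L, ]),
    stringsAsFactors = FALSE
  )
  rownames(predTable) <- NULL

  new("BMAResult",
      models = models[, c("model", "k", "r2", "bf_vs_null", "prior_prob", "post_prob")],
      predictors = predTable,
      bestModel = models$model[which.max(models$post_prob)],
      config = list(jzsScale = jzsScale, modelPrior = modelPrior,
                    outcomeTransform = outcomeTransform, n = n,
                    outcome = outcome, predictorNames = predictors))
}

#' Inclusion Bayes factor from prior and posterior inclusion probabilities
#'
#' The change from prior to posterior inclusion odds:
#' BF_inclusion = (post / (1 - post)) / (prior / (1 - prior)). With the
#' uniform model prior (prior inclusion 0.50) a posterior inclusion of
#' 0.31 gives 0.45.
#'
#' @param priorIncl prior inclusion probability.
#' @param postIncl posterior inclusion probability.
#' @return the inclusion Bayes factor.
#' @export
#' @examples
#' inclusionBF(0.50, 0.31)  # 0.45
inclusionBF <- function(priorIncl, postIncl) {
  (postIncl / (1 - postIncl)) / (priorIncl / (1 - priorIncl))
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing predictor j on the remaining
#' predictors; perfect collinearity is reported as `Inf`.
#'
#' @param table data.frame.
#' @param predictors character vector of predictor column names.
#' @return named numeric vector of VIFs.
#' @export
vifScores <- function(table, predictors) {
  dat <- table[stats::complete.cases(table[, predictors, drop = FALSE]),
               predictors, drop = FALSE]
  stopifnot(nrow(dat) > length(predictors))
  vapply(predictors, function(pr) {
    others <- setdiff(predictors, pr)
    if (length(others) == 0L) return(1)
    fit <- stats::lm(stats::reformulate(others, response = pr), data = dat)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

#' Residual-normality gate
#'
#' Shapiro-Wilk test on model residuals; when normality is rejected at the
#' 0.05 level a log transform of the outcome is suggested (the standard
#' remedy when ITC outcomes produce right-skewed residuals).
#'
#' @param residuals numeric vector of residuals.
#' @param alpha rejection level (0.05).
#' @return list with `available`, `W`, `p_value`, `suggestLog`.
#' @export
residualNormalityGate <- function(residuals, alpha = 0.05) {
  residuals <- residuals[is.finite(residuals)]
  if (length(residuals) < 3L) {
    return(list(available = FALSE, W = NA_real_, p_value = NA_real_,
                suggestLog = NA))
  }
  sw <- stats::shapiro.test(residuals)
  list(available = TRUE, W = unname(sw$statistic), p_value = sw$p.value,
       suggestLog = sw$p.value < alpha)
}

#' Sensitivity harness over model and regression priors
#'
#' Reruns the model-averaged regression over the crossing of model priors
#' (uniform, beta-binomial) and JZS scales (0.354, 0.5, 0.707) and reports
#' the best model under each setting, plus whether the best model's
#' predictor set ever changes.
#'
#' @param table,outcome,predictors as in [modelAverage()].
#' @param outcomeTransform passed through.
#' @return list with `grid` (data.frame of settings and best models) and
#'   `stable` (logical).
#' @export
bmaSensitivity <- function(table, outcome, predictors,
                           outcomeTransform = "none") {
  settings <- expand.grid(modelPrior = c("uniform", "betabinomial"),
                          r = c(0.354, 0.5, 0.707),
                          stringsAsFactors = FALSE)
  best <- vapply(seq_len(nrow(settings)), function(i) {
    res <- modelAverage(table, outcome, predictors,
                        jzsScale = settings$r[i],
                        modelPrior = settings$modelPrior[i],
                        outcomeTransform = outcomeTransform)
    res@bestModel
  }, character(1))
  settings$best_model <- best
  list(grid = settings, stable = length(unique(best)) == 1L)
}
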