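#' Enumerate estimable genetic-architecture models
#'
#' A model is a subset of the c-matrix effects (the grand mean is implicit
#' in every model, including the empty one).  A subset is estimable when
#' the design matrix — intercept column plus the selected c-matrix columns
#' — has full column rank.  Rank is judged by singular values with a
#' relative cutoff of `tol` times the largest singular value; the
#' dependencies of the standard five-cohort design (e.g. `AdAd` is
#' proportional to `Ad`; `AaCa` equals `1 - Aa + Ca` row-wise) are exact
#' rationals, far from the cutoff.
#'
#' @param cm a [cmatrix()].
#' @param max_effects largest subset size; defaults to
#'   `nrow(cm) - 1` (one fewer than the number of cohorts, so no model has
#'   more parameters than data points).
#' @param tol relative singular-value cutoff for the rank test.
#' @return list of character vectors (effect subsets), ordered by size
#'   then lexicographically within size; the first element is the
#'   intercept-only model `character(0)`.
#' @examples
#' length(enumerate_models(cmatrix(solanum_pedigree())))  # 243
#' @export
enumerate_models <- function(cm, max_effects = nrow(cm) - 1L, tol = 1e-8) {
  if (nrow(cm) < 2L)
    stop("c-matrix must have at least two cohorts", call. = FALSE)
  effects <- sort(colnames(cm))
  models <- list(character(0))
  for (k in seq_len(min(max_effects, length(effects)))) {
    subsets <- utils::combn(effects, k, simplify = FALSE)
    keep <- vapply(subsets, function(s) {
      X <- cbind(1, unclass(cm)[, s, drop = FALSE])
      d <- svd(X, nu = 0L, nv = 0L)$d
      d[length(d)] > tol * d[1L]
    }, NA)
    models <- c(models, subsets[keep])
  }
  models
}

#' Fit one architecture model by weighted least squares
#'
#' Cohort means are regressed on the selected c-matrix columns (plus
#' intercept) with the cohort SEs treated as known measurement standard
#' deviations, i.e. generalized least squares with diagonal weights
#' `1/se^2`.  Parameter standard errors come from the weighted normal
#' equations without a residual-variance rescale, consistent with the
#' known-variance likelihood used for AICc.
#'
#' @param effects character vector of effect labels (possibly empty for
#'   the intercept-only model).
#' @param cm a [cmatrix()] whose rows define the cohort order.
#' @param summaries cohort-summary data frame for a single trait, with one
#'   row per c-matrix cohort and strictly positive `se`.
#' @return list of class `"lca_fit"`: `effects`, `coef` (named, first
#'   element `"(Intercept)"`), `se`, `wrss` (weighted residual sum of
#'   squares), `loglik`, `K` (intercept + effects), `aicc`, `fitted`.
#' @examples
#' cm <- cmatrix(solanum_pedigree())
#' s <- data.frame(cohort = rownames(cm), trait = "t",
#'                 mean = c(14, 6, 10, 12, 8), se = 0.5)
#' fit_model("Aa", cm, s)$coef  # intercept 10, Aa 4, wrss 0
#' @export
fit_model <- function(effects, cm, summaries) {
  stopifnot(is.character(effects) || length(effects) == 0L)
  effects <- as.character(effects)
  bad <- setdiff(effects, colnames(cm))
  if (length(bad))
    stop("effect(s) not in c-matrix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  s <- summaries[match(rownames(cm), summaries$cohort), ]
  if (any(is.na(s$mean)))
    stop("missing cohort summaries for: ",
         paste(setdiff(rownames(cm), summaries$cohort), collapse = ", "),
         call. = FALSE)
  if (any(s$se <= 0))
    stop("all cohort SEs must be positive; supply a positive SE for ",
         paste(s$cohort[s$se <= 0], collapse = ", "), call. = FALSE)
  y <- s$mean
  w <- 1 / s$se^2
  X <- cbind("(Intercept)" = 1, unclass(cm)[, effects, drop = FALSE])
  sw <- sqrt(w)
  qrx <- qr(X * sw)
  if (qrx$rank < ncol(X))
    stop("singular design for model {", paste(effects, collapse = ", "),
         "}: not estimable for this c-matrix", call. = FALSE)
  beta <- qr.coef(qrx, y * sw)
  XtWXi <- chol2inv(qr.R(qrx))
  fitted <- drop(X %*% beta)
  wrss <- sum(w * (y - fitted)^2)
  loglik <- -0.5 * (wrss + sum(log(2 * pi * s$se^2)))
  K <- length(beta)
  fit <- structure(
    list(effects = effects, coef = beta,
         se = stats::setNames(sqrt(diag(XtWXi)), names(beta)),
         wrss = wrss, loglik = loglik, K = K,
         fitted = stats::setNames(fitted, rownames(cm)),
         n = nrow(cm)),
    class = "lca_fit")
  fit$aicc <- aicc(fit$loglik, fit$K, fit$n)
  fit
}

#' Small-sample-corrected AIC
#'
#' `AICc = -2*loglik + 2K + 2K(K+1)/(n - K - 1)`, with `K` the number of
#' regression parameters (intercept plus effects; the cohort variances are
#' known, not estimated) and `n` the number of cohorts.  When
#' `n - K - 1 <= 0` the correction is undefined and the model receives an
#' `Inf` sentinel: it stays listed in the model space but gets zero
#' Akaike weight.
#'
#' @param loglik Gaussian known-variance log-likelihood (or an
#'   `"lca_fit"`, from which `loglik` and `K` are taken).
#' @param K number of regression parameters.
#' @param n number of cohorts.
#' @return the AICc value, possibly `Inf`.
#' @export
aicc <- function(loglik, K, n) {
  if (inherits(loglik, "lca_fit")) {
    fit <- loglik
    if (missing(n)) n <- fit$n
    K <- fit$K
    loglik <- fit$loglik
  }
  if (n - K - 1 <= 0) return(Inf)
  -2 * loglik + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' @export
print.lca_fit <- function(x, ...) {
  cat("WLS architecture model {",
      if (length(x$effects)) paste(x$effects, collapse = ", ") else "grand mean only",
      "}\n", sep = "")
  print(rbind(estimate = x$coef, se = x$se), ...)
  cat(sprintf("weighted RSS %.4g, logLik %.4g, K %d, AICc %s\n",
              x$wrss, x$loglik, x$K, format(x$aicc, digits = 6)))
  invisible(x)
}

#' Fit the full model space for one trait
#'
#' Enumerates every estimable model (see [enumerate_models()]) and fits
#' each by weighted least squares, the first stage of the
#' information-theoretic line cross analysis.
#'
#' @inheritParams fit_model
#' @inheritParams enumerate_models
#' @return list of class `"lca_model_space"`: `fits` (list of
#'   [fit_model()] results in enumeration order), `cm`, `summaries`, and
#'   `table`, a data frame with one row per model (`model`, `K`, `wrss`,
#'   `loglik`, `aicc`).
#' @export
fit_model_space <- function(cm, summaries, max_effects = nrow(cm) - 1L,
                            tol = 1e-8) {
  models <- enumerate_models(cm, max_effects = max_effects, tol = tol)
  fits <- lapply(models, fit_model, cm = cm, summaries = summaries)
  tab <- data.frame(
    model = vapply(models, function(m)
      if (length(m)) paste(m, collapse = "+") else "(Intercept)", ""),
    K = vapply(fits, `[[`, 0L, "K"),
    wrss = vapply(fits, `[[`, 0, "wrss"),
    loglik = vapply(fits, `[[`, 0, "loglik"),
    aicc = vapply(fits, `[[`, 0, "aicc"),
    stringsAsFactors = FALSE)
  structure(list(fits = fits, cm = cm, summaries = summaries, table = tab),
            class = "lca_model_space")
}

#' @export
print.lca_model_space <- function(x, n = 10L, ...) {
  cat("Model space:", nrow(x$table), "estimable models on",
      nrow(x$cm), "cohorts\n")
  ord <- order(x$table$aicc)
  print(utils::head(x$table[ord, ], n), row.names = FALSE)
  invisible(x)
}
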