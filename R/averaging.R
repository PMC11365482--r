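#' Akaike weights and the confidence set of models
#'
#' Converts per-model AICc values into Akaike weights
#' `w_i = exp(-delta_i/2) / sum_j exp(-delta_j/2)` with
#' `delta_i = AICc_i - min(AICc)`, taken over the finite-AICc models;
#' infinite-AICc models keep weight 0.  The confidence set is the smallest
#' prefix of the weight-sorted models whose cumulative weight reaches
#' `level` (ties in AICc are broken by model order, so the set is
#' deterministic).
#'
#' @param mspace an `"lca_model_space"` from [fit_model_space()], or a
#'   bare numeric vector of AICc values.
#' @param level confidence level of the model set (default 0.95).
#' @return list of class `"lca_weights"`: `delta`, `weight`,
#'   `in_confidence_set` (all in model order), `order` (weight-sorted
#'   indices), `cumulative` (cumulative weight in sorted order), `level`,
#'   and the originating `mspace` (if supplied).
#' @examples
#' akaike_weights(c(10, 12))$weight  # 0.731, 0.269
#' @export
akaike_weights <- function(mspace, level = 0.95) {
  if (level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  aic <- if (inherits(mspace, "lca_model_space")) mspace$table$aicc
         else as.numeric(mspace)
  finite <- is.finite(aic)
  if (!any(finite))
    stop("no model has finite AICc; nothing to weight", call. = FALSE)
  delta <- aic - min(aic[finite])
  w <- ifelse(finite, exp(-delta / 2), 0)
  w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)        # stable: ties keep model order
  cum <- cumsum(w[ord])
  n_set <- which(cum >= level)[1L]
  flags <- logical(length(w))
  flags[ord[seq_len(n_set)]] <- TRUE
  structure(list(delta = delta, weight = w, in_confidence_set = flags,
                 order = ord, cumulative = cum, level = level,
                 mspace = if (inherits(mspace, "lca_model_space")) mspace),
            class = "lca_weights")
}

#' @export
print.lca_weights <- function(x, ...) {
  cat(sprintf("Akaike weights over %d models; %d in the %g%% confidence set\n",
              length(x$weight), sum(x$in_confidence_set), 100 * x$level))
  invisible(x)
}

#' Model-averaged composite effect estimates
#'
#' Averages each effect over the models of the confidence set with
#' renormalized weights and zero-substitution: a model that omits the
#' effect contributes an estimate of 0 (with SE 0), so averaged estimates
#' are shrunk in proportion to the evidence against the effect.  The
#' unconditional standard error folds model-selection uncertainty into the
#' parameter uncertainty:
#' `use = sum_i w_i * sqrt(se_i^2 + (beta_i - betabar)^2)`.
#' Variable importance is the summed (renormalized) weight of
#' confidence-set models containing the effect.
#'
#' @param wset an `"lca_weights"` object carrying its model space.
#' @param scope `"confidence"` (default) renormalizes weights over the
#'   confidence set; `"all"` averages over every finite-AICc model with
#'   the full-set weights.
#' @return data frame of class `"lca_averaged"`, one row per c-matrix
#'   effect: `effect`, `estimate`, `unconditional_se`,
#'   `variable_importance`, `included` (`NA` until
#'   [apply_inclusion_criteria()] is applied).
#' @export
model_average <- function(wset, scope = c("confidence", "all")) {
  stopifnot(inherits(wset, "lca_weights"))
  scope <- match.arg(scope)
  if (is.null(wset$mspace))
    stop("model_average() needs weights computed from a model space",
         call. = FALSE)
  fits <- wset$mspace$fits
  keep <- if (scope == "confidence") wset$in_confidence_set
          else wset$weight > 0
  w <- wset$weight[keep] / sum(wset$weight[keep])
  fits <- fits[keep]
  effects <- colnames(wset$mspace$cm)
  avg <- lapply(effects, function(e) {
    beta <- vapply(fits, function(f)
      if (e %in% f$effects) unname(f$coef[e]) else 0, 0)
    se <- vapply(fits, function(f)
      if (e %in% f$effects) unname(f$se[e]) else 0, 0)
    vi <- sum(w[vapply(fits, function(f) e %in% f$effects, NA)])
    est <- sum(w * beta)
    use <- sum(w * sqrt(se^2 + (beta - est)^2))
    data.frame(effect = e, estimate = est, unconditional_se = use,
               variable_importance = vi, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, avg)
  out$included <- NA
  attr(out, "confidence_set_size") <- sum(wset$in_confidence_set)
  attr(out, "scope") <- scope
  class(out) <- c("lca_averaged", "data.frame")
  out
}

#' Inclusion criteria for averaged effects
#'
#' An effect is retained when its variable importance strictly exceeds
#' `vi_threshold` *and* its averaged estimate differs from zero by
#' strictly more than `se_multiplier` unconditional standard errors (so a
#' `+/- 1 SE` interval excluding zero, by default).
#'
#' @param avg an `"lca_averaged"` table from [model_average()].
#' @param vi_threshold minimum variable importance (default 0.5).
#' @param se_multiplier width of the zero-exclusion interval in
#'   unconditional SEs (default 1).
#' @return `avg` with the `included` column filled in.
#' @export
apply_inclusion_criteria <- function(avg, vi_threshold = 0.5,
                                     se_multiplier = 1) {
  stopifnot(inherits(avg, "lca_averaged"))
  avg$included <- avg$variable_importance > vi_threshold &
    abs(avg$estimate) - se_multiplier * avg$unconditional_se > 0
  avg
}

#' Pool included effects into architecture proportions
#'
#' Each included effect contributes the absolute value of its averaged
#' estimate; contributions are scaled to sum to one and pooled by mode of
#' gene action: `Aa` and `Ca` are additive, `Ad` dominance, the five
#' two-way interactions epistatic, and `Mea`/`Med` maternal (maternal
#' effects are reported only in the maternal column, not under
#' additive/dominance).  When nothing passes the inclusion criteria all
#' proportions are `NA`: no architecture can be inferred for the trait.
#'
#' @param avg an `"lca_averaged"` table with `included` filled in.
#' @param trait trait label for the summary row.
#' @return one-row data frame of class `"lca_architecture"`: `trait`,
#'   `additive`, `dominance`, `epistatic`, `maternal`,
#'   `confidence_set_size`.
#' @examples
#' # two included effects with |estimates| 3 (Ca) and 4 (AaAa):
#' # additive 3/7, epistatic 4/7
#' @export
pool_effects <- function(avg, trait = "trait") {
  stopifnot(inherits(avg, "lca_averaged"))
  if (any(is.na(avg$included)))
    stop("apply_inclusion_criteria() before pooling", call. = FALSE)
  inc <- avg[avg$included, , drop = FALSE]
  cats <- c("additive", "dominance", "epistatic", "maternal")
  if (!nrow(inc)) {
    props <- stats::setNames(rep(NA_real_, 4L), cats)
  } else {
    contrib <- abs(inc$estimate) / sum(abs(inc$estimate))
    cat_of <- EFFECT_CATEGORY[inc$effect]
    props <- vapply(cats, function(cc) sum(contrib[cat_of == cc]), 0)
  }
  out <- data.frame(trait = trait, t(props),
                    confidence_set_size = attr(avg, "confidence_set_size") %||%
                      NA_integer_,
                    stringsAsFactors = FALSE)
  class(out) <- c("lca_architecture", "data.frame")
  out
}
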