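test_that("Akaike weights follow exp(-delta/2) and normalize", {
  w <- akaike_weights(c(10, 10))
  expect_equal(w$weight, c(0.5, 0.5))
  w <- akaike_weights(c(10, 12))
  expect_equal(w$weight, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w$weight, 3), c(0.731, 0.269))
  expect_equal(min(w$delta), 0)
  # infinite-AICc models keep zero weight but stay listed
  w <- akaike_weights(c(3, Inf, 5))
  expect_equal(sum(w$weight), 1)
  expect_equal(w$weight[2], 0)
  expect_false(w$in_confidence_set[2])
  expect_error(akaike_weights(c(Inf, Inf)), "finite")
})

test_that("the confidence set is the minimal weight-ordered prefix", {
  set.seed(21)
  for (rep in 1:20) {
    a <- rnorm(sample(3:40, 1), sd = 3)
    w <- akaike_weights(a, level = 0.95)
    expect_equal(sum(w$weight), 1)
    in_w <- sum(w$weight[w$in_confidence_set])
    expect_gte(in_w, 0.95)
    # dropping the lightest member of the set falls below the level
    members <- which(w$in_confidence_set)
    if (length(members) > 1) {
      lightest <- members[which.min(w$weight[members])]
      expect_lt(in_w - w$weight[lightest], 0.95)
    }
    # the set is the top of the weight ordering
    expect_true(all(w$weight[w$in_confidence_set] >=
                      max(0, w$weight[!w$in_confidence_set])))
  }
  # a single model is its own confidence set with weight 1
  w1 <- akaike_weights(4.2)
  expect_equal(w1$weight, 1)
  expect_equal(sum(w1$in_confidence_set), 1L)
})

test_that("model averaging zero-substitutes absent effects", {
  cm <- cmatrix(solanum_pedigree())
  # near-tied Aa architectures so the confidence set holds several models
  s <- summary_for(cm, c(14, 6, 10.05, 11.9, 8.1), se = 0.3)
  w <- akaike_weights(fit_model_space(cm, s, max_effects = 2))
  avg <- model_average(w)
  expect_equal(nrow(avg), ncol(cm))
  # an effect in every confidence-set model has VI 1; Aa dominates here
  expect_gt(avg$variable_importance[avg$effect == "Aa"], 0.95)
  expect_true(all(avg$variable_importance >= 0 &
                    avg$variable_importance <= 1))
  # the averaged estimate is shrunk toward 0 relative to conditional ones
  fits <- w$mspace$fits[w$in_confidence_set]
  cond <- vapply(fits, function(f)
    if ("Med" %in% f$effects) unname(f$coef["Med"]) else NA_real_, 0)
  if (any(!is.na(cond))) {
    est <- avg$estimate[avg$effect == "Med"]
    expect_lte(abs(est), max(abs(cond), na.rm = TRUE))
  }
})

test_that("two equal-weight models average an effect present in one of them", {
  # hand-built weight set: equal AICc, effect estimate 4 in one model only
  cm <- cmatrix(solanum_pedigree(), cohorts = c("P1", "P2"), effects = "Aa")
  s <- summary_for(cm, c(10, 2))
  ms <- fit_model_space(cm, s, max_effects = 1)
  # force equal weights by overwriting the AICc column (the averaging
  # machinery only consumes aicc, coef and se)
  ms$table$aicc <- c(0, 0)
  w <- akaike_weights(ms, level = 0.999)
  expect_equal(w$weight, c(0.5, 0.5))
  avg <- model_average(w)
  i <- avg$effect == "Aa"
  expect_equal(avg$estimate[i], 0.5 * unname(ms$fits[[2]]$coef["Aa"]))
  expect_equal(avg$variable_importance[i], 0.5)
  # the unconditional SE folds in the between-model spread
  b <- unname(ms$fits[[2]]$coef["Aa"]); se_b <- unname(ms$fits[[2]]$se["Aa"])
  expect_equal(avg$unconditional_se[i],
               0.5 * abs(0 - b / 2) + 0.5 * sqrt(se_b^2 + (b - b / 2)^2))
})

test_that("inclusion needs variable importance > 0.5 and a zero-free interval", {
  avg <- structure(
    data.frame(effect = c("Aa", "Ad", "Ca", "Mea"),
               estimate = c(2.0, 1.0, 5.0, 2.0),
               unconditional_se = c(1.0, 1.5, 0.5, 1.0),
               variable_importance = c(0.9, 0.9, 0.26, 0.5),
               included = NA),
    class = c("lca_averaged", "data.frame"))
  out <- apply_inclusion_criteria(avg)
  expect_equal(out$included, c(TRUE, FALSE, FALSE, FALSE))
  # both criteria are strict: VI 0.26 fails however large the estimate,
  # VI exactly at the threshold fails, an interval touching zero fails
  border <- avg
  border$estimate <- c(2, 2, 2, 2)
  border$unconditional_se <- c(2, 1, 1, 1)
  out2 <- apply_inclusion_criteria(border)
  expect_equal(out2$included, c(FALSE, TRUE, FALSE, FALSE))
  # the SE multiplier is a knob: a 2 +/- 1.2 estimate clears a 1-SE
  # interval but not a 1.96-SE one
  knob <- avg
  knob$unconditional_se <- c(1.2, 1.5, 0.5, 1.0)
  expect_true(apply_inclusion_criteria(knob)$included[1])
  expect_false(apply_inclusion_criteria(knob, se_multiplier = 1.96)$included[1])
})

test_that("pooled architecture proportions are scaled absolute contributions", {
  mk <- function(effects, est, vi = 0.9, se = 1e-6, css = 3L) {
    avg <- structure(
      data.frame(effect = effects, estimate = est, unconditional_se = se,
                 variable_importance = vi, included = NA),
      class = c("lca_averaged", "data.frame"),
      confidence_set_size = css)
    apply_inclusion_criteria(avg)
  }
  # |Ca| = 3 additive and |AaAa| = 4 epistatic: 3/7 vs 4/7
  arch <- pool_effects(mk(c("Ca", "AaAa"), c(3, -4)), trait = "area")
  expect_equal(arch$additive, 3 / 7)
  expect_equal(arch$epistatic, 4 / 7)
  expect_equal(arch$dominance, 0)
  expect_equal(arch$maternal, 0)
  expect_equal(arch$confidence_set_size, 3L)
  # a single included effect takes its whole category
  arch1 <- pool_effects(mk("Aa", 2.2), trait = "length")
  expect_equal(arch1$additive, 1)
  # maternal effects pool only into the maternal column
  archm <- pool_effects(mk(c("Mea", "AaAd"), c(1, -1)), trait = "width")
  expect_equal(archm$maternal, 0.5)
  expect_equal(archm$epistatic, 0.5)
  expect_equal(archm$additive, 0)
  # nothing included: the all-NA row
  none <- mk("Aa", 0.001, vi = 0.2)
  archna <- pool_effects(none, trait = "areal_ratio")
  expect_true(all(is.na(
    archna[c("additive", "dominance", "epistatic", "maternal")])))
})

test_that("proportions sum to one whenever anything is included", {
  set.seed(31)
  cm <- cmatrix(solanum_pedigree())
  for (rep in 1:15) {
    beta <- stats::setNames(numeric(10), colnames(cm))
    beta[sample(10, 2)] <- rnorm(2, 0, 3)
    y <- expected_cohort_means(cm, 10, beta) + rnorm(5, 0, 0.2)
    res <- lca(summary_for(cm, y, se = 0.2), cm)
    arch <- res$architecture
    p <- as.numeric(arch[c("additive", "dominance", "epistatic", "maternal")])
    if (!any(is.na(p))) expect_equal(sum(p), 1, tolerance = 1e-12)
    vi <- res$traits[[1]]$averaged$variable_importance
    expect_true(all(vi >= 0 & vi <= 1 + 1e-12))
  }
})

test_that("full-set weight scope is available as a convention switch", {
  cm <- cmatrix(solanum_pedigree())
  s <- summary_for(cm, c(14, 6, 10.1, 11.9, 8.2), se = 0.4)
  w <- akaike_weights(fit_model_space(cm, s, max_effects = 2))
  a_conf <- model_average(w, scope = "confidence")
  a_all <- model_average(w, scope = "all")
  expect_equal(attr(a_conf, "scope"), "confidence")
  expect_equal(attr(a_all, "scope"), "all")
  # both are valid VI definitions; they need not agree numerically
  expect_true(all(a_all$variable_importance >= 0 &
                    a_all$variable_importance <= 1))
})
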