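#' Expected cohort means under a known architecture
#'
#' `mu + C %*% beta`: the grand mean plus each cohort's exposure-weighted
#' sum of true composite effects.  With only `Aa` nonzero the cohort means
#' fall on the straight line between the parental means when plotted
#' against genome proportion — the purely additive expectation.
#'
#' @param cm a [cmatrix()].
#' @param grand_mean intercept `mu` (trait units).
#' @param true_effects named numeric vector of effect sizes; names must be
#'   c-matrix columns, unnamed effects are zero.
#' @return named per-cohort numeric vector.
#' @examples
#' expected_cohort_means(cmatrix(solanum_pedigree()), 10, c(Aa = 4))
#' # P1 14, P2 6, F2 10, BC1 12, rBC2 8
#' @export
expected_cohort_means <- function(cm, grand_mean, true_effects = numeric()) {
  if (length(true_effects)) {
    bad <- setdiff(names(true_effects), colnames(cm))
    if (length(bad))
      stop("unknown effect label(s) in true_effects: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  beta <- stats::setNames(numeric(ncol(cm)), colnames(cm))
  beta[names(true_effects)] <- true_effects
  drop(unclass(cm) %*% beta) + grand_mean
}

# replicate counts of the study design: two plants per cohort and
# 23/14/13/14/21 leaves across P1, P2, F2, BC1, rBC2
solanum_obs_per_plant <- function() {
  list(P1 = c(12L, 11L), P2 = c(7L, 7L), F2 = c(7L, 6L),
       BC1 = c(7L, 7L), rBC2 = c(11L, 10L))
}

#' Simulate a plant-nested phenotype dataset with known architecture
#'
#' Generates individual measurements for each cohort of a c-matrix under a
#' two-level Gaussian model: plant effects are drawn around the cohort's
#' expected mean with SD `sigma_plant`, and replicate observations
#' (leaves) around each plant's value with SD `sigma_obs`.  The defaults
#' mirror the tomato study design: two plants per cohort with
#' 23/14/13/14/21 total leaves over P1, P2, F2, BC1, rBC2.  Per-cohort RNG
#' streams are derived deterministically from `seed`, so a dataset is
#' reproducible cohort-by-cohort.
#'
#' @param cm a [cmatrix()].
#' @param grand_mean,true_effects as in [expected_cohort_means()].
#' @param sigma_plant between-plant SD (trait units).
#' @param sigma_obs within-plant replicate SD (trait units).
#' @param obs_per_plant named list: for each cohort, an integer vector of
#'   replicate counts, one entry per plant.  For traits measured on
#'   independent individuals (e.g. individually weighed seeds) use
#'   one-observation plants and fold the noise into `sigma_plant`.
#' @param trait trait label written into the records.
#' @param seed integer seed.
#' @return list of class `"lca_sim"`: `records` (data frame with columns
#'   `cohort`, `plant_id`, `trait`, `value`), `expected_means`, and
#'   `truth` (the full configuration, enabling recovery scoring).
#' @examples
#' sim <- simulate_cohorts(cmatrix(solanum_pedigree()),
#'                         grand_mean = 10, true_effects = c(Aa = 4),
#'                         seed = 1)
#' table(sim$records$cohort)
#' @export
simulate_cohorts <- function(cm, grand_mean = 10, true_effects = c(Aa = 4),
                             sigma_plant = 0.5, sigma_obs = 1,
                             obs_per_plant = NULL, trait = "trait1",
                             seed = 1L) {
  if (is.null(obs_per_plant)) {
    obs_per_plant <- if (setequal(rownames(cm),
                                  c("P1", "P2", "F2", "BC1", "rBC2")))
      solanum_obs_per_plant()[rownames(cm)]
    else stats::setNames(rep(list(c(12L, 11L)), nrow(cm)), rownames(cm))
  }
  miss <- setdiff(rownames(cm), names(obs_per_plant))
  if (length(miss))
    stop("obs_per_plant missing cohort(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(unlist(obs_per_plant) < 1L))
    stop("obs_per_plant entries must be positive", call. = FALSE)
  if (sigma_plant < 0 || sigma_obs < 0)
    stop("noise SDs must be non-negative", call. = FALSE)
  mu <- expected_cohort_means(cm, grand_mean, true_effects)
  recs <- vector("list", nrow(cm))
  for (i in seq_len(nrow(cm))) {
    ch <- rownames(cm)[i]
    set.seed((as.integer(seed) + 104729L * i) %% .Machine$integer.max)
    counts <- obs_per_plant[[ch]]
    plant_means <- mu[ch] + stats::rnorm(length(counts), 0, sigma_plant)
    recs[[i]] <- data.frame(
      cohort = ch,
      plant_id = paste0(ch, "_plant", rep(seq_along(counts), counts)),
      trait = trait,
      value = stats::rnorm(sum(counts), rep(plant_means, counts), sigma_obs),
      stringsAsFactors = FALSE)
  }
  structure(
    list(records = do.call(rbind, recs), expected_means = mu,
         truth = list(grand_mean = grand_mean, true_effects = true_effects,
                      sigma_plant = sigma_plant, sigma_obs = sigma_obs,
                      obs_per_plant = obs_per_plant, trait = trait,
                      seed = as.integer(seed))),
    class = "lca_sim")
}

#' @export
print.lca_sim <- function(x, ...) {
  cat("Simulated line cross dataset:", nrow(x$records), "observations,",
      length(x$expected_means), "cohorts, seed", x$truth$seed, "\n")
  nz <- x$truth$true_effects[x$truth$true_effects != 0]
  cat("  true architecture:",
      if (length(nz)) paste(names(nz), "=", nz, collapse = ", ")
      else "null (grand mean only)", "\n")
  invisible(x)
}

#' Monte-Carlo recovery experiment
#'
#' Repeatedly simulates a dataset under a known architecture, runs the
#' full analysis on each replicate, and scores how well the truth is
#' recovered: the mean averaged estimate and bias per effect, the fraction
#' of replicates in which each effect passed the inclusion criteria
#' (power for true effects, spurious-inclusion rate for null ones), and
#' the fraction of replicates whose included set was exactly the true
#' one.  Operationalizes the power question: more plants or replicates
#' shrink the cohort SEs and raise inclusion rates.
#'
#' @inheritParams simulate_cohorts
#' @param replicates number of simulated datasets.
#' @param ... further arguments to [lca()] (thresholds, scope, ...).
#' @return list of class `"lca_recovery"`: `per_effect` (data frame with
#'   `effect`, `true_value`, `mean_estimate`, `bias`,
#'   `inclusion_fraction`), `exact_recovery_fraction`,
#'   `mean_additive_proportion` (over replicates where anything was
#'   included), and `replicates`.
#' @export
recovery_experiment <- function(cm, grand_mean = 10, true_effects = c(Aa = 4),
                                sigma_plant = 0.5, sigma_obs = 1,
                                obs_per_plant = NULL, replicates = 200L,
                                seed = 1L, ...) {
  stopifnot(replicates >= 1L)
  effects <- colnames(cm)
  est <- matrix(0, replicates, length(effects),
                dimnames = list(NULL, effects))
  inc <- matrix(FALSE, replicates, length(effects),
                dimnames = list(NULL, effects))
  arch <- matrix(NA_real_, replicates, 4L,
                 dimnames = list(NULL, c("additive", "dominance",
                                         "epistatic", "maternal")))
  truth <- stats::setNames(numeric(length(effects)), effects)
  truth[names(true_effects)] <- true_effects
  for (r in seq_len(replicates)) {
    sim <- simulate_cohorts(cm, grand_mean = grand_mean,
                            true_effects = true_effects,
                            sigma_plant = sigma_plant, sigma_obs = sigma_obs,
                            obs_per_plant = obs_per_plant,
                            seed = (as.integer(seed) + 7919L * r) %%
                              .Machine$integer.max)
    s <- summarize_phenotypes(sim$records, cohorts = rownames(cm))
    res <- lca(s, cm, ...)$traits[[1L]]
    est[r, ] <- res$averaged$estimate
    inc[r, ] <- res$averaged$included
    arch[r, ] <- as.numeric(res$architecture[
      , c("additive", "dominance", "epistatic", "maternal")])
  }
  true_set <- names(truth)[truth != 0]
  exact <- mean(apply(inc, 1L, function(z)
    setequal(effects[z], true_set)))
  per_effect <- data.frame(
    effect = effects, true_value = unname(truth),
    mean_estimate = colMeans(est),
    bias = colMeans(est) - unname(truth),
    inclusion_fraction = colMeans(inc),
    row.names = NULL, stringsAsFactors = FALSE)
  any_inc <- rowSums(inc) > 0
  structure(list(per_effect = per_effect,
                 exact_recovery_fraction = exact,
                 mean_additive_proportion =
                   if (any(any_inc)) mean(arch[any_inc, "additive"]) else NA_real_,
                 additive_one_fraction = mean(any_inc &
                   !is.na(arch[, "additive"]) & arch[, "additive"] == 1),
                 replicates = replicates),
            class = "lca_recovery")
}

#' @export
print.lca_recovery <- function(x, digits = 3, ...) {
  cat("Recovery experiment over", x$replicates, "replicates\n")
  pe <- x$per_effect
  pe[-1L] <- lapply(pe[-1L], round, digits = digits)
  print(pe, row.names = FALSE)
  cat(sprintf("exact recovery of the true effect set: %.1f%%\n",
              100 * x$exact_recovery_fraction))
  invisible(x)
}
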