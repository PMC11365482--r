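#' Information-theoretic line cross analysis
#'
#' Runs the full analysis for each trait of a cohort-summary table: fit
#' every estimable architecture model by weighted least squares, weight
#' models by AICc, build the confidence set, model-average the composite
#' effects, apply the inclusion criteria, and pool the surviving effects
#' into additive / dominance / epistatic / maternal proportions.
#'
#' @param summaries cohort-summary data frame (columns `cohort`, `trait`,
#'   `mean`, `se`), e.g. from [summarize_phenotypes()] or
#'   [read_cohort_summaries()].
#' @param cm a [cmatrix()] whose rows name the expected cohorts.
#' @param max_effects largest model size (default `nrow(cm) - 1`).
#' @param level confidence level of the model set (default 0.95).
#' @param vi_threshold,se_multiplier inclusion criteria, see
#'   [apply_inclusion_criteria()].
#' @param scope model-averaging weight scope, see [model_average()].
#' @return object of class `"lca"`: a list with one element per trait,
#'   each holding `mspace`, `weights`, `averaged`, `architecture`; plus an
#'   `architecture` data frame binding all traits' rows.
#' @examples
#' cm <- cmatrix(solanum_pedigree())
#' s <- data.frame(cohort = rownames(cm), trait = "length",
#'                 mean = c(14.1, 5.9, 10.1, 12.0, 8.0), se = 0.4)
#' fit <- lca(s, cm)
#' fit$architecture
#' @export
lca <- function(summaries, cm, max_effects = nrow(cm) - 1L, level = 0.95,
                vi_threshold = 0.5, se_multiplier = 1,
                scope = c("confidence", "all")) {
  scope <- match.arg(scope)
  missing_cohorts <- setdiff(rownames(cm), unique(summaries$cohort))
  if (length(missing_cohorts))
    stop("summaries lack cohort(s): ",
         paste(missing_cohorts, collapse = ", "), call. = FALSE)
  traits <- unique(as.character(summaries$trait))
  per_trait <- lapply(traits, function(tr) {
    s <- summaries[summaries$trait == tr, ]
    mspace <- fit_model_space(cm, s, max_effects = max_effects)
    wset <- akaike_weights(mspace, level = level)
    avg <- apply_inclusion_criteria(
      model_average(wset, scope = scope),
      vi_threshold = vi_threshold, se_multiplier = se_multiplier)
    list(trait = tr, summaries = s, mspace = mspace, weights = wset,
         averaged = avg, architecture = pool_effects(avg, trait = tr))
  })
  names(per_trait) <- traits
  arch <- do.call(rbind, lapply(per_trait, `[[`, "architecture"))
  rownames(arch) <- NULL
  structure(list(traits = per_trait, architecture = arch, cm = cm,
                 settings = list(max_effects = max_effects, level = level,
                                 vi_threshold = vi_threshold,
                                 se_multiplier = se_multiplier,
                                 scope = scope)),
            class = "lca")
}

#' @export
print.lca <- function(x, digits = 2, ...) {
  cat("Line cross analysis:", length(x$traits), "trait(s),",
      nrow(x$traits[[1L]]$mspace$table), "models per trait\n")
  arch <- x$architecture
  num <- vapply(arch, is.numeric, NA)
  arch[num] <- lapply(arch[num], round, digits = digits)
  print(arch, row.names = FALSE)
  invisible(x)
}

#' Model-space report table
#'
#' One row per model with its AICc, Akaike weight, cumulative weight in
#' weight order, and confidence-set membership — the standard diagnostic
#' table of an information-theoretic analysis.
#'
#' @param trait_result one element of an [lca()] object's `traits` list.
#' @return data frame sorted by descending weight.
#' @export
model_report <- function(trait_result) {
  tab <- trait_result$mspace$table
  w <- trait_result$weights
  tab$delta <- w$delta
  tab$weight <- w$weight
  tab$in_confidence_set <- w$in_confidence_set
  tab <- tab[w$order, ]
  tab$cumulative_weight <- cumsum(tab$weight)
  rownames(tab) <- NULL
  tab
}

#' Plot cohort means against genome proportion
#'
#' The classic line cross summary plot: cohort phenotype means (with SE
#' bars) against the expected proportion of the P2 founder genome, with a
#' dotted line joining the two parental means — the expectation for every
#' cohort under a purely additive architecture.  Deviations from the line
#' suggest dominance, epistatic, maternal or cytotype contributions.
#'
#' @param summaries cohort-summary rows for one trait.
#' @param cm a [cmatrix()] containing an `Aa` column (used to place each
#'   cohort on the genome-proportion axis).
#' @param main plot title (defaults to the trait label).
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the data frame of plotted coordinates.
#' @export
plot_cohort_means <- function(summaries, cm, main = NULL, ...) {
  if (!"Aa" %in% colnames(cm))
    stop("c-matrix must contain an Aa column to place cohorts", call. = FALSE)
  s <- summaries[match(rownames(cm), summaries$cohort), ]
  p2 <- (1 - unclass(cm)[, "Aa"]) / 2   # 0 = all-P1 genome, 1 = all-P2
  ylim <- range(s$mean - s$se, s$mean + s$se)
  graphics::plot(p2, s$mean, pch = 19, xlim = c(0, 1), ylim = ylim,
                 xlab = "Proportion of P2 genome", ylab = "Phenotype mean",
                 main = main %||% unique(as.character(s$trait))[1L], ...)
  graphics::arrows(p2, s$mean - s$se, p2, s$mean + s$se,
                   angle = 90, code = 3, length = 0.04)
  par_idx <- order(p2)[c(1L, length(p2))]
  graphics::segments(p2[par_idx[1L]], s$mean[par_idx[1L]],
                     p2[par_idx[2L]], s$mean[par_idx[2L]], lty = 3)
  graphics::text(p2, s$mean, labels = rownames(cm), pos = 4, cex = 0.8)
  invisible(data.frame(cohort = rownames(cm), p2 = p2, mean = s$mean,
                       se = s$se))
}
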