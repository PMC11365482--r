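#' Cohort mean as the mean of plant means
#'
#' Leaves (or other replicate samples) from the same plant are
#' non-independent, so the cohort mean is the unweighted mean over plants
#' of each plant's own mean.  Plants contribute equally regardless of how
#' many replicates they carry; this is deliberately *not* the pooled mean
#' of all observations.
#'
#' @param value numeric vector of trait observations for one cohort and
#'   trait.
#' @param plant plant identifier for each observation (same length as
#'   `value`).
#' @return the cohort mean (trait units).
#' @examples
#' cohort_mean(c(2, 4, 3), c("A", "A", "B"))  # plant means (3, 3) -> 3
#' @export
cohort_mean <- function(value, plant) {
  if (!length(value)) stop("no observations supplied", call. = FALSE)
  stopifnot(length(value) == length(plant))
  if (any(!is.finite(value)))
    stop("non-finite trait values are not allowed", call. = FALSE)
  mean(tapply(value, plant, mean))
}

#' Cohort standard error from within-plant variation
#'
#' Standard error of a plant-nested cohort,
#' `SE = sqrt(sum_i sigma_i^2 / s_i)`,
#' where `sigma_i` is the standard deviation of the trait among the `s_i`
#' replicate samples of plant `i` and the sum runs over the cohort's
#' plants.  This is the published form, implemented exactly as printed:
#' it carries no `1/n` factor, i.e. it is the SE of the *sum* of plant
#' means rather than of their mean.  [se_of_mean_of_means()] provides the
#' `1/n` variant under its own name; it is never the default.
#'
#' @param sigma per-plant replicate standard deviations (`n-1`
#'   denominator); a plant with a single observation contributes 0.
#' @param s per-plant replicate counts, all `>= 1`.
#' @return non-negative SE in trait units.
#' @examples
#' cohort_se(c(1, 2), c(4, 1))  # sqrt(0.25 + 4) = sqrt(4.25)
#' @export
cohort_se <- function(sigma, s) {
  stopifnot(length(sigma) == length(s))
  if (any(s < 1)) stop("replicate counts s must all be >= 1", call. = FALSE)
  if (any(sigma < 0)) stop("sigma must be non-negative", call. = FALSE)
  sqrt(sum(sigma^2 / s))
}

#' @rdname cohort_se
#' @details `se_of_mean_of_means()` divides the summed variance by `n^2`
#'   (equivalently the SE by `n`), giving the standard error of the mean
#'   of the plant means.
#' @export
se_of_mean_of_means <- function(sigma, s) {
  cohort_se(sigma, s) / length(sigma)
}

#' Summarize plant-nested phenotype records by cohort and trait
#'
#' Converts a long table of individual measurements into the cohort
#' mean/SE table that is the sole statistical input to line cross
#' analysis.  The mean is the mean of plant means ([cohort_mean()]) and
#' the SE is the plant-nested form ([cohort_se()]).  Plants observed only
#' once have an undefined sample SD; they enter the SE with
#' `sigma_i = 0` and a warning is issued (relevant for individually
#' weighed seeds, where each seed is a one-observation "plant").
#'
#' @param records data frame with columns `cohort`, `plant_id`, `trait`,
#'   `value`.
#' @param cohorts optional character vector fixing the cohort universe and
#'   output order (e.g. a pedigree's measured set).  Records with a cohort
#'   outside it are an error; traits are ordered alphabetically within
#'   cohort order.
#' @return data frame of class `"cohort_summary"` with columns `cohort`,
#'   `trait`, `mean`, `se`, `n_plants`, `n_obs`.
#' @examples
#' rec <- data.frame(cohort = "P1", plant_id = rep(c("a", "b"), c(3, 2)),
#'                   trait = "length", value = c(5, 6, 7, 4, 6))
#' summarize_phenotypes(rec)
#' @export
summarize_phenotypes <- function(records, cohorts = NULL) {
  need <- c("cohort", "plant_id", "trait", "value")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(records$value)))
    stop("records contain non-finite trait values", call. = FALSE)
  if (is.null(cohorts)) {
    cohorts <- unique(as.character(records$cohort))
  } else {
    bad <- setdiff(unique(as.character(records$cohort)), cohorts)
    if (length(bad))
      stop("unknown cohort label(s) in records: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  traits <- sort(unique(as.character(records$trait)))
  partial <- traits[vapply(traits, function(tr)
    length(unique(records$cohort[records$trait == tr])) < length(cohorts),
    NA)]
  if (length(partial))
    warning("trait(s) not observed in every cohort: ",
            paste(partial, collapse = ", "), call. = FALSE)
  singletons <- FALSE
  rows <- list()
  for (ch in cohorts) for (tr in traits) {
    sub <- records[records$cohort == ch & records$trait == tr, ]
    if (!nrow(sub)) next
    pm <- tapply(sub$value, as.character(sub$plant_id), mean)
    s <- tapply(sub$value, as.character(sub$plant_id), length)
    sigma <- tapply(sub$value, as.character(sub$plant_id), stats::sd)
    if (any(s == 1)) { singletons <- TRUE; sigma[s == 1] <- 0 }
    rows[[length(rows) + 1L]] <- data.frame(
      cohort = ch, trait = tr, mean = mean(pm),
      se = cohort_se(as.numeric(sigma), as.numeric(s)),
      n_plants = length(pm), n_obs = nrow(sub),
      stringsAsFactors = FALSE)
  }
  if (singletons)
    warning("plants with a single observation contribute sigma = 0 to the SE",
            call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Read / write phenotype and summary tables
#'
#' `read_phenotypes()` reads a delimited table of individual measurements
#' (required columns `cohort`, `plant_id`, `trait`, `value`).
#' `read_cohort_summaries()` / `write_cohort_summaries()` handle the
#' summary format (`cohort`, `trait`, `mean`, `se`, and optionally
#' `n_plants`, `n_obs`), which doubles as the direct-input path for users
#' who only have published means and SEs.
#'
#' @param path file path.
#' @param sep field delimiter (default comma; use `"\t"` for TSV).
#' @return a data frame (`"cohort_summary"` for the summary readers).
#' @export
read_phenotypes <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("cohort", "plant_id", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_phenotypes
#' @export
read_cohort_summaries <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("cohort", "trait", "mean", "se"), names(df))
  if (length(miss))
    stop("summary file '", path, "' is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(df$se < 0)) stop("negative SE in '", path, "'", call. = FALSE)
  class(df) <- c("cohort_summary", "data.frame")
  df
}

#' @rdname read_phenotypes
#' @param summaries a cohort-summary data frame.
#' @export
write_cohort_summaries <- function(summaries, path, sep = ",") {
  utils::write.table(as.data.frame(summaries), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
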