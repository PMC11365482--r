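# Composite genetic effects supported by the two-founder cohort class.
# Base effects: autosomal additive (Aa), autosomal dominance (Ad), cytotype
# additive (Ca), maternal effect additive (Mea), maternal effect dominance
# (Med).  Epistatic effects are two-way products of autosomal and cytotype
# terms; maternal terms do not enter epistatic combinations here.
BASE_EFFECTS <- c("Aa", "Ad", "Ca", "Mea", "Med")
EPISTATIC_EFFECTS <- c("AaAa", "AaAd", "AdAd", "AaCa", "AdCa")
ALL_EFFECTS <- c(BASE_EFFECTS, EPISTATIC_EFFECTS)

EFFECT_CATEGORY <- c(
  Aa = "additive", Ca = "additive", Ad = "dominance",
  Mea = "maternal", Med = "maternal",
  AaAa = "epistatic", AaAd = "epistatic", AdAd = "epistatic",
  AaCa = "epistatic", AdCa = "epistatic")

#' Base composite-effect coefficients for one cohort
#'
#' Derives the five base coefficients of a cohort from its pedigree by
#' recursion over sire and dam down to the two founders:
#' \describe{
#'   \item{Aa}{autosomal additive, `2*theta - 1`, where `theta` is the
#'     expected proportion of the genome inherited from the first (P1)
#'     founder; `theta` of a child is the mean of its parents' values.}
#'   \item{Ad}{autosomal dominance, the expected heterozygosity
#'     `theta_s*(1 - theta_d) + theta_d*(1 - theta_s)` under independent
#'     parental gametes; 0 for founders.}
#'   \item{Ca}{cytotype additive, +1 if the strict maternal (dam) lineage
#'     terminates at the P1 founder and -1 otherwise.}
#'   \item{Mea, Med}{maternal additive and dominance: the dam's own `Aa`
#'     and `Ad`.}
#' }
#' The independent-gamete heterozygosity is exact for crosses among the
#' founders, their F1, and combinations of those (F2, backcrosses); this is
#' the supported pedigree class.
#'
#' @param ped an [pedigree()] object.
#' @param cohort cohort name (founder or derived).
#' @return named numeric vector `c(Aa, Ad, Ca, Mea, Med)`, with the
#'   cohort's `theta` attached as attribute `"theta"`.
#' @examples
#' ped <- solanum_pedigree()
#' base_coefficients(ped, "P1")   # Aa = 1, Ad = 0, Ca = 1, Mea = 1, Med = 0
#' base_coefficients(ped, "BC1")  # Aa = 0.5, Ad = 0.5, Ca = -1, Mea = 0, Med = 1
#' @export
base_coefficients <- function(ped, cohort) {
  stopifnot(inherits(ped, "lca_pedigree"))
  theta <- function(name) {
    if (name == ped$founders[1L]) return(1)
    if (name == ped$founders[2L]) return(0)
    row <- ped$cohorts[ped$cohorts$cohort == name, ]
    if (nrow(row) != 1L)
      stop("cohort '", name, "' has unresolvable ancestry: not a founder ",
           "and not defined by a cross", call. = FALSE)
    (theta(row$sire) + theta(row$dam)) / 2
  }
  het <- function(name) {
    if (name %in% ped$founders) return(0)
    row <- ped$cohorts[ped$cohorts$cohort == name, ]
    ts <- theta(row$sire); td <- theta(row$dam)
    ts * (1 - td) + td * (1 - ts)
  }
  cyto <- function(name) {
    while (!name %in% ped$founders)
      name <- ped$cohorts$dam[ped$cohorts$cohort == name]
    if (name == ped$founders[1L]) 1 else -1
  }
  dam_of <- function(name) {
    if (name %in% ped$founders) name
    else ped$cohorts$dam[ped$cohorts$cohort == name]
  }
  if (!cohort %in% c(ped$founders, ped$cohorts$cohort))
    stop("cohort '", cohort, "' is not in the pedigree", call. = FALSE)
  th <- theta(cohort)
  dam <- dam_of(cohort)
  out <- c(Aa = 2 * th - 1, Ad = het(cohort), Ca = cyto(cohort),
           Mea = 2 * theta(dam) - 1, Med = het(dam))
  attr(out, "theta") <- th
  out
}

#' Coefficient of a single composite effect
#'
#' Base effects are returned directly from the base coefficient vector;
#' two-way epistatic effects are the product of their two constituent base
#' coefficients (`AaCa = Aa * Ca`, etc.).  Labels outside the ten
#' supported composite effects are rejected: the five-cohort class only
#' identifies two-partner epistasis.
#'
#' @param base named vector from [base_coefficients()].
#' @param effect one of `r paste(ALL_EFFECTS, collapse = ", ")`.
#' @return the coefficient, a dimensionless value in `[-1, 1]`.
#' @examples
#' b <- base_coefficients(solanum_pedigree(), "BC1")
#' composite_coefficient(b, "AaCa")  # 0.5 * -1 = -0.5
#' @export
composite_coefficient <- function(base, effect) {
  if (length(effect) != 1L || !effect %in% ALL_EFFECTS)
    stop("unknown effect label '", paste(effect, collapse = ","),
         "'; supported labels: ", paste(ALL_EFFECTS, collapse = ", "),
         call. = FALSE)
  if (effect %in% BASE_EFFECTS) return(unname(base[effect]))
  parts <- regmatches(effect, gregexpr("[A-Z][a-z]+", effect))[[1L]]
  unname(base[parts[1L]] * base[parts[2L]])
}

#' Build the c-matrix of a cohort set
#'
#' The c-matrix is the cohorts-by-effects coefficient table at the heart of
#' line cross analysis: entry `(j, e)` is cohort `j`'s expected exposure to
#' composite genetic effect `e`, so that under architecture `beta` the
#' cohort phenotype means are `mu + C %*% beta`.
#'
#' @param ped an [pedigree()] object.
#' @param cohorts cohort names forming the rows, in order; defaults to the
#'   pedigree's `measured` set.
#' @param effects effect labels forming the columns; defaults to all ten
#'   supported composite effects.
#' @return a numeric matrix of class `"cmatrix"` with cohort row names and
#'   effect column names.
#' @examples
#' cmatrix(solanum_pedigree())
#' cmatrix(solanum_pedigree(), cohorts = c("P1", "P2"), effects = "Aa")
#' @export
cmatrix <- function(ped, cohorts = ped$measured, effects = ALL_EFFECTS) {
  stopifnot(inherits(ped, "lca_pedigree"))
  if (length(cohorts) < 2L)
    stop("at least two cohorts are required", call. = FALSE)
  if (anyDuplicated(cohorts))
    stop("duplicate cohort names: ",
         paste(unique(cohorts[duplicated(cohorts)]), collapse = ", "),
         call. = FALSE)
  if (!length(effects)) stop("effects must be non-empty", call. = FALSE)
  bad <- setdiff(effects, ALL_EFFECTS)
  if (length(bad))
    stop("unknown effect label(s) ", paste(bad, collapse = ", "),
         "; supported labels: ", paste(ALL_EFFECTS, collapse = ", "),
         call. = FALSE)
  C <- matrix(NA_real_, length(cohorts), length(effects),
              dimnames = list(cohorts, effects))
  for (ch in cohorts) {
    b <- base_coefficients(ped, ch)
    C[ch, ] <- vapply(effects, composite_coefficient, 0, base = b)
  }
  structure(C, class = c("cmatrix", class(C)))
}

#' @export
print.cmatrix <- function(x, ...) {
  cat("c-matrix (", nrow(x), " cohorts x ", ncol(x),
      " composite genetic effects)\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Read / write a c-matrix as delimited text
#'
#' The file has a header row of effect labels and a first column of cohort
#' labels, so the study matrix round-trips through a plain CSV.
#'
#' @param path file path.
#' @param sep field delimiter (default comma; use `"\t"` for TSV).
#' @return `read_cmatrix()` returns a `"cmatrix"` matrix; `write_cmatrix()`
#'   returns `path` invisibly.
#' @export
read_cmatrix <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  C <- as.matrix(df[, -1L, drop = FALSE])
  rownames(C) <- df[[1L]]
  storage.mode(C) <- "double"
  structure(C, class = c("cmatrix", class(C)))
}

#' @rdname read_cmatrix
#' @param cm a c-matrix.
#' @export
write_cmatrix <- function(cm, path, sep = ",") {
  df <- data.frame(cohort = rownames(cm), unclass(cm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
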