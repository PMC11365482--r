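#' Build a two-founder cross pedigree
#'
#' A line cross experiment starts from two founder strains and builds
#' derived cohorts by crossing.  Each derived cohort is defined by its sire
#' and dam, which may themselves be founders or earlier cohorts; selfing is
#' expressed by giving the same cohort as sire and dam.  All coefficient
#' derivations ([base_coefficients()], [cmatrix()]) are computed by
#' recursion over this structure, so every cohort's ancestry must resolve
#' to the two founders.
#'
#' @param founders character vector of length 2 naming the founder
#'   cohorts, in the order (P1-founder, P2-founder).  The first founder is
#'   the one whose genome proportion defines the additive scale
#'   (`Aa = +1`), the second gets `Aa = -1`.
#' @param crosses named character vector of crosses in `"sire x dam"`
#'   notation, e.g. `c(F1 = "P1 x P2", BC1 = "P1 x F1")`.  Parents must be
#'   founders or previously defined cohorts.
#' @param measured optional character vector of cohort names that are
#'   phenotyped (used as the default row set of [cmatrix()]).  Defaults to
#'   all cohorts, founders first.
#' @return an object of class `"lca_pedigree"`: a list with elements
#'   `founders`, `cohorts` (data frame with columns `cohort`, `sire`,
#'   `dam`) and `measured`.
#' @examples
#' ped <- pedigree(
#'   founders = c("P1", "P2"),
#'   crosses  = c(F1 = "P1 x P2", F2 = "F1 x F1",
#'                BC1 = "P1 x F1", rBC2 = "F1 x P2"))
#' ped
#' @seealso [solanum_pedigree()] for the built-in five-cohort tomato design
#' @export
pedigree <- function(founders, crosses = character(), measured = NULL) {
  if (length(founders) != 2L || anyDuplicated(founders))
    stop("exactly two distinct founder names are required", call. = FALSE)
  founders <- as.character(founders)
  parsed <- lapply(crosses, parse_cross)
  cohorts <- data.frame(
    cohort = names(crosses) %||% character(),
    sire = vapply(parsed, `[[`, "", 1L),
    dam = vapply(parsed, `[[`, "", 2L),
    stringsAsFactors = FALSE, row.names = NULL)
  if (length(crosses) && (is.null(names(crosses)) || any(!nzchar(names(crosses)))))
    stop("every cross must be named (the cohort it produces)", call. = FALSE)
  all_names <- c(founders, cohorts$cohort)
  if (anyDuplicated(all_names))
    stop("duplicate cohort names: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "),
         call. = FALSE)
  ped <- structure(
    list(founders = founders, cohorts = cohorts,
         measured = measured %||% all_names),
    class = "lca_pedigree")
  validate_pedigree(ped)
  ped
}

parse_cross <- function(x) {
  parts <- strsplit(trimws(x), "\\s*[x×]\\s*")[[1L]]
  if (length(parts) != 2L || any(!nzchar(parts)))
    stop("cannot parse cross '", x, "': expected 'sire x dam'", call. = FALSE)
  parts
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_pedigree <- function(ped) {
  known <- ped$founders
  for (i in seq_len(nrow(ped$cohorts))) {
    row <- ped$cohorts[i, ]
    for (p in c(row$sire, row$dam)) {
      if (!p %in% known)
        stop("cohort '", row$cohort, "' has parent '", p,
             "' that is neither a founder nor a previously defined cohort",
             call. = FALSE)
    }
    known <- c(known, row$cohort)
  }
  bad <- setdiff(ped$measured, known)
  if (length(bad))
    stop("measured cohorts not in pedigree: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(ped)
}

#' @export
print.lca_pedigree <- function(x, ...) {
  cat("Line cross pedigree\n")
  cat("  founders: ", x$founders[1L], " (P1 role), ", x$founders[2L],
      " (P2 role)\n", sep = "")
  if (nrow(x$cohorts))
    for (i in seq_len(nrow(x$cohorts)))
      cat(sprintf("  %s = %s x %s\n", x$cohorts$cohort[i],
                  x$cohorts$sire[i], x$cohorts$dam[i]))
  cat("  measured:", paste(x$measured, collapse = ", "), "\n")
  invisible(x)
}

#' The five-cohort Solanum pedigree
#'
#' The standard design used for the *Solanum pennellii* (P1) by
#' *S. lycopersicum* (P2) line cross: the two selfed parents, the F2, and
#' the two backcrosses BC1 = P1 x F1 and rBC2 = F1 x P2 (sire-by-dam
#' notation).  The F1 itself is part of the pedigree (it is needed to
#' derive the other cohorts' coefficients) but is not among the measured
#' cohorts, so the default c-matrix has five rows.
#'
#' @return an [pedigree()] object with measured cohorts
#'   P1, P2, F2, BC1, rBC2.
#' @examples
#' cmatrix(solanum_pedigree())
#' @export
solanum_pedigree <- function() {
  pedigree(
    founders = c("P1", "P2"),
    crosses  = c(F1 = "P1 x P2", F2 = "F1 x F1",
                 BC1 = "P1 x F1", rBC2 = "F1 x P2"),
    measured = c("P1", "P2", "F2", "BC1", "rBC2"))
}

#' Read / write a pedigree configuration file
#'
#' The file is YAML with three keys: `founders` (list of two names, P1
#' role first), `crosses` (map cohort name -> `"sire x dam"`), and
#' optionally `measured` (list of phenotyped cohorts).
#'
#' @param path file path.
#' @return `read_pedigree()` returns an [pedigree()] object;
#'   `write_pedigree()` returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' write_pedigree(solanum_pedigree(), f)
#' read_pedigree(f)
#' @export
read_pedigree <- function(path) {
  cfg <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse pedigree file '", path, "': ", conditionMessage(e),
         call. = FALSE))
  bad <- setdiff(names(cfg), c("founders", "crosses", "measured"))
  if (length(bad))
    stop("unknown keys in pedigree file: ", paste(bad, collapse = ", "),
         "; valid keys are founders, crosses, measured", call. = FALSE)
  if (is.null(cfg$founders))
    stop("pedigree file must declare 'founders'", call. = FALSE)
  pedigree(founders = unlist(cfg$founders),
           crosses = unlist(cfg$crosses) %||% character(),
           measured = if (!is.null(cfg$measured)) unlist(cfg$measured))
}

#' @rdname read_pedigree
#' @param ped an [pedigree()] object.
#' @export
write_pedigree <- function(ped, path) {
  stopifnot(inherits(ped, "lca_pedigree"))
  crosses <- as.list(paste(ped$cohorts$sire, "x", ped$cohorts$dam))
  names(crosses) <- ped$cohorts$cohort
  yaml::write_yaml(
    list(founders = as.list(ped$founders), crosses = crosses,
         measured = as.list(ped$measured)),
    path)
  invisible(path)
}
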