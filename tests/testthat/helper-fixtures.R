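# Reference coefficient matrix for the five-cohort Solanum design
# (the published cohorts-by-effects table; rows P1, P2, F2, BC1, rBC2).
reference_cmatrix <- function() {
  C <- rbind(
    P1   = c( 1.0, 0.0,  1,  1, 0, 1.00,  0.00, 0.00,  1.0,  0.0),
    P2   = c(-1.0, 0.0, -1, -1, 0, 1.00,  0.00, 0.00,  1.0,  0.0),
    F2   = c( 0.0, 0.5, -1,  0, 1, 0.00,  0.00, 0.25,  0.0, -0.5),
    BC1  = c( 0.5, 0.5, -1,  0, 1, 0.25,  0.25, 0.25, -0.5, -0.5),
    rBC2 = c(-0.5, 0.5, -1, -1, 0, 0.25, -0.25, 0.25,  0.5, -0.5))
  colnames(C) <- c("Aa", "Ad", "Ca", "Mea", "Med",
                   "AaAa", "AaAd", "AdAd", "AaCa", "AdCa")
  C
}

# summary rows for one trait directly from stated cohort means/SEs,
# in the c-matrix cohort order
summary_for <- function(cm, means, se = 0.5, trait = "t") {
  data.frame(cohort = rownames(cm), trait = trait, mean = means,
             se = se, stringsAsFactors = FALSE)
}

# random valid pedigree over two founders: each new cohort crosses two
# uniformly chosen existing cohorts (selfing allowed)
random_pedigree <- function(n_crosses = 5L, founders = c("A", "B")) {
  crosses <- character(0)
  pool <- founders
  for (i in seq_len(n_crosses)) {
    nm <- paste0("X", i)
    crosses[nm] <- paste(sample(pool, 1L), "x", sample(pool, 1L))
    pool <- c(pool, nm)
  }
  pedigree(founders = founders, crosses = crosses)
}
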