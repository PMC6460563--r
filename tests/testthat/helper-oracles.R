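# Independent brute-force oracles and small fixtures shared across tests.

# Parent-of-origin rule written from first principles, scalar, no vectorized
# shortcuts: the reference the production implementation is checked against.
oracle_assign <- function(d1, d2, f, m1 = NA, m2 = NA) {
  if (d1 == d2) {
    return("not_informative")
  }
  if (is.na(f) || !(f %in% c(d1, d2))) {
    return("inconsistent")
  }
  maternal <- if (f == d1) d2 else d1
  if (!is.na(m1) && !(maternal %in% c(m1, m2))) {
    return("inconsistent")
  }
  "informative"
}

# All (daughter, father, mother) biallelic genotype combinations for one
# ref/alt pair, mother optionally missing.
enumerate_trio_genotypes <- function(ref = "A", alt = "G") {
  gts <- c(paste(ref, ref, sep = "/"), paste(ref, alt, sep = "/"),
    paste(alt, alt, sep = "/"))
  grid <- expand.grid(
    daughter_gt = gts,
    father_allele = c(ref, alt),
    mother_gt = c(gts, NA),
    stringsAsFactors = FALSE
  )
  tibble::as_tibble(grid)
}

# Textbook paired one-sided t-test (mean of differences > 0), independent of
# stats::t.test.
oracle_paired_t <- function(d) {
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, df = n - 1, p = 1 - pt(t_stat, n - 1))
}

# A small cohort configuration reused across tests (cheap but exercises all
# site classes and gene statuses).
small_config <- function(seed = 11, ...) {
  defaults <- list(
    n_trios = 6, n_genes = 30, snvs_per_individual = c(30L, 60L), seed = seed
  )
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# Simulate per-individual median measures of balance for n independent
# individuals: skew from the precursor model, per-SNV counts binomial.
simulate_balance_medians <- function(n, n_cells = 8, n_snvs = 30,
                                     coverage = 30) {
  theta <- draw_individual_skew(n_cells, n)
  vapply(theta, function(th) {
    alt <- rbinom(n_snvs, coverage, th)
    median(measure_of_balance(coverage - alt, alt))
  }, numeric(1))
}
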