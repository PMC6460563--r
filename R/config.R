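#' GRCh37 pseudoautosomal regions of the X chromosome
#'
#' Coordinates of PAR1 and PAR2 on GRCh37 chrX, as a BED-style tibble
#' (0-based, half-open). Sites inside these regions recombine with the Y
#' chromosome and are excluded from X-inactivation analysis.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
#' @examples
#' par_intervals_grch37()
par_intervals_grch37 <- function() {
  tibble::tibble(
    chrom = "X",
    start = c(60000L, 154931043L),
    end   = c(2699520L, 155260560L),
    name  = c("PAR1", "PAR2")
  )
}

#' Configuration for the synthetic trio cohort generator
#'
#' Bundles every knob of the generator into a validated list. The defaults
#' describe the study conditions the package emulates: 79 mother-father-
#' daughter trios, per-daughter skew drawn from an 8-precursor-cell binomial
#' model, 30-150 informative heterozygous exonic non-PAR SNVs per individual,
#' negative-binomial read coverage, and a slight reference bias that shifts
#' allelic ratios left of 0.5.
#'
#' @param n_trios Number of trios (daughters). Mothers are simulated as
#'   independent individuals with their own skew.
#' @param n_cells Number of embryonic precursor cells in the skew model; each
#'   cell independently inactivates the maternal or paternal X with
#'   probability 0.5, so the true skew is `Binomial(n_cells, 0.5)/n_cells`.
#' @param n_genes Number of simulated non-PAR X-linked genes.
#' @param snvs_per_individual Integer range (length 2) for the number of
#'   informative (daughter-heterozygous, exonic, non-PAR) SNVs per individual.
#' @param coverage_mean,coverage_dispersion Mean and size (dispersion) of the
#'   negative-binomial read-coverage model.
#' @param coverage_min Lower truncation of coverage: coverage is
#'   `coverage_min + NB(mu = coverage_mean - coverage_min, size)`.
#' @param reference_bias Probability beta that a read carrying the
#'   alternative allele is captured, relative to a reference read (each
#'   alternative read is retained with probability `beta/(1-beta)`, capped at
#'   1). `0.5` means no bias; the default `0.49` reproduces the slight
#'   leftward shift of allelic ratios typical of alignment reference bias.
#' @param escapee_fraction Fraction of genes that escape X-inactivation
#'   (expressed from both alleles).
#' @param variable_escapee_fraction Fraction of escapee genes that escape
#'   only in a random subset of individuals.
#' @param variable_escape_prob Per-individual probability that a variable
#'   escapee escapes in that individual.
#' @param mendelian_error_rate Fraction of daughter-heterozygous sites where
#'   the mother's genotype is corrupted so that it lacks the maternal allele
#'   (a Mendelian inconsistency the phaser must flag).
#' @param n_homozygous,n_par_sites,n_nonexonic Numbers of additional
#'   daughter-homozygous, pseudoautosomal and non-exonic sites per trio, so
#'   every downstream filter is exercised.
#' @param include_mothers Simulate allele-specific counts for mothers too
#'   (needed for the mother-daughter balance correlation).
#' @param par_intervals BED-style tibble of pseudoautosomal intervals.
#' @param chrom,chrom_length Name and length of the simulated X chromosome.
#' @param seed Master RNG seed; all stages draw from named substreams derived
#'   from it, so a fixed seed gives byte-identical cohorts.
#'
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_trios = 4, seed = 1)
#' cfg$n_cells
cohort_config <- function(n_trios = 79,
                          n_cells = 8,
                          n_genes = 120,
                          snvs_per_individual = c(30L, 150L),
                          coverage_mean = 50,
                          coverage_dispersion = 5,
                          coverage_min = 0,
                          reference_bias = 0.49,
                          escapee_fraction = 0.15,
                          variable_escapee_fraction = 0.5,
                          variable_escape_prob = 0.5,
                          mendelian_error_rate = 0,
                          n_homozygous = 10,
                          n_par_sites = 5,
                          n_nonexonic = 5,
                          include_mothers = TRUE,
                          par_intervals = par_intervals_grch37(),
                          chrom = "X",
                          chrom_length = 155270560,
                          seed = 1L) {
  stopifnot(
    n_trios >= 1, n_cells >= 1, n_genes >= 2,
    length(snvs_per_individual) == 2,
    snvs_per_individual[1] >= 1,
    snvs_per_individual[1] <= snvs_per_individual[2],
    coverage_mean > coverage_min, coverage_dispersion > 0, coverage_min >= 0,
    reference_bias > 0, reference_bias < 1,
    escapee_fraction >= 0, escapee_fraction < 1,
    variable_escapee_fraction >= 0, variable_escapee_fraction <= 1,
    variable_escape_prob >= 0, variable_escape_prob <= 1,
    mendelian_error_rate >= 0, mendelian_error_rate < 1,
    is.data.frame(par_intervals)
  )
  structure(
    list(
      n_trios = as.integer(n_trios),
      n_cells = as.integer(n_cells),
      n_genes = as.integer(n_genes),
      snvs_per_individual = as.integer(snvs_per_individual),
      coverage_mean = coverage_mean,
      coverage_dispersion = coverage_dispersion,
      coverage_min = coverage_min,
      reference_bias = reference_bias,
      escapee_fraction = escapee_fraction,
      variable_escapee_fraction = variable_escapee_fraction,
      variable_escape_prob = variable_escape_prob,
      mendelian_error_rate = mendelian_error_rate,
      n_homozygous = as.integer(n_homozygous),
      n_par_sites = as.integer(n_par_sites),
      n_nonexonic = as.integer(n_nonexonic),
      include_mothers = isTRUE(include_mothers),
      par_intervals = par_intervals,
      chrom = chrom,
      chrom_length = chrom_length,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf(
    "  %d trios, %d precursor cells, %d genes, %d-%d informative SNVs\n",
    x$n_trios, x$n_cells, x$n_genes,
    x$snvs_per_individual[1], x$snvs_per_individual[2]
  ))
  cat(sprintf(
    "  coverage NB(mu=%g, size=%g, min=%g), reference bias %g, seed %d\n",
    x$coverage_mean, x$coverage_dispersion, x$coverage_min,
    x$reference_bias, x$seed
  ))
  invisible(x)
}

# Deterministic per-stage substream seed derived from the master seed, so each
# generation stage is reproducible in isolation. Kept below 2^31 - 1.
stage_seed <- function(seed, stage) {
  offsets <- c(
    genes = 101L, status = 211L, genotypes = 307L, skew = 401L,
    counts = 503L, mothers = 601L, precursor = 701L
  )
  if (!stage %in% names(offsets)) stop("unknown RNG stage: ", stage)
  (abs(as.integer(seed)) + offsets[[stage]] * 97003L) %% 2147483647L
}
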