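toy_exons <- tibble::tibble(
  chrom = "X",
  start = c(1000L, 5000L, 9000L),
  end = c(2000L, 6000L, 10000L),
  gene_id = c("GENE_A", "GENE_B", "GENE_C")
)
toy_par <- tibble::tibble(chrom = "X", start = 0L, end = 500L, name = "PAR1")

toy_record <- function(pos, ref_count, alt_count) {
  tibble::tibble(
    sample_id = "S1", chrom = "X", pos = pos,
    ref = "A", alt = "G",
    ref_count = ref_count, alt_count = alt_count
  )
}

test_that("measure of balance follows its definition", {
  expect_equal(measure_of_balance(7, 3), 0.3)
  expect_equal(measure_of_balance(5, 5), 0.5)
  expect_equal(measure_of_balance(10, 0), 0)
  expect_true(is.nan(measure_of_balance(0, 0)))
  expect_error(measure_of_balance(-1, 3), "non-negative")
  # equals min(r, 1 - r) for the allelic ratio r
  refs <- c(12, 3, 8, 0, 40)
  alts <- c(3, 14, 8, 10, 1)
  r <- alts / (refs + alts)
  expect_equal(measure_of_balance(refs, alts), pmin(r, 1 - r))
})

test_that("the SNV filters keep exactly the qualifying records", {
  # toy fixture: cov 12 exonic non-PAR; cov 8 exonic; cov 30 intronic;
  # cov 40 exonic PAR; cov 10 exonic non-PAR; cov 0 exonic -> 3 survive
  par_toy <- tibble::tibble(chrom = "X", start = 3000L, end = 4000L)
  exons6 <- dplyr::bind_rows(
    toy_exons,
    tibble::tibble(
      chrom = "X", start = 3000L, end = 3500L, gene_id = "GENE_PAR"
    )
  )
  records <- dplyr::bind_rows(
    toy_record(5500L, 6L, 6L), # cov 12, GENE_B, keep
    toy_record(5600L, 4L, 4L), # cov 8: low coverage
    toy_record(8000L, 20L, 10L), # intronic
    toy_record(3200L, 30L, 10L), # exonic but PAR
    toy_record(9500L, 5L, 5L), # cov 10 boundary, GENE_C, keep
    toy_record(1500L, 0L, 0L), # zero coverage
    toy_record(1200L, 40L, 12L) # cov 52, GENE_A, keep
  )
  suppressMessages({
    kept <- filter_snvs(records, exons6, par_toy, min_coverage = 10)
  })
  expect_equal(nrow(kept), 3)
  expect_setequal(unlist(kept$gene_ids), c("GENE_A", "GENE_B", "GENE_C"))
  excl <- attr(kept, "exclusions")
  expect_equal(sum(excl), nrow(records))
  expect_equal(unname(excl["kept"]), 3L)
  expect_equal(unname(excl["low_coverage"]), 2L)
  expect_equal(unname(excl["non_exonic"]), 1L)
  expect_equal(unname(excl["in_par"]), 1L)

  # brute-force overlap oracle over every record
  overlap <- vapply(records$pos, function(p) {
    any(p > exons6$start & p <= exons6$end)
  }, logical(1))
  in_par <- vapply(records$pos, function(p) {
    any(p > par_toy$start & p <= par_toy$end)
  }, logical(1))
  manual_keep <- records$pos[
    (records$ref_count + records$alt_count) >= 10 & overlap & !in_par
  ]
  expect_setequal(kept$pos, manual_keep)
})

test_that("coverage boundary is inclusive and filtering is monotone in min_coverage", {
  records <- dplyr::bind_rows(
    toy_record(1500L, 5L, 4L), # 9 reads
    toy_record(1600L, 5L, 5L) # 10 reads
  )
  suppressMessages({
    kept <- filter_snvs(records, toy_exons, toy_par, min_coverage = 10)
  })
  expect_equal(kept$pos, 1600L)

  cohort <- generate_cohort(small_config(seed = 9))
  suppressMessages({
    phased <- phase_counts(
      cohort$counts[grepl("_d$", cohort$counts$sample_id), ],
      assign_parent_of_origin(cohort$genotypes)
    )
    n10 <- nrow(filter_snvs(phased, cohort$exons, cohort$par, 10))
    n20 <- nrow(filter_snvs(phased, cohort$exons, cohort$par, 20))
    n0 <- nrow(filter_snvs(phased, cohort$exons, cohort$par, 0))
  })
  expect_lte(n20, n10)
  expect_lte(n10, n0)
})

test_that("empty filter output warns", {
  records <- toy_record(8000L, 20L, 10L) # intronic only
  suppressMessages(
    expect_warning(
      filter_snvs(records, toy_exons, toy_par), "uninformative"
    )
  )
})

test_that("per-individual summaries compute Mx, Sx and balance medians", {
  mk <- function(paternal_ratios, sample = "S1") {
    n <- length(paternal_ratios)
    cov <- 20L
    pat <- as.integer(round(paternal_ratios * cov))
    tibble::tibble(
      sample_id = sample, chrom = "X", pos = seq_len(n),
      ref = "A", alt = "G",
      ref_count = pat, alt_count = cov - pat, # paternal = ref here
      paternal_count = pat, maternal_count = cov - pat,
      total_count = cov,
      allelic_ratio = (cov - pat) / cov,
      paternal_ratio = pat / cov,
      balance = pmin(pat, cov - pat) / cov
    )
  }
  s1 <- summarize_individuals(mk(c(1, 1, 1)))
  expect_equal(s1$median_paternal_ratio, 1)
  expect_equal(s1$chromosome_skew_factor, 0.5)

  s2 <- summarize_individuals(mk(c(0.4, 0.5, 0.6)))
  expect_equal(s2$median_paternal_ratio, 0.5)
  expect_equal(s2$chromosome_skew_factor, 0)
  expect_equal(s2$n_informative_snvs, 3L)

  # even count: mean of the two central order statistics
  s3 <- summarize_individuals(mk(c(0.2, 0.4, 0.6, 1)))
  expect_equal(s3$median_paternal_ratio, 0.5)

  # median measure of balance equals a brute-force recomputation from the
  # realized allelic ratios
  withr::with_seed(3, {
    rec <- mk(round(runif(25), 2))
    s4 <- summarize_individuals(rec)
    expect_equal(
      s4$median_measure_of_balance,
      median(pmin(rec$allelic_ratio, 1 - rec$allelic_ratio))
    )
  })
})

test_that("Mx recovers the true skew from simulated SNVs", {
  withr::with_seed(21, {
    cov <- 50L
    pat <- rbinom(101, cov, 0.8)
    rec <- tibble::tibble(
      sample_id = "S1", chrom = "X", pos = seq_len(101),
      ref = "A", alt = "G",
      ref_count = pat, alt_count = cov - pat,
      paternal_count = pat, maternal_count = cov - pat,
      allelic_ratio = (cov - pat) / cov,
      paternal_ratio = pat / cov,
      balance = pmin(pat, cov - pat) / cov
    )
    s <- summarize_individuals(rec)
    # median of 101 draws sits between the 35% and 65% binomial quantiles
    # with probability > 0.999
    expect_gte(s$median_paternal_ratio, qbinom(0.35, cov, 0.8) / cov)
    expect_lte(s$median_paternal_ratio, qbinom(0.65, cov, 0.8) / cov)
  })
})

test_that("relabeling parents mirrors Mx and preserves Sx and balance", {
  cohort <- generate_cohort(small_config(seed = 14))
  suppressMessages({
    phased <- phase_counts(
      cohort$counts, assign_parent_of_origin(cohort$genotypes)
    )
    f <- filter_snvs(phased, cohort$exons, cohort$par)
    f_swapped <- filter_snvs(
      swap_parental_labels(phased), cohort$exons, cohort$par
    )
  })
  s <- summarize_individuals(f)
  s_swapped <- summarize_individuals(f_swapped)
  expect_equal(
    s_swapped$median_paternal_ratio, 1 - s$median_paternal_ratio
  )
  expect_equal(s_swapped$chromosome_skew_factor, s$chromosome_skew_factor)
  expect_equal(
    s_swapped$median_measure_of_balance, s$median_measure_of_balance
  )
  expect_equal(s_swapped$median_allelic_ratio, s$median_allelic_ratio)
})
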