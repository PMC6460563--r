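gene_rec <- function(sx, sg, agree = TRUE, gene = "G1") {
  tibble::tibble(
    gene_id = gene,
    sample_id = paste0("S", seq_along(sx)),
    n_snvs_in_gene = 2L,
    Mg = 0.5 + ifelse(agree, sg, -sg), # direction irrelevant to the test
    Sg = sg,
    Mx = 0.5 + sx,
    Sx = sx,
    agrees_with_chromosome = agree
  )
}

test_that("gene-sample medians and agreement flags are computed per gene", {
  filtered <- tibble::tibble(
    sample_id = c("S1", "S1", "S1", "S2"),
    chrom = "X", pos = c(1L, 2L, 3L, 1L),
    ref = "A", alt = "G",
    ref_count = 10L, alt_count = 10L,
    paternal_ratio = c(0.1, 0.2, 0.9, 0.5),
    allelic_ratio = 0.5, balance = 0.5,
    gene_ids = list("G1", "G1", "G1", "G2")
  )
  summaries <- tibble::tibble(
    sample_id = c("S1", "S2"),
    median_paternal_ratio = c(0.2, 0.9)
  )
  recs <- gene_sample_medians(filtered, summaries, c("S1", "S2"))
  g1 <- recs[recs$gene_id == "G1", ]
  expect_equal(g1$Mg, 0.2) # median of three
  expect_equal(g1$n_snvs_in_gene, 3L)
  expect_true(g1$agrees_with_chromosome) # both below 0.5
  g2 <- recs[recs$gene_id == "G2", ]
  expect_equal(g2$Mg, 0.5) # single-SNV median, tie case
  expect_equal(g2$Sg, 0)
  expect_true(g2$agrees_with_chromosome) # ties count as agreement
})

test_that("the escape test matches an independent paired-t oracle", {
  sx <- c(0.30, 0.25, 0.35, 0.40, 0.28)
  sg <- c(0.05, 0.02, 0.10, 0.00, 0.04)
  res <- escape_test(gene_rec(sx, sg))
  oracle <- oracle_paired_t(sx - sg)
  expect_equal(res$t_statistic, oracle$t)
  expect_equal(res$p_value, oracle$p)
  expect_equal(res$degrees_of_freedom, 4)
  # frozen values from the oracle: mean difference 0.274, t ~= 8.64,
  # one-sided p ~= 5e-4
  expect_equal(mean(sx - sg), 0.274)
  expect_equal(res$t_statistic, 8.639, tolerance = 1e-3)
  expect_equal(res$p_value, 4.94e-4, tolerance = 1e-2)
  expect_true(res$escapee_call)

  # disagreeing genes enter with a negative signed skew factor
  res2 <- escape_test(gene_rec(sx, sg, agree = FALSE))
  oracle2 <- oracle_paired_t(sx + sg)
  expect_equal(res2$t_statistic, oracle2$t)
  expect_equal(res2$p_value, oracle2$p)
})

test_that("degenerate and under-sampled genes are handled explicitly", {
  sx <- c(0.3, 0.2, 0.4, 0.25, 0.35)
  expect_warning(
    res <- escape_test(gene_rec(sx, sx)), "zero variance"
  )
  expect_true(res$untestable)
  expect_true(is.na(res$escapee_call))

  small <- gene_rec(sx[1:4], rep(0, 4))
  res2 <- escape_test(small)
  expect_true(is.na(res2$p_value))
  expect_equal(res2$n_samples, 4L)
})

test_that("the pseudocode argument-order variant is the reversed one-sided test", {
  sx <- c(0.30, 0.25, 0.35, 0.40, 0.28)
  sg <- c(0.05, 0.02, 0.10, 0.00, 0.04)
  stated <- escape_test(gene_rec(sx, sg), hypothesis = "stated")
  pseudo <- escape_test(gene_rec(sx, sg), hypothesis = "pseudocode")
  expect_equal(stated$p_value + pseudo$p_value, 1)
  expect_equal(stated$t_statistic, pseudo$t_statistic)
})

test_that("the screen calls synthetic escapees and not inactivated genes", {
  cfg <- cohort_config(
    n_trios = 40, n_genes = 25, snvs_per_individual = c(100L, 150L),
    coverage_mean = 60, coverage_min = 30, reference_bias = 0.5,
    escapee_fraction = 0.2, variable_escapee_fraction = 0,
    include_mothers = FALSE, seed = 19
  )
  cohort <- generate_cohort(cfg)
  suppressMessages({
    phased <- phase_counts(
      cohort$counts, assign_parent_of_origin(cohort$genotypes)
    )
    filtered <- filter_snvs(phased, cohort$exons, cohort$par)
  })
  screen <- run_escape_screen(filtered)
  status <- cohort$truth$genes
  merged <- dplyr::inner_join(
    tibble::as_tibble(screen), status,
    by = "gene_id"
  )
  esc <- merged[merged$status == "escapee", ]
  inact <- merged[merged$status == "inactivated", ]
  expect_gt(nrow(esc), 0)
  expect_gt(mean(esc$escapee_call), 0.8)
  expect_lt(mean(inact$escapee_call), 0.2)
  # escapee genes are less skewed than the chromosome in the audit records
  recs <- dplyr::inner_join(
    attr(screen, "records"), status,
    by = "gene_id"
  )
  expect_lt(
    mean(recs$Sg[recs$status == "escapee"]),
    mean(recs$Sx[recs$status == "escapee"])
  )
  # determinism
  screen2 <- run_escape_screen(filtered)
  expect_equal(tibble::as_tibble(screen), tibble::as_tibble(screen2))
  # XIST opposes the chromosome-wide skew
  xist <- xist_check(attr(screen, "records"))
  expect_equal(xist$status, "ok")
  expect_gt(xist$fraction_opposed, 0.9)
})

test_that("the screen is invariant under global parental relabeling", {
  cohort <- generate_cohort(small_config(seed = 23, n_trios = 20))
  suppressMessages({
    phased <- phase_counts(
      cohort$counts, assign_parent_of_origin(cohort$genotypes)
    )
    f1 <- filter_snvs(phased, cohort$exons, cohort$par)
    f2 <- filter_snvs(
      swap_parental_labels(phased), cohort$exons, cohort$par
    )
  })
  s1 <- run_escape_screen(f1)
  s2 <- run_escape_screen(f2)
  # Mg/Mx in the audit records mirror (attributes excluded); the result
  # table itself must be identical
  expect_equal(
    dplyr::arrange(tibble::as_tibble(s1), gene_id),
    dplyr::arrange(tibble::as_tibble(s2), gene_id),
    ignore_attr = TRUE
  )
  r1 <- dplyr::arrange(attr(s1, "records"), gene_id, sample_id)
  r2 <- dplyr::arrange(attr(s2, "records"), gene_id, sample_id)
  expect_equal(r1$Sg, r2$Sg)
  expect_equal(r1$Sx, r2$Sx)
  expect_equal(r1$agrees_with_chromosome, r2$agrees_with_chromosome)
})

test_that("xist opposition flags individual samples", {
  recs <- tibble::tibble(
    gene_id = "XIST", sample_id = c("a", "b"),
    n_snvs_in_gene = 1L,
    Mg = c(0.1, 0.9), Sg = 0.4,
    Mx = c(0.9, 0.9), Sx = 0.4,
    agrees_with_chromosome = c(FALSE, TRUE)
  )
  chk <- xist_check(recs)
  expect_equal(chk$per_sample$opposed, c(TRUE, FALSE))
  expect_equal(chk$fraction_opposed, 0.5)
  empty <- xist_check(recs[0, ])
  expect_equal(empty$status, "uninformative")
})
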