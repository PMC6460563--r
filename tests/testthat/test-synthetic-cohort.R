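test_that("individual skew follows the precursor-cell binomial model", {
  expect_error(draw_individual_skew(0), "n_cells")
  expect_error(draw_individual_skew(NA), "n_cells")

  withr::with_seed(101, {
    one_cell <- draw_individual_skew(1, n = 2000)
    expect_true(all(one_cell %in% c(0, 1)))
    expect_lt(abs(mean(one_cell) - 0.5), 3 * 0.5 / sqrt(2000))
  })

  # exact probabilities by brute-force enumeration of all cell-choice vectors
  enum8 <- as.matrix(expand.grid(rep(list(0:1), 8)))
  expect_equal(mean(rowMeans(enum8) >= 6 / 8), 37 / 256)
  enum4 <- as.matrix(expand.grid(rep(list(0:1), 4)))
  expect_equal(mean(rowMeans(enum4) == 1), 1 / 16)

  withr::with_seed(202, {
    draws <- draw_individual_skew(8, n = 1e5)
    expect_true(all(draws * 8 == round(draws * 8)))
    p_hat <- mean(draws >= 6 / 8)
    se <- sqrt((37 / 256) * (1 - 37 / 256) / 1e5)
    expect_lt(abs(p_hat - 37 / 256), 3 * se)
    expect_lt(abs(var(draws) - 1 / 32), 3e-3)
  })
})

test_that("trio genotypes are Mendelian-consistent with informative counts in range", {
  cfg <- small_config()
  g <- generate_trio_genotypes(cfg)
  inf <- dplyr::count(dplyr::filter(g, site_class == "informative"), trio_id)
  expect_true(all(inf$n >= 30 & inf$n <= 60))

  # every informative site: daughter het, father allele in daughter,
  # maternal allele carried by mother
  suppressMessages({
    a <- assign_parent_of_origin(g)
  })
  inf_rows <- a[a$site_class == "informative", ]
  expect_true(all(inf_rows$phase_status == "informative"))
  hom_rows <- a[a$site_class == "homozygous", ]
  expect_true(all(hom_rows$phase_status == "not_informative"))

  # determinism under a fixed seed
  expect_identical(g, generate_trio_genotypes(cfg))
})

test_that("injected Mendelian errors are flagged at the injected rate", {
  cfg <- cohort_config(
    n_trios = 30, n_genes = 30, snvs_per_individual = c(100L, 150L),
    mendelian_error_rate = 0.05, seed = 5
  )
  g <- generate_trio_genotypes(cfg)
  a <- assign_parent_of_origin(g)
  het <- a[a$site_class != "homozygous", ]
  expect_identical(
    het$phase_status == "inconsistent",
    het$mendelian_error
  )
  n_het <- nrow(het)
  rate <- mean(het$phase_status == "inconsistent")
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_het))
})

test_that("generated counts respect gene status and skew", {
  # forced configurations, beta = 0.5 (no bias)
  genotypes <- tibble::tibble(
    trio_id = "T001", sample_id = "T001_d", chrom = "X",
    pos = c(1000L, 2000L, 3000L),
    ref = "A", alt = "G",
    daughter_gt = "A/G", mother_gt = "G/G", father_allele = "A",
    true_gene = c("g_inact", "g_esc", "g_xist"),
    site_class = "informative", mendelian_error = FALSE
  )
  truth <- list(
    individuals = tibble::tibble(
      sample_id = "T001_d", trio_id = "T001", role = "daughter",
      theta = 1, n_cells = 8
    ),
    genes = tibble::tibble(
      gene_id = c("g_inact", "g_esc", "g_xist"),
      status = c("inactivated", "escapee", "xist")
    ),
    variable_escape = tibble::tibble(
      gene_id = character(), sample_id = character(), escapes = logical()
    )
  )
  cfg <- cohort_config(n_trios = 1, reference_bias = 0.5, seed = 2)
  counts <- generate_counts(genotypes, truth, cfg)
  # theta = 1, paternal = A = ref: inactivated gene fully paternal,
  # xist fully maternal, escapee mixed
  expect_equal(counts$alt_count[1], 0L) # all reads paternal (ref)
  expect_equal(counts$ref_count[3], 0L) # xist: all reads maternal (alt)
  expect_gt(counts$ref_count[2], 0L)
  expect_gt(counts$alt_count[2], 0L)

  bad_truth <- truth
  bad_truth$genes$status[1] <- "mystery"
  expect_error(
    generate_counts(genotypes, bad_truth, cfg), NA
  ) # unknown status strings fall back to inactivated behaviour
  bad_genes <- genotypes
  bad_genes$true_gene[1] <- "unlisted_gene"
  expect_error(generate_counts(bad_genes, truth, cfg), "truth status")
})

test_that("escapee genes are balanced and XIST opposes skew in expectation", {
  cfg <- cohort_config(
    n_trios = 20, n_genes = 40, snvs_per_individual = c(80L, 120L),
    coverage_mean = 60, coverage_min = 30, reference_bias = 0.5,
    escapee_fraction = 0.25, variable_escapee_fraction = 0,
    include_mothers = FALSE, seed = 31
  )
  cohort <- generate_cohort(cfg)
  suppressMessages({
    a <- assign_parent_of_origin(cohort$genotypes)
    phased <- phase_counts(cohort$counts, a)
  })
  truthy <- dplyr::left_join(
    dplyr::inner_join(
      phased,
      dplyr::select(cohort$genotypes, sample_id, pos, true_gene),
      by = c("sample_id", "pos")
    ),
    cohort$truth$genes,
    by = c(true_gene = "gene_id")
  )
  truthy <- dplyr::left_join(
    truthy,
    dplyr::select(cohort$truth$individuals, sample_id, theta),
    by = "sample_id"
  )
  esc <- dplyr::filter(truthy, status %in% "escapee")
  expect_lt(abs(mean(esc$paternal_ratio) - 0.5), 0.02)
  skewed <- dplyr::filter(truthy, abs(theta - 0.5) >= 0.25, !is.na(status))
  xist <- dplyr::filter(skewed, status %in% "xist")
  inact <- dplyr::filter(skewed, status %in% "inactivated")
  expect_gt(nrow(xist), 0)
  # per-read expectation: xist paternal fraction = 1 - theta
  expect_lt(
    abs(mean(xist$paternal_ratio) - mean(1 - xist$theta)), 0.05
  )
  expect_lt(abs(mean(inact$paternal_ratio) - mean(inact$theta)), 0.05)
})

test_that("reference bias shifts allelic ratios left and beta = 0.5 leaves them centred", {
  base <- list(
    n_trios = 30, n_genes = 30, snvs_per_individual = c(60L, 100L),
    include_mothers = FALSE, seed = 77
  )
  biased <- generate_cohort(do.call(
    cohort_config, c(base, reference_bias = 0.45)
  ))
  unbiased <- generate_cohort(do.call(
    cohort_config, c(base, reference_bias = 0.5)
  ))
  ratio <- function(cohort) {
    counts <- cohort$counts
    keep <- counts$ref_count + counts$alt_count >= 10
    mean(counts$alt_count[keep] / (counts$ref_count + counts$alt_count)[keep])
  }
  expect_lt(ratio(biased), 0.48)
  expect_lt(abs(ratio(unbiased) - 0.5), 0.01)
})

test_that("cohort bundles are self-consistent and byte-identical under a seed", {
  cfg <- small_config(seed = 42)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$truth, c2$truth)

  expect_true(all(c1$counts$ref_count >= 0 & c1$counts$alt_count >= 0))
  expect_setequal(
    unique(c1$truth$genes$status[c1$truth$genes$gene_id == "XIST"]), "xist"
  )
  expect_equal(sum(c1$truth$genes$status == "xist"), 1)
  # theta on the precursor grid
  th <- c1$truth$individuals$theta
  expect_true(all(th * cfg$n_cells == round(th * cfg$n_cells)))
  # counts exist for daughters and mothers
  expect_setequal(
    sort(unique(c1$counts$sample_id)),
    sort(c(c1$trios$daughter, c1$trios$mother))
  )
})
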