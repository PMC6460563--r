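#' Draw per-individual X-inactivation skew from the precursor-cell model
#'
#' Each of `n_cells` embryonic precursor cells independently inactivates the
#' maternal or the paternal X with probability 0.5; the individual's true skew
#' is the fraction of cells that kept the paternal X active. The marginal
#' distribution is therefore `Binomial(n_cells, 0.5) / n_cells`, taking values
#' on the grid `k / n_cells`.
#'
#' Uses the current RNG state; wrap in [withr::with_seed()] (or call
#' `set.seed()`) for reproducibility.
#'
#' @param n_cells Number of precursor cells (>= 1).
#' @param n Number of individuals to draw.
#' @return Numeric vector of length `n` with values in `[0, 1]`.
#' @export
#' @examples
#' set.seed(1)
#' draw_individual_skew(8, n = 5)
draw_individual_skew <- function(n_cells, n = 1) {
  if (length(n_cells) != 1 || is.na(n_cells) || n_cells < 1) {
    stop("`n_cells` must be a single integer >= 1", call. = FALSE)
  }
  stats::rbinom(n, size = as.integer(n_cells), prob = 0.5) / as.integer(n_cells)
}

bases <- c("A", "C", "G", "T")

# random alternative base different from ref, vectorized
random_alt_base <- function(ref) {
  bases[(match(ref, bases) + sample.int(3, length(ref), replace = TRUE) - 1) %% 4 + 1]
}

sort_gt <- function(a1, a2) {
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

# Simulated gene catalog: non-overlapping genes tiled across the non-PAR X,
# each with a handful of exons, plus one gene inside PAR1 so the PAR filter is
# exercised. Returns list(genes, exons) with BED-style 0-based half-open exons.
make_gene_catalog <- function(config) {
  withr::with_seed(stage_seed(config$seed, "genes"), {
    par <- config$par_intervals
    region_start <- max(par$end[par$start < config$chrom_length / 2]) + 100000
    region_end <- min(par$start[par$start > config$chrom_length / 2]) - 100000
    window <- floor((region_end - region_start) / config$n_genes)
    gene_id <- sprintf("GENE%04d", seq_len(config$n_genes))
    gene_start <- region_start + (seq_len(config$n_genes) - 1) * window +
      floor(runif(config$n_genes, 0, window / 4))
    exons <- purrr::map2_dfr(gene_id, gene_start, function(g, gs) {
      n_ex <- sample(2:8, 1)
      widths <- sample(200:1500, n_ex, replace = TRUE)
      gaps <- sample(500:4000, n_ex, replace = TRUE)
      starts <- gs + cumsum(gaps) + c(0, cumsum(widths))[seq_len(n_ex)]
      tibble::tibble(
        chrom = config$chrom, start = starts, end = starts + widths, gene_id = g
      )
    })
    # rename the gene nearest the X-inactivation centre (~73 Mb on GRCh37) XIST
    mids <- gene_start + window / 2
    xist_idx <- which.min(abs(mids - 73e6))
    exons$gene_id[exons$gene_id == gene_id[xist_idx]] <- "XIST"
    gene_id[xist_idx] <- "XIST"
    # one expressed gene inside PAR1 (escapes inactivation by definition)
    par1 <- par[which.min(par$start), ]
    par_starts <- par1$start + 1e6 + c(0, 3000, 6000)
    par_exons <- tibble::tibble(
      chrom = config$chrom, start = par_starts, end = par_starts + 1500,
      gene_id = "PAR1GENE"
    )
    list(
      genes = tibble::tibble(gene_id = c(gene_id, "PAR1GENE")),
      exons = dplyr::arrange(dplyr::bind_rows(exons, par_exons), .data$start)
    )
  })
}

# Gene escape statuses and per-individual skew: the cohort truth table.
make_truth <- function(config, catalog, sample_ids) {
  genes <- catalog$genes$gene_id
  nonpar <- setdiff(genes, "PAR1GENE")
  withr::with_seed(stage_seed(config$seed, "status"), {
    status <- setNames(rep("inactivated", length(nonpar)), nonpar)
    status["XIST"] <- "xist"
    eligible <- setdiff(nonpar, "XIST")
    n_esc <- round(config$escapee_fraction * length(eligible))
    esc <- sample(eligible, n_esc)
    status[esc] <- "escapee"
    n_var <- round(config$variable_escapee_fraction * n_esc)
    if (n_var > 0) status[sample(esc, n_var)] <- "variable_escapee"
    gene_status <- tibble::tibble(
      gene_id = c(nonpar, "PAR1GENE"),
      status = c(unname(status[nonpar]), "par")
    )
    var_genes <- gene_status$gene_id[gene_status$status == "variable_escapee"]
    variable_escape <- tidyr::expand_grid(
      gene_id = var_genes, sample_id = sample_ids
    )
    variable_escape$escapes <-
      runif(nrow(variable_escape)) < config$variable_escape_prob
    list(genes = gene_status, variable_escape = variable_escape)
  })
}

draw_coverage <- function(n, config) {
  config$coverage_min + stats::rnbinom(
    n,
    size = config$coverage_dispersion,
    mu = config$coverage_mean - config$coverage_min
  )
}

# Sample SNV positions from exons (weighted by exon width); 1-based positions.
sample_exonic_positions <- function(exons, n) {
  w <- exons$end - exons$start
  idx <- sample.int(nrow(exons), n, replace = TRUE, prob = w)
  tibble::tibble(
    pos = exons$start[idx] + floor(runif(n) * w[idx]) + 1,
    gene_id = exons$gene_id[idx]
  )
}

#' Generate trio genotypes at simulated X-chromosomal SNVs
#'
#' For each trio, produces daughter-heterozygous ("informative") sites inside
#' exons and outside the PARs -- the father hemizygous for one of the two
#' alleles and the mother carrying the complementary (maternal) allele -- plus
#' daughter-homozygous, pseudoautosomal and non-exonic sites so that every
#' downstream filter has work to do. A configurable fraction of sites carries
#' an injected Mendelian inconsistency (mother lacking the maternal allele).
#'
#' @param config A [cohort_config()].
#' @param catalog Optional gene catalog (as built internally); when `NULL` a
#'   catalog is derived from `config`.
#' @return A tibble with one row per (trio, site): `trio_id`, `sample_id` (the
#'   daughter), `chrom`, `pos`, `ref`, `alt`, `daughter_gt`, `mother_gt`,
#'   `father_allele`, plus generator annotations `true_gene` and `site_class`.
#' @export
#' @examples
#' g <- generate_trio_genotypes(cohort_config(n_trios = 2, seed = 1))
#' table(g$site_class)
generate_trio_genotypes <- function(config, catalog = NULL) {
  if (is.null(catalog)) catalog <- make_gene_catalog(config)
  exons <- catalog$exons
  nonpar_exons <- exons[exons$gene_id != "PAR1GENE", ]
  par_exons <- exons[exons$gene_id == "PAR1GENE", ]
  withr::with_seed(stage_seed(config$seed, "genotypes"), {
    purrr::map_dfr(seq_len(config$n_trios), function(i) {
      trio_id <- sprintf("T%03d", i)
      n_inf <- sample(
        config$snvs_per_individual[1]:config$snvs_per_individual[2], 1
      )
      # informative: draw extra, deduplicate positions, keep exactly n_inf
      inf <- sample_exonic_positions(nonpar_exons, ceiling(n_inf * 1.3))
      inf <- dplyr::distinct(inf, .data$pos, .keep_all = TRUE)
      inf <- inf[seq_len(min(n_inf, nrow(inf))), ]
      inf$site_class <- "informative"

      hom <- sample_exonic_positions(nonpar_exons, config$n_homozygous)
      hom$site_class <- "homozygous"
      par_sites <- sample_exonic_positions(par_exons, config$n_par_sites)
      par_sites$site_class <- "par"
      # non-exonic: uniform over the chromosome, rejecting exon overlaps
      cand <- floor(runif(config$n_nonexonic * 4, 1, config$chrom_length))
      in_exon <- vapply(
        cand, function(p) any(p > exons$start & p <= exons$end), logical(1)
      )
      in_par <- vapply(
        cand,
        function(p) {
          any(p > config$par_intervals$start & p <= config$par_intervals$end)
        },
        logical(1)
      )
      nx <- tibble::tibble(
        pos = cand[!in_exon & !in_par][seq_len(config$n_nonexonic)],
        gene_id = NA_character_, site_class = "nonexonic"
      )

      sites <- dplyr::bind_rows(inf, hom, par_sites, nx)
      sites <- dplyr::distinct(sites, .data$pos, .keep_all = TRUE)
      n <- nrow(sites)
      ref <- sample(bases, n, replace = TRUE)
      alt <- random_alt_base(ref)
      het <- sites$site_class != "homozygous"

      father <- ifelse(runif(n) < 0.5, ref, alt)
      maternal <- ifelse(father == ref, alt, ref)
      mother_other <- ifelse(runif(n) < 0.5, ref, alt)
      daughter_gt <- sort_gt(father, maternal)
      mother_gt <- sort_gt(maternal, mother_other)
      # homozygous daughter sites: both alleles identical, trio consistent
      hom_allele <- ifelse(runif(n) < 0.5, ref, alt)
      daughter_gt[!het] <- sort_gt(hom_allele, hom_allele)[!het]
      father[!het] <- hom_allele[!het]
      mother_gt[!het] <- sort_gt(hom_allele, hom_allele)[!het]
      # injected Mendelian errors: mother homozygous for the paternal allele
      err <- het & runif(n) < config$mendelian_error_rate
      mother_gt[err] <- sort_gt(father, father)[err]

      tibble::tibble(
        trio_id = trio_id,
        sample_id = paste0(trio_id, "_d"),
        chrom = config$chrom,
        pos = sites$pos,
        ref = ref, alt = alt,
        daughter_gt = daughter_gt,
        mother_gt = mother_gt,
        father_allele = father,
        true_gene = sites$gene_id,
        site_class = sites$site_class,
        mendelian_error = err
      )
    })
  })
}

# expected paternal-read fraction per record given gene status and skew theta
expected_paternal_fraction <- function(status, theta, escapes) {
  dplyr::case_when(
    status %in% c("escapee", "par") ~ 0.5,
    status == "variable_escapee" & escapes ~ 0.5,
    status == "xist" ~ 1 - theta,
    TRUE ~ theta # inactivated, variable not escaping, or unannotated
  )
}

#' Generate allele-specific read counts for daughters
#'
#' For each genotyped site of each daughter, draws read coverage from the
#' configured negative-binomial model, splits reads between the paternal and
#' maternal allele as `Binomial(coverage, f)` -- where `f` is the daughter's
#' true skew for inactivated genes, 0.5 for escapees, and `1 - skew` for XIST
#' (expressed from the inactive X) -- relabels reads as reference/alternative
#' according to which allele is paternal, and finally thins alternative-allele
#' reads to emulate reference bias.
#'
#' @param genotypes Output of [generate_trio_genotypes()].
#' @param truth Truth tables as built by [generate_cohort()] (`$individuals`,
#'   `$genes`, `$variable_escape`).
#' @param config A [cohort_config()].
#' @return Counts tibble: `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`.
#' @export
generate_counts <- function(genotypes, truth, config) {
  status_tbl <- truth$genes
  bad <- setdiff(
    unique(stats::na.omit(genotypes$true_gene)), status_tbl$gene_id
  )
  if (length(bad) > 0) {
    stop("genes without a truth status: ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  withr::with_seed(stage_seed(config$seed, "counts"), {
    g <- genotypes %>%
      dplyr::left_join(status_tbl, by = c(true_gene = "gene_id")) %>%
      dplyr::left_join(
        dplyr::select(
          truth$individuals, "sample_id", "theta"
        ),
        by = "sample_id"
      ) %>%
      dplyr::left_join(
        truth$variable_escape,
        by = c(true_gene = "gene_id", "sample_id")
      )
    n <- nrow(g)
    cov <- draw_coverage(n, config)
    f_pat <- expected_paternal_fraction(
      g$status, g$theta, !is.na(g$escapes) & g$escapes
    )
    pat <- stats::rbinom(n, cov, f_pat)
    pat_is_ref <- g$father_allele == g$ref
    ref_count <- ifelse(pat_is_ref, pat, cov - pat)
    # daughter-homozygous sites express the single allele only
    hom <- g$site_class == "homozygous"
    hom_is_ref <- substr(g$daughter_gt, 1, 1) == g$ref
    ref_count[hom] <- ifelse(hom_is_ref[hom], cov[hom], 0L)
    alt_count <- cov - ref_count
    # reference bias: keep each alternative read with probability beta/(1-beta)
    keep <- min(1, config$reference_bias / (1 - config$reference_bias))
    alt_count <- stats::rbinom(n, alt_count, keep)
    tibble::tibble(
      sample_id = g$sample_id, chrom = g$chrom, pos = g$pos,
      ref = g$ref, alt = g$alt,
      ref_count = as.integer(ref_count), alt_count = as.integer(alt_count)
    )
  })
}

# Mothers are unphased: at each heterozygous site it is random which homolog
# carries the alternative allele, so the alt-read fraction is theta or
# 1 - theta with equal probability (symmetric, as the measure of balance
# requires). Mothers get their own exonic non-PAR heterozygous sites.
generate_mother_counts <- function(truth, catalog, config) {
  mothers <- truth$individuals[truth$individuals$role == "mother", ]
  if (nrow(mothers) == 0) {
    return(tibble::tibble(
      sample_id = character(), chrom = character(), pos = integer(),
      ref = character(), alt = character(),
      ref_count = integer(), alt_count = integer()
    ))
  }
  exons <- catalog$exons[catalog$exons$gene_id != "PAR1GENE", ]
  status_tbl <- truth$genes
  withr::with_seed(stage_seed(config$seed, "mothers"), {
    purrr::map_dfr(seq_len(nrow(mothers)), function(i) {
      m <- mothers[i, ]
      n_sites <- sample(
        config$snvs_per_individual[1]:config$snvs_per_individual[2], 1
      )
      sites <- sample_exonic_positions(exons, ceiling(n_sites * 1.3))
      sites <- dplyr::distinct(sites, .data$pos, .keep_all = TRUE)
      sites <- sites[seq_len(min(n_sites, nrow(sites))), ]
      n <- nrow(sites)
      ref <- sample(bases, n, replace = TRUE)
      alt <- random_alt_base(ref)
      status <- status_tbl$status[match(sites$gene_id, status_tbl$gene_id)]
      escapes <- rep(FALSE, n)
      if (nrow(truth$variable_escape) > 0) {
        ve <- truth$variable_escape[
          truth$variable_escape$sample_id == m$sample_id,
        ]
        idx <- match(sites$gene_id, ve$gene_id)
        escapes <- !is.na(idx) & ve$escapes[idx]
        escapes[is.na(escapes)] <- FALSE
      }
      f_hap1 <- expected_paternal_fraction(status, m$theta, escapes)
      alt_on_hap1 <- runif(n) < 0.5
      f_alt <- ifelse(alt_on_hap1, f_hap1, 1 - f_hap1)
      cov <- draw_coverage(n, config)
      alt_raw <- stats::rbinom(n, cov, f_alt)
      keep <- min(1, config$reference_bias / (1 - config$reference_bias))
      tibble::tibble(
        sample_id = m$sample_id, chrom = config$chrom, pos = sites$pos,
        ref = ref, alt = alt,
        ref_count = as.integer(cov - alt_raw),
        alt_count = as.integer(stats::rbinom(n, alt_raw, keep))
      )
    })
  })
}

#' Generate a complete synthetic trio cohort
#'
#' Produces a self-consistent bundle -- trio genotypes, allele-specific read
#' counts for daughters (and optionally mothers), exon and PAR annotation, and
#' the ground-truth tables (per-individual skew, per-gene escape status) --
#' with the statistical structure the downstream analysis assumes. Fixing
#' `config$seed` makes the bundle bit-identical across runs.
#'
#' @param config A [cohort_config()].
#' @return A list of class `xi_cohort` with elements `genotypes`, `counts`,
#'   `exons`, `par`, `trios`, `truth` (list: `individuals`, `genes`,
#'   `variable_escape`) and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_trios = 3, seed = 7))
#' cohort
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  catalog <- make_gene_catalog(config)
  trio_id <- sprintf("T%03d", seq_len(config$n_trios))
  individuals <- tibble::tibble(
    sample_id = c(
      paste0(trio_id, "_d"),
      if (config$include_mothers) paste0(trio_id, "_m")
    ),
    trio_id = c(trio_id, if (config$include_mothers) trio_id),
    role = c(
      rep("daughter", config$n_trios),
      if (config$include_mothers) rep("mother", config$n_trios)
    )
  )
  individuals$theta <- withr::with_seed(
    stage_seed(config$seed, "skew"),
    draw_individual_skew(config$n_cells, nrow(individuals))
  )
  individuals$n_cells <- config$n_cells
  truth <- make_truth(config, catalog, individuals$sample_id)
  truth$individuals <- individuals

  genotypes <- generate_trio_genotypes(config, catalog)
  counts <- dplyr::bind_rows(
    generate_counts(genotypes, truth, config),
    generate_mother_counts(truth, catalog, config)
  )
  structure(
    list(
      genotypes = genotypes,
      counts = counts,
      exons = catalog$exons,
      par = config$par_intervals,
      trios = tibble::tibble(
        trio_id = trio_id,
        daughter = paste0(trio_id, "_d"),
        father = paste0(trio_id, "_f"),
        mother = paste0(trio_id, "_m")
      ),
      truth = truth,
      config = config
    ),
    class = "xi_cohort"
  )
}

#' @export
print.xi_cohort <- function(x, ...) {
  cat("<xi_cohort>\n")
  cat(sprintf(
    "  %d trios, %d genotyped sites, %d count records, %d genes\n",
    x$config$n_trios, nrow(x$genotypes), nrow(x$counts),
    nrow(x$truth$genes)
  ))
  cat(sprintf(
    "  gene statuses: %s\n",
    paste(names(table(x$truth$genes$status)),
      table(x$truth$genes$status),
      sep = "=", collapse = ", "
    )
  ))
  invisible(x)
}
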