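#' Run the full X-inactivation skewing analysis
#'
#' Orchestrates every stage on a cohort (an `xi_cohort` object or the list
#' returned by [read_inputs()]): parent-of-origin assignment, count phasing,
#' SNV filtering, per-individual summaries and skew classification for
#' daughters, balance-based summaries for mothers, the mother-daughter
#' correlation, the gene-level escape screen, the XIST opposition check, and
#' the precursor-cell model fit on the per-daughter median paternal ratios.
#'
#' @param cohort `xi_cohort` or [read_inputs()] list.
#' @param min_coverage Minimum reads per SNV (default 10).
#' @param alpha Escapee call threshold (default 0.05).
#' @param min_gene_samples Minimum skewed samples per tested gene (default 5).
#' @param skew_lower,skew_upper Skew thresholds on Mx (0.35 / 0.65).
#' @param candidates Precursor-cell counts to compare (default 4, 8, 16, 32).
#' @param reps Simulated individuals per candidate (default 10000).
#' @param xist_gene Gene id of XIST in the exon annotation.
#' @param seed Seed for the precursor simulations.
#' @return List of class `xi_result` with elements `phased`, `filtered`,
#'   `summaries`, `classified`, `distribution`, `mother_summaries`,
#'   `mother_classified`, `pairs`, `correlation`, `screen`, `xist`,
#'   `precursor_fit`, `exclusions`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_trios = 6, seed = 3))
#' res <- run_pipeline(cohort, reps = 1000)
#' res$distribution
run_pipeline <- function(cohort,
                         min_coverage = 10,
                         alpha = 0.05,
                         min_gene_samples = 5,
                         skew_lower = 0.35,
                         skew_upper = 0.65,
                         candidates = c(4L, 8L, 16L, 32L),
                         reps = 10000,
                         xist_gene = "XIST",
                         seed = 1L) {
  stopifnot(all(c("genotypes", "counts", "exons", "par") %in% names(cohort)))
  trios <- cohort$trios
  daughters <- trios$daughter
  mothers <- if ("mother" %in% names(trios)) trios$mother else character()

  assignments <- assign_parent_of_origin(cohort$genotypes)
  d_counts <- cohort$counts[cohort$counts$sample_id %in% daughters, ]
  m_counts <- cohort$counts[cohort$counts$sample_id %in% mothers, ]
  phased <- phase_counts(d_counts, assignments)
  filtered <- filter_snvs(
    phased, cohort$exons, cohort$par,
    min_coverage = min_coverage
  )
  summaries <- summarize_individuals(filtered)
  classified <- classify_skew(
    summaries,
    lower = skew_lower, upper = skew_upper
  )
  distribution <- population_distribution(classified)

  mother_summaries <- NULL
  mother_classified <- NULL
  pairs <- NULL
  correlation <- NULL
  if (nrow(m_counts) > 0) {
    m_filtered <- filter_snvs(
      m_counts, cohort$exons, cohort$par,
      min_coverage = min_coverage
    )
    mother_summaries <- summarize_individuals(m_filtered)
    mother_classified <- classify_skew(
      mother_summaries,
      measure = "balance", lower = skew_lower
    )
    pairs <- trios %>%
      dplyr::transmute(
        .data$trio_id,
        daughter_balance = summaries$median_measure_of_balance[
          match(.data$daughter, summaries$sample_id)
        ],
        mother_balance = mother_summaries$median_measure_of_balance[
          match(.data$mother, mother_summaries$sample_id)
        ]
      )
    n_complete <- sum(!is.na(pairs$daughter_balance) &
      !is.na(pairs$mother_balance))
    correlation <- if (n_complete >= 3) {
      mother_daughter_correlation(pairs)
    } else {
      NULL
    }
  }

  screen <- run_escape_screen(
    filtered, summaries,
    alpha = alpha, min_samples = min_gene_samples,
    lower = skew_lower, upper = skew_upper
  )
  xist <- xist_check(
    attr(screen, "records") %||% gene_sample_medians(
      filtered, summaries,
      classified$sample_id[!is.na(classified$skew_class) &
        classified$skew_class != "balanced"]
    ),
    xist_gene = xist_gene
  )
  mx <- classified$median_paternal_ratio[
    !is.na(classified$median_paternal_ratio)
  ]
  precursor_fit <- select_precursor_count(
    mx,
    candidates = candidates, reps = reps, seed = seed
  )
  structure(
    list(
      phased = phased,
      filtered = filtered,
      summaries = summaries,
      classified = classified,
      distribution = distribution,
      mother_summaries = mother_summaries,
      mother_classified = mother_classified,
      pairs = pairs,
      correlation = correlation,
      screen = screen,
      xist = xist,
      precursor_fit = precursor_fit,
      exclusions = attr(filtered, "exclusions")
    ),
    class = "xi_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.xi_result <- function(x, ...) {
  cat("<xi_result>\n")
  cat(sprintf(
    "  %d daughters summarized; skew classes: %s\n",
    nrow(x$summaries),
    paste(x$distribution$skew_class, x$distribution$n,
      sep = "=", collapse = ", "
    )
  ))
  cn <- attr(x$screen, "counts")
  if (!is.null(cn)) {
    cat(sprintf(
      "  escape screen: %d genes seen, %d informative, %d called escapee\n",
      cn[["total_genes"]], cn[["informative_genes"]], cn[["called_genes"]]
    ))
  }
  cat(sprintf(
    "  precursor fit: %d cells selected\n",
    x$precursor_fit$selected_count
  ))
  invisible(x)
}

#' Write pipeline results to disk
#'
#' Emits the per-SNV phased/filtered table, per-individual summaries with
#' skew classes, the escape-screen results and audit records, the XIST
#' per-sample table, and a JSON report (class distribution, correlation,
#' precursor fit, filter exclusion counts).
#'
#' @param result An `xi_result` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  stopifnot(inherits(result, "xi_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  filtered_flat <- result$filtered %>%
    dplyr::mutate(
      gene_ids = vapply(.data$gene_ids, paste, "", collapse = ",")
    )
  readr::write_tsv(filtered_flat, p("snvs_filtered.tsv"))
  readr::write_tsv(result$classified, p("individuals.tsv"))
  if (!is.null(result$mother_classified)) {
    readr::write_tsv(result$mother_classified, p("mothers.tsv"))
  }
  readr::write_tsv(tibble::as_tibble(result$screen), p("escape_screen.tsv"))
  recs <- attr(result$screen, "records")
  if (!is.null(recs)) readr::write_tsv(recs, p("escape_screen_audit.tsv"))
  readr::write_tsv(result$xist$per_sample, p("xist_check.tsv"))
  jsonlite::write_json(
    list(
      skew_distribution = result$distribution,
      severity = as.list(attr(result$distribution, "severity")),
      mother_daughter_correlation = result$correlation,
      xist_fraction_opposed = result$xist$fraction_opposed,
      precursor_fit = list(
        candidates = result$precursor_fit$candidates,
        selected_count = result$precursor_fit$selected_count,
        reps = result$precursor_fit$reps
      ),
      exclusions = as.list(result$exclusions),
      escape_counts = as.list(attr(result$screen, "counts"))
    ),
    p("report.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = 6
  )
  invisible(dir)
}
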