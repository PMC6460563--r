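#' Per-gene, per-sample median paternal ratios for skewed individuals
#'
#' For every (gene, skewed sample) combination with at least one qualifying
#' SNV, computes the gene's median paternal ratio `Mg`, the gene skew factor
#' `Sg = |Mg - 0.5|`, and whether the gene's deviation from 0.5 points the
#' same way as the sample's chromosome-wide deviation (`Mx`). A gene median
#' of exactly 0.5 has `Sg = 0` and is treated as agreeing -- the two test
#' branches coincide there.
#'
#' @param filtered Output of [filter_snvs()] on phased daughter counts
#'   (must carry the `gene_ids` list-column).
#' @param summaries Output of [summarize_individuals()] for the same samples
#'   (provides `Mx`).
#' @param skewed_samples Character vector of skewed sample ids; gene records
#'   are restricted to these.
#' @return Tibble: `gene_id`, `sample_id`, `n_snvs_in_gene`, `Mg`, `Sg`,
#'   `Mx`, `Sx`, `agrees_with_chromosome`.
#' @export
gene_sample_medians <- function(filtered, summaries, skewed_samples) {
  stopifnot("gene_ids" %in% names(filtered))
  filtered %>%
    dplyr::filter(.data$sample_id %in% skewed_samples) %>%
    tidyr::unnest(cols = "gene_ids") %>%
    dplyr::rename(gene_id = "gene_ids") %>%
    dplyr::group_by(.data$gene_id, .data$sample_id) %>%
    dplyr::summarise(
      n_snvs_in_gene = dplyr::n(),
      Mg = median(.data$paternal_ratio),
      .groups = "drop"
    ) %>%
    dplyr::left_join(
      summaries %>%
        dplyr::transmute(
          .data$sample_id,
          Mx = .data$median_paternal_ratio,
          Sx = abs(.data$median_paternal_ratio - 0.5)
        ),
      by = "sample_id"
    ) %>%
    dplyr::mutate(
      Sg = abs(.data$Mg - 0.5),
      agrees_with_chromosome =
        (.data$Mg - 0.5) * (.data$Mx - 0.5) >= 0
    )
}

#' Paired skew-factor test for escape from X-inactivation in one gene
#'
#' Across skewed individuals, compares the gene skew factor `Sg` with the
#' chromosome-wide skew factor `Sx` of the same sample. The null hypothesis
#' is that the gene is as skewed as the rest of the X; the alternative is
#' that the gene sits closer to 0.5 (balanced biallelic expression --
#' escapee behaviour). When a gene's median deviates to the opposite side of
#' 0.5 from the chromosome, its skew factor enters with a negative sign. The
#' statistic is a one-sided paired t-test on
#' `d = Sx - (if agree, Sg, -Sg)` against `mean(d) > 0`.
#'
#' `hypothesis = "pseudocode"` runs the literal reversed-argument variant
#' `t.test(Sx, g, paired = TRUE, alternative = "less")` for comparison; its
#' alternative points the opposite way and it is not the default.
#'
#' @param records Gene-sample records for one gene
#'   (rows of [gene_sample_medians()]).
#' @param alpha Call threshold on the one-sided p-value (default 0.05).
#' @param min_samples Minimum number of skewed samples with SNVs in the gene
#'   (default 5); genes below it are not tested.
#' @param hypothesis `"stated"` (default) or `"pseudocode"` (see Details).
#' @return One-row tibble: `gene_id`, `n_samples`, `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `escapee_call`, `untestable`.
#' @export
#' @examples
#' rec <- tibble::tibble(
#'   gene_id = "G", sample_id = letters[1:5],
#'   n_snvs_in_gene = 2,
#'   Sx = c(0.30, 0.25, 0.35, 0.40, 0.28),
#'   Sg = c(0.05, 0.02, 0.10, 0.00, 0.04),
#'   agrees_with_chromosome = TRUE
#' )
#' escape_test(rec)
escape_test <- function(records, alpha = 0.05, min_samples = 5,
                        hypothesis = c("stated", "pseudocode")) {
  hypothesis <- match.arg(hypothesis)
  gene_id <- unique(records$gene_id)
  stopifnot(length(gene_id) == 1)
  n <- nrow(records)
  if (n < min_samples) {
    return(tibble::tibble(
      gene_id = gene_id, n_samples = n, t_statistic = NA_real_,
      degrees_of_freedom = NA_real_, p_value = NA_real_,
      escapee_call = NA, untestable = NA
    ))
  }
  g_signed <- ifelse(records$agrees_with_chromosome, records$Sg, -records$Sg)
  d <- records$Sx - g_signed
  if (stats::sd(d) == 0) {
    warning("gene ", gene_id, ": zero variance of paired differences; ",
      "untestable",
      call. = FALSE
    )
    return(tibble::tibble(
      gene_id = gene_id, n_samples = n, t_statistic = NA_real_,
      degrees_of_freedom = n - 1, p_value = NA_real_,
      escapee_call = NA, untestable = TRUE
    ))
  }
  if (hypothesis == "stated") {
    tt <- stats::t.test(d, mu = 0, alternative = "greater")
  } else {
    tt <- stats::t.test(records$Sx, g_signed,
      paired = TRUE, alternative = "less"
    )
  }
  tibble::tibble(
    gene_id = gene_id,
    n_samples = n,
    t_statistic = unname(tt$statistic),
    degrees_of_freedom = unname(tt$parameter),
    p_value = tt$p.value,
    escapee_call = tt$p.value < alpha,
    untestable = FALSE
  )
}

#' Screen every informative gene for escape from X-inactivation
#'
#' Identifies skewed individuals from the chromosome-wide summaries, builds
#' the per-gene per-sample medians, and runs [escape_test()] on every gene
#' with SNV coverage in at least `min_samples` skewed individuals. Genes in
#' which more than 90% of all SNV reads carry the reference allele across
#' samples are annotated `reference_bias_suspect` (a mapping-artifact guard)
#' but are not removed.
#'
#' @param filtered Output of [filter_snvs()] on phased daughter counts.
#' @param summaries Optional precomputed [summarize_individuals()] output.
#' @param alpha,min_samples,hypothesis Passed to [escape_test()].
#' @param lower,upper Chromosome-skew thresholds defining "skewed"
#'   individuals (defaults 0.35 / 0.65).
#' @return Tibble of class `escape_screen`, one row per informative gene,
#'   ordered by p-value; attributes `counts` (total / informative / tested /
#'   called genes and skewed samples) and `records` (the per-gene audit
#'   table).
#' @export
run_escape_screen <- function(filtered, summaries = NULL,
                              alpha = 0.05, min_samples = 5,
                              hypothesis = c("stated", "pseudocode"),
                              lower = 0.35, upper = 0.65) {
  hypothesis <- match.arg(hypothesis)
  if (is.null(summaries)) summaries <- summarize_individuals(filtered)
  classified <- classify_skew(summaries, lower = lower, upper = upper)
  skewed <- classified$sample_id[
    !is.na(classified$skew_class) & classified$skew_class != "balanced"
  ]
  all_genes <- unique(unlist(filtered$gene_ids))
  if (length(skewed) == 0) {
    warning("no skewed individuals; escape screen is empty", call. = FALSE)
    out <- tibble::tibble(
      gene_id = character(), n_samples = integer(), t_statistic = double(),
      degrees_of_freedom = double(), p_value = double(),
      escapee_call = logical(), untestable = logical(),
      reference_bias_suspect = logical()
    )
    attr(out, "counts") <- c(
      total_genes = length(all_genes), informative_genes = 0L,
      tested_genes = 0L, called_genes = 0L, skewed_samples = 0L
    )
    class(out) <- c("escape_screen", class(out))
    return(out)
  }
  recs <- gene_sample_medians(filtered, summaries, skewed)
  results <- recs %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::group_split() %>%
    purrr::map_dfr(
      escape_test,
      alpha = alpha, min_samples = min_samples, hypothesis = hypothesis
    )
  # reference-bias guard: fraction of reference reads pooled over samples
  ref_frac <- filtered %>%
    dplyr::filter(.data$sample_id %in% skewed) %>%
    tidyr::unnest(cols = "gene_ids") %>%
    dplyr::rename(gene_id = "gene_ids") %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(
      ref_fraction = sum(.data$ref_count) /
        sum(.data$ref_count + .data$alt_count),
      .groups = "drop"
    )
  out <- results %>%
    dplyr::left_join(ref_frac, by = "gene_id") %>%
    dplyr::mutate(reference_bias_suspect = .data$ref_fraction > 0.9) %>%
    dplyr::select(-"ref_fraction") %>%
    dplyr::filter(.data$n_samples >= min_samples) %>%
    dplyr::arrange(.data$p_value)
  attr(out, "counts") <- c(
    total_genes = length(all_genes),
    informative_genes = nrow(out),
    tested_genes = sum(!out$untestable, na.rm = TRUE),
    called_genes = sum(out$escapee_call, na.rm = TRUE),
    skewed_samples = length(skewed)
  )
  attr(out, "records") <- recs
  class(out) <- c("escape_screen", class(out))
  out
}

#' @export
glance.escape_screen <- function(x, ...) {
  cn <- attr(x, "counts")
  tibble::tibble(
    total_genes = cn[["total_genes"]],
    informative_genes = cn[["informative_genes"]],
    tested_genes = cn[["tested_genes"]],
    called_genes = cn[["called_genes"]],
    skewed_samples = cn[["skewed_samples"]]
  )
}

#' Check that XIST opposes the chromosome-wide skew
#'
#' XIST is expressed from the inactive X, so in a skewed individual its
#' median paternal ratio should fall on the opposite side of 0.5 from the
#' chromosome-wide median. Reports the per-sample opposition flag and the
#' cohort fraction among informative skewed samples.
#'
#' @param gene_medians Output of [gene_sample_medians()] (or the `records`
#'   attribute of an `escape_screen`).
#' @param xist_gene Gene identifier of XIST in the annotation.
#' @return List with `per_sample` (tibble: `sample_id`, `Mg`, `Mx`,
#'   `opposed`), `fraction_opposed`, `n_samples`, `status`.
#' @export
xist_check <- function(gene_medians, xist_gene = "XIST") {
  x <- gene_medians[gene_medians$gene_id == xist_gene, ]
  if (nrow(x) == 0) {
    return(list(
      per_sample = tibble::tibble(
        sample_id = character(), Mg = double(), Mx = double(),
        opposed = logical()
      ),
      fraction_opposed = NA_real_, n_samples = 0L, status = "uninformative"
    ))
  }
  per_sample <- x %>%
    dplyr::transmute(
      .data$sample_id, .data$Mg, .data$Mx,
      opposed = (.data$Mg - 0.5) * (.data$Mx - 0.5) < 0
    )
  list(
    per_sample = per_sample,
    fraction_opposed = mean(per_sample$opposed),
    n_samples = nrow(per_sample),
    status = "ok"
  )
}
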