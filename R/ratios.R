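#' Measure of balance of an allele-specific count pair
#'
#' `min(alternative, reference) / (alternative + reference)`: the distance-
#' free analogue of the allelic ratio, equal to `min(r, 1 - r)` for allelic
#' ratio `r`. It is 0.5 for perfectly balanced counts, 0 for monoallelic
#' expression, and usable when parental origin is unknown (mothers).
#'
#' @param ref_count,alt_count Non-negative read counts (vectorized).
#' @return Numeric vector in `[0, 0.5]`; `NaN` where total coverage is zero.
#' @export
#' @examples
#' measure_of_balance(7, 3)
#' measure_of_balance(c(5, 10), c(5, 0))
measure_of_balance <- function(ref_count, alt_count) {
  if (any(ref_count < 0 | alt_count < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  pmin(ref_count, alt_count) / (ref_count + alt_count)
}

# 1-based positions vs BED 0-based half-open intervals: position p overlaps
# [start, end) iff start < p <= end.
overlap_hits <- function(pos, intervals) {
  q <- IRanges::IRanges(start = pos, width = 1)
  s <- IRanges::IRanges(start = intervals$start + 1, end = intervals$end)
  IRanges::findOverlaps(q, s)
}

#' Apply the SNV inclusion filters
#'
#' Keeps records with total coverage (`ref_count + alt_count`) of at least
#' `min_coverage` reads, a position overlapping at least one annotated exon,
#' and a position outside every pseudoautosomal interval. Overlapping gene
#' identifiers are attached as a list-column (`gene_ids`): an SNV inside two
#' overlapping genes contributes to both in the gene-level analysis but
#' remains a single row of the chromosome-wide summary.
#'
#' Excluded records are tallied by reason (one category per record, in the
#' order unphased > low coverage > non-exonic > PAR) in the `exclusions`
#' attribute of the result and reported via `message()`.
#'
#' @param records Phased-counts tibble from [phase_counts()], or any counts
#'   tibble with `chrom`, `pos`, `ref_count`, `alt_count` (mothers have no
#'   phasing columns).
#' @param exons BED-style tibble (`chrom`, `start`, `end`, `gene_id`),
#'   0-based half-open.
#' @param par_intervals BED-style tibble of PAR intervals, or `NULL` to skip
#'   the PAR filter.
#' @param min_coverage Minimum total read count (default 10).
#' @return Filtered tibble with added `gene_ids` list-column and `exonic`,
#'   `in_par` flags; attribute `exclusions` holds the per-category counts.
#' @export
filter_snvs <- function(records, exons, par_intervals = NULL,
                        min_coverage = 10) {
  stopifnot(all(c("pos", "ref_count", "alt_count") %in% names(records)))
  stopifnot(all(c("start", "end", "gene_id") %in% names(exons)))
  if (nrow(records) == 0) {
    warning("no input records to filter", call. = FALSE)
    return(records)
  }
  total <- records$ref_count + records$alt_count
  hits <- overlap_hits(records$pos, exons)
  gene_ids <- split(
    exons$gene_id[S4Vectors::subjectHits(hits)],
    factor(S4Vectors::queryHits(hits), levels = seq_len(nrow(records)))
  )
  gene_ids <- lapply(gene_ids, unique)
  exonic <- lengths(gene_ids) > 0
  in_par <- rep(FALSE, nrow(records))
  if (!is.null(par_intervals) && nrow(par_intervals) > 0) {
    ph <- overlap_hits(records$pos, par_intervals)
    in_par[unique(S4Vectors::queryHits(ph))] <- TRUE
  }
  unphased <- if ("phase_status" %in% names(records)) {
    records$phase_status != "informative"
  } else {
    rep(FALSE, nrow(records))
  }
  category <- dplyr::case_when(
    unphased ~ "unphased",
    total < min_coverage ~ "low_coverage",
    !exonic ~ "non_exonic",
    in_par ~ "in_par",
    TRUE ~ "kept"
  )
  out <- records %>%
    dplyr::mutate(
      gene_ids = unname(gene_ids),
      exonic = exonic,
      in_par = in_par
    ) %>%
    dplyr::filter(category == "kept")
  excl <- table(factor(
    category,
    levels = c("kept", "unphased", "low_coverage", "non_exonic", "in_par")
  ))
  message(
    "SNV filter: ",
    paste(names(excl), as.integer(excl), sep = "=", collapse = ", ")
  )
  if (nrow(out) == 0) {
    warning("all records removed by the SNV filters; summaries will be ",
      "uninformative",
      call. = FALSE
    )
  }
  attr(out, "exclusions") <- setNames(as.integer(excl), names(excl))
  out
}

#' Summarize ratio statistics per individual
#'
#' For each sample, computes the number of informative SNVs, the mean and
#' median allelic and paternal ratios (the per-individual median paternal
#' ratio is the skew statistic `Mx`), the chromosome skew factor
#' `Sx = |Mx - 0.5|`, and the median measure of balance. Samples lacking
#' parental phasing (mothers) get `NA` for the paternal statistics.
#'
#' @param filtered Output of [filter_snvs()].
#' @return One row per sample: `sample_id`, `n_informative_snvs`,
#'   `mean_allelic_ratio`, `median_allelic_ratio`, `mean_paternal_ratio`,
#'   `median_paternal_ratio` (Mx), `chromosome_skew_factor` (Sx),
#'   `median_measure_of_balance`.
#' @export
summarize_individuals <- function(filtered) {
  if (!"allelic_ratio" %in% names(filtered)) {
    filtered <- dplyr::mutate(
      filtered,
      allelic_ratio = .data$alt_count / (.data$ref_count + .data$alt_count)
    )
  }
  if (!"balance" %in% names(filtered)) {
    filtered <- dplyr::mutate(
      filtered,
      balance = measure_of_balance(.data$ref_count, .data$alt_count)
    )
  }
  has_paternal <- "paternal_ratio" %in% names(filtered)
  if (!has_paternal) {
    filtered$paternal_ratio <- NA_real_
  }
  filtered %>%
    dplyr::group_by(.data$sample_id) %>%
    dplyr::summarise(
      n_informative_snvs = dplyr::n(),
      mean_allelic_ratio = mean(.data$allelic_ratio),
      median_allelic_ratio = median(.data$allelic_ratio),
      mean_paternal_ratio = mean(.data$paternal_ratio),
      median_paternal_ratio = median(.data$paternal_ratio),
      median_measure_of_balance = median(.data$balance),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      chromosome_skew_factor = abs(.data$median_paternal_ratio - 0.5)
    )
}
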