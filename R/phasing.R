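#' Assign parent of origin to daughter alleles from trio genotypes
#'
#' On the X chromosome the father is hemizygous, so at every
#' daughter-heterozygous SNV the allele matching the father's single allele is
#' paternal and the remaining allele maternal. The mother's genotype is used
#' only as a consistency check: when available it must carry the inferred
#' maternal allele, otherwise the site is a Mendelian inconsistency.
#'
#' Assignment never looks at read counts.
#'
#' @param genotypes Tibble with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `daughter_gt` (e.g. `"A/G"`), `mother_gt` (may be `NA`),
#'   `father_allele` (single base; diploid homozygous calls like `"A/A"` are
#'   accepted and collapsed).
#' @return The input with added columns `paternal_allele`, `maternal_allele`
#'   (NA unless informative), `phase_status` (one of `"informative"`,
#'   `"not_informative"`, `"inconsistent"`) and `mother_checked`.
#' @export
#' @examples
#' g <- tibble::tibble(
#'   sample_id = "S1", chrom = "X", pos = 1:2, ref = "A", alt = "G",
#'   daughter_gt = c("A/G", "A/A"), mother_gt = "G/G", father_allele = "A"
#' )
#' assign_parent_of_origin(g)[, c("pos", "phase_status", "paternal_allele")]
assign_parent_of_origin <- function(genotypes) {
  required <- c(
    "sample_id", "pos", "ref", "alt",
    "daughter_gt", "mother_gt", "father_allele"
  )
  missing_cols <- setdiff(required, names(genotypes))
  if (length(missing_cols) > 0) {
    stop("genotypes lack columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (any(is.na(genotypes$daughter_gt))) {
    stop("missing daughter genotypes; remove or impute them before phasing",
      call. = FALSE
    )
  }
  d <- strsplit(genotypes$daughter_gt, "/", fixed = TRUE)
  d1 <- vapply(d, `[`, character(1), 1)
  d2 <- vapply(d, `[`, character(1), 2)
  # father: accept hemizygous "A" and diploid homozygous "A/A" dialects;
  # a heterozygous diploid call on the non-PAR X is itself inconsistent
  f <- strsplit(ifelse(is.na(genotypes$father_allele), "",
    genotypes$father_allele
  ), "/", fixed = TRUE)
  f1 <- vapply(f, function(x) if (length(x) >= 1) x[1] else NA_character_,
    character(1)
  )
  f2 <- vapply(f, function(x) if (length(x) >= 2) x[2] else NA_character_,
    character(1)
  )
  father <- ifelse(!is.na(f2) & f2 != f1, NA_character_, f1)
  father[father == ""] <- NA_character_

  het <- d1 != d2
  father_in_daughter <- !is.na(father) & (father == d1 | father == d2)
  maternal <- ifelse(father == d1, d2, d1)

  has_mother <- !is.na(genotypes$mother_gt)
  m <- strsplit(ifelse(has_mother, genotypes$mother_gt, "N/N"), "/",
    fixed = TRUE
  )
  m1 <- vapply(m, `[`, character(1), 1)
  m2 <- vapply(m, `[`, character(1), 2)
  mother_ok <- !has_mother | (maternal == m1 | maternal == m2)

  status <- dplyr::case_when(
    !het ~ "not_informative",
    !father_in_daughter ~ "inconsistent",
    !mother_ok ~ "inconsistent",
    TRUE ~ "informative"
  )
  genotypes %>%
    dplyr::mutate(
      phase_status = status,
      paternal_allele = ifelse(status == "informative", father, NA_character_),
      maternal_allele = ifelse(status == "informative", maternal,
        NA_character_
      ),
      mother_checked = has_mother
    )
}

#' Resolve allele-specific read counts to paternal/maternal counts
#'
#' Joins per-sample per-SNV reference/alternative read counts with the
#' parent-of-origin assignments and computes both ratio statistics: the
#' allelic ratio `alt / (alt + ref)` (origin-free) and the paternal ratio
#' `paternal / (paternal + maternal)`. Count rows without an informative
#' assignment are dropped with a message stating how many and why.
#'
#' Zero-coverage records are retained with undefined (NaN) ratios; the
#' coverage filter removes them later.
#'
#' @param counts Tibble with `sample_id`, `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`.
#' @param assignments Output of [assign_parent_of_origin()].
#' @return A phased-counts tibble, one row per (sample, SNV), with counts for
#'   both labelings, both ratios, and the measure of balance.
#' @export
phase_counts <- function(counts, assignments) {
  stopifnot(all(c("ref_count", "alt_count") %in% names(counts)))
  keys <- c("sample_id", "chrom", "pos", "ref", "alt")
  joined <- dplyr::inner_join(
    counts,
    dplyr::select(
      assignments, dplyr::all_of(keys),
      "phase_status", "paternal_allele", "maternal_allele"
    ),
    by = keys
  )
  n_unmatched <- nrow(counts) - nrow(joined)
  if (n_unmatched > 0) {
    message(
      n_unmatched, " count record(s) without a genotype record were dropped"
    )
  }
  by_status <- table(joined$phase_status)
  dropped <- sum(by_status[setdiff(names(by_status), "informative")])
  if (dropped > 0) {
    message(
      dropped, " count record(s) at non-informative or inconsistent sites ",
      "were dropped (",
      paste(names(by_status), by_status, sep = "=", collapse = ", "), ")"
    )
  }
  joined %>%
    dplyr::filter(.data$phase_status == "informative") %>%
    dplyr::mutate(
      paternal_count = ifelse(.data$paternal_allele == .data$ref,
        .data$ref_count, .data$alt_count
      ),
      maternal_count = ifelse(.data$paternal_allele == .data$ref,
        .data$alt_count, .data$ref_count
      ),
      total_count = .data$ref_count + .data$alt_count,
      allelic_ratio = .data$alt_count / .data$total_count,
      paternal_ratio = .data$paternal_count / .data$total_count,
      balance = measure_of_balance(.data$ref_count, .data$alt_count)
    )
}

#' Swap paternal and maternal labels cohort-wide
#'
#' A pure relabeling: paternal and maternal alleles and counts are exchanged
#' and the paternal ratio becomes `1 - r`. Allelic ratios, the measure of
#' balance, skew factors and escapee calls are invariant under this map,
#' which makes it a useful audit of the whole pipeline.
#'
#' @param phased Output of [phase_counts()].
#' @return The relabeled phased-counts tibble.
#' @export
swap_parental_labels <- function(phased) {
  phased %>%
    dplyr::mutate(
      tmp_allele = .data$paternal_allele,
      paternal_allele = .data$maternal_allele,
      maternal_allele = .data$tmp_allele,
      tmp_count = .data$paternal_count,
      paternal_count = .data$maternal_count,
      maternal_count = .data$tmp_count,
      paternal_ratio = 1 - .data$paternal_ratio
    ) %>%
    dplyr::select(-"tmp_allele", -"tmp_count")
}
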