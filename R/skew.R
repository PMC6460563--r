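#' Classify individuals by X-inactivation skew
#'
#' With parental phasing (`measure = "paternal"`), classification uses the
#' median paternal ratio Mx: maternal-skewed when `Mx <= lower` (default
#' 0.35), paternal-skewed when `Mx >= upper` (default 0.65), balanced in
#' between; `extreme` flags `Mx >= 0.85` or `<= 0.15` and `complete` flags
#' `Mx` exactly 0 or 1 (inactivation of the same X in all cells). Boundaries
#' are closed. Without phasing (`measure = "balance"`, used for mothers),
#' the median measure of balance is classified against mirrored thresholds:
#' skewed when balance `<= lower`, extreme when `<= extreme_lower`,
#' direction unknown.
#'
#' @param summaries Output of [summarize_individuals()].
#' @param measure `"paternal"` or `"balance"`.
#' @param lower,upper Skew thresholds on Mx (defaults 0.35 / 0.65).
#' @param extreme_lower,extreme_upper Extreme-skew thresholds (0.15 / 0.85).
#' @param complete_tol Tolerance around 0/1 for the `complete` flag
#'   (default 0: exact).
#' @return `summaries` with added `skew_class` (factor), `extreme`,
#'   `complete` columns.
#' @export
#' @examples
#' s <- tibble::tibble(
#'   sample_id = c("a", "b", "c"), n_informative_snvs = 50,
#'   median_paternal_ratio = c(0.2, 0.5, 1),
#'   median_measure_of_balance = c(0.2, 0.45, 0)
#' )
#' classify_skew(s)[, c("sample_id", "skew_class", "extreme", "complete")]
classify_skew <- function(summaries,
                          measure = c("paternal", "balance"),
                          lower = 0.35, upper = 0.65,
                          extreme_lower = 0.15, extreme_upper = 0.85,
                          complete_tol = 0) {
  measure <- match.arg(measure)
  stopifnot(lower < upper, extreme_lower <= lower, extreme_upper >= upper)
  if (measure == "paternal") {
    mx <- summaries$median_paternal_ratio
    cls <- dplyr::case_when(
      is.na(mx) ~ NA_character_,
      mx <= lower ~ "maternal_skewed",
      mx >= upper ~ "paternal_skewed",
      TRUE ~ "balanced"
    )
    summaries %>%
      dplyr::mutate(
        skew_class = factor(
          cls,
          levels = c("maternal_skewed", "balanced", "paternal_skewed")
        ),
        extreme = !is.na(mx) & (mx <= extreme_lower | mx >= extreme_upper),
        complete = !is.na(mx) &
          (mx <= complete_tol | mx >= 1 - complete_tol),
        unclassified_reason = ifelse(
          is.na(mx), "no informative phased SNVs", NA_character_
        )
      )
  } else {
    b <- summaries$median_measure_of_balance
    cls <- dplyr::case_when(
      is.na(b) ~ NA_character_,
      b <= lower ~ "skewed",
      TRUE ~ "balanced"
    )
    summaries %>%
      dplyr::mutate(
        skew_class = factor(cls, levels = c("skewed", "balanced")),
        extreme = !is.na(b) & b <= extreme_lower,
        complete = !is.na(b) & b <= complete_tol,
        unclassified_reason = ifelse(
          is.na(b), "no informative SNVs", NA_character_
        )
      )
  }
}

#' Cohort-level skew class distribution
#'
#' Counts and fractions per skew class, with empty classes reported as zero
#' rather than omitted, plus counts of the severity flags.
#'
#' @param classified Output of [classify_skew()].
#' @return A tibble with `skew_class`, `n`, `fraction`.
#' @export
population_distribution <- function(classified) {
  stopifnot("skew_class" %in% names(classified))
  done <- classified[!is.na(classified$skew_class), ]
  if (nrow(done) == 0) stop("no classified individuals", call. = FALSE)
  out <- done %>%
    dplyr::count(.data$skew_class, .drop = FALSE, name = "n") %>%
    dplyr::mutate(fraction = .data$n / sum(.data$n))
  attr(out, "severity") <- c(
    extreme = sum(done$extreme), complete = sum(done$complete),
    unclassified = sum(is.na(classified$skew_class))
  )
  out
}

#' Mother-daughter skew correlation
#'
#' Pearson product-moment correlation (with the standard t-based two-sided
#' p-value) between the median measures of balance of mothers and their
#' daughters. Under random X-inactivation no correlation is expected. Pairs
#' with a missing member are excluded and counted.
#'
#' @param pairs Tibble with one row per mother-daughter pair.
#' @param daughter_col,mother_col Names of the two balance columns.
#' @return One-row tibble: `r`, `p_value`, `n_pairs`, `n_excluded`.
#' @export
#' @examples
#' set.seed(1)
#' pairs <- tibble::tibble(
#'   daughter_balance = runif(20, 0, 0.5),
#'   mother_balance = runif(20, 0, 0.5)
#' )
#' mother_daughter_correlation(pairs)
mother_daughter_correlation <- function(pairs,
                                        daughter_col = "daughter_balance",
                                        mother_col = "mother_balance") {
  stopifnot(all(c(daughter_col, mother_col) %in% names(pairs)))
  x <- pairs[[mother_col]]
  y <- pairs[[daughter_col]]
  ok <- !is.na(x) & !is.na(y)
  n_excluded <- sum(!ok)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) {
    stop("need at least 3 complete mother-daughter pairs, got ", length(x),
      call. = FALSE
    )
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance in one member; correlation undefined",
      call. = FALSE
    )
    return(tibble::tibble(
      r = NA_real_, p_value = NA_real_,
      n_pairs = length(x), n_excluded = n_excluded
    ))
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble::tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n_pairs = length(x),
    n_excluded = n_excluded
  )
}
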