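#' Simulate population paternal-ratio distributions under k precursor cells
#'
#' Each simulated individual consists of `n_cells` cells that independently
#' keep the paternal X active with probability 0.5; the individual's paternal
#' ratio is the mean of those Bernoulli outcomes. Ratios are exact multiples
#' of `1 / n_cells`.
#'
#' Uses the current RNG state; seed externally for reproducibility.
#'
#' @param n_cells Number of precursor cells (>= 1).
#' @param n_individuals Number of simulated individuals (>= 1).
#' @return Numeric vector of `n_individuals` ratios in `[0, 1]`.
#' @export
#' @examples
#' set.seed(1)
#' table(simulate_ratios(4, 100))
simulate_ratios <- function(n_cells, n_individuals) {
  if (length(n_individuals) != 1 || is.na(n_individuals) ||
    n_individuals < 1) {
    stop("`n_individuals` must be a single integer >= 1", call. = FALSE)
  }
  draw_individual_skew(n_cells, n = as.integer(n_individuals))
}

#' Probability of complete skewing under k precursor cells
#'
#' With `n_cells` precursor cells each inactivating one X at random, all
#' cells silence the same specific chromosome with probability
#' `(1/2)^n_cells` (one direction), and all silence the same chromosome --
#' whichever it is -- with probability `(1/2)^(n_cells - 1)`. With four
#' precursor cells one individual in eight is completely skewed; with 32 the
#' chance is about 5e-10.
#'
#' @param n_cells Number of precursor cells (>= 1, vectorized).
#' @return Tibble: `n_cells`, `one_direction`, `either_direction`.
#' @export
#' @examples
#' complete_skew_probability(c(1, 4, 8, 32))
complete_skew_probability <- function(n_cells) {
  if (any(is.na(n_cells) | n_cells < 1)) {
    stop("`n_cells` must be >= 1", call. = FALSE)
  }
  tibble::tibble(
    n_cells = as.integer(n_cells),
    one_direction = 0.5^n_cells,
    either_direction = 0.5^(n_cells - 1)
  )
}

#' Two-sample Kolmogorov-Smirnov comparison of ratio distributions
#'
#' Standard two-sample KS statistic and asymptotic p-value. Ratio samples
#' are discrete (multiples of `1/n_cells`), so ties are certain; the
#' asymptotic approximation is used deliberately and tie warnings are
#' suppressed.
#'
#' @param empirical,simulated Non-empty numeric vectors.
#' @return One-row tibble: `statistic` (D), `p_value`.
#' @export
#' @examples
#' set.seed(1)
#' ks_compare(simulate_ratios(8, 500), simulate_ratios(8, 500))
ks_compare <- function(empirical, simulated) {
  if (length(empirical) == 0 || length(simulated) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  kt <- suppressWarnings(
    stats::ks.test(empirical, simulated, exact = FALSE)
  )
  tibble::tibble(
    statistic = unname(kt$statistic),
    p_value = kt$p.value
  )
}

# One-sample KS distance between an empirical sample and the analytic
# Binomial(k, 0.5)/k distribution. The theoretical CDF is a step function, so
# the supremum is taken over the union of its atoms and the data points
# (stats::ks.test's one-sample mode assumes a continuous null and would
# overstate D by the size of the largest jump). The p-value uses the
# asymptotic Kolmogorov distribution.
ks_exact_binomial <- function(empirical, k) {
  cdf <- function(x) stats::pbinom(floor(x * k + 1e-9), k, 0.5)
  ec <- stats::ecdf(empirical)
  xs <- sort(unique(c((0:k) / k, empirical)))
  eps <- 1e-9
  d <- max(abs(ec(xs) - cdf(xs)), abs(ec(xs - eps) - cdf(xs - eps)))
  t_stat <- sqrt(length(empirical)) * d
  j <- seq_len(100)
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * t_stat^2))
  tibble::tibble(statistic = d, p_value = min(1, max(0, p)))
}

#' Select the precursor-cell count best fitting an empirical skew sample
#'
#' Simulates the population paternal-ratio distribution for each candidate
#' cell count (`reps` individuals each, seeded substreams) and compares it
#' with the empirical sample of per-individual median paternal ratios by the
#' two-sample KS test. The candidate with the highest KS p-value is selected
#' (ties broken by smaller D, then smaller cell count).
#'
#' An exact one-sample mode (`method = "exact"`) compares the empirical
#' sample directly with the analytic `Binomial(n, 0.5)/n` distribution
#' function instead of a simulated sample.
#'
#' @param empirical Numeric vector of per-individual median paternal ratios.
#' @param candidates Candidate cell counts (default 4, 8, 16, 32).
#' @param reps Simulated individuals per candidate (default 10000).
#' @param seed Integer seed for the candidate substreams, or `NULL` to use
#'   the current RNG state.
#' @param method `"simulated"` (two-sample, default) or `"exact"`
#'   (one-sample against the analytic CDF).
#' @return Object of class `precursor_fit`: list with `candidates` (tibble:
#'   `n_cells`, `statistic`, `p_value`), `selected_count`, `reps`, `seed`,
#'   `empirical` and the simulated samples (for plotting).
#' @export
#' @examples
#' set.seed(2)
#' emp <- simulate_ratios(8, 400)
#' fit <- select_precursor_count(emp, reps = 2000, seed = 1)
#' fit$selected_count
select_precursor_count <- function(empirical,
                                   candidates = c(4L, 8L, 16L, 32L),
                                   reps = 10000, seed = NULL,
                                   method = c("simulated", "exact")) {
  method <- match.arg(method)
  if (length(candidates) == 0) stop("no candidate cell counts", call. = FALSE)
  if (length(empirical) == 0) stop("empty empirical sample", call. = FALSE)
  candidates <- as.integer(candidates)
  sims <- purrr::imap(setNames(candidates, candidates), function(k, i) {
    if (method == "exact") {
      return(NULL)
    }
    draw <- function() simulate_ratios(k, reps)
    if (is.null(seed)) {
      draw()
    } else {
      withr::with_seed(
        (as.integer(seed) + match(k, candidates) * 7919L) %% 2147483647L,
        draw()
      )
    }
  })
  per_candidate <- purrr::map_dfr(candidates, function(k) {
    if (method == "simulated") {
      res <- ks_compare(empirical, sims[[as.character(k)]])
    } else {
      res <- ks_exact_binomial(empirical, k)
    }
    dplyr::mutate(res, n_cells = k, .before = 1)
  })
  ranked <- dplyr::arrange(
    per_candidate,
    dplyr::desc(.data$p_value), .data$statistic, .data$n_cells
  )
  structure(
    list(
      candidates = per_candidate,
      selected_count = ranked$n_cells[1],
      reps = reps,
      seed = seed,
      method = method,
      empirical = empirical,
      simulated = sims
    ),
    class = "precursor_fit"
  )
}

#' @export
print.precursor_fit <- function(x, ...) {
  cat("<precursor_fit>\n")
  cat(sprintf(
    "  empirical n = %d, %s comparison, reps = %d\n",
    length(x$empirical), x$method, x$reps
  ))
  print(x$candidates)
  cat(sprintf("  selected precursor-cell count: %d\n", x$selected_count))
  invisible(x)
}

#' @describeIn select_precursor_count Per-candidate KS statistics as a tibble.
#' @param x A `precursor_fit`.
#' @param ... Unused.
#' @export
tidy.precursor_fit <- function(x, ...) {
  dplyr::mutate(x$candidates, selected = .data$n_cells == x$selected_count)
}

#' @describeIn select_precursor_count One-row model-level summary.
#' @export
glance.precursor_fit <- function(x, ...) {
  best <- x$candidates[x$candidates$n_cells == x$selected_count, ]
  tibble::tibble(
    selected_count = x$selected_count,
    statistic = best$statistic,
    p_value = best$p_value,
    n_empirical = length(x$empirical),
    reps = x$reps
  )
}

#' @describeIn select_precursor_count ECDF overlay of the empirical sample
#'   and each candidate's simulated distribution.
#' @param object A `precursor_fit`.
#' @export
autoplot.precursor_fit <- function(object, ...) {
  if (object$method == "exact") {
    stop("autoplot requires simulated candidate samples", call. = FALSE)
  }
  sim_df <- purrr::imap_dfr(object$simulated, function(v, k) {
    tibble::tibble(ratio = v, n_cells = paste0(k, " cells"))
  })
  emp_df <- tibble::tibble(ratio = object$empirical)
  ggplot2::ggplot(sim_df, ggplot2::aes(.data$ratio)) +
    ggplot2::stat_ecdf(ggplot2::aes(colour = .data$n_cells)) +
    ggplot2::stat_ecdf(
      data = emp_df, colour = "black", linewidth = 1
    ) +
    ggplot2::labs(
      x = "paternal ratio", y = "cumulative fraction of individuals",
      colour = "precursor cells",
      title = sprintf(
        "Empirical skew vs precursor-cell models (selected: %d cells)",
        object$selected_count
      )
    ) +
    ggplot2::theme_minimal()
}
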