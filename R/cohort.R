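#' Simulate an individual-level cohort for a binary marker
#'
#' Subjects are drawn from the four-cell multinomial over the population
#' fractions `(a, b, c, d)` solved from the generating odds ratio and
#' prevalences, so the empirical odds ratio is unbiased for the generating
#' one by construction. Reproducible under a fixed seed.
#'
#' @inheritParams solve_two_by_two
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed for the random draw.
#' @return A tibble with `n` rows and columns `marker` (0/1) and `disease`
#'   (0/1); generating parameters are attached as the `params` attribute.
#' @examples
#' simulate_binary_cohort(20, 0.10, 0.01, n = 1000, seed = 1)
#' @export
simulate_binary_cohort <- function(odds_ratio, marker_prev, disease_prev,
                                   n, seed = 1L) {
  check_cohort_n(n)
  tab <- solve_two_by_two(odds_ratio, marker_prev, disease_prev)
  probs <- c(tab$a, tab$b, tab$c, tab$d)
  counts <- withr::with_seed(seed, as.vector(stats::rmultinom(1, size = n, prob = probs)))
  cells <- tibble::tibble(
    marker = c(1L, 1L, 0L, 0L),
    disease = c(1L, 0L, 1L, 0L),
    k = counts
  )
  out <- tidyr::uncount(cells, weights = .data$k)
  attr(out, "params") <- list(
    type = "binary", odds_ratio = odds_ratio, marker_prev = marker_prev,
    disease_prev = disease_prev, n = n, seed = seed
  )
  out
}

check_cohort_n <- function(n) {
  if (length(n) != 1L || is.na(n) || n < 1 || n != floor(n)) {
    abort_input("`n` must be a single positive integer.")
  }
}

#' Simulate an individual-level cohort for a continuous marker
#'
#' Disease labels are Bernoulli with the requested prevalence; marker values
#' are drawn from the class-conditional Gaussian of a calibrated
#' [binormal_marker()] pair.
#'
#' @param pair A single-row [binormal_marker()].
#' @inheritParams q_unexposed
#' @inheritParams simulate_binary_cohort
#' @return A tibble with columns `marker` (numeric) and `disease` (0/1), and
#'   a `params` attribute.
#' @examples
#' simulate_continuous_cohort(binormal_marker(50), 0.01, n = 1000, seed = 1)
#' @export
simulate_continuous_cohort <- function(pair, disease_prev, n, seed = 1L) {
  check_cohort_n(n)
  check_fraction(disease_prev, "disease_prev")
  if (!inherits(pair, "binormal_marker") || nrow(pair) != 1L) {
    abort_input("`pair` must be a single-row binormal_marker.")
  }
  out <- withr::with_seed(seed, {
    disease <- stats::rbinom(n, 1L, disease_prev)
    mu <- ifelse(disease == 1L, pair$mu_d, pair$mu_nd)
    tibble::tibble(marker = stats::rnorm(n, mu, pair$sigma), disease = disease)
  })
  attr(out, "params") <- list(
    type = "continuous", odds_ratio = pair$odds_ratio, mu_nd = pair$mu_nd,
    mu_d = pair$mu_d, sigma = pair$sigma, disease_prev = disease_prev,
    n = n, seed = seed
  )
  out
}

#' Plug-in empirical benefit report from a cohort
#'
#' Counts the empirical 2x2 table of a cohort — dichotomising continuous
#' markers at `threshold` — and applies the analytic binary-marker formulas
#' to the observed cell fractions. For large cohorts the empirical
#' sensitivity, specificity, PAR%, RPB and NB converge to the analytic
#' values of the generating scenario.
#'
#' @param cohort A data frame with columns `marker` and `disease` (binary
#'   0/1 disease; marker 0/1 or continuous).
#' @param threshold Cut point for a continuous marker (`marker > threshold`
#'   is a positive call); leave `NULL` for a 0/1 marker.
#' @inheritParams binary_benefit
#' @return A one-row tibble with the observed cell fractions, `n`, and all
#'   binary benefit metrics.
#' @examples
#' simulate_binary_cohort(20, 0.10, 0.01, n = 1e4, seed = 1) |>
#'   empirical_benefit(f2 = 0.03)
#' @export
empirical_benefit <- function(cohort, threshold = NULL, f1 = 1, f2,
                              eta = NULL, delta = 0, h = 0, nb_weight = NULL) {
  if (!is.data.frame(cohort) || !all(c("marker", "disease") %in% names(cohort))) {
    abort_input("`cohort` must have columns `marker` and `disease`.")
  }
  if (length(unique(cohort$disease)) < 2L) {
    rlang::abort("Cohort contains a single disease class; estimation is degenerate.",
      class = "popbenefit_estimation_degeneracy"
    )
  }
  positive <- if (is.null(threshold)) cohort$marker == 1 else cohort$marker > threshold
  disease <- cohort$disease == 1
  n <- nrow(cohort)
  tab <- tibble::tibble(
    a = sum(positive & disease) / n,
    b = sum(positive & !disease) / n,
    c = sum(!positive & disease) / n,
    d = sum(!positive & !disease) / n
  )
  if (is.null(nb_weight)) nb_weight <- f2 / f1
  out <- two_by_two_metrics(tab)
  out$n <- n
  out$rpb <- rpb_detection(tab, f1 = f1, f2 = f2)
  out$nb <- net_benefit(tab, nb_weight = nb_weight)
  out$absolute_gain <- absolute_gain(tab, f1 = f1, f2 = f2, h = h)
  if (!is.null(eta)) {
    out$rpb_prevention <- rpb_prevention(tab, f1 = f1, f2 = f2, eta = eta, delta = delta)
  }
  out
}

#' Read/write cohort files
#'
#' Cohorts are exchanged as tab-delimited text with a header and two columns,
#' `marker` and `disease`; binary markers are encoded 0/1. [write_cohort()]
#' also writes a JSON sidecar (`<path>.json`) with the generating parameters
#' when the cohort carries them.
#'
#' @param cohort A cohort tibble.
#' @param path Output (input) file path.
#' @return `write_cohort()` returns `path` invisibly; [read_cohort()] returns
#'   a cohort tibble.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  params <- attr(cohort, "params")
  if (!is.null(params)) {
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_tsv(path,
    show_col_types = FALSE,
    col_types = readr::cols(
      marker = readr::col_double(),
      disease = readr::col_integer()
    )
  )
  if (!all(c("marker", "disease") %in% names(out))) {
    abort_input("Cohort file must have columns `marker` and `disease`.")
  }
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    attr(out, "params") <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  out
}
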