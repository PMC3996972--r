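#' Reconstruct the population 2x2 exposure-by-disease table
#'
#' Given the odds ratio of a binary marker (or risk-factor exposure), the
#' marker prevalence and the disease prevalence, solves for the joint
#' population fractions of the standard 2x2 contingency table with cells
#' `a` (marker+/diseased), `b` (marker+/non-diseased), `c` (marker-/diseased)
#' and `d` (marker-/non-diseased). The margins fix `a + b = marker_prev` and
#' `a + c = disease_prev`, and the cross-product constraint `ad/(bc) = OR`
#' reduces to the quadratic
#' \deqn{(1 - OR)a^2 + [1 - p - w + OR(p + w)]a - OR\,p\,w = 0}
#' in the true-positive fraction `a` (with `p` the marker prevalence and `w`
#' the disease prevalence). Exactly one root places all four cells in
#' \eqn{[0, 1]}; that root is returned. `OR = 1` is handled as exact
#' independence, `a = p w`.
#'
#' Both quadratic roots are computed in a cancellation-free form (the
#' larger-magnitude branch first, then Vieta's product for the other), so the
#' solution is accurate even for extreme odds ratios.
#'
#' @param odds_ratio Positive odds ratio(s) relating marker positivity to
#'   disease.
#' @param marker_prev Marker (or exposure) prevalence as a fraction in (0, 1).
#' @param disease_prev Disease prevalence as a fraction in (0, 1).
#' @return A tibble with one row per scenario and columns `odds_ratio`,
#'   `marker_prev`, `disease_prev`, `a`, `b`, `c`, `d`. The cell columns are
#'   population fractions summing to 1.
#' @examples
#' solve_two_by_two(odds_ratio = 20, marker_prev = 0.10, disease_prev = 0.01)
#' @export
solve_two_by_two <- function(odds_ratio, marker_prev, disease_prev) {
  check_positive(odds_ratio, "odds_ratio")
  check_fraction(marker_prev, "marker_prev")
  check_fraction(disease_prev, "disease_prev")
  args <- recycle_args(
    odds_ratio = odds_ratio, marker_prev = marker_prev,
    disease_prev = disease_prev
  )
  a <- purrr::pmap_dbl(args, solve_cell_a)
  tibble::tibble(
    odds_ratio = args$odds_ratio,
    marker_prev = args$marker_prev,
    disease_prev = args$disease_prev,
    a = a,
    b = args$marker_prev - a,
    c = args$disease_prev - a,
    d = 1 - args$marker_prev - args$disease_prev + a
  )
}

# scalar solver for the true-positive fraction a
solve_cell_a <- function(odds_ratio, marker_prev, disease_prev) {
  p <- marker_prev
  w <- disease_prev
  if (odds_ratio == 1) {
    return(p * w)
  }
  A <- 1 - odds_ratio
  B <- 1 - p - w + odds_ratio * (p + w)
  C <- -odds_ratio * p * w
  disc <- B^2 - 4 * A * C
  if (disc < 0) {
    if (disc > -1e-12) disc <- 0 else {
      rlang::abort("No real root for the 2x2 cell equation; inputs are inconsistent.",
        class = "popbenefit_internal"
      )
    }
  }
  s <- if (B >= 0) 1 else -1
  q <- -(B + s * sqrt(disc)) / 2
  roots <- c(q / A, C / q)
  lo <- max(0, p + w - 1)
  hi <- min(p, w)
  tol <- 1e-12 * max(1, hi)
  ok <- roots >= lo - tol & roots <= hi + tol
  if (sum(ok) != 1L) {
    # both roots can sit in range only at a degenerate boundary; pick the one
    # whose implied table reproduces the odds ratio
    if (sum(ok) == 0L) {
      rlang::abort("No admissible root for the 2x2 cell equation.",
        class = "popbenefit_internal"
      )
    }
    err <- vapply(roots, function(a) {
      abs(a * (1 - p - w + a) - odds_ratio * (p - a) * (w - a))
    }, numeric(1))
    return(min(max(roots[which.min(err)], lo), hi))
  }
  min(max(roots[ok], lo), hi)
}

#' Construct a 2x2 table from cell values
#'
#' Accepts either population fractions summing to 1 or integer counts, which
#' are normalised (the total is kept in the `n` column for count input).
#'
#' @param a,b,c,d Cell values: marker+/diseased, marker+/non-diseased,
#'   marker-/diseased, marker-/non-diseased.
#' @return A tibble with columns `a`, `b`, `c`, `d` (fractions) and `n`
#'   (total count, `NA` for fraction input).
#' @examples
#' two_by_two(a = 45, b = 500, c = 20, d = 9435)
#' @export
two_by_two <- function(a, b, c, d) {
  args <- recycle_args(a = a, b = b, c = c, d = d)
  cells <- do.call(cbind, args)
  if (any(cells < 0) || anyNA(cells)) {
    abort_input("Cell values `a`, `b`, `c`, `d` must be non-negative.")
  }
  tot <- rowSums(cells)
  if (any(tot == 0)) abort_input("Cell values sum to zero.")
  is_fraction <- abs(tot - 1) < 1e-6
  tibble::tibble(
    a = unname(cells[, 1] / tot), b = unname(cells[, 2] / tot),
    c = unname(cells[, 3] / tot), d = unname(cells[, 4] / tot),
    n = unname(ifelse(is_fraction, NA_real_, tot))
  )
}

#' Classification and attributable-risk metrics of a 2x2 table
#'
#' Adds to a table of cell fractions the marker's sensitivity `a/(a+c)` and
#' specificity `d/(b+d)`, the overall disease risk `r1 = a+c`, the risk in the
#' unexposed `r2 = c/(c+d)`, the risk in the exposed `a/(a+b)`, the population
#' attributable risk percent `PAR% = (r1 - r2)/r1 * 100`, and the recomputed
#' odds ratio.
#'
#' Note on naming: some sources label `r1` the "prevalence" and `r2` the
#' "false negative fraction". The formulas implemented here are the printed
#' ones — `r1` is the overall disease risk and `r2` the disease risk among
#' marker-negative subjects (the false negative *fraction* in the usual sense
#' is `1 - sensitivity = c/(a+c)`, a different quantity).
#'
#' @param data A data frame with cell-fraction columns `a`, `b`, `c`, `d`
#'   (e.g. from [solve_two_by_two()] or [two_by_two()]).
#' @return The input tibble with columns `sensitivity`, `specificity`, `r1`,
#'   `r2`, `risk_exposed`, `par_percent`, `odds_ratio` appended (an existing
#'   `odds_ratio` column is overwritten with the recomputed value).
#' @examples
#' solve_two_by_two(20, 0.10, 0.01) |> two_by_two_metrics()
#' @export
two_by_two_metrics <- function(data) {
  check_table_cols(data)
  margins <- list(
    "a + c" = data$a + data$c, "b + d" = data$b + data$d,
    "a + b" = data$a + data$b, "c + d" = data$c + data$d
  )
  zero <- vapply(margins, function(m) any(m <= 0), logical(1))
  if (any(zero)) {
    abort_degenerate(sprintf(
      "Margin %s is zero; metrics are undefined.",
      paste(names(margins)[zero], collapse = ", ")
    ))
  }
  dplyr::mutate(
    tibble::as_tibble(data),
    sensitivity = .data$a / (.data$a + .data$c),
    specificity = .data$d / (.data$b + .data$d),
    r1 = .data$a + .data$c,
    r2 = .data$c / (.data$c + .data$d),
    risk_exposed = .data$a / (.data$a + .data$b),
    par_percent = (.data$r1 - .data$r2) / .data$r1 * 100,
    odds_ratio = (.data$a * .data$d) / (.data$b * .data$c)
  )
}

check_table_cols <- function(data, cols = c("a", "b", "c", "d")) {
  if (!is.data.frame(data)) abort_input("`data` must be a data frame.")
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort_input(sprintf(
      "`data` lacks column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

#' Marker accuracy and PAR% in the rare-disease limit
#'
#' As disease prevalence tends to zero, the solved 2x2 table yields the
#' closed forms
#' \deqn{sens = \frac{p\,OR}{p\,OR + 1 - p}, \qquad spec = 1 - p,}
#' \deqn{PAR\% = 100\,\frac{p(OR - 1)}{p(OR - 1) + 1},}
#' with `p` the marker prevalence. These are the forms used in back-of-envelope
#' evaluation of association studies of rare diseases (e.g. a genotype with
#' OR 1.9 and 51% carrier prevalence gives 66% sensitivity, 49% specificity
#' and a PAR% of 31).
#'
#' @inheritParams solve_two_by_two
#' @return A tibble with columns `odds_ratio`, `marker_prev`, `sensitivity`,
#'   `specificity`, `par_percent`.
#' @examples
#' rare_disease_metrics(odds_ratio = 1.9, marker_prev = 0.51)
#' @export
rare_disease_metrics <- function(odds_ratio, marker_prev) {
  check_positive(odds_ratio, "odds_ratio")
  check_fraction(marker_prev, "marker_prev")
  args <- recycle_args(odds_ratio = odds_ratio, marker_prev = marker_prev)
  p <- args$marker_prev
  or <- args$odds_ratio
  tibble::tibble(
    odds_ratio = or,
    marker_prev = p,
    sensitivity = p * or / (p * or + 1 - p),
    specificity = 1 - p,
    par_percent = 100 * p * (or - 1) / (p * (or - 1) + 1)
  )
}

#' Stratified (confounder-adjusted) weighted average of an index
#'
#' Confounder adjustment by stratification: the adjusted index is the average
#' of the stratum-specific values weighted by the proportion of cases in each
#' stratum, \eqn{\sum_i p_i x_i}. Used for both adjusted PAR%
#' ([par_adjusted()]) and adjusted RPB ([rpb_adjusted()]).
#'
#' @param data A data frame with one row per stratum.
#' @param value Column (tidy-eval) holding the stratum-specific index.
#' @param weights Column holding the case-proportion weights `p_i`; must be
#'   non-negative and sum to 1 (within 1e-9).
#' @return A single numeric value.
#' @examples
#' strata <- tibble::tibble(p = c(0.25, 0.75), par_percent = c(63.92, 0))
#' par_adjusted(strata)
#' @export
adjust_stratified <- function(data, value, weights = .data$p) {
  if (!is.data.frame(data)) abort_input("`data` must be a data frame.")
  v <- dplyr::pull(dplyr::transmute(data, v = {{ value }}), "v")
  p <- dplyr::pull(dplyr::transmute(data, p = {{ weights }}), "p")
  if (any(p < 0) || anyNA(p)) {
    abort_input("Stratum weights must be non-negative.", class = "popbenefit_invalid_strata")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    rlang::abort(
      sprintf("Stratum weights must sum to 1 (got %.12g).", sum(p)),
      class = c("popbenefit_invalid_strata", "popbenefit_invalid_input")
    )
  }
  sum(p * v)
}

#' @rdname adjust_stratified
#' @export
par_adjusted <- function(data, value = .data$par_percent, weights = .data$p) {
  adjust_stratified(data, {{ value }}, {{ weights }})
}

#' Read a 2x2 table from delimited text
#'
#' The file must have a header with columns `a`, `b`, `c`, `d` holding either
#' population fractions or counts; counts are normalised by [two_by_two()].
#'
#' @param path Path to a tab- or comma-delimited text file.
#' @return A tibble as from [two_by_two()].
#' @export
read_two_by_two <- function(path) {
  raw <- readr::read_delim(path,
    delim = guess_delim(path), show_col_types = FALSE,
    col_types = readr::cols(.default = readr::col_double())
  )
  check_table_cols(raw)
  two_by_two(raw$a, raw$b, raw$c, raw$d)
}

guess_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}
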