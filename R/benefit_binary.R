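#' Ratio of population benefit (RPB) for a binary marker: early detection
#'
#' The RPB weighs, over the whole population, the lives gained by
#' early-detecting the `a` true-positive cases (worth `f1` each) against the
#' loss inflicted on the `b` false positives (worth `f2` each, the
#' utility-loss adjustment of an unnecessary intervention), relative to the
#' total population stake:
#' \deqn{RPB = \frac{a f_1 - b f_2}{a f_1 + b f_2 + c f_1 + d f_2}.}
#' The denominator collapses to \eqn{f_1 w + f_2 (1 - w)} with `w = a + c`
#' the disease prevalence, so it does not depend on the marker at all — only
#' the numerator does. Negative, zero and positive values mean the
#' marker-guided program is detrimental, neutral or beneficial at the
#' population level.
#'
#' @param data A data frame with cell-fraction columns `a`, `b`, `c`, `d`
#'   (from [solve_two_by_two()], [two_by_two()] or a dichotomised continuous
#'   scenario).
#' @param f1 Life-value gained per early-detected case (> 0; default 1).
#' @param f2 Life-value lost per false-positive intervention (>= 0). For
#'   cancer surgery this is 1 minus the quality-of-life utility weight of the
#'   procedure, e.g. 0.03 (esophageal adenocarcinoma), 0.06 (breast), 0.15
#'   (ovarian).
#' @return A numeric vector, one RPB per row of `data`, in `[-1, 1]`.
#' @examples
#' solve_two_by_two(20, 0.10, 0.01) |> rpb_detection(f2 = 0.03)
#' @export
rpb_detection <- function(data, f1 = 1, f2) {
  check_table_cols(data)
  check_weights(f1, f2)
  den <- rpb_denominator(data, f1, f2)
  (data$a * f1 - data$b * f2) / den
}

rpb_denominator <- function(data, f1, f2) {
  den <- f1 * (data$a + data$c) + f2 * (data$b + data$d)
  if (any(den <= 0)) {
    abort_input("RPB denominator is zero: f1 and f2 cannot both vanish.")
  }
  den
}

#' RPB for a binary marker: preventive intervention
#'
#' When marker positivity triggers a preventive measure with efficacy `eta`
#' (fraction of would-be cases averted among treated carriers) and a per
#' treated person adverse-effect loss `delta`, the benefit accrues only to
#' the `a` carriers who would develop disease, while the adverse effect hits
#' every treated subject (`a + b`):
#' \deqn{RPB = \frac{a\eta f_1 - a\delta - b\delta}
#'                  {a f_1 + b f_2 + c f_1 + d f_2}.}
#' With `delta = 0` the value is non-negative whenever `eta > 0`.
#'
#' @inheritParams rpb_detection
#' @param eta Prevention efficacy in `[0, 1]`.
#' @param delta Adverse-effect loss per treated person (>= 0), in the same
#'   life-value units as `f1`.
#' @return A numeric vector of prevention RPB values.
#' @examples
#' solve_two_by_two(1.9, 0.51, 0.01) |>
#'   rpb_prevention(f2 = 0.03, eta = 1, delta = 0)
#' @export
rpb_prevention <- function(data, f1 = 1, f2, eta, delta = 0) {
  check_table_cols(data)
  check_weights(f1, f2)
  check_fraction(eta, "eta", open = FALSE)
  check_positive(delta, "delta", strict = FALSE)
  den <- rpb_denominator(data, f1, f2)
  (data$a * eta * f1 - data$a * delta - data$b * delta) / den
}

#' Prevention RPB restricted to the diseased group
#'
#' If attention is limited to diseased subjects only (ignoring `b`, `d` and
#' `f2`), the prevention RPB collapses to the marker's sensitivity scaled by
#' the dimensionless net-efficacy factor:
#' \deqn{RPB_{restr} = sens \cdot \frac{\eta f_1 - \delta}{f_1}.}
#'
#' @param sensitivity Marker sensitivity (or sensitivities) in `[0, 1]`.
#' @inheritParams rpb_prevention
#' @return Numeric vector.
#' @examples
#' rpb_restricted(sensitivity = 0.675, eta = 0.8, delta = 0.1)
#' @export
rpb_restricted <- function(sensitivity, f1 = 1, eta, delta = 0) {
  check_fraction(sensitivity, "sensitivity", open = FALSE)
  check_positive(f1, "f1")
  check_fraction(eta, "eta", open = FALSE)
  check_positive(delta, "delta", strict = FALSE)
  sensitivity * (eta * f1 - delta) / f1
}

#' Decision-curve net benefit of a binary marker
#'
#' \deqn{NB = a - w_{nb}\, b} per unit population, where `w_nb` weights the
#' cost of a false positive relative to the value of a true positive. For
#' comparability with the RPB the default weight is `f2/f1`; with `f1 = 1`
#' this makes `NB * f1` equal the RPB numerator per unit population.
#'
#' @inheritParams rpb_detection
#' @param nb_weight Non-negative false-positive cost weight `w_nb`.
#' @return Numeric vector of net-benefit values.
#' @examples
#' solve_two_by_two(20, 0.10, 0.01) |> net_benefit(nb_weight = 0.03)
#' @export
net_benefit <- function(data, nb_weight) {
  check_table_cols(data)
  check_positive(nb_weight, "nb_weight", strict = FALSE)
  tot <- data$a + data$b + data$c + data$d
  (data$a - nb_weight * data$b) / tot
}

#' Absolute population gain with intervention cost
#'
#' The absolute (not ratio) gain per unit population, after charging a
#' per-person cost `h` for treating every marker-positive subject:
#' detection \eqn{(a f_1 - b f_2) - h(a + b)}; prevention
#' \eqn{(a\eta f_1 - a\delta - b\delta) - h(a + b)}. With `h = 0` these are
#' the corresponding RPB numerators.
#'
#' @inheritParams rpb_prevention
#' @param h Per-person cost coefficient of intervening on marker-positive
#'   subjects (>= 0).
#' @param eta Prevention efficacy; leave `NULL` for the early-detection form.
#' @return Numeric vector of signed gains per unit population.
#' @examples
#' solve_two_by_two(20, 0.10, 0.01) |> absolute_gain(f2 = 0.03, h = 0.01)
#' @export
absolute_gain <- function(data, f1 = 1, f2, eta = NULL, delta = 0, h = 0) {
  check_table_cols(data)
  check_positive(h, "h", strict = FALSE)
  num <- if (is.null(eta)) {
    check_weights(f1, f2)
    data$a * f1 - data$b * f2
  } else {
    data$a * eta * f1 - data$a * delta - data$b * delta
  }
  num - h * (data$a + data$b)
}

#' @rdname adjust_stratified
#' @export
rpb_adjusted <- function(data, value = .data$rpb, weights = .data$p) {
  adjust_stratified(data, {{ value }}, {{ weights }})
}

#' One-call benefit report for binary marker scenarios
#'
#' Pipes a tibble of scenario parameters through the whole binary pipeline:
#' solve the population 2x2 table, derive sensitivity/specificity/PAR%, and
#' attach RPB, net benefit and absolute gain. Scenario columns `odds_ratio`,
#' `marker_prev`, `disease_prev` are required; per-row `f1`/`f2` columns
#' override the arguments.
#'
#' @param data A data frame of scenarios with columns `odds_ratio`,
#'   `marker_prev`, `disease_prev` (and optionally `f1`, `f2`).
#' @inheritParams rpb_prevention
#' @inheritParams absolute_gain
#' @param nb_weight False-positive cost weight for net benefit; default
#'   `f2/f1`.
#' @return A tibble: the scenario columns plus `a`, `b`, `c`, `d`,
#'   `sensitivity`, `specificity`, `par_percent`, `rpb`, `nb`,
#'   `absolute_gain`, and `rpb_prevention` when `eta` is supplied.
#' @examples
#' tibble::tibble(odds_ratio = c(10, 20), marker_prev = 0.10, disease_prev = 0.01) |>
#'   binary_benefit(f2 = 0.03)
#' @export
binary_benefit <- function(data, f1 = 1, f2, eta = NULL, delta = 0, h = 0,
                           nb_weight = NULL) {
  if (!is.data.frame(data)) abort_input("`data` must be a data frame of scenarios.")
  need <- c("odds_ratio", "marker_prev", "disease_prev")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort_input(sprintf("Scenario data lacks column(s): %s.", paste(missing, collapse = ", ")))
  }
  if ("f1" %in% names(data)) f1 <- data$f1
  if ("f2" %in% names(data)) f2 <- data$f2
  if (is.null(nb_weight)) nb_weight <- f2 / f1
  tab <- solve_two_by_two(data$odds_ratio, data$marker_prev, data$disease_prev)
  out <- two_by_two_metrics(tab)
  out$odds_ratio <- tab$odds_ratio # keep the input OR, not its float recomputation
  out$rpb <- rpb_detection(tab, f1 = f1, f2 = f2)
  out$nb <- net_benefit(tab, nb_weight = nb_weight)
  out$absolute_gain <- absolute_gain(tab, f1 = f1, f2 = f2, h = h)
  if (!is.null(eta)) {
    out$rpb_prevention <- rpb_prevention(tab, f1 = f1, f2 = f2, eta = eta, delta = delta)
    out$absolute_gain_prevention <-
      absolute_gain(tab, f1 = f1, f2 = f2, eta = eta, delta = delta, h = h)
  }
  out
}

#' Classify an RPB value
#'
#' Sign semantics of the index: negative = detrimental, zero = neutral,
#' positive = beneficial at the population level.
#'
#' @param rpb Numeric vector of RPB values.
#' @return A factor with levels `detrimental`, `neutral`, `beneficial`.
#' @export
rpb_verdict <- function(rpb) {
  factor(
    dplyr::case_when(rpb < 0 ~ "detrimental", rpb > 0 ~ "beneficial", TRUE ~ "neutral"),
    levels = c("detrimental", "neutral", "beneficial")
  )
}
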