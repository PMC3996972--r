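#' Equal-variance binormal marker model calibrated to an odds ratio
#'
#' Models a continuous marker as Gaussian within the non-diseased
#' (mean `mu_nd`) and diseased (mean `mu_d`) groups with common standard
#' deviation `sigma`. Under this model the disease log-odds are linear in the
#' marker with slope \eqn{(\mu_D - \mu_{\bar D})/\sigma^2}, so a target
#' per-unit odds ratio fixes the mean separation:
#' \deqn{\mu_D = \mu_{\bar D} + \sigma^2 \ln(OR).}
#' The defaults (`mu_nd = 0`, `sigma = 0.5`) match the reference numerical
#' illustrations; e.g. `OR = 50` gives `mu_d = 0.25 ln 50 = 0.978`.
#'
#' @param odds_ratio Positive odds ratio per unit increase of the marker.
#' @param sigma Common class-conditional standard deviation (> 0).
#' @param mu_nd Mean of the marker among non-diseased subjects.
#' @return A tibble of class `binormal_marker` with columns `odds_ratio`,
#'   `mu_nd`, `mu_d`, `sigma`.
#' @examples
#' binormal_marker(odds_ratio = 50)
#' @export
binormal_marker <- function(odds_ratio, sigma = 0.5, mu_nd = 0) {
  check_positive(odds_ratio, "odds_ratio")
  check_positive(sigma, "sigma")
  args <- recycle_args(odds_ratio = odds_ratio, sigma = sigma, mu_nd = mu_nd)
  out <- tibble::tibble(
    odds_ratio = args$odds_ratio,
    mu_nd = args$mu_nd,
    mu_d = args$mu_nd + args$sigma^2 * log(args$odds_ratio),
    sigma = args$sigma
  )
  class(out) <- c("binormal_marker", class(out))
  out
}

#' General class-conditional density pair
#'
#' An escape hatch from the Gaussian default: wrap arbitrary (vectorised)
#' density functions for the diseased and non-diseased groups. Tail areas are
#' obtained by adaptive quadrature, and thresholds by monotone root finding,
#' so any pair of proper densities on a common support works (e.g. kernel
#' estimates from a cohort).
#'
#' @param f_d Density of the marker among diseased subjects.
#' @param f_nd Density among non-diseased subjects.
#' @param lower,upper Support bounds used for integration and root finding.
#' @return An object of class `density_pair`.
#' @examples
#' dp <- density_pair(function(x) dnorm(x, 1, 1), dnorm, lower = -8, upper = 9)
#' marker_sensitivity(dp, threshold = 1)
#' @export
density_pair <- function(f_d, f_nd, lower = -Inf, upper = Inf) {
  stopifnot(is.function(f_d), is.function(f_nd))
  structure(list(f_d = f_d, f_nd = f_nd, lower = lower, upper = upper),
    class = "density_pair"
  )
}

#' Sensitivity and specificity of a continuous marker at a threshold
#'
#' Positive calls are made above the threshold `c`, so
#' \eqn{sens(c) = P(X_D > c) = \Phi((\mu_D - c)/\sigma)} and
#' \eqn{spec(c) = P(X_{\bar D} \le c) = 1 - \Phi((\mu_{\bar D} - c)/\sigma)}
#' for the binormal model; general density pairs are integrated numerically.
#'
#' @param pair A [binormal_marker()] (single- or multi-row, recycled against
#'   `threshold`) or a [density_pair()].
#' @param threshold Threshold value(s) `c`.
#' @param ... Passed to methods.
#' @return Numeric vector of rates in `[0, 1]`.
#' @export
marker_sensitivity <- function(pair, threshold, ...) {
  UseMethod("marker_sensitivity")
}

#' @rdname marker_sensitivity
#' @export
marker_specificity <- function(pair, threshold, ...) {
  UseMethod("marker_specificity")
}

#' @export
marker_sensitivity.binormal_marker <- function(pair, threshold, ...) {
  args <- recycle_args(mu = pair$mu_d, sigma = pair$sigma, c = threshold)
  stats::pnorm((args$mu - args$c) / args$sigma)
}

#' @export
marker_specificity.binormal_marker <- function(pair, threshold, ...) {
  args <- recycle_args(mu = pair$mu_nd, sigma = pair$sigma, c = threshold)
  1 - stats::pnorm((args$mu - args$c) / args$sigma)
}

#' @export
marker_sensitivity.density_pair <- function(pair, threshold, ...) {
  vapply(threshold, function(c) tail_area(pair$f_d, c, pair$upper), numeric(1))
}

#' @export
marker_specificity.density_pair <- function(pair, threshold, ...) {
  vapply(threshold, function(c) 1 - tail_area(pair$f_nd, c, pair$upper), numeric(1))
}

tail_area <- function(f, lower, upper, tol = 1e-10) {
  if (lower >= upper) return(0)
  res <- stats::integrate(f, lower, upper,
    rel.tol = tol, abs.tol = tol, stop.on.error = FALSE
  )
  if (res$message != "OK" && res$message != "the integral is probably divergent") {
    rlang::abort(
      sprintf("Quadrature failed over (%g, %g): %s", lower, upper, res$message),
      class = "popbenefit_integration_failure"
    )
  }
  min(max(res$value, 0), 1)
}

#' Solve a threshold under a policy
#'
#' Threshold policies mirror the reference table layout:
#' `fixed_sensitivity` keeps sensitivity at `level`
#' (\eqn{c = \mu_D - \sigma\Phi^{-1}(level)}), `fixed_specificity` keeps
#' specificity at `level` (\eqn{c = \mu_{\bar D} + \sigma\Phi^{-1}(level)}),
#' `balanced` makes sensitivity equal specificity (the midpoint
#' \eqn{(\mu_D + \mu_{\bar D})/2} for equal variances), and `explicit` passes
#' `level` through as the threshold itself. For a [density_pair()] the fixed
#' and balanced policies are solved by monotone root finding to `1e-9`.
#'
#' @inheritParams marker_sensitivity
#' @param policy One of `"balanced"`, `"fixed_sensitivity"`,
#'   `"fixed_specificity"`, `"explicit"`.
#' @param level Target rate in (0, 1) for the fixed policies; the threshold
#'   itself for `"explicit"`; ignored for `"balanced"`.
#' @return Numeric threshold(s).
#' @examples
#' pair <- binormal_marker(50)
#' solve_threshold(pair, "fixed_specificity", 0.95)
#' @export
solve_threshold <- function(pair, policy = c(
                              "balanced", "fixed_sensitivity",
                              "fixed_specificity", "explicit"
                            ),
                            level = NULL) {
  policy <- rlang::arg_match(policy)
  if (policy %in% c("fixed_sensitivity", "fixed_specificity")) {
    if (is.null(level)) abort_input("`level` is required for fixed policies.")
    check_fraction(level, "level")
  }
  if (policy == "explicit") {
    if (is.null(level)) abort_input("`level` (the threshold) is required for policy 'explicit'.")
    return(level)
  }
  if (inherits(pair, "binormal_marker")) {
    return(switch(policy,
      fixed_sensitivity = pair$mu_d - pair$sigma * stats::qnorm(level),
      fixed_specificity = pair$mu_nd + pair$sigma * stats::qnorm(level),
      balanced = (pair$mu_d + pair$mu_nd) / 2
    ))
  }
  solve_threshold_numeric(pair, policy, level)
}

solve_threshold_numeric <- function(pair, policy, level) {
  lo <- if (is.finite(pair$lower)) pair$lower else -50
  hi <- if (is.finite(pair$upper)) pair$upper else 50
  obj <- switch(policy,
    fixed_sensitivity = function(c) marker_sensitivity(pair, c) - level,
    fixed_specificity = function(c) marker_specificity(pair, c) - level,
    balanced = function(c) marker_sensitivity(pair, c) - marker_specificity(pair, c)
  )
  if (obj(lo) * obj(hi) > 0) {
    rlang::abort("Threshold root is not bracketed by the support bounds.",
      class = "popbenefit_solver_failure"
    )
  }
  stats::uniroot(obj, c(lo, hi), tol = 1e-12)$root
}

#' ROC curve of a continuous marker
#'
#' Sweeps a threshold grid and records (1 - specificity, sensitivity) pairs,
#' anchored at (0, 0) and (1, 1). The area under the curve is computed by
#' trapezoid; for the equal-variance binormal model it converges to the
#' closed form \eqn{\Phi\big((\mu_D - \mu_{\bar D})/(\sigma\sqrt2)\big)}.
#'
#' @inheritParams marker_sensitivity
#' @param n_points Number of grid points per curve (>= 2).
#' @return A tibble of class `roc_curve` with columns `odds_ratio` (for
#'   binormal input), `fpr`, `tpr`, and attribute `auc` (a tibble of
#'   trapezoid and, where available, closed-form AUC per curve).
#' @examples
#' roc_curve(binormal_marker(c(2, 50))) |> attr("auc")
#' @export
roc_curve <- function(pair, n_points = 201) {
  if (n_points < 2) abort_input("`n_points` must be at least 2.")
  if (inherits(pair, "binormal_marker")) {
    curves <- purrr::pmap(
      list(pair$odds_ratio, pair$mu_nd, pair$mu_d, pair$sigma),
      function(or, mu_nd, mu_d, sigma) {
        span <- range(mu_nd, mu_d)
        grid <- seq(span[1] - 6 * sigma, span[2] + 6 * sigma, length.out = n_points)
        tibble::tibble(
          odds_ratio = or,
          fpr = c(1, 1 - stats::pnorm((grid - mu_nd) / sigma), 0),
          tpr = c(1, stats::pnorm((mu_d - grid) / sigma), 0)
        )
      }
    )
    out <- dplyr::arrange(dplyr::bind_rows(curves), .data$odds_ratio, .data$fpr, .data$tpr)
    auc <- dplyr::summarise(
      dplyr::group_by(out, .data$odds_ratio),
      auc = trapezoid_auc(.data$fpr, .data$tpr),
      .groups = "drop"
    )
    auc$auc_closed_form <- stats::pnorm((pair$mu_d - pair$mu_nd) / (pair$sigma * sqrt(2)))
  } else {
    lo <- if (is.finite(pair$lower)) pair$lower else -50
    hi <- if (is.finite(pair$upper)) pair$upper else 50
    grid <- seq(lo, hi, length.out = n_points)
    out <- tibble::tibble(
      fpr = c(1, 1 - marker_specificity(pair, grid), 0),
      tpr = c(1, marker_sensitivity(pair, grid), 0)
    )
    out <- dplyr::arrange(out, .data$fpr, .data$tpr)
    auc <- tibble::tibble(auc = trapezoid_auc(out$fpr, out$tpr))
  }
  structure(out, auc = auc, class = c("roc_curve", class(out)))
}

trapezoid_auc <- function(fpr, tpr) {
  ord <- order(fpr, tpr)
  x <- fpr[ord]
  y <- tpr[ord]
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @rdname roc_curve
#' @param object,x A `roc_curve` tibble.
#' @exportS3Method ggplot2::autoplot
autoplot.roc_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$fpr, .data$tpr))
  if ("odds_ratio" %in% names(object)) {
    p <- p + ggplot2::aes(colour = factor(.data$odds_ratio)) +
      ggplot2::labs(colour = "Odds ratio")
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname roc_curve
#' @param ... Unused.
#' @export
plot.roc_curve <- function(x, ...) print(autoplot.roc_curve(x, ...))
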