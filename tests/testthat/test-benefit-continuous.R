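pair50 <- binormal_marker(50)
c_bal <- solve_threshold(pair50, "balanced")
c_spec <- solve_threshold(pair50, "fixed_specificity", 0.95)

test_that("risk among marker-negatives and continuous PAR% behave as limits demand", {
  pair1 <- binormal_marker(1)
  expect_equal(q_unexposed(pair1, 0.3, 0.02), 0.02, tolerance = 1e-12)
  expect_equal(par_continuous(pair1, 0.3, 0.02), 0, tolerance = 1e-10)
  # frozen from the closed form: sens = spec = pnorm(0.978)
  expect_equal(q_unexposed(pair50, c_bal, 0.01), 0.0019782, tolerance = 1e-3)
  expect_equal(par_continuous(pair50, c_bal, 0.01), 80.17, tolerance = 0.2)
  # sensitivity near 1 at still-positive specificity: residual risk vanishes
  expect_lt(q_unexposed(pair50, -3, 0.01), 1e-6)
  # a threshold below the whole support leaves no marker-negative subjects
  expect_error(q_unexposed(pair50, -40, 0.01), class = "popbenefit_degenerate")
  expect_error(q_unexposed(pair50, 0.3, 0), class = "popbenefit_invalid_input")
})

test_that("detection RPB: closed form, quadrature and printed anchors agree", {
  expect_equal(round(rpb_detection_continuous(pair50, c_spec, 0.01, f2 = 0.03), 3), 0.119)
  expect_equal(round(rpb_detection_continuous(pair50, c_bal, 0.03, f2 = 0.06), 3), 0.176)
  thr <- seq(-0.5, 1.5, length.out = 9)
  cf <- rpb_detection_continuous(pair50, thr, 0.01, f2 = 0.03)
  quad <- rpb_detection_continuous(pair50, thr, 0.01, f2 = 0.03, method = "quadrature")
  expect_equal(cf, quad, tolerance = 1e-8)
  # zero crossing when the weighted gains balance
  sens <- marker_sensitivity(pair50, thr)
  spec <- marker_specificity(pair50, thr)
  balance <- 0.01 * sens - 0.99 * 0.03 * (1 - spec)
  expect_equal(sign(cf), sign(balance))
})

test_that("the RPB denominator is threshold-invariant", {
  thr <- seq(-1, 2, length.out = 7)
  num <- 0.01 * marker_sensitivity(pair50, thr) -
    0.99 * 0.03 * (1 - marker_specificity(pair50, thr))
  rpb <- rpb_detection_continuous(pair50, thr, 0.01, f2 = 0.03)
  expect_equal(num / rpb, rep(0.01 + 0.99 * 0.03, 7), tolerance = 1e-9)
})

test_that("detection RPB has a unique interior optimum in the threshold for OR > 1", {
  for (or in c(1.5, 4, 10, 20, 50)) {
    pair <- binormal_marker(or)
    # analytic optimum: density ratio f_D/f_ND equals (1-w) f2 / (w f1)
    c_star <- pair$sigma^2 * log(0.99 * 0.03 / 0.01) / (pair$mu_d - pair$mu_nd) +
      (pair$mu_d + pair$mu_nd) / 2
    thr <- seq(c_star - 3, c_star + 3, length.out = 301)
    rpb <- rpb_detection_continuous(pair, thr, 0.01, f2 = 0.03)
    d <- diff(rpb)
    # quasi-concave: rises to a single peak at the analytic optimum, then falls
    peak <- which.max(rpb)
    expect_lt(abs(thr[peak] - c_star), diff(thr)[1] + 1e-9)
    expect_true(all(d[seq_len(peak - 1)] > -1e-12))
    expect_true(all(d[seq(peak, length(d))] < 1e-12))
  }
})

test_that("prevention RPB handles constant and marker-dependent profiles", {
  expect_equal(rpb_prevention_continuous(pair50, c_bal, 0.01, f2 = 0.03, eta = 0, delta = 0), 0)
  # constant eta, delta = 0 reduces to eta * w * sens / denominator
  sens <- marker_sensitivity(pair50, c_bal)
  expect_equal(
    rpb_prevention_continuous(pair50, c_bal, 0.01, f2 = 0.03, eta = 0.5),
    0.5 * 0.01 * sens / 0.0397,
    tolerance = 1e-8
  )
  # eta = 1, delta = 0 matches the detection formula's diseased-group term
  expect_equal(
    rpb_prevention_continuous(pair50, c_bal, 0.01, f2 = 0.03, eta = 1),
    0.01 * sens / 0.0397,
    tolerance = 1e-8
  )
  # delta = 0 keeps prevention RPB non-negative across thresholds and efficacies
  for (thr in c(-0.5, 0.489, 1.5)) {
    expect_gte(rpb_prevention_continuous(pair50, thr, 0.01, f2 = 0.03, eta = 0.3), 0)
  }
  # marker-dependent profiles against the Monte Carlo oracle (3 SE)
  eta_fn <- function(x) pnorm(x)
  delta_fn <- function(x) 0.02 * plogis(x)
  got <- rpb_prevention_continuous(pair50, c_bal, 0.01, f2 = 0.03, eta = eta_fn, delta = delta_fn)
  mc_eta <- mc_weighted_tail(pair50, c_bal, eta_fn, n = 4e5, seed = 3)
  mc_delta_d <- mc_weighted_tail(pair50, c_bal, delta_fn, n = 4e5, seed = 4)
  nd <- binormal_marker(1) # same sigma, mean 0: the non-diseased density
  mc_delta_nd <- mc_weighted_tail(nd, c_bal, delta_fn, n = 4e5, seed = 5)
  num_mc <- 0.01 * mc_eta$value - 0.01 * mc_delta_d$value - 0.99 * mc_delta_nd$value
  se <- sqrt((0.01 * mc_eta$se)^2 + (0.01 * mc_delta_d$se)^2 + (0.99 * mc_delta_nd$se)^2)
  expect_lt(abs(got - num_mc / 0.0397), 3 * se / 0.0397)
})

test_that("restricted-to-diseased RPB integrates efficacy over the positive tail", {
  expect_equal(
    rpb_restricted_continuous(pair50, c_bal, eta = 1),
    marker_sensitivity(pair50, c_bal),
    tolerance = 1e-8
  )
  expect_equal(rpb_restricted_continuous(pair50, c_bal, eta = 0), 0)
  eta_fn <- function(x) pnorm(x)
  got <- rpb_restricted_continuous(pair50, c_bal, eta = eta_fn)
  mc <- mc_weighted_tail(pair50, c_bal, eta_fn, n = 4e5, seed = 9)
  expect_lt(abs(got - mc$value), 3 * mc$se)
  expect_gte(got, 0)
})

test_that("total gain recovers the RPB numerator at h = 0 and decreases with cost", {
  num <- 0.01 * marker_sensitivity(pair50, c_spec) -
    0.99 * 0.03 * (1 - marker_specificity(pair50, c_spec))
  expect_equal(total_gain_continuous(pair50, c_spec, 0.01, f2 = 0.03, h = 0), num,
    tolerance = 1e-12
  )
  # frozen arithmetic from the closed forms at h = 0.01:
  # 0.0047366 - 0.01*(0.01*0.6221575 + 0.99*0.05) = 0.0041794
  expect_equal(
    unname(total_gain_continuous(pair50, c_spec, 0.01, f2 = 0.03, h = 0.01)),
    0.0041794,
    tolerance = 1e-4
  )
  hs <- seq(0, 0.05, by = 0.01)
  gains <- vapply(hs, function(h) {
    total_gain_continuous(pair50, c_spec, 0.01, f2 = 0.03, h = h)
  }, numeric(1))
  expect_true(all(diff(gains) < 0))
  # prevention form at h = 0 recovers the prevention numerator
  prev_gain <- total_gain_continuous(pair50, c_bal, 0.01, f2 = 0.03, h = 0, eta = 0.5)
  expect_equal(prev_gain, 0.5 * 0.01 * marker_sensitivity(pair50, c_bal), tolerance = 1e-8)
})

test_that("continuous net benefit matches its identity with the RPB numerator", {
  expect_equal(round(nb_continuous(pair50, c_spec, 0.01, nb_weight = 0.03), 3), 0.005)
  num <- 0.01 * marker_sensitivity(pair50, c_spec) -
    0.03 * 0.99 * (1 - marker_specificity(pair50, c_spec))
  expect_equal(nb_continuous(pair50, c_spec, 0.01, nb_weight = 0.03), num, tolerance = 1e-12)
  # all-negative threshold: nothing gained
  expect_lte(nb_continuous(pair50, 40, 0.01, nb_weight = 0.03), 0)
})

test_that("dichotomising the marker reproduces the continuous results through the binary path", {
  for (or in c(1.5, 10, 50)) {
    pair <- binormal_marker(or)
    thr <- solve_threshold(pair, "balanced")
    cells <- dichotomise(pair, thr, 0.01)
    expect_equal(cells$a + cells$b + cells$c + cells$d, 1, tolerance = 1e-12)
    expect_equal(
      rpb_detection(cells, f2 = 0.03),
      rpb_detection_continuous(pair, thr, 0.01, f2 = 0.03),
      tolerance = 1e-12
    )
    expect_equal(
      net_benefit(cells, nb_weight = 0.03),
      nb_continuous(pair, thr, 0.01, nb_weight = 0.03),
      tolerance = 1e-12
    )
    m <- two_by_two_metrics(cells)
    expect_equal(m$par_percent, par_continuous(pair, thr, 0.01), tolerance = 1e-10)
  }
})

test_that("stratified continuous RPB adjustment is the case-weighted average", {
  strata <- tibble::tibble(p = c(0.6, 0.4), rpb = c(0.119, -0.008))
  expect_equal(rpb_adjusted_continuous(strata), 0.0682)
  single <- tibble::tibble(p = 1, rpb = 0.119)
  expect_equal(rpb_adjusted_continuous(single), 0.119)
})

test_that("the continuous scenario pipeline composes the unit operations", {
  rep <- tibble::tibble(
    odds_ratio = 50,
    policy = c("fixed_sensitivity", "fixed_specificity", "balanced"),
    disease_prev = 0.01
  ) |> continuous_benefit(f2 = 0.03, level = 0.95)
  expect_equal(rep$sensitivity[1], 0.95, tolerance = 1e-12)
  expect_equal(rep$specificity[2], 0.95, tolerance = 1e-12)
  expect_equal(round(rep$rpb[2], 3), 0.119)
  expect_equal(round(rep$nb[2], 3), 0.005)
  expect_equal(rep$sensitivity[3], rep$specificity[3], tolerance = 1e-12)
  expect_equal(
    rep$rpb[3],
    rpb_detection_continuous(pair50, c_bal, 0.01, f2 = 0.03),
    tolerance = 1e-12
  )
})
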