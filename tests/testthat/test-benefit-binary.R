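tab20 <- solve_two_by_two(20, 0.10, 0.01)

test_that("detection RPB reproduces printed values and closed-form limits", {
  expect_equal(round(rpb_detection(tab20, f2 = 0.03), 3), 0.100)
  # numerator vanishes when a*f1 == b*f2
  bal <- tibble::tibble(a = 0.03, b = 0.30, c = 0.07, d = 0.60)
  expect_equal(rpb_detection(bal, f1 = 1, f2 = 0.1), 0)
  # perfect marker attains the prevalence-determined upper bound
  perfect <- tibble::tibble(a = 0.01, b = 0, c = 0, d = 0.99)
  expect_equal(rpb_detection(perfect, f2 = 0.03), 0.01 / 0.0397, tolerance = 1e-12)
})

test_that("RPB denominator depends only on prevalence and weights", {
  grid <- tidyr::expand_grid(
    odds_ratio = c(1.5, 2, 4, 10, 20, 50),
    marker_prev = c(0.001, 0.01, 0.1, 0.3, 0.7)
  )
  tab <- solve_two_by_two(grid$odds_ratio, grid$marker_prev, 0.01)
  den <- 1 * (tab$a + tab$c) + 0.03 * (tab$b + tab$d)
  expect_equal(den, rep(0.01 + 0.99 * 0.03, nrow(tab)), tolerance = 1e-12)
})

test_that("detection RPB is bounded, monotone in a, and decreasing in f2", {
  w <- 0.01
  bound <- w / (w + 0.03 * (1 - w))
  ors <- c(1.5, 4, 20, 50, 500)
  rpb <- solve_two_by_two(ors, 0.1, w) |> rpb_detection(f2 = 0.03)
  expect_true(all(rpb <= bound + 1e-12))
  expect_true(all(rpb >= -1) && all(rpb <= 1))
  # move mass from c to a (margins' complement fixed): RPB strictly increases
  a <- seq(0.001, 0.009, by = 0.002)
  shift <- tibble::tibble(a = a, b = 0.1 - a, c = 0.01 - a, d = 0.89 + a)
  expect_true(all(diff(rpb_detection(shift, f2 = 0.03)) > 0))
  f2s <- c(0.01, 0.03, 0.06, 0.15)
  by_f2 <- vapply(f2s, function(f2) rpb_detection(tab20, f2 = f2), numeric(1))
  expect_true(all(diff(by_f2) < 0))
})

test_that("prevention RPB reduces correctly and its sign follows the numerator", {
  expect_equal(rpb_prevention(tab20, f2 = 0.03, eta = 0, delta = 0), 0)
  # eta=1, delta=0 gives a*f1/denominator
  expect_equal(
    rpb_prevention(tab20, f2 = 0.03, eta = 1, delta = 0),
    tab20$a / 0.0397,
    tolerance = 1e-12
  )
  expect_equal(round(tab20$a / 0.0397, 4), 0.1701)
  # delta = 0 implies non-negative benefit
  withr::local_seed(11)
  for (i in 1:20) {
    tab <- solve_two_by_two(exp(runif(1, 0, 5)), runif(1, 0.01, 0.9), runif(1, 0.01, 0.5))
    expect_gte(rpb_prevention(tab, f2 = 0.05, eta = runif(1), delta = 0), 0)
  }
  # adverse effect large enough to outweigh the averted cases
  big_delta <- rpb_prevention(tab20, f2 = 0.03, eta = 1, delta = 0.5)
  expect_lt(big_delta, 0)
})

test_that("restricted-to-diseased RPB is sensitivity times net efficacy", {
  expect_equal(rpb_restricted(0.675, eta = 1, delta = 0), 0.675)
  expect_equal(rpb_restricted(0.5, eta = 0.8, delta = 0.1), 0.35)
  expect_equal(rpb_restricted(0, eta = 1, delta = 0.2), 0)
})

test_that("net benefit matches the printed anchor and the RPB-numerator identity", {
  expect_equal(round(net_benefit(tab20, nb_weight = 0.03), 3), 0.004)
  no_tp <- tibble::tibble(a = 0, b = 0.1, c = 0.01, d = 0.89)
  expect_lte(net_benefit(no_tp, nb_weight = 0.03), 0)
  # with w_nb = f2/f1, NB*f1 equals the RPB numerator per unit population
  f1 <- 2
  f2 <- 0.1
  nb <- net_benefit(tab20, nb_weight = f2 / f1)
  num <- tab20$a * f1 - tab20$b * f2
  expect_equal(nb * f1, num, tolerance = 1e-12)
  expect_error(net_benefit(tab20, nb_weight = -0.1), class = "popbenefit_invalid_input")
})

test_that("absolute gain charges the treatment cost on all marker-positives", {
  expect_equal(
    absolute_gain(tab20, f2 = 0.03, h = 0),
    tab20$a - 0.03 * tab20$b,
    tolerance = 1e-14
  )
  expect_equal(
    absolute_gain(tab20, f2 = 0.03, h = 0.01),
    (tab20$a - 0.03 * tab20$b) - 0.01 * 0.1,
    tolerance = 1e-12
  )
  hs <- c(0, 0.01, 0.05, 0.2)
  gains <- vapply(hs, function(h) absolute_gain(tab20, f2 = 0.03, h = h), numeric(1))
  expect_true(all(diff(gains) < 0))
  expect_lt(absolute_gain(tab20, f2 = 0.03, h = 1), 0)
  # prevention form
  expect_equal(
    absolute_gain(tab20, f2 = 0.03, eta = 0.8, delta = 0.01, h = 0.005),
    tab20$a * 0.8 - (tab20$a + tab20$b) * 0.01 - 0.005 * 0.1,
    tolerance = 1e-12
  )
})

test_that("stratified RPB adjustment is the case-weighted average", {
  strata <- tibble::tibble(p = c(0.5, 0.5), rpb = c(0.100, -0.046))
  expect_equal(rpb_adjusted(strata), 0.027)
  expect_equal(rpb_adjusted(tibble::tibble(p = 1, rpb = 0.1)), 0.1)
  expect_error(
    rpb_adjusted(tibble::tibble(p = c(0.2, 0.2), rpb = c(0, 0))),
    class = "popbenefit_invalid_strata"
  )
})

test_that("the scenario pipeline composes the individual operations", {
  rep3 <- tibble::tibble(odds_ratio = 10, marker_prev = 0.30, disease_prev = 0.03) |>
    binary_benefit(f2 = 0.03)
  expect_equal(round(rep3$rpb, 3), 0.266)
  rep50 <- tibble::tibble(odds_ratio = 50, marker_prev = 0.01, disease_prev = 0.01) |>
    binary_benefit(f2 = 0.15)
  expect_equal(round(rep50$rpb, 3), 0.010)
  # independence closed form
  p <- 0.2
  w <- 0.05
  f2 <- 0.06
  indep <- tibble::tibble(odds_ratio = 1, marker_prev = p, disease_prev = w) |>
    binary_benefit(f2 = f2)
  expect_equal(indep$rpb, (p * w - p * (1 - w) * f2) / (w + (1 - w) * f2),
    tolerance = 1e-12
  )
  # report fields agree with the unit operations
  rep20 <- tibble::tibble(odds_ratio = 20, marker_prev = 0.10, disease_prev = 0.01) |>
    binary_benefit(f2 = 0.03, eta = 1, delta = 0)
  expect_equal(rep20$rpb, rpb_detection(tab20, f2 = 0.03))
  expect_equal(rep20$nb, net_benefit(tab20, nb_weight = 0.03))
  expect_equal(rep20$rpb_prevention, rpb_prevention(tab20, f2 = 0.03, eta = 1))
})

test_that("RPB sign classifies population effect", {
  expect_equal(
    as.character(rpb_verdict(c(-0.1, 0, 0.2))),
    c("detrimental", "neutral", "beneficial")
  )
})
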