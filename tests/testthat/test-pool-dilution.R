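make_series <- function(no2_fun, no3_fun = function(t) rep(1, length(t)),
                        nh4_fun = function(t) rep(10, length(t)),
                        times = c(0, 6, 12, 18, 20),
                        volume = 1.5, weight = 5) {
  incubation_series(
    "c1", volume, weight,
    tibble::tibble(time_h = times, nh4 = nh4_fun(times),
                   no2 = no2_fun(times), no3 = no3_fun(times)),
    tibble::tibble(time_h = c(0, 20), ape_nox = c(5, 3)))
}

test_that("pool-dilution estimator reproduces the analytic two-point solution", {
  est <- gross_rates_ipd(10, 14, 5, 3, 20 / 24)
  expect_equal(est$gross_production, 7.28727, tolerance = 1e-5)
  expect_equal(est$consumption, 2.48727, tolerance = 1e-5)
  expect_equal(est$net_change, 4.8, tolerance = 1e-6)
  expect_identical(est$flags, "")

  # constant pool: the logarithm-free limiting form C ln(APE0/APEt) / t
  lim <- gross_rates_ipd(10, 10, 4, 2, 1)
  expect_equal(lim$gross_production, 10 * log(2), tolerance = 1e-9)
  expect_equal(lim$consumption, 10 * log(2), tolerance = 1e-9)
})

test_that("no enrichment dilution means zero gross production", {
  est <- gross_rates_ipd(10, 14, 5, 5, 1)
  expect_equal(est$gross_production, 0)
  # consumption = -net change is a model violation (pool grew without
  # production); value is preserved and flagged
  expect_equal(est$consumption, -4)
  expect_match(est$flags, "model_violation")
})

test_that("only the enrichment ratio enters the estimator", {
  a <- gross_rates_ipd(10, 14, 5, 3, 1)
  b <- gross_rates_ipd(10, 14, 0.5, 0.3, 1)
  expect_equal(a$gross_production, b$gross_production)
  expect_equal(a$consumption, b$consumption)
})

test_that("increasing enrichment is flagged, not estimated", {
  est <- gross_rates_ipd(10, 14, 3, 5, 1)
  expect_true(is.na(est$gross_production))
  expect_true(is.na(est$consumption))
  expect_identical(est$flags, "enrichment_increased")
  expect_error(gross_rates_ipd(0, 14, 5, 3, 1),
               class = "nitrosponge_validation_error")
})

test_that("estimator recovers the truth on noise-free forward simulations", {
  # grid over realistic gross production / consumption rates
  for (p in c(0.5, 2, 8, 20)) {
    for (cons in c(0, 0.4, 3, 7)) {
      fwd <- oracle_forward(p, cons, c0 = 12, ape0 = 8, t = 20 / 24)
      est <- gross_rates_ipd(12, fwd$c, 8, fwd$ape, 20 / 24)
      if (p == 0) next
      expect_equal(est$gross_production, p, tolerance = 0.01)
      expect_lt(abs(est$consumption - cons), 0.01 * max(cons, p))
    }
  }
})

test_that("volumetric rates normalize to wet weight by V/W", {
  expect_equal(to_specific_rate(7.287, 1.5, 5), 2.1861)
  expect_equal(to_specific_rate(3, 2, 2000), 3 / 1000)
  expect_equal(to_specific_rate(0, 1.5, 5), 0)
  expect_error(to_specific_rate(1, 0, 5),
               class = "nitrosponge_validation_error")
})

test_that("net fluxes are linear concentration changes normalized to biomass", {
  s <- make_series(no2_fun = function(t) 2 + (5 - 2) * (t - 6) / 12)
  f <- net_flux(s, "no2")
  expect_equal(f$value, 1.8, tolerance = 1e-9)

  s0 <- make_series(no2_fun = function(t) rep(3, length(t)))
  expect_equal(net_flux(s0, "no2")$value, 0)

  # declining ammonium: sign preserved (net consumption)
  s2 <- make_series(no2_fun = function(t) rep(1, length(t)),
                    nh4_fun = function(t) 25 - (t - 6), weight = 6)
  expect_equal(net_flux(s2, "nh4")$value, -24 * 1.5 / 6, tolerance = 1e-9)
})

test_that("net flux is linear in the concentration series", {
  base <- function(t) 2 + 0.3 * t
  s1 <- make_series(no2_fun = base)
  s3 <- make_series(no2_fun = function(t) 3 * base(t))
  expect_equal(net_flux(s3, "no2")$value, 3 * net_flux(s1, "no2")$value)
})

test_that("window endpoints interpolate within tolerance, else error", {
  # samples at 5.5 and 6.5 h bracket the 6 h endpoint within 1 h
  s <- incubation_series(
    "c1", 1.5, 5,
    tibble::tibble(time_h = c(0, 5.5, 6.5, 18), nh4 = 10,
                   no2 = c(1, 2, 3, 9), no3 = 1),
    tibble::tibble(time_h = c(0, 20), ape_nox = c(5, 3)))
  f <- net_flux(s, "no2")
  expect_equal(f$value, (9 - 2.5) / 0.5 * 1.5 / 5, tolerance = 1e-9)

  s_gap <- incubation_series(
    "c1", 1.5, 5,
    tibble::tibble(time_h = c(0, 12, 18), nh4 = 10, no2 = c(1, 5, 9),
                   no3 = 1),
    tibble::tibble(time_h = c(0, 20), ape_nox = c(5, 3)))
  expect_error(net_flux(s_gap, "no2"),
               class = "nitrosponge_window_uncovered")
})

test_that("net nitrification adds the product fluxes and exposes the NO2:NO3 ratio", {
  mk <- function(v) tibble::tibble(container_id = "c1", kind = "net_flux",
                                   species = "x", t_start_h = 6,
                                   t_end_h = 18, value = v, flags = "")
  nn <- net_nitrification(mk(1.8), mk(0.6))
  expect_equal(nn$value, 2.4)
  expect_equal(nn$no2_no3_ratio, 3)
  expect_equal(net_nitrification(mk(1.8), mk(-1.8))$value, 0)

  n32 <- net_nitrification(mk(0.9), mk(0.32))
  expect_equal(n32$value, 1.22)
  expect_equal(n32$no2_no3_ratio, 2.8125, tolerance = 1e-6)

  bad <- mk(0.6); bad$t_end_h <- 24
  expect_error(net_nitrification(mk(1.8), bad),
               class = "nitrosponge_validation_error")
})

test_that("label additions are planned as a fraction of the post-addition pool", {
  plan <- plan_label_addition(10, 0.10)
  expect_equal(plan$addition_um, 10 / 9, tolerance = 1e-9)
  expect_equal(plan$ape0, 9.76337, tolerance = 1e-5)

  # vanishing target fraction -> vanishing addition
  expect_lt(plan_label_addition(10, 1e-6)$addition_um, 2e-5)

  # pre-addition basis is the plain product
  expect_equal(plan_label_addition(10, 0.05, fraction_basis = "pre")$addition_um,
               0.5)

  expect_error(plan_label_addition(0, 0.1),
               class = "nitrosponge_validation_error")
  expect_error(plan_label_addition(10, 0.2),
               class = "nitrosponge_validation_error")
})

test_that("series-level gross rates combine IPD with biomass normalization", {
  cfg <- simulation_config(seed = 11, gross_production = 7.287,
                           nox_consumption = 2.487)
  s <- simulate_incubation(cfg)
  g <- gross_rates(s)
  truth <- attr(s, "truth")
  expect_equal(g$value, truth$gross_production_specific, tolerance = 1e-3)
  expect_equal(g$consumption, truth$nox_consumption_specific,
               tolerance = 5e-3)
})
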