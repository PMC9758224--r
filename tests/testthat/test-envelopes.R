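test_that("snap_to_envelope rounds to the 5-degree acclimation grid", {
  e <- snap_to_envelope(6.3, 27.8)
  expect_equal(c(e$t_min_C, e$t_max_C), c(5, 30))
  e <- snap_to_envelope(-1.4, 21.0)   # lower clamp at 5
  expect_equal(c(e$t_min_C, e$t_max_C), c(5, 20))
  e <- snap_to_envelope(7.5, 22.5)    # ties round upward
  expect_equal(c(e$t_min_C, e$t_max_C), c(10, 25))
  expect_error(snap_to_envelope(25, 5), "t_min_C")
})

test_that("snap_to_envelope is idempotent and non-degenerate", {
  for (lo in seq(5, 25, 5)) for (hi in seq(lo + 5, 30, 5)) {
    e <- snap_to_envelope(lo, hi)
    expect_equal(c(e$t_min_C, e$t_max_C), c(lo, hi))
  }
  # degenerate snaps widen downward (or upward at the 5-degree floor)
  e <- snap_to_envelope(19, 21)
  expect_equal(c(e$t_min_C, e$t_max_C), c(15, 20))
  e <- snap_to_envelope(4, 6)
  expect_equal(c(e$t_min_C, e$t_max_C), c(5, 10))
})

test_that("subpopulations split at the latitudinal cline, inclusive north", {
  expect_equal(assign_subpopulation(c(40, 39.75, 44.25)),
               c("north", "south", "north"))
  expect_equal(assign_subpopulation(40.25, cline_lat = 41), "south")
})

test_that("envelope table recovers a single shared E exactly", {
  acc <- gen_acclimation_data(E_north = 0.6, E_south = 0.6, noise_sd = 0)
  tab <- build_envelope_E_table(acc)
  expect_equal(nrow(tab), 15 * 2)  # 15 envelopes x 2 subpopulations
  expect_equal(tab$E_eV, rep(0.6, nrow(tab)), tolerance = 1e-9)
  expect_true(all(tab$r_squared > 1 - 1e-9))
})

test_that("two-temperature envelopes give exact two-point fits", {
  d <- gen_arrhenius_measurements(0.5, 2, temps_C = c(5, 10),
                                  subpopulation = "north")
  tab <- build_envelope_E_table(d, envelopes = data.frame(t_min_C = 5,
                                                          t_max_C = 10))
  expect_equal(tab$E_eV, 0.5, tolerance = 1e-9)
  expect_equal(tab$r_squared, 1)
  expect_equal(tab$n, 2L)
})

test_that("a mixed cold/warm E pools to an intermediate envelope fit", {
  cold <- gen_arrhenius_measurements(0.5, 2, temps_C = c(5, 10, 15),
                                     subpopulation = "south")
  # warm segment's intercept chosen so the two Arrhenius lines meet near
  # 22.5 degC; the pooled OLS slope then falls between the segment slopes
  lnA_warm <- 2 + (0.9 - 0.5) / (8.617e-5 * (22.5 + 273.15))
  warm <- gen_arrhenius_measurements(0.9, lnA_warm,
                                     temps_C = c(20, 25, 30),
                                     subpopulation = "south")
  pooled <- rbind(cold, warm)
  tab <- build_envelope_E_table(pooled,
                                envelopes = data.frame(t_min_C = 5,
                                                       t_max_C = 30),
                                include_33 = FALSE)
  expect_gt(tab$E_eV, 0.5)
  expect_lt(tab$E_eV, 0.9)
  # and it matches a direct OLS on the pooled subset
  ora <- ols_oracle(pooled$temp_C, pooled$rate)
  expect_equal(tab$E_eV, ora$E, tolerance = 1e-10)
})

test_that("33-degree assays join only 30-bounded envelopes (and can be excluded)", {
  acc <- gen_acclimation_data(noise_sd = 0, n_reps = 1)
  north <- acc[acc$subpopulation == "north", ]
  n_in <- function(lo, hi, inc)
    nrow(pibcm:::.envelope_subset(north, lo, hi, include_33 = inc))
  expect_equal(n_in(5, 30, TRUE), 7)   # 5..30 plus 33
  expect_equal(n_in(5, 30, FALSE), 6)
  expect_equal(n_in(5, 25, TRUE), 5)   # 33 never joins a 25-bounded envelope
  # full-range envelope fit equals fit_arrhenius on the full subpopulation data
  tab <- build_envelope_E_table(north,
                                envelopes = data.frame(t_min_C = 5,
                                                       t_max_C = 30))
  full <- fit_arrhenius(north)
  expect_equal(tab$E_eV, full$E_eV, tolerance = 1e-12)
})

test_that("envelope table errors name data-poor envelopes", {
  d <- gen_arrhenius_measurements(0.5, 2, temps_C = c(5, 10),
                                  subpopulation = "north")
  expect_error(build_envelope_E_table(d,
                                      envelopes = data.frame(t_min_C = 15,
                                                             t_max_C = 25)),
               "15-25")
})

test_that("annual E variance reflects between-envelope switching only", {
  # thermal sensitivity differs between the cold and warm acclimation range,
  # so different envelopes carry different fitted E values
  acc <- rbind(
    gen_arrhenius_measurements(0.5, 2, temps_C = c(5, 10, 15, 20),
                               subpopulation = "north"),
    gen_arrhenius_measurements(0.9, 4, temps_C = c(25, 30, 33),
                               subpopulation = "north"))
  # constant years
  yrs <- data.frame(t_min_C = rep(6, 10), t_max_C = rep(24, 10))
  expect_equal(as.numeric(annual_E_variance(yrs, "north", acc)), 0)
  # sub-bin wobble is absorbed by snapping
  yrs <- data.frame(t_min_C = c(5.8, 6.1, 6.4, 5.9),
                    t_max_C = c(24.0, 24.4, 23.8, 24.2))
  expect_equal(as.numeric(annual_E_variance(yrs, "north", acc)), 0)
  # alternating envelopes -> closed-form variance of the two-valued series
  yrs <- data.frame(t_min_C = rep(c(6, 6), 5), t_max_C = rep(c(24, 29), 5))
  v <- annual_E_variance(yrs, "north", acc)
  Es <- attr(v, "E_series")
  ab <- unique(Es)
  expect_length(ab, 2L)
  # sample variance of a balanced two-valued sequence of length 2m:
  # m (a - b)^2 / (2m - 1) / 2
  m <- 5
  expect_equal(as.numeric(v),
               m * (ab[1] - ab[2])^2 / (2 * m - 1) / 2,
               tolerance = 1e-12)
  expect_error(annual_E_variance(yrs[1, ], "north", acc), "2 years")
})
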