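make_daily <- function(lat, lon, years, value_fun) {
  dates <- seq(as.Date(sprintf("%d-01-01", min(years))),
               as.Date(sprintf("%d-12-31", max(years))), by = "day")
  arr <- array(NA_real_, c(length(lat), length(lon), length(dates)))
  for (t in seq_along(dates))
    arr[, , t] <- value_fun(dates[t])
  list(sst = arr, dates = dates)
}

test_that("monthly climatology averages by calendar month across years", {
  lat <- c(38.25, 38.75); lon <- c(-73.75, -73.25)
  d <- make_daily(lat, lon, 2000:2001, function(dt) 10)
  clim <- monthly_climatology(d$sst, d$dates, lat, lon)
  expect_equal(as.numeric(clim$monthly), rep(10, 2 * 2 * 12))

  d <- make_daily(lat, lon, 2000:2001,
                  function(dt) as.integer(format(dt, "%m")))
  clim <- monthly_climatology(d$sst, d$dates, lat, lon)
  for (m in 1:12) expect_equal(as.numeric(clim$monthly[, , m]),
                               rep(m, 4))

  # two years with different January values average directly
  d <- make_daily(lat, lon, 2000:2001, function(dt) {
    if (format(dt, "%m") != "01") return(10)
    if (format(dt, "%Y") == "2000") 2 else 4
  })
  clim <- monthly_climatology(d$sst, d$dates, lat, lon)
  expect_equal(as.numeric(clim$monthly[, , 1]), rep(3, 4))
  expect_error(monthly_climatology(array(1, c(2, 2, 0)), as.Date(character()),
                                   lat, lon), "empty")
})

test_that("extremes and range come from the 12 monthly layers", {
  lat <- 38.25; lon <- -73.75
  arr <- array(rep(1:12, each = 1), c(1, 1, 12))
  ext <- extremes_and_range(clim_grid(lat, lon, arr))
  expect_equal(ext$t_min[1, 1], 1)
  expect_equal(ext$t_max[1, 1], 12)
  expect_equal(ext$sst_range[1, 1], 11)

  arr0 <- array(10, c(1, 1, 12))
  ext0 <- extremes_and_range(clim_grid(lat, lon, arr0))
  expect_equal(ext0$sst_range[1, 1], 0)

  # sinusoid sampled at month midpoints: range = max - min of the samples
  s <- 15 + 8 * sin(2 * pi * (1:12) / 12)
  exts <- extremes_and_range(clim_grid(lat, lon, array(s, c(1, 1, 12))))
  expect_equal(exts$sst_range[1, 1], max(s) - min(s))
})

test_that("coarsening is a mask-aware cos-latitude weighted block mean", {
  lat <- seq(0.025, 0.975, by = 0.05)  # equatorial: near-uniform weights
  lon <- seq(0.025, 0.975, by = 0.05)
  const <- clim_grid(lat, lon, array(7, c(20, 20, 12)))
  cc <- coarsen(const, 10L)
  expect_equal(length(cc$lat), 2L)
  expect_equal(as.numeric(cc$monthly), rep(7, 2 * 2 * 12))
  expect_equal(cc$lat, c(0.25, 0.75))

  # half-masked blocks still average the unmasked value exactly
  arr <- array(5, c(20, 20, 12))
  arr[seq(1, 20, 2), , ] <- NA
  cm <- coarsen(clim_grid(lat, lon, arr), 10L)
  expect_equal(as.numeric(cm$monthly), rep(5, 2 * 2 * 12))

  # checkerboard 0/2 -> ~1 (cos weights nearly uniform near the equator)
  chk <- array(0, c(20, 20, 12))
  chk[] <- outer((1:20 + rep(1:20, each = 20)) %% 2 * 2, rep(1, 12))
  cchk <- coarsen(clim_grid(lat, lon, chk), 10L)
  expect_equal(as.numeric(cchk$monthly), rep(1, 48), tolerance = 1e-4)

  expect_error(coarsen(const, 7L), "divisible")
})

test_that("depth mask keeps the closed 0-10 m band and drops land", {
  b <- matrix(c(5, 200, 10, -3, 0, 9.99), 2, 3)
  m <- depth_mask(b)
  expect_equal(as.vector(m), c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_error(depth_mask(1:5), "matrix")
})

test_that("thin-plate spline reproduces nodes and affine fields exactly", {
  set.seed(3)
  nodes <- data.frame(lat = runif(12, 35, 40), lon = runif(12, -75, -70))
  targets <- data.frame(lat = runif(30, 35, 40), lon = runif(30, -75, -70))

  # constant field
  nodes$value <- 4.2
  expect_equal(tps_interpolate(nodes, targets), rep(4.2, 30),
               tolerance = 1e-8)
  # interpolation exactness at the nodes themselves
  nodes$value <- rnorm(12)
  expect_equal(tps_interpolate(nodes, nodes[c("lat", "lon")]), nodes$value,
               tolerance = 1e-8)
  # affine reproduction
  nodes$value <- 2 * nodes$lat + 3 * nodes$lon + 1
  got <- tps_interpolate(nodes, targets)
  expect_equal(got, 2 * targets$lat + 3 * targets$lon + 1,
               tolerance = 1e-8)

  expect_error(tps_interpolate(nodes[1:2, ], targets), "3 nodes")
  col <- data.frame(lat = 1:5, lon = 2 * (1:5) + 1, value = rnorm(5))
  expect_error(tps_interpolate(col, targets), "collinear")
})

test_that("delta downscaling is exact for zero, constant and affine deltas", {
  spec <- scenario_spec(seed = 11, years = 2000, noise_sd = 0.2)
  sc <- gen_coastal_sst(spec)
  clim_f <- monthly_climatology(sc$sst, sc$dates, sc$lat, sc$lon)
  baseline <- coarsen(clim_f, 10L)

  pair0 <- gen_model_pair(spec, list(type = "constant", value = 0))
  out0 <- delta_downscale(pair0$hist, pair0$future, baseline)
  expect_identical(out0$mask, baseline$mask)
  expect_equal(out0$monthly, baseline$monthly, tolerance = 1e-12)

  pair2 <- gen_model_pair(spec, list(type = "constant", value = 2))
  out2 <- delta_downscale(pair2$hist, pair2$future, baseline)
  expect_equal(out2$monthly, baseline$monthly + 2, tolerance = 1e-6)

  paira <- gen_model_pair(spec, list(type = "affine", intercept = 0,
                                     b_lat = 0.05, b_lon = 0))
  outa <- delta_downscale(paira$hist, paira$future, baseline)
  want <- baseline$monthly +
    outer(0.05 * baseline$lat,
          matrix(1, length(baseline$lon), 12))
  dim(want) <- dim(baseline$monthly)
  expect_equal(outa$monthly, want, tolerance = 1e-6)
})

test_that("ensemble mean averages members cell-wise", {
  lat <- c(38.25, 38.75); lon <- c(-73.75)
  a <- clim_grid(lat, lon, array(1:24 * 1.0, c(2, 1, 12)))
  b <- clim_grid(lat, lon, array(1:24 + 2.0, c(2, 1, 12)))
  m <- ensemble_mean(list(a, b))
  expect_equal(m$monthly, a$monthly + 1)
  expect_equal(ensemble_mean(list(a))$monthly, a$monthly)
  c3 <- clim_grid(lat, lon, array(0, c(2, 1, 12)))
  m3 <- ensemble_mean(list(a, b, c3))
  expect_equal(m3$monthly, (a$monthly + b$monthly + 0) / 3)
  wrong <- clim_grid(lat + 1, lon, array(1, c(2, 1, 12)))
  expect_error(ensemble_mean(list(a, wrong)), "geometry")
})

test_that("masked cells stay masked through the chain", {
  lat <- seq(0.025, 0.975, by = 0.05); lon <- lat
  arr <- array(rnorm(20 * 20 * 12, 15), c(20, 20, 12))
  arr[1:10, 1:10, ] <- NA  # one fully-masked coarse block
  fine <- clim_grid(lat, lon, arr)
  co <- coarsen(fine, 10L)
  expect_false(co$mask[1, 1])
  expect_true(all(is.na(co$monthly[1, 1, ])))
  ext <- extremes_and_range(co)
  expect_true(is.na(ext$sst_range[1, 1]))
})
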