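test_that("cell classification follows the three stay/relocate conditions", {
  cfg <- pibcm_config()
  expect_equal(classify_cell(28, 30, 2e-9, 1e-9, cfg), "stay_c1")
  # exceeding the break temperature always relocates
  expect_equal(classify_cell(28, 33, 2e-9, 1e-9, cfg), "move_c3")
  expect_equal(classify_cell(28, 33, 1e-9, 2e-9, cfg), "move_c3")
  # warmer and larger MRR relocates below the break too
  expect_equal(classify_cell(28, 30, 2e-9, 3e-9, cfg), "move_c3")
  # cooling future goes to condition 2
  expect_equal(classify_cell(28, 27, 1e-9, 2e-9, cfg), "stay_c2")
  # boundary equalities resolve in favour of staying
  expect_equal(classify_cell(30, 30, 2e-9, 2e-9, cfg), "stay_c1")
  expect_equal(classify_cell(30, 32, 2e-9, 2e-9, cfg), "stay_c1")
  expect_error(classify_cell(28, NA, 1e-9, 1e-9, cfg), "finite")
})

test_that("nearest refuge minimizes haversine distance among qualifiers", {
  cfg <- pibcm_config()
  states <- data.frame(
    lat = c(38, 38, 38, 38.5),
    lon = c(-75, -74.5, -73.5, -75),
    t_max_now = 28, t_max_fut = c(33, 29, 29, 29),
    mrr_now = c(2e-9, 1e-9, 1e-9, 1e-9),
    mrr_fut = c(3e-9, 1.5e-9, 1.5e-9, 1.5e-9))
  src <- states[1, ]
  # all three candidates qualify (mrr_fut 1.5e-9 <= source mrr_now 2e-9);
  # half a degree of longitude at 38 N is the shortest hop
  expect_equal(nearest_refuge(src, states, cfg), 2L)
  # no qualifier -> NA
  tight <- states; tight$mrr_fut <- 1e-8
  expect_true(is.na(nearest_refuge(src, tight, cfg)))
  expect_true(is.na(nearest_refuge(src, states[0, ], cfg)))

  # exact distance tie: equidistant north/south neighbours, lower lat wins
  sym <- data.frame(lat = c(38, 37.5, 38.5), lon = -75,
                    t_max_now = 28, t_max_fut = c(33, 29, 29),
                    mrr_now = 2e-9, mrr_fut = c(3e-9, 1e-9, 1e-9))
  expect_equal(nearest_refuge(sym[1, ], sym, cfg), 2L)
})

test_that("refuge distance ordering matches the longhand haversine", {
  sc <- random_scenario(5, 5, seed = 99)
  cfg <- pibcm_config()
  src <- sc$states[7, ]
  d_pkg <- pibcm:::.haversine_m(src$lat, src$lon, sc$states$lat,
                                sc$states$lon)
  d_ora <- haversine_oracle(src$lat, src$lon, sc$states$lat, sc$states$lon)
  expect_equal(d_pkg, d_ora, tolerance = 1e-9)
})

test_that("identical contemporary and future fields leave the map unchanged", {
  sc <- random_scenario(4, 4, seed = 5)
  st <- sc$states
  st$t_max_fut <- st$t_max_now
  st$mrr_fut <- st$mrr_now
  proj <- project_habitat(sc$map, st)
  expect_true(all(proj$condition == "stay_c1"))
  ord <- order(sc$map$lat, sc$map$lon)
  expect_equal(proj$future$p, sc$map$p[ord])
  expect_equal(proj$diagnostics$overflow_total, 0)
})

test_that("capping records overflow and zeroes the source", {
  cfg <- pibcm_config()
  # 1-D, 3 cells: A must move (hot), only B qualifies
  states <- data.frame(
    lat = c(38, 38, 38), lon = c(-75, -74.5, -74),
    t_max_now = c(30, 25, 25), t_max_fut = c(33, 26, 26),
    mrr_now = c(2e-9, 1e-9, 1e-9), mrr_fut = c(3e-9, 0.8e-9, 0.9e-9))
  map <- data.frame(lat = 38, lon = c(-75, -74.5, -74),
                    p = c(0.6, 0.7, 0.1))
  proj <- project_habitat(map, states, cfg)
  got <- proj$future
  expect_equal(got$p[got$lon == -75], 0)
  expect_equal(got$p[got$lon == -74.5], 1.0)
  expect_equal(proj$overflow[got$lon == -74.5], 0.3, tolerance = 1e-12)
  expect_equal(proj$diagnostics$pre_cap_total, 1.4, tolerance = 1e-12)
})

test_that("projection matches the brute-force oracle across random grids", {
  cfg <- pibcm_config()
  for (seed in 1:25) {
    nr <- 2 + seed %% 5; nc <- 2 + (seed * 7) %% 5
    sc <- random_scenario(nr, nc, seed = seed)
    proj <- project_habitat(sc$map, sc$states, cfg)
    ora <- pibcm_oracle(sc$map, sc$states)
    expect_equal(proj$condition, ora$condition)
    expect_equal(proj$future$p, ora$p, tolerance = 1e-12)
    expect_equal(proj$overflow, ora$overflow, tolerance = 1e-12)
    expect_equal(proj$stranded, ora$stranded)
  }
})

test_that("probability is conserved up to stranding, and capping is sane", {
  for (seed in c(2, 13, 27)) {
    sc <- random_scenario(5, 5, seed = seed)
    proj <- project_habitat(sc$map, sc$states)
    d <- proj$diagnostics
    expect_equal(d$pre_cap_total, d$input_total - d$stranded_mass,
                 tolerance = 1e-12)
    expect_true(all(proj$future$p <= 1))
    expect_true(all(proj$future$p >= 0))
    expect_equal(d$post_cap_total, d$pre_cap_total - d$overflow_total,
                 tolerance = 1e-12)
  }
})

test_that("uniform extra warming cannot reduce the number of movers", {
  cfg <- pibcm_config()
  for (seed in c(3, 8)) {
    sc <- random_scenario(5, 5, seed = seed)
    base_moves <- sum(classify_cell(sc$states$t_max_now,
                                    sc$states$t_max_fut,
                                    sc$states$mrr_now, sc$states$mrr_fut,
                                    cfg) == "move_c3")
    warmer <- sc$states
    warmer$t_max_fut <- warmer$t_max_fut + 1.5
    more_moves <- sum(classify_cell(warmer$t_max_now, warmer$t_max_fut,
                                    warmer$mrr_now, warmer$mrr_fut,
                                    cfg) == "move_c3")
    expect_gte(more_moves, base_moves)
  }
})

test_that("probability delta is future minus contemporary", {
  a <- data.frame(lat = c(38, 38.5), lon = -75, p = c(0.4, 0.2))
  b <- data.frame(lat = c(38, 38.5), lon = -75, p = c(1.0, 0.2))
  d <- probability_delta(b, a)
  expect_equal(d$delta, c(0.6, 0))
  expect_error(probability_delta(b, a[1, ]), "identical")
})

test_that("end-to-end: localized warming only displaces where it bites", {
  # warming confined to the southern half of a synthetic coast
  acc <- gen_acclimation_data(E_north = 0.5, E_south = 0.7)
  tab <- build_envelope_E_table(acc)
  cfg <- pibcm_config(cline_lat = 39)
  grid <- expand.grid(lat = seq(38.25, 39.75, 0.5),
                      lon = seq(-74.75, -74.25, 0.5))
  south <- grid$lat < 39
  states <- data.frame(
    lat = grid$lat, lon = grid$lon,
    t_max_now = 26, t_max_fut = ifelse(south, 33, 26),
    mrr_now = 1e-8, mrr_fut = ifelse(south, 2e-8, 1e-8))
  map <- data.frame(lat = grid$lat, lon = grid$lon, p = 0.5)
  proj <- project_habitat(map, states, cfg)
  moved <- proj$condition == "move_c3"
  expect_equal(sort(unique(proj$contemporary$lat[moved])),
               sort(unique(grid$lat[south])))
  # the northern cells keep or gain probability, never lose
  north_p <- proj$future$p[proj$future$lat >= 39]
  expect_true(all(north_p >= 0.5 - 1e-12))
})

test_that("classification logic is exhaustive over its truth table", {
  cfg <- pibcm_config()
  set.seed(1)
  tn <- runif(500, 20, 35); tf <- tn + runif(500, -3, 6)
  mn <- runif(500); mf <- mn * runif(500, 0.3, 3)
  cond <- classify_cell(tn, tf, mn, mf, cfg)
  expect_true(all(cond %in% c("stay_c1", "stay_c2", "move_c3")))
})
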