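#' Generate synthetic Arrhenius-Boltzmann rate measurements
#'
#' Inverts the fitted model: rates are
#' \eqn{\exp(\ln A_0 - E/kT)\cdot e^\varepsilon} with multiplicative
#' lognormal noise (\eqn{\varepsilon \sim N(0, sd^2)}, additive on the log
#' scale the regression uses), so noise-free data are recovered exactly and
#' noisy data are unbiased on the fitted scale. Deterministic for a fixed
#' seed.
#'
#' @param E_true activation energy (eV).
#' @param ln_A0 log normalization constant.
#' @param temps_C assay temperatures (degC).
#' @param noise_sd standard deviation of the log-scale noise (>= 0).
#' @param n_reps replicates per temperature.
#' @param seed RNG seed (required when \code{noise_sd > 0}).
#' @param species,subpopulation,mass_g measurement metadata.
#' @return Data frame with columns \code{species, subpopulation, mass_g,
#'   temp_C, rate}.
#' @export
gen_arrhenius_measurements <- function(E_true, ln_A0, temps_C,
                                       noise_sd = 0, n_reps = 1L,
                                       seed = NULL,
                                       species = "synthetic",
                                       subpopulation = "unspecified",
                                       mass_g = 10) {
  if (length(temps_C) == 0L) stop("'temps_C' must be non-empty",
                                  call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  temp_C <- rep(temps_C, each = n_reps)
  mu <- ln_A0 - E_true / (boltzmann_eV_K * (temp_C + 273.15))
  eps <- 0
  if (noise_sd > 0) {
    if (is.null(seed)) stop("a seed is required for noisy generation",
                            call. = FALSE)
    set.seed(seed)
    eps <- stats::rnorm(length(temp_C), 0, noise_sd)
  }
  data.frame(species = species, subpopulation = subpopulation,
             mass_g = mass_g, temp_C = temp_C, rate = exp(mu + eps),
             stringsAsFactors = FALSE)
}

#' Specification of a synthetic coastal scenario
#'
#' Describes the synthetic study system: a small coastal domain with a
#' latitudinal mean-SST gradient, a seasonal cycle whose amplitude grows
#' with latitude (mid/high-latitude estuaries see the larger ranges), and
#' interannual noise; a shelf bathymetry whose shallow (< 10 m) band hugs
#' the western (coastal) edge; and a smooth occupancy-probability field on
#' the half-degree grid. Resolutions mirror the real data sources: a
#' 0.05-degree daily SST product upscaled to the 0.5-degree habitat grid,
#' and a ~1-degree climate-model grid for delta downscaling.
#'
#' @param lat_range,lon_range domain bounds (degrees); default a 2 x 2
#'   degree mid-Atlantic coastal box.
#' @param fine_res fine SST resolution (degrees), default 0.05.
#' @param grid_res habitat grid resolution (degrees), default 0.5.
#' @param model_res climate-model grid resolution (degrees), default 1.
#' @param years calendar years of the daily series, default 2000:2002.
#' @param sst_at_ref mean SST (degC) at \code{ref_lat}.
#' @param ref_lat reference latitude for the mean gradient.
#' @param gradient mean-SST latitudinal gradient (degC per degree lat,
#'   negative northward).
#' @param amp0,amp_per_deg seasonal amplitude (degC) at the southern edge
#'   and its growth per degree of latitude.
#' @param noise_sd daily interannual noise sd (degC).
#' @param warming_delta_C constant warming (degC) imposed on the future
#'   period when generating daily series directly.
#' @param shelf_width_deg width (degrees of longitude) of the shallow
#'   shelf band along the western edge.
#' @param prob_smoothness e-folding scale (degrees) of the habitat
#'   probability field.
#' @param seed mandatory RNG seed; generated fields are reproducible
#'   bit-for-bit from (spec, seed).
#' @return A list of class \code{"scenario_spec"}.
#' @export
scenario_spec <- function(lat_range = c(38, 40), lon_range = c(-74, -72),
                          fine_res = 0.05, grid_res = 0.5, model_res = 1,
                          years = 2000:2002,
                          sst_at_ref = 18, ref_lat = 39, gradient = -1.5,
                          amp0 = 6, amp_per_deg = 1, noise_sd = 0.3,
                          warming_delta_C = 0,
                          shelf_width_deg = 0.6, prob_smoothness = 1,
                          seed) {
  if (missing(seed)) stop("'seed' is mandatory", call. = FALSE)
  for (r in list(lat_range, lon_range))
    if (length(r) != 2L || r[1L] >= r[2L])
      stop("ranges must be increasing length-2 vectors", call. = FALSE)
  if (abs((grid_res / fine_res) - round(grid_res / fine_res)) > 1e-9)
    stop("'grid_res' must be a multiple of 'fine_res'", call. = FALSE)
  structure(list(lat_range = lat_range, lon_range = lon_range,
                 fine_res = fine_res, grid_res = grid_res,
                 model_res = model_res, years = years,
                 sst_at_ref = sst_at_ref, ref_lat = ref_lat,
                 gradient = gradient, amp0 = amp0,
                 amp_per_deg = amp_per_deg, noise_sd = noise_sd,
                 warming_delta_C = warming_delta_C,
                 shelf_width_deg = shelf_width_deg,
                 prob_smoothness = prob_smoothness, seed = seed),
            class = "scenario_spec")
}

.centers <- function(range, res) seq(range[1L] + res / 2, range[2L], by = res)

.base_sst <- function(spec, lat) {
  spec$sst_at_ref + spec$gradient * (lat - spec$ref_lat)
}

.seasonal_amp <- function(spec, lat) {
  spec$amp0 + spec$amp_per_deg * (lat - spec$lat_range[1L])
}

#' Generate a synthetic coastal SST scenario
#'
#' Builds the daily fine-resolution SST cube
#' \eqn{SST(lat, lon, d) = base(lat) + A(lat)\sin(2\pi doy/365.25 - \pi/2)
#' + \Delta + \varepsilon}, the shelf bathymetry, and a smooth habitat
#' probability map on the half-degree grid restricted to the shallow-water
#' mask.
#'
#' @param spec a [scenario_spec()].
#' @return A list with elements \code{sst} (array nlat x nlon x ndays),
#'   \code{dates}, \code{lat}, \code{lon} (fine centers),
#'   \code{bathymetry} (fine matrix, m, positive down), and
#'   \code{habitat} (data frame lat, lon, p on the coarse grid).
#' @export
gen_coastal_sst <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  lat <- .centers(spec$lat_range, spec$fine_res)
  lon <- .centers(spec$lon_range, spec$fine_res)
  dates <- seq(as.Date(sprintf("%d-01-01", min(spec$years))),
               as.Date(sprintf("%d-12-31", max(spec$years))), by = "day")
  doy <- as.integer(format(dates, "%j"))
  nlat <- length(lat); nlon <- length(lon); nd <- length(dates)

  set.seed(spec$seed)
  base <- .base_sst(spec, lat)
  amp <- .seasonal_amp(spec, lat)
  seasonal <- outer(amp, sin(2 * pi * doy / 365.25 - pi / 2))  # peak mid-year
  sst <- array(NA_real_, c(nlat, nlon, nd))
  for (j in seq_len(nlon)) {
    noise <- if (spec$noise_sd > 0)
      matrix(stats::rnorm(nlat * nd, 0, spec$noise_sd), nlat, nd)
    else 0
    sst[, j, ] <- base + seasonal + spec$warming_delta_C + noise
  }

  # shelf: shallow (2-8 m) band along the western edge, deepening offshore
  off <- outer(rep(1, nlat), lon - spec$lon_range[1L])
  bathy <- ifelse(off <= spec$shelf_width_deg,
                  2 + 6 * off / spec$shelf_width_deg,
                  8 + 192 * (off - spec$shelf_width_deg) /
                    max(diff(spec$lon_range) - spec$shelf_width_deg, 1e-6))

  # coarse habitat probability on the 0.5-degree grid, on the shallow mask
  lat_c <- .centers(spec$lat_range, spec$grid_res)
  lon_c <- .centers(spec$lon_range, spec$grid_res)
  fac <- as.integer(round(spec$grid_res / spec$fine_res))
  mask_f <- depth_mask(bathy)
  mask_c <- matrix(FALSE, length(lat_c), length(lon_c))
  for (i in seq_along(lat_c)) for (j in seq_along(lon_c)) {
    ri <- ((i - 1L) * fac + 1L):(i * fac); cj <- ((j - 1L) * fac + 1L):(j * fac)
    mask_c[i, j] <- any(mask_f[ri, cj])
  }
  ctr_lat <- mean(lat_c); ctr_lon <- min(lon_c)
  idx <- which(mask_c, arr.ind = TRUE)
  hl <- lat_c[idx[, 1L]]; ho <- lon_c[idx[, 2L]]
  p <- 0.9 * exp(-(((hl - ctr_lat)^2 + (ho - ctr_lon)^2) /
                     (2 * spec$prob_smoothness^2)))
  habitat <- data.frame(lat = hl, lon = ho, p = pmin(pmax(p, 0), 1))

  list(sst = sst, dates = dates, lat = lat, lon = lon,
       bathymetry = bathy, habitat = habitat)
}

#' Generate a matched coarse historical/future climate-model pair
#'
#' Analytic monthly climatologies on the coarse model grid: the historical
#' member follows the scenario's mean gradient and seasonal cycle sampled
#' at month midpoints; the future member adds a known warming delta
#' (constant, affine in lat/lon, or a smooth Gaussian bump). The true
#' delta function is returned for oracle checks.
#'
#' @param spec a [scenario_spec()].
#' @param delta_spec list describing the warming field: \code{type} one of
#'   \code{"constant"} (\code{value}), \code{"affine"}
#'   (\code{intercept, b_lat, b_lon}), \code{"bump"} (\code{value, lat0,
#'   lon0, width}); optionally \code{monthly_scale}, a length-12
#'   multiplier.
#' @return List with \code{hist} and \code{future} [clim_grid()]s and
#'   \code{delta_fun(lat, lon, month)}.
#' @export
gen_model_pair <- function(spec, delta_spec = list(type = "constant",
                                                   value = 2)) {
  stopifnot(inherits(spec, "scenario_spec"))
  lat <- .centers(spec$lat_range, spec$model_res)
  lon <- .centers(spec$lon_range, spec$model_res)
  mid_doy <- (c(0, cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30))) +
                c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31) / 2)
  sc <- delta_spec$monthly_scale %||% rep(1, 12)

  delta_fun <- function(lat, lon, month) {
    base <- switch(delta_spec$type,
      constant = rep(delta_spec$value, length(lat)),
      affine = delta_spec$intercept + delta_spec$b_lat * lat +
        delta_spec$b_lon * lon,
      bump = delta_spec$value *
        exp(-((lat - delta_spec$lat0)^2 + (lon - delta_spec$lon0)^2) /
              (2 * delta_spec$width^2)),
      stop("unknown delta type", call. = FALSE))
    base * sc[month]
  }

  hist_arr <- array(NA_real_, c(length(lat), length(lon), 12L))
  fut_arr <- hist_arr
  for (m in 1:12) {
    seas <- outer(.seasonal_amp(spec, lat) *
                    sin(2 * pi * mid_doy[m] / 365.25 - pi / 2),
                  rep(1, length(lon)))
    hist_arr[, , m] <- .base_sst(spec, lat) + seas
    g <- expand.grid(lat = lat, lon = lon, KEEP.OUT.ATTRS = FALSE)
    fut_arr[, , m] <- hist_arr[, , m] +
      matrix(delta_fun(g$lat, g$lon, m), length(lat), length(lon))
  }
  list(hist = clim_grid(lat, lon, hist_arr),
       future = clim_grid(lat, lon, fut_arr),
       delta_fun = delta_fun)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic acclimation dataset for both subpopulations
#'
#' Convenience wrapper generating killifish-style acclimation measurements
#' over the full assay array (5..30 by 5, plus 33 degC) for the northern
#' and southern subpopulations, with subpopulation-specific activation
#' energies (southern fish run warmer E, mirroring their greater thermal
#' sensitivity).
#'
#' @param E_north,E_south subpopulation activation energies (eV).
#' @param ln_A0 log normalization constant.
#' @param temps_C assay temperatures.
#' @param noise_sd,n_reps,seed passed to [gen_arrhenius_measurements()].
#' @return Data frame of rate measurements for both subpopulations.
#' @export
gen_acclimation_data <- function(E_north = 0.51, E_south = 0.73,
                                 ln_A0 = 3,
                                 temps_C = c(5, 10, 15, 20, 25, 30, 33),
                                 noise_sd = 0, n_reps = 2L, seed = 1L) {
  north <- gen_arrhenius_measurements(E_north, ln_A0, temps_C, noise_sd,
                                      n_reps, seed = seed,
                                      species = "Fundulus heteroclitus",
                                      subpopulation = "north")
  south <- gen_arrhenius_measurements(E_south, ln_A0, temps_C, noise_sd,
                                      n_reps, seed = seed + 1L,
                                      species = "Fundulus heteroclitus",
                                      subpopulation = "south")
  rbind(north, south)
}
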