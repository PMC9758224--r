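#' Read a metabolic-rate table from CSV
#'
#' Expects header columns \code{species, subpopulation, mass_g, temp_C,
#' rate}. Validates positivity of masses and rates and the plausible
#' assay-temperature range.
#'
#' @param path CSV file path.
#' @return Data frame of rate measurements.
#' @export
read_rate_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "subpopulation", "mass_g", "temp_C", "rate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (any(!is.finite(d$rate)) || any(d$rate <= 0))
    stop(sprintf("%s: rates must be finite and > 0", path), call. = FALSE)
  if (any(!is.finite(d$mass_g)) || any(d$mass_g <= 0))
    stop(sprintf("%s: masses must be finite and > 0", path), call. = FALSE)
  if (any(d$temp_C < -5 | d$temp_C > 45))
    stop(sprintf("%s: temp_C outside [-5, 45]", path), call. = FALSE)
  d
}

#' Write Arrhenius fit summaries to CSV
#'
#' One row per fit, mirroring the usual E-value summary table layout
#' (E value, R2, P, assay temperatures, mean weight, environment).
#'
#' @param fits a list of \code{arrhenius_fit} objects, named by dataset.
#' @param path output CSV path.
#' @return The summary data frame, invisibly.
#' @export
write_fit_csv <- function(fits, path) {
  rows <- lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(dataset = nm, E_eV = f$E_eV, r_squared = f$r_squared,
               p_value = f$p_value, n = f$n, E_stderr = f$E_stderr,
               temps = paste(sort(unique(f$data$temp_C)), collapse = ";"),
               mean_weight_g = mean(f$data$mass_g),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' Read / write half-degree habitat probability maps
#'
#' CSV with columns \code{lat, lon, p} (AquaMaps-style cell-center
#' exports; a \code{probability} column is accepted on read).
#'
#' @param path CSV path.
#' @return Data frame (lat, lon, p).
#' @export
read_habitat_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("probability" %in% names(d) && !"p" %in% names(d))
    names(d)[names(d) == "probability"] <- "p"
  if (!all(c("lat", "lon", "p") %in% names(d)))
    stop(sprintf("%s: need columns lat, lon, p (or probability)", path),
         call. = FALSE)
  if (any(!is.finite(d$p)) || any(d$p < 0 | d$p > 1))
    stop(sprintf("%s: probabilities outside [0, 1]", path), call. = FALSE)
  d[c("lat", "lon", "p")]
}

#' @rdname read_habitat_csv
#' @param map data frame (lat, lon, p).
#' @export
write_habitat_csv <- function(map, path) {
  utils::write.csv(map[c("lat", "lon", "p")], path, row.names = FALSE)
  invisible(map)
}

#' Read / write climatology grids as long-format CSV
#'
#' Plain-text representation of a [clim_grid()]: columns \code{lat, lon,
#' month, sst}, one row per cell-month, with masked cells written as
#' empty values so the mask survives the round trip.
#'
#' @param clim a [clim_grid()].
#' @param path CSV path.
#' @export
write_grid_csv <- function(clim, path) {
  stopifnot(inherits(clim, "clim_grid"))
  g <- expand.grid(lat = clim$lat, lon = clim$lon, month = 1:12,
                   KEEP.OUT.ATTRS = FALSE)
  g$sst <- as.vector(clim$monthly)
  utils::write.csv(g, path, row.names = FALSE)
  invisible(clim)
}

#' @rdname write_grid_csv
#' @return \code{read_grid_csv} returns the reconstructed [clim_grid()].
#' @export
read_grid_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("lat", "lon", "month", "sst") %in% names(d)))
    stop(sprintf("%s: need columns lat, lon, month, sst", path),
         call. = FALSE)
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon))
  arr <- array(NA_real_, c(length(lat), length(lon), 12L))
  i <- match(d$lat, lat); j <- match(d$lon, lon)
  arr[cbind(i, j, d$month)] <- d$sst
  clim_grid(lat, lon, arr)
}

#' Write per-cell SST extremes to CSV
#'
#' Columns \code{lat, lon, t_min, t_max, sst_range}; masked cells omitted.
#'
#' @param ext a [extremes_and_range()] result.
#' @param path CSV path.
#' @export
write_extremes_csv <- function(ext, path) {
  stopifnot(inherits(ext, "cell_extremes"))
  idx <- which(ext$mask, arr.ind = TRUE)
  out <- data.frame(lat = ext$lat[idx[, 1L]], lon = ext$lon[idx[, 2L]],
                    t_min = ext$t_min[idx], t_max = ext$t_max[idx],
                    sst_range = ext$sst_range[idx])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}

#' NetCDF round trip for climatology grids
#'
#' CF-style layout (dimensions lon/lat/time, variable \code{sst} in degC,
#' \code{_FillValue} honoured for masked cells). Requires the optional
#' \pkg{ncdf4} package; the CSV pair [write_grid_csv()] /
#' [read_grid_csv()] is the always-available plain-text alternative.
#'
#' @param clim a [clim_grid()].
#' @param path NetCDF file path.
#' @export
write_grid_nc <- function(clim, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("package 'ncdf4' is required for NetCDF output", call. = FALSE)
  stopifnot(inherits(clim, "clim_grid"))
  dlon <- ncdf4::ncdim_def("lon", "degrees_east", clim$lon)
  dlat <- ncdf4::ncdim_def("lat", "degrees_north", clim$lat)
  dt <- ncdf4::ncdim_def("time", "month", 1:12)
  v <- ncdf4::ncvar_def("sst", "degC", list(dlon, dlat, dt),
                        missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, v)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, v, aperm(clim$monthly, c(2L, 1L, 3L)))
  invisible(clim)
}

#' @rdname write_grid_nc
#' @export
read_grid_nc <- function(path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("package 'ncdf4' is required for NetCDF input", call. = FALSE)
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  sst <- ncdf4::ncvar_get(nc, "sst")  # [lon, lat, time]; NA from _FillValue
  clim_grid(lat, lon, aperm(sst, c(2L, 1L, 3L)))
}
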