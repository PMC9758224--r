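#' Construct a regular lat/lon monthly climatology grid
#'
#' Container for a 12-month climatological SST field on a regular grid of
#' cell centers. Masked cells are stored as \code{NA}, never silently zero.
#'
#' @param lat,lon ascending, regularly spaced cell-center coordinates.
#' @param monthly numeric array \code{[nlat, nlon, 12]} of monthly mean SST
#'   (degC); \code{NA} marks masked cells.
#' @param mask optional logical matrix \code{[nlat, nlon]}; default: a cell
#'   is valid iff at least one month is non-NA. Masked cells are forced to
#'   NA in all months.
#' @return An object of class \code{"clim_grid"}.
#' @export
clim_grid <- function(lat, lon, monthly, mask = NULL) {
  .check_regular(lat, "lat"); .check_regular(lon, "lon")
  if (length(dim(monthly)) != 3L || dim(monthly)[3L] != 12L)
    stop("'monthly' must be an [nlat, nlon, 12] array", call. = FALSE)
  if (dim(monthly)[1L] != length(lat) || dim(monthly)[2L] != length(lon))
    stop("'monthly' dimensions do not match lat/lon", call. = FALSE)
  if (is.null(mask)) {
    mask <- apply(!is.na(monthly), c(1L, 2L), any)
  } else {
    if (!is.logical(mask) || !identical(dim(mask), dim(monthly)[1:2]))
      stop("'mask' must be a logical [nlat, nlon] matrix", call. = FALSE)
  }
  monthly[rep(!mask, times = 12L)] <- NA_real_
  structure(list(lat = as.numeric(lat), lon = as.numeric(lon),
                 monthly = monthly, mask = mask),
            class = "clim_grid")
}

.check_regular <- function(x, what) {
  if (length(x) < 1L || any(!is.finite(x)))
    stop(sprintf("'%s' must be finite and non-empty", what), call. = FALSE)
  if (length(x) > 1L) {
    d <- diff(x)
    if (any(d <= 0) || any(abs(d - d[1L]) > 1e-8))
      stop(sprintf("'%s' must be ascending and regularly spaced", what),
           call. = FALSE)
  }
}

#' @export
print.clim_grid <- function(x, ...) {
  cat(sprintf("clim_grid: %d x %d cells, lat [%g, %g], lon [%g, %g]\n",
              length(x$lat), length(x$lon),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  cat(sprintf("  %d of %d cells unmasked; SST span %s degC\n",
              sum(x$mask), length(x$mask),
              paste(format(range(x$monthly, na.rm = TRUE), digits = 4),
                    collapse = " to ")))
  invisible(x)
}

.same_geometry <- function(a, b, tol = 1e-8) {
  length(a$lat) == length(b$lat) && length(a$lon) == length(b$lon) &&
    all(abs(a$lat - b$lat) < tol) && all(abs(a$lon - b$lon) < tol)
}

#' Monthly climatology from a daily (or sub-monthly) SST series
#'
#' Averages all values whose timestamp falls in calendar month m, across
#' all years, into layer m — the long-term monthly mean field. Cells with
#' no finite data in any month are masked. Partial months are averaged
#' over the available days.
#'
#' @param sst numeric array \code{[nlat, nlon, ntime]} of SST (degC).
#' @param dates \code{Date} vector of length \code{ntime}.
#' @param lat,lon cell-center coordinates.
#' @return A [clim_grid()].
#' @export
monthly_climatology <- function(sst, dates, lat, lon) {
  if (length(dim(sst)) != 3L)
    stop("'sst' must be an [nlat, nlon, ntime] array", call. = FALSE)
  if (dim(sst)[3L] != length(dates))
    stop("'dates' length must match the time dimension", call. = FALSE)
  if (length(dates) == 0L) stop("empty series", call. = FALSE)
  month <- as.integer(format(as.Date(dates), "%m"))
  nlat <- dim(sst)[1L]; nlon <- dim(sst)[2L]
  clim <- array(NA_real_, c(nlat, nlon, 12L))
  for (m in 1:12) {
    idx <- which(month == m)
    if (length(idx) == 0L) next
    sl <- sst[, , idx, drop = FALSE]
    clim[, , m] <- apply(sl, c(1L, 2L), function(v)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }
  clim_grid(lat, lon, clim)
}

#' Per-cell climatological SST extremes and range
#'
#' The minimum and maximum over the 12 monthly climatological layers, and
#' their difference (the location-specific SST range).
#'
#' @param clim a [clim_grid()].
#' @return A list of class \code{"cell_extremes"} with matrices
#'   \code{t_min}, \code{t_max}, \code{sst_range} (NA on masked cells) and
#'   the grid coordinates.
#' @export
extremes_and_range <- function(clim) {
  stopifnot(inherits(clim, "clim_grid"))
  t_max <- apply(clim$monthly, c(1L, 2L), function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  t_min <- apply(clim$monthly, c(1L, 2L), function(v)
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  structure(list(lat = clim$lat, lon = clim$lon,
                 t_min = t_min, t_max = t_max,
                 sst_range = t_max - t_min, mask = clim$mask),
            class = "cell_extremes")
}

#' @export
print.cell_extremes <- function(x, ...) {
  cat(sprintf("cell_extremes on %d x %d grid; SST range %s degC\n",
              length(x$lat), length(x$lon),
              paste(format(range(x$sst_range, na.rm = TRUE), digits = 4),
                    collapse = " to ")))
  invisible(x)
}

#' Coarsen a fine climatology grid by block averaging
#'
#' Aggregates factor x factor blocks of fine cells into one coarse cell
#' using cos(latitude) area weights, ignoring masked fine cells (e.g.
#' upscaling a 0.05-degree product to the 0.5-degree model grid). A coarse
#' cell is masked only when every fine cell in its block is masked.
#'
#' @param fine a [clim_grid()].
#' @param factor integer block size (10 takes 0.05 to 0.5 degrees).
#' @return A coarser [clim_grid()].
#' @export
coarsen <- function(fine, factor = 10L) {
  stopifnot(inherits(fine, "clim_grid"))
  factor <- as.integer(factor)
  nlat <- length(fine$lat); nlon <- length(fine$lon)
  if (nlat %% factor != 0L || nlon %% factor != 0L)
    stop("grid dimensions must be divisible by 'factor'", call. = FALSE)
  nlat_c <- nlat %/% factor; nlon_c <- nlon %/% factor
  lat_c <- vapply(seq_len(nlat_c), function(i)
    mean(fine$lat[((i - 1L) * factor + 1L):(i * factor)]), numeric(1))
  lon_c <- vapply(seq_len(nlon_c), function(j)
    mean(fine$lon[((j - 1L) * factor + 1L):(j * factor)]), numeric(1))
  w_lat <- cos(fine$lat * pi / 180)
  out <- array(NA_real_, c(nlat_c, nlon_c, 12L))
  for (m in 1:12) {
    layer <- fine$monthly[, , m]
    for (i in seq_len(nlat_c)) {
      ri <- ((i - 1L) * factor + 1L):(i * factor)
      for (j in seq_len(nlon_c)) {
        cj <- ((j - 1L) * factor + 1L):(j * factor)
        block <- layer[ri, cj]
        w <- matrix(w_lat[ri], nrow = factor, ncol = factor)
        ok <- !is.na(block)
        if (any(ok))
          out[i, j, m] <- sum(block[ok] * w[ok]) / sum(w[ok])
      }
    }
  }
  clim_grid(lat_c, lon_c, out)
}

#' Shallow-water habitat mask from bathymetry
#'
#' TRUE where water depth lies in \code{[d_min, d_max]} metres (closed
#' interval; default the 0-10 m estuarine band). Land — depth <= 0 under
#' the positive-down convention — is always FALSE.
#'
#' @param bathymetry numeric matrix of depths (m, positive down).
#' @param d_min,d_max depth bounds (m).
#' @return Logical matrix of the same shape.
#' @export
depth_mask <- function(bathymetry, d_min = 0, d_max = 10) {
  if (!is.matrix(bathymetry))
    stop("'bathymetry' must be a matrix co-registered with the SST grid",
         call. = FALSE)
  ok <- is.finite(bathymetry) & bathymetry > 0 &
    bathymetry >= d_min & bathymetry <= d_max
  ok
}

#' Unweighted ensemble mean of climatology grids
#'
#' Per-cell, per-month mean across ensemble members (e.g. the downscaled
#' products of several climate models). All members must share geometry
#' and masks.
#'
#' @param members list of [clim_grid()] objects.
#' @return A [clim_grid()].
#' @export
ensemble_mean <- function(members) {
  if (!is.list(members) || length(members) == 0L)
    stop("'members' must be a non-empty list of clim_grid objects",
         call. = FALSE)
  ref <- members[[1L]]
  for (m in members) {
    stopifnot(inherits(m, "clim_grid"))
    if (!.same_geometry(ref, m) || !identical(ref$mask, m$mask))
      stop("ensemble members must share geometry and masks", call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(members, `[[`, "monthly"))
  clim_grid(ref$lat, ref$lon, acc / length(members), mask = ref$mask)
}
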