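#' Trapezoidal relative environmental suitability (RES) envelope
#'
#' Four SST thresholds defining the trapezoid: absolute minimum, preferred
#' minimum, preferred maximum, absolute maximum. Defaults are the Atlantic
#' killifish SST envelope (5.63, 7.74, 21.97, 27.05 degC).
#'
#' @param t_min,t_pref_min,t_pref_max,t_max envelope temperatures (degC),
#'   non-decreasing.
#' @return An object of class \code{"res_envelope"}.
#' @export
res_envelope <- function(t_min = 5.63, t_pref_min = 7.74,
                         t_pref_max = 21.97, t_max = 27.05) {
  v <- c(t_min, t_pref_min, t_pref_max, t_max)
  if (any(!is.finite(v)) || is.unsorted(v))
    stop("envelope must satisfy t_min <= t_pref_min <= t_pref_max <= t_max",
         call. = FALSE)
  structure(list(t_min = t_min, t_pref_min = t_pref_min,
                 t_pref_max = t_pref_max, t_max = t_max),
            class = "res_envelope")
}

#' @export
print.res_envelope <- function(x, ...) {
  cat(sprintf("RES envelope (degC): %g / %g / %g / %g\n",
              x$t_min, x$t_pref_min, x$t_pref_max, x$t_max))
  invisible(x)
}

#' Relative environmental suitability of an SST value
#'
#' Trapezoidal response: 0 at or beyond the absolute bounds, 1 on the
#' preferred range, linear ramps between. A zero-width ramp (absolute and
#' preferred bound equal) takes the preferred value 1 at the shared point.
#'
#' @param sst_C sea-surface temperature(s), degC.
#' @param env a [res_envelope()].
#' @return Suitability in \[0, 1\], vectorized over \code{sst_C}; NA
#'   propagates.
#' @examples
#' res_suitability(c(4, 6.685, 15, 30), res_envelope())
#' @export
res_suitability <- function(sst_C, env = res_envelope()) {
  stopifnot(inherits(env, "res_envelope"))
  s <- rep(0, length(sst_C))
  inside_pref <- sst_C >= env$t_pref_min & sst_C <= env$t_pref_max
  rise <- sst_C > env$t_min & sst_C < env$t_pref_min
  fall <- sst_C > env$t_pref_max & sst_C < env$t_max
  s[inside_pref] <- 1
  s[rise] <- (sst_C[rise] - env$t_min) / (env$t_pref_min - env$t_min)
  s[fall] <- (env$t_max - sst_C[fall]) / (env$t_max - env$t_pref_max)
  s[is.na(sst_C)] <- NA_real_
  s
}

#' RES habitat map from an annual-mean SST climatology
#'
#' Evaluates the trapezoidal suitability of the annual mean (mean of the 12
#' monthly layers) in every unmasked cell.
#'
#' @param clim a [clim_grid()].
#' @param env a [res_envelope()].
#' @return Data frame (lat, lon, p) over unmasked cells.
#' @export
project_res_map <- function(clim, env = res_envelope()) {
  stopifnot(inherits(clim, "clim_grid"))
  annual <- apply(clim$monthly, c(1L, 2L), mean)  # NA on masked cells
  idx <- which(clim$mask, arr.ind = TRUE)
  data.frame(lat = clim$lat[idx[, 1L]], lon = clim$lon[idx[, 2L]],
             p = res_suitability(annual[idx], env))
}
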