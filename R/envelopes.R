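#' Acclimation temperature grid used for envelope fits
#'
#' Killifish acclimation experiments span 5, 10, 15, 20, 25, 30 and 33 degC;
#' envelope bounds live on the multiples of 5 between 5 and 30.
#' @keywords internal
.envelope_bounds <- seq(5, 30, by = 5)

.snap5 <- function(x) floor(x / 5 + 0.5) * 5  # nearest multiple of 5, ties up

#' Snap habitat temperature extremes to a discrete thermal envelope
#'
#' Rounds each climatological extreme to the nearest multiple of 5 degC
#' (ties upward), clamps to the acclimation range \[5, 30\], and widens a
#' degenerate envelope (both endpoints equal after snapping) by one 5-degree
#' step so a coastal cell with a tiny seasonal range remains modellable:
#' the lower bound is dropped one step, except at the 5 degC floor where the
#' upper bound is raised instead.
#'
#' @param t_min_C,t_max_C habitat temperature extremes (degC),
#'   \code{t_min_C <= t_max_C}.
#' @return An object of class \code{"thermal_envelope"}: a list with
#'   \code{t_min_C} and \code{t_max_C}, both multiples of 5 in \[5, 30\] with
#'   \code{t_min_C < t_max_C}.
#' @examples
#' snap_to_envelope(6.3, 27.8)   # (5, 30)
#' snap_to_envelope(-1.4, 21.0)  # (5, 20)
#' @export
snap_to_envelope <- function(t_min_C, t_max_C) {
  if (!is.finite(t_min_C) || !is.finite(t_max_C))
    stop("temperature extremes must be finite", call. = FALSE)
  if (t_min_C > t_max_C)
    stop("'t_min_C' must not exceed 't_max_C'", call. = FALSE)
  lo <- min(max(.snap5(t_min_C), 5), 30)
  hi <- min(max(.snap5(t_max_C), 5), 30)
  if (lo == hi) {
    if (lo > 5) lo <- lo - 5 else hi <- hi + 5
  }
  structure(list(t_min_C = lo, t_max_C = hi), class = "thermal_envelope")
}

#' @export
print.thermal_envelope <- function(x, ...) {
  cat(sprintf("thermal envelope %g-%g degC\n", x$t_min_C, x$t_max_C))
  invisible(x)
}

#' All candidate thermal envelopes on the 5-degree acclimation grid
#'
#' @return A data frame with columns \code{t_min_C}, \code{t_max_C}, one row
#'   per pair with \code{t_min_C < t_max_C} (15 envelopes for bounds 5..30).
#' @export
all_envelopes <- function() {
  g <- expand.grid(t_min_C = .envelope_bounds, t_max_C = .envelope_bounds)
  g <- g[g$t_min_C < g$t_max_C, , drop = FALSE]
  g <- g[order(g$t_min_C, g$t_max_C), ]
  rownames(g) <- NULL
  g
}

#' Assign a grid cell to a killifish subpopulation by latitude
#'
#' The North American East-Coast killifish cline sits where the Hudson River
#' meets the Atlantic: cells at or above the cline latitude use the northern
#' subpopulation's physiology, cells below use the southern's.
#'
#' @param lat_deg latitude(s) in decimal degrees.
#' @param cline_lat dividing latitude, default 40 (configurable so 39-41 N
#'   robustness runs are possible).
#' @return Character vector, \code{"north"} or \code{"south"}.
#' @examples
#' assign_subpopulation(c(40, 39.75, 44.25))
#' @export
assign_subpopulation <- function(lat_deg, cline_lat = 40.0) {
  if (any(!is.finite(lat_deg)))
    stop("'lat_deg' must be finite", call. = FALSE)
  ifelse(lat_deg >= cline_lat, "north", "south")
}

.envelope_subset <- function(measurements, t_min_C, t_max_C,
                             include_33 = TRUE) {
  sel <- measurements$temp_C >= t_min_C & measurements$temp_C <= t_max_C
  if (include_33 && t_max_C == 30)
    sel <- sel | measurements$temp_C == 33
  measurements[sel, , drop = FALSE]
}

#' Build a table of envelope-specific activation energies
#'
#' For each requested thermal envelope and subpopulation, subsets the
#' acclimation measurements to assay temperatures inside the envelope
#' (inclusive bounds) and fits the Arrhenius activation energy on the
#' subset. Measurements at 33 degC, the warm end of the acclimation array,
#' are included in envelopes whose upper bound is 30 degC (configurable
#' off with \code{include_33 = FALSE}).
#'
#' @param acclimation_data data frame of rate measurements with columns
#'   \code{species, subpopulation, mass_g, temp_C, rate}.
#' @param envelopes data frame with columns \code{t_min_C}, \code{t_max_C}
#'   (default [all_envelopes()]).
#' @param subpopulations subpopulations to fit; default the ones present in
#'   the data.
#' @param include_33 include 33 degC assays in 30-degC-bounded envelopes.
#' @return A data frame of class \code{"envelope_E_table"} with columns
#'   \code{t_min_C, t_max_C, subpopulation, E_eV, r_squared, p_value, n,
#'   E_stderr}.
#' @export
build_envelope_E_table <- function(acclimation_data,
                                   envelopes = all_envelopes(),
                                   subpopulations = NULL,
                                   include_33 = TRUE) {
  if (!all(c("subpopulation", "temp_C", "rate") %in% names(acclimation_data)))
    stop("acclimation data needs columns subpopulation, temp_C, rate",
         call. = FALSE)
  if (is.null(subpopulations))
    subpopulations <- sort(unique(acclimation_data$subpopulation))
  rows <- vector("list", nrow(envelopes) * length(subpopulations))
  i <- 0L
  for (r in seq_len(nrow(envelopes))) {
    lo <- envelopes$t_min_C[r]; hi <- envelopes$t_max_C[r]
    for (sp in subpopulations) {
      sub <- acclimation_data[acclimation_data$subpopulation == sp, ,
                              drop = FALSE]
      sub <- .envelope_subset(sub, lo, hi, include_33)
      if (length(unique(sub$temp_C)) < 2L)
        stop(sprintf(
          "envelope %g-%g degC (%s): fewer than 2 assay temperatures inside",
          lo, hi, sp), call. = FALSE)
      fit <- fit_arrhenius(sub, min_n = 2L)
      i <- i + 1L
      rows[[i]] <- data.frame(
        t_min_C = lo, t_max_C = hi, subpopulation = sp,
        E_eV = fit$E_eV, r_squared = fit$r_squared,
        p_value = fit$p_value, n = fit$n, E_stderr = fit$E_stderr,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(i)])
  class(out) <- c("envelope_E_table", "data.frame")
  out
}

#' Look up the activation energy for an envelope and subpopulation
#'
#' @param table an \code{envelope_E_table}.
#' @param t_min_C,t_max_C snapped envelope bounds.
#' @param subpopulation \code{"north"} or \code{"south"}.
#' @return The fitted E (eV); errors if the pair is absent.
#' @export
envelope_E <- function(table, t_min_C, t_max_C, subpopulation) {
  hit <- table$t_min_C == t_min_C & table$t_max_C == t_max_C &
    table$subpopulation == subpopulation
  if (!any(hit))
    stop(sprintf("no E entry for envelope %g-%g degC (%s)",
                 t_min_C, t_max_C, subpopulation), call. = FALSE)
  table$E_eV[which(hit)[1L]]
}

#' Interannual variance of envelope-specific activation energies
#'
#' For each year's habitat temperature extremes, snaps the pair to a thermal
#' envelope, looks up that envelope's fitted E for the given subpopulation,
#' and returns the sample variance of the yearly E series. Because
#' snapping absorbs sub-bin variation, a site whose yearly extremes wander
#' within one 5-degree bin has zero variance. Map displays conventionally
#' scale the variance by 10^3.
#'
#' @param yearly_extremes data frame with columns \code{t_min_C},
#'   \code{t_max_C}, one row per year (>= 2 rows).
#' @param subpop \code{"north"} or \code{"south"}.
#' @param acclimation_data measurements from which envelope fits are built.
#' @param include_33 passed to [build_envelope_E_table()].
#' @return The sample variance of the yearly E series (eV^2), with the
#'   series attached as attribute \code{"E_series"}.
#' @export
annual_E_variance <- function(yearly_extremes, subpop, acclimation_data,
                              include_33 = TRUE) {
  if (nrow(yearly_extremes) < 2L)
    stop("need at least 2 years of extremes", call. = FALSE)
  envs <- lapply(seq_len(nrow(yearly_extremes)), function(i)
    snap_to_envelope(yearly_extremes$t_min_C[i], yearly_extremes$t_max_C[i]))
  uniq <- unique(data.frame(
    t_min_C = vapply(envs, `[[`, numeric(1), "t_min_C"),
    t_max_C = vapply(envs, `[[`, numeric(1), "t_max_C")))
  table <- build_envelope_E_table(acclimation_data, envelopes = uniq,
                                  subpopulations = subpop,
                                  include_33 = include_33)
  E_series <- vapply(envs, function(e)
    envelope_E(table, e$t_min_C, e$t_max_C, subpop), numeric(1))
  structure(stats::var(E_series), E_series = E_series)
}
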