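#' Configuration of the physiology-integrated bioclimate model
#'
#' @param t_break_C physiological break temperature (degC) above which a
#'   cell is uninhabitable; default 32 (killifish metabolic performance
#'   peaks at 30 degC and collapses by 33).
#' @param cline_lat latitude separating northern and southern
#'   subpopulations; default 40 N.
#' @param mass_g reference body mass for MRR calculations; default 10 g.
#' @param b0 MTE normalization constant; default 14.47.
#' @param mass_exponent allometric exponent; default 3/4.
#' @param refuge_compare whether a relocation target must have future MRR
#'   no greater than the source's \emph{contemporary} MRR (default) or its
#'   \emph{future} MRR.
#' @param include_33 include 33 degC assays in 30-degC-bounded envelope
#'   fits.
#' @return An object of class \code{"pibcm_config"}.
#' @export
pibcm_config <- function(t_break_C = 32, cline_lat = 40.0, mass_g = 10,
                         b0 = 14.47, mass_exponent = 0.75,
                         refuge_compare = c("contemporary", "future"),
                         include_33 = TRUE) {
  refuge_compare <- match.arg(refuge_compare)
  if (!is.finite(t_break_C)) stop("'t_break_C' must be finite", call. = FALSE)
  if (!is.finite(mass_g) || mass_g <= 0)
    stop("'mass_g' must be positive", call. = FALSE)
  structure(list(t_break_C = t_break_C, cline_lat = cline_lat,
                 mass_g = mass_g,
                 params = mte_params(b0 = b0, mass_exponent = mass_exponent),
                 refuge_compare = refuge_compare,
                 include_33 = include_33),
            class = "pibcm_config")
}

#' @export
print.pibcm_config <- function(x, ...) {
  cat(sprintf(
    "PIBCM config: break %g degC, cline %g N, mass %g g, b0 %g, refuge vs %s MRR\n",
    x$t_break_C, x$cline_lat, x$mass_g, x$params$b0, x$refuge_compare))
  invisible(x)
}

#' Per-cell physiological state for the habitat projection
#'
#' Combines contemporary and future climatological extremes with the
#' envelope-specific activation-energy table into the per-cell quantities
#' the stay/relocate rules consume: contemporary and future maximum SST
#' and metabolic rate range (MRR). Each cell's envelope is its snapped
#' (t_min, t_max) pair; its E value is the envelope- and
#' subpopulation-specific fit; its MRR is evaluated at the cell's actual
#' (unsnapped) extremes for the configured reference mass.
#'
#' @param contemp,future [extremes_and_range()] results on the same grid.
#' @param E_table an \code{envelope_E_table} covering every envelope
#'   occurring in the grids (build with [build_envelope_E_table()] over
#'   [all_envelopes()]).
#' @param cfg a [pibcm_config()].
#' @param cells optional data frame (lat, lon) restricting to habitat
#'   cells; default all unmasked cells of \code{contemp}.
#' @return Data frame of class \code{"cell_states"}: lat, lon,
#'   subpopulation, t_max_now, t_max_fut, mrr_now, mrr_fut, E_now, E_fut.
#' @export
cell_states <- function(contemp, future, E_table, cfg = pibcm_config(),
                        cells = NULL) {
  stopifnot(inherits(contemp, "cell_extremes"),
            inherits(future, "cell_extremes"))
  if (length(contemp$lat) != length(future$lat) ||
      any(abs(contemp$lat - future$lat) > 1e-8) ||
      any(abs(contemp$lon - future$lon) > 1e-8))
    stop("contemporary and future extremes must share the grid",
         call. = FALSE)
  if (is.null(cells)) {
    idx <- which(contemp$mask, arr.ind = TRUE)
    cells <- data.frame(lat = contemp$lat[idx[, 1L]],
                        lon = contemp$lon[idx[, 2L]])
  }
  n <- nrow(cells)
  i_lat <- match(round(cells$lat, 6), round(contemp$lat, 6))
  i_lon <- match(round(cells$lon, 6), round(contemp$lon, 6))
  if (any(is.na(i_lat)) || any(is.na(i_lon)))
    stop("requested cells fall outside the grid", call. = FALSE)
  sp <- assign_subpopulation(cells$lat, cfg$cline_lat)
  out <- data.frame(lat = cells$lat, lon = cells$lon, subpopulation = sp,
                    t_max_now = NA_real_, t_max_fut = NA_real_,
                    mrr_now = NA_real_, mrr_fut = NA_real_,
                    E_now = NA_real_, E_fut = NA_real_,
                    stringsAsFactors = FALSE)
  for (r in seq_len(n)) {
    i <- i_lat[r]; j <- i_lon[r]
    tn_min <- contemp$t_min[i, j]; tn_max <- contemp$t_max[i, j]
    tf_min <- future$t_min[i, j];  tf_max <- future$t_max[i, j]
    if (any(is.na(c(tn_min, tn_max, tf_min, tf_max))))
      stop(sprintf("cell (%g, %g) has masked extremes",
                   cells$lat[r], cells$lon[r]), call. = FALSE)
    env_n <- snap_to_envelope(tn_min, tn_max)
    env_f <- snap_to_envelope(tf_min, tf_max)
    E_n <- envelope_E(E_table, env_n$t_min_C, env_n$t_max_C, sp[r])
    E_f <- envelope_E(E_table, env_f$t_min_C, env_f$t_max_C, sp[r])
    out$t_max_now[r] <- tn_max
    out$t_max_fut[r] <- tf_max
    out$E_now[r] <- E_n
    out$E_fut[r] <- E_f
    out$mrr_now[r] <- metabolic_rate_range(cfg$mass_g, tn_min, tn_max, E_n,
                                           cfg$params)
    out$mrr_fut[r] <- metabolic_rate_range(cfg$mass_g, tf_min, tf_max, E_f,
                                           cfg$params)
  }
  class(out) <- c("cell_states", "data.frame")
  out
}

#' Classify habitat cells into the three stay/relocate conditions
#'
#' The rules, evaluated in order per cell (T = future maximum SST, break =
#' \code{t_break_C}):
#' \enumerate{
#'   \item \strong{stay_c1}: T <= break, T >= contemporary maximum, and
#'     future MRR <= contemporary MRR — the population compensates by
#'     modulating E and stays.
#'   \item \strong{stay_c2}: T <= break and (T <= contemporary maximum or
#'     future MRR <= contemporary MRR) — conditions no worse, stays.
#'   \item \strong{move_c3}: T > break, or T >= contemporary maximum with
#'     future MRR >= contemporary MRR — relocates to the nearest refuge.
#' }
#' Boundary equalities resolve in favour of staying.
#'
#' @param t_max_now,t_max_fut contemporary / future maximum SST (degC).
#' @param mrr_now,mrr_fut contemporary / future metabolic rate range.
#' @param cfg a [pibcm_config()].
#' @return Character vector: \code{"stay_c1"}, \code{"stay_c2"} or
#'   \code{"move_c3"}.
#' @export
classify_cell <- function(t_max_now, t_max_fut, mrr_now, mrr_fut,
                          cfg = pibcm_config()) {
  vals <- cbind(t_max_now, t_max_fut, mrr_now, mrr_fut)
  if (any(!is.finite(vals)))
    stop("classification inputs must be finite", call. = FALSE)
  brk <- cfg$t_break_C
  c1 <- t_max_fut <= brk & t_max_fut >= t_max_now & mrr_fut <= mrr_now
  c2 <- !c1 & t_max_fut <= brk & (t_max_fut <= t_max_now | mrr_fut <= mrr_now)
  c3 <- !c1 & !c2 &
    (t_max_fut > brk | (t_max_fut >= t_max_now & mrr_fut >= mrr_now))
  out <- rep(NA_character_, length(c1))
  out[c1] <- "stay_c1"; out[c2] <- "stay_c2"; out[c3] <- "move_c3"
  if (any(is.na(out)))
    stop("internal consistency error: cell matched no model condition",
         call. = FALSE)
  out
}

# Great-circle distance (m) on a 6371 km sphere. Written so that exactly
# symmetric hops (equal |dlat| or |dlon|) give bit-identical distances,
# which the deterministic lat/lon tie-break of nearest_refuge relies on.
.haversine_m <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371000 * asin(pmin(1, sqrt(a)))
}

#' Nearest metabolic refuge for a relocating population
#'
#' Among candidate habitat cells, returns the one nearest to the source by
#' great-circle (haversine) distance between cell centers, restricted to
#' candidates whose future maximum SST stays at or below the break
#' temperature and whose future MRR does not exceed the source's reference
#' MRR (contemporary by default, see [pibcm_config()]). Ties break to the
#' lower latitude, then lower longitude.
#'
#' @param source single-row slice of a \code{cell_states} data frame.
#' @param candidates \code{cell_states} rows to search (the source itself
#'   is ignored if present).
#' @param cfg a [pibcm_config()].
#' @return The row index (into \code{candidates}) of the chosen refuge, or
#'   \code{NA} if none qualifies.
#' @export
nearest_refuge <- function(source, candidates, cfg = pibcm_config()) {
  if (nrow(candidates) == 0L) return(NA_integer_)
  mrr_ref <- if (cfg$refuge_compare == "contemporary") source$mrr_now
  else source$mrr_fut
  ok <- candidates$mrr_fut <= mrr_ref &
    candidates$t_max_fut <= cfg$t_break_C &
    !(candidates$lat == source$lat & candidates$lon == source$lon)
  if (!any(ok)) return(NA_integer_)
  idx <- which(ok)
  d <- .haversine_m(source$lat, source$lon,
                    candidates$lat[idx], candidates$lon[idx])
  ord <- order(d, candidates$lat[idx], candidates$lon[idx])
  idx[ord[1L]]
}

#' Project a habitat probability map under the stay/relocate algorithm
#'
#' Classifies every habitat cell, leaves stay-cell probabilities in place,
#' transfers each relocating cell's contemporary probability to its nearest
#' refuge (the source is zeroed; populations with no qualifying refuge are
#' stranded and their probability is dropped, reported in the diagnostics),
#' then caps each cell's accumulated probability at 1, recording the
#' discarded overflow. Transfers are computed from the input map and
#' processed in ascending (lat, lon) order; capping is applied once, after
#' all transfers.
#'
#' @param contemp_map data frame (lat, lon, p) of contemporary occupancy
#'   probabilities in \[0, 1\].
#' @param states a [cell_states()] data frame covering every cell of
#'   \code{contemp_map}.
#' @param cfg a [pibcm_config()].
#' @return An object of class \code{"pibcm_projection"}: the future map
#'   (lat, lon, p), per-cell condition, destination index, overflow,
#'   stranded flag, and a \code{diagnostics} list (counts and fractions
#'   per condition, stranded cells, pre- and post-cap totals).
#' @export
project_habitat <- function(contemp_map, states, cfg = pibcm_config()) {
  if (!all(c("lat", "lon", "p") %in% names(contemp_map)))
    stop("'contemp_map' needs columns lat, lon, p", call. = FALSE)
  if (any(!is.finite(contemp_map$p)) || any(contemp_map$p < 0) ||
      any(contemp_map$p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  key <- function(d) paste(round(d$lat, 6), round(d$lon, 6))
  m <- match(key(contemp_map), key(states))
  if (any(is.na(m)))
    stop("every habitat cell needs a physiological state", call. = FALSE)
  st <- states[m, , drop = FALSE]

  ord <- order(contemp_map$lat, contemp_map$lon)
  contemp_map <- contemp_map[ord, , drop = FALSE]
  st <- st[ord, , drop = FALSE]
  rownames(contemp_map) <- rownames(st) <- NULL
  n <- nrow(contemp_map)

  cond <- classify_cell(st$t_max_now, st$t_max_fut, st$mrr_now, st$mrr_fut,
                        cfg)
  p_new <- contemp_map$p
  dest <- rep(NA_integer_, n)
  stranded <- rep(FALSE, n)
  movers <- which(cond == "move_c3")
  for (i in movers) {
    d <- nearest_refuge(st[i, , drop = FALSE], st, cfg)
    p_new[i] <- p_new[i] - contemp_map$p[i]  # original mass leaves
    if (is.na(d)) {
      stranded[i] <- TRUE
    } else {
      dest[i] <- d
      p_new[d] <- p_new[d] + contemp_map$p[i]
    }
  }
  pre_cap_total <- sum(p_new)
  overflow <- pmax(p_new - 1, 0)
  p_cap <- pmin(p_new, 1)

  diagnostics <- list(
    n_cells = n,
    counts = c(stay_c1 = sum(cond == "stay_c1"),
               stay_c2 = sum(cond == "stay_c2"),
               move_c3 = sum(cond == "move_c3")),
    fractions = c(stay_c1 = mean(cond == "stay_c1"),
                  stay_c2 = mean(cond == "stay_c2"),
                  move_c3 = mean(cond == "move_c3")),
    n_stranded = sum(stranded),
    stranded_mass = sum(contemp_map$p[stranded]),
    input_total = sum(contemp_map$p),
    pre_cap_total = pre_cap_total,
    post_cap_total = sum(p_cap),
    overflow_total = sum(overflow))

  structure(list(
    future = data.frame(lat = contemp_map$lat, lon = contemp_map$lon,
                        p = p_cap),
    contemporary = contemp_map,
    condition = cond, destination = dest, overflow = overflow,
    stranded = stranded, diagnostics = diagnostics, config = cfg),
    class = "pibcm_projection")
}

#' @export
print.pibcm_projection <- function(x, ...) {
  d <- x$diagnostics
  cat("PIBCM habitat projection\n")
  cat(sprintf("  %d habitat cells: %d stay (condition 1), %d stay (condition 2), %d move (condition 3)\n",
              d$n_cells, d$counts[["stay_c1"]], d$counts[["stay_c2"]],
              d$counts[["move_c3"]]))
  cat(sprintf("  stranded: %d cells (probability mass %.4g)\n",
              d$n_stranded, d$stranded_mass))
  cat(sprintf("  probability: input %.4g -> pre-cap %.4g -> post-cap %.4g (overflow %.4g)\n",
              d$input_total, d$pre_cap_total, d$post_cap_total,
              d$overflow_total))
  invisible(x)
}

#' @export
summary.pibcm_projection <- function(object, ...) {
  d <- object$diagnostics
  out <- data.frame(
    condition = names(d$counts),
    n = as.integer(d$counts),
    fraction = as.numeric(d$fractions))
  attr(out, "diagnostics") <- d
  out
}

#' Per-cell probability change between two habitat maps
#'
#' @param future_map,contemp_map data frames (lat, lon, p) on the same
#'   cells.
#' @return Data frame (lat, lon, delta) with \code{delta} = future minus
#'   contemporary, in \[-1, 1\].
#' @export
probability_delta <- function(future_map, contemp_map) {
  key <- function(d) paste(round(d$lat, 6), round(d$lon, 6))
  m <- match(key(future_map), key(contemp_map))
  if (nrow(future_map) != nrow(contemp_map) || any(is.na(m)))
    stop("maps must cover identical cells", call. = FALSE)
  data.frame(lat = future_map$lat, lon = future_map$lon,
             delta = future_map$p - contemp_map$p[m])
}
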