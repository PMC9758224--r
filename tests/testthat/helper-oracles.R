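# Independent oracles, coded from first principles and kept free of the
# package's own implementation paths.

k_B <- 8.617e-5  # eV/K

# Closed-form OLS of ln(rate) on 1/T via the normal equations.
ols_oracle <- function(temp_C, rate) {
  x <- 1 / (temp_C + 273.15)
  y <- log(rate)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  list(slope = slope, intercept = intercept, E = -slope * k_B)
}

# Haversine distance (m) on a 6371 km sphere, written out longhand.
haversine_oracle <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371000 * asin(pmin(1, sqrt(a)))
}

# Brute-force re-implementation of the stay/relocate projection:
# per-cell condition logic re-coded, exhaustive refuge search over all
# cells, sequential accumulation, one capping pass.
pibcm_oracle <- function(map, states, t_break = 32,
                         refuge_compare = "contemporary") {
  key <- paste(round(map$lat, 6), round(map$lon, 6))
  st <- states[match(key, paste(round(states$lat, 6),
                                round(states$lon, 6))), , drop = FALSE]
  ord <- order(map$lat, map$lon)
  map <- map[ord, , drop = FALSE]
  st <- st[ord, , drop = FALSE]
  n <- nrow(map)
  cond <- character(n)
  for (i in seq_len(n)) {
    tn <- st$t_max_now[i]; tf <- st$t_max_fut[i]
    mn <- st$mrr_now[i]; mf <- st$mrr_fut[i]
    if (tf <= t_break && tf >= tn && mf <= mn) {
      cond[i] <- "stay_c1"
    } else if (tf <= t_break && (tf <= tn || mf <= mn)) {
      cond[i] <- "stay_c2"
    } else if (tf > t_break || (tf >= tn && mf >= mn)) {
      cond[i] <- "move_c3"
    } else {
      stop("oracle: unclassifiable cell")
    }
  }
  p_new <- map$p
  stranded <- logical(n)
  dest_of <- rep(NA_integer_, n)
  for (i in which(cond == "move_c3")) {
    ref <- if (refuge_compare == "contemporary") st$mrr_now[i]
    else st$mrr_fut[i]
    best <- NA_integer_; best_d <- Inf
    for (j in seq_len(n)) {
      if (j == i) next
      if (st$lat[j] == st$lat[i] && st$lon[j] == st$lon[i]) next
      if (!(st$mrr_fut[j] <= ref && st$t_max_fut[j] <= t_break)) next
      d <- haversine_oracle(st$lat[i], st$lon[i], st$lat[j], st$lon[j])
      better <- is.na(best) || d < best_d ||
        (d == best_d && (st$lat[j] < st$lat[best] ||
                           (st$lat[j] == st$lat[best] &&
                              st$lon[j] < st$lon[best])))
      if (better) { best <- j; best_d <- d }
    }
    p_new[i] <- p_new[i] - map$p[i]
    if (is.na(best)) stranded[i] <- TRUE
    else { dest_of[i] <- best; p_new[best] <- p_new[best] + map$p[i] }
  }
  list(lat = map$lat, lon = map$lon, condition = cond,
       pre_cap = p_new, p = pmin(p_new, 1), overflow = pmax(p_new - 1, 0),
       stranded = stranded, dest = dest_of)
}

# Randomized cell-state grid + habitat map on an nr x nc half-degree patch.
random_scenario <- function(nr, nc, seed) {
  set.seed(seed)
  g <- expand.grid(lat = 35 + 0.5 * seq_len(nr), lon = -75 + 0.5 * seq_len(nc))
  states <- data.frame(
    lat = g$lat, lon = g$lon,
    t_max_now = runif(nrow(g), 20, 31),
    mrr_now = runif(nrow(g), 1e-9, 1e-7))
  states$t_max_fut <- states$t_max_now + runif(nrow(g), -1, 4)
  states$mrr_fut <- states$mrr_now * runif(nrow(g), 0.5, 2)
  map <- data.frame(lat = g$lat, lon = g$lon,
                    p = round(runif(nrow(g)), 3))
  list(states = states, map = map)
}
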