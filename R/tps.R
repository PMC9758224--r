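#' Exact thin-plate-spline interpolation of scattered values
#'
#' Classical 2-D thin-plate spline with radial kernel \eqn{r^2 \log r} and
#' an affine polynomial part, solved as an exact interpolant (zero
#' smoothing by default): it reproduces the node values exactly and any
#' affine function of (lat, lon) exactly everywhere. Coordinates are
#' treated as planar degrees, the convention of delta-method regridding on
#' small coastal domains.
#'
#' @param nodes data frame with columns \code{lat}, \code{lon},
#'   \code{value}; at least 3 non-collinear nodes.
#' @param targets data frame with columns \code{lat}, \code{lon}.
#' @param lambda ridge on the kernel block (smoothing); 0 = exact
#'   interpolation, the default, since delta regridding interpolates
#'   rather than smooths.
#' @return Numeric vector of interpolated values at the targets.
#' @export
tps_interpolate <- function(nodes, targets, lambda = 0) {
  if (!all(c("lat", "lon", "value") %in% names(nodes)))
    stop("'nodes' needs columns lat, lon, value", call. = FALSE)
  if (!all(c("lat", "lon") %in% names(targets)))
    stop("'targets' needs columns lat, lon", call. = FALSE)
  n <- nrow(nodes)
  if (n < 3L)
    stop("degenerate design: need at least 3 nodes", call. = FALSE)
  P <- cbind(1, nodes$lat, nodes$lon)
  if (qr(P)$rank < 3L)
    stop("degenerate design: nodes are collinear", call. = FALSE)

  eta <- function(r2) {
    # r^2 log r = 0.5 * r^2 log r^2; define 0 at r = 0
    out <- ifelse(r2 > 0, 0.5 * r2 * log(r2), 0)
    out
  }
  d2 <- function(a_lat, a_lon, b_lat, b_lon) {
    outer(a_lat, b_lat, `-`)^2 + outer(a_lon, b_lon, `-`)^2
  }

  K <- eta(d2(nodes$lat, nodes$lon, nodes$lat, nodes$lon))
  if (lambda != 0) K <- K + diag(lambda, n)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3L, 3L)))
  rhs <- c(nodes$value, numeric(3L))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("thin-plate spline system is singular: ", conditionMessage(e),
         call. = FALSE))
  w <- sol[seq_len(n)]
  a <- sol[n + 1:3]

  Kt <- eta(d2(targets$lat, targets$lon, nodes$lat, nodes$lon))
  as.numeric(Kt %*% w + cbind(1, targets$lat, targets$lon) %*% a)
}

#' Delta-method downscaling of coarse climate-model SST
#'
#' Additive statistical downscaling: for each calendar month, takes the
#' climate-model change signal (future minus historical climatology) on the
#' coarse model grid, regrids it to the fine baseline grid by exact
#' thin-plate-spline interpolation, and adds it to the observed contemporary
#' baseline climatology. The baseline's mask is preserved; a zero delta
#' returns the baseline unchanged.
#'
#' @param model_hist,model_future coarse [clim_grid()] objects sharing
#'   geometry (e.g. 1961-1990 historical and 2040-2069 / 2070-2099 future
#'   climatologies of one climate model).
#' @param baseline fine (half-degree) [clim_grid()] contemporary
#'   climatology.
#' @param lambda smoothing passed to [tps_interpolate()]; default 0.
#' @return A [clim_grid()] on the baseline geometry.
#' @export
delta_downscale <- function(model_hist, model_future, baseline, lambda = 0) {
  stopifnot(inherits(model_hist, "clim_grid"),
            inherits(model_future, "clim_grid"),
            inherits(baseline, "clim_grid"))
  if (!.same_geometry(model_hist, model_future))
    stop("model historical and future grids must share geometry",
         call. = FALSE)
  out <- baseline$monthly
  tg <- expand.grid(lat = baseline$lat, lon = baseline$lon,
                    KEEP.OUT.ATTRS = FALSE)
  for (m in 1:12) {
    delta <- model_future$monthly[, , m] - model_hist$monthly[, , m]
    nd <- expand.grid(lat = model_hist$lat, lon = model_hist$lon,
                      KEEP.OUT.ATTRS = FALSE)
    nd$value <- as.vector(delta)
    nd <- nd[is.finite(nd$value), , drop = FALSE]
    dfine <- tps_interpolate(nd, tg, lambda = lambda)
    out[, , m] <- out[, , m] +
      matrix(dfine, length(baseline$lat), length(baseline$lon))
  }
  clim_grid(baseline$lat, baseline$lon, out, mask = baseline$mask)
}
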