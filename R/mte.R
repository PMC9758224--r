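#' Boltzmann constant in electron-volts per Kelvin
#'
#' The constant used throughout the package to convert between Arrhenius
#' slopes and activation energies: 8.617e-5 eV/K.
#' @export
boltzmann_eV_K <- 8.617e-5

.celsius_to_kelvin <- function(temp_C) temp_C + 273.15

#' Parameters of the metabolic-theory rate equation
#'
#' Bundles the normalization constant and mass-scaling exponent of the
#' metabolic theory of ecology (MTE) rate equation
#' \deqn{B = b_0 M^{3/4} e^{-E/kT}}
#' where \eqn{M} is body mass (g), \eqn{T} absolute temperature (K),
#' \eqn{E} the averaged enzyme activation energy (eV) and \eqn{k} the
#' Boltzmann constant. The Boltzmann constant is fixed; \code{b0} and the
#' mass exponent are configurable.
#'
#' @param b0 positive multiplicative normalization constant. The default
#'   14.47 is the metabolic scaling component used for teleost fish.
#' @param mass_exponent allometric scaling exponent, default 3/4.
#' @return An object of class \code{"mte_params"}.
#' @export
mte_params <- function(b0 = 14.47, mass_exponent = 0.75) {
  if (!is.numeric(b0) || length(b0) != 1L || !is.finite(b0) || b0 <= 0)
    stop("'b0' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(mass_exponent) || length(mass_exponent) != 1L ||
      !is.finite(mass_exponent))
    stop("'mass_exponent' must be a single finite number", call. = FALSE)
  structure(list(b0 = b0, mass_exponent = mass_exponent,
                 boltzmann_eV_per_K = boltzmann_eV_K),
            class = "mte_params")
}

#' @export
print.mte_params <- function(x, ...) {
  cat("MTE parameters: b0 =", x$b0,
      " mass exponent =", x$mass_exponent,
      " k =", x$boltzmann_eV_per_K, "eV/K\n")
  invisible(x)
}

#' Routine metabolic rate from the MTE equation
#'
#' Evaluates \eqn{B = b_0 M^{3/4} e^{-E/kT}} with \eqn{T} in Kelvin
#' (converted internally from Celsius as \code{temp_C + 273.15}).
#' Vectorized over all rate arguments with the usual recycling rules.
#'
#' @param mass_g body mass in grams, > 0.
#' @param temp_C temperature in degrees Celsius.
#' @param E_eV activation energy in eV.
#' @param params an [mte_params()] object.
#' @return Metabolic rate in the (opaque) units implied by \code{b0}.
#' @examples
#' metabolic_rate(10, 15, 0.6, mte_params(b0 = 1))
#' @export
metabolic_rate <- function(mass_g, temp_C, E_eV, params = mte_params()) {
  if (!is.numeric(mass_g) || any(!is.finite(mass_g)) || any(mass_g <= 0))
    stop("'mass_g' must be finite and > 0", call. = FALSE)
  if (!is.numeric(temp_C) || any(!is.finite(temp_C)))
    stop("'temp_C' must be finite", call. = FALSE)
  if (!is.numeric(E_eV) || any(!is.finite(E_eV)))
    stop("'E_eV' must be finite", call. = FALSE)
  T_K <- .celsius_to_kelvin(temp_C)
  params$b0 * mass_g^params$mass_exponent *
    exp(-E_eV / (params$boltzmann_eV_per_K * T_K))
}

#' Fold change in metabolic rate for a shift in activation energy
#'
#' Ratio of two MTE rates identical except that their activation energies
#' differ by \code{delta_E_eV}: \eqn{\exp(\Delta E / kT)}. A 0.1 eV shift
#' corresponds to roughly a 70-fold rate change at 0 degC falling to about
#' 40-fold at 40 degC.
#'
#' @param delta_E_eV difference in activation energy (eV).
#' @param temp_C temperature in degrees Celsius.
#' @return The (positive) rate ratio; 1 when \code{delta_E_eV} is 0.
#' @examples
#' fold_change(0.1, 0)   # ~70
#' fold_change(0.1, 40)  # ~40
#' @export
fold_change <- function(delta_E_eV, temp_C) {
  if (!is.numeric(delta_E_eV) || any(!is.finite(delta_E_eV)))
    stop("'delta_E_eV' must be finite", call. = FALSE)
  if (!is.numeric(temp_C) || any(!is.finite(temp_C)))
    stop("'temp_C' must be finite", call. = FALSE)
  exp(delta_E_eV / (boltzmann_eV_K * .celsius_to_kelvin(temp_C)))
}

#' Fit an Arrhenius-Boltzmann activation energy to metabolic-rate data
#'
#' Ordinary least-squares (model I) regression of \eqn{\ln(rate)} on inverse
#' absolute temperature \eqn{1/T}. Under the Arrhenius-Boltzmann relationship
#' \eqn{R_b = A_0 e^{-E/kT}} the slope equals \eqn{-E/k}, so the activation
#' energy is recovered as \code{E_eV = -slope * k}. The fit is returned
#' regardless of significance; the p-value (two-sided t test on the slope,
#' n - 2 df) is only reported.
#'
#' @param data a data frame of rate measurements with at least columns
#'   \code{temp_C} and \code{rate} (rates > 0); typically the format returned
#'   by [read_rate_csv()] or [gen_arrhenius_measurements()].
#' @param min_n minimum number of measurements, default 3 (published E-value
#'   syntheses require three or more temperature treatments). Envelope fits
#'   on two-temperature subsets may lower this to 2, in which case the line
#'   passes through both points exactly and p-value/stderr are \code{NA}.
#' @return An object of class \code{"arrhenius_fit"} with components
#'   \code{E_eV}, \code{ln_A0} (intercept), \code{r_squared}, \code{p_value},
#'   \code{n}, \code{E_stderr}, \code{slope}, the underlying \code{lm} fit
#'   and the data. Supports \code{print}, \code{summary}, \code{coef},
#'   \code{predict}, \code{residuals} and \code{plot}.
#' @examples
#' d <- gen_arrhenius_measurements(E_true = 0.5, ln_A0 = 3,
#'                                 temps_C = seq(5, 30, 5), seed = 1)
#' fit <- fit_arrhenius(d)
#' coef(fit)
#' @export
fit_arrhenius <- function(data, min_n = 3L) {
  if (!is.data.frame(data) || !all(c("temp_C", "rate") %in% names(data)))
    stop("'data' must be a data frame with columns 'temp_C' and 'rate'",
         call. = FALSE)
  temp_C <- data$temp_C
  rate <- data$rate
  n <- length(rate)
  if (n < min_n)
    stop(sprintf("insufficient data: %d measurement(s), need at least %d",
                 n, min_n), call. = FALSE)
  if (any(!is.finite(rate)) || any(rate <= 0))
    stop("all rates must be finite and > 0 (log-transform required)",
         call. = FALSE)
  if (any(!is.finite(temp_C)) || any(temp_C < -5) || any(temp_C > 45))
    stop("assay temperatures must be finite and within [-5, 45] degC",
         call. = FALSE)
  if (length(unique(temp_C)) < 2L)
    stop("degenerate design: need at least 2 distinct assay temperatures",
         call. = FALSE)

  inv_T <- 1 / .celsius_to_kelvin(temp_C)
  ln_rate <- log(rate)
  fit <- stats::lm(ln_rate ~ inv_T)
  sm <- suppressWarnings(summary(fit))  # noise-free data fit perfectly
  slope <- unname(stats::coef(fit)[2L])
  se_slope <- sm$coefficients["inv_T", "Std. Error"]
  p <- if (fit$df.residual > 0L)
    sm$coefficients["inv_T", "Pr(>|t|)"]
  else NA_real_
  r2 <- sm$r.squared
  if (!is.finite(r2)) r2 <- NA_real_  # constant-response degenerate case
  if (fit$df.residual == 0L) {
    r2 <- 1
    se_slope <- NA_real_
  }

  structure(list(
    E_eV = -slope * boltzmann_eV_K,
    ln_A0 = unname(stats::coef(fit)[1L]),
    r_squared = r2,
    p_value = unname(p),
    n = n,
    E_stderr = unname(se_slope) * boltzmann_eV_K,
    slope = slope,
    lm_fit = fit,
    data = data
  ), class = "arrhenius_fit")
}

#' @export
print.arrhenius_fit <- function(x, digits = 4, ...) {
  cat("Arrhenius-Boltzmann fit (ln rate ~ 1/T, OLS)\n")
  cat(sprintf("  E = %s eV (se %s), ln A0 = %s\n",
              format(x$E_eV, digits = digits),
              format(x$E_stderr, digits = digits),
              format(x$ln_A0, digits = digits)))
  cat(sprintf("  R^2 = %s, p = %s, n = %d\n",
              format(x$r_squared, digits = digits),
              format(x$p_value, digits = digits), x$n))
  invisible(x)
}

#' @export
summary.arrhenius_fit <- function(object, ...) {
  out <- list(fit = object,
              lm_summary = suppressWarnings(summary(object$lm_fit)))
  class(out) <- "summary.arrhenius_fit"
  out
}

#' @export
print.summary.arrhenius_fit <- function(x, ...) {
  print(x$fit)
  cat("\nUnderlying linear model (ln rate ~ 1/T_K):\n")
  print(x$lm_summary$coefficients)
  invisible(x)
}

#' @export
coef.arrhenius_fit <- function(object, ...) {
  c(E_eV = object$E_eV, ln_A0 = object$ln_A0)
}

#' Predict rates from a fitted Arrhenius relationship
#'
#' @param object an \code{arrhenius_fit}.
#' @param temp_C temperatures (degC) at which to predict; defaults to the
#'   fitted data's temperatures.
#' @param ... unused.
#' @return Predicted rates on the original (not log) scale.
#' @export
predict.arrhenius_fit <- function(object, temp_C = object$data$temp_C, ...) {
  exp(object$ln_A0 -
        object$E_eV / (boltzmann_eV_K * .celsius_to_kelvin(temp_C)))
}

#' @export
residuals.arrhenius_fit <- function(object, ...) {
  stats::residuals(object$lm_fit)
}

#' Arrhenius plot of a fitted activation energy
#'
#' ln(rate) against 1/T with the fitted line.
#' @param x an \code{arrhenius_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.arrhenius_fit <- function(x, ...) {
  inv_T <- 1 / .celsius_to_kelvin(x$data$temp_C)
  graphics::plot(inv_T, log(x$data$rate),
                 xlab = "1 / T (1/K)", ylab = "ln(rate)",
                 main = sprintf("Arrhenius plot: E = %.3f eV", x$E_eV), ...)
  graphics::abline(a = x$ln_A0, b = x$slope, col = "steelblue")
  invisible(x)
}

#' Metabolic rate range (MRR) between two habitat temperatures
#'
#' Difference between MTE routine metabolic rates evaluated at the
#' climatological maximum and minimum habitat temperature,
#' \eqn{MRR = B(T_{max}) - B(T_{min})}. Non-negative whenever
#' \eqn{E \ge 0}; zero iff the endpoints coincide or E = 0.
#'
#' @param mass_g body mass (g); habitat projections use 10 g.
#' @param t_min_C,t_max_C minimum and maximum habitat temperature (degC),
#'   \code{t_min_C <= t_max_C}.
#' @param E_eV activation energy (eV).
#' @param params an [mte_params()] object.
#' @return The metabolic rate range in rate units.
#' @export
metabolic_rate_range <- function(mass_g, t_min_C, t_max_C, E_eV,
                                 params = mte_params()) {
  if (any(t_min_C > t_max_C))
    stop("'t_min_C' must not exceed 't_max_C'", call. = FALSE)
  metabolic_rate(mass_g, t_max_C, E_eV, params) -
    metabolic_rate(mass_g, t_min_C, E_eV, params)
}

#' Sensitivity surface of the MTE rate over mass, temperature and E
#'
#' Evaluates log10 metabolic rate on the grid
#' \code{mass_grid x temp_grid x E_grid}, and, when \code{temp_grid} is
#' uniformly spaced, the metabolic rate range over consecutive temperature
#' windows (e.g. 0-2, 2-4 degC) for each (mass, E) combination. For
#' activation energies well above \eqn{2kT} the rate is convex in
#' temperature, so consecutive-window MRR increases with temperature; at
#' very low E (~0.01 eV) this monotonicity breaks down.
#'
#' @param mass_grid positive masses (g).
#' @param temp_grid temperatures (degC).
#' @param E_grid activation energies (eV).
#' @param params an [mte_params()] object.
#' @return A list of class \code{"mte_sensitivity"}: \code{log10_rate}, an
#'   array indexed (mass, temp, E); \code{mrr_windows}, an array indexed
#'   (mass, window, E) or \code{NULL} if the temperature grid is not
#'   uniform; and the grids.
#' @export
sensitivity_surface <- function(mass_grid, temp_grid, E_grid,
                                params = mte_params()) {
  if (length(mass_grid) == 0L || length(temp_grid) == 0L ||
      length(E_grid) == 0L)
    stop("all grids must be non-empty", call. = FALSE)
  dims <- c(length(mass_grid), length(temp_grid), length(E_grid))
  rate <- array(NA_real_, dims,
                dimnames = list(mass = format(mass_grid),
                                temp = format(temp_grid),
                                E = format(E_grid)))
  for (k in seq_along(E_grid))
    for (j in seq_along(temp_grid))
      rate[, j, k] <- metabolic_rate(mass_grid, temp_grid[j], E_grid[k],
                                     params)
  mrr <- NULL
  steps <- diff(temp_grid)
  if (length(temp_grid) >= 2L &&
      isTRUE(all(abs(steps - steps[1L]) < 1e-9)) && steps[1L] > 0) {
    nw <- length(temp_grid) - 1L
    wn <- paste(format(temp_grid[-length(temp_grid)]),
                format(temp_grid[-1L]), sep = "-")
    mrr <- array(NA_real_, c(dims[1L], nw, dims[3L]),
                 dimnames = list(mass = format(mass_grid), window = wn,
                                 E = format(E_grid)))
    for (k in seq_len(dims[3L]))
      mrr[, , k] <- rate[, -1L, k] - rate[, -dims[2L], k]
  }
  structure(list(log10_rate = log10(rate), mrr_windows = mrr,
                 mass_grid = mass_grid, temp_grid = temp_grid,
                 E_grid = E_grid, params = params),
            class = "mte_sensitivity")
}

#' @export
print.mte_sensitivity <- function(x, ...) {
  cat("MTE sensitivity surface:",
      length(x$mass_grid), "masses x",
      length(x$temp_grid), "temperatures x",
      length(x$E_grid), "E values\n")
  cat("log10 rate span:",
      format(range(x$log10_rate), digits = 4), "\n")
  if (!is.null(x$mrr_windows))
    cat("consecutive-window MRR available for",
        dim(x$mrr_windows)[2L], "windows\n")
  invisible(x)
}
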