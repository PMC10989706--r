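# Thermodynamic curves from a fitted spline. With y = ln Keq fitted as
# S(x(T)) on either scale, the fundamental relation dG = -RT ln Keq and the
# van 't Hoff equation give closed forms for all potentials in terms of S,
# S' and S'' at x(T).

#' Thermodynamic curves from a fitted van 't Hoff model
#'
#' Evaluates, on a temperature grid inside the fitted range,
#' \deqn{\Delta G(T) = -R T\, S(x(T)),}
#' \deqn{\Delta H(T) = R T^2 \frac{dx}{dT} S'(x(T)),}
#' \deqn{\Delta S(T) = \frac{\Delta H(T) - \Delta G(T)}{T},}
#' and the heat-capacity difference \eqn{\Delta C_p(T) = d\Delta H/dT}:
#' on the reciprocal scale (\eqn{x = 1/T}, \eqn{dx/dT = -T^{-2}})
#' \eqn{\Delta C_p = R\,S''(x)/T^2}; on the linear scale (\eqn{x = T})
#' \eqn{\Delta C_p = 2RT\,S'(T) + RT^2 S''(T)}.
#'
#' Each grid point carries a `constrained` flag: `TRUE` when some data point
#' lies within `constrained_factor` times the mean inter-datum spacing (in
#' the fit coordinate). Outside such neighbourhoods the spline's trend is an
#' extrapolation of the functional form, not of the data, and should not be
#' over-interpreted.
#'
#' @param fit A `"vh_fit"` from [fit_free_knot_spline()] or
#'   [select_model()].
#' @param t_grid Optional numeric temperature grid (K); must map into the
#'   fitted coordinate range. Default: `grid_n` equally spaced temperatures
#'   across the fitted range.
#' @param grid_n Grid size when `t_grid` is `NULL` (default 200).
#' @param constrained_factor Multiplier on the mean data spacing used for
#'   the `constrained` flag (default 1).
#' @return A data frame of class `"thermo_curves"` with columns `T_K`,
#'   `dG_J_per_mol`, `dH_J_per_mol`, `TdS_J_per_mol`, `dS_J_per_mol_K`,
#'   `dCp_J_per_mol_K` and `constrained`; the molar gas constant used and
#'   the scale are recorded as attributes.
#' @examples
#' s <- simulate_lnkeq_series(two_state_spec(300, 1e5, 300), seq(283, 323, 2),
#'                            seed = 1)
#' fit <- fit_free_knot_spline(s, 1, "reciprocal")
#' head(compute_thermo(fit, grid_n = 5))
#' @export
compute_thermo <- function(fit, t_grid = NULL, grid_n = 200,
                           constrained_factor = 1) {
  stopifnot(inherits(fit, "vh_fit"))
  if (is.null(t_grid)) {
    stopifnot(grid_n >= 2)
    t_grid <- seq(fit$temperature_range[1], fit$temperature_range[2],
                  length.out = grid_n)
  }
  if (any(t_grid <= 0)) stop("grid temperatures must be positive")
  x <- if (fit$scale == "linear") t_grid else 1 / t_grid
  s <- fit$spline
  rng <- range(s$positions)
  if (any(x < rng[1] - 1e-9 * diff(rng) | x > rng[2] + 1e-9 * diff(rng)))
    stop("temperature grid extends beyond the fitted range [",
         format(fit$temperature_range[1]), ", ",
         format(fit$temperature_range[2]), "] K")
  s0 <- spline_eval(s, x, 0)
  s1 <- spline_eval(s, x, 1)
  s2 <- spline_eval(s, x, 2)
  r <- .RGAS
  dg <- -r * t_grid * s0
  if (fit$scale == "linear") {
    dh <- r * t_grid^2 * s1
    dcp <- 2 * r * t_grid * s1 + r * t_grid^2 * s2
  } else {
    dh <- -r * s1                       # RT^2 * (-1/T^2) * S'
    dcp <- r * s2 / t_grid^2
  }
  ds <- (dh - dg) / t_grid
  # trusted only near data: compare each grid x to the data-knot coordinate
  data_x <- fit$data_x
  if (is.null(data_x)) data_x <- fit$knots$positions
  spacing <- mean(diff(sort(data_x)))
  nearest <- vapply(x, function(xx) min(abs(xx - data_x)), numeric(1))
  constrained <- nearest <= constrained_factor * spacing
  structure(data.frame(T_K = t_grid,
                       dG_J_per_mol = dg,
                       dH_J_per_mol = dh,
                       TdS_J_per_mol = dh - dg,
                       dS_J_per_mol_K = ds,
                       dCp_J_per_mol_K = dcp,
                       constrained = constrained),
            class = c("thermo_curves", "data.frame"),
            gas_constant = r, scale = fit$scale)
}

#' @export
print.thermo_curves <- function(x, ...) {
  cat(sprintf("thermodynamic curves (%s scale), %d grid points, %.2f-%.2f K\n",
              attr(x, "scale"), nrow(x), min(x$T_K), max(x$T_K)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ... (", nrow(x) - 6, " more rows)\n")
  invisible(x)
}

#' Write thermodynamic curves to CSV
#'
#' Writes the machine-readable SI columns plus kJ-scaled display columns.
#'
#' @param curves A `"thermo_curves"`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  stopifnot(inherits(curves, "thermo_curves"))
  out <- as.data.frame(curves)
  out$dG_kJ_per_mol <- out$dG_J_per_mol / 1000
  out$dH_kJ_per_mol <- out$dH_J_per_mol / 1000
  out$TdS_kJ_per_mol <- out$TdS_J_per_mol / 1000
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Q10 temperature coefficient and its implied enthalpy
#'
#' The Q10 coefficient is the ratio of equilibrium constants measured
#' `delta` = 10 K apart, computed from the fitted spline as
#' \eqn{\ln Q_{10}(T) = S(x(T+10)) - S(x(T))}. Treating the finite
#' difference as the van 't Hoff derivative at the lower temperature T
#' yields the enthalpy estimate
#' \deqn{\Delta H_{Q10}(T) = \frac{R T^2 \ln Q_{10}(T)}{10\,\mathrm{K}}.}
#' Because the derivative is approximated by a forward difference, the
#' estimate is biased even for a perfectly linear van 't Hoff plot: for
#' constant \eqn{\Delta H}, \eqn{\Delta H_{Q10}(T) = \Delta H\, T/(T+10)},
#' about 3\% low near 300 K. The generalized step `delta` lets the bias be
#' tracked to zero.
#'
#' @param fit A `"vh_fit"`.
#' @param t_grid Temperatures T (K) at which to evaluate; points with
#'   `T + delta` beyond the fitted range are dropped with a warning.
#'   Default: 200 points spanning the representable range.
#' @param delta Temperature step in K (default 10, the Q10 convention).
#' @return A data frame of class `"q10_curve"` with columns `T_K`, `Q10`
#'   and `dH_Q10_J_per_mol`; `delta` is recorded as an attribute.
#' @export
q10_curve <- function(fit, t_grid = NULL, delta = 10) {
  stopifnot(inherits(fit, "vh_fit"), delta > 0)
  t_lo <- fit$temperature_range[1]; t_hi <- fit$temperature_range[2]
  if (is.null(t_grid)) {
    if (t_hi - delta <= t_lo)
      stop("fitted temperature range is narrower than delta = ", delta, " K")
    t_grid <- seq(t_lo, t_hi - delta, length.out = 200)
  }
  keep <- t_grid >= t_lo - 1e-9 * (t_hi - t_lo) & t_grid + delta <= t_hi +
    1e-9 * (t_hi - t_lo)
  if (!all(keep)) {
    warning(sum(!keep), " temperature(s) dropped: T or T + ", delta,
            " K outside the fitted range")
    t_grid <- t_grid[keep]
  }
  if (!length(t_grid))
    stop("no grid temperature admits a ", delta, " K step inside the range")
  xf <- function(tt) if (fit$scale == "linear") tt else 1 / tt
  lnq <- spline_eval(fit$spline, xf(t_grid + delta)) -
    spline_eval(fit$spline, xf(t_grid))
  structure(data.frame(T_K = t_grid,
                       Q10 = exp(lnq),
                       dH_Q10_J_per_mol = .RGAS * t_grid^2 * lnq / delta),
            class = c("q10_curve", "data.frame"),
            delta = delta, gas_constant = .RGAS)
}

#' @export
print.q10_curve <- function(x, ...) {
  cat(sprintf("Q10 curve (step %g K), %d temperatures\n",
              attr(x, "delta"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ... (", nrow(x) - 6, " more rows)\n")
  invisible(x)
}

#' Plot thermodynamic curves
#'
#' Three stacked panels: Gibbs free energy; enthalpy and entropy-temperature
#' product; heat-capacity difference. Temperature intervals where the spline
#' is not constrained by data are shaded.
#'
#' @param x A `"thermo_curves"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.thermo_curves <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(4, 4.5, 1, 1))
  on.exit(graphics::par(op))
  shade <- function() {
    if (any(!x$constrained)) {
      runs <- rle(x$constrained)
      ends <- cumsum(runs$lengths)
      starts <- c(1, utils::head(ends, -1) + 1)
      usr <- graphics::par("usr")
      for (j in which(!runs$values))
        graphics::rect(x$T_K[starts[j]], usr[3], x$T_K[ends[j]], usr[4],
                       col = grDevices::grey(0.9), border = NA)
    }
  }
  kj <- 1 / 1000
  graphics::plot(x$T_K, x$dG_J_per_mol * kj, type = "n",
                 xlab = "T (K)", ylab = expression(Delta * G ~ "(kJ/mol)"),
                 ...)
  shade(); graphics::lines(x$T_K, x$dG_J_per_mol * kj, lwd = 2)
  ylim <- range(c(x$dH_J_per_mol, x$TdS_J_per_mol)) * kj
  graphics::plot(x$T_K, x$dH_J_per_mol * kj, type = "n", ylim = ylim,
                 xlab = "T (K)",
                 ylab = expression(Delta * H * "," ~ T * Delta * S ~ "(kJ/mol)"))
  shade()
  graphics::lines(x$T_K, x$dH_J_per_mol * kj, lwd = 2, col = "blue")
  graphics::lines(x$T_K, x$TdS_J_per_mol * kj, lwd = 2, lty = 2, col = "red")
  graphics::legend("topright", c(expression(Delta * H),
                                 expression(T * Delta * S)),
                   lty = c(1, 2), col = c("blue", "red"), bty = "n")
  graphics::plot(x$T_K, x$dCp_J_per_mol_K, type = "n", xlab = "T (K)",
                 ylab = expression(Delta * C[p] ~ "(J/mol/K)"))
  shade(); graphics::lines(x$T_K, x$dCp_J_per_mol_K, lwd = 2)
  invisible(x)
}

#' Plot a Q10 curve
#'
#' @param x A `"q10_curve"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.q10_curve <- function(x, ...) {
  graphics::plot(x$T_K, x$dH_Q10_J_per_mol / 1000, type = "l", lwd = 2,
                 col = "red", lty = 2, xlab = "T (K)",
                 ylab = expression(Delta * H[Q10] ~ "(kJ/mol)"), ...)
  invisible(x)
}
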