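# Ground-truth two-state gating simulator. The truth model integrates a
# (constant or temperature-dependent) heat-capacity difference into
# temperature-dependent enthalpy and entropy differences,
#   dH(T) = dH(T0) + int_{T0}^{T} dCp(T') dT',
#   dS(T) = dS(T0) + int_{T0}^{T} dCp(T')/T' dT',
# and maps them to ln Keq = -dH/(RT) + dS/R. Noise is Gaussian on ln Keq,
# or on replicate open probabilities in replicate mode.

#' Specify a two-state ground-truth model
#'
#' @param t_ref Reference temperature \eqn{T_0} in K.
#' @param dh_ref Enthalpy difference \eqn{\Delta H(T_0)} in J/mol.
#' @param ds_ref Entropy difference \eqn{\Delta S(T_0)} in J/(mol K).
#' @param dcp Heat-capacity difference in J/(mol K): a single number
#'   (constant \eqn{\Delta C_p}, closed-form integrals) or a function of
#'   temperature (integrated numerically with a fixed-step trapezoid at
#'   0.01 K resolution).
#' @param sigma_lnkeq Gaussian noise standard deviation on ln Keq used by
#'   [simulate_lnkeq_series()].
#' @param sigma_p Gaussian noise standard deviation on replicate open
#'   probabilities used by [simulate_open_prob()].
#' @param n_replicates Replicates per temperature in replicate mode (at
#'   least 2).
#' @return A list of class `"two_state_spec"`.
#' @examples
#' two_state_spec(300, 1e5, 300, dcp = 0, sigma_lnkeq = 0.05)
#' @export
two_state_spec <- function(t_ref, dh_ref, ds_ref, dcp = 0,
                           sigma_lnkeq = 0.05, sigma_p = 0.02,
                           n_replicates = 5L) {
  stopifnot(t_ref > 0, sigma_lnkeq >= 0, sigma_p >= 0)
  if (!is.function(dcp)) stopifnot(is.numeric(dcp), length(dcp) == 1)
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2)
    stop("'n_replicates' must be at least 2 (a standard error needs spread)")
  structure(list(t_ref = t_ref, dh_ref = dh_ref, ds_ref = ds_ref,
                 dcp = dcp, sigma_lnkeq = sigma_lnkeq, sigma_p = sigma_p,
                 n_replicates = n_replicates),
            class = "two_state_spec")
}

#' @export
print.two_state_spec <- function(x, ...) {
  dcp_txt <- if (is.function(x$dcp)) "temperature-dependent (function)"
             else sprintf("%g J/(mol K)", x$dcp)
  cat(sprintf(paste0("two-state ground truth: dH(%g K) = %g J/mol, ",
                     "dS(%g K) = %g J/(mol K), dCp = %s\n"),
              x$t_ref, x$dh_ref, x$t_ref, x$ds_ref, dcp_txt))
  invisible(x)
}

# trapezoid integrals of dcp and dcp/T from t_ref to each t (0.01 K step)
.dcp_integrals <- function(dcp_fun, t_ref, t) {
  vapply(t, function(tt) {
    if (abs(tt - t_ref) < 1e-12) return(c(0, 0))
    grid <- seq(t_ref, tt, by = if (tt > t_ref) 0.01 else -0.01)
    if (grid[length(grid)] != tt) grid <- c(grid, tt)
    f <- dcp_fun(grid)
    w <- diff(grid)
    c(sum(w * (f[-1] + f[-length(f)]) / 2),
      sum(w * (f[-1] / grid[-1] + f[-length(f)] / grid[-length(grid)]) / 2))
  }, numeric(2))
}

#' Ground-truth thermodynamic curves of a two-state model
#'
#' @param spec A [two_state_spec()].
#' @param temperature Absolute temperatures (K), strictly positive.
#' @return A data frame with columns `temperature`, `dH`, `dS`, `dG`
#'   (J/mol, J/(mol K), J/mol) and `lnkeq`.
#' @examples
#' truth_curves(two_state_spec(300, 1e5, 300), c(290, 300, 310))
#' @export
truth_curves <- function(spec, temperature) {
  stopifnot(inherits(spec, "two_state_spec"))
  t <- as.numeric(temperature)
  if (any(t <= 0)) stop("temperatures must be strictly positive")
  if (is.function(spec$dcp)) {
    ints <- .dcp_integrals(spec$dcp, spec$t_ref, t)
    dh <- spec$dh_ref + ints[1, ]
    ds <- spec$ds_ref + ints[2, ]
  } else {
    dh <- spec$dh_ref + spec$dcp * (t - spec$t_ref)
    ds <- spec$ds_ref + spec$dcp * log(t / spec$t_ref)
  }
  dg <- dh - t * ds
  data.frame(temperature = t, dH = dh, dS = ds, dG = dg,
             lnkeq = -dh / (.RGAS * t) + ds / .RGAS)
}

#' Simulate a van 't Hoff series with Gaussian noise on ln Keq
#'
#' Adds homoscedastic Gaussian noise of standard deviation
#' `spec$sigma_lnkeq` to the ground-truth ln Keq and records that value as
#' the standard error of every point. When `sigma_lnkeq` is zero the series
#' equals the truth exactly and the recorded standard error is floored at
#' `1e-6` (with a warning) so that downstream weighted fits remain defined.
#'
#' @param spec A [two_state_spec()].
#' @param t_grid Temperatures (K), sorted or not; must be unique.
#' @param seed Optional integer seed; identical seed and spec give an
#'   identical series. The caller's RNG state is left untouched.
#' @return A [vanthoff_series()] with provenance `"synthetic"`.
#' @export
simulate_lnkeq_series <- function(spec, t_grid, seed = NULL) {
  stopifnot(inherits(spec, "two_state_spec"))
  truth <- truth_curves(spec, t_grid)
  y <- .with_seed(seed,
                  truth$lnkeq + stats::rnorm(length(t_grid),
                                             sd = spec$sigma_lnkeq))
  sigma <- spec$sigma_lnkeq
  if (sigma == 0) {
    warning("sigma_lnkeq = 0: recording floor standard errors of 1e-6")
    sigma <- 1e-6
  }
  vanthoff_series(t_grid, y, rep(sigma, length(t_grid)),
                  provenance = "synthetic")
}

#' Simulate replicate open-probability measurements
#'
#' Maps the ground-truth ln Keq to open probabilities
#' \eqn{P = K_{eq}/(1+K_{eq})} and draws `spec$n_replicates` Gaussian
#' replicates of standard deviation `spec$sigma_p` per temperature.
#' Replicates falling outside (0, 1) are redrawn (rejection) rather than
#' clipped, which keeps the replicate mean unbiased; the number of redraws
#' is recorded in the `redraws` attribute.
#'
#' @param spec A [two_state_spec()] with `sigma_p > 0`.
#' @param t_grid Temperatures (K).
#' @param seed Optional integer seed.
#' @return An [open_prob_table()] with attribute `redraws`.
#' @export
simulate_open_prob <- function(spec, t_grid, seed = NULL) {
  stopifnot(inherits(spec, "two_state_spec"))
  truth <- truth_curves(spec, t_grid)
  p_true <- open_prob_from_keq(exp(truth$lnkeq))
  n_rep <- spec$n_replicates
  res <- .with_seed(seed, {
    p0 <- rep(p_true, each = n_rep)
    p <- p0 + stats::rnorm(length(p0), sd = spec$sigma_p)
    redraws <- 0L
    while (any(bad <- p <= 0 | p >= 1)) {
      redraws <- redraws + sum(bad)
      p[bad] <- p0[bad] + stats::rnorm(sum(bad), sd = spec$sigma_p)
    }
    list(p = p, redraws = redraws)
  })
  tab <- open_prob_table(rep(t_grid, each = n_rep), res$p)
  attr(tab, "redraws") <- res$redraws
  tab
}

#' Matched linear and reciprocal series on one temperature grid
#'
#' Generates two series on the same grid and with the same noise level: one
#' from the linear-in-temperature function \eqn{f(T) = a + bT} and one from
#' the reciprocal function \eqn{g(T) = c - d/T}. Over a narrow (e.g.
#' physiological) temperature span the two are practically
#' indistinguishable; their difference only becomes visible when the
#' absolute temperature is varied by orders of magnitude.
#'
#' @param a,b Intercept and slope of the linear function.
#' @param c_,d Intercept and reciprocal coefficient of \eqn{g}.
#' @param t_grid Temperatures (K).
#' @param sigma Gaussian noise standard deviation on both series (0 for
#'   noiseless values; standard errors are then floored as in
#'   [simulate_lnkeq_series()]).
#' @param seed Optional integer seed (noise draws are independent between
#'   the two series but jointly reproducible).
#' @return A list with elements `linear` and `reciprocal`, both
#'   [vanthoff_series()].
#' @export
linear_reciprocal_pair <- function(a, b, c_, d, t_grid, sigma = 0,
                                   seed = NULL) {
  t_grid <- as.numeric(t_grid)
  if (any(t_grid <= 0)) stop("temperatures must be strictly positive")
  f <- a + b * t_grid
  g <- c_ - d / t_grid
  noise <- .with_seed(seed, matrix(stats::rnorm(2 * length(t_grid),
                                                sd = max(sigma, 0)),
                                   ncol = 2))
  sig <- if (sigma > 0) sigma else 1e-6
  list(linear = vanthoff_series(t_grid, f + noise[, 1],
                                rep(sig, length(t_grid)),
                                provenance = "synthetic"),
       reciprocal = vanthoff_series(t_grid, g + noise[, 2],
                                    rep(sig, length(t_grid)),
                                    provenance = "synthetic"))
}
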