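# Independent oracles used across the suite. These deliberately do not share
# code with the package: the tridiagonal solve is a dense Gaussian
# elimination, derivatives come from finite differences, and the N = 1 fit
# oracle is textbook weighted least squares.

# knot second derivatives of the natural cubic interpolant via a dense solve
oracle_natural_m2 <- function(s, v) {
  k <- length(s)
  if (k == 2) return(c(0, 0))
  h <- diff(s)
  a <- matrix(0, k, k)
  rhs <- numeric(k)
  a[1, 1] <- 1
  a[k, k] <- 1
  for (i in 2:(k - 1)) {
    a[i, i - 1] <- h[i - 1] / 6
    a[i, i] <- (h[i - 1] + h[i]) / 3
    a[i, i + 1] <- h[i] / 6
    rhs[i] <- (v[i + 1] - v[i]) / h[i] - (v[i] - v[i - 1]) / h[i - 1]
  }
  as.numeric(solve(a, rhs))
}

# central finite differences of a function on a uniform grid
fd_deriv <- function(f, x, h) (f(x + h) - f(x - h)) / (2 * h)
fd_deriv2 <- function(f, x, h) (f(x + h) - 2 * f(x) + f(x - h)) / h^2

# random knot set with the package's separation invariant honoured
random_knot_set <- function(n_intervals, xlim = c(0, 1)) {
  repeat {
    pos <- sort(c(xlim, stats::runif(n_intervals - 1, xlim[1], xlim[2])))
    if (all(diff(pos) > 2e-3 * diff(xlim))) break
  }
  knot_set(pos, stats::rnorm(n_intervals + 1))
}

# weighted least-squares straight line, by the normal equations
oracle_wls_line <- function(x, y, sigma) {
  w <- 1 / sigma^2
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  c(intercept = (sxx * sy - sx * sxy) / det,
    slope = (sw * sxy - sx * sy) / det)
}

# flat-enthalpy and strong-heat-capacity ground truths used by several tests
flat_spec <- function(sigma = 0.05)
  two_state_spec(300, 1e5, 300, dcp = 0, sigma_lnkeq = sigma)
curved_spec <- function(sigma = 0.05)
  two_state_spec(310, 0, 0, dcp = -1e4, sigma_lnkeq = sigma)

# noiseless series exactly on a given function of T
exact_series <- function(f, t_grid, sigma = 0.01)
  vanthoff_series(t_grid, f(t_grid), rep(sigma, length(t_grid)))
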