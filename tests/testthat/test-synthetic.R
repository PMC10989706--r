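# Ground-truth two-state simulator.

r_gas <- gas_constant()

test_that("truth curves evaluate the constant-dCp closed forms", {
  spec0 <- two_state_spec(300, 1e5, 300, dcp = 0)
  tr <- truth_curves(spec0, 300)
  expect_equal(tr$lnkeq, -1e5 / (r_gas * 300) + 300 / r_gas,
               tolerance = 1e-12)
  expect_equal(tr$lnkeq, -4.0090, tolerance = 1e-4)

  spec5k <- two_state_spec(300, 1e5, 300, dcp = 5000)
  tr2 <- truth_curves(spec5k, c(300, 310))
  expect_equal(tr2$dH[2] - tr2$dH[1], 5000 * 10, tolerance = 1e-9)
  expect_equal(tr2$dS[2] - tr2$dS[1], 5000 * log(310 / 300),
               tolerance = 1e-9)
  expect_equal(tr2$dS[2] - tr2$dS[1], 163.95, tolerance = 1e-4)
  # at the reference temperature the integrals collapse
  at_ref <- truth_curves(spec5k, 300)
  expect_identical(at_ref$dH, 1e5)
  expect_identical(at_ref$dS, 300)
  expect_error(truth_curves(spec5k, -1), "strictly positive")
})

test_that("a constant dCp function integrates to the closed forms", {
  spec_fun <- two_state_spec(300, 1e5, 300, dcp = function(t) rep(5000, length(t)))
  spec_const <- two_state_spec(300, 1e5, 300, dcp = 5000)
  t_grid <- c(285, 300, 317.3)
  trf <- truth_curves(spec_fun, t_grid)
  trc <- truth_curves(spec_const, t_grid)
  expect_equal(trf$dH, trc$dH, tolerance = 1e-6)
  expect_equal(trf$dS, trc$dS, tolerance = 1e-8)
})

test_that("truth satisfies dG = dH - T dS and the van 't Hoff derivative", {
  specs <- list(two_state_spec(300, 1e5, 300, dcp = 0),
                two_state_spec(310, 0, 0, dcp = -1e4),
                two_state_spec(295, -5e4, -150, dcp = 3000))
  h <- 0.01
  for (spec in specs) {
    t_grid <- seq(284, 322, 2)
    tr <- truth_curves(spec, t_grid)
    expect_equal(tr$dG, tr$dH - t_grid * tr$dS, tolerance = 1e-12)
    # d lnKeq / dT = dH / (R T^2)
    fd <- (truth_curves(spec, t_grid + h)$lnkeq -
             truth_curves(spec, t_grid - h)$lnkeq) / (2 * h)
    expect_equal(fd, tr$dH / (r_gas * t_grid^2), tolerance = 1e-6)
  }
})

test_that("lnKeq simulation is seeded, honest about noise, and calibrated", {
  spec <- flat_spec(0.1)
  t_grid <- seq(283, 323, 2)
  s1 <- simulate_lnkeq_series(spec, t_grid, seed = 9)
  s2 <- simulate_lnkeq_series(spec, t_grid, seed = 9)
  expect_identical(s1$lnkeq, s2$lnkeq)
  expect_false(identical(s1$lnkeq,
                         simulate_lnkeq_series(spec, t_grid, seed = 10)$lnkeq))

  spec0 <- two_state_spec(300, 1e5, 300, dcp = 0, sigma_lnkeq = 0)
  expect_warning(s0 <- simulate_lnkeq_series(spec0, t_grid, seed = 1),
                 "floor")
  expect_equal(s0$lnkeq, truth_curves(spec0, t_grid)$lnkeq)
  expect_equal(s0$sigma, rep(1e-6, length(t_grid)))

  # law of large numbers: realized noise sd close to sigma_lnkeq
  big_grid <- seq(200, 400, length.out = 1000)
  sb <- simulate_lnkeq_series(spec, big_grid, seed = 11)
  resid <- sb$lnkeq - truth_curves(spec, big_grid)$lnkeq
  expect_gt(sd(resid), 0.09)
  expect_lt(sd(resid), 0.11)
})

test_that("seeded simulation leaves the caller's RNG state untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_lnkeq_series(flat_spec(), seq(283, 323, 5), seed = 4))
  invisible(simulate_open_prob(flat_spec(), seq(295, 305, 5), seed = 4))
  expect_identical(.Random.seed, before)
})

test_that("replicate open probabilities centre on the truth", {
  # lnKeq = 0 at the reference temperature: mean replicate P near 0.5
  spec <- two_state_spec(300, 0, 0, dcp = 0, sigma_p = 0.02,
                         n_replicates = 2000L)
  tab <- simulate_open_prob(spec, 300, seed = 12)
  expect_equal(mean(tab$open_prob), 0.5, tolerance = 0.005)
  expect_error(two_state_spec(300, 0, 0, n_replicates = 1), "at least 2")
})

test_that("propagated error bars cover the truth at the Student-t rate", {
  # (y - truth)/sigma_m is t-distributed with N_m - 1 degrees of freedom
  # because sigma_m is estimated from the replicates; coverage of +/- 1
  # standard error is therefore 2 pt(1, N_m - 1) - 1, which approaches the
  # Gaussian 68.3% as the replicate count grows
  coverage_for <- function(n_rep, n_seeds) {
    spec <- two_state_spec(300, 1e5, 300, dcp = 0, sigma_p = 0.02,
                           n_replicates = n_rep)
    # temperatures where this truth keeps the mean open probability inside
    # [0.2, 0.8], the small-noise regime of the delta method
    t_grid <- seq(322, 345, length.out = 40)
    truth <- truth_curves(spec, t_grid)$lnkeq
    hits <- 0L; total <- 0L
    for (seed in seq_len(n_seeds)) {
      tab <- simulate_open_prob(spec, t_grid, seed = seed)
      s <- suppressWarnings(lnkeq_from_replicates(tab, p_bounds = NULL))
      keep <- match(s$temperature, t_grid)
      hits <- hits + sum(abs(s$lnkeq - truth[keep]) <= s$sigma)
      total <- total + nrow(s)
    }
    hits / total
  }
  expect_equal(coverage_for(5L, 500), 2 * pt(1, 4) - 1, tolerance = 0.02)
  expect_equal(coverage_for(50L, 100), 2 * pt(1, 49) - 1, tolerance = 0.02)
})

test_that("matched linear/reciprocal pairs only separate on wide ranges", {
  t_range <- c(283, 323)
  a <- -30.3; b <- 0.1
  # choose c, d so that g matches f at both endpoints
  d <- b * prod(t_range)
  c_ <- a + b * t_range[1] + d / t_range[1]
  narrow <- seq(t_range[1], t_range[2], length.out = 101)
  wide <- seq(t_range[1] / 10, t_range[2] * 10, length.out = 101)
  pn <- linear_reciprocal_pair(a, b, c_, d, narrow)
  pw <- linear_reciprocal_pair(a, b, c_, d, wide)
  gap_narrow <- max(abs(pn$linear$lnkeq - pn$reciprocal$lnkeq))
  gap_wide <- max(abs(pw$linear$lnkeq - pw$reciprocal$lnkeq))
  expect_gt(gap_wide / gap_narrow, 100)

  # degenerate reciprocal part is constant
  pc <- linear_reciprocal_pair(0, 0, 2, 0, narrow)
  expect_equal(unique(pc$reciprocal$lnkeq), 2)

  # seeded reproducibility
  pa <- linear_reciprocal_pair(a, b, c_, d, narrow, sigma = 0.05, seed = 3)
  pb <- linear_reciprocal_pair(a, b, c_, d, narrow, sigma = 0.05, seed = 3)
  expect_identical(pa$linear$lnkeq, pb$linear$lnkeq)
  expect_identical(pa$reciprocal$lnkeq, pb$reciprocal$lnkeq)
})
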