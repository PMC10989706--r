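# Series containers, open-probability conversion and table I/O.

test_that("replicate conversion reproduces hand-computed log-odds and error", {
  tab <- open_prob_table(rep(300, 3), c(0.4, 0.5, 0.6))
  s <- lnkeq_from_replicates(tab)
  # pbar = 0.5, unbiased variance 0.01:
  # sigma = sqrt((1/3) * (1/(0.5 - 0.25))^2 * 0.01)
  expect_equal(s$lnkeq, 0)
  expect_equal(s$sigma, sqrt((1 / 3) * 16 * 0.01), tolerance = 1e-12)
  expect_identical(attr(s, "provenance"), "open_prob")
})

test_that("log-odds round trip through noise-free replicates recovers lnKeq", {
  lnk <- seq(-3, 3, length.out = 13)
  p <- exp(lnk) / (1 + exp(lnk))
  # symmetric +/- delta replicates keep the mean at p while giving the
  # strictly positive variance the container requires
  delta <- 1e-6
  tab <- open_prob_table(rep(seq(280, 340, 5), each = 2),
                         as.vector(rbind(p + delta, p - delta)))
  s <- lnkeq_from_replicates(tab, p_bounds = NULL)
  expect_equal(s$lnkeq, lnk, tolerance = 1e-10)
})

test_that("keq_from_open_prob and its inverse are mutually inverse", {
  p <- seq(0.001, 0.999, length.out = 201)
  expect_equal(open_prob_from_keq(keq_from_open_prob(p)), p,
               tolerance = 1e-12)
  k <- 10^seq(-4, 4, length.out = 81)
  expect_equal(keq_from_open_prob(open_prob_from_keq(k)) / k,
               rep(1, length(k)), tolerance = 1e-12)
  expect_equal(keq_from_open_prob(0.5), 1)
  expect_equal(keq_from_open_prob(0.9), 9)
  expect_error(keq_from_open_prob(1), "strictly in \\(0, 1\\)")
  expect_error(keq_from_open_prob(0), "strictly in \\(0, 1\\)")
  expect_error(open_prob_from_keq(-1), "strictly positive")
})

test_that("propagated standard error matches Monte-Carlo replicate scatter", {
  set.seed(42)
  for (pbar in c(0.2, 0.5, 0.8)) {
    n_rep <- 5
    sigma_p <- 0.015
    draws <- matrix(pbar + rnorm(10000 * n_rep, sd = sigma_p), ncol = n_rep)
    y <- log(rowMeans(draws) / (1 - rowMeans(draws)))
    # formula value at the true mean, with the true replicate variance
    sigma_formula <- sqrt((1 / n_rep) * (1 / (pbar - pbar^2))^2 * sigma_p^2)
    expect_equal(sd(y), sigma_formula, tolerance = 0.1)
  }
})

test_that("validation rejects degenerate replicate structures", {
  expect_error(lnkeq_from_replicates(open_prob_table(c(300, 310, 310),
                                                     c(0.5, 0.4, 0.6))),
               "fewer than 2 replicates")
  expect_error(lnkeq_from_replicates(open_prob_table(rep(300, 3),
                                                     rep(0.7, 3))),
               "zero replicate variance")
  tab <- open_prob_table(rep(c(300, 310), each = 2),
                         c(0.9985, 0.9995, 0.4, 0.6))
  expect_warning(s <- lnkeq_from_replicates(tab), "outside \\(0.01, 0.99\\)")
  expect_equal(nrow(s), 1)
  expect_error(suppressWarnings(
    lnkeq_from_replicates(open_prob_table(rep(300, 2), c(0.9985, 0.9995)))),
    "filtered out")
})

test_that("series construction validates and normalizes", {
  s <- vanthoff_series(c(310, 300, 320), c(1, 0, 2), c(0.1, 0.2, 0.3))
  expect_equal(s$temperature, c(300, 310, 320)) # sorted
  expect_equal(s$sigma, c(0.2, 0.1, 0.3))       # carried along
  sc <- vanthoff_series(c(25, 30), c(0, 1), c(0.1, 0.1),
                        temperature_unit = "C")
  expect_equal(sc$temperature, c(298.15, 303.15))
  expect_error(vanthoff_series(c(300, 300), c(0, 1), c(0.1, 0.1)),
               "duplicate temperatures")
  expect_error(vanthoff_series(300, Inf, 0.1), "non-finite")
  expect_error(vanthoff_series(c(300, 310), c(0, 1), c(0.1, 0)),
               "strictly positive \\(rows: 2\\)")
  expect_true(attr(vanthoff_series(c(300, 310), c(0, 1)), "unit_weights"))
})

test_that("read_series parses lnKeq tables, units and delimiters", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature,lnKeq,sigma",
               "300,-1,0.1", "310,0,0.1", "320,1,0.1"), f)
  s <- read_series(f)
  expect_s3_class(s, "vanthoff_series")
  expect_equal(s$temperature, c(300, 310, 320))
  expect_equal(s$lnkeq, c(-1, 0, 1))

  fc <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature,lnKeq,sigma", "25,-1,0.1", "30,0,0.1"), fc)
  expect_equal(read_series(fc, temperature_unit = "C")$temperature,
               c(298.15, 303.15))

  ft <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("temperature\tlnKeq\tsigma", "300\t-1\t0.1", "310\t0\t0.1"),
             ft)
  expect_equal(read_series(ft)$lnkeq, c(-1, 0))

  fbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature,lnKeq,sigma", "300,-1,0.1", "310,0,0"), fbad)
  expect_error(read_series(fbad), "rows: 2")

  fnn <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature,lnKeq,sigma", "300,abc,0.1"), fnn)
  expect_error(read_series(fnn), "non-numeric")

  expect_error(read_series("no/such/file.csv"), "not found")
})

test_that("read_series handles replicate tables, wide and long", {
  flong <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature,open_prob",
               "300,0.4", "300,0.6", "310,0.7", "310,0.8"), flong)
  tab <- read_series(flong)
  expect_s3_class(tab, "open_prob_table")
  expect_equal(nrow(tab), 4)

  fwide <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature,open_prob_1,open_prob_2",
               "300,0.4,0.6", "310,0.7,0.8"), fwide)
  tabw <- read_series(fwide)
  expect_s3_class(tabw, "open_prob_table")
  expect_equal(sort(tabw$open_prob), sort(tab$open_prob))

  fdup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temperature,open_prob_1,open_prob_2",
               "300,0.4,0.6", "300,0.7,0.8"), fdup)
  expect_error(read_series(fdup), "duplicate temperature rows")

  fmap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("temp_K,logK", "300,-1", "310,0"), fmap)
  s <- read_series(fmap, columns = c(temperature = "temp_K",
                                     lnKeq = "logK"))
  expect_equal(s$lnkeq, c(-1, 0))
  expect_error(read_series(fmap), "could not resolve|no 'temperature'")
})
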