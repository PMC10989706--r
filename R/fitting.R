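# Free-knot spline fitting of van 't Hoff data. For a candidate number of
# knot intervals N and a temperature scale, the weighted sum of squared
# residuals is minimized over the N-1 interior knot positions and the N+1
# knot values. The knot values enter the natural spline linearly, so for any
# interior-position candidate they are profiled out by weighted least
# squares; the optimizer only moves positions. Model selection across N and
# scale is by BIC.

#' Fitting configuration
#'
#' Collects every tunable of the free-knot fit and the model scan.
#'
#' @param scale `"auto"` (scan both), `"linear"` (fit coordinate `x = T`) or
#'   `"reciprocal"` (`x = 1/T`).
#' @param n_max Largest number of knot intervals N to scan; each candidate N
#'   additionally requires at least `2N + 1` data points.
#' @param multistart Number of optimizer starts per candidate with interior
#'   knots. Start 1 places interior knots at equally spaced quantiles of the
#'   data coordinate; the rest jitter the start with the seeded RNG.
#' @param seed Integer seed driving every random element of the fit.
#' @param min_sep_frac Minimum knot separation as a fraction of the data
#'   range (keeps iterates feasible via a monotone reparameterization).
#' @param chi2_tol Relative convergence tolerance on the objective.
#' @param bic_tie_tol BIC differences below this are treated as ties and
#'   broken in favour of fewer knots, then of the reciprocal scale.
#' @return A list of class `"fit_config"`.
#' @export
fit_config <- function(scale = c("auto", "linear", "reciprocal"),
                       n_max = 8L, multistart = 10L, seed = 1L,
                       min_sep_frac = 1e-3, chi2_tol = 1e-10,
                       bic_tie_tol = 1e-6) {
  scale <- match.arg(scale)
  stopifnot(n_max >= 1, multistart >= 1, min_sep_frac > 0,
            min_sep_frac < 0.5, chi2_tol > 0, bic_tie_tol >= 0)
  structure(list(scale = scale, n_max = as.integer(n_max),
                 multistart = as.integer(multistart), seed = as.integer(seed),
                 min_sep_frac = min_sep_frac, chi2_tol = chi2_tol,
                 bic_tie_tol = bic_tie_tol),
            class = "fit_config")
}

# Run code with a temporarily seeded RNG, restoring any prior state.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Map a series onto a fit coordinate
#'
#' Transforms temperatures to the fit coordinate: `x = T` (linear scale) or
#' `x = 1/T` (reciprocal scale). The output is sorted ascending in `x`; on
#' the reciprocal scale that reverses the temperature order. Standard errors
#' are untouched (the noise lives on `lnkeq`, not on the coordinate).
#'
#' @param series A [vanthoff_series()].
#' @param scale `"linear"` or `"reciprocal"`.
#' @return A list with elements `x`, `y`, `sigma`, `temperature` (sorted
#'   along with `x`), `scale` and `unit_weights`.
#' @export
transform_scale <- function(series, scale = c("linear", "reciprocal")) {
  scale <- match.arg(scale)
  stopifnot(inherits(series, "vanthoff_series"))
  t_k <- series$temperature
  if (any(t_k <= 0))
    stop("temperatures must be strictly positive")
  x <- if (scale == "linear") t_k else 1 / t_k
  ord <- order(x)
  list(x = x[ord], y = series$lnkeq[ord], sigma = series$sigma[ord],
       temperature = t_k[ord], scale = scale,
       unit_weights = isTRUE(attr(series, "unit_weights")))
}

#' Weighted residual sum of squares against a spline
#'
#' \deqn{\chi^2 = \sum_m \left(\frac{y_m - S(x_m)}{\sigma_m}\right)^2}
#'
#' @param data A transformed series as returned by [transform_scale()] (a
#'   list with `x`, `y`, `sigma`).
#' @param spline A `"natural_spline"` whose domain covers every `x`.
#' @return The chi-square value (dimensionless, non-negative).
#' @export
chi_squared <- function(data, spline) {
  sum(((data$y - spline_eval(spline, data$x)) / data$sigma)^2)
}

#' Bayesian information criterion for a fitted spline
#'
#' A spline with N knot intervals has 2N free parameters (N - 1 interior
#' positions plus N + 1 knot values). Reading the weighted residual sum of
#' squares as a Gaussian negative log-likelihood gives
#' \deqn{\mathrm{BIC} = \chi^2_{min} + 2N \ln(n),}
#' where \eqn{n} is the number of data points.
#'
#' @param chi2_min Minimized chi-square.
#' @param n_intervals Number of knot intervals N.
#' @param n_points Number of data points; must exceed `2 * n_intervals`.
#' @return The BIC value.
#' @examples
#' bic(10, 2, 11) # 10 + 4 * log(11)
#' @export
bic <- function(chi2_min, n_intervals, n_points) {
  stopifnot(chi2_min >= 0, n_intervals >= 1)
  if (n_points <= 2 * n_intervals)
    stop("n_points must exceed 2N = ", 2 * n_intervals,
         " (no residual degrees of freedom)")
  chi2_min + 2 * n_intervals * log(n_points)
}

# Monotone reparameterization of interior knot positions. z (length N-1,
# unconstrained) maps through softmax gap weights to strictly increasing
# positions with gaps >= eps * range. Inverse used to build starts.
.z_to_inner <- function(z, x0, x1, eps) {
  n <- length(z) + 1L                     # number of gaps
  w <- exp(c(z, 0) - max(c(z, 0)))
  frac <- eps + (1 - n * eps) * w / sum(w)
  x0 + (x1 - x0) * cumsum(frac)[-n]
}

.inner_to_z <- function(inner, x0, x1, eps) {
  n <- length(inner) + 1L
  gaps <- diff(c(x0, inner, x1)) / (x1 - x0)
  gaps <- pmax(gaps, eps * 1.0000001)
  w <- (gaps - eps) / (1 - n * eps)
  w <- pmax(w, 1e-12)
  log(w[-n]) - log(w[n])
}

# Profiled chi-square: for fixed knot positions solve the weighted linear
# least-squares problem in the knot values via the cardinal basis.
.profile_fit <- function(positions, data) {
  bmat <- .natural_basis(positions, data$x)
  aw <- bmat / data$sigma
  bw <- data$y / data$sigma
  fit <- tryCatch(stats::.lm.fit(aw, bw), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients))
    return(list(chi2 = Inf, values = NULL))
  list(chi2 = sum(fit$residuals^2), values = fit$coefficients)
}

#' Fit a free-knot natural spline to a van 't Hoff series
#'
#' Minimizes the weighted residual sum of squares over the spline's free
#' parameters for a fixed number of knot intervals `n_intervals` and a fixed
#' temperature scale. The edge knots are pinned at the smallest and largest
#' data coordinate; the `n_intervals - 1` interior knot positions move
#' freely inside that interval (kept ordered and separated by a monotone
#' reparameterization), and the `n_intervals + 1` knot values are profiled
#' out exactly by weighted least squares at every candidate position set.
#' Multiple optimizer starts guard against the multimodality of free-knot
#' problems; the best local minimum over all starts is returned.
#'
#' @param series A [vanthoff_series()] with at least `2 * n_intervals + 1`
#'   points.
#' @param n_intervals Number of knot intervals N (so `n_intervals + 1`
#'   knots).
#' @param scale `"linear"` or `"reciprocal"`.
#' @param config A [fit_config()].
#' @param warm_start Optional `"natural_spline"` used as one extra start
#'   (its knots, refined by one, when it has fewer intervals). Used by
#'   [select_model()] so that the attainable chi-square never increases
#'   with N.
#' @return An object of class `"vh_fit"`: a list with the optimized
#'   [knot_set()], the fitted `"natural_spline"`, `chi2_min`, `n_params`,
#'   `bic`, a convergence flag and the per-start chi-square log.
#' @export
fit_free_knot_spline <- function(series, n_intervals,
                                 scale = c("reciprocal", "linear"),
                                 config = fit_config(),
                                 warm_start = NULL) {
  scale <- match.arg(scale)
  stopifnot(inherits(series, "vanthoff_series"))
  n_intervals <- as.integer(n_intervals)
  n_pts <- nrow(series)
  if (n_intervals < 1)
    stop("'n_intervals' must be at least 1")
  if (n_pts < 2 * n_intervals + 1)
    stop("need at least ", 2 * n_intervals + 1, " data points for N = ",
         n_intervals, " (got ", n_pts, ")")
  data <- transform_scale(series, scale)
  x0 <- data$x[1]; x1 <- data$x[length(data$x)]
  eps <- config$min_sep_frac

  # final knot_set built with a hair of slack: the reparameterization can
  # land a gap exactly on the eps bound up to rounding
  eps_chk <- eps * (1 - 1e-6)

  if (n_intervals == 1L) {
    # no interior knots: the natural 2-knot spline is a straight line and
    # the fit is closed-form weighted least squares
    pf <- .profile_fit(c(x0, x1), data)
    knots <- knot_set(c(x0, x1), pf$values, min_sep_frac = eps_chk)
    starts <- data.frame(start = 1L, chi2 = pf$chi2, converged = TRUE)
    best_chi2 <- pf$chi2
    best_pos <- c(x0, x1); best_val <- pf$values
    converged <- is.finite(pf$chi2)
  } else {
    d <- n_intervals - 1L
    objective <- function(z) {
      .profile_fit(c(x0, .z_to_inner(z, x0, x1, eps), x1), data)$chi2
    }
    z_starts <- .with_seed(config$seed, {
      q1 <- x0 + (x1 - x0) * seq_len(d) / n_intervals
      z0 <- .inner_to_z(q1, x0, x1, eps)
      zs <- list(z0)
      if (config$multistart > 1)
        for (j in seq_len(config$multistart - 1L))
          zs[[j + 1L]] <- z0 + stats::rnorm(d, sd = 1)
      zs
    })
    if (!is.null(warm_start)) {
      ws <- warm_start
      if (length(ws$positions) == n_intervals)   # one interval fewer: refine
        ws <- insert_knot(ws, .widest_gap_mid(ws$positions))
      if (length(ws$positions) == n_intervals + 1L) {
        inner <- ws$positions[-c(1, length(ws$positions))]
        inner <- pmin(pmax(inner, x0 + 1.5 * eps * (x1 - x0)),
                      x1 - 1.5 * eps * (x1 - x0))
        if (all(diff(c(x0, sort(inner), x1)) > eps * (x1 - x0)))
          z_starts[[length(z_starts) + 1L]] <-
            .inner_to_z(sort(inner), x0, x1, eps)
      }
    }
    best_chi2 <- Inf; best_z <- z_starts[[1]]
    log_chi2 <- numeric(length(z_starts))
    log_conv <- logical(length(z_starts))
    for (j in seq_along(z_starts)) {
      start_val <- objective(z_starts[[j]])
      opt <- tryCatch(
        stats::nlminb(z_starts[[j]], objective,
                      control = list(rel.tol = config$chi2_tol,
                                     iter.max = 500, eval.max = 1000)),
        error = function(e) NULL)
      if (is.null(opt) || !is.finite(opt$objective) ||
          opt$objective > start_val) {
        cand <- start_val; cand_z <- z_starts[[j]]
        log_conv[j] <- FALSE
      } else {
        cand <- opt$objective; cand_z <- opt$par
        log_conv[j] <- opt$convergence == 0 || is.finite(opt$objective)
      }
      log_chi2[j] <- cand
      if (cand < best_chi2) { best_chi2 <- cand; best_z <- cand_z }
    }
    starts <- data.frame(start = seq_along(z_starts), chi2 = log_chi2,
                         converged = log_conv)
    best_pos <- c(x0, .z_to_inner(best_z, x0, x1, eps), x1)
    pf <- .profile_fit(best_pos, data)
    best_chi2 <- pf$chi2; best_val <- pf$values
    converged <- any(log_conv) && is.finite(best_chi2)
    knots <- knot_set(best_pos, best_val, min_sep_frac = eps_chk)
  }

  if (!converged)
    warning("free-knot fit did not converge for N = ", n_intervals,
            " on the ", scale, " scale")
  spline <- natural_spline(knots)
  structure(list(scale = scale,
                 knots = knots,
                 spline = spline,
                 chi2_min = best_chi2,
                 n_intervals = n_intervals,
                 n_params = 2L * n_intervals,
                 n_points = n_pts,
                 bic = bic(best_chi2, n_intervals, n_pts),
                 converged = converged,
                 starts = starts,
                 unit_weights = data$unit_weights,
                 data_x = data$x,
                 temperature_range = range(series$temperature)),
            class = "vh_fit")
}

.widest_gap_mid <- function(positions) {
  gaps <- diff(positions)
  i <- which.max(gaps)
  positions[i] + gaps[i] / 2
}

#' @export
print.vh_fit <- function(x, ...) {
  cat(sprintf(
    "free-knot van 't Hoff fit: %s scale, N = %d intervals (%d knots)\n",
    x$scale, x$n_intervals, x$n_intervals + 1L))
  cat(sprintf("  chi2_min = %.6g, BIC = %.6g, converged: %s\n",
              x$chi2_min, x$bic, x$converged))
  if (isTRUE(x$unit_weights))
    cat("  unit weights: chi2 and BIC are relative-only\n")
  invisible(x)
}

#' Scan knot counts and temperature scales, select the best model by BIC
#'
#' Fits every candidate (N, scale) combination — N from 1 up to the smaller
#' of `config$n_max` and `(n_points - 1) / 2`, both temperature scales under
#' `scale = "auto"` — and returns all fits together with the BIC table and
#' the selected model. Within each scale, each fit with N intervals also
#' seeds one optimizer start by refining the best fit with N - 1 intervals
#' (knot insertion leaves the attained function unchanged), so chi-square is
#' non-increasing in N. BIC ties within `config$bic_tie_tol` are broken in
#' favour of fewer knots, then of the reciprocal scale.
#'
#' On physiological temperature spans a linear and a reciprocal temperature
#' dependence are practically indistinguishable, so the full candidate table
#' is always retained for inspection rather than only the winner.
#'
#' @param series A [vanthoff_series()] with at least 3 points.
#' @param config A [fit_config()].
#' @return An object of class `"model_selection"`: a list with `fits` (all
#'   `"vh_fit"` objects), `table` (one row per candidate), `selected` (index
#'   into `fits`), `fit` (the selected `"vh_fit"`) and `config`.
#' @export
select_model <- function(series, config = fit_config()) {
  stopifnot(inherits(series, "vanthoff_series"))
  n_pts <- nrow(series)
  if (n_pts < 3)
    stop("at least 3 data points are needed to fit even the N = 1 model")
  scales <- if (config$scale == "auto") c("linear", "reciprocal")
            else config$scale
  n_hi <- min(config$n_max, (n_pts - 1L) %/% 2L)
  fits <- list()
  for (sc in scales) {
    prev <- NULL
    for (n_int in seq_len(n_hi)) {
      fit <- fit_free_knot_spline(series, n_int, sc, config,
                                  warm_start = prev)
      fits[[length(fits) + 1L]] <- fit
      prev <- fit$spline
    }
  }
  tab <- data.frame(
    scale = vapply(fits, `[[`, character(1), "scale"),
    n_intervals = vapply(fits, `[[`, integer(1), "n_intervals"),
    n_params = vapply(fits, `[[`, integer(1), "n_params"),
    chi2_min = vapply(fits, `[[`, numeric(1), "chi2_min"),
    bic = vapply(fits, `[[`, numeric(1), "bic"),
    converged = vapply(fits, `[[`, logical(1), "converged"))
  ok <- which(tab$converged)
  if (!length(ok))
    stop("no candidate model converged")
  tie <- ok[tab$bic[ok] <= min(tab$bic[ok]) + config$bic_tie_tol]
  tie <- tie[tab$n_intervals[tie] == min(tab$n_intervals[tie])]
  if (length(tie) > 1 && any(tab$scale[tie] == "reciprocal"))
    tie <- tie[tab$scale[tie] == "reciprocal"]
  selected <- tie[1]
  structure(list(fits = fits, table = tab, selected = selected,
                 fit = fits[[selected]], config = config,
                 relative_only = isTRUE(fits[[selected]]$unit_weights)),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("van 't Hoff model selection (BIC; smaller is better)\n")
  tab <- x$table
  tab$selected <- ifelse(seq_len(nrow(tab)) == x$selected, "*", "")
  print(tab, row.names = FALSE, ...)
  if (isTRUE(x$relative_only))
    cat("note: no standard errors supplied; BIC comparisons are relative only\n")
  cat(sprintf("selected: %s scale, N = %d intervals (%d knots)\n",
              x$fit$scale, x$fit$n_intervals, x$fit$n_intervals + 1L))
  invisible(x)
}

#' Write a model-selection report to JSON
#'
#' Serializes the full candidate table (scale, N, chi-square, parameter
#' count, BIC, convergence, knot coordinates), the selected index and an
#' echo of the configuration including the seed, so that every number in
#' the report can be regenerated by calling the fitting functions directly.
#'
#' @param selection A `"model_selection"`.
#' @param path Output file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_selection_json <- function(selection, path = NULL) {
  stopifnot(inherits(selection, "model_selection"))
  cand <- lapply(selection$fits, function(f) {
    list(scale = f$scale, n_intervals = f$n_intervals,
         n_params = f$n_params, chi2_min = f$chi2_min, bic = f$bic,
         converged = f$converged,
         knots = list(positions = f$knots$positions,
                      values = f$knots$values))
  })
  obj <- list(candidates = cand,
              selected = selection$selected,
              relative_only = isTRUE(selection$relative_only),
              config = unclass(selection$config))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
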