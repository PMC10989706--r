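# Natural cubic splines parameterized by knot coordinates. The interpolant
# through a given set of (position, value) pairs with vanishing second
# derivative at both edge knots is unique; all fitting in this package moves
# knot coordinates and rebuilds this interpolant.

#' Construct a knot set
#'
#' A knot set is the parameterization of every spline in this package: knot
#' positions \eqn{s_0 < s_1 < \dots < s_N} in the fit coordinate and the
#' spline values at those positions. Positions must be strictly increasing
#' with a minimum separation of `min_sep_frac` times the total range, which
#' keeps the interpolation problem well conditioned.
#'
#' @param positions Strictly increasing numeric vector, length at least 2.
#' @param values Numeric vector of spline values at `positions`.
#' @param min_sep_frac Minimum allowed knot separation as a fraction of the
#'   range (default `1e-3`).
#' @return A list of class `"knot_set"` with elements `positions` and
#'   `values`.
#' @export
knot_set <- function(positions, values, min_sep_frac = 1e-3) {
  positions <- as.numeric(positions)
  values <- as.numeric(values)
  if (length(positions) < 2)
    stop("a knot set needs at least 2 knots (one interval)")
  if (length(values) != length(positions))
    stop("'values' must match the length of 'positions'")
  if (anyNA(positions) || anyNA(values))
    stop("missing values in knot coordinates")
  gaps <- diff(positions)
  rng <- positions[length(positions)] - positions[1]
  if (any(gaps <= 0))
    stop("knot positions must be strictly increasing")
  if (any(gaps < min_sep_frac * rng))
    stop("knot separation below ", min_sep_frac, " of the range; ",
         "nearly coincident knots make the spline ill-conditioned")
  structure(list(positions = positions, values = values),
            class = "knot_set")
}

#' @export
print.knot_set <- function(x, ...) {
  cat(sprintf("knot set: %d knots (%d intervals) on [%g, %g]\n",
              length(x$positions), length(x$positions) - 1L,
              x$positions[1], x$positions[length(x$positions)]))
  print(data.frame(position = x$positions, value = x$values), ...)
  invisible(x)
}

# Second derivatives M_i at the knots of the natural cubic interpolant,
# by the Thomas algorithm on the standard tridiagonal system
#   (h_{i-1}/6) M_{i-1} + ((h_{i-1}+h_i)/3) M_i + (h_i/6) M_{i+1}
#     = (v_{i+1}-v_i)/h_i - (v_i-v_{i-1})/h_{i-1},   M_0 = M_N = 0.
# `values` may be a matrix (one column per interpolation problem sharing the
# same positions); returns a matrix of the same shape.
.natural_m2 <- function(positions, values) {
  values <- as.matrix(values)
  k <- length(positions)
  m <- matrix(0, k, ncol(values))
  if (k > 2) {
    h <- diff(positions)
    slopes <- diff(values) / h
    d <- (h[-(k - 1)] + h[-1]) / 3            # diagonal, length k-2
    e <- h[2:(k - 2 + 1)][-(k - 2)] / 6       # off-diagonals h_i/6, i=2..k-2
    rhs <- slopes[-1, , drop = FALSE] - slopes[-(k - 1), , drop = FALSE]
    n <- k - 2
    if (n == 1) {
      m[2, ] <- rhs[1, ] / d[1]
    } else {
      # forward sweep
      cp <- numeric(n - 1)
      dp <- d
      for (i in 2:n) {
        w <- e[i - 1] / dp[i - 1]
        dp[i] <- d[i] - w * e[i - 1]
        rhs[i, ] <- rhs[i, ] - w * rhs[i - 1, ]
        cp[i - 1] <- w
      }
      sol <- matrix(0, n, ncol(values))
      sol[n, ] <- rhs[n, ] / dp[n]
      for (i in (n - 1):1)
        sol[i, ] <- (rhs[i, ] - e[i] * sol[i + 1, ]) / dp[i]
      m[2:(k - 1), ] <- sol
    }
  }
  m
}

#' Build the natural cubic spline through a knot set
#'
#' Returns the unique twice continuously differentiable piecewise-cubic
#' interpolant through the knot coordinates whose second derivative vanishes
#' at both edge knots (natural boundary conditions). The knot second
#' derivatives are obtained by an O(N) forward/backward sweep of the standard
#' tridiagonal system.
#'
#' @param knots A [knot_set()], or a numeric vector of positions when
#'   `values` is also given.
#' @param values Spline values at the positions (only when `knots` is a bare
#'   position vector).
#' @param min_sep_frac Passed to [knot_set()] when constructing from bare
#'   vectors.
#' @return An object of class `"natural_spline"` with elements `positions`,
#'   `values` and `m2` (second derivatives at the knots; first and last are
#'   exactly zero).
#' @examples
#' sp <- natural_spline(c(0, 1, 2), c(0, 1, 0))
#' spline_eval(sp, 0.5)      # 0.6875
#' spline_eval(sp, 1, 2)     # -3
#' @export
natural_spline <- function(knots, values = NULL, min_sep_frac = 1e-3) {
  if (!inherits(knots, "knot_set"))
    knots <- knot_set(knots, values, min_sep_frac = min_sep_frac)
  m2 <- .natural_m2(knots$positions, knots$values)[, 1]
  structure(list(positions = knots$positions, values = knots$values,
                 m2 = m2),
            class = "natural_spline")
}

#' @export
print.natural_spline <- function(x, ...) {
  cat(sprintf("natural cubic spline: %d knots on [%g, %g]\n",
              length(x$positions), x$positions[1],
              x$positions[length(x$positions)]))
  invisible(x)
}

#' Evaluate a natural spline or its derivatives
#'
#' Evaluates \eqn{S}, \eqn{S'} or \eqn{S''} at points inside the spline
#' domain \eqn{[s_0, s_N]}. Points outside the domain are an error: the edge
#' knots are pinned to the data extremes during fitting, so nothing outside
#' the domain is ever constrained by data and silent extrapolation would be
#' misleading.
#'
#' @param spline A `"natural_spline"`.
#' @param x Numeric evaluation points.
#' @param deriv Derivative order: 0, 1 or 2.
#' @return Numeric vector of the same length as `x`.
#' @export
spline_eval <- function(spline, x, deriv = 0L) {
  stopifnot(inherits(spline, "natural_spline"))
  deriv <- as.integer(deriv)
  if (!deriv %in% 0:2)
    stop("'deriv' must be 0, 1 or 2")
  s <- spline$positions; v <- spline$values; m <- spline$m2
  k <- length(s)
  rng <- s[k] - s[1]
  tol <- 1e-9 * rng
  out_of_range <- x < s[1] - tol | x > s[k] + tol
  if (any(out_of_range))
    stop("evaluation points outside the spline domain [",
         format(s[1]), ", ", format(s[k]), "]: ",
         paste(format(x[out_of_range]), collapse = ", "))
  x <- pmin(pmax(x, s[1]), s[k])
  i <- findInterval(x, s, rightmost.closed = TRUE)
  i[i >= k] <- k - 1L
  h <- s[i + 1] - s[i]
  a <- (s[i + 1] - x) / h
  b <- (x - s[i]) / h
  if (deriv == 0L) {
    a * v[i] + b * v[i + 1] +
      ((a^3 - a) * m[i] + (b^3 - b) * m[i + 1]) * h^2 / 6
  } else if (deriv == 1L) {
    (v[i + 1] - v[i]) / h -
      (3 * a^2 - 1) * h / 6 * m[i] + (3 * b^2 - 1) * h / 6 * m[i + 1]
  } else {
    a * m[i] + b * m[i + 1]
  }
}

#' Piecewise polynomial coefficients of a natural spline
#'
#' Returns, for each interval \eqn{[s_{i-1}, s_i]}, the coefficients
#' \eqn{a_0, \dots, a_3} of
#' \eqn{S_i(x) = \sum_n a_n (x - s_{i-1})^n}.
#'
#' @param spline A `"natural_spline"`.
#' @return A numeric matrix with one row per interval and columns
#'   `a0`..`a3`.
#' @export
spline_coefs <- function(spline) {
  stopifnot(inherits(spline, "natural_spline"))
  s <- spline$positions; v <- spline$values; m <- spline$m2
  k <- length(s)
  h <- diff(s)
  i <- seq_len(k - 1)
  a0 <- v[i]
  a1 <- (v[i + 1] - v[i]) / h - h / 6 * (2 * m[i] + m[i + 1])
  a2 <- m[i] / 2
  a3 <- (m[i + 1] - m[i]) / (6 * h)
  matrix(c(a0, a1, a2, a3), ncol = 4,
         dimnames = list(NULL, c("a0", "a1", "a2", "a3")))
}

#' Insert a knot into a natural spline without changing its shape
#'
#' Adds a knot at `x_new` with value \eqn{S(x_{new})} and rebuilds. Because
#' the original spline is itself a twice continuously differentiable
#' piecewise cubic with natural boundary conditions on the refined knot
#' sequence, the rebuilt interpolant reproduces the original function
#' exactly (uniqueness of the natural interpolant). Used to warm-start fits
#' with one more knot interval.
#'
#' @param spline A `"natural_spline"`.
#' @param x_new Position of the new knot, strictly inside the domain and not
#'   coincident with an existing knot.
#' @return A `"natural_spline"` with one more knot.
#' @export
insert_knot <- function(spline, x_new) {
  stopifnot(inherits(spline, "natural_spline"), length(x_new) == 1)
  s <- spline$positions
  if (x_new <= s[1] || x_new >= s[length(s)])
    stop("new knot must lie strictly inside the spline domain")
  v_new <- spline_eval(spline, x_new)
  pos <- sort(c(s, x_new))
  vals <- numeric(length(pos))
  vals[match(s, pos)] <- spline$values
  vals[match(x_new, pos)] <- v_new
  # refinement preserves the function, so only guard against coincidence,
  # not the fitting parameterization's separation fraction
  natural_spline(pos, vals, min_sep_frac = 1e-9)
}

# Cardinal natural-spline basis: matrix B with B[m, j] = C_j(x_m), where C_j
# is the natural spline through value 1 at knot j and 0 elsewhere. The
# interpolant through values v is then B %*% v; chi-square is quadratic in v.
.natural_basis <- function(positions, x) {
  k <- length(positions)
  m2 <- .natural_m2(positions, diag(k))
  s <- positions
  i <- findInterval(x, s, rightmost.closed = TRUE)
  i[i >= k] <- k - 1L
  i[i < 1L] <- 1L
  h <- s[i + 1] - s[i]
  a <- (s[i + 1] - x) / h
  b <- (x - s[i]) / h
  bmat <- matrix(0, length(x), k)
  idx <- cbind(seq_along(x), i)
  bmat[idx] <- a
  bmat[cbind(seq_along(x), i + 1L)] <- bmat[cbind(seq_along(x), i + 1L)] + b
  wm_lo <- (a^3 - a) * h^2 / 6
  wm_hi <- (b^3 - b) * h^2 / 6
  bmat + wm_lo * m2[i, , drop = FALSE] + wm_hi * m2[i + 1L, , drop = FALSE]
}

#' Serialize a natural spline to JSON
#'
#' The spline is stored as knot positions and values only; the piecewise
#' coefficients are recomputed on load, so the serialized form is exactly
#' the fit parameterization.
#'
#' @param spline A `"natural_spline"`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
spline_to_json <- function(spline, path = NULL) {
  stopifnot(inherits(spline, "natural_spline"))
  js <- jsonlite::toJSON(list(positions = spline$positions,
                              values = spline$values),
                         digits = NA, auto_unbox = FALSE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a natural spline from JSON
#'
#' @param json A JSON string or path to a JSON file produced by
#'   [spline_to_json()].
#' @return A `"natural_spline"`.
#' @export
spline_from_json <- function(json) {
  obj <- if (length(json) == 1 && file.exists(json))
    jsonlite::fromJSON(json) else jsonlite::fromJSON(json)
  natural_spline(obj$positions, obj$values)
}
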