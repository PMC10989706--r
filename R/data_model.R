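# Containers and I/O for equilibrium-constant series and replicate
# open-probability tables. Temperatures are Kelvin-only internally; the unit
# of an input file is declared, never guessed.

# molar gas constant, J mol^-1 K^-1 (CODATA exact value)
.RGAS <- 8.31446261815324

#' Molar gas constant
#'
#' Returns the molar gas constant R used throughout the package,
#' 8.31446261815324 J mol^-1 K^-1.
#'
#' @return A length-one numeric, in J/(mol K).
#' @export
gas_constant <- function() .RGAS

#' Construct a van 't Hoff series
#'
#' A van 't Hoff series holds measurements of the natural logarithm of a
#' two-state equilibrium constant, \eqn{y_m = \ln K_{eq}(T_m)}, together with
#' the standard error of each value. It is the observable every fit in this
#' package consumes. Rows are sorted by temperature and temperatures must be
#' unique.
#'
#' @param temperature Numeric vector of absolute temperatures. Interpreted in
#'   the unit given by `temperature_unit` and stored in Kelvin.
#' @param lnkeq Numeric vector of \eqn{\ln K_{eq}} values (dimensionless),
#'   finite.
#' @param sigma Numeric vector of strictly positive standard errors of
#'   `lnkeq`, or `NULL`. When `NULL`, unit weights are used and any model
#'   comparison downstream is flagged as relative-only.
#' @param temperature_unit `"K"` or `"C"`. Celsius values are converted with
#'   \eqn{T_K = T_C + 273.15}.
#' @param provenance Free-text origin of the values, e.g. `"lnkeq"` for
#'   directly measured values or `"open_prob"` for values converted from
#'   replicate open probabilities.
#'
#' @return A data frame of class `"vanthoff_series"` with columns
#'   `temperature` (K), `lnkeq` and `sigma`, and attributes
#'   `temperature_unit_origin`, `provenance` and `unit_weights`.
#' @examples
#' vanthoff_series(c(300, 310, 320), c(-1, 0, 1), c(0.1, 0.1, 0.1))
#' @export
vanthoff_series <- function(temperature, lnkeq, sigma = NULL,
                            temperature_unit = c("K", "C"),
                            provenance = "lnkeq") {
  temperature_unit <- match.arg(temperature_unit)
  temperature <- as.numeric(temperature)
  lnkeq <- as.numeric(lnkeq)
  if (length(temperature) != length(lnkeq))
    stop("'temperature' and 'lnkeq' must have the same length")
  if (temperature_unit == "C")
    temperature <- temperature + 273.15
  if (anyNA(temperature) || anyNA(lnkeq))
    stop("missing values in 'temperature' or 'lnkeq'")
  if (any(temperature <= 0))
    stop("all temperatures must be > 0 K (rows: ",
         paste(which(temperature <= 0), collapse = ", "), ")")
  if (any(!is.finite(lnkeq)))
    stop("non-finite lnKeq values (rows: ",
         paste(which(!is.finite(lnkeq)), collapse = ", "),
         "); open probabilities of exactly 0 or 1 cannot be used")
  unit_weights <- is.null(sigma)
  if (unit_weights) {
    sigma <- rep(1, length(lnkeq))
  } else {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(lnkeq))
      stop("'sigma' must match the length of 'lnkeq'")
    if (anyNA(sigma) || any(sigma <= 0))
      stop("standard errors must be strictly positive (rows: ",
           paste(which(is.na(sigma) | sigma <= 0), collapse = ", "), ")")
  }
  if (anyDuplicated(temperature))
    stop("duplicate temperatures: ",
         paste(unique(temperature[duplicated(temperature)]), collapse = ", "),
         " K; aggregate replicates first (see lnkeq_from_replicates)")
  ord <- order(temperature)
  out <- data.frame(temperature = temperature[ord],
                    lnkeq = lnkeq[ord],
                    sigma = sigma[ord])
  structure(out,
            class = c("vanthoff_series", "data.frame"),
            temperature_unit_origin = temperature_unit,
            provenance = provenance,
            unit_weights = unit_weights)
}

#' @export
print.vanthoff_series <- function(x, ...) {
  cat(sprintf("van 't Hoff series: %d temperatures, %.2f-%.2f K (%s)\n",
              nrow(x), min(x$temperature), max(x$temperature),
              attr(x, "provenance")))
  if (isTRUE(attr(x, "unit_weights")))
    cat("  no standard errors supplied: unit weights (relative chi-square only)\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Construct a replicate open-probability table
#'
#' Long-format table of replicate open-probability measurements: one row per
#' (temperature, replicate). Open probabilities must lie strictly inside
#' (0, 1); values of exactly 0 or 1 carry no finite log-odds and are rejected.
#'
#' @param temperature Numeric vector of absolute temperatures (unit per
#'   `temperature_unit`), repeated across replicates.
#' @param open_prob Numeric vector of open probabilities in (0, 1).
#' @param temperature_unit `"K"` or `"C"`.
#'
#' @return A data frame of class `"open_prob_table"` with columns
#'   `temperature` (K) and `open_prob`.
#' @examples
#' open_prob_table(rep(c(300, 310), each = 3),
#'                 c(0.2, 0.25, 0.22, 0.6, 0.55, 0.65))
#' @export
open_prob_table <- function(temperature, open_prob,
                            temperature_unit = c("K", "C")) {
  temperature_unit <- match.arg(temperature_unit)
  temperature <- as.numeric(temperature)
  open_prob <- as.numeric(open_prob)
  if (length(temperature) != length(open_prob))
    stop("'temperature' and 'open_prob' must have the same length")
  if (temperature_unit == "C")
    temperature <- temperature + 273.15
  if (anyNA(temperature) || anyNA(open_prob))
    stop("missing values in open-probability table")
  if (any(temperature <= 0))
    stop("all temperatures must be > 0 K")
  bad <- which(open_prob <= 0 | open_prob >= 1)
  if (length(bad))
    stop("open probabilities must lie strictly in (0, 1) (rows: ",
         paste(bad, collapse = ", "), ")")
  ord <- order(temperature)
  structure(data.frame(temperature = temperature[ord],
                       open_prob = open_prob[ord]),
            class = c("open_prob_table", "data.frame"),
            temperature_unit_origin = temperature_unit)
}

#' @export
print.open_prob_table <- function(x, ...) {
  nt <- length(unique(x$temperature))
  cat(sprintf("open-probability table: %d measurements at %d temperatures\n",
              nrow(x), nt))
  print.data.frame(x, ...)
  invisible(x)
}

#' Equilibrium constant from open probability
#'
#' For a two-state channel the equilibrium constant between the open and
#' closed state is \eqn{K_{eq} = P/(1-P)} where \eqn{P} is the open
#' probability. Strictly increasing in \eqn{P}; defined only on (0, 1).
#'
#' @param p Open probabilities in (0, 1).
#' @return \eqn{K_{eq}} values (dimensionless).
#' @seealso [open_prob_from_keq()] for the inverse.
#' @examples
#' keq_from_open_prob(0.5) # 1
#' keq_from_open_prob(0.9) # 9
#' @export
keq_from_open_prob <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p <= 0 | p >= 1))
    stop("open probability must lie strictly in (0, 1)")
  p / (1 - p)
}

#' Open probability from equilibrium constant
#'
#' Inverse of [keq_from_open_prob()]: \eqn{P = K_{eq}/(1+K_{eq})}.
#'
#' @param keq Strictly positive equilibrium constants.
#' @return Open probabilities in (0, 1).
#' @export
open_prob_from_keq <- function(keq) {
  keq <- as.numeric(keq)
  if (anyNA(keq) || any(keq <= 0))
    stop("equilibrium constant must be strictly positive")
  keq / (1 + keq)
}

#' Convert replicate open probabilities to a van 't Hoff series
#'
#' For each temperature with \eqn{N_m \ge 2} replicates, computes the sample
#' mean \eqn{\bar P_m} and unbiased sample variance
#' \eqn{\tilde\sigma_m^2} of the replicates, sets
#' \eqn{y_m = \ln(\bar P_m / (1 - \bar P_m))}, and propagates the replicate
#' scatter to the log equilibrium constant via the delta method:
#' \deqn{\sigma_m = \sqrt{\frac{1}{N_m}
#'   \left(\frac{1}{\bar P_m - \bar P_m^2}\right)^2 \tilde\sigma_m^2}.}
#'
#' Macroscopic currents carry non-gating variability near the extremes of the
#' temperature range, where channels are almost always closed or almost
#' always open. Temperatures whose mean open probability falls outside
#' `p_bounds` are therefore dropped, with a warning naming each dropped
#' temperature.
#'
#' @param table An [open_prob_table()].
#' @param p_bounds Length-two numeric `(p_min, p_max)` filter on the mean
#'   open probability, or `NULL` to disable filtering. Default `c(0.01, 0.99)`.
#'
#' @return A [vanthoff_series()] with provenance `"open_prob"`.
#' @examples
#' tab <- open_prob_table(rep(300, 3), c(0.4, 0.5, 0.6))
#' lnkeq_from_replicates(tab) # y = 0, sigma ~= 0.231
#' @export
lnkeq_from_replicates <- function(table, p_bounds = c(0.01, 0.99)) {
  if (!inherits(table, "open_prob_table"))
    table <- open_prob_table(table$temperature, table$open_prob)
  if (!is.null(p_bounds)) {
    if (length(p_bounds) != 2 || p_bounds[1] >= p_bounds[2])
      stop("'p_bounds' must be c(p_min, p_max) with p_min < p_max")
  }
  t_k <- sort(unique(table$temperature))
  # group by index, not by name: character round trips lose precision
  grp <- split(table$open_prob, match(table$temperature, t_k))
  n_m <- lengths(grp)
  if (any(n_m < 2))
    stop("temperatures with fewer than 2 replicates cannot yield a standard ",
         "error and are not imputed: ",
         paste(format(t_k[n_m < 2]), collapse = ", "), " K")
  pbar <- vapply(grp, mean, numeric(1))
  keep <- rep(TRUE, length(pbar))
  if (!is.null(p_bounds)) {
    keep <- pbar > p_bounds[1] & pbar < p_bounds[2]
    if (any(!keep))
      warning("dropped ", sum(!keep), " temperature(s) with mean open ",
              "probability outside (", p_bounds[1], ", ", p_bounds[2], "): ",
              paste(format(t_k[!keep]), collapse = ", "), " K")
    if (!any(keep))
      stop("all temperatures were filtered out by 'p_bounds'")
  }
  svar <- vapply(grp, stats::var, numeric(1)) # unbiased, N_m - 1 denominator
  t_k <- t_k[keep]; n_m <- n_m[keep]; pbar <- pbar[keep]; svar <- svar[keep]
  if (any(svar == 0))
    stop("zero replicate variance at ",
         paste(format(t_k[svar == 0]), collapse = ", "),
         " K: standard errors must be strictly positive")
  y <- log(pbar / (1 - pbar))
  sigma <- sqrt((1 / n_m) * (1 / (pbar - pbar^2))^2 * svar)
  vanthoff_series(t_k, y, sigma, provenance = "open_prob")
}

# Resolve a canonical column name against a header, honouring a user mapping.
.resolve_col <- function(canonical, header, columns) {
  if (!is.null(columns) && canonical %in% names(columns)) {
    if (!columns[[canonical]] %in% header)
      stop("mapped column '", columns[[canonical]], "' (for '", canonical,
           "') not found in file header")
    return(columns[[canonical]])
  }
  hit <- header[tolower(header) == tolower(canonical)]
  if (length(hit) > 1)
    stop("ambiguous columns for '", canonical, "'")
  if (length(hit) == 1) hit else NA_character_
}

#' Read a van 't Hoff data table from a delimited text file
#'
#' Reads a CSV/TSV table into either a [vanthoff_series()] (columns
#' `temperature`, `lnKeq` and optionally `sigma`) or an [open_prob_table()]
#' (long format: columns `temperature`, `open_prob`, one row per replicate;
#' or wide format with replicate columns named `open_prob_1`, `open_prob_2`,
#' ...). Column names are matched case-insensitively; non-canonical names can
#' be mapped through `columns`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param temperature_unit `"K"` or `"C"`; never guessed from the values.
#' @param delim Field delimiter. `NULL` (default) sniffs `\\t` versus `,`
#'   from the header line.
#' @param columns Optional named character vector mapping canonical names
#'   (`temperature`, `lnKeq`, `sigma`, `open_prob`) to the file's column
#'   names.
#'
#' @return A `vanthoff_series` or an `open_prob_table`, depending on which
#'   columns the file provides.
#' @examples
#' f <- system.file("extdata", "two_state_synthetic_lnkeq.csv",
#'                  package = "vanthoff")
#' read_series(f)
#' @export
read_series <- function(path, temperature_unit = c("K", "C"), delim = NULL,
                        columns = NULL) {
  temperature_unit <- match.arg(temperature_unit)
  if (!file.exists(path))
    stop("file not found: ", path)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          strip.white = TRUE)
  header <- names(df)
  t_col <- .resolve_col("temperature", header, columns)
  if (is.na(t_col))
    stop("no 'temperature' column found in ", path)
  lnk_col <- .resolve_col("lnKeq", header, columns)
  p_col <- .resolve_col("open_prob", header, columns)
  wide_p <- header[grepl("^open_prob[_.]?[0-9]+$", tolower(header))]

  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop("non-numeric values in column '", col, "' (rows: ",
           paste(bad, collapse = ", "), ")")
    v
  }

  if (!is.na(lnk_col)) {
    sig_col <- .resolve_col("sigma", header, columns)
    sigma <- if (!is.na(sig_col)) num(sig_col) else NULL
    vanthoff_series(num(t_col), num(lnk_col), sigma,
                    temperature_unit = temperature_unit)
  } else if (!is.na(p_col)) {
    open_prob_table(num(t_col), num(p_col),
                    temperature_unit = temperature_unit)
  } else if (length(wide_p)) {
    tt <- num(t_col)
    if (anyDuplicated(tt))
      stop("duplicate temperature rows in wide-format replicate table")
    reps <- lapply(wide_p, num)
    long_t <- rep(tt, times = length(wide_p))
    long_p <- unlist(reps, use.names = FALSE)
    ok <- !is.na(long_p)
    open_prob_table(long_t[ok], long_p[ok],
                    temperature_unit = temperature_unit)
  } else {
    stop("could not resolve columns in ", path,
         ": need 'lnKeq' or 'open_prob' next to 'temperature' ",
         "(or pass a 'columns' mapping)")
  }
}
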