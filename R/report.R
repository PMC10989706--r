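# Pipeline orchestration: read -> (convert) -> model scan -> curves ->
# report files. These functions add no computation of their own; every
# number they write is reproducible by calling the underlying functions
# with the echoed configuration.

#' Fit a van 't Hoff data set and write a report
#'
#' Reads a delimited table (or takes a ready series), converts replicate
#' open probabilities to ln Keq with propagated errors when needed, scans
#' knot counts and temperature scales with [select_model()], and writes
#' `report.json` (the full BIC candidate table plus the selected model and
#' configuration echo), `curves.csv` (thermodynamic curves of the selected
#' model) and, when the fitted range allows a 10 K step, `q10.csv`. With
#' `plot = TRUE` a `curves.pdf` with the standard panel layout is added.
#'
#' @param input Path to a CSV/TSV table, a [vanthoff_series()] or an
#'   [open_prob_table()].
#' @param output_dir Directory for the report files (created if missing).
#' @param config A [fit_config()].
#' @param temperature_unit `"K"` or `"C"`, used when `input` is a path.
#' @param p_bounds Mean open-probability filter passed to
#'   [lnkeq_from_replicates()] when the input holds replicates; ignored for
#'   ln Keq input.
#' @param grid_n Temperature-grid resolution for the curves (default 200).
#' @param plot Also write `curves.pdf`.
#' @return Invisibly, a list with the `"model_selection"`, the
#'   `"thermo_curves"`, the `"q10_curve"` (or `NULL`) and the paths
#'   written.
#' @export
run_fit <- function(input, output_dir, config = fit_config(),
                    temperature_unit = "K", p_bounds = c(0.01, 0.99),
                    grid_n = 200, plot = FALSE) {
  series <- .as_series(input, temperature_unit, p_bounds)
  if (nrow(series) < 3)
    stop("at least 3 data points are required (got ", nrow(series), ")")
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  sel <- select_model(series, config)
  curves <- compute_thermo(sel$fit, grid_n = grid_n)
  paths <- list(report = file.path(output_dir, "report.json"),
                curves = file.path(output_dir, "curves.csv"))
  write_selection_json(sel, paths$report)
  write_curves(curves, paths$curves)
  q10 <- NULL
  if (diff(sel$fit$temperature_range) > 10) {
    q10 <- q10_curve(sel$fit)
    paths$q10 <- file.path(output_dir, "q10.csv")
    utils::write.csv(as.data.frame(q10), paths$q10, row.names = FALSE)
  } else {
    message("fitted range narrower than 10 K: skipping q10.csv")
  }
  if (plot) {
    paths$plot <- file.path(output_dir, "curves.pdf")
    grDevices::pdf(paths$plot, width = 6, height = 8)
    plot(curves)
    if (!is.null(q10)) plot(q10)
    grDevices::dev.off()
  }
  invisible(list(selection = sel, curves = curves, q10 = q10,
                 paths = paths))
}

.as_series <- function(input, temperature_unit = "K",
                       p_bounds = c(0.01, 0.99)) {
  if (inherits(input, "vanthoff_series")) return(input)
  if (inherits(input, "open_prob_table"))
    return(lnkeq_from_replicates(input, p_bounds))
  tab <- read_series(input, temperature_unit = temperature_unit)
  if (inherits(tab, "open_prob_table"))
    tab <- lnkeq_from_replicates(tab, p_bounds)
  tab
}

#' Simulate a two-state data set and write it to disk
#'
#' Writes the simulated table in the same CSV dialect [read_series()]
#' reads, next to a sidecar JSON recording the ground-truth model and the
#' seed.
#'
#' @param spec A [two_state_spec()].
#' @param t_grid Temperatures (K).
#' @param output_dir Output directory (created if missing).
#' @param seed Integer seed.
#' @param mode `"lnkeq"` for a ln Keq series with standard errors,
#'   `"open_prob"` for a long-format replicate table.
#' @return Invisibly, a list with the simulated object and the paths
#'   written.
#' @export
run_simulate <- function(spec, t_grid, output_dir, seed = 1L,
                         mode = c("lnkeq", "open_prob")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "two_state_spec"))
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  if (mode == "lnkeq") {
    obj <- simulate_lnkeq_series(spec, t_grid, seed = seed)
    out <- data.frame(temperature = obj$temperature, lnKeq = obj$lnkeq,
                      sigma = obj$sigma)
    data_path <- file.path(output_dir, "simulated_lnkeq.csv")
  } else {
    obj <- simulate_open_prob(spec, t_grid, seed = seed)
    out <- data.frame(temperature = obj$temperature,
                      open_prob = obj$open_prob)
    data_path <- file.path(output_dir, "simulated_open_prob.csv")
  }
  utils::write.csv(out, data_path, row.names = FALSE)
  truth_path <- file.path(output_dir, "ground_truth.json")
  spec_list <- unclass(spec)
  if (is.function(spec_list$dcp))
    spec_list$dcp <- "temperature-dependent function (not serialized)"
  writeLines(jsonlite::toJSON(c(spec_list, list(seed = seed, mode = mode)),
                              digits = NA, auto_unbox = TRUE, pretty = TRUE),
             truth_path)
  invisible(list(object = obj, paths = list(data = data_path,
                                            truth = truth_path)))
}

#' Q10 analysis of a data set
#'
#' Fits the data exactly as [run_fit()] does, then writes the Q10 curve of
#' the selected model to `q10.csv`.
#'
#' @inheritParams run_fit
#' @param delta Temperature step in K (default 10).
#' @return Invisibly, a list with the selection, the `"q10_curve"` and the
#'   path written.
#' @export
run_q10 <- function(input, output_dir, config = fit_config(),
                    temperature_unit = "K", p_bounds = c(0.01, 0.99),
                    delta = 10) {
  series <- .as_series(input, temperature_unit, p_bounds)
  if (nrow(series) < 3)
    stop("at least 3 data points are required (got ", nrow(series), ")")
  if (!dir.exists(output_dir))
    dir.create(output_dir, recursive = TRUE)
  sel <- select_model(series, config)
  q10 <- q10_curve(sel$fit, delta = delta)
  path <- file.path(output_dir, "q10.csv")
  utils::write.csv(as.data.frame(q10), path, row.names = FALSE)
  invisible(list(selection = sel, q10 = q10, paths = list(q10 = path)))
}
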