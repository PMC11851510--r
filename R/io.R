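# Configuration and data I/O, and the synthetic-measurement generator that
# stands in for experimental flow-rate series. All writes are atomic
# (write-temp-then-rename).

#' Noise model for synthetic measurements
#'
#' @param kind `"multiplicative_lognormal"` (mean-one lognormal factor),
#'   `"additive_gaussian"`, or `"none"`.
#' @param sigma Noise scale (>= 0).
#' @param seed RNG seed.
#' @return List of class `ad_noise`.
#' @export
noise_model <- function(kind = c("multiplicative_lognormal",
                                 "additive_gaussian", "none"),
                        sigma = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("sigma must be >= 0")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "ad_noise")
}

#' Synthesize a measurement series from known parameters
#'
#' Simulates the model under ground-truth parameters, samples the flow at a
#' fixed cadence, and applies the noise model. With `sigma = 0` (or kind
#' `"none"`) the series equals the simulated samples exactly. Fully
#' determined by the noise seed.
#'
#' @param params_true Ground-truth `ad_parameters`.
#' @param config,feed Reactor and feedstock.
#' @param noise An `ad_noise` model.
#' @param cadence Sampling interval, days (default 1, daily).
#' @param kind Flow kind to sample: `"CH4"` or `"biogas"`.
#' @param dt,method,ph_mode Solver settings.
#' @return An `ad_measurements` object.
#' @export
synthesize_measurements <- function(params_true, config, feed,
                                    noise = noise_model(), cadence = 1,
                                    kind = c("CH4", "biogas"),
                                    dt = 0.02, method = "euler",
                                    ph_mode = "resolve") {
  kind <- match.arg(kind)
  sim <- simulate_ad(params_true, config, feed, dt = dt, method = method,
                     ph_mode = ph_mode, save_dt = min(0.25, cadence / 2))
  times <- seq(cadence, config$t_total, by = cadence)
  q <- if (kind == "CH4") sim$Q_CH4 else sim$Q_biogas
  flows <- stats::approx(sim$time, q, xout = times, rule = 2)$y
  if (noise$kind != "none" && noise$sigma > 0) {
    set.seed(noise$seed)
    z <- stats::rnorm(length(flows))
    flows <- switch(noise$kind,
      multiplicative_lognormal =
        flows * exp(noise$sigma * z - noise$sigma^2 / 2),
      additive_gaussian = pmax(0, flows + noise$sigma * z))
  }
  measurement_series(times, flows, kind)
}

#' Write / read a measurement CSV
#'
#' Two columns with mandatory header `time_day, flow_L_per_day`.
#'
#' @param meas An `ad_measurements`.
#' @param path File path.
#' @param kind Flow kind declared for the series being read.
#' @return `read_measurements` returns an `ad_measurements`.
#' @export
write_measurements <- function(meas, path) {
  df <- data.frame(time_day = meas$times, flow_L_per_day = meas$flows)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path, kind = c("CH4", "biogas")) {
  kind <- match.arg(kind)
  df <- utils::read.csv(path)
  if (!all(c("time_day", "flow_L_per_day") %in% names(df))) {
    stop("measurement file ", path,
         " must have header columns time_day, flow_L_per_day")
  }
  measurement_series(df$time_day, df$flow_L_per_day, kind)
}

#' Load a run configuration (YAML)
#'
#' Schema: blocks `bioreactor` (pH_init, T_C, V_liq, V_gas, p_total,
#' t_total), `feedstock` (concentration fields and a `tm` map), optional
#' `solver` (dt, method, ph_mode), optional `seed` and `output_dir`.
#'
#' @param path YAML file.
#' @return List of class `ad_run_config` with parsed `config` and `feed`
#'   objects and solver settings.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (blk in c("bioreactor", "feedstock")) {
    if (is.null(raw[[blk]])) stop("config ", path, ": missing block '", blk, "'")
  }
  br <- raw$bioreactor
  need <- c("pH_init", "T_C", "V_liq", "V_gas", "p_total", "t_total")
  miss <- setdiff(need, names(br))
  if (length(miss)) {
    stop("config ", path, ": bioreactor block missing ",
         paste(miss, collapse = ", "))
  }
  config <- bioreactor_config(br$pH_init, br$T_C, br$V_liq, br$V_gas,
                              br$p_total, br$t_total)
  fs <- raw$feedstock
  tm <- unlist(fs$tm)
  fs$tm <- NULL
  feed <- do.call(feedstock_composition,
                  c(fs, list(tm = if (is.null(tm)) numeric(0) else tm)))
  solver <- utils::modifyList(
    list(dt = 0.01, method = "rk4", ph_mode = "resolve"),
    if (is.null(raw$solver)) list() else raw$solver)
  seed <- if (is.null(raw$seed)) 1L else as.integer(raw$seed)
  if (seed < 0) stop("seed must be a non-negative integer")
  structure(list(config = config, feed = feed, solver = solver,
                 seed = seed, output_dir = raw$output_dir),
            class = "ad_run_config")
}

#' Path to a shipped example data file
#' @param file File name under the package's `extdata` (empty: list them).
#' @return Full path.
#' @export
ad_example <- function(file = NULL) {
  if (is.null(file)) {
    dir(system.file("extdata", package = "admetal"))
  } else {
    system.file("extdata", file, package = "admetal", mustWork = TRUE)
  }
}
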