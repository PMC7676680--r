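#' Simulation configuration
#'
#' Bundles the model parameters with a network spec, an interaction mode, a
#' shock type and an RNG seed. Parameter names follow the model's standard
#' vocabulary; all have the conventional defaults.
#'
#' @param network A network code (see [network_spec()]), an
#'   `fcs_network_spec`, or an `fcs_network`.
#' @param TotalProduction Crop volume produced by all producers combined per
#'   production cycle (default 100).
#' @param TotalDemand Crop volume required by all consumers combined per
#'   production cycle (default 120; demand deliberately exceeds supply).
#' @param N_CropTypes Number of crop types (default 2).
#' @param StockPersistence Fraction of trader stock that persists into the
#'   next production cycle, in `[0, 1]` (default 0.95).
#' @param Periods Consumption (trading) periods per production cycle
#'   (default 12).
#' @param SpinupPeriod,StationaryPeriod,ShockDuration Lengths, in production
#'   cycles, of the spin-up, pre-shock, and shock phases (defaults 100 each).
#' @param ChoiceModel Partner-selection mode: `"random"`, `"weighted"`, or
#'   `"preference"`.
#' @param BasePreference Floor weight given to every trader in the weighted
#'   and preference modes (default 0.01).
#' @param ExpPreference Extra weight given to historic trading partners in
#'   the preference mode (default 100).
#' @param ShockType Level the shock hits: `"producer"`, `"trader"`, or
#'   `"consumer"`.
#' @param ShockSeverity Fraction of agents at the shocked level affected, in
#'   `[0, 1]` (default 0.5).
#' @param PostShockPeriod Optional number of recovery cycles appended after
#'   the shock, during which shocked agents regain their remembered
#'   production/demand (default 0).
#' @param seed Integer RNG seed for the run (default 1).
#' @return An object of class `fcs_config`.
#' @examples
#' cfg <- sim_config("bs", ChoiceModel = "random", seed = 42)
#' @export
sim_config <- function(network = "bs",
                       TotalProduction = 100,
                       TotalDemand = 120,
                       N_CropTypes = 2L,
                       StockPersistence = 0.95,
                       Periods = 12L,
                       SpinupPeriod = 100L,
                       StationaryPeriod = 100L,
                       ShockDuration = 100L,
                       ChoiceModel = c("random", "weighted", "preference"),
                       BasePreference = 0.01,
                       ExpPreference = 100,
                       ShockType = c("producer", "trader", "consumer"),
                       ShockSeverity = 0.5,
                       PostShockPeriod = 0L,
                       seed = 1L) {
  ChoiceModel <- match.arg(ChoiceModel)
  ShockType <- match.arg(ShockType)
  if (inherits(network, "fcs_network")) network <- network$spec
  if (is.character(network)) network <- network_spec(network)
  stopifnot(inherits(network, "fcs_network_spec"))

  chk_num <- function(x, name, lo = 0, hi = Inf) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
      stop(name, " must be a single number in [", lo, ", ", hi, "]",
           call. = FALSE)
    as.numeric(x)
  }
  chk_count <- function(x, name, lo = 0L) {
    x <- chk_num(x, name, lo)
    if (x != as.integer(x)) stop(name, " must be an integer", call. = FALSE)
    as.integer(x)
  }

  cfg <- list(
    network = network,
    TotalProduction = chk_num(TotalProduction, "TotalProduction"),
    TotalDemand = chk_num(TotalDemand, "TotalDemand"),
    N_CropTypes = chk_count(N_CropTypes, "N_CropTypes", 1L),
    StockPersistence = chk_num(StockPersistence, "StockPersistence", 0, 1),
    Periods = chk_count(Periods, "Periods", 1L),
    SpinupPeriod = chk_count(SpinupPeriod, "SpinupPeriod"),
    StationaryPeriod = chk_count(StationaryPeriod, "StationaryPeriod"),
    ShockDuration = chk_count(ShockDuration, "ShockDuration"),
    ChoiceModel = ChoiceModel,
    BasePreference = chk_num(BasePreference, "BasePreference"),
    ExpPreference = chk_num(ExpPreference, "ExpPreference"),
    ShockType = ShockType,
    ShockSeverity = chk_num(ShockSeverity, "ShockSeverity", 0, 1),
    PostShockPeriod = chk_count(PostShockPeriod, "PostShockPeriod"),
    seed = chk_count(seed, "seed")
  )
  structure(cfg, class = "fcs_config")
}

#' @export
print.fcs_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: network %s, mode %s, shock %s (severity %g)\n",
    x$network$code, x$ChoiceModel, x$ShockType, x$ShockSeverity))
  cat(sprintf(
    "  production %g, demand %g, %d crop(s), %d period(s)/cycle, persistence %g\n",
    x$TotalProduction, x$TotalDemand, x$N_CropTypes, x$Periods,
    x$StockPersistence))
  cat(sprintf("  phases: %d spinup + %d stationary + %d shock + %d post-shock cycles; seed %d\n",
              x$SpinupPeriod, x$StationaryPeriod, x$ShockDuration,
              x$PostShockPeriod, x$seed))
  invisible(x)
}

.config_scalar_keys <- c(
  "TotalProduction", "TotalDemand", "N_CropTypes", "StockPersistence",
  "Periods", "SpinupPeriod", "StationaryPeriod", "ShockDuration",
  "ChoiceModel", "BasePreference", "ExpPreference", "ShockType",
  "ShockSeverity", "PostShockPeriod", "seed")

#' Read a simulation configuration from YAML or JSON
#'
#' Keys mirror the parameter names of [sim_config()]. The network is given
#' either as `network_code` or as the triple
#' `n_producers`/`n_traders`/`n_consumers`. Omitted keys take the defaults;
#' unknown keys are rejected.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file. An empty file gives
#'   an all-defaults configuration.
#' @return An `fcs_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  allowed <- c(.config_scalar_keys, "network_code",
               "n_producers", "n_traders", "n_consumers")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)

  if (!is.null(raw$network_code)) {
    if (!is.null(raw$n_producers) || !is.null(raw$n_traders) ||
        !is.null(raw$n_consumers))
      stop("give either network_code or explicit layer sizes, not both",
           call. = FALSE)
    net <- network_spec(raw$network_code)
  } else if (!is.null(raw$n_producers)) {
    net <- network_spec("custom", raw$n_producers, raw$n_traders,
                        raw$n_consumers)
  } else {
    net <- network_spec("bs")
  }
  args <- raw[intersect(names(raw), .config_scalar_keys)]
  do.call(sim_config, c(list(network = net), args))
}

#' Write a simulation configuration to YAML or JSON
#'
#' @param config An `fcs_config`.
#' @param path Output path; format chosen by extension (`.json` or YAML
#'   otherwise).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "fcs_config"))
  out <- unclass(config)[.config_scalar_keys]
  if (config$network$code == "custom") {
    out$n_producers <- config$network$n_producers
    out$n_traders <- config$network$n_traders
    out$n_consumers <- config$network$n_consumers
  } else {
    out$network_code <- config$network$code
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(out, path)
  }
  invisible(path)
}
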