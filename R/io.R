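# Structured run outputs and manifests --------------------------------------

fmt_num <- function(x) {
  # 12 significant digits keeps cross-platform CSV diffs stable
  ifelse(is.na(x), NA, format(x, digits = 12, trim = TRUE, scientific = FALSE))
}

#' Export the outputs of a run to a directory
#'
#' Writes `series.csv` (per-cycle `cycle`, `phase`, `H_mean`, `total_stock`),
#' `trade_log.tsv` (`cycle`, `period`, `source_id`, `target_id`, `crop`,
#' `volume`), pre-shock (and, when present, shock-window) flow edge lists,
#' and a JSON run manifest sufficient to re-execute the run bit-identically.
#'
#' @param run An `fcs_run`.
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
export_run <- function(run, dir) {
  stopifnot(inherits(run, "fcs_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  series <- data.frame(cycle = run$series$cycle, phase = run$series$phase,
                       H_mean = fmt_num(run$series$H),
                       total_stock = fmt_num(run$series$stock_pre))
  utils::write.csv(series, file.path(dir, "series.csv"), row.names = FALSE,
                   quote = FALSE)
  log <- run$trade_log
  utils::write.table(
    data.frame(cycle = log$cycle, period = log$period, source_id = log$source,
               target_id = log$target, crop = log$crop,
               volume = fmt_num(log$volume)),
    file.path(dir, "trade_log.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  cfg <- run$config
  p1 <- window_cycles(cfg, "stationary")
  if (length(p1))
    write_flows(aggregate_flows(run, range(p1)),
                file.path(dir, "flows_preshock.tsv"))
  p2 <- window_cycles(cfg, "shock")
  if (length(p2))
    write_flows(aggregate_flows(run, range(p2)),
                file.path(dir, "flows_shock.tsv"))
  write_manifest(dir, cfg)
}

#' Write a JSON run manifest
#'
#' Records the full configuration snapshot, seed, package version,
#' timestamp, and an inventory (with MD5 checksums) of the files in the
#' output directory.
#'
#' @param dir Output directory whose files are inventoried.
#' @param config The `fcs_config` of the run(s).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(dir, config) {
  cfg_path <- file.path(dir, "config.yaml")
  save_config(config, cfg_path)
  files <- setdiff(list.files(dir), "manifest.json")
  manifest <- list(
    package = "foodchainsim",
    version = as.character(utils::packageVersion("foodchainsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    config_file = basename(cfg_path),
    files = lapply(files, function(f) list(
      name = f, md5 = unname(tools::md5sum(file.path(dir, f))))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Export a factorial run table and its summaries
#'
#' @param table A [run_factorial()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_factorial <- function(table, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(table, file.path(dir, "factorial_summary.csv"),
                   row.names = FALSE)
  s <- summarize_factorial(table)
  utils::write.csv(s$impact_cells, file.path(dir, "impact_by_cell.csv"),
                   row.names = FALSE)
  utils::write.csv(s$stock_cells, file.path(dir, "stock_by_network_mode.csv"),
                   row.names = FALSE)
  utils::write.csv(s$scatter, file.path(dir, "impact_vs_ratio.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Export OFAT sweeps
#'
#' Writes `ofat_raw.csv` (all grid-point outputs), `ofat_per_combo.csv`
#' (slopes and signs per combination), and `ofat_signs.csv` (the wide sign
#' table, one row per output, one column per parameter).
#'
#' @param records A list of `fcs_ofat` objects.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_ofat <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  raw <- do.call(rbind, lapply(records, function(r)
    cbind(parameter = r$parameter, r$raw)))
  per_combo <- do.call(rbind, lapply(records, function(r)
    cbind(parameter = r$parameter, r$per_combo)))
  utils::write.csv(raw, file.path(dir, "ofat_raw.csv"), row.names = FALSE)
  utils::write.csv(per_combo, file.path(dir, "ofat_per_combo.csv"),
                   row.names = FALSE)
  utils::write.csv(ofat_sign_table(records), file.path(dir, "ofat_signs.csv"),
                   row.names = FALSE)
  invisible(dir)
}
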