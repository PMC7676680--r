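# ---------------------------------------------------------------------------
# Factorial study ------------------------------------------------------------

#' Enumerate the factorial study design
#'
#' The full numerical design crosses the three interaction modes with the
#' seven named networks and the three shock types (63 cells), with a number
#' of seeded replicates per cell. Per-run seeds are drawn once from the base
#' seed, so results are identical regardless of execution order.
#'
#' @param modes Interaction modes to include.
#' @param networks Network codes to include.
#' @param shocks Shock types to include.
#' @param replicates Replicates per cell (default 100).
#' @param base_seed Base RNG seed for the per-run seed draw.
#' @return A data frame of class `fcs_design` with one row per run:
#'   `cell`, `mode`, `network`, `shock`, `replicate`, `seed`.
#' @examples
#' d <- factorial_design(replicates = 2)
#' nrow(d)  # 126
#' @export
factorial_design <- function(modes = c("random", "weighted", "preference"),
                             networks = network_table()$code,
                             shocks = c("producer", "trader", "consumer"),
                             replicates = 100L,
                             base_seed = 1L) {
  stopifnot(replicates >= 1L)
  cells <- expand.grid(mode = modes, network = networks, shock = shocks,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$cell <- seq_len(nrow(cells))
  design <- merge(cells, data.frame(replicate = seq_len(replicates)))
  design <- design[order(design$cell, design$replicate), ]
  rownames(design) <- NULL
  set.seed(base_seed)
  design$seed <- sample.int(.Machine$integer.max, nrow(design))
  design <- design[, c("cell", "mode", "network", "shock", "replicate",
                       "seed")]
  structure(design, class = c("fcs_design", "data.frame"),
            base_seed = base_seed)
}

# run one design row into one summary row
run_design_row <- function(row, config_args) {
  cfg <- do.call(sim_config, c(
    list(network = row$network, ChoiceModel = row$mode, ShockType = row$shock,
         seed = row$seed),
    config_args))
  run <- run_simulation(cfg)
  s <- run$summary
  g <- function(m, what) if (is.null(m)) NA_real_ else m[[what]]
  data.frame(
    cell = row$cell, mode = row$mode, network = row$network,
    shock = row$shock, replicate = row$replicate, seed = row$seed,
    H_p1 = s$H_p1, H_p2 = s$H_p2, E = s$E, stock = s$stock_p1,
    A_p1 = g(s$metrics_p1, "A"), B_p1 = g(s$metrics_p1, "B"),
    C_p1 = g(s$metrics_p1, "C"), ratio_p1 = g(s$metrics_p1, "ratio"),
    A_p2 = g(s$metrics_p2, "A"), B_p2 = g(s$metrics_p2, "B"),
    C_p2 = g(s$metrics_p2, "C"), ratio_p2 = g(s$metrics_p2, "ratio"),
    error = NA_character_, stringsAsFactors = FALSE)
}

#' Execute a factorial design
#'
#' Runs one simulation per design row and collects one summary row per run.
#' Failed runs are recorded (column `error`), never silently dropped.
#'
#' @param design An [factorial_design()] data frame.
#' @param ... Further arguments passed to [sim_config()] for every run
#'   (e.g. shortened phases for scaled studies).
#' @param progress Print a line per completed cell?
#' @return A data frame with one row per run: the design columns plus
#'   `H_p1`, `H_p2`, `E`, `stock`, the pre-shock (`*_p1`) and shock-window
#'   (`*_p2`) information metrics, and `error`.
#' @export
run_factorial <- function(design, ..., progress = FALSE) {
  stopifnot(inherits(design, "fcs_design") || is.data.frame(design))
  config_args <- list(...)
  out <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    out[[i]] <- tryCatch(run_design_row(row, config_args), error = function(e) {
      data.frame(cell = row$cell, mode = row$mode, network = row$network,
                 shock = row$shock, replicate = row$replicate, seed = row$seed,
                 H_p1 = NA_real_, H_p2 = NA_real_, E = NA_real_,
                 stock = NA_real_, A_p1 = NA_real_, B_p1 = NA_real_,
                 C_p1 = NA_real_, ratio_p1 = NA_real_, A_p2 = NA_real_,
                 B_p2 = NA_real_, C_p2 = NA_real_, ratio_p2 = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    if (progress && (i == nrow(design) || design$cell[i + 1L] != row$cell))
      message(sprintf("cell %d/%d done (%s / %s / %s)", row$cell,
                      max(design$cell), row$mode, row$network, row$shock))
  }
  do.call(rbind, out)
}

#' Summarize a factorial run table
#'
#' Produces plot-ready long-format tables: impact by design cell, stock by
#' network and mode, and the impact-versus-A:B scatter, together with
#' per-cell distribution summaries (median and quartiles).
#'
#' @param table A [run_factorial()] result.
#' @return A list of data frames: `impact` (per replicate), `impact_cells`
#'   (per-cell median/quartiles of `E`), `stock` and `stock_cells`
#'   (by network and mode), and `scatter` (`E` vs pre-shock `A:B`).
#' @export
summarize_factorial <- function(table) {
  qtab <- function(df, value, by) {
    if (nrow(df) == 0L)
      return(cbind(df[, by, drop = FALSE],
                   data.frame(q1 = numeric(0), median = numeric(0),
                              q3 = numeric(0))))
    agg <- stats::aggregate(df[[value]], df[by], function(v)
      stats::quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE))
    out <- cbind(agg[by], as.data.frame(agg$x))
    names(out) <- c(by, "q1", "median", "q3")
    out
  }
  impact <- table[, c("mode", "network", "shock", "replicate", "E")]
  stock <- table[, c("mode", "network", "shock", "replicate", "stock")]
  scatter <- table[, c("mode", "network", "shock", "replicate", "E",
                       "ratio_p1")]
  list(
    impact = impact,
    impact_cells = qtab(impact, "E", c("mode", "network", "shock")),
    stock = stock,
    stock_cells = qtab(stock, "stock", c("mode", "network")),
    scatter = scatter)
}

# ---------------------------------------------------------------------------
# One-factor-at-a-time sensitivity analysis ---------------------------------

.ofat_parameters <- c("BasePreference", "ExpPreference", "Periods",
                      "ShockSeverity", "StockPersistence", "TotalDemand")

#' Default OFAT parameter grids
#'
#' Each grid spans the parameter's default symmetrically and covers the
#' regimes of interest (e.g. few trading periods per cycle, fully
#' perishable to non-perishable stock).
#'
#' @param parameter One of the six OFAT parameters.
#' @return A numeric grid.
#' @export
ofat_grid <- function(parameter) {
  switch(match.arg(parameter, .ofat_parameters),
    BasePreference = seq(0, 0.1, by = 0.01),
    ExpPreference = seq(0, 200, by = 20),
    Periods = 1:24,
    ShockSeverity = seq(0, 1, by = 0.1),
    StockPersistence = seq(0, 1, by = 0.1),
    TotalDemand = seq(60, 240, by = 20))
}

#' Default OFAT factor combinations
#'
#' The OFAT sweeps are repeated for every combination of interaction mode,
#' network type (the small representative of each of the four structural
#' types), and shock level: 3 x 4 x 3 = 36 combinations.
#'
#' @return A data frame with columns `mode`, `network`, `shock`.
#' @export
ofat_combinations <- function() {
  expand.grid(mode = c("random", "weighted", "preference"),
              network = c("bs", "is", "h", "ds"),
              shock = c("producer", "trader", "consumer"),
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

.ofat_outputs <- c("A_rel", "B_rel", "C", "H_p1", "H_p2", "H_diff", "E",
                   "stock")

#' Run a one-factor-at-a-time sensitivity sweep
#'
#' Sweeps one parameter across a grid (all other parameters at their
#' defaults) for each factor combination, averages outputs over replicates,
#' and classifies the trend of every output quantity as `-`, `0`, or `+`.
#' Output quantities are relative efficiency `A/C`, relative resilience
#' `B/C`, capacity `C`, satisfaction in the pre-shock and shock windows,
#' their difference, impact `E`, and mean pre-shock stock.
#'
#' @param parameter One of `BasePreference`, `ExpPreference`, `Periods`,
#'   `ShockSeverity`, `StockPersistence`, `TotalDemand`.
#' @param grid Monotone numeric grid (default [ofat_grid()]).
#' @param combinations Data frame of `mode` / `network` / `shock`
#'   combinations (default [ofat_combinations()]).
#' @param replicates Seeded replicates averaged per grid point (default 1).
#' @param base_seed Base seed for the per-run seed draw.
#' @param tau Trend-classification threshold passed to [classify_trend()].
#' @param ... Further [sim_config()] arguments applied to every run.
#' @return An object of class `fcs_ofat`: list with `parameter`, `grid`,
#'   `raw` (one row per combination and grid point, outputs averaged over
#'   replicates), `replicates` (one row per individual run), `per_combo`
#'   (slope and sign per combination and output, classified on the
#'   replicate-level points), and `signs` (aggregated sign per output:
#'   `-`, `0`, `+`, or `mixed`).
#' @export
run_ofat <- function(parameter, grid = NULL, combinations = NULL,
                     replicates = 1L, base_seed = 1L, tau = 0.05, ...) {
  parameter <- match.arg(parameter, .ofat_parameters)
  if (is.null(grid)) grid <- ofat_grid(parameter)
  if (is.unsorted(grid) || length(unique(grid)) < 3L)
    stop("grid must be monotone with at least 3 distinct points",
         call. = FALSE)
  if (is.null(combinations)) combinations <- ofat_combinations()
  config_args <- list(...)

  n_runs <- nrow(combinations) * length(grid) * replicates
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max, n_runs)
  seed_i <- 0L

  raw <- vector("list", nrow(combinations) * length(grid))
  rep_rows <- vector("list", nrow(combinations) * length(grid))
  k <- 0L
  for (r in seq_len(nrow(combinations))) {
    combo <- combinations[r, ]
    for (g in grid) {
      vals <- matrix(NA_real_, replicates, length(.ofat_outputs),
                     dimnames = list(NULL, .ofat_outputs))
      for (rep in seq_len(replicates)) {
        seed_i <- seed_i + 1L
        args <- c(list(network = combo$network, ChoiceModel = combo$mode,
                       ShockType = combo$shock, seed = seeds[seed_i]),
                  config_args)
        args[[parameter]] <- g
        run <- run_simulation(do.call(sim_config, args))
        s <- run$summary
        m1 <- s$metrics_p1
        vals[rep, ] <- c(
          A_rel = if (!is.null(m1) && m1$C > 0) m1$A / m1$C else NA_real_,
          B_rel = if (!is.null(m1) && m1$C > 0) m1$B / m1$C else NA_real_,
          C = if (!is.null(m1)) m1$C else NA_real_,
          H_p1 = s$H_p1, H_p2 = s$H_p2, H_diff = s$H_p1 - s$H_p2,
          E = s$E, stock = s$stock_p1)
      }
      k <- k + 1L
      raw[[k]] <- cbind(combo, q = g,
                        as.data.frame(t(colMeans(vals, na.rm = TRUE))))
      rep_rows[[k]] <- cbind(combo[rep(1L, replicates), , drop = FALSE],
                             q = g, replicate = seq_len(replicates),
                             as.data.frame(vals))
    }
  }
  raw <- do.call(rbind, raw)
  rownames(raw) <- NULL
  reps_tab <- do.call(rbind, rep_rows)
  rownames(reps_tab) <- NULL

  # pooled scale per output: the observed range across all combinations and
  # grid points, so a flat-but-noisy combination is judged against the
  # output's overall variation, not its own noise
  scales <- vapply(.ofat_outputs, function(o)
    diff(range(raw[[o]], na.rm = TRUE)), numeric(1))

  # classify on replicate-level points so the slope's significance can be
  # judged against the replicate noise
  per_combo <- do.call(rbind, lapply(seq_len(nrow(combinations)), function(r) {
    combo <- combinations[r, ]
    sub <- reps_tab[reps_tab$mode == combo$mode &
                      reps_tab$network == combo$network &
                      reps_tab$shock == combo$shock, ]
    do.call(rbind, lapply(.ofat_outputs, function(o) {
      ct <- classify_trend(sub$q, sub[[o]], tau = tau, scale = scales[[o]])
      cbind(combo, output = o, slope = attr(ct, "slope"), sign = as.character(ct),
            stringsAsFactors = FALSE)
    }))
  }))
  rownames(per_combo) <- NULL

  signs <- vapply(.ofat_outputs, function(o) {
    s <- per_combo$sign[per_combo$output == o]
    if (all(s == "0")) "0"
    else if (any(s == "+") && !any(s == "-")) "+"
    else if (any(s == "-") && !any(s == "+")) "-"
    else "mixed"
  }, character(1))

  structure(list(parameter = parameter, grid = grid, raw = raw,
                 replicates = reps_tab, per_combo = per_combo, signs = signs,
                 tau = tau),
            class = "fcs_ofat")
}

#' Classify the trend of an output along a parameter grid
#'
#' Least-squares slope of the output against the min-max-normalized
#' parameter (`q` may contain repeated values when replicate-level points
#' are supplied). A trend is reported only when it is both *material* —
#' the fitted total change over the grid is at least `tau * scale` — and
#' *distinguishable from replicate noise* — the slope differs from zero at
#' significance level `alpha`. Otherwise the class is `0`. An inert
#' parameter whose sweep shows nothing but noise is thereby classified
#' flat with high probability, while any consistent monotone response is
#' picked up.
#'
#' @param q Parameter grid values (at least 3 distinct).
#' @param y Output values, same length.
#' @param tau Relative threshold for the `0` class (default 0.05).
#' @param scale Reference scale; defaults to `diff(range(y))`. Pass a pooled
#'   scale when classifying one of several related sweeps.
#' @param alpha Significance level for the slope (default 0.01).
#' @return `"-"`, `"0"`, or `"+"`, with the fitted change as attribute
#'   `"slope"`.
#' @export
classify_trend <- function(q, y, tau = 0.05, scale = NULL, alpha = 0.01) {
  ok <- is.finite(q) & is.finite(y)
  q <- q[ok]; y <- y[ok]
  if (length(unique(q)) < 3L)
    stop("need at least 3 distinct grid points", call. = FALSE)
  qn <- (q - min(q)) / diff(range(q))
  fit <- stats::lm(y ~ qn)
  slope <- unname(stats::coef(fit)[2L])
  if (is.null(scale)) scale <- diff(range(y))
  p <- tryCatch(
    suppressWarnings(stats::summary.lm(fit)$coefficients[2L, 4L]),
    error = function(e) NA_real_)
  insignificant <- is.finite(p) && p > alpha
  cls <- if (!is.finite(slope) || scale <= 0 || abs(slope) < tau * scale ||
               insignificant) "0"
         else if (slope > 0) "+" else "-"
  structure(cls, slope = slope)
}

#' Combine OFAT sweeps into a sign table
#'
#' Arranges the aggregated signs of several [run_ofat()] results as a wide
#' table: one row per output quantity, one column per swept parameter.
#'
#' @param ... `fcs_ofat` objects (or a single list of them).
#' @return A data frame with an `output` column and one sign column per
#'   parameter.
#' @export
ofat_sign_table <- function(...) {
  records <- list(...)
  if (length(records) == 1L && !inherits(records[[1L]], "fcs_ofat"))
    records <- records[[1L]]
  stopifnot(all(vapply(records, inherits, logical(1), "fcs_ofat")))
  out <- data.frame(output = .ofat_outputs)
  for (rec in records) out[[rec$parameter]] <- unname(rec$signs)
  out
}

#' @export
print.fcs_ofat <- function(x, ...) {
  cat(sprintf("OFAT sweep of %s over [%g, %g] (%d points, %d combinations)\n",
              x$parameter, min(x$grid), max(x$grid), length(x$grid),
              nrow(unique(x$raw[c("mode", "network", "shock")]))))
  print(x$signs)
  invisible(x)
}
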