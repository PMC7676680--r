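# ---------------------------------------------------------------------------
# Consumer satisfaction and shock impact ------------------------------------

#' Mean consumer satisfaction for one production cycle
#'
#' Satisfaction of a consumer is the minimum, over the crops it demands, of
#' the ratio of consumption to requirement, capped at 1 (a consumer cannot
#' be more than fully satisfied). Crops with zero requirement are excluded
#' from the minimum; a consumer with no requirement at all counts as fully
#' satisfied. The cycle value is the mean over consumers.
#'
#' @param consumed Numeric matrix (`n_consumers x n_crops`) of volumes
#'   consumed this cycle.
#' @param demand Numeric matrix of the same shape with the cycle
#'   requirements.
#' @return The mean satisfaction, with the per-consumer values attached as
#'   attribute `"per_consumer"`.
#' @examples
#' mean_satisfaction(matrix(c(3, 6), 1), matrix(c(4, 6), 1))  # 0.75
#' @export
mean_satisfaction <- function(consumed, demand) {
  consumed <- as.matrix(consumed)
  demand <- as.matrix(demand)
  stopifnot(identical(dim(consumed), dim(demand)),
            nrow(consumed) >= 1L,
            all(consumed >= 0), all(demand >= 0))
  r <- consumed / demand
  r[demand <= 0] <- Inf
  s <- do.call(pmin, lapply(seq_len(ncol(r)), function(c) r[, c]))
  s[is.infinite(s)] <- 1
  s <- pmin(s, 1)
  structure(mean(s), per_consumer = s)
}

#' Relative impact of a shock on consumer satisfaction
#'
#' `E = (H_p2 - H_p1) / H_p1`: the relative change in mean satisfaction from
#' the pre-shock window to the shock window. Negative values mean the shock
#' lowered satisfaction; `E = -1` is total loss.
#'
#' @param H_p1 Mean satisfaction over the pre-shock (stationary) window;
#'   must be positive.
#' @param H_p2 Mean satisfaction over the shock window.
#' @return The impact `E` (a dimensionless fraction).
#' @examples
#' impact(0.8, 0.6)  # -0.25
#' @export
impact <- function(H_p1, H_p2) {
  stopifnot(is.numeric(H_p1), is.numeric(H_p2))
  if (any(H_p1 <= 0))
    stop("impact is undefined for H_p1 <= 0", call. = FALSE)
  (H_p2 - H_p1) / H_p1
}

# ---------------------------------------------------------------------------
# Flow matrices --------------------------------------------------------------

#' Time-averaged flow matrix from a trade log
#'
#' Averages the traded crop volume per ordered agent pair over a window of
#' production cycles: `F(i, j)` is the total volume logged from `i` to `j`
#' within the window, divided by the window length in cycles. When a network
#' is supplied, every potential link is present in the result, with zero
#' flow for pairs that never traded.
#'
#' @param trade_log A trade log as produced by [run_simulation()] (columns
#'   `cycle`, `source`, `target`, `volume`; extra columns are ignored), or
#'   an `fcs_run`.
#' @param window Integer vector of length 2: first and last cycle of the
#'   window (inclusive).
#' @param network Optional `fcs_network` used to include untraded potential
#'   links as zero flows.
#' @return An object of class `fcs_flows`: a data frame with columns
#'   `source`, `target`, `flow`, plus attributes `window` and
#'   `window_length`.
#' @export
aggregate_flows <- function(trade_log, window, network = NULL) {
  if (inherits(trade_log, "fcs_run")) {
    if (is.null(network)) network <- trade_log$network
    trade_log <- trade_log$trade_log
  }
  stopifnot(length(window) == 2L, window[2] >= window[1])
  len <- window[2] - window[1] + 1L
  dt <- data.table::as.data.table(trade_log)
  dt <- dt[dt$cycle >= window[1] & dt$cycle <= window[2], ]
  agg <- dt[, list(flow = sum(volume) / len), by = c("source", "target")]
  if (!is.null(network)) {
    links <- data.table::as.data.table(network$potential_links)
    agg <- merge(links, agg, by = c("source", "target"), all.x = TRUE)
    agg$flow[is.na(agg$flow)] <- 0
  }
  data.table::setorderv(agg, c("source", "target"))
  structure(as.data.frame(agg), class = c("fcs_flows", "data.frame"),
            window = as.integer(window), window_length = len)
}

#' Read / write a flow edge list as TSV
#'
#' Three tab-separated columns `source_id`, `target_id`, `mean_flow`, so the
#' information metrics double as a standalone tool on externally supplied
#' weighted directed networks.
#'
#' @param path File path.
#' @return `read_flows()` returns an `fcs_flows` data frame;
#'   `write_flows()` returns `path` invisibly.
#' @export
read_flows <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("source_id", "target_id", "mean_flow") %in% names(df)))
    stop("expected columns source_id, target_id, mean_flow", call. = FALSE)
  structure(data.frame(source = df$source_id, target = df$target_id,
                       flow = df$mean_flow),
            class = c("fcs_flows", "data.frame"))
}

#' @rdname read_flows
#' @param flows An `fcs_flows` data frame (or any data frame with columns
#'   `source`, `target`, `flow`).
#' @export
write_flows <- function(flows, path) {
  utils::write.table(
    data.frame(source_id = flows$source, target_id = flows$target,
               mean_flow = flows$flow),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Information-theoretic capacity / efficiency / resilience -------------------

#' Capacity, efficiency and resilience of a flow network
#'
#' Decomposes a weighted directed flow network into total capacity `C`,
#' efficiency `A` (ascendency: the flow-weighted mutual information of
#' sources and sinks), and resilience `B` (reserve: the redundancy of
#' parallel pathways), with `C = A + B`:
#' \deqn{A = \sum_{i,j} F_{ij} \log\!\frac{F_{ij} F_{..}}{F_{i.} F_{.j}},
#'   \quad
#'   B = -\sum_{i,j} F_{ij} \log\!\frac{F_{ij}^2}{F_{i.} F_{.j}},
#'   \quad
#'   C = -\sum_{i,j} F_{ij} \log\!\frac{F_{ij}}{F_{..}}.}
#' Natural logarithms are used; `C = A + B` and the ratio `A/B` are
#' base-invariant. Zero flows contribute zero (the `x log x -> 0` limit
#' convention). An all-zero network returns zeros so severe-shock windows
#' remain computable.
#'
#' `C` is evaluated independently of `A + B` and the two are cross-checked
#' to floating tolerance.
#'
#' @param flows An `fcs_flows` data frame, any data frame with columns
#'   `source`, `target`, `flow`, or a square numeric matrix `F[i, j]`.
#' @return An object of class `fcs_ulanowicz`: a list with `C`, `A`, `B`,
#'   `ratio` (`A/B`, `NA` when `B = 0`), and `total_flow`.
#' @examples
#' # a single chain with flow f on both links: A = 2 f log 2, B = 0
#' chain <- data.frame(source = c(1, 2), target = c(2, 3), flow = c(1, 1))
#' ulanowicz(chain)
#' @export
ulanowicz <- function(flows) {
  if (is.matrix(flows)) {
    flows <- data.frame(
      source = rep(seq_len(nrow(flows)), times = ncol(flows)),
      target = rep(seq_len(ncol(flows)), each = nrow(flows)),
      flow = as.vector(flows))
  }
  stopifnot(all(c("source", "target", "flow") %in% names(flows)))
  f <- flows$flow
  if (any(f < 0)) stop("flows must be nonnegative", call. = FALSE)
  ftot <- sum(f)
  if (ftot <= 0)
    return(structure(list(C = 0, A = 0, B = 0, ratio = NA_real_,
                          total_flow = 0), class = "fcs_ulanowicz"))
  fi <- stats::ave(f, flows$source, FUN = sum)  # F(i, .) per row's source
  fj <- stats::ave(f, flows$target, FUN = sum)  # F(., j) per row's target
  pos <- f > 0
  f <- f[pos]; fi <- fi[pos]; fj <- fj[pos]
  A <- sum(f * log(f * ftot / (fi * fj)))
  B <- -sum(f * log(f^2 / (fi * fj)))
  C <- -sum(f * log(f / ftot))
  if (B == 0) B <- 0  # normalize negative zero
  if (A == 0) A <- 0
  if (abs(C - (A + B)) > 1e-8 * max(1, abs(C)))
    warning("C and A + B disagree beyond floating tolerance")
  structure(list(C = C, A = A, B = B,
                 ratio = if (B > 0) A / B else NA_real_,
                 total_flow = ftot),
            class = "fcs_ulanowicz")
}

#' @export
print.fcs_ulanowicz <- function(x, ...) {
  cat(sprintf(
    "Flow-network information metrics (nats * volume / cycle):\n  C = %.6g, A (efficiency) = %.6g, B (resilience) = %.6g, A:B = %.6g\n",
    x$C, x$A, x$B, x$ratio))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Sliding-window diagnostics -------------------------------------------------

#' Sliding-window time series of satisfaction, stock, A and B
#'
#' At each cycle `t`, averages satisfaction and stock and recomputes the
#' information metrics over the window of `window_length` consecutive cycles
#' starting at `t`. Used to verify that the system reaches a quasi-steady
#' state within each phase.
#'
#' @param run An `fcs_run` (with a trade log).
#' @param window_length Window size in cycles (default 5). A window of 1
#'   reduces to per-cycle values.
#' @param phase Optional phase name (`"spinup"`, `"stationary"`, `"shock"`,
#'   `"postshock"`): restrict to windows lying entirely inside that phase.
#' @return A data frame with one row per window start: `cycle`, `phase`
#'   (phase of the window start), `H`, `stock`, `A`, `B`.
#' @export
sliding_window_metrics <- function(run, window_length = 5L, phase = NULL) {
  stopifnot(inherits(run, "fcs_run"), window_length >= 1L)
  n <- nrow(run$series)
  if (n < window_length) stop("run shorter than window", call. = FALSE)
  per_cycle <- data.table::as.data.table(run$trade_log)[
    , list(volume = sum(volume)), by = c("cycle", "source", "target")]
  if (is.null(phase)) {
    starts <- seq_len(n - window_length + 1L)
  } else {
    cyc <- window_cycles(run$config, phase)
    if (length(cyc) < window_length)
      stop("phase shorter than window", call. = FALSE)
    starts <- cyc[seq_len(length(cyc) - window_length + 1L)]
  }
  out <- lapply(starts, function(t0) {
    win <- c(t0, t0 + window_length - 1L)
    fl <- per_cycle[per_cycle$cycle >= win[1] & per_cycle$cycle <= win[2], ]
    m <- if (nrow(fl)) {
      ulanowicz(fl[, list(flow = sum(volume) / window_length),
                   by = c("source", "target")])
    } else {
      list(A = 0, B = 0)
    }
    idx <- win[1]:win[2]
    data.frame(cycle = t0, phase = run$series$phase[t0],
               H = mean(run$series$H[idx]),
               stock = mean(run$series$stock_pre[idx]),
               A = m$A, B = m$B)
  })
  do.call(rbind, out)
}

#' Windowed efficiency-to-resilience ratio of a phase
#'
#' Evaluates the information metrics per short sliding window inside one
#' phase and averages them, returning `mean(A) / mean(B)`. Short windows see
#' only the links actually active around each cycle, so the estimator
#' reflects the operating trade network rather than the union of all links
#' ever realized; it is the estimator used for comparing efficiency and
#' resilience across network types (the full-window metric from
#' [aggregate_flows()] plus [ulanowicz()] complements it).
#'
#' @param run An `fcs_run`.
#' @param phase Phase to evaluate (default the pre-shock stationary phase).
#' @param window_length Sliding-window length in cycles (default 5).
#' @return A list with `A`, `B` (window means) and `ratio`.
#' @export
windowed_ab_ratio <- function(run, phase = "stationary", window_length = 5L) {
  sw <- sliding_window_metrics(run, window_length, phase = phase)
  A <- mean(sw$A); B <- mean(sw$B)
  list(A = A, B = B, ratio = if (B > 0) A / B else NA_real_)
}
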