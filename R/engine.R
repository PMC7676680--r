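# ---------------------------------------------------------------------------
# Model state -----------------------------------------------------------------
#
# The mutable world of one simulation lives in an environment so the per-cycle
# step functions can update it in place. All stochastic draws consume the
# global RNG stream, seeded once from the config, in a fixed documented order:
# per cycle (1) crop assignment, (2) producer partner draws, (3) one consumer
# partner draw block per period; shock onset additionally draws the shocked
# agent set (and, for consumer shocks, the crop shifts) at the start of the
# first shock cycle.

#' Initialize a simulation
#'
#' Producers are assigned equal fixed production `TotalProduction /
#' n_producers` (remembered for post-shock recovery); consumers are assigned
#' equal demand `TotalDemand / n_consumers`, split equally over crop types
#' and spread equally over the trading periods of a cycle. Stocks start
#' empty, historic-partner sets empty, and the RNG is seeded from
#' `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return A model-state environment of class `fcs_state`.
#' @export
init_simulation <- function(config) {
  stopifnot(inherits(config, "fcs_config"))
  net <- make_network(config$network)
  np <- length(net$producer_ids)
  nt <- length(net$trader_ids)
  nc <- length(net$consumer_ids)
  k  <- config$N_CropTypes

  set.seed(config$seed)

  s <- new.env(parent = emptyenv())
  s$config <- config
  s$net <- net
  s$np <- np; s$nt <- nt; s$nc <- nc; s$ncrop <- k

  s$production <- rep(config$TotalProduction / np, np)
  s$production_memory <- s$production
  s$crop <- rep(1L, np)

  s$stock <- matrix(0, nt, k)

  s$demand_cycle <- matrix(config$TotalDemand / (nc * k), nc, k)
  s$demand_memory <- s$demand_cycle
  s$demand_period <- s$demand_cycle / config$Periods
  s$consumed <- matrix(0, nc, k)

  s$prod_hist <- matrix(FALSE, np, nt)
  s$cons_hist <- matrix(FALSE, nc, nt)
  s$my_trader_producer <- rep(NA_integer_, np)
  s$my_trader_consumer <- rep(NA_integer_, nc)

  s$cycle <- 1L
  s$phase <- "spinup"
  s$shocked <- integer(0)

  # cumulative-sum helper matrix for vectorized categorical draws
  s$cum_mat <- upper.tri(diag(nt), diag = TRUE) * 1

  # trade log accumulators (lists of vectors, bound once at run end)
  s$log_chunks <- vector("list", 0L)
  class(s) <- c("fcs_state", class(s))
  s
}

#' @export
print.fcs_state <- function(x, ...) {
  cat(sprintf("Model state: network %s, cycle %d (%s), total stock %.3f\n",
              x$net$spec$code, x$cycle, x$phase, sum(x$stock)))
  invisible(x)
}

# vectorized categorical draw: one index per row of the weight matrix W,
# using uniforms u (one per row). Rows with non-positive total fall back to
# a uniform draw.
draw_rows <- function(W, u, cum_mat) {
  tot <- rowSums(W)
  bad <- !(tot > 0)
  if (any(bad)) {
    W[bad, ] <- 1
    tot[bad] <- ncol(W)
  }
  cw <- W %*% cum_mat
  idx <- rowSums(cw < u * tot) + 1L
  pmin(idx, ncol(W))
}

#' Assign each producer a crop for the current cycle
#'
#' Crop types are drawn independently and uniformly from the seeded stream.
#'
#' @param state An `fcs_state`.
#' @return The state, invisibly (modified in place).
#' @export
assign_crops <- function(state) {
  state$crop <- sample.int(state$ncrop, state$np, replace = TRUE)
  invisible(state)
}

# Selection weight matrices -------------------------------------------------
#
# Raw weights realize "negatively / positively weighted by the traders'
# stock": for a producer of crop c, w(t) = BasePreference +
# (max_u stock[u, c] - stock[t, c]); for a consumer with focal crop c*,
# w(t) = BasePreference + stock[t, c*]. The preference mode adds
# ExpPreference for every historic partner; the random mode uses unit
# weights. Selection is a single draw with probability w / sum(w).

#' Producer-side selection weights
#'
#' @param state An `fcs_state` (crops must be assigned for the cycle).
#' @return An `n_producers x n_traders` matrix of raw selection weights.
#' @export
producer_weights <- function(state) {
  cfg <- state$config
  if (cfg$ChoiceModel == "random")
    return(matrix(1, state$np, state$nt))
  m <- apply(state$stock, 2L, max)
  W <- cfg$BasePreference +
    matrix(m[state$crop], state$np, state$nt) -
    t(state$stock[, state$crop, drop = FALSE])
  if (cfg$ChoiceModel == "preference")
    W <- W + cfg$ExpPreference * state$prod_hist
  W
}

#' Consumer-side selection weights and focal crops
#'
#' The focal crop of a consumer is the crop with the lowest cumulative
#' fulfilment of the requirement so far this cycle (ties and zero-demand
#' crops resolved toward the lowest eligible crop index).
#'
#' @param state An `fcs_state`.
#' @param period Current period index within the cycle (1-based).
#' @return A list with `W` (`n_consumers x n_traders` weight matrix) and
#'   `focal` (integer focal crop per consumer).
#' @export
consumer_weights <- function(state, period) {
  cfg <- state$config
  req <- period * state$demand_period
  fulfil <- state$consumed / req
  fulfil[req <= 0] <- Inf
  focal <- max.col(-fulfil, ties.method = "first")
  if (cfg$ChoiceModel == "random") {
    W <- matrix(1, state$nc, state$nt)
  } else {
    W <- cfg$BasePreference + t(state$stock[, focal, drop = FALSE])
    if (cfg$ChoiceModel == "preference")
      W <- W + cfg$ExpPreference * state$cons_hist
  }
  list(W = W, focal = focal)
}

#' Select a trader for one producer
#'
#' Single-agent form of the vectorized selection used by [run_simulation()]:
#' draws one trader with the mode-dependent weights, updates the producer's
#' current and historic partner sets, and returns the trader id.
#'
#' @param state An `fcs_state`.
#' @param producer Producer index (1-based within the producer layer).
#' @return The selected trader's agent id.
#' @export
select_trader_for_producer <- function(state, producer) {
  W <- producer_weights(state)[producer, , drop = FALSE]
  t_idx <- draw_rows(W, stats::runif(1L), state$cum_mat)
  state$my_trader_producer[producer] <- t_idx
  state$prod_hist[producer, t_idx] <- TRUE
  state$net$trader_ids[t_idx]
}

#' Select a trader for one consumer
#'
#' @param state An `fcs_state`.
#' @param consumer Consumer index (1-based within the consumer layer).
#' @param period Current period within the cycle.
#' @return The selected trader's agent id.
#' @export
select_trader_for_consumer <- function(state, consumer, period) {
  cw <- consumer_weights(state, period)
  W <- cw$W[consumer, , drop = FALSE]
  t_idx <- draw_rows(W, stats::runif(1L), state$cum_mat)
  state$my_trader_consumer[consumer] <- t_idx
  state$cons_hist[consumer, t_idx] <- TRUE
  state$net$trader_ids[t_idx]
}

#' Split a trader's stock among its buyers
#'
#' Implements the even-split allocation rule: per crop, each buyer is offered
#' an equal share `stock / n_buyers` and receives the smaller of that share
#' and its remaining cycle demand. Left-over stock stays with the trader.
#'
#' @param stock_row Numeric vector, the trader's stock per crop.
#' @param remaining Numeric matrix (`n_buyers x n_crops`) of the buyers'
#'   remaining cycle demand.
#' @return A matrix of the same shape as `remaining` with the delivered
#'   volumes.
#' @export
allocate_to_consumers <- function(stock_row, remaining) {
  nb <- nrow(remaining)
  if (nb == 0L) return(remaining)
  share <- stock_row / nb
  pmin(remaining, rep(share, each = nb))
}

#' Apply the shock at the onset of the shock phase
#'
#' Draws `round(ShockSeverity * n_level)` distinct agents of the shocked
#' level (round half up) and applies the level effect: shocked producers
#' stop producing; shocked traders lose their stock (re-applied at every
#' shock-cycle start); shocked consumers move the whole demand of one
#' uniformly drawn crop onto another uniformly drawn crop. The shocked set
#' is fixed for the entire shock phase.
#'
#' @param state An `fcs_state`.
#' @return The state, invisibly (modified in place).
#' @export
apply_shock_onset <- function(state) {
  cfg <- state$config
  n_level <- switch(cfg$ShockType,
                    producer = state$np,
                    trader = state$nt,
                    consumer = state$nc)
  n_sh <- as.integer(floor(cfg$ShockSeverity * n_level + 0.5))
  state$shocked <- if (n_sh > 0L) sort(sample.int(n_level, n_sh)) else integer(0)
  if (n_sh == 0L) return(invisible(state))
  switch(cfg$ShockType,
    producer = {
      state$production[state$shocked] <- 0
    },
    trader = {
      state$stock[state$shocked, ] <- 0
    },
    consumer = {
      if (state$ncrop > 1L) {
        for (y in state$shocked) {
          src <- sample.int(state$ncrop, 1L)
          others <- setdiff(seq_len(state$ncrop), src)
          tgt <- others[sample.int(length(others), 1L)]
          state$demand_cycle[y, tgt] <- state$demand_cycle[y, tgt] +
            state$demand_cycle[y, src]
          state$demand_cycle[y, src] <- 0
        }
        state$demand_period <- state$demand_cycle / cfg$Periods
      }
    })
  invisible(state)
}

#' Close a production cycle
#'
#' Applies stock persistence (each trader stock entry is multiplied by
#' `StockPersistence`), resets the consumers' consumption ledger, and
#' advances the clock. When the shock phase has just ended, production and
#' demand are restored from the remembered pre-shock values.
#'
#' @param state An `fcs_state`.
#' @return The state, invisibly (modified in place).
#' @export
end_of_cycle <- function(state) {
  state$stock <- state$stock * state$config$StockPersistence
  state$consumed[] <- 0
  state$cycle <- state$cycle + 1L
  invisible(state)
}

# restore remembered production/demand at shock end (post-shock phase)
recover_from_shock <- function(state) {
  state$production <- state$production_memory
  state$demand_cycle <- state$demand_memory
  state$demand_period <- state$demand_cycle / state$config$Periods
  state$shocked <- integer(0)
  invisible(state)
}

# per-cycle mean consumer satisfaction from the current ledgers:
# mean over consumers of min over demanded crops of min(consumed/demand, 1);
# consumers with no demand at all count as fully satisfied.
cycle_satisfaction <- function(consumed, demand) {
  r <- consumed / demand
  r[demand <= 0] <- Inf
  s <- do.call(pmin, lapply(seq_len(ncol(r)), function(c) r[, c]))
  s[is.infinite(s)] <- 1
  mean(pmin(s, 1))
}

#' Run one simulation
#'
#' Executes the spin-up, pre-shock (stationary), shock, and optional
#' post-shock phases. Per cycle the schedule is: (shock upkeep,) crop
#' assignment, producer trader-selection and delivery, `Periods` consumption
#' rounds (consumer trader-selection, then each selected trader splits its
#' stock evenly among its buyers up to their remaining cycle demand), then
#' stock persistence and ledger reset. Partner selection within a round is
#' simultaneous: all agents observe the same start-of-round stocks.
#'
#' @param config An [sim_config()] object (or a network code, for an
#'   all-defaults run on that network).
#' @param keep_log Keep the full trade log? (default `TRUE`; the log is
#'   required for flow-matrix metrics).
#' @return An object of class `fcs_run` with elements `config`, `network`,
#'   `series` (per-cycle data frame: `cycle`, `phase`, `H`, `stock_pre`,
#'   `stock_post`), `trade_log` (data.table: `cycle`, `period`, `source`,
#'   `target`, `crop`, `volume`; producer deliveries carry `period = 0`),
#'   and `summary` (see [run_summary()]).
#' @examples
#' run <- run_simulation(sim_config("bs", SpinupPeriod = 5,
#'                                  StationaryPeriod = 5, ShockDuration = 5))
#' run$summary$H_p1
#' @export
run_simulation <- function(config, keep_log = TRUE) {
  if (!inherits(config, "fcs_config")) config <- sim_config(config)
  s <- init_simulation(config)
  cfg <- config
  n_cycles <- cfg$SpinupPeriod + cfg$StationaryPeriod + cfg$ShockDuration +
    cfg$PostShockPeriod
  phases <- rep(c("spinup", "stationary", "shock", "postshock"),
                c(cfg$SpinupPeriod, cfg$StationaryPeriod, cfg$ShockDuration,
                  cfg$PostShockPeriod))
  shock_start <- cfg$SpinupPeriod + cfg$StationaryPeriod + 1L
  shock_end <- shock_start + cfg$ShockDuration - 1L

  H <- numeric(n_cycles)
  stock_pre <- numeric(n_cycles)
  stock_post <- numeric(n_cycles)
  chunks <- vector("list", n_cycles * (cfg$Periods + 1L))
  n_chunk <- 0L

  tids <- s$net$trader_ids
  cids <- s$net$consumer_ids
  pids <- s$net$producer_ids

  for (cycle in seq_len(n_cycles)) {
    s$cycle <- cycle
    s$phase <- phases[cycle]
    if (cfg$ShockDuration > 0L && cycle == shock_start)
      apply_shock_onset(s)
    in_shock <- cfg$ShockDuration > 0L && cycle >= shock_start &&
      cycle <= shock_end
    if (in_shock && cfg$ShockType == "trader" && length(s$shocked))
      s$stock[s$shocked, ] <- 0
    if (cfg$PostShockPeriod > 0L && cfg$ShockDuration > 0L &&
        cycle == shock_end + 1L)
      recover_from_shock(s)

    # --- production and producer-side trading -----------------------------
    assign_crops(s)
    active <- which(s$production > 0)
    if (length(active)) {
      W <- producer_weights(s)[active, , drop = FALSE]
      t_idx <- draw_rows(W, stats::runif(length(active)), s$cum_mat)
      s$my_trader_producer[active] <- t_idx
      s$prod_hist[cbind(active, t_idx)] <- TRUE
      vol <- s$production[active]
      crop <- s$crop[active]
      # accumulate deliveries into trader stocks
      for (i in seq_along(active))
        s$stock[t_idx[i], crop[i]] <- s$stock[t_idx[i], crop[i]] + vol[i]
      if (keep_log) {
        n_chunk <- n_chunk + 1L
        chunks[[n_chunk]] <- list(cycle = rep.int(cycle, length(active)),
                                  period = rep.int(0L, length(active)),
                                  source = pids[active],
                                  target = tids[t_idx],
                                  crop = crop, volume = vol)
      }
    }

    # --- consumption rounds ----------------------------------------------
    for (p in seq_len(cfg$Periods)) {
      cw <- consumer_weights(s, p)
      t_idx <- draw_rows(cw$W, stats::runif(s$nc), s$cum_mat)
      s$my_trader_consumer <- t_idx
      s$cons_hist[cbind(seq_len(s$nc), t_idx)] <- TRUE
      req <- p * s$demand_period
      # every selected trader splits its stock evenly among its buyers
      n_buyers <- tabulate(t_idx, s$nt)
      remaining <- pmax(req - s$consumed, 0)
      share <- s$stock[t_idx, , drop = FALSE] / n_buyers[t_idx]
      give <- pmin(remaining, share)
      delivered <- rowsum(give, t_idx)
      sellers <- as.integer(rownames(delivered))
      s$consumed <- s$consumed + give
      s$stock[sellers, ] <- pmax(s$stock[sellers, , drop = FALSE] - delivered,
                                 0)
      if (keep_log) {
        nz <- which(give > 0)
        if (length(nz)) {
          row <- (nz - 1L) %% s$nc + 1L
          n_chunk <- n_chunk + 1L
          chunks[[n_chunk]] <- list(
            cycle = rep.int(cycle, length(nz)),
            period = rep.int(p, length(nz)),
            source = tids[t_idx[row]],
            target = cids[row],
            crop = (nz - 1L) %/% s$nc + 1L,
            volume = give[nz])
        }
      }
    }

    # --- bookkeeping ------------------------------------------------------
    H[cycle] <- cycle_satisfaction(s$consumed, s$demand_cycle)
    stock_pre[cycle] <- sum(s$stock)
    end_of_cycle(s)
    stock_post[cycle] <- sum(s$stock)
  }

  trade_log <- if (keep_log && n_chunk > 0L) {
    data.table::rbindlist(chunks[seq_len(n_chunk)])
  } else {
    data.table::data.table(cycle = integer(), period = integer(),
                           source = integer(), target = integer(),
                           crop = integer(), volume = numeric())
  }

  series <- data.frame(cycle = seq_len(n_cycles), phase = phases, H = H,
                       stock_pre = stock_pre, stock_post = stock_post)
  run <- structure(list(config = cfg, network = s$net, series = series,
                        trade_log = trade_log, final_state = s),
                   class = "fcs_run")
  run$summary <- run_summary(run)
  run
}

#' Per-run summary scalars
#'
#' Computes the pre-shock and shock window means of consumer satisfaction,
#' the relative impact of the shock, mean accumulated trader stock over the
#' pre-shock window, and the capacity/efficiency/resilience decomposition of
#' the window-averaged flow matrices.
#'
#' @param run An `fcs_run`.
#' @return A list with `H_p1`, `H_p2`, `E`, `stock_p1`, and `metrics_p1` /
#'   `metrics_p2` (each an `fcs_ulanowicz`). Shock-window entries are `NA`
#'   when the run has no shock phase.
#' @export
run_summary <- function(run) {
  cfg <- run$config
  p1 <- window_cycles(cfg, "stationary")
  p2 <- window_cycles(cfg, "shock")
  H_p1 <- if (length(p1)) mean(run$series$H[p1]) else NA_real_
  H_p2 <- if (length(p2)) mean(run$series$H[p2]) else NA_real_
  E <- if (!is.na(H_p1) && !is.na(H_p2) && H_p1 > 0) impact(H_p1, H_p2)
       else NA_real_
  stock_p1 <- if (length(p1)) mean(run$series$stock_pre[p1]) else NA_real_
  m1 <- if (length(p1) && nrow(run$trade_log))
    ulanowicz(aggregate_flows(run$trade_log, range(p1), run$network)) else NULL
  m2 <- if (length(p2) && nrow(run$trade_log))
    ulanowicz(aggregate_flows(run$trade_log, range(p2), run$network)) else NULL
  list(H_p1 = H_p1, H_p2 = H_p2, E = E, stock_p1 = stock_p1,
       metrics_p1 = m1, metrics_p2 = m2)
}

# cycle indices of a named phase window
window_cycles <- function(cfg, phase = c("spinup", "stationary", "shock",
                                         "postshock")) {
  phase <- match.arg(phase)
  lens <- c(spinup = cfg$SpinupPeriod, stationary = cfg$StationaryPeriod,
            shock = cfg$ShockDuration, postshock = cfg$PostShockPeriod)
  start <- cumsum(c(0, lens))[match(phase, names(lens))]
  if (lens[[phase]] == 0L) return(integer(0))
  start + seq_len(lens[[phase]])
}

#' @export
print.fcs_run <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Simulation run: network %s, mode %s, shock %s\n",
              x$config$network$code, x$config$ChoiceModel, x$config$ShockType))
  cat(sprintf("  H (pre-shock) = %.4f, H (shock) = %.4f, impact E = %.4f\n",
              s$H_p1, s$H_p2, s$E))
  cat(sprintf("  mean pre-shock stock = %.3f\n", s$stock_p1))
  if (!is.null(s$metrics_p1))
    cat(sprintf("  pre-shock flows: C = %.3f, A = %.3f, B = %.3f, A:B = %.4f\n",
                s$metrics_p1$C, s$metrics_p1$A, s$metrics_p1$B,
                s$metrics_p1$ratio))
  invisible(x)
}
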