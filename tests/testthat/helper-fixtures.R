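# Shared helpers for the test suite -----------------------------------------

# short-phase configuration for fast engine tests
short_config <- function(network = "bs", spinup = 5L, stationary = 10L,
                         shock = 5L, ...) {
  sim_config(network, SpinupPeriod = spinup, StationaryPeriod = stationary,
             ShockDuration = shock, ...)
}

# independent loop-based oracle for the information decomposition on a
# square flow matrix (never shares code with ulanowicz())
brute_ulanowicz <- function(M) {
  Ftot <- sum(M)
  fi <- rowSums(M)
  fj <- colSums(M)
  A <- B <- C <- 0
  for (i in seq_len(nrow(M))) for (j in seq_len(ncol(M))) {
    f <- M[i, j]
    if (f > 0) {
      A <- A + f * log(f * Ftot / (fi[i] * fj[j]))
      B <- B - f * log(f^2 / (fi[i] * fj[j]))
      C <- C - f * log(f / Ftot)
    }
  }
  list(A = A, B = B, C = C)
}

# per-cycle mass-balance ledger from a run's log and stock series:
# stock_pre[c] must equal stock_post[c-1] + deliveries_in - consumer_sales
ledger_residuals <- function(run) {
  log <- run$trade_log
  n <- nrow(run$series)
  inflow <- outflow <- numeric(n)
  prod_rows <- log$period == 0L
  a <- tapply(log$volume[prod_rows], log$cycle[prod_rows], sum)
  inflow[as.integer(names(a))] <- a
  b <- tapply(log$volume[!prod_rows], log$cycle[!prod_rows], sum)
  outflow[as.integer(names(b))] <- b
  prev <- c(0, run$series$stock_post[-n])
  run$series$stock_pre - (prev + inflow - outflow)
}
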