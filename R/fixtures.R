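#' Small deterministic test scenarios
#'
#' A registry of tiny configurations and a hand-written trade log with a
#' known flow matrix, used by the test suite and for demonstrations.
#'
#' * `"minimal-chain"`: 1 producer, 1 trader, 1 consumer (2 potential
#'   links); every trade must use the single chain.
#' * `"two-path"`: 1 producer, 2 traders, 1 consumer; with equal routing
#'   its flow matrix is the parallel-path case where efficiency equals
#'   resilience.
#' * `"bs-defaults"`: the small block network with all default parameters.
#' * `"hand-log"`: a 6-record trade log over the minimal two-path network,
#'   spanning cycles 1-2; averaged over that window the documented flow
#'   matrix is P1->T2: 7.5, T2->C4: 4, P1->T3: 2.5, T3->C4: 1 (agent ids
#'   1 = producer, 2-3 = traders, 4 = consumer).
#'
#' @param name Fixture name.
#' @return For config fixtures, an [sim_config()] object; for `"hand-log"`,
#'   a list with `log` (data.table), `network`, `window`, and the documented
#'   `flows` data frame.
#' @export
make_fixture <- function(name = c("minimal-chain", "two-path", "bs-defaults",
                                  "hand-log")) {
  name <- match.arg(name)
  switch(name,
    "minimal-chain" = sim_config(network_spec("custom", 1, 1, 1), seed = 1L),
    "two-path" = sim_config(network_spec("custom", 1, 2, 1), seed = 1L),
    "bs-defaults" = sim_config("bs", seed = 1L),
    "hand-log" = {
      net <- make_network(network_spec("custom", 1, 2, 1))
      log <- data.table::data.table(
        cycle  = c(1L, 1L, 1L, 2L, 2L, 2L),
        period = c(0L, 1L, 0L, 0L, 1L, 2L),
        source = c(1L, 2L, 1L, 1L, 3L, 2L),
        target = c(2L, 4L, 3L, 2L, 4L, 4L),
        crop   = 1L,
        volume = c(10, 3, 5, 5, 2, 5))
      flows <- data.frame(source = c(1L, 1L, 2L, 3L),
                          target = c(2L, 3L, 4L, 4L),
                          flow = c(7.5, 2.5, 4, 1))
      list(log = log, network = net, window = c(1L, 2L), flows = flows)
    })
}
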