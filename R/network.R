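#' Named layered trade-network topologies
#'
#' The simulator uses strictly hierarchical three-layer networks: producers
#' sell only to traders, traders sell only to consumers. Seven named
#' topologies cover four structural types (block, inverse pyramid, hourglass,
#' diamond) at one or two sizes each.
#'
#' @return A data frame with one row per named network and columns
#'   `code`, `type`, `n_producers`, `n_traders`, `n_consumers`.
#' @export
network_table <- function() {
  data.frame(
    code        = c("bs", "bl", "is", "il", "h", "ds", "dl"),
    type        = c("block", "block", "inverse_pyramid", "inverse_pyramid",
                    "hourglass", "diamond", "diamond"),
    n_producers = c(5L, 20L, 5L, 10L, 25L, 5L, 10L),
    n_traders   = c(5L, 20L, 25L, 50L, 5L, 50L, 100L),
    n_consumers = c(5L, 20L, 50L, 100L, 50L, 25L, 50L),
    stringsAsFactors = FALSE
  )
}

#' Specify a layered network
#'
#' Either give one of the seven named codes (`"bs"`, `"bl"`, `"is"`, `"il"`,
#' `"h"`, `"ds"`, `"dl"`), whose layer sizes are fixed, or `code = "custom"`
#' together with explicit positive layer counts.
#'
#' @param code Network code, one of the seven named codes or `"custom"`.
#' @param n_producers,n_traders,n_consumers Layer sizes; required (and only
#'   allowed) when `code = "custom"`.
#' @return An object of class `fcs_network_spec`.
#' @examples
#' network_spec("h")
#' network_spec("custom", 1, 1, 1)
#' @export
network_spec <- function(code = "custom", n_producers = NULL,
                         n_traders = NULL, n_consumers = NULL) {
  tab <- network_table()
  if (code %in% tab$code) {
    row <- tab[tab$code == code, ]
    if (!is.null(n_producers) || !is.null(n_traders) || !is.null(n_consumers))
      stop("layer sizes are fixed for named network code '", code,
           "'; use code = \"custom\" to set them", call. = FALSE)
    spec <- list(code = code, type = row$type,
                 n_producers = row$n_producers, n_traders = row$n_traders,
                 n_consumers = row$n_consumers)
  } else if (identical(code, "custom")) {
    counts <- c(n_producers, n_traders, n_consumers)
    if (length(counts) != 3L || any(is.na(counts)) || any(counts < 1) ||
        any(counts != as.integer(counts)))
      stop("custom networks need three strictly positive integer layer sizes",
           call. = FALSE)
    spec <- list(code = "custom", type = "custom",
                 n_producers = as.integer(n_producers),
                 n_traders = as.integer(n_traders),
                 n_consumers = as.integer(n_consumers))
  } else {
    stop("unknown network code '", code, "'", call. = FALSE)
  }
  structure(spec, class = "fcs_network_spec")
}

#' Build a layered producer-trader-consumer network
#'
#' Agent identifiers are integers assigned layer by layer, producers first,
#' so networks (and everything derived from them, e.g. flow matrices and
#' edge lists) are deterministic for a given spec.
#'
#' @param spec An `fcs_network_spec`, or a network code passed to
#'   [network_spec()].
#' @param ... Passed on to [network_spec()] when `spec` is a code.
#' @return An object of class `fcs_network` with integer id vectors
#'   `producer_ids`, `trader_ids`, `consumer_ids` and the data frame
#'   `potential_links` (columns `source`, `target`) holding every permitted
#'   producer-to-trader and trader-to-consumer pair.
#' @examples
#' net <- make_network("bs")
#' count_potential_links(net)
#' @export
make_network <- function(spec, ...) {
  if (is.character(spec)) spec <- network_spec(spec, ...)
  stopifnot(inherits(spec, "fcs_network_spec"))
  np <- spec$n_producers; nt <- spec$n_traders; nc <- spec$n_consumers
  producer_ids <- seq_len(np)
  trader_ids   <- np + seq_len(nt)
  consumer_ids <- np + nt + seq_len(nc)
  pt <- expand.grid(source = producer_ids, target = trader_ids,
                    KEEP.OUT.ATTRS = FALSE)
  tc <- expand.grid(source = trader_ids, target = consumer_ids,
                    KEEP.OUT.ATTRS = FALSE)
  links <- rbind(pt, tc)
  links <- links[order(links$source, links$target), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(
    spec = spec,
    producer_ids = producer_ids,
    trader_ids = trader_ids,
    consumer_ids = consumer_ids,
    potential_links = links
  ), class = "fcs_network")
}

#' Count the potential trade links of a layered network
#'
#' The "hard" boundary of the topology: every producer can in principle sell
#' to every trader and every trader to every consumer, giving
#' `n_producers * n_traders + n_traders * n_consumers` ordered pairs.
#'
#' @param net An `fcs_network` (or spec/code accepted by [make_network()]).
#' @return Integer link count.
#' @examples
#' count_potential_links(make_network("h"))  # 375
#' @export
count_potential_links <- function(net) {
  if (!inherits(net, "fcs_network")) net <- make_network(net)
  s <- net$spec
  as.integer(s$n_producers * s$n_traders + s$n_traders * s$n_consumers)
}

#' @export
print.fcs_network <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Layered trade network '%s' (%s): %d producers, %d traders, %d consumers; %d potential links\n",
              s$code, s$type, s$n_producers, s$n_traders, s$n_consumers,
              count_potential_links(x)))
  invisible(x)
}

#' Write the potential-link set as a two-column TSV edge list
#'
#' @param net An `fcs_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_potential_links <- function(net, path) {
  stopifnot(inherits(net, "fcs_network"))
  utils::write.table(
    data.frame(source_id = net$potential_links$source,
               target_id = net$potential_links$target),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# layer lookup used by the engine and metrics
agent_layer <- function(net, ids) {
  out <- character(length(ids))
  out[ids %in% net$producer_ids] <- "producer"
  out[ids %in% net$trader_ids]   <- "trader"
  out[ids %in% net$consumer_ids] <- "consumer"
  out
}
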