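test_that("initialization spreads production and demand equally", {
  s <- init_simulation(sim_config("bs"))
  expect_equal(s$production, rep(20, 5))           # 100 / 5 producers
  expect_equal(s$production_memory, s$production)
  expect_equal(rowSums(s$demand_cycle), rep(24, 5))  # 120 / 5 consumers
  expect_equal(s$demand_period, matrix(1, 5, 2))   # 24 / 2 crops / 12 periods
  expect_true(all(s$stock == 0))
  expect_false(any(s$prod_hist) || any(s$cons_hist))

  s1 <- init_simulation(sim_config("bs", seed = 11))
  s2 <- init_simulation(sim_config("bs", seed = 11))
  for (f in c("production", "demand_cycle", "stock", "crop"))
    expect_identical(s1[[f]], s2[[f]])
})

test_that("crop assignment is uniform over crop types", {
  cfg <- sim_config("bs", N_CropTypes = 1L)
  s <- init_simulation(cfg)
  assign_crops(s)
  expect_true(all(s$crop == 1L))

  s <- init_simulation(sim_config("bs", N_CropTypes = 2L, seed = 5))
  draws <- integer(0)
  for (i in 1:2000) {  # 10 000 producer-cycles
    assign_crops(s)
    draws <- c(draws, s$crop)
  }
  counts <- tabulate(draws, 2L)
  p <- chisq.test(counts)$p.value
  expect_gt(p, 1e-3)
})

test_that("random-mode partner selection is uniform over traders", {
  s <- init_simulation(sim_config("bs", ChoiceModel = "random", seed = 2))
  assign_crops(s)
  picks <- replicate(5000, select_trader_for_producer(s, 1L))
  counts <- table(factor(picks, levels = s$net$trader_ids))
  expect_gt(chisq.test(counts)$p.value, 1e-3)
})

test_that("weighted producer selection matches the brute-force weight vector", {
  # two traders with stocks (20, 60) of the producer's crop, floor weight 10:
  # raw weights (10 + 40, 10 + 0) so trader 1 has probability 50/60
  cfg <- sim_config(network_spec("custom", 1, 2, 1), ChoiceModel = "weighted",
                    BasePreference = 10, seed = 8)
  s <- init_simulation(cfg)
  s$crop <- 1L
  s$stock <- matrix(c(20, 60, 0, 0), 2, 2)
  W <- producer_weights(s)
  expect_equal(as.vector(W), c(10 + 40, 10 + 0))
  p1 <- W[1] / sum(W)
  picks <- replicate(6000, select_trader_for_producer(s, 1L))
  freq <- mean(picks == s$net$trader_ids[1])
  expect_lt(abs(freq - p1), 0.02)
})

test_that("preference consumer selection matches the closed-form probability", {
  # two traders, equal stock 5, one historic partner: weights
  # (0.01 + 5 + 100, 0.01 + 5)
  cfg <- sim_config(network_spec("custom", 1, 2, 1),
                    ChoiceModel = "preference", seed = 13)
  s <- init_simulation(cfg)
  s$stock <- matrix(5, 2, s$ncrop)
  hist0 <- s$cons_hist
  hist0[1, 1] <- TRUE
  s$cons_hist <- hist0
  W <- consumer_weights(s, 1L)$W
  expect_equal(as.vector(W), c(105.01, 5.01))
  p1 <- W[1] / sum(W)
  hits <- logical(4000)
  for (i in seq_along(hits)) {
    s$cons_hist <- hist0  # keep the historic set fixed across draws
    hits[i] <- select_trader_for_consumer(s, 1L, 1L) == s$net$trader_ids[1]
  }
  expect_lt(abs(mean(hits) - p1), 0.02)

  # all traders empty in weighted mode: weights collapse to the floor
  s2 <- init_simulation(sim_config(network_spec("custom", 1, 3, 2),
                                   ChoiceModel = "weighted", seed = 3))
  W2 <- consumer_weights(s2, 1L)$W
  expect_true(all(W2 == W2[1]))
})

test_that("a single trader is always selected regardless of mode", {
  for (mode in c("random", "weighted", "preference")) {
    s <- init_simulation(sim_config(network_spec("custom", 2, 1, 2),
                                    ChoiceModel = mode, seed = 4))
    assign_crops(s)
    expect_identical(select_trader_for_producer(s, 1L), s$net$trader_ids[1])
    expect_identical(select_trader_for_consumer(s, 2L, 1L),
                     s$net$trader_ids[1])
  }
})

test_that("traders split stock evenly up to the buyers' remaining demand", {
  # stock 10, 4 buyers each wanting 2: everyone gets 2, 2 stays in store
  give <- allocate_to_consumers(10, matrix(2, 4, 1))
  expect_equal(as.vector(give), rep(2, 4))
  # stock 4, 4 buyers wanting 5 each: everyone gets the equal share 1
  give <- allocate_to_consumers(4, matrix(5, 4, 1))
  expect_equal(as.vector(give), rep(1, 4))
  # a buyer with zero remaining demand receives nothing
  give <- allocate_to_consumers(9, matrix(c(3, 0, 3), 3, 1))
  expect_equal(as.vector(give), c(3, 0, 3))
})

test_that("production deliveries conserve mass into trader stocks", {
  cfg <- short_config(shock = 0L, seed = 21)
  run <- run_simulation(cfg)
  prod <- run$trade_log[run$trade_log$period == 0L, ]
  per_cycle <- tapply(prod$volume, prod$cycle, sum)
  expect_true(all(abs(per_cycle - 100) < 1e-9))  # TotalProduction delivered
})

test_that("the per-cycle mass-balance ledger holds exactly", {
  for (shock_type in c("producer", "consumer")) {
    run <- run_simulation(short_config(shock = 5L, ShockType = shock_type,
                                       seed = 31))
    expect_lt(max(abs(ledger_residuals(run))), 1e-9)
    # persistence loss is exactly (1 - StockPersistence) of pre-persistence stock
    expect_equal(run$series$stock_post,
                 run$series$stock_pre * run$config$StockPersistence)
  }
  run0 <- run_simulation(short_config(shock = 0L, seed = 32))
  expect_lt(max(abs(ledger_residuals(run0))), 1e-9)
})

test_that("every logged trade uses a potential link and is nonnegative", {
  run <- run_simulation(short_config(network = "is", shock = 5L, seed = 41))
  links <- run$network$potential_links
  key <- paste(run$trade_log$source, run$trade_log$target)
  expect_true(all(key %in% paste(links$source, links$target)))
  expect_true(all(run$trade_log$volume > 0))
})

test_that("same seed gives bit-identical trade logs, different seeds differ", {
  r1 <- run_simulation(short_config(seed = 7))
  r2 <- run_simulation(short_config(seed = 7))
  expect_identical(r1$trade_log, r2$trade_log)
  expect_identical(r1$series, r2$series)
  r3 <- run_simulation(short_config(seed = 8))
  expect_false(identical(r1$trade_log, r3$trade_log))
})

test_that("shock onset draws round(severity x level size) distinct agents", {
  cfg <- sim_config("bl", ShockType = "producer", ShockSeverity = 0.5)
  s <- init_simulation(cfg)
  apply_shock_onset(s)
  expect_length(s$shocked, 10L)  # 0.5 x 20 producers
  expect_false(any(duplicated(s$shocked)))
  expect_true(all(s$production[s$shocked] == 0))

  s <- init_simulation(sim_config("bs", ShockSeverity = 0))
  apply_shock_onset(s)
  expect_length(s$shocked, 0L)
})

test_that("a zero-severity shock leaves the trajectory untouched", {
  a <- run_simulation(short_config(ShockSeverity = 0, ShockType = "producer",
                                   seed = 51))
  b <- run_simulation(short_config(ShockSeverity = 0, ShockType = "consumer",
                                   seed = 51))
  expect_identical(a$trade_log, b$trade_log)
  noshock <- run_simulation(short_config(shock = 0L, seed = 51))
  shared <- a$trade_log[a$trade_log$cycle <= max(noshock$series$cycle), ]
  expect_equal(as.data.frame(shared), as.data.frame(noshock$trade_log))
})

test_that("a full-severity producer shock stops all production", {
  run <- run_simulation(short_config(ShockSeverity = 1,
                                     ShockType = "producer", seed = 61))
  shock_cycles <- which(run$series$phase == "shock")
  prod <- run$trade_log[run$trade_log$period == 0L, ]
  expect_false(any(prod$cycle %in% shock_cycles))
})

test_that("shocked consumers shift all demand of one crop onto another", {
  cfg <- sim_config("bs", ShockType = "consumer", ShockSeverity = 1)
  s <- init_simulation(cfg)
  before <- s$demand_cycle
  apply_shock_onset(s)
  expect_equal(rowSums(s$demand_cycle), rowSums(before))  # demand conserved
  expect_true(all(apply(s$demand_cycle, 1, function(r) sum(r == 0)) == 1))
  expect_equal(s$demand_memory, before)  # memory untouched
})

test_that("stock persistence scales stocks at cycle end", {
  cfg <- sim_config("bs", StockPersistence = 0.95)
  s <- init_simulation(cfg)
  s$stock[] <- 100
  end_of_cycle(s)
  expect_true(all(s$stock == 95))

  # persistence 0 empties all stores at each cycle boundary
  run <- run_simulation(short_config(StockPersistence = 0, shock = 0L,
                                     seed = 71))
  expect_true(all(run$series$stock_post == 0))

  # persistence 1 with no trade keeps stock constant
  cfg <- sim_config("bs", StockPersistence = 1)
  s <- init_simulation(cfg)
  s$stock[] <- 7
  end_of_cycle(s)
  expect_true(all(s$stock == 7))
})

test_that("zero total demand yields full satisfaction and zero impact", {
  run <- run_simulation(short_config(TotalDemand = 0, seed = 81))
  expect_true(all(run$series$H == 1))
  expect_equal(run$summary$E, 0)
})

test_that("runs simulate the configured number of cycles and rounds", {
  cfg <- short_config(spinup = 3L, stationary = 4L, shock = 2L, seed = 91)
  run <- run_simulation(cfg)
  expect_identical(nrow(run$series), 9L)
  expect_identical(run$series$phase,
                   rep(c("spinup", "stationary", "shock"), c(3, 4, 2)))
  # consumption rounds: Periods per cycle
  expect_true(all(run$trade_log$period %in% 0:cfg$Periods))
})

test_that("post-shock recovery restores production and demand", {
  run <- run_simulation(short_config(ShockType = "producer", ShockSeverity = 1,
                                     PostShockPeriod = 5L, seed = 95))
  post_cycles <- which(run$series$phase == "postshock")
  prod <- run$trade_log[run$trade_log$period == 0L, ]
  per_cycle <- tapply(prod$volume, prod$cycle, sum)
  expect_true(all(abs(per_cycle[as.character(post_cycles)] - 100) < 1e-9))
})

test_that("long-run random-mode link occupancy is uniform over producer-trader pairs", {
  run <- run_simulation(sim_config("bs", ChoiceModel = "random",
                                   SpinupPeriod = 0L, StationaryPeriod = 200L,
                                   ShockDuration = 0L, seed = 101))
  prod <- run$trade_log[run$trade_log$period == 0L, ]
  counts <- table(factor(paste(prod$source, prod$target),
                         levels = paste(rep(1:5, each = 5), rep(6:10, 5))))
  expect_gt(chisq.test(as.vector(counts))$p.value, 1e-3)
})
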