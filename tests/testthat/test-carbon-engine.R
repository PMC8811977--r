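# The 14-pool annual state machine: decay scaling, flow ordering,
# disturbance flows, conservation.

test_that("effective decay rate reproduces Q10 scaling", {
  expect_equal(effective_decay_rate(0.2, 10, 10, 2.0), 0.2)
  expect_equal(effective_decay_rate(0.2, 20, 10, 2.0) / 0.2, 2.0)
  expect_equal(effective_decay_rate(0.2, 20, 10, 2.65) / 0.2, 2.65)
  # closed-form equivalence exp((T-Tref)*ln(Q10)*0.1) == Q10^((T-Tref)/10)
  for (Temp in seq(-20, 40, by = 2.5)) {
    expect_equal(effective_decay_rate(1, Temp, 10, 2.65),
                 2.65^((Temp - 10) / 10))
  }
  expect_error(effective_decay_rate(-0.1, 10), "bdr")
  expect_error(effective_decay_rate(0.1, 10, q10 = 0), "q10")
})

test_that("single-flow arithmetic: snag fall moves carbon down, nothing else", {
  fl <- forestflux:::resolve_flows(ff_params()$flows, list(
    species_name = DF, class = "softwood"))
  fl$snag_fall[] <- c(0.1, 0)
  fl$bdr[] <- 0
  sched <- forestflux:::null_schedule(10)
  st <- carbon_base_step(pool_vector(SnagStem = 10), 1, sched, fl)
  expect_equal(unname(st$pools[1, "SnagStem"]), 9)
  expect_equal(unname(st$pools[1, "AbovegroundMedium"]), 1)
  expect_equal(sum(st$pools), 10)
  # all-zero state with zero growth stays zero with a zero ledger
  z <- carbon_base_step(pool_vector(), 1, sched, fl, growth_mult = 0)
  expect_true(all(z$pools == 0))
  expect_true(all(unlist(z$ledger[c("npp", "rh", "turnover")]) == 0))
})

test_that("base step conserves mass: dTEC = NPP - Rh", {
  set.seed(101)
  for (i in 1:100) {
    fl <- ff_random_flows()
    sched <- ff_random_schedule()
    P <- matrix(runif(14 * 3, 0, 50), 3, 14,
                dimnames = list(NULL, carbon_pools()))
    st <- carbon_base_step(P, sample(0:20, 3, TRUE), sched, fl,
                           temp = runif(1, -5, 25),
                           growth_mult = runif(3, 0, 2),
                           dm_fast = runif(3, 0.5, 1.8),
                           dm_slow = runif(3, 0.5, 1.8))
    dtec <- rowSums(st$pools) - rowSums(P)
    expect_true(all(abs(dtec - (st$ledger$npp - st$ledger$rh)) <
                      1e-9 * pmax(rowSums(P), 1)))
    expect_true(all(st$pools >= 0))
  }
})

test_that("the 8-step flow order matches an independent scalar oracle", {
  params <- ff_params()
  df <- ff_species(DF)
  fl <- forestflux:::resolve_flows(params$flows, as.list(df))
  tabs <- ff_tables(DF)[[DF]]
  sched <- attr(tabs, "context")$schedule
  p0 <- tabs$fire$stocks[81, ]  # a mid-aged stand state
  age <- 81L
  dmf <- 1.3; dms <- 1.1
  # --- oracle: scalar re-implementation of the ordered steps ---
  x <- p0
  rh <- 0
  edr <- fl$bdr * fl$q10^((df$mean_temp_c - 10) / 10)
  dm <- ifelse(fl$q10 == 2.65, dmf, dms)
  dec <- function(x, pool, slow) {
    out <- x[[pool]] * min(edr[[pool]] * dm[[pool]], 1)
    x[[pool]] <- x[[pool]] - out
    rh <<- rh + fl$p_air[[pool]] * out
    x[[slow]] <- x[[slow]] + (1 - fl$p_air[[pool]]) * out
    x
  }
  fs <- x[["SnagStem"]] * fl$snag_fall[["SnagStem"]]
  fb <- x[["SnagBranch"]] * fl$snag_fall[["SnagBranch"]]
  x[["SnagStem"]] <- x[["SnagStem"]] - fs
  x[["AbovegroundMedium"]] <- x[["AbovegroundMedium"]] + fs
  x[["SnagBranch"]] <- x[["SnagBranch"]] - fb
  x[["AbovegroundFast"]] <- x[["AbovegroundFast"]] + fb
  x <- dec(x, "SnagStem", "AbovegroundSlow")
  x <- dec(x, "SnagBranch", "AbovegroundSlow")
  x <- dec(x, "AbovegroundMedium", "AbovegroundSlow")
  x <- dec(x, "BelowgroundSlow", "BelowgroundSlow")
  for (pool in carbon_pools("live")) {
    t_out <- x[[pool]] * fl$turnover[[pool]]
    x[[pool]] <- x[[pool]] - t_out
    dst <- forestflux:::FF_TURNOVER_DEST[[pool]]
    x[[dst]] <- x[[dst]] + t_out
  }
  x <- dec(x, "BelowgroundVeryFast", "BelowgroundSlow")
  x <- dec(x, "BelowgroundFast", "BelowgroundSlow")
  x <- dec(x, "AbovegroundVeryFast", "AbovegroundSlow")
  x <- dec(x, "AbovegroundFast", "AbovegroundSlow")
  x <- dec(x, "AbovegroundSlow", "AbovegroundSlow")
  tr <- x[["AbovegroundSlow"]] * fl$slow_transfer
  x[["AbovegroundSlow"]] <- x[["AbovegroundSlow"]] - tr
  x[["BelowgroundSlow"]] <- x[["BelowgroundSlow"]] + tr
  x[carbon_pools("live")] <- x[carbon_pools("live")] +
    sched$npp[age + 1] * sched$pnpp[age + 1, ]
  # --- engine ---
  st <- carbon_base_step(p0, age, sched, fl, temp = df$mean_temp_c,
                         dm_fast = dmf, dm_slow = dms)
  expect_equal(st$pools[1, ], x, tolerance = 1e-12)
  expect_equal(st$ledger$rh, rh, tolerance = 1e-12)
})

test_that("extreme decay multipliers are capped, never negative", {
  fl <- forestflux:::resolve_flows(ff_params()$flows,
                                   list(species_name = DF,
                                        class = "softwood"))
  P <- pool_vector(AbovegroundVeryFast = 10, BelowgroundFast = 5)
  st <- carbon_base_step(P, 1, forestflux:::null_schedule(10), fl,
                         dm_fast = 1e6, dm_slow = 1e6)
  expect_true(all(st$pools >= 0))
  expect_gt(st$ledger$clipped, 0)  # capping is logged, never silent
})

test_that("transition flows move proportions and conserve mass", {
  dmat <- ff_params()$disturbance
  # identity matrix (all proportions zero) leaves the state unchanged
  id <- data.frame(transition_type = "noop", source_pool = "Merchantable",
                   destination = "atmosphere", proportion = 0)
  P <- pool_vector(Merchantable = 100, Foliage = 5)
  st <- apply_transition_flows(P, id, "noop")
  expect_equal(st$pools[1, ], P)
  # clearcut arithmetic on a custom matrix: 0.9 of merchantable to export
  cc <- data.frame(transition_type = "cc", source_pool = "Merchantable",
                   destination = "export", proportion = 0.9)
  st <- apply_transition_flows(pool_vector(Merchantable = 100), cc, "cc")
  expect_equal(st$ledger$harvest, 90)
  expect_equal(unname(st$pools[1, "Merchantable"]), 10)
  expect_error(apply_transition_flows(P, dmat, "no_such_transition"),
               "unknown transition")
  # conservation on random states across all packaged transition types
  set.seed(202)
  for (tr in unique(dmat$transition_type)) {
    P <- matrix(runif(14 * 4, 0, 80), 4, 14,
                dimnames = list(NULL, carbon_pools()))
    st <- apply_transition_flows(P, dmat, tr)
    tec0 <- rowSums(P)
    tec1 <- rowSums(st$pools) + st$ledger$combustion + st$ledger$harvest
    expect_true(all(abs(tec0 - tec1) < 1e-9 * pmax(tec0, 1)))
    expect_true(all(st$pools >= 0))
  }
  # insect transitions: mortality only, no emission or export
  for (tr in c("insect_high", "insect_medium", "insect_low")) {
    st <- apply_transition_flows(pool_vector(Merchantable = 50, Foliage = 5),
                                 dmat, tr)
    expect_equal(st$ledger$combustion, 0)
    expect_equal(st$ledger$harvest, 0)
    expect_gt(st$ledger$mortality, 0)
  }
})

test_that("carbon to CO2 conversion uses the 44/12 molar ratio", {
  expect_equal(carbon_to_co2(0), 0)
  expect_equal(carbon_to_co2(12), 44)
  expect_equal(carbon_to_co2(73.5), 269.5)
  expect_error(carbon_to_co2(-1), "mass_c")
})
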