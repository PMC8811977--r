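# Scenario orchestration: accounting identities, toggles, determinism.

test_that("accounting identities hold on a disturbed, climate-driven run", {
  d <- ff_demo()
  cfg <- scenario_config(years = 10, clearcut_fraction = 0.005,
                         selection_fraction = 0.002,
                         urbanization_prob = 0.001, seed = 3)
  res <- run_scenario(d$landscape, ff_params(), d$tables, cfg,
                      climate = d$climate, fire_events = d$fire)
  acc <- res$accounts
  expect_equal(acc$nep, acc$npp - acc$rh)
  expect_equal(acc$nbp, acc$nep - acc$combustion - acc$harvest)
  # stratum sums equal national totals
  nat <- aggregate_outputs(res)$national
  expect_equal(nat$nbp, res$annual$nbp)
  # cumulative NBP grid telescopes to total NBP
  expect_equal(sum(res$cum_nbp) * d$landscape$cell_area_ha,
               sum(res$annual$nbp), tolerance = 1e-9)
  # dTEC = NBP year over year
  tecs <- c(sum(d$landscape$pools) * d$landscape$cell_area_ha,
            res$annual$tec)
  expect_equal(diff(tecs), res$annual$nbp, tolerance = 1e-6)
})

test_that("same config and seed give bitwise-identical outputs", {
  d <- ff_demo()
  cfg <- scenario_config(years = 5, clearcut_fraction = 0.01, seed = 99)
  a <- run_scenario(d$landscape, ff_params(), d$tables, cfg,
                    climate = d$climate, fire_events = d$fire)
  b <- run_scenario(d$landscape, ff_params(), d$tables, cfg,
                    climate = d$climate, fire_events = d$fire)
  expect_identical(a$annual, b$annual)
  expect_identical(a$landscape$pools, b$landscape$pools)
  expect_identical(a$landscape$state_class, b$landscape$state_class)
})

test_that("disturbance only removes carbon: climate-only NBP dominates", {
  d <- ff_demo()
  base <- scenario_config(years = 8, climate_effects = TRUE,
                          lulc_disturbance = FALSE, seed = 5)
  dist <- scenario_config(years = 8, climate_effects = TRUE,
                          lulc_disturbance = TRUE,
                          clearcut_fraction = 0.01, seed = 5)
  a <- run_scenario(d$landscape, ff_params(), d$tables, base,
                    climate = d$climate)
  b <- run_scenario(d$landscape, ff_params(), d$tables, dist,
                    climate = d$climate, fire_events = d$fire)
  expect_true(all(a$annual$nbp >= b$annual$nbp))
})

test_that("steady state: NBP from the saturated stand matches the table oracle", {
  tabs <- ff_tables(DF)
  ctx <- attr(tabs[[DF]], "context")
  n <- 4L
  ls <- list(nrow = 2L, ncol = 2L, n = n, cell_area_ha = 1,
             species_names = DF, state_class = rep(1L, n),
             species = rep(1L, n), age = rep(300L, n), tst = rep(0L, n),
             last_dist = rep("fire", n), frozen = logical(n),
             stratum = rep(1L, n), protected = NULL, pools = NULL)
  ls <- initialize_landscape(ls, tabs)
  res <- run_scenario(ls, ff_params(), tabs,
                      scenario_config(years = 1, climate_effects = FALSE,
                                      lulc_disturbance = FALSE))
  # oracle: step the age-300 table row once directly
  st <- carbon_base_step(tabs[[DF]]$fire$stocks[301, ], 301, ctx$schedule,
                         ctx$flows, temp = ctx$temp)
  expect_equal(res$annual$npp, n * st$ledger$npp, tolerance = 1e-12)
  expect_equal(res$annual$rh, n * st$ledger$rh, tolerance = 1e-12)
  # mature stand: NPP approximately balances Rh (NBP near zero)
  expect_lt(abs(res$annual$nbp) / res$annual$npp, 0.15)
})

test_that("imposed clearcut everywhere exports the matrix share of stocks", {
  tabs <- ff_tables(DF)
  n <- 25L
  ls <- list(nrow = 5L, ncol = 5L, n = n, cell_area_ha = 1,
             species_names = DF, state_class = rep(1L, n),
             species = rep(1L, n), age = rep(80L, n), tst = rep(0L, n),
             last_dist = rep("clearcut", n), frozen = logical(n),
             stratum = rep(1L, n), protected = NULL, pools = NULL)
  ls <- initialize_landscape(ls, tabs)
  # reference run without harvest gives the pre-transition pools
  ref <- run_scenario(ls, ff_params(), tabs,
                      scenario_config(years = 1, climate_effects = FALSE,
                                      lulc_disturbance = FALSE,
                                      record_pools = TRUE))
  pre <- ref$pools_by_year[[1]]
  dmat <- ff_params()$disturbance
  cc <- dmat[dmat$transition_type == "clearcut" & dmat$destination == "export", ]
  expected <- sum(vapply(seq_len(nrow(cc)), function(i)
    sum(pre[, cc$source_pool[i]]) * cc$proportion[i], numeric(1)))
  res <- run_scenario(ls, ff_params(), tabs,
                      scenario_config(years = 1, climate_effects = FALSE,
                                      clearcut_fraction = 1, seed = 1))
  expect_equal(res$annual$harvest, expected, tolerance = 1e-9)
  expect_true(all(res$landscape$age == 0L))
})

test_that("aggregation arithmetic: density, mass, additivity", {
  # one cell, 0.5 tons C/ha/yr over 100 ha = 50 tons C/yr
  tabs <- ff_tables(DF)
  d <- ff_demo()
  res <- run_scenario(d$landscape, ff_params(), d$tables,
                      scenario_config(years = 2, climate_effects = FALSE,
                                      lulc_disturbance = FALSE))
  agg <- aggregate_outputs(res)
  expect_equal(sum(agg$by_stratum$nbp[agg$by_stratum$year == 1]),
               agg$national$nbp[1])
  expect_equal(agg$national$nbp_tg_c, agg$national$nbp / 1e6)
  expect_equal(unname(unlist(agg$mean_annual["nbp_tg_c"])),
               mean(res$annual$nbp) / 1e6)
})
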