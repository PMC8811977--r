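# State-and-transition scheduling, severity, recovery, bootstrap,
# reforestation, and state bookkeeping rules.

# a bare non-carbon landscape for scheduling tests
bare_landscape <- function(n, class = 1L, species = 1L, age = 50L,
                           nrow = n, ncol = 1L) {
  list(nrow = nrow, ncol = ncol, n = n, cell_area_ha = 100,
       species_names = DF, state_class = rep(as.integer(class), n),
       species = rep(as.integer(species), n), age = rep(as.integer(age), n),
       tst = rep(0L, n), last_dist = rep("clearcut", n), frozen = logical(n),
       stratum = rep(1L, n), protected = NULL, pools = NULL)
}

test_that("probability scheduling matches the binomial oracle", {
  n <- 100000L
  ls <- bare_landscape(n)
  def <- transition_definition("clearcut", 1L, "probability",
                               probability = 0.05)
  got <- schedule_transitions(ls, list(def), seed = 31)
  p <- 0.05
  expect_lt(abs(nrow(got) / n - p), 4 * sqrt(p * (1 - p) / n))
  # probability 0: nothing fires
  def0 <- transition_definition("clearcut", 1L, "probability",
                                probability = 0)
  expect_identical(nrow(schedule_transitions(ls, list(def0), seed = 31)), 0L)
  # determinism
  again <- schedule_transitions(ls, list(def), seed = 31)
  expect_identical(got, again)
})

test_that("event and target-area scheduling count cells exactly", {
  n <- 1000L
  ls <- bare_landscape(n)
  mask <- logical(n); mask[c(5, 77, 300)] <- TRUE
  defe <- transition_definition("fire", 1L, "event", event = "fire")
  got <- schedule_transitions(ls, list(defe), events = list(fire = mask))
  expect_setequal(got$cell, c(5, 77, 300))
  deft <- transition_definition("clearcut", 1L, "target_area",
                                target_fraction = 0.1)
  gt <- schedule_transitions(ls, list(deft), seed = 5)
  expect_identical(nrow(gt), 100L)
  # min-age rule removes young stands from eligibility
  ls$age[1:900] <- 10L
  defm <- transition_definition("clearcut", 1L, "target_area",
                                target_fraction = 1, min_age = 40L)
  gm <- schedule_transitions(ls, list(defm), seed = 5)
  expect_identical(nrow(gm), 100L)
  expect_true(all(ls$age[gm$cell] >= 40L))
})

test_that("fire severity draws follow the stratum multinomial split", {
  cells <- seq_len(30000L)
  sev <- assign_fire_severity(cells, rep(1L, length(cells)),
                              c(high = 1, medium = 0, low = 0), seed = 1)
  expect_true(all(sev == "fire_high"))
  sev3 <- assign_fire_severity(cells, rep(1L, length(cells)),
                               c(high = 1/3, medium = 1/3, low = 1/3),
                               seed = 2)
  fr <- table(sev3) / length(cells)
  tol <- 4 * sqrt((1/3) * (2/3) / length(cells))
  expect_true(all(abs(fr - 1/3) < tol))
  expect_identical(assign_fire_severity(integer(0), integer(0),
                                        c(high = 1, medium = 0, low = 0)),
                   character(0))
  expect_error(assign_fire_severity(1L, 1L, c(high = 0.5, medium = 0.2,
                                              low = 0.2)), "sum to 1")
})

test_that("post-fire recovery matches the configured probability", {
  n <- 100000L
  ls <- bare_landscape(n, class = state_classes()[["postfire_shrub"]])
  rec <- postfire_recovery(ls, probability = 0.064, seed = 77)
  p <- 0.064
  expect_lt(abs(length(rec) / n - p), 4 * sqrt(p * (1 - p) / n))
  expect_identical(postfire_recovery(ls, probability = 0, seed = 77),
                   integer(0))
  # geometric residence: mean time-to-recovery ~ 1/p
  set.seed(3)
  waits <- rgeom(20000, 0.064) + 1
  expect_lt(abs(mean(waits) - 1 / 0.064), 4 * (sqrt(1 - 0.064) / 0.064) /
              sqrt(20000))
})

test_that("bootstrap sampling stays on the historical support", {
  hist <- data.frame(year = 2001:2010, transition = "clearcut",
                     value = c(5, 8, 2, 9, 4, 7, 3, 6, 1, 10))
  got <- bootstrap_future_rates(hist, 1:10000, seed = 12)
  expect_true(all(got$value %in% hist$value))
  expect_lt(abs(mean(got$value) - mean(hist$value)),
            4 * sd(hist$value) / sqrt(10000))
  one <- data.frame(year = 2001, transition = "fire", value = 42)
  expect_true(all(bootstrap_future_rates(one, 1:5)$value == 42))
  expect_error(bootstrap_future_rates(hist[0, ], 1:5), "empty")
})

test_that("reforestation spreads the target area evenly within the mask", {
  n <- 400L
  ls <- bare_landscape(n, class = state_classes()[["shrubland"]],
                       species = 0L, age = 0L)
  ls$species[1:10] <- 1L  # a few burned cells remember their forest type
  mask <- c(rep(TRUE, 200), rep(FALSE, 200))
  sched <- schedule_reforestation(ls, mask, 3, 7, total_area_ha = 100 * 100,
                                  seed = 8)
  cells <- do.call(rbind, sched)
  expect_identical(nrow(cells), 100L)
  expect_true(all(cells$cell <= 200))
  counts <- vapply(sched, nrow, 1L)
  expect_true(all(abs(counts - 20) <= 1))
  expect_identical(length(schedule_reforestation(ls, mask, 3, 7, 0)), 0L)
  expect_warning(schedule_reforestation(ls, mask, 3, 7, 100 * 1e6),
                 "truncated")
})

test_that("state bookkeeping follows the age and class rules", {
  params <- ff_params()
  tabs <- ff_tables(DF)
  ls <- bare_landscape(5, age = 80L)
  ls <- initialize_landscape(ls, tabs)
  asg <- data.frame(
    cell = 1:4,
    transition = c("clearcut", "fire_high", "selection", "fire_low"),
    stringsAsFactors = FALSE)
  out <- apply_transitions(ls, asg, params)
  ls2 <- out$landscape
  # clearcut: same class, age reset to 0
  expect_identical(ls2$state_class[1], 1L)
  expect_identical(ls2$age[1], 0L)
  expect_identical(ls2$last_dist[1], "clearcut")
  # high severity fire: post-fire shrubland, species remembered, age 0
  expect_identical(ls2$state_class[2], state_classes()[["postfire_shrub"]])
  expect_identical(ls2$species[2], 1L)
  expect_identical(ls2$age[2], 0L)
  # selection harvest: age not reset
  expect_identical(ls2$age[3], 80L)
  # low severity: class and age unchanged, time-since-transition reset
  expect_identical(ls2$state_class[4], 1L)
  expect_identical(ls2$age[4], 80L)
  expect_identical(ls2$tst[4], 0L)
  # untouched cell unchanged
  expect_identical(ls2$age[5], 80L)
  # recovery returns the remembered forest class
  rec <- data.frame(cell = 2L, transition = "postfire_recovery")
  ls3 <- apply_transitions(ls2, rec, params)$landscape
  expect_identical(ls3$state_class[2], 1L)
  # conversions freeze the cell
  urb <- data.frame(cell = 5L, transition = "urbanization")
  ls4 <- apply_transitions(ls3, urb, params)$landscape
  expect_true(ls4$frozen[5])
  expect_identical(ls4$state_class[5], state_classes()[["developed"]])
})
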