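# Annual scenario orchestration: climate multipliers + carbon base step +
# landscape transitions + accounting.
#
# Sign conventions: NEP = NPP - Rh; NBP = NEP - combustion - harvest
# export (land-conversion removals are combustion/export ledgered the year
# the transition fires); positive NBP = net ecosystem sink. The change in
# total ecosystem carbon each year equals NBP exactly (checked to 1e-9
# relative unless disabled).

#' Scenario configuration
#'
#' The two toggles reproduce the standard sensitivity design: both on
#' (reference), climate only, disturbance only, and no effects.
#'
#' @param years Number of annual timesteps.
#' @param climate_effects If `FALSE`, all growth/decay multipliers are 1.
#' @param lulc_disturbance If `FALSE`, no transitions are scheduled.
#' @param severity_split Named vector `c(high=, medium=, low=)` summing to
#'   1, or a list keyed by stratum id.
#' @param recovery_prob Annual post-fire shrubland to forest recovery
#'   probability (default 0.064).
#' @param clearcut_fraction,selection_fraction Annual harvest target
#'   fractions of eligible forest cells.
#' @param urbanization_prob,ag_expansion_prob Annual per-cell land-use
#'   conversion probabilities (forest sources).
#' @param enforce_min_harvest_age If `TRUE`, harvest eligibility respects
#'   each species' minimum clearcut/selection age (projection-year rule).
#' @param reforestation Optional list `(mask, start_year, end_year,
#'   total_area_ha, species)` passed to [schedule_reforestation()].
#' @param seed Master RNG seed; per-operation seeds derive from it.
#' @param check_invariants Abort if the annual accounting identities are
#'   violated (default `TRUE`).
#' @param record_pools If `TRUE`, keep the full n x 14 pool matrix for
#'   every year (memory!).
#' @return List of class `ff_scenario_config`.
#' @export
scenario_config <- function(years = 20L, climate_effects = TRUE,
                            lulc_disturbance = TRUE,
                            severity_split = c(high = 0.30, medium = 0.35,
                                               low = 0.35),
                            recovery_prob = 0.064,
                            clearcut_fraction = 0, selection_fraction = 0,
                            urbanization_prob = 0, ag_expansion_prob = 0,
                            enforce_min_harvest_age = FALSE,
                            reforestation = NULL, seed = 1L,
                            check_invariants = TRUE, record_pools = FALSE) {
  structure(list(years = as.integer(years),
                 climate_effects = isTRUE(climate_effects),
                 lulc_disturbance = isTRUE(lulc_disturbance),
                 severity_split = severity_split,
                 recovery_prob = recovery_prob,
                 clearcut_fraction = clearcut_fraction,
                 selection_fraction = selection_fraction,
                 urbanization_prob = urbanization_prob,
                 ag_expansion_prob = ag_expansion_prob,
                 enforce_min_harvest_age = isTRUE(enforce_min_harvest_age),
                 reforestation = reforestation, seed = as.integer(seed),
                 check_invariants = isTRUE(check_invariants),
                 record_pools = isTRUE(record_pools)),
            class = "ff_scenario_config")
}

# Internal: harvest/land-use transition definitions for one year.
scenario_transition_defs <- function(landscape, params, config) {
  defs <- list()
  forest_classes <- seq_along(landscape$species_names)
  add <- function(d) defs[[length(defs) + 1L]] <<- d
  if (config$clearcut_fraction > 0 || config$selection_fraction > 0) {
    if (config$enforce_min_harvest_age) {
      for (sid in forest_classes) {
        sp <- species_row(params$species, landscape$species_names[sid])
        ma <- min_harvest_age(sp)
        if (config$clearcut_fraction > 0)
          add(transition_definition("clearcut", sid, "target_area",
                                    target_fraction = config$clearcut_fraction,
                                    min_age = ma$clearcut_age))
        if (config$selection_fraction > 0)
          add(transition_definition("selection", sid, "target_area",
                                    target_fraction = config$selection_fraction,
                                    min_age = ma$selection_age))
      }
    } else {
      if (config$clearcut_fraction > 0)
        add(transition_definition("clearcut", forest_classes, "target_area",
                                  target_fraction = config$clearcut_fraction))
      if (config$selection_fraction > 0)
        add(transition_definition("selection", forest_classes, "target_area",
                                  target_fraction = config$selection_fraction))
    }
  }
  if (config$urbanization_prob > 0)
    add(transition_definition("urbanization", forest_classes, "probability",
                              probability = config$urbanization_prob))
  if (config$ag_expansion_prob > 0)
    add(transition_definition("ag_expansion", forest_classes, "probability",
                              probability = config$ag_expansion_prob))
  defs
}

#' Run a scenario simulation
#'
#' Per year: (i) climate multipliers (all 1 if disabled or no climate
#' supplied); (ii) the carbon base step on every forest-carbon-bearing
#' cell (post-fire shrubland runs decay-only); (iii) scheduling and
#' application of transitions and their triggered carbon flows (none if
#' disabled); (iv) age/time-since-transition bookkeeping; (v) ledger
#' aggregation by stratum with invariant checks.
#'
#' @param landscape Initialized landscape ([initialize_landscape()]).
#' @param params Parameter bundle ([load_parameters()]).
#' @param tables State attribute tables ([build_all_tables()]); used for
#'   NPP schedules and species contexts.
#' @param config A [scenario_config()].
#' @param climate Optional climate series ([make_climate()]).
#' @param fire_events Optional list of per-year burn masks
#'   ([make_fire_events()]).
#' @param insect_events Optional list of per-year named lists
#'   `list(insect_high = mask, ...)`.
#' @return List of class `ff_scenario_result`: `accounts` (tidy per
#'   year x stratum data frame, tons C), `annual` (per-year totals with
#'   `nbp_tg_c`), `landscape` (final state), `cum_nbp` (per-cell
#'   cumulative NBP grid, tons C/ha), `transitions` (per-year counts),
#'   and `pools_by_year` when requested.
#' @export
run_scenario <- function(landscape, params, tables, config = scenario_config(),
                         climate = NULL, fire_events = NULL,
                         insect_events = NULL) {
  ls <- landscape
  if (is.null(ls$pools)) stop("landscape has no pools; run initialize_landscape()")
  n <- ls$n
  area <- ls$cell_area_ha

  ctxs <- lapply(tables, attr, "context")
  for (nm in ls$species_names) {
    if (!(nm %in% names(ctxs)) || is.null(ctxs[[nm]]))
      stop("missing species context/tables for ", nm)
  }

  refo <- NULL
  if (config$lulc_disturbance && !is.null(config$reforestation)) {
    r <- config$reforestation
    refo <- schedule_reforestation(ls, r$mask, r$start_year, r$end_year,
                                   r$total_area_ha, species = r$species,
                                   seed = derive_seed(config$seed, "refo"))
  }

  defs <- if (config$lulc_disturbance)
    scenario_transition_defs(ls, params, config) else list()
  fire_def <- transition_definition("fire", seq_along(ls$species_names),
                                    "event", event = "fire")

  accounts <- list(); annual <- list(); trans_log <- list()
  cum_nbp <- numeric(n)
  clipped <- 0L
  pools_by_year <- if (config$record_pools) vector("list", config$years)

  for (year in seq_len(config$years)) {
    # (i) multipliers
    if (config$climate_effects && !is.null(climate)) {
      m <- climate_multipliers(climate$mat[[year]], climate$map[[year]],
                               climate$mat_norm, climate$map_norm)
      anom <- as.numeric(m$npp_anom)
      dmf <- as.numeric(m$dm_fast)
      dms <- as.numeric(m$dm_slow)
    } else {
      anom <- dmf <- dms <- rep(1, n)
    }

    tec0 <- sum(ls$pools) * area

    # (ii) base carbon step
    led <- list(npp = numeric(n), rh = numeric(n), turnover = numeric(n),
                dom_transfer = numeric(n), combustion = numeric(n),
                harvest = numeric(n), mortality = numeric(n))
    shrub_code <- FF_NONFOREST_CLASSES[["postfire_shrub"]]
    active_forest <- ls$state_class <= FF_CLASS_MAX_FOREST & !ls$frozen
    active_shrub <- ls$state_class == shrub_code & !ls$frozen &
      ls$species > 0L
    for (sid in sort(unique(ls$species[active_forest | active_shrub]))) {
      ctx <- ctxs[[ls$species_names[sid]]]
      for (shrub in c(FALSE, TRUE)) {
        idx <- which(ls$species == sid & (if (shrub) active_shrub
                                          else active_forest))
        if (!length(idx)) next
        st <- carbon_base_step(ls$pools[idx, , drop = FALSE],
                               age = ls$age[idx] + 1L,
                               schedule = ctx$schedule, flows = ctx$flows,
                               temp = ctx$temp,
                               growth_mult = if (shrub) 0 else anom[idx],
                               dm_fast = dmf[idx], dm_slow = dms[idx])
        ls$pools[idx, ] <- st$pools
        clipped <- clipped + st$ledger$clipped
        for (f in c("npp", "rh", "turnover", "dom_transfer"))
          led[[f]][idx] <- led[[f]][idx] + st$ledger[[f]]
      }
    }
    # age/time bookkeeping (resets below override)
    ls$age[active_forest] <- ls$age[active_forest] + 1L
    ls$tst[!ls$frozen] <- ls$tst[!ls$frozen] + 1L

    # (iii) transitions
    assignments <- data.frame(cell = integer(0), transition = character(0),
                              stringsAsFactors = FALSE)
    if (config$lulc_disturbance) {
      year_defs <- defs
      events <- list()
      if (!is.null(fire_events) && length(fire_events) >= year &&
          any(fire_events[[year]])) {
        year_defs <- c(list(fire_def), year_defs)
        events$fire <- fire_events[[year]]
      }
      if (!is.null(insect_events) && length(insect_events) >= year) {
        for (nm in names(insect_events[[year]])) {
          year_defs <- c(year_defs, list(
            transition_definition(nm, seq_along(ls$species_names), "event",
                                  event = nm)))
          events[[nm]] <- insect_events[[year]][[nm]]
        }
      }
      assignments <- schedule_transitions(
        ls, year_defs, events,
        seed = derive_seed(config$seed, "transitions", year))
      isfire <- assignments$transition == "fire"
      if (any(isfire)) {
        assignments$transition[isfire] <- assign_fire_severity(
          assignments$cell[isfire], ls$stratum[assignments$cell[isfire]],
          config$severity_split,
          seed = derive_seed(config$seed, "severity", year))
      }
      rec <- postfire_recovery(ls, config$recovery_prob,
                               seed = derive_seed(config$seed, "recovery",
                                                  year))
      rec <- setdiff(rec, assignments$cell)
      if (length(rec))
        assignments <- rbind(assignments,
                             data.frame(cell = rec,
                                        transition = "postfire_recovery",
                                        stringsAsFactors = FALSE))
      if (!is.null(refo) && !is.null(refo[[as.character(year)]])) {
        rf <- refo[[as.character(year)]]
        rf <- rf[!(rf$cell %in% assignments$cell), , drop = FALSE]
        if (nrow(rf)) {
          add <- data.frame(cell = rf$cell, transition = "reforestation",
                            stringsAsFactors = FALSE)
          assignments$species <- NA_integer_
          add$species <- rf$species
          assignments <- rbind(assignments, add)
        }
      }
      if (nrow(assignments)) {
        tr <- apply_transitions(ls, assignments, params)
        ls <- tr$landscape
        for (f in c("combustion", "harvest", "mortality", "dom_transfer"))
          led[[f]] <- led[[f]] + tr$ledger[[f]]
      }
    }

    # (v) accounting
    nbp_cell <- led$npp - led$rh - led$combustion - led$harvest
    cum_nbp <- cum_nbp + nbp_cell
    tec1 <- sum(ls$pools) * area
    tot <- function(x, idx) sum(x[idx]) * area
    for (s in sort(unique(ls$stratum))) {
      idx <- ls$stratum == s
      accounts[[length(accounts) + 1L]] <- data.frame(
        year = year, stratum = s,
        npp = tot(led$npp, idx), rh = tot(led$rh, idx),
        nep = tot(led$npp, idx) - tot(led$rh, idx),
        combustion = tot(led$combustion, idx),
        harvest = tot(led$harvest, idx),
        mortality = tot(led$mortality, idx),
        turnover = tot(led$turnover, idx),
        nbp = tot(nbp_cell, idx),
        tec = sum(ls$pools[idx, ]) * area)
    }
    ann <- data.frame(year = year, npp = sum(led$npp) * area,
                      rh = sum(led$rh) * area,
                      combustion = sum(led$combustion) * area,
                      harvest = sum(led$harvest) * area,
                      mortality = sum(led$mortality) * area,
                      nbp = sum(nbp_cell) * area, tec = tec1)
    ann$nep <- ann$npp - ann$rh
    annual[[year]] <- ann
    if (config$check_invariants) {
      scale <- max(abs(tec0), abs(tec1), 1)
      if (abs((tec1 - tec0) - ann$nbp) > 1e-9 * scale)
        stop(sprintf("conservation violated in year %d: dTEC=%.6g NBP=%.6g",
                     year, tec1 - tec0, ann$nbp))
    }
    if (nrow(assignments)) {
      tl <- as.data.frame(table(assignments$transition),
                          stringsAsFactors = FALSE)
      names(tl) <- c("transition", "cells")
      tl$year <- year
      trans_log[[length(trans_log) + 1L]] <- tl
    }
    if (config$record_pools) pools_by_year[[year]] <- ls$pools
  }

  accounts <- do.call(rbind, accounts)
  annual <- do.call(rbind, annual)
  annual$nbp_tg_c <- annual$nbp / 1e6
  if (clipped > 0)
    warning(sprintf("decay outflow proportion > 1 capped in %d cell-years", clipped))
  structure(list(accounts = accounts, annual = annual, landscape = ls,
                 clipped = clipped,
                 cum_nbp = matrix(cum_nbp, ls$nrow, ls$ncol),
                 transitions = if (length(trans_log))
                   do.call(rbind, trans_log) else NULL,
                 pools_by_year = if (config$record_pools) pools_by_year,
                 config = config),
            class = "ff_scenario_result")
}

#' @export
print.ff_scenario_result <- function(x, ...) {
  cat("<scenario result>", max(x$annual$year), "years |",
      "mean NBP", sprintf("%.3f", mean(x$annual$nbp_tg_c)), "Tg C/yr\n")
  invisible(x)
}

#' Aggregate scenario accounts
#'
#' Density (tons C/ha/yr) and mass (Tg C/yr) views of the per-stratum
#' accounts, plus national totals.
#'
#' @param result An `ff_scenario_result` (or its `accounts` data frame
#'   together with `area_ha`, the total stratum areas).
#' @return List with `by_stratum` (adds `nbp_tg_c`), `national` (per-year
#'   totals), `mean_annual` (one row of period means, Tg C/yr).
#' @export
aggregate_outputs <- function(result) {
  acc <- result$accounts
  acc$nbp_tg_c <- acc$nbp / 1e6
  national <- stats::aggregate(
    cbind(npp, rh, nep, combustion, harvest, mortality, nbp, tec) ~ year,
    acc, sum)
  national$nbp_tg_c <- national$nbp / 1e6
  mean_annual <- data.frame(t(colMeans(
    national[, c("npp", "rh", "nep", "combustion", "harvest", "nbp")])))
  mean_annual <- mean_annual / 1e6
  names(mean_annual) <- paste0(names(mean_annual), "_tg_c")
  list(by_stratum = acc, national = national, mean_annual = mean_annual)
}

#' Verification by reproduction
#'
#' Runs the landscape driver on a single 1-ha, age-0, fire-initialized
#' cell for the length of the state attribute table with all multipliers
#' at 1 and no transitions, and compares every pool at every age against
#' the fire-initialized stock-by-age table.
#'
#' @param species_name Packaged species name.
#' @param params Parameter bundle.
#' @param tables Optional precomputed [build_all_tables()] result for the
#'   species.
#' @param config Spin-up configuration used if tables must be built.
#' @return List: `max_rel_diff`, the table, and the simulated trajectory.
#' @export
verify_reproduction <- function(species_name, params, tables = NULL,
                                config = spinup_config()) {
  if (is.null(tables))
    tables <- stats::setNames(
      list(build_state_attribute_tables(species_name, params, config)),
      species_name)
  tab <- tables[[species_name]]$fire
  n_years <- max(tab$ages)
  ls <- list(nrow = 1L, ncol = 1L, n = 1L, cell_area_ha = 1,
             species_names = species_name, state_class = 1L, species = 1L,
             age = 0L, tst = 0L, last_dist = "fire", frozen = FALSE,
             stratum = 1L, protected = NULL, pools = NULL)
  ls <- initialize_landscape(ls, tables)
  res <- run_scenario(ls, params, tables,
                      scenario_config(years = n_years,
                                      climate_effects = FALSE,
                                      lulc_disturbance = FALSE,
                                      record_pools = TRUE))
  sim <- do.call(rbind, lapply(res$pools_by_year, function(p) p[1, ]))
  sim <- rbind(tab$stocks[1, ], sim)  # age 0 row = initialization
  denom <- pmax(abs(tab$stocks), 1e-8)
  list(max_rel_diff = max(abs(sim - tab$stocks) / denom),
       table = tab, simulated = sim)
}
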