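# Dead-organic-matter spin-up and landscape carbon initialization.
#
# DOM pools (especially the belowground slow / soil pool) need a long
# pre-simulation to reach a quasi-steady state consistent with the
# species' historical fire regime. Starting from zero carbon at age zero,
# the stand is run for `duration` years with stand-replacing wildfire
# applied deterministically every MRI years (the species' mean fire return
# interval). The stand state just before the final fire ("mature state")
# is then disturbed once by high-severity fire and once by clearcut
# harvest, and each post-disturbance stand is run for another 300 years to
# build the two state attribute tables (pool stocks by age and last
# disturbance) used to initialize landscape carbon.

#' Spin-up configuration
#'
#' @param duration Spin-up length in years (default 3000).
#' @param tolerance Relative steady-state tolerance on the belowground slow
#'   pool between successive fire cycles (default 1e-3).
#' @param table_length Length in years of the post-disturbance state
#'   attribute tables (default 300).
#' @param stochastic If `TRUE`, fire intervals are drawn from a geometric
#'   distribution with mean MRI instead of occurring at exact MRI
#'   multiples.
#' @param seed RNG seed used only when `stochastic = TRUE`.
#' @return List of class `ff_spinup_config`.
#' @export
spinup_config <- function(duration = 3000L, tolerance = 1e-3,
                          table_length = 300L, stochastic = FALSE,
                          seed = 1L) {
  stopifnot(duration >= 1, tolerance > 0, table_length >= 1)
  structure(list(duration = as.integer(duration), tolerance = tolerance,
                 table_length = as.integer(table_length),
                 stochastic = isTRUE(stochastic), seed = as.integer(seed)),
            class = "ff_spinup_config")
}

# Internal: bundle everything the engine needs for one species.
species_context <- function(species, params) {
  species <- as.list(species)
  flows <- resolve_flows(params$flows, species)
  ref <- reference_simulation(species, params$expansion, params$flows)
  schedule <- npp_from_reference(ref, params$flows, species)
  list(species = species, flows = flows, schedule = schedule,
       reference = ref, temp = species$mean_temp_c)
}

#' Spin up DOM pools for one species
#'
#' Runs the carbon engine from zero stocks at age zero for
#' `config$duration` years with stand-replacing high-severity fire every
#' MRI years (multipliers all 1, decay at the species' range mean
#' temperature). Reports per-cycle convergence of the belowground slow
#' pool and warns (without failing) if the configured tolerance is not met
#' by the end of the run.
#'
#' @param species One row of [read_species_params()] (or a species name,
#'   resolved against `params$species`).
#' @param params Parameter bundle from [load_parameters()].
#' @param config A [spinup_config()].
#' @param ctx Optional precomputed `species_context` (internal reuse).
#' @return List of class `ff_spinup`: `end_state` (1 x 14 pool matrix just
#'   after the final fire), `mature_state` (just before it), `mature_age`,
#'   `n_fires`, `bg_slow` (belowground-slow stock at each post-fire
#'   moment), `rel_change` (relative change between successive post-fire
#'   values), `converged`.
#' @export
spinup <- function(species, params, config = spinup_config(), ctx = NULL) {
  if (is.character(species)) species <- species_row(params$species, species)
  if (is.null(ctx)) ctx <- species_context(species, params)
  mri <- as.integer(ctx$species$mri_years)

  if (config$stochastic) {
    set.seed(config$seed)
    fire_years <- integer(0)
    y <- 0L
    repeat {
      y <- y + 1L + stats::rgeom(1, 1 / mri)
      if (y > config$duration) break
      fire_years <- c(fire_years, y)
    }
  } else {
    fire_years <- seq_len(config$duration %/% mri) * mri
  }

  P <- matrix(0, 1, length(FF_POOLS), dimnames = list(NULL, FF_POOLS))
  age <- 0L
  bg_slow <- numeric(0)
  mature_state <- P
  mature_age <- 0L
  clipped <- 0L
  is_fire <- logical(config$duration)
  is_fire[fire_years] <- TRUE
  for (year in seq_len(config$duration)) {
    st <- carbon_base_step(P, age + 1L, ctx$schedule, ctx$flows,
                           temp = ctx$temp)
    P <- st$pools
    clipped <- clipped + st$ledger$clipped
    age <- age + 1L
    if (is_fire[year]) {
      mature_state <- P
      mature_age <- age
      tr <- apply_transition_flows(P, params$disturbance, "fire_high")
      P <- tr$pools
      age <- 0L
      bg_slow <- c(bg_slow, P[1, "BelowgroundSlow"])
    }
  }
  rel_change <- if (length(bg_slow) > 1) {
    abs(diff(bg_slow)) / pmax(bg_slow[-length(bg_slow)], .Machine$double.eps)
  } else numeric(0)
  converged <- length(rel_change) > 0 &&
    rel_change[length(rel_change)] < config$tolerance
  if (!converged && length(bg_slow) > 1) {
    warning(sprintf(
      "spin-up for '%s' not converged after %d years (last per-cycle change %.2e > %.2e)",
      ctx$species$species_name, config$duration,
      rel_change[length(rel_change)], config$tolerance))
  }
  structure(list(species_name = ctx$species$species_name,
                 end_state = P, mature_state = mature_state,
                 mature_age = mature_age, age = age,
                 n_fires = length(fire_years), bg_slow = bg_slow,
                 rel_change = rel_change, converged = converged,
                 clipped = clipped),
            class = "ff_spinup")
}

#' Build the per-disturbance state attribute tables
#'
#' From the end of the spin-up, applies each of the two stand-replacing
#' disturbances (high-severity fire, clearcut harvest) to the mature stand
#' and runs the engine for another `config$table_length` years, recording
#' pool stocks at every age.
#'
#' @inheritParams spinup
#' @param spin Optional precomputed [spinup()] result.
#' @return List with elements `fire` and `clearcut`, each an
#'   `ff_stock_table` over ages `0..table_length`, plus the `spinup` result
#'   and the species `context` (attributes of the list).
#' @export
build_state_attribute_tables <- function(species, params,
                                         config = spinup_config(),
                                         ctx = NULL, spin = NULL) {
  if (is.character(species)) species <- species_row(params$species, species)
  if (is.null(ctx)) ctx <- species_context(species, params)
  if (is.null(spin)) spin <- spinup(species, params, config, ctx = ctx)

  run_table <- function(transition, dist_label) {
    tr <- apply_transition_flows(spin$mature_state, params$disturbance,
                                 transition)
    P <- tr$pools
    n <- config$table_length
    stocks <- matrix(0, n + 1L, length(FF_POOLS),
                     dimnames = list(NULL, FF_POOLS))
    stocks[1L, ] <- P
    for (a in seq_len(n)) {
      st <- carbon_base_step(P, a, ctx$schedule, ctx$flows, temp = ctx$temp)
      P <- st$pools
      stocks[a + 1L, ] <- P
    }
    stock_table(ctx$species$species_name, dist_label, stocks)
  }
  out <- list(fire = run_table("fire_high", "fire"),
              clearcut = run_table("clearcut", "clearcut"))
  attr(out, "spinup") <- spin
  attr(out, "context") <- ctx
  out
}

#' Build state attribute tables for several species
#'
#' @param params Parameter bundle from [load_parameters()].
#' @param species_names Character vector; default all packaged species.
#' @param config A [spinup_config()].
#' @return Named list: per species, the [build_state_attribute_tables()]
#'   result.
#' @export
build_all_tables <- function(params, species_names = NULL,
                             config = spinup_config()) {
  if (is.null(species_names)) species_names <- params$species$species_name
  out <- lapply(species_names, function(nm)
    build_state_attribute_tables(nm, params, config))
  stats::setNames(out, species_names)
}

#' Initialize landscape carbon stocks from state attribute tables
#'
#' Each forest cell receives the table row for its (species, last
#' stand-replacing disturbance, age), with ages above the table length
#' clamped to the last row. Non-forest cells get zero forest pools.
#'
#' @param landscape A landscape object (see [make_landscape()]).
#' @param tables Result of [build_all_tables()] covering every forest
#'   species present.
#' @return The landscape with its `pools` matrix filled.
#' @export
initialize_landscape <- function(landscape, tables) {
  ls <- landscape
  ls$pools <- matrix(0, ls$n, length(FF_POOLS),
                     dimnames = list(NULL, FF_POOLS))
  forest <- which(ls$species > 0L & ls$state_class <= FF_CLASS_MAX_FOREST)
  sp_names <- ls$species_names[ls$species[forest]]
  unknown <- setdiff(unique(sp_names), names(tables))
  if (length(unknown)) {
    stop("no state attribute tables for species: ",
         paste(unknown, collapse = ", "), " (",
         sum(sp_names %in% unknown), " cells)")
  }
  for (nm in unique(sp_names)) {
    for (dist in c("fire", "clearcut")) {
      idx <- forest[sp_names == nm & ls$last_dist[forest] == dist]
      if (!length(idx)) next
      tab <- tables[[nm]][[dist]]
      rows <- pmin(ls$age[idx], max(tab$ages)) + 1L
      ls$pools[idx, ] <- tab$stocks[rows, , drop = FALSE]
    }
  }
  ls
}

#' Total ecosystem carbon grid
#'
#' @param landscape Initialized landscape.
#' @return Matrix (nrow x ncol) of total ecosystem carbon (tons C/ha): the
#'   cellwise sum of all 14 pools.
#' @export
tec_grid <- function(landscape) {
  matrix(rowSums(landscape$pools), landscape$nrow, landscape$ncol)
}
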