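# State-and-transition dynamics over the raster landscape.
#
# A landscape is a set of co-registered per-cell vectors (row-major grids):
# state class, species, age, time-since-transition, last stand-replacing
# disturbance, stratum, and the n x 14 pool matrix. State classes 1..28
# are forest type-groups (the class code IS the species id); codes >= 50
# are non-forest NLCD-style classes, with post-fire shrubland kept
# distinct because it remembers its originating forest type and can
# recover.

FF_CLASS_MAX_FOREST <- 28L

FF_NONFOREST_CLASSES <- c(
  postfire_shrub = 50L, grassland = 60L, shrubland = 61L, cropland = 62L,
  pasture = 63L, developed = 64L, wetland = 65L, barren = 66L
)

#' Non-forest state class codes
#' @return Named integer vector of the non-forest class codes.
#' @export
state_classes <- function() FF_NONFOREST_CLASSES

#' Derive a per-module RNG seed from a master seed
#'
#' Documented splitting rule so that every stochastic operation can be
#' seeded independently and reproducibly from one master seed.
#'
#' @param master Master seed (integer).
#' @param purpose Character label of the consuming operation.
#' @param year Optional year index.
#' @return Integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(master, purpose, year = 0L) {
  h <- sum(utf8ToInt(purpose) * seq_along(utf8ToInt(purpose)))
  as.integer((abs(as.numeric(master)) * 69069 + h * 97 + year * 1000003) %%
               2147483647)
}

#' Define a landscape transition
#'
#' @param name Transition name; must match a disturbance-matrix transition
#'   type unless `carbon = FALSE`.
#' @param source_classes Integer state-class codes eligible to transition.
#' @param mode Scheduling mode: `"probability"` (independent annual
#'   probability per eligible cell), `"target_area"` (fixed fraction of
#'   eligible cells drawn without replacement), or `"event"` (an annual
#'   event mask supplies the cells).
#' @param probability Annual probability (mode `"probability"`).
#' @param target_fraction Fraction of eligible cells (mode
#'   `"target_area"`).
#' @param event Name of the event mask in the per-year events list (mode
#'   `"event"`).
#' @param min_age Minimum stand age for eligibility (e.g. harvest rules).
#' @param adjacency Logical; weight target-area draws by the fraction of
#'   like-class 3x3 neighbours (simplified adjacency multiplier). Default
#'   off.
#' @return List of class `ff_transition_def`.
#' @export
transition_definition <- function(name, source_classes,
                                  mode = c("probability", "target_area",
                                           "event"),
                                  probability = 0, target_fraction = 0,
                                  event = NULL, min_age = 0L,
                                  adjacency = FALSE) {
  mode <- match.arg(mode)
  if (mode == "probability" && (probability < 0 || probability > 1))
    stop("probability must be in [0, 1]")
  structure(list(name = name, source_classes = as.integer(source_classes),
                 mode = mode, probability = probability,
                 target_fraction = target_fraction, event = event,
                 min_age = as.integer(min_age), adjacency = adjacency),
            class = "ff_transition_def")
}

# Internal: eligibility mask for one definition.
eligible_cells <- function(landscape, def) {
  ok <- landscape$state_class %in% def$source_classes & !landscape$frozen
  if (def$min_age > 0L) ok <- ok & landscape$age >= def$min_age
  if (!is.null(landscape$protected)) ok <- ok & !landscape$protected
  which(ok)
}

# Internal: fraction of 3x3 neighbours sharing the cell's state class.
like_neighbour_fraction <- function(landscape, cells) {
  nr <- landscape$nrow; nc <- landscape$ncol
  cls <- matrix(landscape$state_class, nr, nc)
  r <- (cells - 1L) %% nr + 1L
  c <- (cells - 1L) %/% nr + 1L
  vapply(seq_along(cells), function(i) {
    rr <- max(1, r[i] - 1):min(nr, r[i] + 1)
    cc <- max(1, c[i] - 1):min(nc, c[i] + 1)
    nb <- cls[rr, cc]
    mean(nb == cls[r[i], c[i]])
  }, numeric(1))
}

#' Schedule landscape transitions for one year
#'
#' @param landscape Landscape object.
#' @param defs List of [transition_definition()]s.
#' @param events Named list of event masks (logical vectors of length n or
#'   matrices) for `"event"`-mode definitions.
#' @param seed Optional RNG seed.
#' @return Data frame `(cell, transition)`; empty if nothing fires. Cells
#'   already claimed by an earlier definition in `defs` are not reassigned
#'   (one transition per cell per year).
#' @export
schedule_transitions <- function(landscape, defs, events = list(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  taken <- logical(landscape$n)
  out_cells <- integer(0); out_names <- character(0)
  for (def in defs) {
    el <- setdiff(eligible_cells(landscape, def), which(taken))
    sel <- integer(0)
    if (length(el)) {
      if (def$mode == "probability") {
        if (def$probability > 0)
          sel <- el[stats::runif(length(el)) < def$probability]
      } else if (def$mode == "target_area") {
        k <- round(def$target_fraction * length(el))
        if (def$target_fraction > 0 && k == 0) k <- 0L
        if (k > length(el)) {
          warning("transition '", def$name,
                  "' target exceeds eligible area; truncated")
          k <- length(el)
        }
        if (k > 0) {
          w <- if (def$adjacency)
            0.05 + like_neighbour_fraction(landscape, el) else NULL
          sel <- if (length(el) == 1L) el
                 else sample(el, k, prob = w)
        }
      } else {
        mask <- events[[def$event]]
        if (is.null(mask)) stop("no event mask '", def$event,
                                "' for transition '", def$name, "'")
        sel <- intersect(which(as.logical(mask)), el)
      }
    }
    if (length(sel)) {
      taken[sel] <- TRUE
      out_cells <- c(out_cells, sel)
      out_names <- c(out_names, rep(def$name, length(sel)))
    }
  }
  data.frame(cell = out_cells, transition = out_names,
             stringsAsFactors = FALSE)
}

#' Assign stochastic fire severity to burned cells
#'
#' Each burned cell draws a severity class from its stratum's severity
#' split (multinomial).
#'
#' @param burn_cells Integer cell indices inside fire perimeters.
#' @param stratum Integer stratum id per burned cell (same length).
#' @param severity_splits Either a numeric vector `c(high=, medium=, low=)`
#'   summing to 1 (applied to all strata) or a named list of such vectors
#'   keyed by stratum id.
#' @param seed Optional RNG seed.
#' @return Character vector `fire_high`/`fire_medium`/`fire_low` per cell.
#' @export
assign_fire_severity <- function(burn_cells, stratum, severity_splits,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!length(burn_cells)) return(character(0))
  levels <- c("fire_high", "fire_medium", "fire_low")
  get_split <- function(s) {
    sp <- if (is.list(severity_splits)) severity_splits[[as.character(s)]]
          else severity_splits
    if (is.null(sp)) stop("no severity split for stratum ", s)
    if (abs(sum(sp) - 1) > 1e-9) stop("severity split must sum to 1")
    sp
  }
  out <- character(length(burn_cells))
  for (s in unique(stratum)) {
    idx <- which(stratum == s)
    sp <- get_split(s)
    out[idx] <- sample(levels, length(idx), replace = TRUE, prob = sp)
  }
  out
}

#' Post-fire shrubland recovery
#'
#' Each post-fire shrubland cell independently reverts to its remembered
#' forest type with the given annual probability.
#'
#' @param landscape Landscape object.
#' @param probability Annual recovery probability (default 0.064).
#' @param seed Optional RNG seed.
#' @return Integer vector of recovering cell indices.
#' @export
postfire_recovery <- function(landscape, probability = 0.064, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  shrub <- which(landscape$state_class == FF_NONFOREST_CLASSES[["postfire_shrub"]] &
                   !landscape$frozen)
  if (!length(shrub) || probability <= 0) return(integer(0))
  shrub[stats::runif(length(shrub)) < probability]
}

#' Bootstrap future transition rates from a historical record
#'
#' For each future year and transition type (independently), one
#' historical year's realized rate is drawn uniformly with replacement.
#'
#' @param history Data frame with columns `year`, `transition`, `value`
#'   (rate or area per year).
#' @param years Integer vector of future year indices.
#' @param seed Optional RNG seed.
#' @return Data frame `(year, transition, value)` for the future years.
#' @export
bootstrap_future_rates <- function(history, years, seed = NULL) {
  if (!nrow(history)) stop("empty rate history")
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (tr in unique(history$transition)) {
    vals <- history$value[history$transition == tr]
    out[[tr]] <- data.frame(
      year = years, transition = tr,
      value = vals[sample.int(length(vals), length(years), replace = TRUE)],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Schedule a reforestation program
#'
#' Spreads a total reforestation area evenly over a span of years,
#' converting randomly drawn eligible non-forest cells to forest at age 0.
#'
#' @param landscape Landscape object.
#' @param eligibility_mask Logical vector (length n) of candidate cells
#'   (non-forest that historically supported forest).
#' @param start_year,end_year First and last program year (inclusive),
#'   indices into the simulation years.
#' @param total_area_ha Total area to reforest (ha).
#' @param species Designated forest species id per converted cell: a
#'   scalar id, a length-n vector, or `NULL` to use each cell's remembered
#'   species where positive and the landscape's modal forest species
#'   elsewhere.
#' @param seed Optional RNG seed.
#' @return List keyed by year (as character) of data frames `(cell,
#'   species)`.
#' @export
schedule_reforestation <- function(landscape, eligibility_mask, start_year,
                                   end_year, total_area_ha, species = NULL,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mask <- which(as.logical(eligibility_mask) &
                  landscape$state_class > FF_CLASS_MAX_FOREST &
                  !landscape$frozen)
  n_cells <- round(total_area_ha / landscape$cell_area_ha)
  if (n_cells > length(mask)) {
    warning("reforestation target exceeds eligible area; truncated")
    n_cells <- length(mask)
  }
  if (n_cells <= 0) return(list())
  years <- start_year:end_year
  # even split with cumulative rounding (per-year counts differ by <= 1)
  cum <- round(seq_along(years) * n_cells / length(years))
  per_year <- diff(c(0L, cum))
  chosen <- if (length(mask) == 1L) mask else sample(mask, n_cells)
  if (is.null(species)) {
    forest_sp <- landscape$species[landscape$species > 0L &
                                     landscape$state_class <= FF_CLASS_MAX_FOREST]
    modal <- if (length(forest_sp))
      as.integer(names(sort(table(forest_sp), decreasing = TRUE))[1]) else 1L
    sp_for <- ifelse(landscape$species[chosen] > 0L,
                     landscape$species[chosen], modal)
  } else if (length(species) == 1L) {
    sp_for <- rep(as.integer(species), n_cells)
  } else {
    sp_for <- as.integer(species[chosen])
  }
  out <- list()
  pos <- 0L
  for (i in seq_along(years)) {
    k <- per_year[i]
    if (k > 0) {
      idx <- (pos + 1L):(pos + k)
      out[[as.character(years[i])]] <-
        data.frame(cell = chosen[idx], species = sp_for[idx])
      pos <- pos + k
    }
  }
  out
}

# Internal: state bookkeeping rules for each transition type. Carbon flows
# are applied separately (apply_transition_flows); this updates class, age,
# time-since-transition, last disturbance, frozen flag.
apply_transition_state <- function(landscape, cells, transition) {
  ls <- landscape
  ls$tst[cells] <- 0L
  if (transition == "fire_high") {
    ls$state_class[cells] <- FF_NONFOREST_CLASSES[["postfire_shrub"]]
    ls$age[cells] <- 0L
    ls$last_dist[cells] <- "fire"
  } else if (transition %in% c("fire_medium", "fire_low")) {
    # class and age unchanged
  } else if (transition == "clearcut") {
    ls$age[cells] <- 0L
    ls$last_dist[cells] <- "clearcut"
  } else if (transition %in% c("selection", "insect_high", "insect_medium",
                               "insect_low")) {
    # age not reset
  } else if (transition == "urbanization") {
    ls$state_class[cells] <- FF_NONFOREST_CLASSES[["developed"]]
    ls$frozen[cells] <- TRUE
  } else if (transition == "ag_expansion") {
    ls$state_class[cells] <- FF_NONFOREST_CLASSES[["cropland"]]
    ls$frozen[cells] <- TRUE
  } else if (transition == "postfire_recovery") {
    ls$state_class[cells] <- ls$species[cells]
    ls$age[cells] <- 0L
  } else if (transition == "reforestation") {
    ls$age[cells] <- 0L
    ls$last_dist[cells] <- "none"
  } else {
    stop("unknown transition type: ", transition)
  }
  ls
}

#' Apply scheduled transitions to the landscape
#'
#' Applies, per transition type, the disturbance-matrix carbon flows
#' (forest-carbon-bearing cells only) followed by the state bookkeeping
#' rules (class, age, time-since-transition, frozen flag). Post-fire
#' shrubland cells keep their originating species for later recovery.
#'
#' @param landscape Landscape object with initialized pools.
#' @param assignments Data frame `(cell, transition)` from
#'   [schedule_transitions()] (fire rows may carry severity-resolved
#'   names), plus optionally `species` for reforestation rows.
#' @param params Parameter bundle (disturbance matrices).
#' @return List: `landscape` (updated) and `ledger` (per-cell vectors:
#'   `combustion`, `harvest`, `mortality`, `dom_transfer`).
#' @export
apply_transitions <- function(landscape, assignments, params) {
  ls <- landscape
  n <- ls$n
  led <- list(combustion = numeric(n), harvest = numeric(n),
              mortality = numeric(n), dom_transfer = numeric(n))
  if (!nrow(assignments)) return(list(landscape = ls, ledger = led))
  no_carbon <- c("postfire_recovery", "reforestation")
  for (tr in unique(assignments$transition)) {
    cells <- assignments$cell[assignments$transition == tr]
    if (!(tr %in% no_carbon)) {
      flows <- apply_transition_flows(ls$pools[cells, , drop = FALSE],
                                      params$disturbance, tr)
      ls$pools[cells, ] <- flows$pools
      led$combustion[cells] <- led$combustion[cells] + flows$ledger$combustion
      led$harvest[cells] <- led$harvest[cells] + flows$ledger$harvest
      led$mortality[cells] <- led$mortality[cells] + flows$ledger$mortality
      led$dom_transfer[cells] <- led$dom_transfer[cells] +
        flows$ledger$dom_transfer
    }
    if (tr == "reforestation" && !is.null(assignments$species)) {
      sp <- assignments$species[assignments$transition == tr]
      ls$species[cells] <- sp
      ls$state_class[cells] <- sp
    }
    ls <- apply_transition_state(ls, cells, tr)
  }
  list(landscape = ls, ledger = led)
}
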