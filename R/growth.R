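# Reference stand simulation and NPP schedule derivation.
#
# The gain-loss engine does not grow trees from first principles: annual
# carbon input is a net primary productivity (NPP) schedule by stand age,
# derived from a deterministic reference simulation of a 1-ha stand in
# which live pools follow the species' merchantable-volume curve expanded
# to the five live components, and DOM pools follow the engine's base
# flows. NPP at age a is the sum over live pools of net growth plus the
# biomass turnover of age a-1 stocks; the allocation proportions pNPP
# split NPP back across live pools so that the engine exactly regrows the
# reference live stocks (round-trip identity).

# Internal: a no-growth schedule used when live pools are set analytically.
null_schedule <- function(max_age = 300L) {
  structure(list(species_name = NA_character_, max_age = as.integer(max_age),
                 npp = numeric(max_age + 1L),
                 pnpp = matrix(0, max_age + 1L, length(FF_LIVE_POOLS),
                               dimnames = list(NULL, FF_LIVE_POOLS))),
            class = "ff_npp_schedule")
}

# Internal stock-table constructor: stocks is (max_age+1) x 14, rows = ages
# 0..max_age.
stock_table <- function(species_name, last_disturbance, stocks) {
  stocks <- as_pool_matrix(stocks)
  structure(list(species_name = species_name,
                 last_disturbance = last_disturbance,
                 ages = 0:(nrow(stocks) - 1L), stocks = stocks),
            class = "ff_stock_table")
}

#' @export
print.ff_stock_table <- function(x, ...) {
  cat("<stock-by-age table>", x$species_name, "| last disturbance:",
      x$last_disturbance, "| ages 0..", max(x$ages), "\n")
  invisible(x)
}

#' Reference stand simulation (stock-by-age table)
#'
#' Simulates a 1-ha stand from age 0 to `max_age` with no disturbance:
#' live-pool carbon is the Von Bertalanffy merchantable volume expanded by
#' the species' biomass expansion factors and carbon fraction; DOM pools
#' receive the engine's base flows (turnover inputs, snag fall, decay at
#' the species' range mean temperature). Deterministic (no RNG).
#'
#' @param species One species row from [read_species_params()].
#' @param expansion Table from [read_expansion_params()].
#' @param flow_params Table from [read_flow_params()].
#' @param max_age Last age simulated (default 300).
#' @return An `ff_stock_table` with `last_disturbance = "none"`.
#' @export
reference_simulation <- function(species, expansion, flow_params,
                                 max_age = 300L) {
  species <- as.list(species)
  ex <- resolve_expansion(expansion, species)
  fl <- resolve_flows(flow_params, species)
  ages <- 0:max_age
  vol <- merchantable_volume(species, ages)
  live <- outer(vol, ex$factors) * ex$carbon_fraction  # (max_age+1) x 5
  colnames(live) <- FF_LIVE_POOLS

  stocks <- matrix(0, max_age + 1L, length(FF_POOLS),
                   dimnames = list(NULL, FF_POOLS))
  P <- matrix(0, 1, length(FF_POOLS), dimnames = list(NULL, FF_POOLS))
  sched0 <- null_schedule(max_age)
  for (a in seq_len(max_age)) {
    st <- carbon_base_step(P, a, sched0, fl, temp = species$mean_temp_c,
                           growth_mult = 0)
    P <- st$pools
    P[1, FF_LIVE_POOLS] <- live[a + 1L, ]  # growth step, set analytically
    stocks[a + 1L, ] <- P
  }
  stock_table(species$species_name, "none", stocks)
}

#' Allocation proportions of NPP across live pools
#'
#' For each age `a >= 1`, the proportion of NPP allocated to live pool i is
#' `(G_i + S_i(a-1) * T_i) / NPP(a)` where `G_i` is the net growth of pool
#' i, `S_i(a-1)` its previous-age stock and `T_i` its turnover rate. Ages
#' with `NPP = 0` carry forward the proportions of the last positive-NPP
#' age; age 0 uses the age-1 proportions.
#'
#' @param table An `ff_stock_table` covering consecutive ages.
#' @param flow_params Table from [read_flow_params()]; resolved for the
#'   table's species.
#' @param species Optional species row (needed only to resolve
#'   class-specific flow overrides; defaults to a softwood lookup by the
#'   table's species name).
#' @return Matrix (ages x 5) of proportions in `[0, 1]`, rows summing to 1.
#' @export
allocation_proportions <- function(table, flow_params, species = NULL) {
  sched <- npp_from_reference(table, flow_params, species)
  sched$pnpp
}

#' Derive the NPP schedule from a stock-by-age table
#'
#' NPP at age a is the sum across the five live pools of net growth
#' `S(a) - S(a-1)` plus biomass turnover `S(a-1) * T`; the allocation
#' proportions are as in [allocation_proportions()]. Feeding the schedule
#' back into the engine regrows the table's live stocks exactly.
#'
#' @inheritParams allocation_proportions
#' @return An `ff_npp_schedule`: list with `npp` (length max_age+1, index
#'   age+1, `npp[1] = 0`) and `pnpp` (matrix, rows = ages 0..max_age).
#' @export
npp_from_reference <- function(table, flow_params, species = NULL) {
  stopifnot(inherits(table, "ff_stock_table"))
  if (any(diff(table$ages) != 1L)) stop("table ages must be consecutive")
  if (is.null(species)) {
    species <- list(species_name = table$species_name, class = "softwood")
  } else {
    species <- as.list(species)
  }
  fl <- resolve_flows(flow_params, species)
  S <- table$stocks[, FF_LIVE_POOLS, drop = FALSE]
  n <- nrow(S)
  max_age <- n - 1L
  G <- S[-1L, , drop = FALSE] - S[-n, , drop = FALSE]
  turn <- sweep(S[-n, , drop = FALSE], 2, fl$turnover[FF_LIVE_POOLS], `*`)
  contrib <- G + turn                     # (max_age) x 5, ages 1..max_age
  npp_a <- rowSums(contrib)
  npp <- c(0, npp_a)

  pnpp <- matrix(0, n, ncol(S), dimnames = list(NULL, FF_LIVE_POOLS))
  last <- NULL
  for (a in seq_len(max_age)) {
    if (npp_a[a] > 0) {
      last <- contrib[a, ] / npp_a[a]
      pnpp[a + 1L, ] <- last
    } else if (!is.null(last)) {
      pnpp[a + 1L, ] <- last
    }
  }
  # age 0 (and any leading zero-NPP ages) use the first positive-NPP split
  first_pos <- which(npp_a > 0)[1]
  if (!is.na(first_pos)) {
    split1 <- contrib[first_pos, ] / npp_a[first_pos]
    for (a in 0:first_pos) {
      if (all(pnpp[a + 1L, ] == 0)) pnpp[a + 1L, ] <- split1
    }
  }
  structure(list(species_name = table$species_name,
                 max_age = as.integer(max_age), npp = npp, pnpp = pnpp),
            class = "ff_npp_schedule")
}

#' @export
print.ff_npp_schedule <- function(x, ...) {
  cat("<NPP schedule>", x$species_name, "| ages 0..", x$max_age,
      "| peak NPP", sprintf("%.2f", max(x$npp)), "tC/ha/yr\n")
  invisible(x)
}
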