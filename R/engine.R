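# The per-cell annual carbon state machine.
#
# Base flows are applied in a fixed 8-step order each year:
#   1. snag fall: SnagStem -> AbovegroundMedium, SnagBranch -> AbovegroundFast
#   2. emission/decay of SnagStem, SnagBranch, AbovegroundMedium
#   3. emission from BelowgroundSlow
#   4. live -> DOM biomass turnover
#   5. emission/decay of BelowgroundVeryFast, BelowgroundFast,
#      AbovegroundVeryFast, AbovegroundFast
#   6. emission from AbovegroundSlow
#   7. transfer AbovegroundSlow -> BelowgroundSlow
#   8. growth of live pools (NPP allocated by pNPP)
# Transition-triggered (disturbance) flows are applied after all base flows,
# at the end of the timestep.
#
# Decay of a DOM pool removes pool * EDR * DM, where EDR is the
# temperature-adjusted effective decay rate and DM a spatial decay
# multiplier; a proportion p_air of the removed carbon is emitted to the
# atmosphere (heterotrophic respiration) and the remainder transferred to
# the slow pool of the same stratum. Slow pools use p_air = 1 by default.

#' Effective decay rate of a DOM pool
#'
#' Temperature adjustment of a base decay rate defined at a reference
#' temperature: `EDR = BDR * exp((T - T_ref) * log(Q10) * 0.1)`, identical
#' to `BDR * Q10^((T - T_ref)/10)`.
#'
#' @param bdr Base decay rate (1/yr) at `t_ref`, `>= 0`.
#' @param temp Mean annual temperature (degrees C).
#' @param t_ref Reference temperature (degrees C), default 10.
#' @param q10 Q10 coefficient (> 0): rate multiplier per +10 degrees C.
#' @return Effective decay rate (1/yr).
#' @examples
#' effective_decay_rate(0.15, 20, 10, 2.0) / 0.15 # 2
#' @export
effective_decay_rate <- function(bdr, temp, t_ref = 10, q10 = 2.0) {
  if (any(bdr < 0)) stop("bdr must be >= 0")
  if (any(q10 <= 0)) stop("q10 must be > 0")
  bdr * exp((temp - t_ref) * log(q10) * 0.1)
}

# Internal: per-species EDR vector over the 9 DOM pools at the species'
# range mean temperature.
species_edr <- function(flows, temp) {
  effective_decay_rate(flows$bdr, temp, flows$t_ref, flows$q10)
}

# Internal: which DM multiplier each DOM pool takes ("fast" pools are those
# with the fast Q10 coefficient).
dm_kind <- function(flows) ifelse(flows$q10 == max(flows$q10), "fast", "slow")

# Internal zero flux ledger for n cells.
empty_ledger <- function(n) {
  list(npp = numeric(n), rh = numeric(n), turnover = numeric(n),
       dom_transfer = numeric(n), combustion = numeric(n),
       harvest = numeric(n), mortality = numeric(n), clipped = 0L)
}

#' One annual base step of the carbon engine
#'
#' Applies the ordered base flows (snag fall, decay/emission, biomass
#' turnover, slow-pool transfer, growth) to one or more cells sharing a
#' species parameter set. Vectorised over cells.
#'
#' @param pools Pool vector (length 14) or n x 14 matrix (tons C/ha).
#' @param age Age (years) the stand is growing *into* this step (scalar or
#'   length n); growth uses `npp$npp[age]` clamped to the schedule length.
#' @param schedule An [npp_schedule] for the species.
#' @param flows Resolved flow parameters (see [read_flow_params()]), with
#'   `edr` precomputed at the species temperature via `species_edr`
#'   (otherwise computed here from `bdr`/`q10` at `t_ref`, i.e. multipliers
#'   of 1).
#' @param temp Temperature (degrees C) used for the effective decay rates;
#'   default the reference temperature (EDR = BDR).
#' @param growth_mult Growth (NPP anomaly) multiplier, scalar or length n.
#' @param dm_fast,dm_slow Decay multipliers for fast-Q10 and slow-Q10 DOM
#'   pools, scalar or length n.
#' @return List with `pools` (n x 14 matrix) and `ledger` (per-cell flux
#'   vectors: `npp`, `rh`, `turnover`, `dom_transfer`, plus zeroed
#'   disturbance categories; `clipped` counts outflow proportions capped at
#'   1).
#' @export
carbon_base_step <- function(pools, age, schedule, flows, temp = flows$t_ref,
                             growth_mult = 1, dm_fast = 1, dm_slow = 1) {
  P <- as_pool_matrix(pools)
  n <- nrow(P)
  if (any(growth_mult < 0) || any(dm_fast < 0) || any(dm_slow < 0))
    stop("multipliers must be >= 0")
  led <- empty_ledger(n)

  edr <- species_edr(flows, temp)
  kind <- dm_kind(flows)
  clipped <- 0L
  # per-pool decay outflow with capping; returns outflow vector (length n)
  decay_of <- function(pool) {
    dm <- if (kind[[pool]] == "fast") dm_fast else dm_slow
    rate <- edr[[pool]] * dm
    over <- rate > 1
    if (any(over)) {
      clipped <<- clipped + sum(over)
      rate <- pmin(rate, 1)
    }
    P[, pool] * rate
  }
  slow_of <- function(pool) {
    if (pool %in% FF_AG_DOM) "AbovegroundSlow" else "BelowgroundSlow"
  }
  emit_decay <- function(pool) {
    out <- decay_of(pool)
    emit <- flows$p_air[[pool]] * out
    keep <- out - emit
    P[, pool] <<- P[, pool] - out
    led$rh <<- led$rh + emit
    if (any(keep > 0)) {
      dst <- slow_of(pool)
      P[, dst] <<- P[, dst] + keep
      led$dom_transfer <<- led$dom_transfer + keep
    }
  }

  # 1. snag fall
  fall_s <- P[, "SnagStem"] * flows$snag_fall[["SnagStem"]]
  fall_b <- P[, "SnagBranch"] * flows$snag_fall[["SnagBranch"]]
  P[, "SnagStem"] <- P[, "SnagStem"] - fall_s
  P[, "AbovegroundMedium"] <- P[, "AbovegroundMedium"] + fall_s
  P[, "SnagBranch"] <- P[, "SnagBranch"] - fall_b
  P[, "AbovegroundFast"] <- P[, "AbovegroundFast"] + fall_b
  led$dom_transfer <- led$dom_transfer + fall_s + fall_b

  # 2. standing and down deadwood decay
  emit_decay("SnagStem"); emit_decay("SnagBranch"); emit_decay("AbovegroundMedium")
  # 3. belowground slow emission
  emit_decay("BelowgroundSlow")
  # 4. live -> DOM turnover
  for (pool in FF_LIVE_POOLS) {
    flux <- P[, pool] * flows$turnover[[pool]]
    P[, pool] <- P[, pool] - flux
    dst <- FF_TURNOVER_DEST[[pool]]
    P[, dst] <- P[, dst] + flux
    led$turnover <- led$turnover + flux
  }
  # 5. fast/very fast DOM decay
  emit_decay("BelowgroundVeryFast"); emit_decay("BelowgroundFast")
  emit_decay("AbovegroundVeryFast"); emit_decay("AbovegroundFast")
  # 6. aboveground slow emission
  emit_decay("AbovegroundSlow")
  # 7. aboveground slow -> belowground slow
  tr <- P[, "AbovegroundSlow"] * flows$slow_transfer
  P[, "AbovegroundSlow"] <- P[, "AbovegroundSlow"] - tr
  P[, "BelowgroundSlow"] <- P[, "BelowgroundSlow"] + tr
  led$dom_transfer <- led$dom_transfer + tr
  # 8. growth
  a <- pmin(pmax(age, 0L), schedule$max_age)
  npp <- schedule$npp[a + 1L] * growth_mult
  if (any(npp > 0)) {
    alloc <- schedule$pnpp[a + 1L, , drop = FALSE] * npp
    P[, FF_LIVE_POOLS] <- P[, FF_LIVE_POOLS] + alloc
  }
  led$npp <- led$npp + npp
  # clipping is logged, never silent: callers surface the count once per run
  led <- lapply(led, unname)
  led$clipped <- clipped
  list(pools = P, ledger = led)
}

#' Apply transition-triggered carbon flows
#'
#' Applies one disturbance/land-use transition matrix to the given cells:
#' all proportional moves are computed simultaneously from the
#' pre-transition state. Moves to `atmosphere` are ledgered as combustion,
#' moves to `export` as harvest (out of the ecosystem), and live-to-DOM
#' moves as mortality.
#'
#' @param pools Pool vector or n x 14 matrix.
#' @param dmat Disturbance matrices table ([read_disturbance_matrices()]).
#' @param transition Transition type name (e.g. `"fire_high"`,
#'   `"clearcut"`).
#' @return List with `pools` and `ledger` (`combustion`, `harvest`,
#'   `mortality`, `dom_transfer` per cell).
#' @export
apply_transition_flows <- function(pools, dmat, transition) {
  P <- as_pool_matrix(pools)
  rows <- dmat[dmat$transition_type == transition, , drop = FALSE]
  if (!nrow(rows)) stop("unknown transition type: ", transition)
  led <- empty_ledger(nrow(P))
  P0 <- P
  inflow <- P * 0
  for (i in seq_len(nrow(rows))) {
    src <- rows$source_pool[i]
    dst <- rows$destination[i]
    moved <- P0[, src] * rows$proportion[i]
    if (dst == "atmosphere") {
      led$combustion <- led$combustion + moved
    } else if (dst == "export") {
      led$harvest <- led$harvest + moved
    } else {
      inflow[, dst] <- inflow[, dst] + moved
      if (src %in% FF_LIVE_POOLS && dst %in% FF_DOM_POOLS) {
        led$mortality <- led$mortality + moved
      } else {
        led$dom_transfer <- led$dom_transfer + moved
      }
    }
  }
  # remove source-pool outflows as totals so a fully vacated pool is
  # exactly zero (no floating-point residue from sequential subtraction)
  tot <- stats::aggregate(proportion ~ source_pool, rows, sum)
  for (i in seq_len(nrow(tot))) {
    src <- tot$source_pool[i]
    P[, src] <- P0[, src] * max(1 - tot$proportion[i], 0)
  }
  P <- P + inflow
  led <- lapply(led, unname)
  led$clipped <- 0L
  list(pools = P, ledger = led)
}
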