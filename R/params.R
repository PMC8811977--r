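# Species parameters, biomass expansion factors, and base flow parameters.
#
# The packaged species table carries, per forest type-group: the Von
# Bertalanffy a (asymptote, m3/ha) and b (1/yr) merchantable-volume
# parameters, the mean annual temperature across the species range (degrees
# C) and the mean historical fire return interval (MRI, years), together
# with crosswalk labels (ecozone, province, reference species).
#
# Expansion factors and flow rates (turnover, base decay, emission
# proportions) are NOT inventory-derived: they are documented plausible
# softwood/hardwood defaults and should be overridden for science use.

# Forest type-groups treated as hardwoods by the packaged defaults.
FF_HARDWOOD_GROUPS <- c(
  "Forest: Oak/Pine Group", "Forest: Oak/Hickory Group",
  "Forest: Oak/Gum/Cypress Group", "Forest: Elm/Ash/Cottonwood Group",
  "Forest: Maple/Beech/Birch Group", "Forest: Aspen/Birch Group",
  "Forest: Alder/Maple Group", "Forest: Western Oak Group",
  "Forest: Tanoak/Laurel Group", "Forest: Other Western Hardwoods Group",
  "Forest: Tropical Hardwoods Group", "Forest: Exotic Hardwoods Group"
)

ff_extdata <- function(file) {
  path <- system.file("extdata", file, package = "forestflux")
  if (!nzchar(path)) stop("packaged data file not found: ", file)
  path
}

#' Read a species parameter table
#'
#' Reads and validates a CSV of per-species growth and disturbance-regime
#' parameters. The packaged file (`path = NULL`) transcribes a 28-row
#' crosswalk of U.S. forest type-groups.
#'
#' @param path CSV path; `NULL` for the packaged table. Required columns:
#'   `species_name, ecozone, province, cbm_species, a, b, mean_temp_c,
#'   mri_years`.
#' @return A `data.frame` of class `ff_species_params`, one row per species,
#'   with an added `class` column (`"softwood"`/`"hardwood"`).
#' @examples
#' sp <- read_species_params()
#' nrow(sp) # 28
#' @export
read_species_params <- function(path = NULL) {
  if (is.null(path)) path <- ff_extdata("species_params.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_name", "ecozone", "province", "cbm_species",
            "a", "b", "mean_temp_c", "mri_years")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("species params missing column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("a", "b", "mean_temp_c", "mri_years")) {
    if (!is.numeric(df[[col]])) stop("species params column not numeric: ", col)
  }
  if (anyDuplicated(df$species_name))
    stop("duplicate species_name in species params")
  if (any(df$a <= 0)) stop("species params: a must be > 0")
  if (any(df$b <= 0)) stop("species params: b must be > 0")
  if (any(df$mri_years < 1)) stop("species params: mri_years must be >= 1")
  df$class <- ifelse(df$species_name %in% FF_HARDWOOD_GROUPS,
                     "hardwood", "softwood")
  class(df) <- c("ff_species_params", "data.frame")
  df
}

#' Write a species parameter table
#'
#' @param params Table from [read_species_params()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_species_params <- function(params, path) {
  cols <- c("species_name", "ecozone", "province", "cbm_species",
            "a", "b", "mean_temp_c", "mri_years")
  utils::write.csv(as.data.frame(params)[, cols], path, row.names = FALSE)
  invisible(path)
}

# Internal: one species row (as a list) by name.
species_row <- function(params, species_name) {
  i <- match(species_name, params$species_name)
  if (is.na(i)) stop("unknown species: ", species_name)
  as.list(params[i, ])
}

#' Read biomass expansion factors
#'
#' Expansion factors map merchantable stem volume (m3/ha) to biomass (tons/ha)
#' in each of the five live tree components; `carbon_fraction` converts
#' biomass to carbon. The packaged defaults are plausible softwood/hardwood
#' values, not inventory-derived, and are selected per species by its
#' `class`.
#'
#' @param path CSV path; `NULL` for packaged defaults. Columns: `class,
#'   foliage, merchantable, other_wood, coarse_root, fine_root,
#'   carbon_fraction`.
#' @return Data frame keyed by `class`.
#' @export
read_expansion_params <- function(path = NULL) {
  if (is.null(path)) path <- ff_extdata("expansion_params.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "foliage", "merchantable", "other_wood",
            "coarse_root", "fine_root", "carbon_fraction")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("expansion params missing column(s): ",
                         paste(miss, collapse = ", "))
  num <- as.matrix(df[, need[-1]])
  if (any(num < 0)) stop("expansion factors must be >= 0")
  if (any(df$carbon_fraction <= 0 | df$carbon_fraction > 1))
    stop("carbon_fraction must be in (0, 1]")
  df
}

# Internal: resolve expansion factors for one species -> list(factors (5,
# named by live pool), carbon_fraction).
resolve_expansion <- function(expansion, species) {
  key <- if (species$class %in% expansion$class) species$class else "default"
  i <- match(key, expansion$class)
  if (is.na(i)) stop("no expansion factors for species class '", species$class,
                     "' and no default row")
  row <- expansion[i, ]
  list(
    factors = c(Foliage = row$foliage, Merchantable = row$merchantable,
                OtherWood = row$other_wood, CoarseRoot = row$coarse_root,
                FineRoot = row$fine_root),
    carbon_fraction = row$carbon_fraction
  )
}

#' Read base carbon flow parameters
#'
#' Long-format table of the engine's base flow rates: live-pool turnover
#' (1/yr), snag fall rates, per-DOM-pool base decay rates (BDR) at the 10
#' degree C reference temperature, the proportion of decayed carbon emitted
#' to the atmosphere (`p_air`, remainder routed to the same-stratum slow
#' pool), per-pool Q10 coefficients, and the aboveground-slow to
#' belowground-slow transfer rate.
#'
#' @param path CSV path; `NULL` for packaged defaults. Columns: `class,
#'   param, pool, value`, with `class` one of `default`, `softwood`,
#'   `hardwood`, or a species name (most specific match wins).
#' @return Data frame of class `ff_flow_params`.
#' @export
read_flow_params <- function(path = NULL) {
  if (is.null(path)) path <- ff_extdata("flow_params.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "param", "pool", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("flow params missing column(s): ",
                         paste(miss, collapse = ", "))
  ok <- df$param %in% c("turnover", "snag_fall", "bdr", "p_air", "q10",
                        "slow_transfer")
  if (any(!ok)) stop("unknown flow param(s): ",
                     paste(unique(df$param[!ok]), collapse = ", "))
  if (any(df$value < 0)) stop("flow rates must be >= 0")
  if (any(df$param %in% c("turnover", "snag_fall", "p_air") & df$value > 1))
    stop("turnover, snag_fall and p_air must be in [0, 1]")
  class(df) <- c("ff_flow_params", "data.frame")
  df
}

# Internal: resolve the flow-parameter set for one species. Lookup
# precedence: species_name > class (softwood/hardwood) > default.
resolve_flows <- function(flow_params, species) {
  pick <- function(param, pools) {
    out <- stats::setNames(rep(NA_real_, length(pools)), pools)
    for (key in c("default", species$class, species$species_name)) {
      sub <- flow_params[flow_params$class == key & flow_params$param == param, ]
      if (nrow(sub)) out[sub$pool] <- sub$value
    }
    if (anyNA(out)) stop("flow param '", param, "' missing for pool(s): ",
                         paste(pools[is.na(out)], collapse = ", "))
    out
  }
  list(
    species_name  = species$species_name,
    turnover      = pick("turnover", FF_LIVE_POOLS),
    snag_fall     = pick("snag_fall", c("SnagStem", "SnagBranch")),
    bdr           = pick("bdr", FF_DOM_POOLS),
    p_air         = pick("p_air", FF_DOM_POOLS),
    q10           = pick("q10", FF_DOM_POOLS),
    slow_transfer = unname(pick("slow_transfer", "AbovegroundSlow")),
    t_ref         = 10
  )
}

#' Merchantable volume from the Von Bertalanffy growth curve
#'
#' Evaluates `y = a * (1 - exp(-b * age))^3`, the merchantable stem volume
#' (m3/ha) of a stand of the given age. `a` is the asymptote and `b` the
#' rate of approach to it.
#'
#' @param params A species row (list/one-row data frame with `a`, `b`), e.g.
#'   from [read_species_params()].
#' @param age Stand age(s) in years, `>= 0`.
#' @return Volume(s) in m3/ha; strictly increasing in age, bounded by `a`.
#' @examples
#' sp <- read_species_params()
#' df <- sp[sp$species_name == "Forest: Douglas-fir Group", ]
#' merchantable_volume(df, 50)
#' @export
merchantable_volume <- function(params, age) {
  if (any(age < 0)) stop("age must be >= 0")
  params <- as.list(params)
  params$a * (1 - exp(-params$b * age))^3
}

#' Minimum harvest ages from the volume curve
#'
#' The minimum clearcut age is the smallest integer age whose merchantable
#' volume reaches `threshold` times the peak volume over ages 0..300; the
#' minimum selection-harvest age is half the clearcut age (rounded up).
#'
#' @param params Species row with `a`, `b`.
#' @param threshold Fraction of peak volume, in (0, 1); default 0.6.
#' @return List with `clearcut_age` and `selection_age` (years).
#' @examples
#' sp <- read_species_params()
#' min_harvest_age(sp[sp$species_name == "Forest: Douglas-fir Group", ])
#' @export
min_harvest_age <- function(params, threshold = 0.6) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ages <- 0:300
  vols <- merchantable_volume(params, ages)
  cc <- ages[which(vols >= threshold * max(vols))[1]]
  list(clearcut_age = cc, selection_age = as.integer(ceiling(cc / 2)))
}

#' Read disturbance (transition) carbon-flow matrices
#'
#' Long-format proportional flow definitions applied when a land-use or
#' disturbance transition fires: for each transition type, the proportion of
#' each source pool moved to a destination pool, to the atmosphere
#' (combustion), or out of the ecosystem (`export`, harvested wood).
#'
#' @param path CSV path; `NULL` for packaged defaults. Columns:
#'   `transition_type, source_pool, destination, proportion`.
#' @return Data frame of class `ff_disturbance_matrices`.
#' @export
read_disturbance_matrices <- function(path = NULL) {
  if (is.null(path)) path <- ff_extdata("disturbance_matrices.csv")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transition_type", "source_pool", "destination", "proportion")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("disturbance matrices missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!all(df$source_pool %in% FF_POOLS))
    stop("unknown source pool(s): ",
         paste(setdiff(df$source_pool, FF_POOLS), collapse = ", "))
  okdest <- df$destination %in% c(FF_POOLS, "atmosphere", "export")
  if (!all(okdest))
    stop("unknown destination(s): ",
         paste(unique(df$destination[!okdest]), collapse = ", "))
  if (any(df$proportion < 0)) stop("proportions must be >= 0")
  tot <- stats::aggregate(proportion ~ transition_type + source_pool, df, sum)
  if (any(tot$proportion > 1 + 1e-9))
    stop("source-pool proportions sum to > 1 for: ",
         paste(unique(tot$transition_type[tot$proportion > 1 + 1e-9]),
               collapse = ", "))
  class(df) <- c("ff_disturbance_matrices", "data.frame")
  df
}

#' Load the full packaged (or user-supplied) parameter set
#'
#' Convenience bundle used by the spin-up and scenario drivers.
#'
#' @param species,expansion,flows,disturbance Optional CSV paths overriding
#'   the packaged defaults.
#' @return List with elements `species`, `expansion`, `flows`,
#'   `disturbance`.
#' @export
load_parameters <- function(species = NULL, expansion = NULL, flows = NULL,
                            disturbance = NULL) {
  list(
    species     = read_species_params(species),
    expansion   = read_expansion_params(expansion),
    flows       = read_flow_params(flows),
    disturbance = read_disturbance_matrices(disturbance)
  )
}
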