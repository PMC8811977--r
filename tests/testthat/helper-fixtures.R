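# Shared fixtures: packaged parameters and memoised state attribute tables
# (spin-ups are deterministic, so one build per species serves every test).

ff_cache <- new.env(parent = emptyenv())

ff_params <- function() {
  if (is.null(ff_cache$params)) ff_cache$params <- load_parameters()
  ff_cache$params
}

ff_species <- function(name) {
  p <- ff_params()
  p$species[p$species$species_name == name, ]
}

DF <- "Forest: Douglas-fir Group"

# Memoised state attribute tables for a set of species.
ff_tables <- function(species_names) {
  if (is.null(ff_cache$tables)) ff_cache$tables <- list()
  missing <- setdiff(species_names, names(ff_cache$tables))
  if (length(missing)) {
    built <- build_all_tables(ff_params(), missing)
    ff_cache$tables[names(built)] <- built
  }
  ff_cache$tables[species_names]
}

# Small initialized demo landscape shared across driver tests.
ff_demo <- function(nrow = 30, ncol = 30, years = 10, seed = 7) {
  key <- paste("demo", nrow, ncol, years, seed, sep = "_")
  if (is.null(ff_cache[[key]])) {
    spec <- fixture_spec(nrow = nrow, ncol = ncol, seed = seed)
    ls <- make_landscape(spec)
    tabs <- ff_tables(spec$species)
    ls <- initialize_landscape(ls, tabs)
    ff_cache[[key]] <- list(spec = spec, landscape = ls, tables = tabs,
                            climate = make_climate(spec, years),
                            fire = make_fire_events(spec, years, ls))
  }
  ff_cache[[key]]
}

# Random valid flow-parameter set for property tests (seeded by caller).
ff_random_flows <- function() {
  pools <- carbon_pools("dom")
  live <- carbon_pools("live")
  list(species_name = "random",
       turnover = stats::setNames(runif(5, 0, 0.5), live),
       snag_fall = c(SnagStem = runif(1, 0, 0.3),
                     SnagBranch = runif(1, 0, 0.3)),
       bdr = stats::setNames(runif(9, 0, 0.5), pools),
       p_air = stats::setNames(runif(9, 0, 1), pools),
       q10 = stats::setNames(sample(c(2, 2.65), 9, TRUE), pools),
       slow_transfer = runif(1, 0, 0.1),
       t_ref = 10)
}

# Random NPP schedule over ages 0..max_age (seeded by caller).
ff_random_schedule <- function(max_age = 20L) {
  pn <- matrix(runif((max_age + 1) * 5), max_age + 1, 5,
               dimnames = list(NULL, carbon_pools("live")))
  pn <- pn / rowSums(pn)
  structure(list(species_name = "random", max_age = max_age,
                 npp = c(0, runif(max_age, 0, 5)), pnpp = pn),
            class = "ff_npp_schedule")
}
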