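# Seed-controlled synthetic landscapes, climate series and disturbance
# events. These stand in for the national land-cover, fire-perimeter and
# gridded-climate products a full-scale run would ingest: every module is
# testable with no download. They make no claim of statistical fidelity to
# real U.S. landscape pattern.

#' Fixture specification
#'
#' @param nrow,ncol Grid dimensions.
#' @param species Character vector of forest type-group names (packaged
#'   species table names).
#' @param mix Species mixing proportions (recycled/normalized); default
#'   equal.
#' @param pattern `"blocks"` (contiguous vertical bands per species) or
#'   `"random"` (independent per cell).
#' @param nonforest_fraction Fraction of cells assigned to a non-forest
#'   class (shrubland), placed at random.
#' @param age_dist `"uniform"` (0..age_max) or `"exponential"` (mean
#'   `age_mean`, truncated at `age_max`).
#' @param age_mean,age_max Age distribution parameters (years).
#' @param fire_init_fraction Fraction of forest cells whose last
#'   stand-replacing disturbance was fire (the rest: clearcut).
#' @param mat_normal,map_normal Climate normals at the grid centre (deg C,
#'   mm/yr); a small north-south gradient is applied.
#' @param mat_sd,map_sd Interannual Gaussian anomaly SDs.
#' @param trend_c_per_decade Linear warming trend (deg C/decade).
#' @param fire_fraction Annual burned fraction of the grid.
#' @param fire_patch Approximate patch edge length (cells) for burn
#'   rectangles.
#' @param clearcut_fraction,selection_fraction Annual harvest fractions of
#'   eligible forest.
#' @param n_strata Number of vertical-band reporting strata.
#' @param cell_area_ha Cell area (ha); default 100 (1-km cells).
#' @param seed Master RNG seed.
#' @return List of class `ff_fixture_spec`.
#' @export
fixture_spec <- function(nrow = 100L, ncol = 100L,
                         species = c("Forest: Douglas-fir Group",
                                     "Forest: Loblolly/Shortleaf Pine Group",
                                     "Forest: Maple/Beech/Birch Group",
                                     "Forest: Lodgepole Pine Group"),
                         mix = NULL, pattern = c("blocks", "random"),
                         nonforest_fraction = 0.1,
                         age_dist = c("uniform", "exponential"),
                         age_mean = 60, age_max = 150,
                         fire_init_fraction = 0.3,
                         mat_normal = 8, map_normal = 900,
                         mat_sd = 0.6, map_sd = 120,
                         trend_c_per_decade = 0,
                         fire_fraction = 0.005, fire_patch = 5L,
                         clearcut_fraction = 0.005,
                         selection_fraction = 0.002,
                         n_strata = 2L, cell_area_ha = 100, seed = 42L) {
  pattern <- match.arg(pattern)
  age_dist <- match.arg(age_dist)
  stopifnot(nonforest_fraction >= 0, nonforest_fraction <= 1,
            fire_fraction >= 0, fire_fraction <= 1,
            mat_sd >= 0, map_sd >= 0)
  if (is.null(mix)) mix <- rep(1, length(species))
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  fire_patch <- as.integer(fire_patch)
  n_strata <- as.integer(n_strata)
  structure(as.list(environment()), class = "ff_fixture_spec")
}

#' Generate a synthetic landscape
#'
#' Builds co-registered state-class, species, age, last-disturbance and
#' stratum grids from a [fixture_spec()]. Pure function of (spec, seed).
#'
#' @param spec A [fixture_spec()].
#' @return A landscape object: list with `nrow`, `ncol`, `n`,
#'   `cell_area_ha`, `species_names`, and per-cell vectors `state_class`,
#'   `species`, `age`, `tst`, `last_dist`, `frozen`, `stratum`; `pools` is
#'   `NULL` until [initialize_landscape()].
#' @export
make_landscape <- function(spec) {
  set.seed(derive_seed(spec$seed, "landscape"))
  n <- spec$nrow * spec$ncol
  mix <- spec$mix / sum(spec$mix)
  n_sp <- length(spec$species)

  if (spec$pattern == "blocks") {
    # vertical bands proportional to the mix
    col_of <- (seq_len(n) - 1L) %/% spec$nrow + 1L
    breaks <- c(0, ceiling(cumsum(mix) * spec$ncol))
    sp_id <- findInterval(col_of, breaks, left.open = TRUE)
    sp_id[sp_id < 1L] <- 1L; sp_id[sp_id > n_sp] <- n_sp
  } else {
    sp_id <- sample.int(n_sp, n, replace = TRUE, prob = mix)
  }
  state_class <- sp_id
  species <- sp_id

  if (spec$nonforest_fraction > 0) {
    nf <- sample.int(n, round(spec$nonforest_fraction * n))
    state_class[nf] <- FF_NONFOREST_CLASSES[["shrubland"]]
    species[nf] <- 0L
  }

  age <- if (spec$age_dist == "uniform") {
    sample.int(spec$age_max + 1L, n, replace = TRUE) - 1L
  } else {
    pmin(as.integer(round(stats::rexp(n, 1 / spec$age_mean))), spec$age_max)
  }
  age[species == 0L] <- 0L

  last_dist <- rep("clearcut", n)
  fire_cells <- stats::runif(n) < spec$fire_init_fraction
  last_dist[fire_cells] <- "fire"
  last_dist[species == 0L] <- "none"

  col_of <- (seq_len(n) - 1L) %/% spec$nrow + 1L
  stratum <- pmin(as.integer(ceiling(col_of / (spec$ncol / spec$n_strata))),
                  spec$n_strata)

  list(nrow = spec$nrow, ncol = spec$ncol, n = n,
       cell_area_ha = spec$cell_area_ha, species_names = spec$species,
       state_class = as.integer(state_class), species = as.integer(species),
       age = as.integer(age), tst = rep(0L, n), last_dist = last_dist,
       frozen = logical(n), stratum = stratum, protected = NULL,
       pools = NULL)
}

#' Generate a synthetic annual climate series
#'
#' Normals have a small north-south gradient; each year adds cellwise
#' Gaussian anomalies around the normals plus an optional linear warming
#' trend. Pure function of (spec, years, seed).
#'
#' @param spec A [fixture_spec()].
#' @param years Number of years.
#' @return List with `mat`, `map` (lists of matrices, one per year) and
#'   `mat_norm`, `map_norm` (matrices).
#' @export
make_climate <- function(spec, years) {
  set.seed(derive_seed(spec$seed, "climate"))
  nr <- spec$nrow; nc <- spec$ncol
  grad <- matrix(rep(seq(-0.5, 0.5, length.out = nr), nc), nr, nc)
  mat_norm <- spec$mat_normal + 2 * grad
  map_norm <- matrix(pmax(spec$map_normal * (1 - 0.2 * grad), 0), nr, nc)
  mat <- vector("list", years); map <- vector("list", years)
  for (y in seq_len(years)) {
    trend <- spec$trend_c_per_decade * y / 10
    mat[[y]] <- mat_norm + trend + matrix(stats::rnorm(nr * nc, 0, spec$mat_sd),
                                          nr, nc)
    map[[y]] <- pmax(map_norm + matrix(stats::rnorm(nr * nc, 0, spec$map_sd),
                                       nr, nc), 0)
  }
  list(mat = mat, map = map, mat_norm = mat_norm, map_norm = map_norm)
}

#' Generate synthetic annual fire-perimeter masks
#'
#' Random rectangular patches are placed until the target burned fraction
#' of burnable cells is reached each year. Masks only cover burnable
#' (forest or post-fire shrubland) classes of the supplied landscape.
#'
#' @param spec A [fixture_spec()].
#' @param years Number of years.
#' @param landscape Landscape used for the burnable-class mask.
#' @return List (one logical vector of length n per year).
#' @export
make_fire_events <- function(spec, years, landscape) {
  set.seed(derive_seed(spec$seed, "fire_events"))
  n <- landscape$n; nr <- landscape$nrow; nc <- landscape$ncol
  burnable <- landscape$state_class <= FF_CLASS_MAX_FOREST
  target <- round(spec$fire_fraction * n)
  out <- vector("list", years)
  for (y in seq_len(years)) {
    mask <- logical(n)
    guard <- 0L
    while (sum(mask & burnable) < target && guard < 1000L) {
      guard <- guard + 1L
      h <- sample.int(spec$fire_patch, 1) + 1L
      w <- sample.int(spec$fire_patch, 1) + 1L
      r0 <- sample.int(max(nr - h, 1), 1)
      c0 <- sample.int(max(nc - w, 1), 1)
      for (cc in c0:min(c0 + w - 1L, nc)) {
        idx <- ((cc - 1L) * nr) + (r0:min(r0 + h - 1L, nr))
        mask[idx] <- TRUE
      }
      if (target == 0) break
    }
    out[[y]] <- mask & burnable
  }
  out
}

#' Write a ready-to-run demo scenario directory
#'
#' Materializes the default demo fixture (landscape, climate, fire events,
#' config) as plain-text files: ASCII grids, CSVs and a JSON scenario
#' config.
#'
#' @param dir Output directory (created if needed).
#' @param spec A [fixture_spec()]; default the packaged demo
#'   (100 x 100 grid, 4 species, 20 years).
#' @param years Number of simulation years.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(dir, spec = fixture_spec(), years = 20L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ls <- make_landscape(spec)
  cl <- make_climate(spec, years)
  ev <- make_fire_events(spec, years, ls)
  gw <- function(x, f) write_ascii_grid(matrix(x, ls$nrow, ls$ncol),
                                        file.path(dir, f))
  gw(ls$state_class, "state_class.asc")
  gw(ls$age, "age.asc")
  gw(ls$stratum, "stratum.asc")
  gw(as.integer(factor(ls$last_dist, c("none", "fire", "clearcut"))) - 1L,
     "last_disturbance.asc")
  write_ascii_grid(cl$mat_norm, file.path(dir, "mat_normal.asc"))
  write_ascii_grid(cl$map_norm, file.path(dir, "map_normal.asc"))
  for (y in seq_len(years)) {
    write_ascii_grid(cl$mat[[y]], file.path(dir, sprintf("mat_%03d.asc", y)))
    write_ascii_grid(cl$map[[y]], file.path(dir, sprintf("map_%03d.asc", y)))
    gw(as.integer(ev[[y]]), sprintf("fire_%03d.asc", y))
  }
  utils::write.csv(data.frame(species_id = seq_along(spec$species),
                              species_name = spec$species),
                   file.path(dir, "species_legend.csv"), row.names = FALSE)
  cfg <- list(years = years, seed = spec$seed,
              cell_area_ha = spec$cell_area_ha,
              clearcut_fraction = spec$clearcut_fraction,
              selection_fraction = spec$selection_fraction,
              fire_fraction = spec$fire_fraction)
  jsonlite::write_json(cfg, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
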