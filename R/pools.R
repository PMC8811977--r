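# Carbon pool structure: 5 live pools + 9 dead organic matter (DOM) pools.
# Pool order is fixed package-wide; all pool matrices use these columns.

FF_LIVE_POOLS <- c("Foliage", "Merchantable", "OtherWood", "CoarseRoot", "FineRoot")

FF_DOM_POOLS <- c(
  "SnagStem", "SnagBranch",
  "AbovegroundMedium", "AbovegroundFast", "AbovegroundVeryFast", "AbovegroundSlow",
  "BelowgroundFast", "BelowgroundVeryFast", "BelowgroundSlow"
)

FF_POOLS <- c(FF_LIVE_POOLS, FF_DOM_POOLS)

# Aboveground vs belowground DOM: decayed-but-not-emitted carbon is routed to
# the slow pool of the same stratum.
FF_AG_DOM <- c("SnagStem", "SnagBranch", "AbovegroundMedium", "AbovegroundFast",
               "AbovegroundVeryFast", "AbovegroundSlow")
FF_BG_DOM <- c("BelowgroundFast", "BelowgroundVeryFast", "BelowgroundSlow")

# Live-pool turnover destinations (CBM-style snag/litter routing).
FF_TURNOVER_DEST <- c(
  Foliage      = "AbovegroundVeryFast",
  Merchantable = "SnagStem",
  OtherWood    = "SnagBranch",
  CoarseRoot   = "BelowgroundFast",
  FineRoot     = "BelowgroundVeryFast"
)

#' Names of the carbon pools tracked by the model
#'
#' The model tracks 14 per-cell carbon pools: five live pools (foliage,
#' merchantable stem, other wood, coarse root, fine root) and nine dead
#' organic matter (DOM) pools covering standing dead trees (snags), down
#' deadwood, litter, and soil, named by decay speed (very fast, fast, medium,
#' slow) and position (above/belowground).
#'
#' @param which One of `"all"`, `"live"`, `"dom"`.
#' @return Character vector of pool names, in the canonical column order.
#' @examples
#' carbon_pools("live")
#' @export
carbon_pools <- function(which = c("all", "live", "dom")) {
  which <- match.arg(which)
  switch(which, all = FF_POOLS, live = FF_LIVE_POOLS, dom = FF_DOM_POOLS)
}

#' Construct a per-cell pool vector
#'
#' @param ... Named pool densities (tons C/ha); unnamed pools default to 0.
#' @return Named numeric vector of length 14 in canonical pool order.
#' @examples
#' pool_vector(Merchantable = 120, SnagStem = 8)
#' @export
pool_vector <- function(...) {
  vals <- c(...)
  out <- stats::setNames(numeric(length(FF_POOLS)), FF_POOLS)
  if (length(vals)) {
    bad <- setdiff(names(vals), FF_POOLS)
    if (length(bad) || is.null(names(vals))) {
      stop("unknown pool name(s): ", paste(bad, collapse = ", "))
    }
    out[names(vals)] <- vals
  }
  if (any(out < 0)) stop("pool densities must be >= 0")
  out
}

# Internal: coerce a pool vector or n x 14 matrix to a matrix with canonical
# columns; errors on wrong shape.
as_pool_matrix <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == length(FF_POOLS))
    x <- matrix(x, nrow = 1, dimnames = list(NULL, FF_POOLS))
  }
  stopifnot(ncol(x) == length(FF_POOLS))
  if (!is.null(colnames(x))) x <- x[, FF_POOLS, drop = FALSE]
  else colnames(x) <- FF_POOLS
  x
}

#' Convert a carbon mass to CO2 mass
#'
#' Multiplies by the molar mass ratio 44/12. Reporting convenience for
#' emissions summaries (e.g. Tg C to Tg CO2).
#'
#' @param mass_c Carbon mass (any mass unit), non-negative.
#' @return CO2 mass in the same unit.
#' @examples
#' carbon_to_co2(12) # 44
#' @export
carbon_to_co2 <- function(mass_c) {
  if (any(mass_c < 0)) stop("mass_c must be >= 0")
  mass_c * 44 / 12
}
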