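# Plain-text grid and table I/O shared across modules.
#
# Grids are numeric matrices serialized as ESRI ASCII grids (.asc): a
# 6-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
# NODATA_value) followed by rows of whitespace-separated values, top row
# first. Areas are always derived from a configured cell_area_ha, never
# from coordinates, so fixtures stay projection-free.

#' Write a grid as an ESRI ASCII raster
#'
#' @param grid Numeric matrix; `NA` written as the nodata value.
#' @param path Output path.
#' @param xllcorner,yllcorner,cellsize Georeferencing header values.
#' @param nodata Nodata sentinel (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path, xllcorner = 0, yllcorner = 0,
                             cellsize = 1000, nodata = -9999) {
  stopifnot(is.matrix(grid))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(grid)), paste("nrows", nrow(grid)),
    paste("xllcorner", format(xllcorner, scientific = FALSE)),
    paste("yllcorner", format(yllcorner, scientific = FALSE)),
    paste("cellsize", format(cellsize, scientific = FALSE)),
    paste("NODATA_value", nodata)), con)
  g <- grid
  g[is.na(g)] <- nodata
  utils::write.table(format(g, trim = TRUE, digits = 17), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path File path.
#' @return Numeric matrix with nodata as `NA`; header fields attached as
#'   attribute `georef`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(lines), "\\s+")
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                         tolower(vapply(kv, `[`, "", 1)))
  vals <- scan(path, skip = 6, quiet = TRUE)
  nr <- hdr[["nrows"]]; nc <- hdr[["ncols"]]
  if (length(vals) != nr * nc)
    stop("grid size mismatch in ", path, ": expected ", nr * nc,
         " values, got ", length(vals))
  g <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  g[g == hdr[["nodata_value"]]] <- NA
  attr(g, "georef") <- hdr
  g
}

#' Check a set of grids for co-registration
#'
#' @param ... Named grids (matrices as returned by [read_ascii_grid()]).
#' @return `TRUE` invisibly; errors naming the offending pair otherwise.
#' @export
check_coregistered <- function(...) {
  grids <- list(...)
  nms <- names(grids)
  ref <- grids[[1]]
  for (i in seq_along(grids)[-1]) {
    if (!all(dim(grids[[i]]) == dim(ref)))
      stop("grids not co-registered: '", nms[1], "' is ",
           paste(dim(ref), collapse = "x"), " but '", nms[i], "' is ",
           paste(dim(grids[[i]]), collapse = "x"))
    g1 <- attr(ref, "georef"); g2 <- attr(grids[[i]], "georef")
    if (!is.null(g1) && !is.null(g2)) {
      for (f in c("xllcorner", "yllcorner", "cellsize")) {
        if (!isTRUE(all.equal(g1[[f]], g2[[f]])))
          stop("grids not co-registered: '", nms[1], "' and '", nms[i],
               "' differ in ", f)
      }
    }
  }
  invisible(TRUE)
}

#' Serialize a stock-by-age table to tidy CSV
#'
#' Long format: `species, last_disturbance, age, pool, tons_c_per_ha`.
#'
#' @param table An `ff_stock_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_stock_table <- function(table, path) {
  stopifnot(inherits(table, "ff_stock_table"))
  df <- data.frame(
    species = table$species_name,
    last_disturbance = table$last_disturbance,
    age = rep(table$ages, times = ncol(table$stocks)),
    pool = rep(colnames(table$stocks), each = length(table$ages)),
    tons_c_per_ha = as.vector(table$stocks))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a stock-by-age table from tidy CSV
#'
#' @param path CSV written by [write_stock_table()].
#' @return An `ff_stock_table`.
#' @export
read_stock_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "last_disturbance", "age", "pool", "tons_c_per_ha")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("stock table missing column(s): ",
                         paste(miss, collapse = ", "))
  ages <- sort(unique(df$age))
  stocks <- matrix(0, length(ages), length(FF_POOLS),
                   dimnames = list(NULL, FF_POOLS))
  for (pool in unique(df$pool)) {
    sub <- df[df$pool == pool, ]
    stocks[match(sub$age, ages), pool] <- sub$tons_c_per_ha
  }
  stock_table(df$species[1], df$last_disturbance[1], stocks)
}

#' Write a run manifest
#'
#' JSON record of a simulation run: seeds, parameter-file checksums
#' (cheap size+name fingerprint), package version and wall-clock times.
#' Written atomically (temp file + rename).
#'
#' @param path Output JSON path.
#' @param seed Master seed used.
#' @param config Any list describing the run configuration.
#' @param files Character vector of input file paths to fingerprint.
#' @param started POSIXct start time (default now).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, seed, config = list(),
                               files = character(0), started = Sys.time()) {
  fp <- lapply(files, function(f)
    list(path = f, bytes = if (file.exists(f)) file.size(f) else NA))
  manifest <- list(
    package = "forestflux",
    version = as.character(utils::packageVersion("forestflux")),
    seed = seed, config = config, inputs = fp,
    started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}
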