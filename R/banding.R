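# Elevation assignment, 200-m banding, species ranges, band x species
# presence-absence matrices.

#' Define an elevation band grid
#'
#' Bands are half-open intervals `[b, b + width)` labeled by their lower
#' edge, starting at `origin`. The defaults (200 m width, 200 m origin)
#' give the band labels 200, 400, ..., matching a study frame restricted
#' to elevations of 200 m asl and above.
#'
#' @param width Band width in meters (> 0).
#' @param origin Lower edge of the first band, m asl.
#' @return A `band_grid` object.
#' @export
band_grid <- function(width = 200, origin = 200) {
  stopifnot(width > 0)
  structure(list(width = width, origin = origin), class = "band_grid")
}

#' Band label for an elevation
#'
#' @param elevation Numeric vector of elevations, m asl; every value must
#'   be at or above the grid origin (elevations below the study frame are
#'   an error, not a band).
#' @param grid A [band_grid()].
#' @return The lower-edge label of the band containing each elevation.
#' @export
band_of <- function(elevation, grid = band_grid()) {
  if (any(elevation < grid$origin, na.rm = TRUE)) {
    stop("elevation below grid origin (", grid$origin,
         " m): outside the study frame")
  }
  grid$origin + grid$width * floor((elevation - grid$origin) / grid$width)
}

# --- DEM (ESRI ASCII grid) ---------------------------------------------------

#' Read a DEM stored as an ESRI ASCII grid
#'
#' Plain-text single-band raster in WGS84 with elevations in meters: a
#' six-line header (`ncols`, `nrows`, `xllcorner`, `yllcorner`, `cellsize`,
#' `nodata_value`) followed by rows of values, northernmost row first.
#'
#' @param path Path to the `.asc` file.
#' @return A `dem_grid` object.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  vals <- scan(text = lines[i:length(lines)], quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  m[m == nodata] <- NA_real_
  structure(list(values = m, ncols = hdr$ncols, nrows = hdr$nrows,
                 xll = hdr$xllcorner, yll = hdr$yllcorner,
                 cellsize = hdr$cellsize),
            class = "dem_grid")
}

#' Sample a DEM at point coordinates (nearest cell)
#'
#' @param dem A [read_ascii_grid()] result.
#' @param lon,lat Coordinate vectors (WGS84 degrees).
#' @return Elevations in meters; `NA` for points outside the raster extent
#'   or over nodata cells.
#' @export
dem_extract <- function(dem, lon, lat) {
  col <- floor((lon - dem$xll) / dem$cellsize) + 1L
  row <- dem$nrows - floor((lat - dem$yll) / dem$cellsize)
  ok <- col >= 1L & col <= dem$ncols & row >= 1L & row <= dem$nrows &
    !is.na(lon) & !is.na(lat)
  out <- rep(NA_real_, length(lon))
  out[ok] <- dem$values[cbind(row[ok], col[ok])]
  out
}

#' Assign elevations to records
#'
#' With a DEM, every record's elevation is set by nearest-cell sampling at
#' its coordinates, overriding any elevation already on the record (the
#' DEM is the authoritative source when present). Without a DEM the
#' record's own elevation field is used. Records left without an
#' obtainable elevation are counted in the cleaning log under
#' `"elevation_missing"` and excluded at banding time.
#'
#' @param rs A `record_set`.
#' @param dem A `dem_grid`, or `NULL` to use record elevations.
#' @return The `record_set` with elevations filled.
#' @export
assign_elevation <- function(rs, dem = NULL) {
  r <- rs$records
  if (!is.null(dem)) {
    sampled <- dem_extract(dem, r$longitude, r$latitude)
    if (anyNA(sampled)) {
      warning(sum(is.na(sampled)),
              " record(s) outside DEM extent or over nodata; ",
              "elevation left missing")
    }
    rs$records$elevation <- sampled
  }
  missing <- sum(is.na(rs$records$elevation))
  if (missing > 0L) {
    rs$cleaning_log <- .bump_log(rs$cleaning_log, "elevation_missing",
                                 missing)
  }
  rs
}

.scope_records <- function(rs, scope) {
  r <- rs$records
  if (is.null(scope) || identical(scope, "study-area")) return(r)
  r[!is.na(r$entity) & r$entity == scope, , drop = FALSE]
}

#' Per-species elevational ranges within a scope
#'
#' @param rs A `record_set` with elevations assigned.
#' @param scope `"study-area"` (or `NULL`) for all records, or an entity
#'   code to restrict to that entity's records.
#' @return Data frame with one row per species present in the scope:
#'   `species`, `genus`, `family`, `min_elev`, `max_elev`, `n_records`,
#'   `scope`. Records without elevation are ignored.
#' @export
species_ranges <- function(rs, scope = "study-area") {
  r <- .scope_records(rs, scope)
  r <- r[!is.na(r$elevation), , drop = FALSE]
  if (nrow(r) == 0L) {
    return(data.frame(species = character(0), genus = character(0),
                      family = character(0), min_elev = numeric(0),
                      max_elev = numeric(0), n_records = integer(0),
                      scope = character(0), stringsAsFactors = FALSE))
  }
  sp <- split(seq_len(nrow(r)), r$species)
  out <- data.frame(
    species = names(sp),
    genus = vapply(sp, function(i) r$genus[i[1]], character(1)),
    family = vapply(sp, function(i) r$family[i[1]], character(1)),
    min_elev = vapply(sp, function(i) min(r$elevation[i]), numeric(1)),
    max_elev = vapply(sp, function(i) max(r$elevation[i]), numeric(1)),
    n_records = vapply(sp, length, integer(1)),
    scope = if (is.null(scope)) "study-area" else scope,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Build a band x species presence-absence matrix
#'
#' In `records` mode (the default) a cell (band, species) is 1 when the
#' species has at least one record whose elevation falls in that band; a
#' species can therefore occupy non-contiguous bands. In `range_fill` mode
#' every band intersecting the species' min-max elevational range is
#' marked, giving contiguous occupancy. Empty bands, records below the
#' grid origin and records without elevation are dropped.
#'
#' @param rs A `record_set` with elevations assigned.
#' @param scope `"study-area"` or an entity code.
#' @param grid A [band_grid()].
#' @param mode `"records"` or `"range_fill"`.
#' @return A `band_matrix` object: binary `occupancy` matrix (rows = band
#'   lower-edge labels, ascending; columns = species), plus `scope`,
#'   `grid`, `mode` and `bands` (numeric band labels).
#' @export
build_band_matrix <- function(rs, scope = "study-area", grid = band_grid(),
                              mode = c("records", "range_fill")) {
  mode <- match.arg(mode)
  r <- .scope_records(rs, scope)
  r <- r[!is.na(r$elevation), , drop = FALSE]
  below <- r$elevation < grid$origin
  if (any(below)) r <- r[!below, , drop = FALSE]
  if (nrow(r) == 0L) stop("empty scope: ", scope)
  band <- band_of(r$elevation, grid)
  if (mode == "records") {
    occ_pairs <- unique(data.frame(band = band, species = r$species,
                                   stringsAsFactors = FALSE))
  } else {
    rng <- species_ranges(record_set(r), scope = "study-area")
    occ_pairs <- do.call(rbind, lapply(seq_len(nrow(rng)), function(i) {
      lo <- band_of(max(rng$min_elev[i], grid$origin), grid)
      hi <- band_of(rng$max_elev[i], grid)
      data.frame(band = seq(lo, hi, by = grid$width),
                 species = rng$species[i], stringsAsFactors = FALSE)
    }))
  }
  bands <- sort(unique(occ_pairs$band))
  species <- sort(unique(occ_pairs$species))
  occ <- matrix(0L, length(bands), length(species),
                dimnames = list(as.character(bands), species))
  occ[cbind(match(occ_pairs$band, bands),
            match(occ_pairs$species, species))] <- 1L
  structure(list(scope = if (is.null(scope)) "study-area" else scope,
                 grid = grid, mode = mode, bands = bands,
                 occupancy = occ),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat("Band matrix [", x$scope, "]: ", length(x$bands), " bands x ",
      ncol(x$occupancy), " species (", x$mode, " occupancy, width ",
      x$grid$width, " m)\n", sep = "")
  invisible(x)
}

#' Serialize a band matrix as TSV plus a JSON sidecar
#'
#' @param M A `band_matrix`.
#' @param path Output TSV path; the sidecar goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(M, path) {
  utils::write.table(M$occupancy, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  jsonlite::write_json(list(scope = M$scope, width = M$grid$width,
                            origin = M$grid$origin, mode = M$mode),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
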