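# Occurrence record I/O, cleaning, deduplication, taxonomic harmonization
# and entity assignment.

#' Construct a record set
#'
#' A `record_set` bundles a table of occurrence records with provenance
#' counts (records per source at read time) and a cleaning log that
#' accumulates per-rule removal counts as the curation functions are applied.
#'
#' @param records Data frame with columns `species`, `genus`, `family`,
#'   `latitude`, `longitude`, `elevation`, `source`, `entity`.
#' @param provenance Named integer vector of record counts per source,
#'   taken before any cleaning.
#' @param cleaning_log Named list of per-rule removal counts.
#' @return An object of class `record_set`.
#' @export
record_set <- function(records, provenance = NULL, cleaning_log = list()) {
  stopifnot(is.data.frame(records))
  needed <- c("species", "genus", "family", "latitude", "longitude",
              "elevation", "source", "entity")
  for (col in setdiff(needed, names(records))) {
    records[[col]] <- if (col %in% c("latitude", "longitude", "elevation"))
      NA_real_ else NA_character_
  }
  records <- records[, needed]
  if (is.null(provenance)) {
    src <- ifelse(is.na(records$source), "unknown", records$source)
    provenance <- if (nrow(records)) table(src) else integer(0)
    provenance <- stats::setNames(as.integer(provenance), names(provenance))
  }
  structure(list(records = records,
                 provenance = provenance,
                 cleaning_log = cleaning_log),
            class = "record_set")
}

#' @export
print.record_set <- function(x, ...) {
  cat("Occurrence record set: ", nrow(x$records), " records, ",
      length(unique(x$records$species)), " species\n", sep = "")
  if (length(x$provenance)) {
    cat("Provenance:", paste(names(x$provenance), x$provenance,
                             sep = "=", collapse = ", "), "\n")
  }
  if (length(x$cleaning_log)) {
    cat("Cleaning log:", paste(names(x$cleaning_log),
                               unlist(x$cleaning_log),
                               sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of records in a record set
#' @param rs A `record_set`.
#' @return Integer record count.
#' @export
n_records <- function(rs) nrow(rs$records)

.default_column_map <- c(species = "scientificName", genus = "genus",
                         family = "family", latitude = "decimalLatitude",
                         longitude = "decimalLongitude",
                         elevation = "elevation", source = "source",
                         entity = "entity")

.bump_log <- function(log, rule, n = 1L) {
  log[[rule]] <- (if (is.null(log[[rule]])) 0L else log[[rule]]) + as.integer(n)
  log
}

#' Read occurrence records from delimited text
#'
#' Reads a comma- or tab-delimited table of occurrence records using
#' Darwin-Core style default headers (`scientificName`, `decimalLatitude`,
#' `decimalLongitude`, ...), overridable through `column_map`. Rows whose
#' coordinates (or elevation, when present) fail numeric coercion are
#' dropped and counted in the cleaning log under `"coercion"`, never fatal;
#' a missing mandatory column is fatal.
#'
#' @param path Path to a delimited text file (UTF-8). The delimiter is
#'   sniffed from the header line (tab wins over comma) unless given.
#' @param column_map Named character vector mapping internal field names
#'   (`species`, `latitude`, `longitude`, and optionally `genus`, `family`,
#'   `elevation`, `source`, `entity`) to file column names. Unnamed fields
#'   fall back to the Darwin-Core defaults.
#' @param delim Optional explicit field delimiter.
#' @return A [record_set()].
#' @export
read_records <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) stop("cannot read records: no such file: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(delim)) delim <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", check.names = FALSE)
  cmap <- .default_column_map
  if (length(column_map)) cmap[names(column_map)] <- column_map
  for (field in c("species", "latitude", "longitude")) {
    if (!cmap[[field]] %in% names(raw)) {
      stop("mandatory column missing from ", path, ": '", cmap[[field]],
           "' (maps to field '", field, "')")
    }
  }
  get_col <- function(field, default) {
    if (cmap[[field]] %in% names(raw)) raw[[cmap[[field]]]]
    else rep(default, nrow(raw))
  }
  rec <- data.frame(
    species   = get_col("species", NA_character_),
    genus     = get_col("genus", NA_character_),
    family    = get_col("family", NA_character_),
    latitude  = suppressWarnings(as.numeric(get_col("latitude", NA))),
    longitude = suppressWarnings(as.numeric(get_col("longitude", NA))),
    elevation = suppressWarnings(as.numeric(get_col("elevation", NA))),
    source    = get_col("source", "aggregator"),
    entity    = get_col("entity", NA_character_),
    stringsAsFactors = FALSE
  )
  # elevation may be legitimately missing; coordinates may not
  elev_raw <- get_col("elevation", NA)
  bad_elev <- !is.na(elev_raw) & elev_raw != "" & is.na(rec$elevation)
  bad <- is.na(rec$latitude) | is.na(rec$longitude) | bad_elev |
    is.na(rec$species) | rec$species == ""
  log <- list()
  if (any(bad)) log <- .bump_log(log, "coercion", sum(bad))
  rs <- record_set(rec, cleaning_log = log)  # provenance from full table
  rs$records <- rs$records[!bad, , drop = FALSE]
  rownames(rs$records) <- NULL
  rs
}

#' Write a record set back to delimited text
#'
#' @param rs A `record_set`.
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_records <- function(rs, path, delim = ",") {
  out <- rs$records
  names(out) <- c("scientificName", "genus", "family", "decimalLatitude",
                  "decimalLongitude", "elevation", "source", "entity")
  utils::write.table(out, path, sep = delim, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Remove records with invalid or suspicious coordinates
#'
#' Applies self-contained coordinate-validity rules: latitude or longitude
#' outside WGS84 bounds, exact (0, 0) points, and records whose latitude
#' equals their longitude to more than four decimals (a classic
#' transposition/entry artefact). Removal counts are recorded per rule in
#' the cleaning log. Gazetteer-dependent tests (country borders, centroids,
#' sea) are out of scope.
#'
#' @param rs A `record_set`.
#' @return The cleaned `record_set`.
#' @export
clean_coordinates <- function(rs) {
  r <- rs$records
  out_of_range <- r$latitude < -90 | r$latitude > 90 |
    r$longitude < -180 | r$longitude > 180
  zero_zero <- !out_of_range & r$latitude == 0 & r$longitude == 0
  lat_eq_lon <- !out_of_range & !zero_zero &
    abs(r$latitude - r$longitude) < 1e-4 & !(r$latitude == 0 & r$longitude == 0)
  log <- rs$cleaning_log
  if (any(out_of_range)) log <- .bump_log(log, "coord_out_of_range", sum(out_of_range))
  if (any(zero_zero))    log <- .bump_log(log, "coord_zero_zero", sum(zero_zero))
  if (any(lat_eq_lon))   log <- .bump_log(log, "coord_lat_eq_lon", sum(lat_eq_lon))
  keep <- !(out_of_range | zero_zero | lat_eq_lon)
  rs$records <- r[keep, , drop = FALSE]
  rownames(rs$records) <- NULL
  rs$cleaning_log <- log
  rs
}

#' Read a synonym table
#'
#' @param path CSV with columns `verbatim`, `species`, `genus`, `family`.
#' @return A `synonym_table` data frame. Duplicate verbatim names are an
#'   error: the mapping must be a function.
#' @export
read_synonyms <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  synonym_table(tab)
}

#' Construct a synonym table
#'
#' @param tab Data frame with columns `verbatim`, `species`, `genus`,
#'   `family` mapping each verbatim name to its accepted taxonomy.
#' @return The validated table with class `synonym_table`.
#' @export
synonym_table <- function(tab) {
  stopifnot(all(c("verbatim", "species", "genus", "family") %in% names(tab)))
  if (anyDuplicated(tab$verbatim))
    stop("synonym table maps a verbatim name to more than one target")
  class(tab) <- c("synonym_table", "data.frame")
  tab
}

#' Harmonize taxonomy against a synonym table
#'
#' Every record whose verbatim species name appears in the table has its
#' species, genus and family replaced by the accepted values; names absent
#' from the table are kept verbatim and counted in the cleaning log under
#' `"unmatched_names"`. Record count is never changed.
#'
#' @param rs A `record_set`.
#' @param syn A [synonym_table()] (possibly empty).
#' @return The harmonized `record_set`.
#' @export
harmonize_taxonomy <- function(rs, syn) {
  if (nrow(syn) == 0L || nrow(rs$records) == 0L) return(rs)
  idx <- match(rs$records$species, syn$verbatim)
  hit <- !is.na(idx)
  rs$records$species[hit] <- syn$species[idx[hit]]
  rs$records$genus[hit]   <- syn$genus[idx[hit]]
  rs$records$family[hit]  <- syn$family[idx[hit]]
  rs$cleaning_log <- .bump_log(rs$cleaning_log, "unmatched_names",
                               sum(!hit))
  rs
}

#' Deduplicate records to unique species-locality pairs
#'
#' Keeps at most one record per (species, rounded latitude, rounded
#' longitude) key, preserving the first-encountered record. Coordinates are
#' rounded to `coord_decimals` places (default 4, about 11 m at the
#' equator) to merge re-entered duplicates while separating distinct
#' localities.
#'
#' @param rs A `record_set`.
#' @param coord_decimals Integer number of decimal places for the key.
#' @return The deduplicated `record_set`; removals logged under
#'   `"duplicates"`.
#' @export
deduplicate <- function(rs, coord_decimals = 4L) {
  r <- rs$records
  key <- paste(r$species,
               formatC(round(r$latitude, coord_decimals),
                       format = "f", digits = coord_decimals),
               formatC(round(r$longitude, coord_decimals),
                       format = "f", digits = coord_decimals),
               sep = "|")
  dup <- duplicated(key)
  if (any(dup))
    rs$cleaning_log <- .bump_log(rs$cleaning_log, "duplicates", sum(dup))
  rs$records <- r[!dup, , drop = FALSE]
  rownames(rs$records) <- NULL
  rs
}

# --- entity polygons ---------------------------------------------------------

#' Read entity polygons from GeoJSON
#'
#' Reads a GeoJSON FeatureCollection of Polygon/MultiPolygon features in
#' WGS84, each carrying a string property `entity`. Feature order in the
#' file is preserved; it is the tie-break for points on shared edges and
#' for overlapping polygons.
#'
#' @param path Path to a GeoJSON file.
#' @return An `entity_polygons` object: a list of features, each with
#'   `entity` (code) and `rings` (list of two-column lon/lat matrices;
#'   ring orientation and holes are not interpreted — every ring is
#'   treated as an outer boundary).
#' @export
read_entity_polygons <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  feats <- lapply(gj$features, function(f) {
    ent <- f$properties$entity
    if (is.null(ent)) stop("GeoJSON feature lacks string property 'entity'")
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = geom$coordinates,
      MultiPolygon = do.call(c, geom$coordinates),
      stop("unsupported geometry type: ", geom$type))
    rings <- lapply(rings, function(rg) {
      m <- do.call(rbind, lapply(rg, function(pt) c(pt[[1]], pt[[2]])))
      colnames(m) <- c("lon", "lat")
      m
    })
    list(entity = as.character(ent), rings = rings)
  })
  structure(feats, class = "entity_polygons")
}

# Ray-casting point-in-polygon; points on an edge or vertex count as inside.
.point_in_ring <- function(lon, lat, ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(n, seq_len(n - 1L))
  inside <- rep(FALSE, length(lon))
  on_edge <- rep(FALSE, length(lon))
  for (k in seq_len(n)) {
    x1 <- x[j[k]]; y1 <- y[j[k]]; x2 <- x[k]; y2 <- y[k]
    # boundary test: point within the segment's bounding box and collinear
    cross <- (lon - x1) * (y2 - y1) - (lat - y1) * (x2 - x1)
    on_seg <- abs(cross) < 1e-12 &
      lon >= pmin(x1, x2) - 1e-12 & lon <= pmax(x1, x2) + 1e-12 &
      lat >= pmin(y1, y2) - 1e-12 & lat <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | on_seg
    crosses <- ((y1 > lat) != (y2 > lat)) &
      (lon < (x2 - x1) * (lat - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | on_edge
}

#' Assign each record to an analysis entity
#'
#' Sets each record's `entity` to the code of the first polygon (in file
#' order) containing its point; records outside all polygons get `NA` and
#' are excluded from entity-scoped analyses while remaining available for
#' study-area scoped ones. Points on a shared edge go to the first polygon
#' in file order. Overlapping polygons trigger a warning.
#'
#' @param rs A `record_set` with cleaned coordinates.
#' @param polygons An [read_entity_polygons()] result.
#' @return The `record_set` with `entity` filled in.
#' @export
assign_entities <- function(rs, polygons) {
  r <- rs$records
  if (nrow(r) == 0L) return(rs)
  hits <- matrix(FALSE, nrow(r), length(polygons))
  for (p in seq_along(polygons)) {
    inp <- rep(FALSE, nrow(r))
    for (ring in polygons[[p]]$rings) {
      inp <- inp | .point_in_ring(r$longitude, r$latitude, ring)
    }
    hits[, p] <- inp
  }
  n_hits <- rowSums(hits)
  if (any(n_hits > 1L)) {
    warning(sum(n_hits > 1L),
            " record(s) fall in overlapping polygons; first feature wins")
  }
  first <- apply(hits, 1L, function(h) which(h)[1])
  codes <- vapply(polygons, `[[`, character(1), "entity")
  rs$records$entity <- ifelse(n_hits > 0L, codes[first], NA_character_)
  rs
}

#' Write the cleaning report as JSON
#'
#' @param rs A `record_set` after curation.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_cleaning_report <- function(rs, path) {
  rep <- list(retained = nrow(rs$records),
              provenance = as.list(rs$provenance),
              cleaning_log = rs$cleaning_log)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
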