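# Synthetic occurrence generator with planted elevational zonation:
# known number of zones, break elevations, species pools and sampling
# intensity, so every pipeline stage can be checked against ground truth.

#' Define a planted zonation scenario
#'
#' Describes `K = length(zone_breaks) + 1` elevational zones over
#' `[origin, top]`, each with its own species pool. Species ranges are
#' placed inside their zone (midpoint uniform, breadth lognormal); with
#' probability `overlap_fraction` a species instead straddles a zone edge
#' (midpoint within one breadth of the edge, range not clipped to the
#' zone), which blurs the planted breaks. Per-species record counts are
#' Poisson (minimum 1), record elevations uniform within the true range
#' plus Gaussian noise, coordinates uniform in `bbox`. Genera and
#' families are nested in zones (blocks) so family-level summaries have
#' structure.
#'
#' The defaults encode the reference study conditions used throughout the
#' package's validation: three zones split at 2,600 and 4,000 m over a
#' 200-4,600 m frame, 25 species per zone, lambda = 5 records per
#' species, no range overlap and no elevation noise. The default breadth
#' distribution (median twice the gradient extent, small dispersion) is
#' deliberately wider than any zone, so after clipping each non-straddling
#' species occupies its whole zone: zone membership, not within-zone
#' position, is the planted compositional signal. Narrower breadths are
#' for sensitivity analyses and give gradient-like within-zone turnover.
#'
#' @param zone_breaks Strictly ascending break elevations (m), inside
#'   `(origin, top)`.
#' @param origin,top Elevation frame limits (m asl).
#' @param species_per_zone Species pool size per zone (scalar or
#'   length-K vector).
#' @param overlap_fraction Fraction of species straddling a zone edge.
#' @param range_breadth_meanlog,range_breadth_sdlog Lognormal parameters
#'   of range breadth (m).
#' @param records_per_species_lambda Poisson mean record count.
#' @param elevation_noise_sd Gaussian noise on record elevations (m).
#' @param bbox Numeric `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param genera_per_zone Genera per zone block.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `zonation_scenario` object.
#' @export
zonation_scenario <- function(zone_breaks = c(2600, 4000),
                              origin = 200, top = 4600,
                              species_per_zone = 25,
                              overlap_fraction = 0,
                              range_breadth_meanlog = log(2 * (top - origin)),
                              range_breadth_sdlog = 0.2,
                              records_per_species_lambda = 5,
                              elevation_noise_sd = 0,
                              bbox = c(-78, -72, 0, 8),
                              genera_per_zone = 5,
                              seed = 1L) {
  stopifnot(all(diff(zone_breaks) > 0),
            all(zone_breaks > origin), all(zone_breaks < top),
            overlap_fraction >= 0, overlap_fraction <= 1,
            all(species_per_zone >= 1), records_per_species_lambda > 0)
  K <- length(zone_breaks) + 1L
  if (length(species_per_zone) == 1L) {
    species_per_zone <- rep(species_per_zone, K)
  }
  stopifnot(length(species_per_zone) == K)
  edges <- c(origin, zone_breaks, top)
  if (any(diff(edges) <= 0)) stop("zone with zero achievable range")
  structure(list(zone_breaks = zone_breaks, origin = origin, top = top,
                 K = K, species_per_zone = as.integer(species_per_zone),
                 overlap_fraction = overlap_fraction,
                 range_breadth_meanlog = range_breadth_meanlog,
                 range_breadth_sdlog = range_breadth_sdlog,
                 records_per_species_lambda = records_per_species_lambda,
                 elevation_noise_sd = elevation_noise_sd,
                 bbox = bbox, genera_per_zone = as.integer(genera_per_zone),
                 seed = as.integer(seed)),
            class = "zonation_scenario")
}

#' Generate occurrence records with planted zonation
#'
#' @param scenario A [zonation_scenario()].
#' @return List with `records` (a [record_set()]) and `truth`, the
#'   generator's own ledger: per-species table (`species`, `genus`,
#'   `family`, `zone`, `true_min`, `true_max`, `obs_min`, `obs_max`,
#'   `n_records` — observed limits recomputed from the emitted records,
#'   independent of the pipeline), plus `K`, `zone_breaks` and the full
#'   per-record elevation ledger.
#' @export
generate_records <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  edges <- c(sc$origin, sc$zone_breaks, sc$top)
  sp_rows <- list()
  rec_rows <- list()
  sp_id <- 0L
  for (z in seq_len(sc$K)) {
    zlo <- edges[z]; zhi <- edges[z + 1L]
    for (s in seq_len(sc$species_per_zone[z])) {
      sp_id <- sp_id + 1L
      gid <- ((s - 1L) %% sc$genera_per_zone) + 1L
      genus <- sprintf("Genus_z%d_%02d", z, gid)
      species <- sprintf("%s sp%03d", genus, sp_id)
      family <- sprintf("Family_z%d", z)
      breadth <- stats::rlnorm(1, sc$range_breadth_meanlog,
                               sc$range_breadth_sdlog)
      straddles <- stats::runif(1) < sc$overlap_fraction && sc$K > 1L
      if (straddles) {
        # pick a zone edge (interior only) and centre the range near it
        cand <- c(if (z > 1L) zlo, if (z < sc$K) zhi)
        edge <- if (length(cand) == 1L) cand else sample(cand, 1L)
        mid <- stats::runif(1, edge - breadth, edge + breadth)
        mid <- min(max(mid, sc$origin), sc$top)  # keep range inside frame
        lo <- max(mid - breadth / 2, sc$origin)
        hi <- min(mid + breadth / 2, sc$top)
      } else {
        mid <- stats::runif(1, zlo, zhi)
        lo <- max(mid - breadth / 2, zlo)
        hi <- min(mid + breadth / 2, zhi)
      }
      n <- max(1L, stats::rpois(1, sc$records_per_species_lambda))
      elev <- stats::runif(n, lo, hi)
      if (sc$elevation_noise_sd > 0) {
        elev <- elev + stats::rnorm(n, 0, sc$elevation_noise_sd)
      }
      elev <- pmin(pmax(elev, sc$origin), sc$top)
      rec_rows[[sp_id]] <- data.frame(
        species = species, genus = genus, family = family,
        latitude = stats::runif(n, sc$bbox[3], sc$bbox[4]),
        longitude = stats::runif(n, sc$bbox[1], sc$bbox[2]),
        elevation = elev, source = "synthetic", entity = NA_character_,
        stringsAsFactors = FALSE)
      sp_rows[[sp_id]] <- data.frame(
        species = species, genus = genus, family = family, zone = z,
        true_min = lo, true_max = hi,
        obs_min = min(elev), obs_max = max(elev), n_records = n,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rec_rows)
  truth <- list(species = do.call(rbind, sp_rows), K = sc$K,
                zone_breaks = sc$zone_breaks,
                record_elevations = records$elevation,
                n_records = nrow(records), scenario = sc)
  list(records = record_set(records), truth = truth)
}

#' Inject cleaning defects into a record set
#'
#' Exercises the curation stages with known defects: exact duplicate rows
#' (appended), bogus-coordinate rows (appended copies placed at (0, 0) or
#' out of range), and in-place synonym renames of species (with the
#' matching synonym table returned so harmonization can undo them). Rates
#' are fractions of the input record count; all randomness from `seed`.
#'
#' @param rs A `record_set`.
#' @param dup_rate,bad_coord_rate,synonym_rate Rates in `[0, 1]`.
#' @param seed Integer seed.
#' @return List with `records` (degraded `record_set`) and `synonyms`
#'   (a [synonym_table()], possibly empty).
#' @export
degrade_records <- function(rs, dup_rate = 0, bad_coord_rate = 0,
                            synonym_rate = 0, seed = 1L) {
  stopifnot(dup_rate >= 0, dup_rate <= 1, bad_coord_rate >= 0,
            bad_coord_rate <= 1, synonym_rate >= 0, synonym_rate <= 1)
  set.seed(seed)
  r <- rs$records
  n <- nrow(r)
  syn <- data.frame(verbatim = character(0), species = character(0),
                    genus = character(0), family = character(0),
                    stringsAsFactors = FALSE)
  if (synonym_rate > 0) {
    n_syn <- round(synonym_rate * n)
    idx <- sample.int(n, n_syn)
    renamed <- unique(r$species[idx])
    syn <- data.frame(verbatim = paste0(renamed, " (syn)"),
                      species = renamed,
                      genus = r$genus[match(renamed, r$species)],
                      family = r$family[match(renamed, r$species)],
                      stringsAsFactors = FALSE)
    r$species[idx] <- paste0(r$species[idx], " (syn)")
  }
  extra <- list()
  if (dup_rate > 0) {
    n_dup <- round(dup_rate * n)
    extra$dup <- r[sample.int(n, n_dup, replace = TRUE), , drop = FALSE]
  }
  if (bad_coord_rate > 0) {
    n_bad <- round(bad_coord_rate * n)
    bad <- r[sample.int(n, n_bad, replace = TRUE), , drop = FALSE]
    kind <- sample(c("zero", "range"), n_bad, replace = TRUE)
    bad$latitude[kind == "zero"] <- 0
    bad$longitude[kind == "zero"] <- 0
    bad$latitude[kind == "range"] <- 95
    extra$bad <- bad
  }
  out <- rbind(r, do.call(rbind, extra))
  rownames(out) <- NULL
  list(records = record_set(out), synonyms = synonym_table(syn))
}
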