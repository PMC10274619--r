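# Spanned-range statistics for candidate altitudinal boundaries and
# comparison of detected cluster breaks with proposed limits.

#' Default altitudinal boundary proposals
#'
#' The four published lower/upper limits proposed for separating Andean
#' from lowland (or high-mountain) anurans: 500 m asl (Pefaur-Rivero),
#' 900 m asl (Lynch), 1,000 m asl (Duellman) and 3,000 m asl
#' (Navas-Lynch).
#'
#' @return Data frame with columns `name` and `elevation` (m asl).
#' @export
boundary_proposals <- function() {
  data.frame(name = c("Pefaur-Rivero", "Lynch", "Duellman", "Navas-Lynch"),
             elevation = c(500, 900, 1000, 3000),
             stringsAsFactors = FALSE)
}

#' Does an elevational range span a boundary?
#'
#' A range spans a candidate boundary when its minimum lies strictly
#' below and its maximum strictly above it; ranges touching the boundary
#' exactly do not span.
#'
#' @param min_elev,max_elev Numeric range limits (m asl), vectorized.
#' @param B Boundary elevation, m asl.
#' @return Logical vector.
#' @export
is_spanned <- function(min_elev, max_elev, B) {
  min_elev < B & max_elev > B
}

.union_ranges <- function(ranges, level) {
  grp <- ranges[[level]]
  data.frame(taxon = names(tapply(ranges$min_elev, grp, min)),
             min_elev = as.numeric(tapply(ranges$min_elev, grp, min)),
             max_elev = as.numeric(tapply(ranges$max_elev, grp, max)),
             stringsAsFactors = FALSE)
}

#' Spanned-range summary for boundary proposals
#'
#' For each proposal, the percentage of species, genera and families
#' whose elevational range spans the boundary. Genus and family ranges
#' are union ranges: minimum and maximum aggregated over member species
#' before the spanning test, so a genus can span a boundary even when no
#' single member species does.
#'
#' @param ranges A [species_ranges()] data frame (one row per species).
#' @param proposals Data frame with `name` and `elevation` columns;
#'   defaults to [boundary_proposals()].
#' @param scope Scope label carried into the output.
#' @return Data frame with one row per proposal: percentages and
#'   spanned/total counts at the three taxonomic levels.
#' @export
spanned_summary <- function(ranges, proposals = boundary_proposals(),
                            scope = "study-area") {
  if (nrow(ranges) == 0L) stop("spanned_summary: empty ranges")
  gen <- .union_ranges(ranges, "genus")
  fam <- .union_ranges(ranges, "family")
  out <- do.call(rbind, lapply(seq_len(nrow(proposals)), function(i) {
    B <- proposals$elevation[i]
    n_sp <- sum(is_spanned(ranges$min_elev, ranges$max_elev, B))
    n_ge <- sum(is_spanned(gen$min_elev, gen$max_elev, B))
    n_fa <- sum(is_spanned(fam$min_elev, fam$max_elev, B))
    data.frame(scope = scope, proposal = proposals$name[i], boundary = B,
               pct_species = 100 * n_sp / nrow(ranges),
               pct_genera = 100 * n_ge / nrow(gen),
               pct_families = 100 * n_fa / nrow(fam),
               n_species_spanned = n_sp, n_species = nrow(ranges),
               n_genera_spanned = n_ge, n_genera = nrow(gen),
               n_families_spanned = n_fa, n_families = nrow(fam),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare detected cluster breaks with proposed boundaries
#'
#' Orders the detected groups by mean band elevation and reports, for each
#' adjacent pair, the break elevation: the boundary between the lower
#' group's topmost band and the upper group's bottommost band. When the
#' two groups are separated by unoccupied bands the midpoint of the empty
#' interval is reported and flagged (`gap = TRUE`); when band memberships
#' interleave the break is flagged (`overlap = TRUE`) and taken as the
#' midpoint between the lower group's top edge and the upper group's
#' bottom edge. Each proposal is then scored by the distance (m) to its
#' nearest detected break.
#'
#' @param membership Named group vector (band label -> group id), e.g.
#'   from [cut_tree()].
#' @param proposals Data frame of `name`/`elevation` proposals.
#' @param grid The [band_grid()] the labels come from.
#' @return List with `breaks` (data frame of detected break elevations)
#'   and `proposals` (data frame with `nearest_break` and `distance_m`,
#'   `NA` when no breaks are detected).
#' @export
compare_breaks <- function(membership, proposals = boundary_proposals(),
                           grid = band_grid()) {
  bands <- as.numeric(names(membership))
  groups <- split(bands, membership)
  if (length(groups) < 2L) {
    brk <- data.frame(lower_group = character(0), upper_group = character(0),
                      break_elev = numeric(0), gap = logical(0),
                      overlap = logical(0))
    prop <- data.frame(proposals, nearest_break = NA_real_,
                       distance_m = NA_real_)
    return(list(breaks = brk, proposals = prop))
  }
  means <- vapply(groups, mean, numeric(1))
  ord <- order(means)
  groups <- groups[ord]
  brk <- do.call(rbind, lapply(seq_len(length(groups) - 1L), function(i) {
    lo <- groups[[i]]; hi <- groups[[i + 1L]]
    top_edge <- max(lo) + grid$width   # upper edge of lower group's top band
    bot_edge <- min(hi)                # lower edge of upper group's bottom band
    overlap <- max(lo) > min(hi)
    gap <- !overlap && bot_edge > top_edge
    data.frame(lower_group = names(groups)[i],
               upper_group = names(groups)[i + 1L],
               break_elev = (top_edge + bot_edge) / 2,
               gap = gap, overlap = overlap, stringsAsFactors = FALSE)
  }))
  rownames(brk) <- NULL
  nearest <- vapply(proposals$elevation, function(B) {
    brk$break_elev[which.min(abs(brk$break_elev - B))]
  }, numeric(1))
  prop <- data.frame(proposals, nearest_break = nearest,
                     distance_m = abs(proposals$elevation - nearest))
  list(breaks = brk, proposals = prop)
}

#' Spanned-percentage table across scopes
#'
#' Convenience wrapper building one [spanned_summary()] per scope and
#' laying the percentages out wide (rows = scopes, columns =
#' proposal x taxonomic level), mirroring the usual presentation of
#' boundary concordance results.
#'
#' @param rs A `record_set` with elevations assigned.
#' @param scopes Character vector of scopes (`"study-area"` and/or entity
#'   codes).
#' @param proposals Proposals data frame.
#' @return Wide data frame of percentages.
#' @export
spanned_table <- function(rs, scopes = "study-area",
                          proposals = boundary_proposals()) {
  rows <- lapply(scopes, function(sc) {
    rng <- species_ranges(rs, scope = sc)
    if (nrow(rng) == 0L) return(NULL)
    s <- spanned_summary(rng, proposals, scope = sc)
    wide <- data.frame(scope = sc, stringsAsFactors = FALSE)
    for (i in seq_len(nrow(s))) {
      wide[[paste0(s$proposal[i], "_species")]] <- s$pct_species[i]
      wide[[paste0(s$proposal[i], "_genera")]] <- s$pct_genera[i]
      wide[[paste0(s$proposal[i], "_families")]] <- s$pct_families[i]
    }
    wide
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
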