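# Independent oracles and small fixture builders shared across tests.

# set-arithmetic beta oracle: components from explicit species-name sets
beta_oracle <- function(x, y) {
  sx <- names(which(x == 1))
  sy <- names(which(y == 1))
  a <- length(intersect(sx, sy))
  b <- length(setdiff(sx, sy))
  cc <- length(setdiff(sy, sx))
  n <- a + b + cc
  list(a = a, b = b, c = cc,
       beta_cc = (b + cc) / n,
       beta_turn = 2 * min(b, cc) / n,
       beta_rich = abs(b - cc) / n)
}

# naive UPGMA oracle: recompute every average linkage from the original
# full matrix at each step (O(n^3) by brute force over member lists)
upgma_oracle_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# random binary band matrix with no empty rows/columns
random_band_occupancy <- function(n_bands, n_species, p = 0.4) {
  repeat {
    m <- matrix(rbinom(n_bands * n_species, 1, p), n_bands, n_species)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(seq(200, by = 200, length.out = n_bands),
                      paste0("sp", seq_len(n_species)))
  m
}

# build a record_set directly from species/elevation vectors
records_fixture <- function(species, elevation,
                            genus = sub(" .*", "", species),
                            family = "Famx",
                            latitude = 4.5, longitude = -75.5,
                            entity = NA_character_) {
  record_set(data.frame(species = species, genus = genus, family = family,
                        latitude = latitude, longitude = longitude,
                        elevation = elevation, source = "literature",
                        entity = entity, stringsAsFactors = FALSE))
}

# minimal GeoJSON writer for square entity polygons
write_square_polygons <- function(path, squares) {
  feats <- vapply(seq_along(squares), function(i) {
    s <- squares[[i]]  # list(entity, lon0, lon1, lat0, lat1)
    ring <- sprintf("[[%f,%f],[%f,%f],[%f,%f],[%f,%f],[%f,%f]]",
                    s$lon0, s$lat0, s$lon1, s$lat0, s$lon1, s$lat1,
                    s$lon0, s$lat1, s$lon0, s$lat0)
    sprintf(paste0('{"type":"Feature","properties":{"entity":"%s"},',
                   '"geometry":{"type":"Polygon","coordinates":[%s]}}'),
            s$entity, ring)
  }, character(1))
  writeLines(sprintf('{"type":"FeatureCollection","features":[%s]}',
                     paste(feats, collapse = ",")), path)
  path
}
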