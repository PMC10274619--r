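test_that("band_of follows the half-open lower-edge convention", {
  g <- band_grid()
  expect_equal(band_of(350, g), 200)
  expect_equal(band_of(400, g), 400)   # lower edge belongs to its own band
  expect_equal(band_of(4401, g), 4400)
  expect_equal(band_of(c(200, 399.99, 4599), g), c(200, 200, 4400))
  expect_error(band_of(150, g), "below grid origin")
  expect_error(band_grid(width = 0))
})

test_that("DEM sampling is nearest-cell with missing outside extent", {
  asc <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 3", "nrows 2", "xllcorner -76", "yllcorner 4",
               "cellsize 1", "nodata_value -9999",
               "10 20 30",
               "40 50 -9999"), asc)
  dem <- read_ascii_grid(asc)
  # northernmost row first: cell (-74.5, 4.5) is bottom row, middle col
  expect_equal(dem_extract(dem, -74.5, 4.5), 50)
  expect_equal(dem_extract(dem, -74.5, 5.5), 20)
  expect_equal(dem_extract(dem, -75.5, 4.5), 40)
  expect_true(is.na(dem_extract(dem, -80, 4.5)))   # outside extent
  expect_true(is.na(dem_extract(dem, -73.5, 4.5))) # nodata cell

  # constant raster: every record gets the constant
  asc2 <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner -80", "yllcorner 0",
               "cellsize 10", "nodata_value -9999",
               "1500 1500", "1500 1500"), asc2)
  rs <- records_fixture(paste("Sp", 1:3), elevation = c(1, 2, 3),
                        latitude = c(2, 8, 5), longitude = c(-75, -72, -78))
  out <- assign_elevation(rs, read_ascii_grid(asc2))
  expect_equal(out$records$elevation, rep(1500, 3))  # DEM overrides records
})

test_that("assign_elevation without a DEM passes record elevations through", {
  rs <- records_fixture(c("Sp a", "Sp b"), elevation = c(730, NA))
  out <- assign_elevation(rs, dem = NULL)
  expect_equal(out$records$elevation, c(730, NA))
  expect_equal(out$cleaning_log$elevation_missing, 1L)
})

test_that("species_ranges computes scoped min/max and counts", {
  rs <- records_fixture(c("Sp a", "Sp a", "Sp a", "Sp b", "Sp b"),
                        elevation = c(300, 900, 2100, 500, 500),
                        entity = c("E1", "E1", "E2", "E1", "E2"))
  rng <- species_ranges(rs)
  expect_equal(rng$min_elev[rng$species == "Sp a"], 300)
  expect_equal(rng$max_elev[rng$species == "Sp a"], 2100)
  expect_equal(rng$n_records[rng$species == "Sp a"], 3L)
  expect_equal(rng$min_elev[rng$species == "Sp b"],
               rng$max_elev[rng$species == "Sp b"])  # single-valued range
  # entity scoping is independent
  e1 <- species_ranges(rs, "E1")
  expect_equal(e1$max_elev[e1$species == "Sp a"], 900)
  expect_equal(nrow(species_ranges(rs, "nowhere")), 0L)
})

test_that("band matrix occupancy modes follow record vs range logic", {
  rs <- records_fixture(c("Sp a", "Sp a"), elevation = c(350, 790))
  rec <- build_band_matrix(rs, mode = "records")
  expect_equal(rec$bands, c(200, 600))    # band 400 unoccupied, dropped
  fill <- build_band_matrix(rs, mode = "range_fill")
  expect_equal(fill$bands, c(200, 400, 600))
  expect_true(all(fill$occupancy == 1))
  expect_error(build_band_matrix(rs, scope = "E9"), "empty scope")
})

test_that("range_fill occupancy is a superset of records occupancy", {
  set.seed(42)
  g <- generate_records(zonation_scenario(seed = 42))
  rec <- build_band_matrix(g$records, mode = "records")
  fill <- build_band_matrix(g$records, mode = "range_fill")
  shared_sp <- colnames(rec$occupancy)
  for (b in rownames(rec$occupancy)) {
    occupied <- shared_sp[rec$occupancy[b, ] == 1]
    expect_true(all(fill$occupancy[b, occupied] == 1))
  }
  # band edges recompute from ranges
  rng <- species_ranges(g$records)
  expect_equal(unname(apply(rec$occupancy, 2, function(col)
    min(as.numeric(rownames(rec$occupancy))[col == 1]))),
    unname(band_of(rng$min_elev[match(colnames(rec$occupancy),
                                      rng$species)])))
})

test_that("dropping empty bands leaves pairwise dissimilarities unchanged", {
  occ <- random_band_occupancy(6, 15)
  bm1 <- beta_matrix(occ)
  # insert an empty band, then drop it again as build_band_matrix would
  occ2 <- rbind(occ[1:3, ], "9999" = 0L, occ[4:6, ])
  occ2 <- occ2[rowSums(occ2) > 0, ]
  bm2 <- beta_matrix(occ2)
  expect_equal(bm2$D, bm1$D)
})

test_that("band matrix matches the generator's bookkeeping", {
  g <- generate_records(zonation_scenario(seed = 5))
  M <- build_band_matrix(g$records)
  expect_equal(ncol(M$occupancy), nrow(g$truth$species))
  # every species' occupied bands sit inside its true range's bands
  grid <- band_grid()
  for (sp in colnames(M$occupancy)) {
    occupied <- as.numeric(rownames(M$occupancy))[M$occupancy[, sp] == 1]
    tr <- g$truth$species[g$truth$species$species == sp, ]
    expect_true(all(occupied >= band_of(tr$true_min, grid)))
    expect_true(all(occupied <= band_of(tr$true_max, grid)))
  }
})
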