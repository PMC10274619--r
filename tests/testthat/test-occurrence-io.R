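test_that("read_records parses delimited text and logs coercion failures", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "scientificName,genus,family,decimalLatitude,decimalLongitude,elevation,source",
    "Pristimantis uno,Pristimantis,Craugastoridae,4.5,-75.6,1200,literature",
    "Pristimantis dos,Pristimantis,Craugastoridae,5.1,-74.2,800,aggregator",
    "Hyloscirtus tres,Hyloscirtus,Hylidae,2.2,-76.9,2500,literature",
    "Atelopus cuatro,Atelopus,Bufonidae,6.0,-73.0,3100,aggregator",
    "Rheobates cinco,Rheobates,Aromobatidae,5.5,-74.9,450,literature"
  ), path)
  rs <- read_records(path)
  expect_s3_class(rs, "record_set")
  expect_equal(n_records(rs), 5L)
  expect_equal(sum(rs$provenance), 5L)
  expect_equal(rs$records$elevation[1], 1200)

  # a row failing numeric coercion is dropped, not fatal
  writeLines(c(
    "scientificName,genus,family,decimalLatitude,decimalLongitude,elevation,source",
    "Pristimantis uno,Pristimantis,Craugastoridae,abc,-75.6,1200,literature",
    "Pristimantis dos,Pristimantis,Craugastoridae,5.1,-74.2,800,aggregator"
  ), path)
  rs <- read_records(path)
  expect_equal(n_records(rs), 1L)
  expect_equal(rs$cleaning_log$coercion, 1L)

  # header-only file gives an empty record set, no error
  writeLines("scientificName,decimalLatitude,decimalLongitude", path)
  expect_equal(n_records(read_records(path)), 0L)
})

test_that("read_records enforces mandatory columns and supports column maps", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sp,lat", "X y,4.5"), path)
  expect_error(read_records(path), "scientificName")
  expect_error(read_records(path, column_map = c(species = "sp",
                                                 latitude = "lat")),
               "decimalLongitude")
  expect_error(read_records("/nonexistent/file.csv"), "no such file")

  writeLines(c("sp\tlat\tlon", "Aa bb\t4.5\t-75.0"), path)
  rs <- read_records(path, column_map = c(species = "sp", latitude = "lat",
                                          longitude = "lon"))
  expect_equal(rs$records$species, "Aa bb")
  expect_equal(rs$records$longitude, -75.0)
})

test_that("clean_coordinates applies the stated removal rules", {
  rs <- records_fixture(paste("Sp", 1:5), elevation = 1000,
                        latitude = c(0, 4.5, 95.0, -3.25, 4.4),
                        longitude = c(0, -75.6, -75.0, -3.25, -70.1))
  # (0,0), out-of-range latitude, and lat == lon (row 4) are removed
  out <- clean_coordinates(rs)
  expect_equal(out$records$latitude, c(4.5, 4.4))
  expect_equal(out$cleaning_log$coord_zero_zero, 1L)
  expect_equal(out$cleaning_log$coord_out_of_range, 1L)
  expect_equal(out$cleaning_log$coord_lat_eq_lon, 1L)
  # conservation: removals + retained == input
  expect_equal(sum(unlist(out$cleaning_log)) + n_records(out), n_records(rs))
  # idempotence
  again <- clean_coordinates(out)
  expect_equal(again$records, out$records)
})

test_that("harmonize_taxonomy maps synonyms and counts unmatched names", {
  rs <- records_fixture(c("Eleutherodactylus w-nigrum", "Pristimantis dos"),
                        elevation = c(900, 1000))
  syn <- synonym_table(data.frame(
    verbatim = "Eleutherodactylus w-nigrum",
    species = "Pristimantis w-nigrum", genus = "Pristimantis",
    family = "Craugastoridae", stringsAsFactors = FALSE))
  out <- harmonize_taxonomy(rs, syn)
  expect_equal(out$records$species,
               c("Pristimantis w-nigrum", "Pristimantis dos"))
  expect_equal(out$records$genus[1], "Pristimantis")
  expect_equal(out$records$family[1], "Craugastoridae")
  expect_equal(out$cleaning_log$unmatched_names, 1L)
  expect_equal(n_records(out), n_records(rs))

  # empty synonym table is the identity
  empty <- synonym_table(data.frame(verbatim = character(0),
                                    species = character(0),
                                    genus = character(0),
                                    family = character(0)))
  expect_equal(harmonize_taxonomy(rs, empty)$records, rs$records)

  # a verbatim name mapping to two targets is rejected
  expect_error(synonym_table(data.frame(
    verbatim = c("A b", "A b"), species = c("C d", "E f"),
    genus = "G", family = "H")), "more than one")
})

test_that("deduplicate keeps one record per species-locality key", {
  rs <- records_fixture(c("Sp a", "Sp a", "Sp a", "Sp b"),
                        elevation = c(100, 200, 300, 400),
                        latitude = c(4.50001, 4.50001, 4.50002, 4.50001),
                        longitude = -75.5)
  out <- deduplicate(rs, coord_decimals = 4L)
  # rows 1-2 share a 4-decimal key; row 3 differs in the 5th decimal only
  # and rounds to the same key; two species at one locality both survive
  expect_equal(n_records(out), 2L)
  expect_equal(out$records$elevation, c(100, 400))  # first kept
  expect_equal(out$cleaning_log$duplicates, 2L)
  # coarser rounding merges more
  expect_equal(n_records(deduplicate(rs, 1L)), 2L)
  # idempotent, never increases
  expect_equal(deduplicate(out, 4L)$records, out$records)
})

test_that("entity assignment uses polygon containment with file-order ties", {
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_square_polygons(gj, list(
    list(entity = "CCW", lon0 = -76, lon1 = -75, lat0 = 4, lat1 = 5),
    list(entity = "CCE", lon0 = -75, lon1 = -74, lat0 = 4, lat1 = 5)))
  polys <- read_entity_polygons(gj)
  rs <- records_fixture(paste("Sp", 1:3), elevation = 1000,
                        latitude = c(4.5, 4.5, 4.5),
                        longitude = c(-75.5, -74.5, -80.0))
  out <- assign_entities(rs, polys)
  expect_equal(out$records$entity, c("CCW", "CCE", NA))

  # point exactly on the shared edge is inside both squares (boundary
  # counts as inside) and goes to the first polygon in file order
  edge <- suppressWarnings(
    assign_entities(records_fixture("Sp e", 1000, latitude = 4.5,
                                    longitude = -75.0), polys))
  expect_equal(edge$records$entity, "CCW")

  # record order does not change assignments
  perm <- sample(3)
  rs2 <- rs; rs2$records <- rs$records[perm, ]
  out2 <- assign_entities(rs2, polys)
  expect_equal(out2$records$entity, out$records$entity[perm])
})

test_that("overlapping polygons warn and first feature wins", {
  gj <- withr::local_tempfile(fileext = ".geojson")
  write_square_polygons(gj, list(
    list(entity = "A", lon0 = -76, lon1 = -74, lat0 = 4, lat1 = 5),
    list(entity = "B", lon0 = -75.5, lon1 = -74, lat0 = 4, lat1 = 5)))
  polys <- read_entity_polygons(gj)
  rs <- records_fixture("Sp o", 1000, latitude = 4.5, longitude = -75.2)
  expect_warning(out <- assign_entities(rs, polys), "overlap")
  expect_equal(out$records$entity, "A")
})

test_that("records round-trip through write_records", {
  rs <- records_fixture(c("Sp a", "Sp b"), elevation = c(350, 2100),
                        latitude = c(4.5, 5.0), longitude = c(-75.5, -74.0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(rs, path)
  back <- read_records(path)
  expect_equal(back$records$species, rs$records$species)
  expect_equal(back$records$elevation, rs$records$elevation)
})
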