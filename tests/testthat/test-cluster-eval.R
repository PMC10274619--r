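test_that("within_dispersion matches hand arithmetic and brute force", {
  D <- matrix(c(0, 0.6, 0.6, 0), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(within_dispersion(D, c(a = 1, b = 2)), 0)   # singletons
  expect_equal(within_dispersion(D, c(a = 1, b = 1)), 0.3) # (1/4)*(2*0.6)

  set.seed(9)
  occ <- random_band_occupancy(8, 20)
  bm <- beta_matrix(occ)
  memb <- setNames(sample(1:3, 8, replace = TRUE), rownames(occ))
  # brute-force double loop
  W <- 0
  for (g in unique(memb)) {
    idx <- names(memb)[memb == g]
    for (i in idx) for (j in idx) W <- W + bm$D[i, j] / (2 * length(idx))
  }
  expect_equal(within_dispersion(bm, memb), W)
  expect_error(within_dispersion(bm, memb[-1]), "cover")
})

test_that("W_k is non-increasing along nested cuts of one tree", {
  set.seed(14)
  occ <- random_band_occupancy(10, 25)
  bm <- beta_matrix(occ)
  t <- upgma_tree(bm)
  W <- vapply(1:9, function(k) within_dispersion(bm, cut_tree(t, k)),
              numeric(1))
  expect_true(all(diff(W) <= 1e-12))
})

test_that("gap curve has the documented structure and is reproducible", {
  g <- generate_records(zonation_scenario(seed = 3))
  M <- build_band_matrix(g$records)
  r1 <- gap_select_k(M, k_max = 5, B_ref = 30, seed = 42)
  expect_length(r1$gap, 5)
  expect_true(all(r1$s_k > 0))
  expect_true(r1$k_selected >= 1 && r1$k_selected <= 5)
  r2 <- gap_select_k(M, k_max = 5, B_ref = 30, seed = 42)
  expect_identical(r1$gap, r2$gap)
  expect_identical(r1$k_selected, r2$k_selected)
  expect_error(gap_select_k(M, k_max = 50, B_ref = 10), "k_max")
})

test_that("gap detects a planted two-zone split and rejects pure noise", {
  # two perfectly disjoint species pools across one elevational break
  g <- generate_records(zonation_scenario(zone_breaks = 2600,
                                          species_per_zone = 30, seed = 8))
  M <- build_band_matrix(g$records)
  r <- gap_select_k(M, k_max = 6, B_ref = 100, seed = 8)
  expect_equal(r$k_selected, 2L)
  grp <- cut_tree(upgma_tree(beta_matrix(M)), 2)
  bands <- as.numeric(names(grp))
  expect_true(all(grp[bands < 2600] == grp[["200"]]))
  expect_true(all(grp[bands >= 2600] != grp[["200"]]))

  # structureless Bernoulli occupancy: modal selection is k = 1
  sels <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    occ <- matrix(rbinom(20 * 40, 1, 0.35), 20, 40,
                  dimnames = list(seq(200, by = 200, length.out = 20),
                                  paste0("sp", 1:40)))
    occ[rowSums(occ) == 0, 1] <- 1L
    occ[1, colSums(occ) == 0] <- 1L
    M0 <- structure(list(scope = "noise", grid = band_grid(),
                         mode = "records",
                         bands = as.numeric(rownames(occ)),
                         occupancy = occ), class = "band_matrix")
    gap_select_k(M0, k_max = 6, B_ref = 60, seed = s)$k_selected
  }, integer(1))
  expect_equal(as.integer(names(which.max(table(sels)))), 1L)
})

test_that("bootstrap support is exact for k = 1 and high for disjoint pools", {
  g <- generate_records(zonation_scenario(seed = 21))
  M <- build_band_matrix(g$records)
  t <- upgma_tree(beta_matrix(M))

  s1 <- bootstrap_support(M, t, k = 1, B_boot = 10, seed = 1)
  expect_identical(unname(s1$J_b), 1)

  s3 <- bootstrap_support(M, t, k = 3, B_boot = 300, seed = 1)
  expect_length(s3$J_b, 3)
  expect_true(all(s3$J_b >= 0.95))  # disjoint zone pools are stable
  expect_true(all(s3$J_b <= 1))

  # reproducibility
  s3b <- bootstrap_support(M, t, k = 3, B_boot = 300, seed = 1)
  expect_identical(s3$J_b, s3b$J_b)
})

test_that("bootstrap support is seed-stable at moderate replicate counts", {
  g <- generate_records(zonation_scenario(overlap_fraction = 0.3, seed = 5))
  M <- build_band_matrix(g$records)
  t <- upgma_tree(beta_matrix(M))
  a <- bootstrap_support(M, t, k = 3, B_boot = 2000, seed = 1)$J_b
  b <- bootstrap_support(M, t, k = 3, B_boot = 2000, seed = 2)$J_b
  expect_true(all(abs(a - b) <= 0.05))
})

test_that("J_b degrades as planted zone overlap increases", {
  mean_jb <- vapply(c(0, 0.5, 1), function(ov) {
    g <- generate_records(zonation_scenario(overlap_fraction = ov,
                                            seed = 17))
    M <- build_band_matrix(g$records)
    t <- upgma_tree(beta_matrix(M))
    mean(bootstrap_support(M, t, k = 3, B_boot = 250, seed = 17)$J_b)
  }, numeric(1))
  expect_true(all(diff(mean_jb) < 0))
})
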