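test_that("rhombic dodecahedron boxes have the analytic volume and image distance", {
  b <- make_box(0.6, 0.2)  # image distance d = 1
  expect_equal(b$volume, sqrt(2) / 2, tolerance = 1e-12)
  expect_identical(b$type, "rhombic_dodecahedron")
  expect_equal(b$vectors[3, ], c(0.5, 0.5, sqrt(2) / 2))

  big <- make_box(400, 25)
  expect_gte(big$image_distance, 450)
  # strictly smaller than the bounding cube
  expect_lt(big$volume, big$image_distance^3)
  expect_error(simulation_box(matrix(0, 3, 3)),
               class = "minicell_validation_error")
})

test_that("water tiling hits the target density and respects min_dist", {
  box <- simulation_box(diag(c(10, 10, 10)), "cubic")
  tw <- tile_water(box, density = 8.33)
  # within one lattice layer of density x volume
  layer <- 3 * ceiling(10 / tw$spacing)^2
  expect_lt(abs(nrow(tw$coords) - 8.33 * 1000), layer)

  solute <- matrix(c(5, 5, 5), 1)
  tw2 <- tile_water(box, solute, density = 8.33, min_dist = 0.5)
  expect_gte(brute_min_dist(tw2$coords, solute), 0.5)
  # removed count is exactly those within min_dist
  expect_identical(nrow(tw$coords) - nrow(tw2$coords),
                   sum(sqrt(rowSums(sweep(tw$coords, 2, c(5, 5, 5))^2)) <
                         0.5))

  tw3 <- tile_water(box, density = 8.33, inside_radius = 3)
  expect_identical(tw3$n_inside + tw3$n_outside, nrow(tw3$coords))
  expect_gt(tw3$n_inside, 0L)
})

test_that("water count scales linearly with box volume at fixed density", {
  counts <- vapply(c(6, 12, 24), function(edge) {
    nrow(tile_water(simulation_box(diag(rep(edge, 3)), "cubic"),
                    density = 8.33)$coords)
  }, 1L)
  vols <- c(6, 12, 24)^3
  dens <- counts / vols
  expect_lt(max(abs(dens - 8.33)) / 8.33, 0.05)
})

test_that("ionization neutralizes exactly and realizes the molarity", {
  box <- simulation_box(diag(c(30, 30, 30)), "cubic")
  w <- tile_water(box, density = 8.33)$coords
  none <- ionize(0L, w, molarity = 0, seed = 1)
  expect_identical(none$n_sodium, 0L)
  expect_identical(none$n_chloride, 0L)

  # full-cell neutralization arithmetic: a net charge of -3.2 million
  # elementary charges demands a sodium excess of exactly 3.2 million
  set.seed(6)
  w_big <- matrix(runif(3 * 3.3e6, 0, 100), ncol = 3)
  big <- ionize(-3200000L, w_big, molarity = 0, seed = 5)
  expect_identical(big$n_sodium - big$n_chloride, 3200000L)
  rm(w_big, big)

  salted <- ionize(-50L, w, charged_sites = w[1:20, , drop = FALSE],
                   molarity = 0.135, seed = 2)
  expect_identical(salted$n_sodium - salted$n_chloride, 50L)
  # molarity round trip from the returned counts: within one pair
  n_pair2 <- salted$n_chloride
  recovered <- 55.5 * n_pair2 / (4 * nrow(w))
  one_pair <- 55.5 / (4 * nrow(w))
  expect_lt(abs(recovered - 0.135), one_pair)
  expect_equal(salted$realized_molarity, recovered)

  # sites consumed exactly once: ions and remaining waters are disjoint
  all_out <- rbind(salted$sodium, salted$chloride, salted$waters)
  expect_identical(nrow(all_out), nrow(w))
  expect_identical(nrow(unique(all_out)), nrow(w))

  expect_error(ionize(0L, w[1:10, , drop = FALSE], molarity = 10, seed = 1),
               class = "minicell_insufficient_solvent_error")
})

test_that("counterions convert the waters nearest to charged sites", {
  box <- simulation_box(diag(c(12, 12, 12)), "cubic")
  w <- tile_water(box, density = 8.33)$coords
  site <- matrix(c(6, 6, 6), 1)
  out <- ionize(-30L, w, charged_sites = site, molarity = 0, seed = 3)
  expect_identical(out$n_sodium, 30L)
  # every converted sodium is within the near cutoff of the charged site
  d <- sqrt(rowSums(sweep(out$sodium, 2, c(6, 6, 6))^2))
  expect_lte(max(d), 1.5)
  # and they are exactly the 30 nearest waters
  d_all <- sort(sqrt(rowSums(sweep(w, 2, c(6, 6, 6))^2)))
  expect_lte(max(d), d_all[31] + 1e-12)
})

test_that("electroneutrality is an exact integer identity across charges", {
  box <- simulation_box(diag(c(8, 8, 8)), "cubic")
  w <- tile_water(box, density = 8.33)$coords
  for (q in c(-137L, -1L, 0L, 1L, 42L)) {
    sp <- ionize(q, w, molarity = 0.05, seed = 4)
    expect_identical(q + sp$n_sodium - sp$n_chloride, 0L)
  }
})
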