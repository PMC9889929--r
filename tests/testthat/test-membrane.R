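test_that("icospheres have sphere topology, exact radii and the right area", {
  s0 <- icosphere(1, 0)
  expect_identical(nrow(s0$vertices), 12L)
  expect_identical(nrow(s0$faces), 20L)
  expect_identical(euler_characteristic(s0), 2L)

  s4 <- icosphere(100, 4)
  expect_identical(euler_characteristic(s4), 2L)
  expect_lt(abs(s4$area - 4 * pi * 100^2) / (4 * pi * 100^2), 0.01)
  expect_lt(max(abs(sqrt(rowSums(s4$vertices^2)) - 100)), 1e-9)
  # outward normals: positive radial component everywhere
  expect_true(all(rowSums(s4$normals * s4$vertices) > 0))
})

test_that("OFF surfaces round-trip", {
  s <- icosphere(5, 1)
  path <- tmpfile(".off")
  write_off(s, path)
  back <- read_off(path)
  expect_equal(back$vertices, s$vertices, tolerance = 1e-5,
               ignore_attr = TRUE)
  expect_identical(back$faces, s$faces)
})

test_that("leaflet counts follow the offset-surface areas", {
  comp <- lipid_composition("CHOL", 1, area_per_lipid = 0.6, thickness = 4)
  s <- icosphere(200, 3)
  lc <- leaflet_counts(s, comp)
  expect_equal(lc$n_outer / lc$n_inner, (202 / 198)^2, tolerance = 1e-3)

  comp0 <- lipid_composition("CHOL", 1, area_per_lipid = 0.6,
                             thickness = 1e-9)
  lc0 <- leaflet_counts(s, comp0)
  expect_identical(lc0$n_outer, lc0$n_inner)

  # flat limit: ratio -> 1
  sflat <- icosphere(1e6, 2)
  lcf <- leaflet_counts(sflat, comp)
  expect_lt(abs(lcf$area_outer / lcf$area_inner - 1), 1e-5)

  expect_error(
    leaflet_counts(icosphere(1.5, 2),
                   lipid_composition("CHOL", 1, thickness = 4)),
    class = "minicell_geometry_error")

  # the outer/inner ratio shrinks monotonically with radius
  ratios <- vapply(c(50, 100, 200, 400), function(r) {
    lc <- leaflet_counts(icosphere(r, 2), comp)
    lc$area_outer / lc$area_inner
  }, 1)
  expect_true(all(diff(ratios) < 0))
  expect_true(all(ratios > 1))
})

test_that("largest-remainder allocation is exact and conservative", {
  expect_identical(allocate_species(1000, c(0.59, 0.18, 0.17, 0.04, 0.02)),
                   c(590L, 180L, 170L, 40L, 20L))
  expect_identical(allocate_species(7, 1), 7L)
  set.seed(10)
  for (i in 1:25) {
    f <- runif(sample(2:6, 1))
    f <- f / sum(f)
    n <- sample(1:500, 1)
    counts <- allocate_species(n, f)
    expect_identical(sum(counts), as.integer(n))
    expect_true(all(abs(counts - n * f) < 1))
  }
})

test_that("vesicle membranes realize the requested composition", {
  comp <- syn3a_lipid_composition()
  mem <- build_membrane(icosphere(30, 4), comp, seed = 2)
  frac <- mean(mem$lipids$species == "CHOL")
  expect_lt(abs(frac - 0.59), 0.01)
  n_tot <- nrow(mem$lipids)
  for (i in seq_along(comp$species)) {
    realized <- mean(mem$lipids$species == comp$species[i])
    expect_lt(abs(realized - comp$fractions[i]), 1 / n_tot + 0.01)
  }
})

test_that("single-species vesicles carry exactly the leaflet counts", {
  comp <- lipid_composition("CHOL", 1, area_per_lipid = 2, thickness = 4)
  surf <- icosphere(15, 3)
  lc <- leaflet_counts(surf, comp)
  mem <- build_membrane(surf, comp, seed = 4)
  expect_identical(nrow(mem$lipids), lc$n_outer + lc$n_inner)
  expect_identical(sum(mem$lipids$leaflet == "outer"), lc$n_outer)
})

test_that("lipid spacing and protein footprints hold on a 30-nm vesicle", {
  comp <- lipid_composition(c("PC", "PG"), c(0.8, 0.2), area_per_lipid = 1.2,
                            thickness = 4)
  prot <- list(list(model = toy_protein(16, 1.4, seed = 3, name = "TMX"),
                    species_id = "TMX", copies = 6L))
  surf <- icosphere(15, 3)
  mem <- build_membrane(surf, comp, prot, seed = 9)
  # exhaustive pairwise head-head spacing check per leaflet
  min_spacing <- 0.7 * sqrt(1.2)
  for (lf in c("outer", "inner")) {
    h <- as.matrix(mem$lipids[mem$lipids$leaflet == lf, c("x", "y", "z")])
    d <- as.matrix(dist(h))
    diag(d) <- Inf
    expect_gte(min(d), min_spacing)
  }
  # no lipid head inside any protein footprint cylinder (lateral distance)
  heads <- as.matrix(mem$lipids[c("x", "y", "z")])
  for (k in seq_len(nrow(mem$proteins))) {
    ctr <- as.numeric(mem$proteins[k, c("x", "y", "z")])
    nrm <- ctr / sqrt(sum(ctr^2))
    d <- sweep(heads, 2, ctr)
    along <- d %*% nrm
    lat <- sqrt(pmax(rowSums(d^2) - along^2, 0))
    expect_gte(min(lat), prot[[1]]$model$bounding_radius + 0.5 - 1e-9)
  }
  # membrane protein beads stay near the mid-surface
  pb <- attr(mem$proteins, "beads")
  expect_lt(max(abs(sqrt(rowSums(pb^2)) - 15)), 1.4 + 0.5)
})

test_that("impossible compositions and crowded surfaces raise errors", {
  expect_error(lipid_composition(c("A", "B"), c(0.6, 0.5)),
               class = "minicell_composition_error")
  # protein footprints larger than the surface cannot fit
  prot <- list(list(model = toy_protein(30, 9, seed = 1), species_id = "BIG",
                    copies = 30L))
  expect_error(
    build_membrane(icosphere(10, 2),
                   lipid_composition("CHOL", 1, area_per_lipid = 2),
                   prot, seed = 1),
    class = "minicell_surface_full_error")
})
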