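toy_bodies <- function(n_species = 4, copies = 50, seed = 1) {
  lapply(seq_len(n_species), function(i) {
    list(model = toy_protein(12, 1.2, charge = -i, seed = seed + i,
                             name = sprintf("S%02d", i)),
         species_id = sprintf("S%02d", i), copies = copies)
  })
}

test_that("single bodies land inside the region with a valid quaternion", {
  b <- list(list(model = toy_protein(5, 1, seed = 1), species_id = "A",
                 copies = 1L))
  pl <- pack(b, pack_region("sphere", radius = 10), seed = 3)
  expect_identical(nrow(pl), 1L)
  expect_lt(sqrt(sum(pl[1, c("x", "y", "z")]^2)), 10)
  expect_equal(sum(pl[1, c("qw", "qx", "qy", "qz")]^2), 1, tolerance = 1e-9)
})

test_that("packing beyond the sphere-packing bound raises a packing error", {
  # 60 unit-diameter spheres cannot reach > 74% of a radius-2 ball
  b <- list(list(model = toy_protein(1, 0, seed = 1), species_id = "A",
                 copies = 60L))
  err <- tryCatch(
    pack(b, pack_region("sphere", radius = 2), seed = 1, threshold = 1,
         max_trials_per_copy = 400L),
    error = function(e) e)
  expect_s3_class(err, "minicell_packing_error")
  expect_lt(err$volume_fraction, 0.74)
})

test_that("dense packings contain no cross-body contacts (O(N^2) oracle)", {
  bodies <- toy_bodies()
  pl <- pack(bodies, pack_region("sphere", radius = 20), seed = 7,
             threshold = 0.47)
  expect_identical(nrow(pl), 200L)
  models <- setNames(lapply(bodies, `[[`, "model"),
                     vapply(bodies, `[[`, "", "species_id"))
  viol <- check_overlaps(pl, models, threshold = 0.47)
  expect_identical(nrow(viol), 0L)
  # spatial-hash fast path agrees with the exhaustive oracle
  viol_grid <- check_overlaps(pl, models, threshold = 0.47, method = "grid")
  expect_identical(nrow(viol_grid), 0L)
})

test_that("overlap checking flags forced coincidences in both modes", {
  m <- toy_protein(8, 1, seed = 2)
  pl <- data.frame(species_id = c("A", "A"), x = c(0, 0), y = c(0, 0),
                   z = c(0, 0), qw = c(1, 1), qx = 0, qy = 0, qz = 0)
  v <- check_overlaps(pl, list(A = m), threshold = 0.47)
  expect_identical(nrow(v), 1L)
  expect_identical(c(v$i, v$j), c(1L, 2L))
  expect_error(check_overlaps(pl, list(B = m)),
               class = "minicell_unknown_species_error")
  # fast path vs exhaustive on random loose placements with real overlaps
  set.seed(9)
  n <- 120
  pl2 <- data.frame(species_id = "A", x = runif(n, -6, 6),
                    y = runif(n, -6, 6), z = runif(n, -6, 6),
                    qw = 1, qx = 0, qy = 0, qz = 0,
                    stringsAsFactors = FALSE)
  a <- check_overlaps(pl2, list(A = m), threshold = 0.8)
  b <- check_overlaps(pl2, list(A = m), threshold = 0.8, method = "grid")
  expect_identical(a[c("i", "j")], b[c("i", "j")])
  expect_gt(nrow(a), 0L)
})

test_that("unbiased single-sphere centers are uniform in the ball", {
  b <- list(list(model = toy_protein(1, 0, seed = 1), species_id = "A",
                 copies = 10000L))
  pl <- pack(b, pack_region("sphere", radius = 10), seed = 31,
             threshold = 1e-3)
  u <- (sqrt(pl$x^2 + pl$y^2 + pl$z^2) / 10)^3  # uniform on [0,1] if uniform
  grid <- seq(0.05, 0.95, by = 0.05)
  emp <- vapply(grid, function(g) mean(u <= g), 1)
  expect_lt(max(abs(emp - grid)), 0.02)
})

test_that("radial bias reshapes the center distribution", {
  b <- list(list(model = toy_protein(1, 0, seed = 1), species_id = "A",
                 copies = 2000L))
  shellward <- function(r) (r / 10)^4
  pl <- pack(b, pack_region("sphere", radius = 10), bias = shellward,
             seed = 5, threshold = 1e-3)
  r <- sqrt(pl$x^2 + pl$y^2 + pl$z^2)
  # E[r] under weight r^4 x r^2 dr is 10 * 7/8; uniform gives 10 * 3/4
  expect_gt(mean(r), 10 * 0.8)
})

test_that("packings are bitwise reproducible from the seed", {
  bodies <- toy_bodies(2, 25)
  reg <- pack_region("sphere", radius = 15)
  expect_identical(pack(bodies, reg, seed = 12),
                   pack(bodies, reg, seed = 12))
  expect_false(identical(pack(bodies, reg, seed = 12),
                         pack(bodies, reg, seed = 13)))
})

test_that("shell and box regions constrain placements; obstacles respected", {
  b <- list(list(model = toy_protein(4, 0.4, seed = 1), species_id = "A",
                 copies = 40L))
  shell <- pack_region("shell", radius = 12, inner_radius = 9)
  pl <- pack(b, shell, seed = 2)
  r <- sqrt(pl$x^2 + pl$y^2 + pl$z^2)
  expect_true(all(r > 8.5 & r < 12.1))

  box <- pack_region("box", extents = c(6, 6, 6))
  plb <- pack(b, box, seed = 2)
  expect_true(all(abs(as.matrix(plb[, c("x", "y", "z")])) <= 3))

  obs <- pack_region("sphere", radius = 8,
                     obstacle_spheres = matrix(c(0, 0, 0, 4), 1))
  plo <- pack(b, obs, seed = 2, threshold = 0.47)
  beads <- attr(plo, "beads")
  expect_gt(min(sqrt(rowSums(beads^2))), 4)
})
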