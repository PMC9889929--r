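test_that("lattice ring growth yields closed self-avoiding rings", {
  # smallest closed ring on the cubic lattice is a unit square
  r4 <- grow_lattice_ring(4, 1, 10, seed = 1)
  b <- r4$positions[c(2:4, 1), ] - r4$positions
  expect_equal(sqrt(rowSums(b^2)), rep(1, 4))
  expect_identical(nrow(unique(round(r4$positions, 9))), 4L)

  # fully blocked lattice stalls with a classed error
  expect_error(
    grow_lattice_ring(10, 1, 5, obstacles = matrix(c(0, 0, 0, 100), 1),
                      seed = 1),
    class = "minicell_growth_stalled_error")

  # 200 monomers around obstacle spheres: exhaustive O(N^2) oracle
  obs <- cbind(c(3, -3), c(0, 2), c(-2, 0), c(1.6, 1.6))
  ring <- grow_lattice_ring(200, 1, 8, obstacles = obs, seed = 5)
  p <- ring$positions
  d <- as.matrix(dist(p))
  diag(d) <- Inf
  expect_gte(min(d), 1 - 1e-9)                       # self-avoidance
  expect_lte(max(sqrt(rowSums(p^2))), 8 + 1e-9)      # boundary
  for (k in 1:2) {                                   # obstacle clearance
    expect_gte(min(sqrt(rowSums(sweep(p, 2, obs[k, 1:3])^2))), obs[k, 4])
  }
  bonds <- sqrt(rowSums((p[c(2:200, 1), ] - p)^2))
  expect_equal(bonds, rep(1, 200))                   # closed ring
})

test_that("WLC energy matches closed forms and zeroes on a rest-state chain", {
  # straight open chain at rest bond length, zero twist: all terms vanish
  p <- wlc_params(l0 = 1, excluded_volume_sigma = 0.5)
  straight <- circular_polymer(cbind(0, 0, 0:9), l0 = 1, circular = FALSE)
  e <- wlc_energy(straight, p)
  expect_equal(e$total, 0)

  # regular N-gon: E_bend = kappa * 2 pi^2 / (N l0), exact discretization
  n <- 100
  rad <- 1 / (2 * sin(pi / n))
  th <- 2 * pi * (0:(n - 1)) / n
  ngon <- circular_polymer(cbind(rad * cos(th), rad * sin(th), 0), l0 = 1)
  pp <- wlc_params(l0 = 1, kappa_bend = 1, kappa_twist = 1, k_stretch = 1,
                   excluded_volume_sigma = 0.5)
  eb <- wlc_energy(ngon, pp)$bend
  expect_equal(eb, 1 * 2 * pi^2 / (n * 1), tolerance = 1e-12)

  # uniform twist: direct quadratic sum
  et <- wlc_energy(ngon, pp, twists = rep(0.01, n))$twist
  expect_equal(et, n * 0.5 * 1e-4)
})

test_that("WLC gradient agrees with numerical differentiation", {
  set.seed(4)
  n <- 14
  th <- 2 * pi * (0:(n - 1)) / n
  pos <- cbind(4 * cos(th), 4 * sin(th), 0) + matrix(rnorm(3 * n, 0, 0.25),
                                                     n, 3)
  p <- wlc_params(l0 = 1.8, confinement_radius = 4.1,
                  excluded_volume_sigma = 2.2)
  poly <- circular_polymer(pos, l0 = p$l0)
  g <- minicell:::wlc_gradient(pos, p, circular = TRUE)
  en <- function(x) {
    poly$positions <- x
    wlc_energy(poly, p)$total
  }
  h <- 1e-6
  for (i in c(1, 5, n)) {
    for (k in 1:3) {
      xp <- pos; xp[i, k] <- xp[i, k] + h
      xm <- pos; xm[i, k] <- xm[i, k] - h
      expect_equal(g[i, k], (en(xp) - en(xm)) / (2 * h), tolerance = 1e-4)
    }
  }
})

test_that("zero-temperature Brownian dynamics never increases the energy", {
  set.seed(11)
  n <- 48
  th <- 2 * pi * (0:(n - 1)) / n
  rad <- 3.4 / (2 * sin(pi / n))
  pos <- cbind(rad * cos(th), rad * sin(th), 0) +
    matrix(rnorm(3 * n, 0, 0.4), n, 3)
  poly <- circular_polymer(pos, l0 = 3.4)
  p <- wlc_params(kBT = 0, excluded_volume_sigma = 2)
  out <- relax_bd(poly, p, 1000, record_energy = TRUE)
  en <- attr(out, "energy")
  expect_true(all(diff(en) <= 1e-9 * pmax(abs(en[-length(en)]), 1)))
  # chain stays closed: wrap bond within 50% of l0
  wrap <- sqrt(sum((out$positions[1, ] - out$positions[n, ])^2))
  expect_lt(abs(wrap - 3.4), 0.5 * 3.4)
})

test_that("BD sampling recovers the bond-length variance kBT/k_stretch", {
  # start from a compact (crumpled) ring: a taut regular ring equilibrates
  # its slow shape modes far too slowly for the bond-length marginal
  poly <- grow_lattice_ring(64, 2, 10, seed = 55)
  # dt is set so even the stiffest normal mode (eigenvalue 4 k_stretch on a
  # ring) is sampled with negligible Euler discretization bias
  p <- wlc_params(k_stretch = 100, kappa_bend = 0.01, kappa_twist = 1,
                  l0 = 2, excluded_volume_sigma = 0.2, kBT = 1, dt = 1e-4)
  poly <- relax_bd(poly, p, 2500, seed = 101)  # burn-in
  acc <- numeric(0)
  set.seed(202)
  for (chunk in 1:1000) {
    poly <- relax_bd(poly, p, 20)
    b <- minicell:::bond_vectors(poly)
    acc <- c(acc, sqrt(rowSums(b^2)) - 2)
  }
  v <- mean(acc^2)
  expect_lt(abs(v - 1 / 100) / (1 / 100), 0.10)
})

test_that("a fixed seed makes the BD trajectory bit-identical", {
  ring <- grow_lattice_ring(40, 3.4, 30, seed = 2)
  p <- wlc_params()
  a <- relax_bd(ring, p, 50, seed = 9)
  b <- relax_bd(ring, p, 50, seed = 9)
  expect_identical(a$positions, b$positions)
  expect_error(relax_bd(circular_polymer(rbind(c(0, 0, 0), c(40, 0, 0),
                                               c(0, 40, 0)), l0 = 3.4),
                        wlc_params(kBT = 0, dt = 1), 5),
               class = "minicell_divergence_error")
})

test_that("periodic spline interpolation reproduces circles at uniform arc", {
  n <- 40
  th <- 2 * pi * (0:(n - 1)) / n
  circ <- circular_polymer(cbind(20 * cos(th), 20 * sin(th), 0),
                           l0 = 2 * 20 * sin(pi / n))
  pts <- interpolate_bp(circ, 400)
  r <- sqrt(rowSums(pts^2))
  expect_lt(max(abs(r - 20)) / 20, 0.001)
  sp <- sqrt(rowSums((pts[c(2:400, 1), ] - pts)^2))
  expect_lt(max(abs(sp - mean(sp))) / mean(sp), 0.01)
  expect_lt(abs(sum(sp) - 2 * pi * 20) / (2 * pi * 20), 0.005)
})

test_that("rotation-minimizing frames are orthonormal with proper closure", {
  # straight path: identical frames everywhere
  z <- cbind(0, 0, seq(0, 10, length.out = 11))
  fr <- rmf_frames(z, twist_per_bp = 0, closed = FALSE)
  expect_equal(fr$normals, matrix(fr$normals[1, ], 11, 3, byrow = TRUE))

  # planar circle, zero twist: radial normals, zero residual twist,
  # checked against a brute-force parallel-transport oracle
  m <- 200
  th <- 2 * pi * (0:(m - 1)) / m
  circ <- cbind(15 * cos(th), 15 * sin(th), 0)
  fr <- rmf_frames(circ, twist_per_bp = 0)
  radial <- circ / 15
  align <- rowSums(fr$normals * radial)
  expect_lt(max(abs(abs(align) - 1)), 1e-6)
  # parallel-transport oracle: project the previous normal onto the plane
  # orthogonal to the new tangent; twist about the tangent must agree
  pt <- fr$normals[1, ]
  worst <- 0
  for (i in 2:m) {
    t_i <- fr$tangents[i, ]
    pt <- pt - sum(pt * t_i) * t_i
    pt <- pt / sqrt(sum(pt^2))
    ang <- atan2(sum(minicell:::crossp(pt, fr$normals[i, ]) * t_i),
                 sum(pt * fr$normals[i, ]))
    worst <- max(worst, min(abs(ang), abs(abs(ang) - 2 * pi / m * (i - 1))))
  }
  # per-step closure correction is the only allowed deviation
  expect_lt(worst, 2 * pi / m + 1e-6)

  # random smooth closed curves: orthonormal triads, det +1, to 1e-9
  for (m2 in c(64, 150)) {
    fr2 <- rmf_frames(smooth_closed_curve(m2))
    expect_lt(max(abs(rowSums(fr2$tangents * fr2$normals))), 1e-9)
    expect_lt(max(abs(rowSums(fr2$normals * fr2$binormals))), 1e-9)
    expect_lt(max(abs(sqrt(rowSums(fr2$normals^2)) - 1)), 1e-9)
    dets <- vapply(seq_len(m2), function(i) {
      det(rbind(fr2$tangents[i, ], fr2$normals[i, ], fr2$binormals[i, ]))
    }, 1)
    expect_lt(max(abs(dets - 1)), 1e-9)
  }
  expect_error(rmf_frames(rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0),
                                c(1, 1, 0))),
               class = "minicell_degenerate_path_error")
})

test_that("backmapping yields 13 beads and -2e per base pair", {
  # 10-bp all-GC helix on a straight path
  z <- cbind(0, 0, 0.34 * (0:9))
  fr10 <- rmf_frames(z, closed = FALSE)
  gc10 <- backmap_dna(fr10, strrep("G", 10))
  expect_identical(nrow(gc10$coords), 130L)
  expect_identical(sum(gc10$charges), -20L)

  m <- 40L
  th <- 2 * pi * (0:(m - 1)) / m
  loop <- cbind(10 * cos(th), 10 * sin(th), 0)
  fr <- rmf_frames(loop)
  seq10 <- paste(rep(c("G", "C"), 20), collapse = "")
  dna <- backmap_dna(fr, seq10)
  expect_identical(nrow(dna$coords), 13L * m)
  expect_identical(sum(dna$charges), -2L * m)
  # every bead within the template radius of its frame origin
  ori <- fr$origins[attr(dna, "bp_index"), ]
  expect_lt(max(sqrt(rowSums((dna$coords - ori)^2))), 1.2)
  # global rotation equivariance
  q <- drop(random_quaternion(1))
  rot <- function(x) quat_rotate(q, x)
  fr_rot <- fr
  for (f in c("origins", "tangents", "normals", "binormals")) {
    fr_rot[[f]] <- rot(fr[[f]])
  }
  dna_rot <- backmap_dna(fr_rot, seq10)
  expect_equal(dna_rot$coords, rot(dna$coords), tolerance = 1e-12)

  expect_error(backmap_dna(fr, paste(rep("N", m), collapse = "")),
               class = "minicell_sequence_alphabet_error")
  expect_error(backmap_dna(fr, "ACGT"), class = "minicell_validation_error")
})

test_that("base-pair templates carry the purine/pyrimidine bead counts", {
  tpl <- bp_templates()
  for (b in c("A", "C", "G", "T")) {
    expect_identical(nrow(tpl[[b]]), 13L)
    expect_identical(sum(tpl[[b]]$charge), -2L)
    expect_lt(max(sqrt(tpl[[b]]$u^2 + tpl[[b]]$v^2 + tpl[[b]]$w^2)), 1.2)
  }
  # purine nucleotide has 7 beads, pyrimidine 6
  expect_identical(sum(tpl[["A"]]$resname == "DA"), 7L)
  expect_identical(sum(tpl[["A"]]$resname == "DT"), 6L)
  expect_identical(sum(tpl[["C"]]$resname == "DC"), 6L)
  expect_identical(sum(tpl[["C"]]$resname == "DG"), 7L)
})

test_that("DNA topology counting scales to the full genome", {
  top <- dna_topology(strrep("A", 543000))
  expect_identical(top$beads, 7059000L)
  expect_lt(abs(top$beads - 7e6) / 7e6, 0.01)
  one <- dna_topology("G")
  expect_identical(one$beads, 13L)
  expect_identical(one$charge, -2L)
  empty <- dna_topology("")
  expect_identical(empty$beads, 0L)
  expect_identical(empty$charge, 0L)
  expect_identical(empty$bonds, 0L)
  expect_error(dna_topology("ACGU"),
               class = "minicell_sequence_alphabet_error")
  # backmap output always equals the topology prediction
  m <- 20
  th <- 2 * pi * (0:(m - 1)) / m
  fr <- rmf_frames(cbind(8 * cos(th), 8 * sin(th), 0))
  s <- random_sequence(m, 0.5, seed = 3)
  dna <- backmap_dna(fr, s)
  expect_identical(nrow(dna$coords), dna_topology(s)$beads)
  expect_identical(sum(dna$charges), dna_topology(s)$charge)
})

test_that("contact maps match an exhaustive oracle and are symmetric", {
  expect_error(contact_map(list(), 1, 10),
               class = "minicell_empty_ensemble_error")
  # two monomers within cutoff: their bins register a contact
  tiny <- circular_polymer(rbind(c(0, 0, 0), c(0.5, 0, 0), c(10, 0, 0),
                                 c(10, 0.5, 0)), l0 = 1, bp_per_monomer = 1)
  cm1 <- contact_map(list(tiny), cutoff = 1, bin_bp = 2)
  expect_identical(cm1[1, 1], 1)
  expect_identical(cm1[1, 2], 0)

  ens <- lapply(1:10, function(s) {
    relax_bd(grow_lattice_ring(100, 1, 6, seed = s),
             wlc_params(l0 = 1, excluded_volume_sigma = 0.7,
                        confinement_radius = 6, dt = 2e-4), 50,
             seed = 100 + s)
  })
  cm <- contact_map(ens, cutoff = 1.5, bin_bp = 50)
  expect_true(all(cm >= 0 & cm <= 1))
  expect_equal(cm, t(cm))
  expect_true(all(diag(cm) == 1))
  # brute-force oracle
  bins <- ((0:99) * 10) %/% 50 + 1
  nb <- max(bins)
  acc <- matrix(0, nb, nb)
  for (e in ens) {
    hit <- matrix(FALSE, nb, nb)
    d <- as.matrix(dist(e$positions))
    close <- which(d < 1.5, arr.ind = TRUE)
    hit[cbind(bins[close[, 1]], bins[close[, 2]])] <- TRUE
    acc <- acc + hit
  }
  expect_equal(cm, acc / 10)
})

test_that("clash relaxation removes close contacts while keeping bonds", {
  set.seed(8)
  x <- matrix(runif(60, 0, 2.2), 20, 3)
  bonds <- cbind(1:19, 2:20)
  rest <- sqrt(rowSums((x[1:19, ] - x[2:20, ])^2))
  out <- minimize_clashes(x, bonds, n_steps = 400, sigma = 0.4,
                          max_step = 0.02)
  d <- as.matrix(dist(out))
  diag(d) <- Inf
  bonded <- rbind(bonds, bonds[, 2:1])
  d[bonded] <- Inf
  expect_gt(min(d), 0.25)  # clashes relaxed
  newrest <- sqrt(rowSums((out[1:19, ] - out[2:20, ])^2))
  expect_lt(max(abs(newrest - rest)), 0.25)  # bonds approximately kept
})
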