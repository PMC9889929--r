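#' Circular polymer container
#'
#' A closed bead chain used for the chromosome at two resolutions: the
#' continuum stage (10 bp per monomer) and the interpolated one-bead-per-bp
#' stage.
#'
#' @param positions \code{N x 3} coordinate matrix (nm).
#' @param l0 rest bond length (nm).
#' @param bp_per_monomer base pairs represented by one monomer.
#' @param circular whether the chain closes back on itself.
#' @return a \code{circular_polymer} object.
#' @export
circular_polymer <- function(positions, l0, bp_per_monomer = 10L,
                             circular = TRUE) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  stopifnot(nrow(positions) >= 3, l0 > 0, bp_per_monomer >= 1)
  structure(list(positions = positions, l0 = l0,
                 bp_per_monomer = as.integer(bp_per_monomer),
                 circular = isTRUE(circular)),
            class = "circular_polymer")
}

#' @export
print.circular_polymer <- function(x, ...) {
  cat(sprintf("circular_polymer: %d monomers (%d bp each), l0 = %.3g nm, %s\n",
              nrow(x$positions), x$bp_per_monomer, x$l0,
              if (x$circular) "closed" else "open"))
  invisible(x)
}

bond_vectors <- function(polymer) {
  p <- polymer$positions
  if (polymer$circular) p[c(2:nrow(p), 1), ] - p else diff(p)
}

#' Grow a closed self-avoiding ring on a cubic lattice
#'
#' Monte Carlo chain growth of a self-avoiding polygon on the cubic lattice
#' inside a spherical boundary, avoiding spherical obstacles (e.g. ribosome
#' positions). Growth is biased toward lattice sites with many occupied or
#' blocked neighbors, which promotes compact, territorially organized
#' conformations; dead ends are handled by retracting the chain head and
#' regrowing. The result is returned in continuum coordinates.
#'
#' @param n_monomers ring length; must be even (cubic-lattice rings have even
#'   length) and at least 4.
#' @param spacing lattice constant = bond length (nm).
#' @param boundary_radius confining sphere radius (nm), centered at origin.
#' @param obstacles optional matrix/data frame with columns \code{x, y, z,
#'   radius} (nm); lattice sites inside an obstacle are blocked.
#' @param seed RNG seed.
#' @param bp_per_monomer stored on the returned polymer.
#' @param locality_bias exponent of the compactness bias (0 = unbiased).
#' @param retract_depth monomers removed when growth dead-ends.
#' @param max_site_attempts total placement budget before giving up.
#' @return a [circular_polymer()].
#' @export
grow_lattice_ring <- function(n_monomers, spacing, boundary_radius,
                              obstacles = NULL, seed = NULL,
                              bp_per_monomer = 10L, locality_bias = 2,
                              retract_depth = 16L,
                              max_site_attempts = NULL) {
  stopifnot(n_monomers >= 4, n_monomers %% 2 == 0, spacing > 0,
            boundary_radius > 0)
  L <- max(1L, floor(boundary_radius / spacing))
  dim_n <- 2L * L + 1L
  ax <- (-L):L
  # allowed sites: inside the boundary sphere, outside every obstacle
  g <- expand.grid(x = ax, y = ax, z = ax)
  r2 <- (g$x^2 + g$y^2 + g$z^2) * spacing^2
  allowed <- array(r2 <= boundary_radius^2, dim = c(dim_n, dim_n, dim_n))
  if (!is.null(obstacles)) {
    obstacles <- as.matrix(obstacles)
    for (k in seq_len(nrow(obstacles))) {
      d2 <- (g$x * spacing - obstacles[k, 1])^2 +
        (g$y * spacing - obstacles[k, 2])^2 +
        (g$z * spacing - obstacles[k, 3])^2
      allowed[d2 < obstacles[k, 4]^2] <- FALSE
    }
  }
  n_allowed <- sum(allowed)
  if (n_allowed < n_monomers) {
    abort(sprintf(
      "lattice has %d usable sites for a %d-ring (longest ring achieved: 0)",
      n_allowed, n_monomers), "minicell_growth_stalled_error",
      longest = 0L)
  }
  if (is.null(max_site_attempts)) {
    max_site_attempts <- max(20000 * n_monomers, 1e6)
  }
  res <- with_seed(seed, {
    grow_ring_lattice(as.integer(n_monomers), L, as.logical(allowed),
                      locality_bias, as.integer(retract_depth),
                      as.numeric(max_site_attempts))
  })
  if (!isTRUE(res$ok)) {
    abort(sprintf("ring growth stalled (longest ring achieved: %d of %d)",
                  res$longest, n_monomers), "minicell_growth_stalled_error",
          longest = res$longest)
  }
  circular_polymer(res$path * spacing, l0 = spacing,
                   bp_per_monomer = bp_per_monomer)
}

#' Twistable worm-like-chain parameters
#'
#' Discretized elasticity of dsDNA at the continuum (10 bp/monomer) stage:
#' harmonic bond stretching, a quadratic bending penalty with modulus
#' \code{kappa_bend / l0} per joint, a quadratic twist penalty with modulus
#' \code{kappa_twist / l0}, a purely repulsive truncated-shifted pair term
#' below \code{excluded_volume_sigma}, and a harmonic confinement outside
#' \code{confinement_radius}. Defaults correspond to canonical dsDNA: a
#' 50-nm bend persistence length and ~100-nm torsional persistence length
#' (in kBT units), with a 3.4-nm bond (10 bp at 0.34 nm rise).
#'
#' @param k_stretch bond spring constant (kBT/nm^2).
#' @param kappa_bend bending modulus (kBT nm).
#' @param kappa_twist twist modulus (kBT nm).
#' @param l0 rest bond length (nm).
#' @param excluded_volume_sigma repulsion onset distance (nm).
#' @param epsilon_ev repulsion strength (kBT).
#' @param kBT thermal energy unit.
#' @param gamma friction coefficient (sets the mobility dt/gamma).
#' @param dt Brownian-dynamics time step.
#' @param confinement_radius confining sphere radius (nm; \code{Inf} = none).
#' @param k_confine confinement spring constant (kBT/nm^2).
#' @return a \code{wlc_params} list.
#' @export
wlc_params <- function(k_stretch = 100, kappa_bend = 50, kappa_twist = 100,
                       l0 = 3.4, excluded_volume_sigma = 2.5,
                       epsilon_ev = 5, kBT = 1, gamma = 1, dt = 1e-3,
                       confinement_radius = Inf, k_confine = 10) {
  p <- list(k_stretch = k_stretch, kappa_bend = kappa_bend,
            kappa_twist = kappa_twist, l0 = l0,
            excluded_volume_sigma = excluded_volume_sigma,
            epsilon_ev = epsilon_ev, kBT = kBT, gamma = gamma, dt = dt,
            confinement_radius = confinement_radius, k_confine = k_confine)
  if (any(unlist(p[c("k_stretch", "kappa_bend", "kappa_twist", "l0",
                     "excluded_volume_sigma", "epsilon_ev", "gamma",
                     "dt")]) <= 0)) {
    abort("all WLC parameters must be positive", "minicell_validation_error")
  }
  # a free bead's RMS displacement per step must stay well below l0
  if (sqrt(2 * kBT * dt / gamma) >= 0.1 * l0 && kBT > 0) {
    abort("dt too large: free-bead RMS step exceeds 0.1 l0",
          "minicell_validation_error")
  }
  structure(p, class = "wlc_params")
}

# bend angles between consecutive bonds (theta = 0 for a straight chain)
bend_angles <- function(b) {
  n <- nrow(b)
  u <- b / pmax(vnorm(b), 1e-300)
  dots <- rowSums(u * u[c(2:n, 1), , drop = FALSE])
  acos(pmin(1, pmax(-1, dots)))
}

# Scatter-add pairwise force contributions (+gd on i, -gd on j) into an
# n x 3 gradient matrix.
accumulate_pairs <- function(n, pairs, gd) {
  acc <- rowsum(rbind(gd, -gd), c(pairs[, 1], pairs[, 2]))
  g <- matrix(0, n, 3)
  g[as.integer(rownames(acc)), ] <- acc
  g
}

ev_pairs <- function(positions, sigma, circular) {
  pr <- grid_self_pairs(positions, sigma)
  if (nrow(pr) == 0) return(pr)
  n <- nrow(positions)
  sep <- abs(pr[, 1] - pr[, 2])
  bonded <- sep == 1L | (circular & sep == n - 1L)
  pr[!bonded, , drop = FALSE]
}

#' Twistable worm-like-chain energy
#'
#' Energy of a bead chain under the discretized twistable WLC model:
#' \deqn{E = \sum \frac{k_s}{2}(|b_i|-l_0)^2
#'       + \sum \frac{\kappa_b}{2 l_0}\theta_i^2
#'       + \sum \frac{\kappa_t}{2 l_0}\phi_i^2 + E_{ev} + E_{conf}}
#' with \eqn{\theta_i} the angle between consecutive bonds and \eqn{\phi_i}
#' per-joint twist angles. The excluded-volume term is the purely repulsive
#' \eqn{\epsilon(1 - r/\sigma)^2} for \eqn{r < \sigma} (zero above, smooth at
#' the cutoff); confinement is harmonic outside the confining sphere, and
#' spherical obstacles contribute the same harmonic penalty inside.
#'
#' @param polymer a [circular_polymer()].
#' @param params a [wlc_params()].
#' @param twists optional per-joint twist angles (radians).
#' @param obstacles optional obstacle matrix (\code{x, y, z, radius}).
#' @return a named list of energy components (\code{stretch}, \code{bend},
#'   \code{twist}, \code{excluded_volume}, \code{confinement}) plus
#'   \code{total}, in kBT.
#' @export
wlc_energy <- function(polymer, params, twists = NULL, obstacles = NULL) {
  p <- polymer$positions
  b <- bond_vectors(polymer)
  bl <- vnorm(b)
  e_stretch <- sum(params$k_stretch / 2 * (bl - params$l0)^2)
  th <- bend_angles(b)
  if (!polymer$circular) th <- th[-length(th)]
  e_bend <- sum(params$kappa_bend / (2 * params$l0) * th^2)
  e_twist <- if (is.null(twists)) 0 else {
    sum(params$kappa_twist / (2 * params$l0) * twists^2)
  }
  pr <- ev_pairs(p, params$excluded_volume_sigma, polymer$circular)
  e_ev <- if (nrow(pr) == 0) 0 else {
    r <- vnorm(p[pr[, 1], , drop = FALSE] - p[pr[, 2], , drop = FALSE])
    sum(params$epsilon_ev * (1 - r / params$excluded_volume_sigma)^2)
  }
  e_conf <- 0
  if (is.finite(params$confinement_radius)) {
    rr <- vnorm(p)
    out <- pmax(rr - params$confinement_radius, 0)
    e_conf <- sum(params$k_confine / 2 * out^2)
  }
  if (!is.null(obstacles)) {
    obstacles <- as.matrix(obstacles)
    for (k in seq_len(nrow(obstacles))) {
      d <- vnorm(sweep(p, 2, obstacles[k, 1:3]))
      pen <- pmax(obstacles[k, 4] - d, 0)
      e_conf <- e_conf + sum(params$k_confine / 2 * pen^2)
    }
  }
  out <- list(stretch = e_stretch, bend = e_bend, twist = e_twist,
              excluded_volume = e_ev, confinement = e_conf)
  out$total <- sum(unlist(out))
  out
}

# Analytic gradient of the position-dependent WLC terms.
wlc_gradient <- function(positions, params, circular = TRUE,
                         obstacles = NULL) {
  n <- nrow(positions)
  g <- matrix(0, n, 3)
  nxt <- if (circular) c(2:n, 1) else NULL
  b <- if (circular) positions[nxt, ] - positions else diff(positions)
  bl <- pmax(vnorm(b), 1e-300)
  # stretch
  fb <- params$k_stretch * (bl - params$l0) / bl
  gb <- b * fb  # dE/d(bond vector)
  if (circular) {
    g <- g - gb + gb[c(n, 1:(n - 1)), ]
  } else {
    g[1:(n - 1), ] <- g[1:(n - 1), ] - gb
    g[2:n, ] <- g[2:n, ] + gb
  }
  # bend: vertex j between i = j-1 and k = j+1; E = kappa/(2 l0) theta^2,
  # theta the deviation from collinearity (pi minus the vertex angle)
  js <- if (circular) 1:n else 2:(n - 1)
  prv <- if (circular) c(n, 1:(n - 1)) else NULL
  for (dummy in 1) {
    if (circular) {
      rij <- positions[prv, ] - positions          # j -> j-1
      rkj <- positions[nxt, ] - positions          # j -> j+1
    } else {
      rij <- positions[js - 1, ] - positions[js, ]
      rkj <- positions[js + 1, ] - positions[js, ]
    }
    lij <- pmax(vnorm(rij), 1e-300)
    lkj <- pmax(vnorm(rkj), 1e-300)
    uij <- rij / lij
    ukj <- rkj / lkj
    cphi <- pmin(1, pmax(-1, rowSums(uij * ukj)))
    phi <- acos(cphi)            # vertex angle; theta = pi - phi
    sphi <- sqrt(pmax(1 - cphi^2, 0))
    theta <- pi - phi
    # dE/dphi = -kappa/l0 * theta; dphi/dri etc. standard angle gradients
    pref <- (params$kappa_bend / params$l0) * ifelse(sphi < 1e-8,
                                                     1, theta / sphi)
    # dE/dri = k' theta * (u_kj - cos(phi) u_ij) / (l_ij sin(phi))
    gi <- (ukj - uij * cphi) / lij * pref
    gk <- (uij - ukj * cphi) / lkj * pref
    if (circular) {
      g[prv, ] <- g[prv, ] + gi
      g[nxt, ] <- g[nxt, ] + gk
      g <- g - gi - gk
    } else {
      g[js - 1, ] <- g[js - 1, ] + gi
      g[js + 1, ] <- g[js + 1, ] + gk
      g[js, ] <- g[js, ] - gi - gk
    }
  }
  # excluded volume
  pr <- ev_pairs(positions, params$excluded_volume_sigma, circular)
  if (nrow(pr) > 0) {
    d <- positions[pr[, 1], , drop = FALSE] - positions[pr[, 2], , drop = FALSE]
    r <- pmax(vnorm(d), 1e-300)
    s <- params$excluded_volume_sigma
    fac <- -2 * params$epsilon_ev * (1 - r / s) / (s * r)
    g <- g + accumulate_pairs(n, pr, d * fac)
  }
  # confinement + obstacles
  if (is.finite(params$confinement_radius)) {
    rr <- pmax(vnorm(positions), 1e-300)
    out <- pmax(rr - params$confinement_radius, 0)
    g <- g + positions * (params$k_confine * out / rr)
  }
  if (!is.null(obstacles)) {
    obstacles <- as.matrix(obstacles)
    for (k in seq_len(nrow(obstacles))) {
      d <- sweep(positions, 2, obstacles[k, 1:3])
      r <- pmax(vnorm(d), 1e-300)
      pen <- pmax(obstacles[k, 4] - r, 0)
      g <- g - d * (params$k_confine * pen / r)
    }
  }
  g
}

#' Relax a polymer by overdamped Brownian dynamics
#'
#' Euler--Maruyama integration of the overdamped Langevin equation
#' \eqn{x \leftarrow x - (dt/\gamma)\nabla E + \sqrt{2 k_B T dt/\gamma}\,\xi}
#' under the twistable WLC energy (positional terms). At \code{kBT = 0} this
#' is plain gradient descent and the energy is non-increasing.
#'
#' @param polymer a [circular_polymer()].
#' @param params a [wlc_params()].
#' @param n_steps number of BD steps.
#' @param seed RNG seed (fixing it makes the trajectory bit-reproducible).
#' @param obstacles optional obstacle spheres (\code{x, y, z, radius}).
#' @param record_energy if \code{TRUE}, attach the per-step total energy as
#'   attribute \code{"energy"}.
#' @return the relaxed [circular_polymer()].
#' @export
relax_bd <- function(polymer, params, n_steps, seed = NULL, obstacles = NULL,
                     record_energy = FALSE) {
  x <- polymer$positions
  n <- nrow(x)
  mob <- params$dt / params$gamma
  noise_sd <- sqrt(2 * params$kBT * params$dt / params$gamma)
  energies <- if (record_energy) numeric(n_steps) else NULL
  with_seed(seed, {
    for (s in seq_len(n_steps)) {
      gr <- wlc_gradient(x, params, polymer$circular, obstacles)
      dx <- -mob * gr
      if (noise_sd > 0) dx <- dx + noise_sd * matrix(rnorm(3 * n), n, 3)
      if (max(abs(dx)) > polymer$l0) {
        abort(sprintf(
          "BD step %d displacement %.3g nm exceeds l0; reduce dt", s,
          max(abs(dx))), "minicell_divergence_error")
      }
      x <- x + dx
      if (record_energy) {
        tmp <- polymer; tmp$positions <- x
        energies[s] <- wlc_energy(tmp, params, obstacles = obstacles)$total
      }
    }
  })
  out <- polymer
  out$positions <- x
  if (record_energy) attr(out, "energy") <- energies
  out
}

#' Interpolate a polymer to one point per base pair
#'
#' Fits a periodic cubic spline through the monomer positions of a closed
#' polymer and resamples it at \code{n_bp} points equally spaced in arc
#' length, converting the 10-bp-resolution chain to a one-bead-per-bp path.
#'
#' @param polymer a closed [circular_polymer()].
#' @param n_bp number of output points (normally
#'   \code{bp_per_monomer * n_monomers}).
#' @param oversample spline evaluation density used for the arc-length
#'   reparameterization.
#' @return an \code{n_bp x 3} matrix of path points (nm).
#' @export
interpolate_bp <- function(polymer, n_bp, oversample = 12L) {
  stopifnot(polymer$circular, n_bp >= 4)
  p <- polymer$positions
  n <- nrow(p)
  t_in <- 0:n
  fx <- splinefun(t_in, c(p[, 1], p[1, 1]), method = "periodic")
  fy <- splinefun(t_in, c(p[, 2], p[1, 2]), method = "periodic")
  fz <- splinefun(t_in, c(p[, 3], p[1, 3]), method = "periodic")
  tt <- seq(0, n, length.out = n_bp * oversample + 1L)
  dense <- cbind(fx(tt), fy(tt), fz(tt))
  seg <- vnorm(diff(dense))
  s_cum <- c(0, cumsum(seg))
  total <- s_cum[length(s_cum)]
  s_target <- (0:(n_bp - 1)) * total / n_bp
  t_target <- approx(s_cum, tt, xout = s_target, ties = "ordered")$y
  cbind(fx(t_target), fy(t_target), fz(t_target))
}

rotate_about_axis <- function(v, axis, angle) {
  # Rodrigues rotation, vectorized over rows of v/axis with per-row angles
  c_ <- cos(angle); s_ <- sin(angle)
  dot <- rowSums(axis * v)
  crx <- cbind(axis[, 2] * v[, 3] - axis[, 3] * v[, 2],
               axis[, 3] * v[, 1] - axis[, 1] * v[, 3],
               axis[, 1] * v[, 2] - axis[, 2] * v[, 1])
  v * c_ + crx * s_ + axis * (dot * (1 - c_))
}

#' Rotation-minimizing frames along a closed path
#'
#' Propagates an orthonormal frame (tangent, normal, binormal) along a
#' closed contour with the double-reflection method, which suppresses
#' spurious rotation about the tangent. For a closed path the residual
#' angular mismatch between the final and initial frame is distributed
#' linearly along the contour, after which a uniform equilibrium twist of
#' \code{twist_per_bp} radians per step is applied about each tangent. The
#' frames are the reference in which base-pair templates are placed.
#'
#' @param path an \code{M x 3} matrix of closed-path points (at least 4;
#'   consecutive points must be distinct).
#' @param twist_per_bp uniform added twist per step (radians); the default
#'   is canonical B-DNA (10.5 bp/turn).
#' @param closed treat the path as a closed loop (the default; the closure
#'   correction only applies then). Open paths get one-sided end tangents
#'   and no closure correction.
#' @return a \code{frame_set}: list with \code{origins}, \code{tangents},
#'   \code{normals}, \code{binormals} (all \code{M x 3}),
#'   \code{twist_per_step} and \code{closure_correction} (radians/step).
#' @export
rmf_frames <- function(path, twist_per_bp = 2 * pi / 10.5, closed = TRUE) {
  path <- matrix(as.numeric(path), ncol = 3)
  m <- nrow(path)
  stopifnot(m >= 4)
  if (any(vnorm(path[2:m, , drop = FALSE] -
                  path[1:(m - 1), , drop = FALSE]) < 1e-12) ||
        (closed && sqrt(sum((path[1, ] - path[m, ])^2)) < 1e-12)) {
    abort("repeated consecutive path point", "minicell_degenerate_path_error")
  }
  if (closed) {
    nxt <- c(2:m, 1)
    prv <- c(m, 1:(m - 1))
    tangents <- normalize_rows(path[nxt, ] - path[prv, ])
  } else {
    tangents <- rbind(path[2, ] - path[1, ],
                      path[3:m, , drop = FALSE] -
                        path[1:(m - 2), , drop = FALSE],
                      path[m, ] - path[m - 1, ])
    tangents <- normalize_rows(tangents)
  }
  # initial normal: any unit vector orthogonal to the first tangent
  t1 <- tangents[1, ]
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  r <- ref - sum(ref * t1) * t1
  r <- r / sqrt(sum(r^2))
  normals <- matrix(0, m, 3)
  normals[1, ] <- r
  reflect <- function(v, mirror, c2) v - (2 * sum(mirror * v) / c2) * mirror
  step_rmf <- function(ri, ti, pi_, pj, tj) {
    v1 <- pj - pi_
    c1 <- sum(v1 * v1)
    rl <- reflect(ri, v1, c1)
    tl <- reflect(ti, v1, c1)
    v2 <- tj - tl
    c2 <- sum(v2 * v2)
    rj <- if (c2 < 1e-30) rl else reflect(rl, v2, c2)
    rj <- rj - sum(rj * tj) * tj
    rj / sqrt(sum(rj * rj))
  }
  for (i in 1:(m - 1)) {
    normals[i + 1, ] <- step_rmf(normals[i, ], tangents[i, ], path[i, ],
                                 path[i + 1, ], tangents[i + 1, ])
  }
  corr <- 0
  idx <- seq_len(m) - 1
  if (closed) {
    # closure: transport once more across the wrap and measure the mismatch
    r_back <- step_rmf(normals[m, ], tangents[m, ], path[m, ], path[1, ],
                       tangents[1, ])
    r0 <- normals[1, ]
    t0 <- tangents[1, ]
    alpha <- atan2(sum(crossp(r0, r_back) * t0), sum(r0 * r_back))
    corr <- -alpha / m
    normals <- rotate_about_axis(normals, tangents, corr * idx)
  }
  # equilibrium twist about the tangent
  if (twist_per_bp != 0) {
    normals <- rotate_about_axis(normals, tangents, twist_per_bp * idx)
  }
  normals <- normalize_rows(normals - tangents * rowSums(normals * tangents))
  binormals <- cbind(
    tangents[, 2] * normals[, 3] - tangents[, 3] * normals[, 2],
    tangents[, 3] * normals[, 1] - tangents[, 1] * normals[, 3],
    tangents[, 1] * normals[, 2] - tangents[, 2] * normals[, 1])
  structure(list(origins = path, tangents = tangents, normals = normals,
                 binormals = binormals, twist_per_step = twist_per_bp,
                 closure_correction = corr),
            class = "frame_set")
}

crossp <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Idealized CG base-pair templates
#'
#' Per-base-pair bead layouts in local frame coordinates (u along the
#' normal, v along the binormal, w along the tangent): each nucleotide has
#' three backbone beads (the first carrying the -1 e phosphate charge) and
#' a purine base contributes four side beads, a pyrimidine three, so every
#' base pair totals 13 beads and -2 e. The two strands are laid out
#' antiparallel on opposite sides of the helix axis. The geometry is an
#' idealized B-DNA-like arrangement (all beads within 1.2 nm of the frame
#' origin) built for structure generation, not taken from any force-field
#' distribution.
#'
#' @return a list keyed by reference-strand base (\code{A}, \code{C},
#'   \code{G}, \code{T}); each element is a data frame with columns
#'   \code{name}, \code{resname}, \code{u}, \code{v}, \code{w},
#'   \code{charge}.
#' @export
bp_templates <- function() {
  nucleotide <- function(base, side) {
    purine <- base %in% c("A", "G")
    az <- c(140, 118, 96, if (purine) c(62, 42, 24, 8) else c(56, 32, 12))
    rr <- c(0.95, 0.84, 0.68, if (purine) c(0.52, 0.38, 0.24, 0.11) else
      c(0.48, 0.32, 0.15))
    ww <- side * c(0.05, 0.08, 0.05, rep(0.0, if (purine) 4 else 3))
    ang <- side * az * pi / 180
    nb <- length(az)
    data.frame(
      name = c("BB1", "BB2", "BB3", paste0("SC", seq_len(nb - 3))),
      resname = paste0("D", base),
      u = rr * cos(ang), v = rr * sin(ang), w = ww,
      charge = c(-1L, rep(0L, nb - 1L)),
      stringsAsFactors = FALSE)
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  setNames(lapply(names(comp), function(b) {
    rbind(nucleotide(b, +1), nucleotide(comp[[b]], -1))
  }), names(comp))
}

#' Backmap a genome sequence onto rotation-minimizing frames
#'
#' Positions one base-pair template per frame: each template bead lands at
#' \code{origin + u * normal + v * binormal + w * tangent}. The complementary
#' strand is implied by the template (antiparallel layout baked in), so the
#' output carries 13 beads and -2 e per base pair.
#'
#' @param frames a [rmf_frames()] frame set.
#' @param sequence A/C/G/T string with one base per frame.
#' @param templates template library from [bp_templates()].
#' @return a [bead_model()] of the full double helix; the per-bead base-pair
#'   index is attached as attribute \code{"bp_index"}.
#' @export
backmap_dna <- function(frames, sequence, templates = bp_templates()) {
  bases <- strsplit(toupper(sequence), "")[[1]]
  if (length(bases) != nrow(frames$origins)) {
    abort("sequence length must equal the number of frames",
          "minicell_validation_error")
  }
  if (!all(bases %in% c("A", "C", "G", "T"))) {
    abort("sequence contains characters outside A/C/G/T",
          "minicell_sequence_alphabet_error")
  }
  n <- length(bases)
  nb_per <- 13L
  total <- n * nb_per
  coords <- matrix(0, total, 3)
  nms <- character(total)
  res <- character(total)
  chg <- integer(total)
  for (b in c("A", "C", "G", "T")) {
    i_bp <- which(bases == b)
    if (length(i_bp) == 0) next
    tpl <- templates[[b]]
    k <- nrow(tpl)
    rows <- rep((i_bp - 1L) * nb_per, each = k) + seq_len(k)
    fi <- rep(i_bp, each = k)
    u <- rep(tpl$u, times = length(i_bp))
    v <- rep(tpl$v, times = length(i_bp))
    w <- rep(tpl$w, times = length(i_bp))
    coords[rows, ] <- frames$origins[fi, ] + frames$normals[fi, ] * u +
      frames$binormals[fi, ] * v + frames$tangents[fi, ] * w
    nms[rows] <- rep(tpl$name, length(i_bp))
    res[rows] <- rep(tpl$resname, length(i_bp))
    chg[rows] <- rep(tpl$charge, length(i_bp))
  }
  m <- bead_model(coords, names = nms, charges = chg,
                  atom_equivalents = 5L, resnames = res)
  attr(m, "bp_index") <- rep(seq_len(n), each = nb_per)
  m
}

#' Topology summary of a CG double helix
#'
#' Counting contract for a sequence at template resolution: 13 beads and
#' -2 e per base pair (purine nucleotide 7 beads + pyrimidine 6). Bonds are
#' counted as 12 intra-base-pair bonds (a spanning tree over the 13 beads)
#' plus two backbone bonds per base-pair step, with the closing step present
#' only for circular molecules.
#'
#' @param sequence A/C/G/T string (empty allowed).
#' @param circular whether the molecule is a closed circle.
#' @return a list with \code{n_bp}, \code{beads}, \code{charge},
#'   \code{bonds}.
#' @export
dna_topology <- function(sequence, circular = TRUE) {
  s <- toupper(sequence)
  n <- nchar(s)
  if (n > 0 && !grepl("^[ACGT]+$", s)) {
    abort("sequence contains characters outside A/C/G/T",
          "minicell_sequence_alphabet_error")
  }
  steps <- if (n == 0) 0L else if (circular) n else n - 1L
  list(n_bp = n, beads = 13L * n, charge = -2L * n,
       bonds = 12L * n + 2L * steps)
}

#' Ensemble contact map
#'
#' Chromosome-conformation-capture-style contact frequencies from an
#' ensemble of simulated polymer conformations: entry (i, j) is the fraction
#' of conformations in which any monomer of genomic bin i lies within
#' \code{cutoff} of any monomer of bin j. The diagonal is 1 by definition.
#'
#' @param ensemble list of [circular_polymer()] objects of equal length.
#' @param cutoff contact distance (nm).
#' @param bin_bp bin width in base pairs.
#' @return a symmetric matrix of contact frequencies in \code{[0, 1]}.
#' @export
contact_map <- function(ensemble, cutoff, bin_bp) {
  if (length(ensemble) == 0) abort("empty conformation ensemble",
                                   "minicell_empty_ensemble_error")
  stopifnot(cutoff > 0, bin_bp >= 1)
  n <- nrow(ensemble[[1]]$positions)
  bpm <- ensemble[[1]]$bp_per_monomer
  if (!all(vapply(ensemble, function(e) nrow(e$positions), 1L) == n)) {
    abort("conformations differ in length", "minicell_validation_error")
  }
  bins <- ((seq_len(n) - 1L) * bpm) %/% bin_bp + 1L
  nb <- max(bins)
  acc <- matrix(0, nb, nb)
  for (e in ensemble) {
    pr <- grid_self_pairs(e$positions, cutoff)
    hit <- matrix(FALSE, nb, nb)
    if (nrow(pr) > 0) {
      bi <- bins[pr[, 1]]
      bj <- bins[pr[, 2]]
      hit[cbind(bi, bj)] <- TRUE
      hit[cbind(bj, bi)] <- TRUE
    }
    diag(hit) <- TRUE
    acc <- acc + hit
  }
  acc / length(ensemble)
}

#' Write a contact map as a dense text matrix
#'
#' Tab-separated dense matrix with a bin header line; readable back with
#' [read_contact_map()].
#'
#' @param cm matrix from [contact_map()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_contact_map <- function(cm, path) {
  colnames(cm) <- paste0("bin", seq_len(ncol(cm)))
  write.table(cm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(path) {
  as.matrix(read.delim(path, sep = "\t", check.names = FALSE))
}

#' Short steepest-descent clash relaxation
#'
#' Displacement-capped steepest descent on harmonic bonds (rest lengths
#' taken from the input geometry) plus a soft repulsion between non-bonded
#' beads closer than \code{sigma}. Used to remove residual clashes after
#' template backmapping; it is a structure-cleanup step, not a force-field
#' minimization.
#'
#' @param coords \code{n x 3} coordinates (nm).
#' @param bonds two-column index matrix of bonded pairs.
#' @param groups optional integer group id per bead (e.g. base-pair index);
#'   beads in the same or adjacent groups are excluded from repulsion.
#' @param n_steps descent steps (default 200).
#' @param sigma repulsion onset distance (nm).
#' @param epsilon repulsion strength.
#' @param k_bond bond spring constant.
#' @param max_step per-coordinate displacement cap (nm).
#' @param refresh neighbor-list refresh interval (steps).
#' @return the relaxed coordinate matrix.
#' @export
minimize_clashes <- function(coords, bonds, groups = NULL, n_steps = 200L,
                             sigma = 0.40, epsilon = 2, k_bond = 100,
                             max_step = 0.03, refresh = 10L) {
  x <- coords
  n <- nrow(x)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  rest <- vnorm(x[bonds[, 1], , drop = FALSE] - x[bonds[, 2], , drop = FALSE])
  pairs <- NULL
  ngroups <- if (is.null(groups)) 0L else max(groups)
  for (s in seq_len(n_steps)) {
    if (is.null(pairs) || (s - 1L) %% refresh == 0L) {
      pairs <- grid_self_pairs(x, sigma)
      if (nrow(pairs) > 0 && !is.null(groups)) {
        gi <- groups[pairs[, 1]]
        gj <- groups[pairs[, 2]]
        dg <- abs(gi - gj)
        near <- dg <= 1L | dg >= ngroups - 1L  # circular adjacency
        pairs <- pairs[!near, , drop = FALSE]
      }
    }
    d <- x[bonds[, 1], , drop = FALSE] - x[bonds[, 2], , drop = FALSE]
    r <- pmax(vnorm(d), 1e-300)
    fb <- k_bond * (r - rest) / r
    g <- accumulate_pairs(n, bonds, d * fb)
    if (nrow(pairs) > 0) {
      d2 <- x[pairs[, 1], , drop = FALSE] - x[pairs[, 2], , drop = FALSE]
      r2 <- pmax(vnorm(d2), 1e-300)
      keep <- r2 < sigma
      if (any(keep)) {
        d2 <- d2[keep, , drop = FALSE]
        r2 <- r2[keep]
        pk <- pairs[keep, , drop = FALSE]
        fac <- -2 * epsilon * (1 - r2 / sigma) / (sigma * r2)
        g <- g + accumulate_pairs(n, pk, d2 * fac)
      }
    }
    step <- -0.002 * g
    step[step > max_step] <- max_step
    step[step < -max_step] <- -max_step
    x <- x + step
  }
  x
}

# Bond list used for clash relaxation of a backmapped helix: a chain through
# each base pair's beads plus backbone links between consecutive base pairs.
dna_relax_bonds <- function(model) {
  bp <- attr(model, "bp_index")
  n_bp <- max(bp)
  per <- 13L
  base <- (seq_len(n_bp) - 1L) * per
  intra_i <- rep(base, each = per - 1L) + rep(1:(per - 1L), n_bp)
  intra_j <- intra_i + 1L
  nxt <- c(2:n_bp, 1L)
  inter_i <- c(base + 1L, base + 8L)
  inter_j <- c((nxt - 1L) * per + 1L, (nxt - 1L) * per + 8L)
  cbind(c(intra_i, inter_i), c(intra_j, inter_j))
}
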