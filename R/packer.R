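#' Packing region
#'
#' Volumetric constraint for rigid-body packing: a sphere, a spherical
#' shell, or an axis-aligned box (all centered at \code{center}), plus an
#' optional list of frozen obstacles. Obstacle beads are prior placements
#' (an \code{n x 3} matrix of bead coordinates); obstacle spheres carry a
#' radius column.
#'
#' @param shape \code{"sphere"}, \code{"shell"} or \code{"box"}.
#' @param radius sphere radius / shell outer radius (nm).
#' @param inner_radius shell inner radius (nm).
#' @param extents box edge lengths (nm, length 3).
#' @param center region center (nm).
#' @param obstacle_beads optional matrix of frozen bead coordinates.
#' @param obstacle_spheres optional matrix with columns \code{x, y, z,
#'   radius}.
#' @return a \code{pack_region} object.
#' @export
pack_region <- function(shape = c("sphere", "shell", "box"), radius = NULL,
                        inner_radius = NULL, extents = NULL,
                        center = c(0, 0, 0), obstacle_beads = NULL,
                        obstacle_spheres = NULL) {
  shape <- match.arg(shape)
  if (shape %in% c("sphere", "shell")) {
    stopifnot(!is.null(radius), radius > 0)
    if (shape == "shell") {
      stopifnot(!is.null(inner_radius), inner_radius >= 0,
                inner_radius < radius)
    }
  } else {
    stopifnot(!is.null(extents), length(extents) == 3, all(extents > 0))
  }
  if (!is.null(obstacle_beads)) {
    obstacle_beads <- matrix(as.numeric(obstacle_beads), ncol = 3)
  }
  if (!is.null(obstacle_spheres)) {
    obstacle_spheres <- matrix(as.numeric(as.matrix(obstacle_spheres)),
                               ncol = 4)
  }
  structure(list(shape = shape, radius = radius,
                 inner_radius = inner_radius, extents = extents,
                 center = center, obstacle_beads = obstacle_beads,
                 obstacle_spheres = obstacle_spheres),
            class = "pack_region")
}

region_contains <- function(region, coords) {
  d <- sweep(coords, 2, region$center)
  switch(region$shape,
    sphere = vnorm(d) <= region$radius,
    shell = {
      r <- vnorm(d)
      r <= region$radius & r >= region$inner_radius
    },
    box = abs(d[, 1]) <= region$extents[1] / 2 &
      abs(d[, 2]) <= region$extents[2] / 2 &
      abs(d[, 3]) <= region$extents[3] / 2)
}

region_volume <- function(region) {
  switch(region$shape,
    sphere = 4 / 3 * pi * region$radius^3,
    shell = 4 / 3 * pi * (region$radius^3 - region$inner_radius^3),
    box = prod(region$extents))
}

sample_region_point <- function(region, n = 1) {
  c0 <- region$center
  if (region$shape == "box") {
    return(sweep(cbind(runif(n, -0.5, 0.5) * region$extents[1],
                       runif(n, -0.5, 0.5) * region$extents[2],
                       runif(n, -0.5, 0.5) * region$extents[3]), 2, c0, "+"))
  }
  rmin <- if (region$shape == "shell") region$inner_radius else 0
  u <- runif(n)
  r <- (rmin^3 + u * (region$radius^3 - rmin^3))^(1 / 3)
  dir <- matrix(rnorm(3 * n), ncol = 3)
  dir <- dir / pmax(vnorm(dir), 1e-12)
  sweep(dir * r, 2, c0, "+")
}

#' Pack rigid bead models into a region
#'
#' Random sequential insertion with collision detection: each copy gets a
#' uniformly random orientation and a candidate position drawn uniformly in
#' the region (or bias-weighted via rejection sampling on a radial weight
#' function); the candidate is accepted only if every bead stays inside the
#' region and no bead comes closer than \code{threshold} to any already
#' placed or obstacle bead. Collision queries run on a uniform spatial hash
#' grid with cell size equal to the threshold. Mirrors how crowded-cytosol
#' models are assembled: large complexes first, then everything else around
#' them.
#'
#' @param bodies list of entries, each a list with \code{model} (a
#'   [bead_model()]), \code{species_id}, and \code{copies}.
#' @param region a [pack_region()].
#' @param bias optional function of radial distance from the region center
#'   returning a relative weight in \code{[0, 1]} scale (any non-negative
#'   scale works; it is normalized by its maximum over the region).
#' @param seed RNG seed; packings are reproducible from it.
#' @param max_trials_per_copy insertion attempts per copy before failing.
#' @param threshold minimum allowed bead--bead center distance across
#'   different bodies (nm); one CG bead diameter by default.
#' @param mode \code{"bead"} for per-bead collision checks or
#'   \code{"bounding_sphere"} for cheap sphere-overlap checks.
#' @return a data frame of placements (\code{species_id, x, y, z, qw, qx,
#'   qy, qz}) with the flattened placed-bead coordinates attached as
#'   attribute \code{"beads"} (plus \code{"bead_placement"}, the placement
#'   row of each bead).
#' @export
pack <- function(bodies, region, bias = NULL, seed = NULL,
                 max_trials_per_copy = 10000L, threshold = 0.47,
                 mode = c("bead", "bounding_sphere")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0)
  bodies <- lapply(bodies, function(b) {
    b$copies <- as.integer(b$copies)
    b
  })
  n_total <- sum(vapply(bodies, function(b) b$copies, 1L))
  placements <- data.frame(
    species_id = character(n_total), x = numeric(n_total),
    y = numeric(n_total), z = numeric(n_total), qw = numeric(n_total),
    qx = numeric(n_total), qy = numeric(n_total), qz = numeric(n_total),
    stringsAsFactors = FALSE)
  placed <- matrix(numeric(0), 0, 3)
  if (!is.null(region$obstacle_beads)) placed <- region$obstacle_beads
  n_obstacle <- nrow(placed)
  bead_placement <- integer(0)
  bias_max <- if (is.null(bias)) 1 else {
    rmax <- switch(region$shape, box = sqrt(sum(region$extents^2)) / 2,
                   region$radius)
    max(vapply(seq(0, rmax, length.out = 512), bias, 1))
  }
  row <- 0L
  with_seed(seed, {
    for (b in bodies) {
      model <- b$model
      if (model$bounding_radius < 0) abort("invalid bounding radius",
                                           "minicell_validation_error")
      for (cp in seq_len(b$copies)) {
        row <- row + 1L
        done <- FALSE
        for (trial in seq_len(max_trials_per_copy)) {
          pos <- drop(sample_region_point(region, 1))
          if (!is.null(bias)) {
            r <- sqrt(sum((pos - region$center)^2))
            if (runif(1) * bias_max > bias(r)) next
          }
          q <- drop(random_quaternion(1))
          coords <- transform_body(model, pos, q)
          if (!all(region_contains(region, coords))) next
          if (!is.null(region$obstacle_spheres)) {
            os <- region$obstacle_spheres
            clash <- FALSE
            for (k in seq_len(nrow(os))) {
              if (any(vnorm(sweep(coords, 2, os[k, 1:3])) <
                        os[k, 4] + threshold)) { clash <- TRUE; break }
            }
            if (clash) next
          }
          if (nrow(placed) > 0) {
            if (mode == "bead") {
              if (any(grid_any_close(coords, placed, threshold))) next
            } else {
              # bounding-sphere pre-check only (cheap, conservative reject)
              ctr <- matrix(colMeans(coords), 1)
              if (any(grid_any_close(ctr, placed,
                                     threshold + model$bounding_radius))) next
            }
          }
          placements$species_id[row] <- b$species_id
          placements[row, 2:4] <- pos
          placements[row, 5:8] <- q
          placed <- rbind(placed, coords)
          bead_placement <- c(bead_placement, rep(row, nrow(coords)))
          done <- TRUE
          break
        }
        if (!done) {
          # achieved volume fraction, beads counted as threshold-diameter
          # spheres
          vol_frac <- nrow(placed) * 4 / 3 * pi * (threshold / 2)^3 /
            region_volume(region)
          abort(sprintf(
            paste0("failed to place copy %d of %s after %d trials ",
                   "(%d of %d copies placed, volume fraction %.3f)"),
            cp, b$species_id, max_trials_per_copy, row - 1L, n_total,
            vol_frac),
            "minicell_packing_error", placed = row - 1L,
            volume_fraction = vol_frac)
        }
      }
    }
  })
  attr(placements, "beads") <-
    placed[seq_len(nrow(placed)) > n_obstacle, , drop = FALSE]
  attr(placements, "bead_placement") <- bead_placement
  placements
}

#' Exhaustive cross-body overlap check
#'
#' Certifies a packing: lists every pair of beads from different placements
#' closer than \code{threshold}. The default method is the exact O(N^2)
#' pairwise scan (the test oracle); \code{method = "grid"} runs the
#' spatial-hash fast path used during packing, which must agree with the
#' exhaustive scan.
#'
#' @param placements a placement data frame as returned by [pack()].
#' @param bodies named list mapping \code{species_id} to [bead_model()].
#' @param threshold contact threshold (nm).
#' @param method \code{"exhaustive"} or \code{"grid"}.
#' @return a data frame of violating placement pairs (\code{i}, \code{j},
#'   \code{distance}); zero rows certify the packing.
#' @export
check_overlaps <- function(placements, bodies, threshold = 0.47,
                           method = c("exhaustive", "grid")) {
  method <- match.arg(method)
  n <- nrow(placements)
  unknown <- setdiff(unique(placements$species_id), names(bodies))
  if (length(unknown) > 0) {
    abort(paste0("no bead model for species ", unknown[1]),
          "minicell_unknown_species_error")
  }
  coords_list <- lapply(seq_len(n), function(i) {
    transform_body(bodies[[placements$species_id[i]]],
                   as.numeric(placements[i, c("x", "y", "z")]),
                   as.numeric(placements[i, c("qw", "qx", "qy", "qz")]))
  })
  owner <- rep(seq_len(n), vapply(coords_list, nrow, 1L))
  all_coords <- do.call(rbind, coords_list)
  viol <- data.frame(i = integer(0), j = integer(0), distance = numeric(0))
  if (method == "grid") {
    pr <- grid_self_pairs(all_coords, threshold)
    if (nrow(pr) > 0) {
      oi <- owner[pr[, 1]]
      oj <- owner[pr[, 2]]
      keep <- oi != oj
      if (any(keep)) {
        d <- vnorm(all_coords[pr[keep, 1], , drop = FALSE] -
                     all_coords[pr[keep, 2], , drop = FALSE])
        # aggregate bead pairs to body pairs, keeping the minimum distance
        key <- paste(pmin(oi[keep], oj[keep]), pmax(oi[keep], oj[keep]))
        dmin <- tapply(d, key, min)
        ij <- do.call(rbind, strsplit(names(dmin), " "))
        viol <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                           distance = unname(dmin))
      }
    }
  } else {
    for (a in seq_len(max(n - 1, 0))) {
      xa <- coords_list[[a]]
      for (b in seq_len(n)[-seq_len(a)]) {
        xb <- coords_list[[b]]
        d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") -
          2 * xa %*% t(xb)
        dmin <- sqrt(max(min(d2), 0))
        if (dmin < threshold) {
          viol <- rbind(viol, data.frame(i = a, j = b, distance = dmin))
        }
      }
    }
  }
  viol <- unique(viol[order(viol$i, viol$j), , drop = FALSE])
  rownames(viol) <- NULL
  viol
}

#' Write / read placement tables
#'
#' Placements are exchanged as TSV with columns \code{species_id, x, y, z,
#' qw, qx, qy, qz} (positions nm, orientation as a unit quaternion).
#'
#' @param placements placement data frame.
#' @param path file path.
#' @return \code{write_placements}: \code{path} invisibly;
#'   \code{read_placements}: the placement data frame.
#' @export
write_placements <- function(placements, path) {
  write.table(placements[c("species_id", "x", "y", "z", "qw", "qx", "qy",
                           "qz")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_placements
#' @export
read_placements <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  req <- c("species_id", "x", "y", "z", "qw", "qx", "qy", "qz")
  if (!all(req %in% names(df))) abort("malformed placements file",
                                      "minicell_parse_error")
  df[req]
}
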