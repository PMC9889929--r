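#' Periodic simulation box
#'
#' Constructs the periodic cell from explicit vectors, or use [make_box()]
#' for the rhombic dodecahedron around a spherical cell.
#'
#' @param vectors 3 x 3 matrix of row box vectors (nm).
#' @param type \code{"rhombic_dodecahedron"}, \code{"cubic"} or
#'   \code{"triclinic"}.
#' @return a \code{simulation_box} with \code{vectors}, \code{type} and
#'   \code{volume}.
#' @export
simulation_box <- function(vectors,
                           type = c("triclinic", "cubic",
                                    "rhombic_dodecahedron")) {
  type <- match.arg(type)
  vectors <- matrix(as.numeric(vectors), 3, 3)
  vol <- abs(det(vectors))
  if (vol <= 0) abort("box has non-positive volume",
                      "minicell_validation_error")
  structure(list(vectors = vectors, type = type, volume = vol),
            class = "simulation_box")
}

#' Rhombic dodecahedron box around a spherical cell
#'
#' The space-filling periodic cell best suited to globular solutes: for an
#' image distance d, the (square-top) box vectors are \code{(d,0,0)},
#' \code{(0,d,0)}, \code{(d/2, d/2, d*sqrt(2)/2)} and the volume is
#' \code{d^3*sqrt(2)/2}, about 71% of the bounding cube. The image distance
#' is \code{cell_diameter + 2*padding}, so no periodic image approaches the
#' cell closer than twice the padding.
#'
#' @param cell_diameter solute diameter (nm).
#' @param padding clearance between the cell surface and its nearest image,
#'   per side (nm).
#' @return a \code{simulation_box} of type \code{rhombic_dodecahedron};
#'   the image distance is attached as \code{$image_distance}.
#' @export
make_box <- function(cell_diameter, padding) {
  stopifnot(cell_diameter > 0, padding > 0)
  d <- cell_diameter + 2 * padding
  b <- simulation_box(rbind(c(d, 0, 0), c(0, d, 0),
                            c(d / 2, d / 2, d * sqrt(2) / 2)),
                      type = "rhombic_dodecahedron")
  b$image_distance <- d
  b
}

#' @export
print.simulation_box <- function(x, ...) {
  cat(sprintf("simulation_box (%s): volume %.4g nm^3\n", x$type, x$volume))
  invisible(x)
}

box_center <- function(box) colSums(box$vectors) / 2

fractional_coords <- function(box, coords) {
  coords %*% solve(box$vectors)
}

# Periodic images of the solute that could touch points inside the primitive
# cell: translated copies kept only if within `buffer` of the cell.
augment_periodic_images <- function(box, coords, buffer) {
  if (nrow(coords) == 0) return(coords)
  v <- box$vectors
  lo <- rep(-buffer, 3)
  hi <- colSums(v) + buffer
  out <- coords
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    if (i == 0 && j == 0 && k == 0) next
    shift <- i * v[1, ] + j * v[2, ] + k * v[3, ]
    img <- sweep(coords, 2, shift, "+")
    keep <- img[, 1] >= lo[1] & img[, 1] <= hi[1] &
      img[, 2] >= lo[2] & img[, 2] <= hi[2] &
      img[, 3] >= lo[3] & img[, 3] <= hi[3]
    if (any(keep)) out <- rbind(out, img[keep, , drop = FALSE])
  }
  out
}

#' Tile CG water across a periodic box
#'
#' Lays a simple-cubic lattice of water beads at the requested number
#' density, clips it to the primitive cell, and removes every bead within
#' \code{min_dist} of a solute bead (periodic images of the solute are
#' taken into account). Waters are classified inside/outside the membrane
#' mid-surface radius around the box center using minimum-image distances.
#' The default density corresponds to bulk water at the four-to-one CG
#' mapping: 33.3 real waters per nm^3 / 4 per bead = 8.33 beads per nm^3.
#'
#' @param box a [simulation_box()].
#' @param solute_beads optional \code{n x 3} matrix of solute coordinates in
#'   box frame (the solute is expected centered on \code{box_center}).
#' @param density water bead number density (beads/nm^3).
#' @param min_dist minimum water--solute distance (nm).
#' @param inside_radius optional membrane mid-surface radius (nm) for the
#'   inside/outside classification.
#' @return list with \code{coords} (water bead positions), \code{n_inside},
#'   \code{n_outside}, \code{spacing}.
#' @export
tile_water <- function(box, solute_beads = NULL, density = 8.33,
                       min_dist = 0.45, inside_radius = NULL) {
  stopifnot(density > 0, min_dist >= 0)
  a <- density^(-1 / 3)
  v <- box$vectors
  hi <- pmax(colSums(pmax(v, 0)), 0)  # bounding corner of the cell
  nx <- ceiling(hi[1] / a); ny <- ceiling(hi[2] / a); nz <- ceiling(hi[3] / a)
  xs <- (seq_len(nx) - 0.5) * a
  ys <- (seq_len(ny) - 0.5) * a
  zs <- (seq_len(nz) - 0.5) * a
  coords <- cbind(rep(xs, times = ny * nz),
                  rep(rep(ys, each = nx), times = nz),
                  rep(zs, each = nx * ny))
  fr <- fractional_coords(box, coords)
  inside_cell <- fr[, 1] >= 0 & fr[, 1] < 1 & fr[, 2] >= 0 & fr[, 2] < 1 &
    fr[, 3] >= 0 & fr[, 3] < 1
  coords <- coords[inside_cell, , drop = FALSE]
  if (!is.null(solute_beads) && nrow(solute_beads) > 0 && min_dist > 0) {
    solute_aug <- augment_periodic_images(box, solute_beads, min_dist)
    clash <- grid_any_close(coords, solute_aug, min_dist)
    coords <- coords[!clash, , drop = FALSE]
  }
  n_inside <- 0L
  if (!is.null(inside_radius)) {
    d2min <- rep(Inf, nrow(coords))
    ctr <- box_center(box)
    for (i in -1:1) for (j in -1:1) for (k in -1:1) {
      c_img <- ctr + i * v[1, ] + j * v[2, ] + k * v[3, ]
      d2 <- (coords[, 1] - c_img[1])^2 + (coords[, 2] - c_img[2])^2 +
        (coords[, 3] - c_img[3])^2
      d2min <- pmin(d2min, d2)
    }
    n_inside <- sum(d2min < inside_radius^2)
  }
  list(coords = coords, n_inside = as.integer(n_inside),
       n_outside = nrow(coords) - as.integer(n_inside), spacing = a)
}

#' Neutralize and salt a solvated system
#'
#' Converts water beads into Na+/Cl- ion beads so that (a) the system is
#' electroneutral and (b) the salt concentration reaches the target
#' molarity. The number of salt pairs follows the water-count convention
#' \code{n_pair = round(molarity * 4 * N_water / 55.5)} (a CG water bead is
#' four real waters; 55.5 mol/L is the molar concentration of pure water).
#' Neutralizing excess ions are placed by converting the waters nearest to
#' the charged solute sites (within \code{near_cutoff}), falling back to
#' random waters when those are exhausted; salt pairs convert uniformly
#' random remaining waters. Every converted site is consumed exactly once.
#'
#' @param net_charge net solute charge (e, integer).
#' @param waters \code{N x 3} water bead coordinates.
#' @param charged_sites coordinates of charged solute beads (used to place
#'   the neutralizing counterions; may be \code{NULL}).
#' @param molarity target NaCl concentration (mol/L).
#' @param seed RNG seed.
#' @param near_cutoff distance within which a water counts as "near" a
#'   charged site (nm).
#' @return list with \code{n_sodium}, \code{n_chloride},
#'   \code{target_molarity}, \code{realized_molarity}, \code{sodium} and
#'   \code{chloride} coordinate matrices, and \code{waters} (the remaining
#'   water coordinates).
#' @export
ionize <- function(net_charge, waters, charged_sites = NULL, molarity = 0.135,
                   seed = NULL, near_cutoff = 1.5) {
  stopifnot(molarity >= 0)
  net_charge <- as.integer(round(net_charge))
  n_w <- nrow(waters)
  n_pair <- as.integer(round(molarity * 4 * n_w / 55.5))
  n_na <- n_pair + max(-net_charge, 0L)
  n_cl <- n_pair + max(net_charge, 0L)
  if (n_na + n_cl > n_w) {
    abort(sprintf("need %d waters to convert but only %d available",
                  n_na + n_cl, n_w), "minicell_insufficient_solvent_error")
  }
  with_seed(seed, {
    n_neut <- abs(net_charge)
    neut_idx <- integer(0)
    if (n_neut > 0) {
      cand <- integer(0)
      if (!is.null(charged_sites) && nrow(charged_sites) > 0) {
        pr <- grid_close_pairs(waters, charged_sites, near_cutoff)
        if (nrow(pr) > 0) {
          d <- vnorm(waters[pr[, 1], , drop = FALSE] -
                       charged_sites[pr[, 2], , drop = FALSE])
          dmin <- tapply(d, pr[, 1], min)
          cand <- as.integer(names(dmin))[order(unname(dmin),
                                                as.integer(names(dmin)))]
        }
      }
      if (length(cand) >= n_neut) {
        neut_idx <- cand[seq_len(n_neut)]
      } else {
        pool <- setdiff(seq_len(n_w), cand)
        extra <- pool[sample.int(length(pool), n_neut - length(cand))]
        neut_idx <- c(cand, extra)
      }
    }
    remaining <- setdiff(seq_len(n_w), neut_idx)
    salt_idx <- remaining[sample.int(length(remaining), 2L * n_pair)]
    na_idx <- c(if (net_charge < 0) neut_idx,
                salt_idx[seq_len(n_pair)])
    cl_idx <- c(if (net_charge > 0) neut_idx,
                if (n_pair > 0) salt_idx[n_pair + seq_len(n_pair)])
    keep <- setdiff(seq_len(n_w), c(na_idx, cl_idx))
    list(n_sodium = length(na_idx), n_chloride = length(cl_idx),
         target_molarity = molarity,
         realized_molarity = 55.5 * n_pair / (4 * n_w),
         sodium = waters[na_idx, , drop = FALSE],
         chloride = waters[cl_idx, , drop = FALSE],
         waters = waters[keep, , drop = FALSE])
  })
}
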