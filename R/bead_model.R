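#' Coarse-grained bead model
#'
#' The basic particle container of the package: a rigid set of named CG beads
#' with coordinates in nanometres, integer charges in elementary units, and a
#' per-bead atom-equivalent count (how many real atoms the bead stands for;
#' a CG bead typically maps about four heavy atoms plus hydrogens).
#'
#' @param coords an \code{n x 3} numeric matrix of bead positions (nm).
#' @param names character vector of bead names (recycled if length 1).
#' @param charges integer charges per bead, elementary units (default 0).
#' @param atom_equivalents positive integers, atoms represented per bead
#'   (default 9).
#' @param resnames residue names per bead (default \code{"MOL"}).
#' @return an object of class \code{bead_model} with fields \code{coords},
#'   \code{bead_names}, \code{charges}, \code{atom_equivalents},
#'   \code{resnames} and \code{bounding_radius} (max bead distance from the
#'   centroid, nm).
#' @export
bead_model <- function(coords, names = "BB", charges = 0L,
                       atom_equivalents = 9L, resnames = "MOL") {
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  if (n == 0) abort("bead model must contain at least one bead",
                    "minicell_empty_structure_error")
  if (any(!is.finite(coords))) abort("non-finite coordinates",
                                     "minicell_format_error")
  names <- rep_len(as.character(names), n)
  charges <- rep_len(as.integer(charges), n)
  atom_equivalents <- rep_len(as.integer(atom_equivalents), n)
  resnames <- rep_len(as.character(resnames), n)
  if (any(atom_equivalents < 1L)) abort("atom_equivalents must be positive",
                                        "minicell_validation_error")
  centroid <- colMeans(coords)
  br <- if (n == 1) 0 else max(vnorm(sweep(coords, 2, centroid)))
  structure(list(
    bead_names = names, coords = coords, charges = charges,
    atom_equivalents = atom_equivalents, resnames = resnames,
    bounding_radius = br
  ), class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat(sprintf(
    "bead_model: %d beads, net charge %+d e, bounding radius %.3f nm\n",
    nrow(x$coords), sum(x$charges), x$bounding_radius))
  invisible(x)
}

n_beads <- function(model) nrow(model$coords)

# Body coordinates under a placement (rotate about the body centroid, then
# translate the centroid to `position`).
transform_body <- function(model, position, quaternion) {
  centroid <- colMeans(model$coords)
  local <- sweep(model$coords, 2, centroid)
  sweep(quat_rotate(quaternion, local), 2, position, "+")
}
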