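#' @useDynLib minicell, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif splinefun approx setNames
#' @importFrom utils read.delim write.table
NULL

# Signal a classed condition so callers can distinguish failure modes
# (e.g. "minicell_packing_error") while still inheriting from "error".
abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "minicell_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic operations in the package route
# through this so that a seed fully determines the output.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

vnorm <- function(x) sqrt(rowSums(x * x))

normalize_rows <- function(x) x / vnorm(x)

#' Uniform random unit quaternions
#'
#' Draws rotations uniformly from SO(3) (Shoemake's method), returned as
#' rows \code{(qw, qx, qy, qz)}.
#'
#' @param n number of quaternions.
#' @return an \code{n x 4} numeric matrix of unit quaternions.
#' @export
random_quaternion <- function(n = 1) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  a <- sqrt(1 - u1); b <- sqrt(u1)
  q <- cbind(
    qw = b * cos(2 * pi * u3),
    qx = a * sin(2 * pi * u2),
    qy = a * cos(2 * pi * u2),
    qz = b * sin(2 * pi * u3)
  )
  q / sqrt(rowSums(q^2))
}

#' Rotate coordinates by a unit quaternion
#'
#' @param q length-4 unit quaternion \code{(qw, qx, qy, qz)}.
#' @param x an \code{n x 3} coordinate matrix.
#' @return the rotated \code{n x 3} matrix.
#' @export
quat_rotate <- function(q, x) {
  x %*% t(quat_matrix(q))
}

quat_matrix <- function(q) {
  w <- q[1]; xx <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (xx * y - w * z), 2 * (xx * z + w * y),
    2 * (xx * y + w * z), 1 - 2 * (xx^2 + z^2), 2 * (y * z - w * xx),
    2 * (xx * z - w * y), 2 * (y * z + w * xx), 1 - 2 * (xx^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Volume fraction of a spherical cell occupied by a surface shell
#'
#' For a cell of the given radius, the fraction of its volume lying within
#' \code{depth} of the surface: \eqn{1 - ((R - d)/R)^3}. Used to quantify the
#' membrane zone of a cell (membrane plus the cytosolic layer beneath it).
#'
#' @param radius cell radius (nm).
#' @param depth shell depth measured inward from the surface (nm).
#' @return the volume fraction in \code{[0, 1]}.
#' @examples
#' shell_volume_fraction(200, 30) # ~0.39 of a 400-nm-diameter cell
#' @export
shell_volume_fraction <- function(radius, depth) {
  stopifnot(radius > 0, depth >= 0, depth <= radius)
  1 - ((radius - depth) / radius)^3
}
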