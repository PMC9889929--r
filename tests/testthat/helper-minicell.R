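# Shared helpers for the minicell test suite.

tmpfile <- function(ext = "") tempfile(fileext = ext)

write_lines_tmp <- function(lines, ext = "") {
  path <- tmpfile(ext)
  writeLines(lines, path)
  path
}

# Exhaustive O(N^2) minimum distance between two coordinate sets, blockwise.
brute_min_dist <- function(a, b, block = 2000L) {
  mn <- Inf
  for (i0 in seq(1, nrow(a), by = block)) {
    ii <- i0:min(i0 + block - 1L, nrow(a))
    d2 <- outer(rowSums(a[ii, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * a[ii, , drop = FALSE] %*% t(b)
    mn <- min(mn, min(d2))
  }
  sqrt(max(mn, 0))
}

# Brute-force list of index pairs (i < j) within cutoff, one coordinate set.
brute_self_pairs <- function(x, cutoff) {
  d <- as.matrix(dist(x))
  d[upper.tri(d, diag = TRUE)] <- Inf
  which(d < cutoff, arr.ind = TRUE)[, c(2, 1), drop = FALSE]
}

# A small closed smooth test curve (trefoil-style) for frame tests.
smooth_closed_curve <- function(m, radius = 10) {
  t <- seq(0, 2 * pi, length.out = m + 1)[1:m]
  cbind(radius * (cos(t) + 0.3 * cos(2 * t)),
        radius * (sin(t) - 0.2 * sin(3 * t)),
        radius * 0.4 * sin(2 * t))
}
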