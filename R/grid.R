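#' Uniform Cartesian grid for the simulation domain
#'
#' Node-centred uniform grid on a rectangle. All level-set functions and
#' extracellular fields live on these nodes; coordinates are in micrometres.
#'
#' @param x_min,x_max,y_min,y_max Domain bounds in um.
#' @param h Node spacing in um (default 0.04). The bounds must be integer
#'   multiples of `h` apart.
#' @return An object of class `ms_grid`: list with bounds, `h`, node counts
#'   `nx`, `ny` and node coordinate vectors `x`, `y`.
#' @export
ms_grid <- function(x_min, x_max, y_min, y_max, h = 0.04) {
  stopifnot(h > 0, x_max > x_min, y_max > y_min)
  nxs <- (x_max - x_min) / h
  nys <- (y_max - y_min) / h
  if (abs(nxs - round(nxs)) > 1e-8 || abs(nys - round(nys)) > 1e-8)
    stop("grid bounds must be integer multiples of h apart")
  nx <- as.integer(round(nxs)) + 1L
  ny <- as.integer(round(nys)) + 1L
  g <- list(
    x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
    h = h, nx = nx, ny = ny,
    x = x_min + h * (seq_len(nx) - 1L),
    y = y_min + h * (seq_len(ny) - 1L)
  )
  class(g) <- "ms_grid"
  g
}

#' @exportS3Method base::print
print.ms_grid <- function(x, ...) {
  cat(sprintf("<ms_grid [%g, %g] x [%g, %g], h = %g, %d x %d nodes>\n",
              x$x_min, x$x_max, x$y_min, x$y_max, x$h, x$nx, x$ny))
  invisible(x)
}

# Node coordinates as an (nx*ny) x 2 matrix, column-major in y (x fastest).
grid_nodes <- function(grid) {
  cbind(rep(grid$x, times = grid$ny), rep(grid$y, each = grid$nx))
}

# Bilinear interpolation of a grid matrix Z (nx x ny) at points (n x 2).
# If `weights` (0/1 matrix, same shape) is given, the four corner values are
# reweighted so that masked nodes do not contribute; points whose four
# corners are all masked get NA.
bilinear_at <- function(grid, Z, pts, weights = NULL) {
  h <- grid$h
  fx <- (pts[, 1] - grid$x_min) / h
  fy <- (pts[, 2] - grid$y_min) / h
  i0 <- pmin(pmax(floor(fx), 0), grid$nx - 2L)
  j0 <- pmin(pmax(floor(fy), 0), grid$ny - 2L)
  tx <- pmin(pmax(fx - i0, 0), 1)
  ty <- pmin(pmax(fy - j0, 0), 1)
  idx <- function(di, dj) (j0 + dj) * grid$nx + (i0 + di) + 1L
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty;       w11 <- tx * ty
  if (!is.null(weights)) {
    w00 <- w00 * weights[idx(0, 0)]; w10 <- w10 * weights[idx(1, 0)]
    w01 <- w01 * weights[idx(0, 1)]; w11 <- w11 * weights[idx(1, 1)]
    tot <- w00 + w10 + w01 + w11
    val <- w00 * Z[idx(0, 0)] + w10 * Z[idx(1, 0)] +
      w01 * Z[idx(0, 1)] + w11 * Z[idx(1, 1)]
    out <- val / tot
    out[tot <= 0] <- NA_real_
    out
  } else {
    w00 * Z[idx(0, 0)] + w10 * Z[idx(1, 0)] +
      w01 * Z[idx(0, 1)] + w11 * Z[idx(1, 1)]
  }
}

# Exact distance from points to a closed polyline (per-segment projection,
# chunked over points to bound memory).
dist_to_polyline <- function(pts, poly) {
  n <- nrow(poly)
  B <- poly[c(2:n, 1L), , drop = FALSE]
  ex <- B[, 1] - poly[, 1]; ey <- B[, 2] - poly[, 2]
  ee <- pmax(ex^2 + ey^2, 1e-300)
  px <- pts[, 1]; py <- pts[, 2]
  dm <- rep(Inf, length(px))
  for (k in seq_len(n)) {       # loop over segments, vectorised over points
    dx <- px - poly[k, 1]; dy <- py - poly[k, 2]
    tt <- (dx * ex[k] + dy * ey[k]) / ee[k]
    tt[tt < 0] <- 0; tt[tt > 1] <- 1
    dm <- pmin(dm, (dx - tt * ex[k])^2 + (dy - tt * ey[k])^2)
  }
  sqrt(dm)
}

# Squared-distance based nearest neighbour from each row of `pts` to the
# rows of `ref` (both n x 2). Uses the |a|^2 + |b|^2 - 2 a.b expansion so the
# heavy lifting is one BLAS matrix product. Returns list(dist, idx).
nearest_point <- function(pts, ref) {
  # argmin_j |p - r_j|^2 = argmax_j (p.r_j - |r_j|^2/2); the -|r_j|^2/2 row
  # rides along in one BLAS product via an augmented column of ones
  score <- cbind(pts, 1) %*% rbind(t(ref), -0.5 * rowSums(ref^2))
  idx <- max.col(score, ties.method = "first")
  best <- score[cbind(seq_len(nrow(pts)), idx)]
  d2min <- rowSums(pts^2) - 2 * best
  list(dist = sqrt(pmax(d2min, 0)), idx = idx)
}
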