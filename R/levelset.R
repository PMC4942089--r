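#' Level-set representation of a cell
#'
#' Each cell carries its own level-set function phi (negative inside, zero on
#' the plasma membrane, positive outside), stored as an `nx x ny` matrix on an
#' [ms_grid()]. The membrane is the zero contour; the cell interior is
#' `phi < 0` and the extracellular space is `phi > 0`.
#'
#' @param center Cell centre (length-2, um).
#' @param radius Cell radius in um (default 1, the model cell size).
#' @param grid An [ms_grid()].
#' @return An object of class `ms_levelset` with fields `phi` (matrix),
#'   `grid`, `cell_id`, `center0`, `radius0`.
#' @export
init_circle_levelset <- function(center, radius, grid, cell_id = "cell") {
  stopifnot(length(center) == 2, radius > 0)
  if (center[1] - radius <= grid$x_min || center[1] + radius >= grid$x_max ||
      center[2] - radius <= grid$y_min || center[2] + radius >= grid$y_max)
    stop("cell circle touches or crosses the domain boundary")
  phi <- sqrt(outer((grid$x - center[1])^2, (grid$y - center[2])^2, "+")) - radius
  structure(list(phi = phi, grid = grid, cell_id = cell_id,
                 center0 = as.numeric(center), radius0 = radius),
            class = "ms_levelset")
}

# One-sided differences of a grid matrix, with edge replication (the cells
# never approach the outer boundary; replication keeps gradients finite).
shift_mat <- function(P, di, dj) {
  nx <- nrow(P); ny <- ncol(P)
  i <- pmin(pmax(seq_len(nx) + di, 1L), nx)
  j <- pmin(pmax(seq_len(ny) + dj, 1L), ny)
  P[i, j, drop = FALSE]
}

#' Advance a level-set function under a normal-velocity field
#'
#' Solves one explicit step of the Hamilton-Jacobi equation
#' `phi_t + V |grad phi| = 0` with a first-order Godunov upwind scheme.
#' Positive V moves the membrane outward along its normal.
#'
#' @param ls An `ms_levelset`.
#' @param V_grid Normal speed per grid node (um/s), matrix like `phi`;
#'   typically nonzero only in a narrow band (see [extend_velocity()]).
#' @param dt Time step in seconds.
#' @return The advanced `ms_levelset`.
#' @export
advance_levelset <- function(ls, V_grid, dt) {
  h <- ls$grid$h
  vmax <- max(abs(V_grid))
  if (vmax * dt / h > 0.9)
    stop(sprintf("CFL violation in advance_levelset: need dt <= %.3g s", 0.9 * h / vmax))
  P <- ls$phi
  Dmx <- (P - shift_mat(P, -1L, 0L)) / h
  Dpx <- (shift_mat(P, 1L, 0L) - P) / h
  Dmy <- (P - shift_mat(P, 0L, -1L)) / h
  Dpy <- (shift_mat(P, 0L, 1L) - P) / h
  pos <- V_grid > 0
  gp <- sqrt(pmax(Dmx, 0)^2 + pmin(Dpx, 0)^2 + pmax(Dmy, 0)^2 + pmin(Dpy, 0)^2)
  gn <- sqrt(pmin(Dmx, 0)^2 + pmax(Dpx, 0)^2 + pmin(Dmy, 0)^2 + pmax(Dpy, 0)^2)
  grad <- ifelse(pos, gp, gn)
  ls$phi <- P - dt * V_grid * grad
  ls
}

#' Restore the signed-distance property of a level-set function
#'
#' Rebuilds phi as the exact signed distance to the current zero contour
#' (sign taken from the incoming field). The zero contour itself moves by
#' less than the marker spacing. With the default `band_width = Inf` the
#' whole grid is rebuilt; the simulation loop passes a finite band and leaves
#' far-field values (never consulted) untouched.
#'
#' @param ls An `ms_levelset`.
#' @param curve Optional pre-extracted [extract_membrane_curve()] result;
#'   extracted afresh when `NULL`.
#' @param band_width Half-width (um) of the node band to rebuild.
#' @export
reinitialize_signed_distance <- function(ls, curve = NULL, band_width = Inf) {
  if (all(ls$phi > 0) || all(ls$phi < 0))
    stop("level-set interface has vanished (phi has a single sign)")
  if (is.null(curve)) curve <- extract_membrane_curve(ls, n_markers = 400L)
  g <- ls$grid
  sel <- if (is.finite(band_width)) {
    # |phi| may have drifted from true distance between reinits, and nodes
    # just ahead of a growing tip can carry stale far-field values; select
    # by stale |phi| AND by a bounding box around the current membrane so
    # the rebuilt shell always covers the curve's neighbourhood
    m <- 2.5 * band_width
    inbox <- outer(g$x >= min(curve$points[, 1]) - m &
                     g$x <= max(curve$points[, 1]) + m,
                   g$y >= min(curve$points[, 2]) - m &
                     g$y <= max(curve$points[, 2]) + m, "&")
    cand <- which(abs(ls$phi) <= m | inbox)
    # coarse prefilter on a subsampled curve keeps the exact pass small
    sub <- curve$points[seq(1L, nrow(curve$points), by = 8L), , drop = FALSE]
    coarse <- nearest_point(grid_nodes(g)[cand, , drop = FALSE], sub)$dist
    cand[coarse <= m + 8 * curve$ds]
  } else seq_along(ls$phi)
  nodes <- grid_nodes(g)[sel, , drop = FALSE]
  # a 2x-subsampled polyline carries an O(ds^2) distance error, far below h
  poly <- if (is.finite(band_width) && nrow(curve$points) > 200L)
    curve$points[seq(1L, nrow(curve$points), by = 2L), , drop = FALSE]
  else curve$points
  ls$phi[sel] <- sign(ls$phi[sel]) * dist_to_polyline(nodes, poly)
  ls
}

#' Extract the membrane as an ordered, equally spaced marker curve
#'
#' Traces the zero contour of phi, orients it counterclockwise, and resamples
#' it to `n_markers` points of equal arc length. Outward unit normals are
#' interpolated from `grad phi` (falling back to the curve tangent where the
#' gradient degenerates).
#'
#' @param ls An `ms_levelset`.
#' @param n_markers Number of markers (default 400).
#' @return An object of class `ms_curve`: `points` (N x 2), `normals` (N x 2,
#'   unit, outward), `arc` (cumulative arc length from marker 1), `ds` (marker
#'   spacing), `length` (perimeter), `center0`, `radius0`, `centroid`.
#' @export
extract_membrane_curve <- function(ls, n_markers = 400L, keep_largest = FALSE) {
  g <- ls$grid
  cl <- grDevices::contourLines(g$x, g$y, ls$phi, levels = 0)
  if (length(cl) == 0) stop("no zero contour found")
  split_flag <- FALSE
  if (length(cl) > 1) {
    # keep the longest component only if the others are spurious specks,
    # or unconditionally when the caller asks for pinch-off tolerance
    lens <- vapply(cl, function(cc) length(cc$x), integer(1))
    if (sort(lens, decreasing = TRUE)[2] > 8) {
      if (!keep_largest) stop("membrane split into multiple components")
      split_flag <- TRUE
    }
    cl <- cl[which.max(lens)]
  }
  px <- cl[[1]]$x; py <- cl[[1]]$y
  # drop duplicated closing point if present
  n <- length(px)
  if (n > 2 && abs(px[1] - px[n]) < 1e-12 && abs(py[1] - py[n]) < 1e-12) {
    px <- px[-n]; py <- py[-n]; n <- n - 1L
  }
  # drop zero-length segments (contour tracing can emit duplicates)
  keep <- c(TRUE, abs(diff(px)) > 1e-12 | abs(diff(py)) > 1e-12)
  px <- px[keep]; py <- py[keep]; n <- length(px)
  # one Newton projection x <- x - phi grad(phi)/|grad(phi)|^2 pulls the
  # traced points onto the zero set (linear edge interpolation is poor where
  # the contour runs almost parallel to a grid line)
  P <- ls$phi
  gxm <- (shift_mat(P, 1L, 0L) - shift_mat(P, -1L, 0L)) / (2 * g$h)
  gym <- (shift_mat(P, 0L, 1L) - shift_mat(P, 0L, -1L)) / (2 * g$h)
  cp <- cbind(px, py)
  phv <- bilinear_at(g, P, cp)
  gxv <- bilinear_at(g, gxm, cp)
  gyv <- bilinear_at(g, gym, cp)
  gg <- pmax(gxv^2 + gyv^2, 1e-12)
  shiftv <- pmin(pmax(phv / gg, -g$h), g$h)   # clamp to one cell
  px <- px - shiftv * gxv
  py <- py - shiftv * gyv
  # projection can merge neighbouring points; drop the duplicates again,
  # including a re-closed last point
  keep <- c(TRUE, abs(diff(px)) > 1e-9 | abs(diff(py)) > 1e-9)
  px <- px[keep]; py <- py[keep]; n <- length(px)
  if (n > 2 && abs(px[n] - px[1]) < 1e-9 && abs(py[n] - py[1]) < 1e-9) {
    px <- px[-n]; py <- py[-n]; n <- n - 1L
  }
  # counterclockwise orientation via the shoelace signed area
  area2 <- sum(px * py[c(2:n, 1)] - px[c(2:n, 1)] * py)
  if (area2 < 0) { px <- rev(px); py <- rev(py) }
  # resample to equal arc length
  seg <- sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2)
  arc <- c(0, cumsum(seg))             # length n+1, arc[n+1] = perimeter
  L <- arc[n + 1]
  # phase-align marker 1 with the rightmost contour point so that symmetric
  # shapes receive symmetric marker sets (contour tracing starts arbitrarily)
  s0 <- arc[which.max(px)]
  s_new <- (s0 + L * (seq_len(n_markers) - 1L) / n_markers) %% L
  xi <- stats::approx(arc, c(px, px[1]), xout = s_new)$y
  yi <- stats::approx(arc, c(py, py[1]), xout = s_new)$y
  pts <- cbind(xi, yi)
  # outward normals from grad phi, bilinearly interpolated at the markers
  P <- ls$phi
  gx <- (shift_mat(P, 1L, 0L) - shift_mat(P, -1L, 0L)) / (2 * g$h)
  gy <- (shift_mat(P, 0L, 1L) - shift_mat(P, 0L, -1L)) / (2 * g$h)
  nxv <- bilinear_at(g, gx, pts)
  nyv <- bilinear_at(g, gy, pts)
  nrm <- sqrt(nxv^2 + nyv^2)
  bad <- !is.finite(nrm) | nrm < 1e-8
  if (any(bad)) {
    # tangent rotated -90 deg is outward for a CCW curve
    nxt <- c(2:n_markers, 1L); prv <- c(n_markers, 1:(n_markers - 1L))
    tx <- pts[nxt, 1] - pts[prv, 1]; ty <- pts[nxt, 2] - pts[prv, 2]
    tl <- sqrt(tx^2 + ty^2)
    nxv[bad] <- (ty / tl)[bad]; nyv[bad] <- (-tx / tl)[bad]
    nrm[bad] <- 1
  }
  normals <- cbind(nxv / nrm, nyv / nrm)
  structure(list(points = pts, normals = normals,
                 arc = L * (seq_len(n_markers) - 1L) / n_markers,
                 ds = L / n_markers, length = L,
                 center0 = ls$center0, radius0 = ls$radius0,
                 centroid = c(mean(xi), mean(yi)), split = split_flag),
            class = "ms_curve")
}

# Signed distance to a closed marker curve with inside/outside decided by
# the even-odd ray-crossing rule (used to purge pinched-off islands).
signed_distance_from_curve <- function(grid, curve) {
  nodes <- grid_nodes(grid)
  dst <- dist_to_polyline(nodes, curve$points)
  px <- curve$points[, 1]; py <- curve$points[, 2]
  n <- length(px)
  jx <- px[c(2:n, 1L)]; jy <- py[c(2:n, 1L)]
  inside <- rep(FALSE, nrow(nodes))
  x <- nodes[, 1]; y <- nodes[, 2]
  for (k in seq_len(n)) {
    crosses <- ((py[k] > y) != (jy[k] > y)) &
      (x < (jx[k] - px[k]) * (y - py[k]) / (jy[k] - py[k]) + px[k])
    inside <- xor(inside, crosses)
  }
  matrix(ifelse(inside, -dst, dst), grid$nx, grid$ny)
}

#' Region masks for a set of cells
#'
#' Partitions the grid into extracellular space (outside every cell), per-cell
#' interiors, and per-cell narrow bands around each membrane.
#'
#' @param ls_list List of `ms_levelset` (may be empty).
#' @param grid The shared [ms_grid()] (required when `ls_list` is empty).
#' @param band_half_width Half-width of the membrane band in um
#'   (default `6 * h`).
#' @return List with logical matrices `exterior`, `interior` (list per cell),
#'   `band` (list per cell), and flag `overlap` (TRUE when two cell
#'   interiors share a node).
#' @export
region_masks <- function(ls_list, grid = NULL, band_half_width = NULL) {
  if (length(ls_list) == 0) {
    stopifnot(!is.null(grid))
    ext <- matrix(TRUE, grid$nx, grid$ny)
    return(list(exterior = ext, interior = list(), band = list(),
                overlap = FALSE))
  }
  grid <- ls_list[[1]]$grid
  if (is.null(band_half_width)) band_half_width <- 6 * grid$h
  interior <- lapply(ls_list, function(l) l$phi < 0)
  band <- lapply(ls_list, function(l) abs(l$phi) <= band_half_width)
  inside_any <- Reduce(`|`, interior)
  n_inside <- Reduce(`+`, lapply(interior, function(m) m * 1L))
  list(exterior = !inside_any, interior = interior, band = band,
       overlap = any(n_inside > 1L))
}
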