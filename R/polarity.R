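#' Parameters of the two-stage membrane polarity circuit
#'
#' The circuit has two stages living on the membrane: stage 1 (u1, a
#' Gbetagamma surrogate) is activated by the normalised pheromone input
#' f_tilde through a Hill term and by its own cooperative positive feedback,
#' and degraded at a rate modulated by the integral-feedback controller v1,
#' which drives the spatial mean of u1 to the setpoint `k1ss`. Stage 2
#' (u2, an active-Cdc42 surrogate) has the same structure with u1 as input
#' and its own controller v2. Only u1 and v1 carry noise.
#'
#' Rates are per time-unit (1 time-unit = 100 s); `Ds` is the lateral
#' membrane diffusion in um^2/time-unit. `beta1` is the reciprocal
#' half-maximum of the input term: raising it to 2.5 (default 0.92) saturates
#' sensing and reproduces the supersensitive (sst2-delta-like) phenotype.
#'
#' @param ... Overrides of any default.
#' @export
polarity_params <- function(...) {
  p <- list(
    Ds = 0.2,
    # stage 1: input, positive feedback, degradation, integral feedback
    k10 = 4, beta1 = 0.92, q1 = 8,
    k11 = 8, gamma1 = 0.7, h1 = 4,
    k12 = 1, k13 = 10,
    k14 = 0.3, k1ss = 1,
    # stage 2
    k20 = 14, beta2 = 0.5, q2 = 12,
    k21 = 14, gamma2 = 0.28, h2 = 6,
    k22 = 1, k23 = 10,
    k24 = 0.1, k2ss = 1.5,
    # noise amplitudes (kappa2 on u1, kappa3 on v1)
    kappa2 = 3, kappa3 = 0.1
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(p))
  if (length(unknown)) stop("unknown polarity parameter(s): ",
                            paste(unknown, collapse = ", "))
  p[names(ov)] <- ov
  p
}

# Saturating Hill activation x^q / (1 + x^q) written against scaled input.
hill_act <- function(x, beta, q) {
  bx <- pmax(beta * x, 0)
  bxq <- bx^q
  bxq / (1 + bxq)
}

#' Fresh uniform polarity state
#' @param n Number of markers.
#' @param params A [polarity_params()] list.
#' @export
polarity_state <- function(n, params = polarity_params(),
                           u1 = params$k1ss, u2 = params$k2ss,
                           v1 = NULL, v2 = NULL) {
  # v initialised at the uniform-state balance for a mid-range input, so the
  # controller starts near its operating point rather than at zero
  if (is.null(v1)) {
    infl <- params$k10 * hill_act(1.1, params$beta1, params$q1) +
      params$k11 * hill_act(params$k1ss, params$gamma1, params$h1)
    v1 <- max((infl / max(params$k1ss, 1e-12) - params$k12) / params$k13, 0.01)
  }
  if (is.null(v2)) {
    infl <- params$k20 * hill_act(params$k1ss, params$beta2, params$q2) +
      params$k21 * hill_act(params$k2ss, params$gamma2, params$h2)
    v2 <- max((infl / max(params$k2ss, 1e-12) - params$k22) / params$k23, 0.01)
  }
  list(u1 = rep(u1, n), v1 = rep(v1, n), u2 = rep(u2, n), v2 = rep(v2, n))
}

# Exact periodic diffusion substep via the discrete Fourier transform:
# each mode decays by exp(-Ds k^2 dt) with k the continuous wavenumber for
# a ring of circumference L.
spectral_diffuse <- function(u, Ds, dt, L) {
  if (Ds <= 0 || dt <= 0) return(u)
  n <- length(u)
  kfreq <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) * (2 * pi / L)
  decay <- exp(-Ds * kfreq^2 * dt)
  Re(stats::fft(stats::fft(u) * decay, inverse = TRUE)) / n
}

#' One Euler-Maruyama step of the membrane polarity system
#'
#' Reactions and noise are stepped explicitly; lateral diffusion is applied
#' as an exact spectral substep on the periodic marker ring (the markers are
#' equally spaced). Noise increments are i.i.d. Normal(0, dt) per marker on
#' u1 and v1 only; negative excursions are clamped to zero.
#'
#' @param state List with u1, v1, u2, v2 (per marker).
#' @param f_tilde Normalised ligand per marker (see [sample_and_normalize()]).
#' @param params A [polarity_params()] list.
#' @param dt Step in time-units (default 0.01).
#' @param L Membrane length (um), sets the diffusion wavenumbers.
#' @param noise_block Number of adjacent markers sharing one noise increment
#'   (the white-noise fields live on the membrane mesh; when markers are
#'   finer than the mesh each mesh cell spans several markers). Default 1.
#' @export
step_polarity <- function(state, f_tilde, params, dt, L, noise_block = 1L) {
  p <- params
  u1 <- state$u1; v1 <- state$v1; u2 <- state$u2; v2 <- state$v2
  u1bar <- mean(u1); u2bar <- mean(u2)
  du1 <- p$k10 * hill_act(f_tilde, p$beta1, p$q1) +
    p$k11 * hill_act(u1, p$gamma1, p$h1) -
    (p$k12 + p$k13 * v1) * u1
  dv1 <- p$k14 * (u1bar - p$k1ss) * v1
  du2 <- p$k20 * hill_act(u1, p$beta2, p$q2) +
    p$k21 * hill_act(u2, p$gamma2, p$h2) -
    (p$k22 + p$k23 * v2) * u2
  dv2 <- p$k24 * (u2bar - p$k2ss) * v2
  n <- length(u1)
  blk_noise <- function() {
    if (noise_block <= 1L) return(stats::rnorm(n, sd = sqrt(dt)))
    nb <- ceiling(n / noise_block)
    rep(stats::rnorm(nb, sd = sqrt(dt)), each = noise_block)[seq_len(n)]
  }
  if (p$kappa2 > 0)
    du1 <- du1 + p$kappa2 * u1 * blk_noise() / dt
  if (p$kappa3 > 0)
    dv1 <- dv1 + p$kappa3 * v1 * blk_noise() / dt
  u1 <- pmax(u1 + dt * du1, 0)
  v1 <- pmax(v1 + dt * dv1, 0)
  u2 <- pmax(u2 + dt * du2, 0)
  v2 <- pmax(v2 + dt * dv2, 0)
  u1 <- spectral_diffuse(u1, p$Ds, dt, L)
  u2 <- spectral_diffuse(u2, p$Ds, dt, L)
  if (max(u1, u2) > 1e6)
    stop("polarity state blow-up (value > 1e6); check parameters")
  list(u1 = pmax(u1, 0), v1 = v1, u2 = pmax(u2, 0), v2 = v2)
}

#' Locate the polarisome
#'
#' The polarisome is the centre of the minimum-length contiguous membrane
#' interval containing at least a fraction `tau` of the total u2 mass
#' (default tau = 0.4). Ties between equal-length windows are broken in
#' favour of the window holding the most mass (for a symmetric peak this is
#' the centred window), then by the smallest start index. Returns a
#' no-polarisome sentinel when u2 is identically zero.
#'
#' @param u2 Per-marker u2.
#' @param curve Matching `ms_curve`.
#' @param tau Mass-fraction threshold.
#' @return List: `found`, `idx` (centre marker), `position` (2-vector),
#'   `angle` (about the curve centroid), `arc` (arc-length position),
#'   `window` (start/end marker indices), `normal` (outward normal there).
#' @export
locate_polarisome <- function(u2, curve, tau = 0.4) {
  n <- length(u2)
  tot <- sum(u2)
  if (tot <= 0) return(list(found = FALSE))
  target <- tau * tot
  ext <- cumsum(c(u2, u2))
  base <- c(0, ext)[1:n]            # cumulative mass before each start
  # smallest j with ext[j] >= base + target  ->  window length j - i + 1
  jpos <- findInterval(base + target - 1e-9 * tot, ext) + 1L
  len <- jpos - seq_len(n) + 1L
  w <- min(len)
  cand <- which(len == w)
  mass <- ext[cand + w - 1L] - base[cand]
  start <- cand[which.max(mass)]    # most massive minimal window, then first
  centre <- ((start - 1L + (w - 1L) %/% 2L) %% n) + 1L
  endi <- ((start + w - 2L) %% n) + 1L
  pos <- curve$points[centre, ]
  cen <- curve$centroid
  list(found = TRUE, idx = centre, position = pos,
       angle = atan2(pos[2] - cen[2], pos[1] - cen[1]),
       arc = curve$arc[centre],
       window = c(start, endi),
       normal = curve$normals[centre, ])
}

#' Circular moving-average smoothing of a membrane profile
#'
#' @param x Per-marker values.
#' @param frac Window length as a fraction of the membrane (default 0.05).
#' @export
smooth_membrane <- function(x, frac = 0.05) {
  n <- length(x)
  w <- max(3L, round(frac * n))
  if (w %% 2 == 0) w <- w + 1L
  halo <- (w - 1L) %/% 2L
  xp <- c(x[(n - halo + 1L):n], x, x[1:halo])
  as.numeric(stats::filter(xp, rep(1 / w, w), sides = 2))[(halo + 1L):(halo + n)]
}

#' Normal membrane velocity from the polarity output
#'
#' `V_i = Vamp * u2_i * max(0, <n_i, d_max>)` where `d_max` is the outward
#' normal at the polarisome centre: growth is proportional to (filtered)
#' active Cdc42 and confined to the membrane sector facing the growth
#' direction. Returns all zeros when no polarisome exists yet.
#'
#' @param u2 Per-marker (smoothed) u2.
#' @param curve `ms_curve`.
#' @param pol Result of [locate_polarisome()].
#' @param Vamp Velocity amplitude in um/s (default 2e-4).
#' @return Per-marker normal speed in um/s.
#' @export
membrane_velocity <- function(u2, curve, pol, Vamp = 2e-4) {
  if (!isTRUE(pol$found)) return(rep(0, nrow(curve$points)))
  dmax <- pol$normal
  proj <- curve$normals[, 1] * dmax[1] + curve$normals[, 2] * dmax[2]
  Vamp * u2 * pmax(proj, 0)
}

#' Extend a per-marker velocity to the grid band
#'
#' Constant extension along normals: each band node inherits the velocity of
#' its nearest membrane marker; nodes outside the band get zero.
#'
#' @param V_markers Per-marker normal speed.
#' @param curve `ms_curve`.
#' @param ls `ms_levelset` (for grid shape).
#' @param band Logical band mask.
#' @export
extend_velocity <- function(V_markers, curve, ls, band) {
  sel <- which(band)
  if (length(sel) == 0) stop("empty velocity-extension band")
  g <- ls$grid
  nodes <- grid_nodes(g)[sel, , drop = FALSE]
  nn <- nearest_point(nodes, curve$points)
  V <- matrix(0, g$nx, g$ny)
  V[sel] <- V_markers[nn$idx]
  V
}

#' Transport membrane species onto a re-extracted curve
#'
#' Species are carried by angular correspondence about the cell centroid
#' (cells remain star-shaped) and re-interpolated periodically onto the new
#' equal-spacing markers. Mass drift per resampling is well below 0.5% for
#' the smooth deformations the simulation produces.
#'
#' @param state Polarity state (u1, v1, u2, v2).
#' @param old_curve,new_curve Successive `ms_curve` extractions of one cell.
#' @export
resample_membrane_state <- function(state, old_curve, new_curve) {
  cen <- old_curve$centroid
  th_old <- atan2(old_curve$points[, 2] - cen[2], old_curve$points[, 1] - cen[1])
  th_new <- atan2(new_curve$points[, 2] - cen[2], new_curve$points[, 1] - cen[1])
  ord <- order(th_old)
  to <- th_old[ord]
  # guard against duplicate angles from degenerate markers
  dup <- c(FALSE, diff(to) <= 0)
  interp_per <- function(y) {
    yo <- y[ord]
    tox <- to[!dup]; yox <- yo[!dup]
    m <- length(tox)
    tx <- c(tox[m] - 2 * pi, tox, tox[1] + 2 * pi)
    ty <- c(yox[m], yox, yox[1])
    stats::approx(tx, ty, xout = th_new, rule = 2)$y
  }
  lapply(state, interp_per)
}
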