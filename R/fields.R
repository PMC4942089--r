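#' Extracellular concentration field
#'
#' Holds one diffusing extracellular species (alpha-factor, a-factor, or the
#' Bar1 protease) on the grid. Values live on extracellular nodes only;
#' interior nodes are held at zero and excluded from all updates (the cell
#' body excludes ligand). Units: concentrations are arbitrary, D in
#' um^2 per time unit (1 time unit = 100 s), decay in 1/time-unit.
#'
#' @param grid An [ms_grid()].
#' @param D Diffusion constant (um^2/time-unit).
#' @param k_decay Basal first-order decay rate (1/time-unit).
#' @param kappa1 Multiplicative noise amplitude (dimensionless).
#' @param species_tag One of "alpha_factor", "a_factor", "bar1".
#' @export
extracellular_field <- function(grid, D, k_decay, kappa1 = 0,
                                species_tag = c("alpha_factor", "a_factor", "bar1"),
                                values = NULL) {
  species_tag <- match.arg(species_tag)
  if (is.null(values)) values <- matrix(0, grid$nx, grid$ny)
  stopifnot(all(dim(values) == c(grid$nx, grid$ny)), all(values >= 0))
  structure(list(values = values, grid = grid, D = D, k_decay = k_decay,
                 kappa1 = kappa1, species_tag = species_tag,
                 clamp_count = 0L, step_count = 0L),
            class = "ms_field")
}

# Source amplitude shared by both pheromones: 1000/sqrt(2*pi).
SOURCE_AMPLITUDE <- 1000 / sqrt(2 * pi)

#' Membrane-localised pheromone source
#'
#' Gaussian source with support on the membrane, expressed through the
#' level-set function: isotropic secretion is
#' `S = A exp(-100 phi^2)` and polarised secretion concentrates around the
#' polarisome via `S = A exp(-100 phi^2 - 20 (1 - u2/u2max)^2)`, with
#' `A = 1000/sqrt(2 pi)`. u2 at a grid node is taken from the nearest
#' membrane marker. The source is zero outside the membrane band.
#'
#' @param ls An `ms_levelset`.
#' @param curve Matching `ms_curve` (needed for polarised mode).
#' @param u2 Per-marker u2 concentrations (polarised mode).
#' @param mode "isotropic" or "polarized".
#' @param band Logical matrix restricting the support (default `|phi| <= 6h`).
#' @param amplitude Peak amplitude A.
#' @return Matrix of source rates on the grid (per time-unit).
#' @export
membrane_source_field <- function(ls, curve = NULL, u2 = NULL,
                                  mode = c("isotropic", "polarized"),
                                  band = NULL, amplitude = SOURCE_AMPLITUDE) {
  mode <- match.arg(mode)
  g <- ls$grid
  if (is.null(band)) band <- abs(ls$phi) <= 6 * g$h
  S <- matrix(0, g$nx, g$ny)
  sel <- which(band)
  if (length(sel) == 0) return(S)
  phi_b <- ls$phi[sel]
  if (mode == "polarized") {
    if (is.null(u2) || is.null(curve) || max(u2) <= 0) {
      mode <- "isotropic"      # pre-polarisation fallback
    }
  }
  if (mode == "isotropic") {
    S[sel] <- amplitude * exp(-100 * phi_b^2)
  } else {
    nodes <- grid_nodes(g)[sel, , drop = FALSE]
    nn <- nearest_point(nodes, curve$points)
    u2n <- u2[nn$idx] / max(u2)
    S[sel] <- amplitude * exp(-100 * phi_b^2 - 20 * (1 - u2n)^2)
  }
  S
}

# Masked 5-point Laplacian with no-flux conditions at the domain boundary
# and at every membrane: a neighbour outside the extracellular mask simply
# does not exchange flux.
masked_laplacian <- function(F, ext, h) {
  Fz <- F * ext
  Ez <- ext * 1
  zshift <- function(M, di, dj) {
    out <- matrix(0, nrow(M), ncol(M))
    nx <- nrow(M); ny <- ncol(M)
    xi <- seq_len(nx) + di; yj <- seq_len(ny) + dj
    okx <- xi >= 1 & xi <= nx; oky <- yj >= 1 & yj <= ny
    out[okx, oky] <- M[xi[okx], yj[oky]]
    out
  }
  nb_sum <- zshift(Fz, 1, 0) + zshift(Fz, -1, 0) + zshift(Fz, 0, 1) + zshift(Fz, 0, -1)
  nb_cnt <- zshift(Ez, 1, 0) + zshift(Ez, -1, 0) + zshift(Ez, 0, 1) + zshift(Ez, 0, -1)
  (nb_sum - nb_cnt * Fz) / h^2
}

#' Explicit Euler-Maruyama step of an extracellular field
#'
#' Advances `df/dt = D Lap f + S - k f + kappa1 f dW` on the extracellular
#' nodes with no-flux boundaries at the outer rectangle and at each membrane.
#' The requested step is internally subdivided to satisfy the explicit
#' diffusion CFL condition; the multiplicative noise increment per substep is
#' i.i.d. Normal(0, dt_sub) per node, so the variance accumulated over `dt`
#' matches the nominal step. Negative excursions are clamped to zero and
#' counted.
#'
#' @param field An `ms_field`.
#' @param source Source-rate matrix (per time-unit), or a scalar.
#' @param ext Logical extracellular mask.
#' @param dt Time step in time-units (e.g. 4e-4).
#' @param decay_rate Optional decay-rate matrix overriding the scalar
#'   `k_decay` (used for Bar1-enhanced alpha-factor degradation).
#' @export
step_field <- function(field, source, ext, dt, decay_rate = NULL) {
  g <- field$grid
  D <- field$D
  dt_cfl <- 0.2 * g$h^2 / max(D, 1e-12)
  m <- max(1L, ceiling(dt / dt_cfl))
  dts <- dt / m
  F <- field$values
  k <- if (is.null(decay_rate)) field$k_decay else decay_rate
  S <- if (length(source) == 1) matrix(source, g$nx, g$ny) else source
  nsel <- which(ext)
  for (i in seq_len(m)) {
    lap <- masked_laplacian(F, ext, g$h)
    dF <- D * lap + S - k * F
    if (field$kappa1 > 0) {
      dW <- matrix(0, g$nx, g$ny)
      dW[nsel] <- stats::rnorm(length(nsel), sd = sqrt(dts))
      dF <- dF + field$kappa1 * F * dW / dts
    }
    F <- F + dts * dF
    neg <- F < 0
    if (any(neg)) {
      field$clamp_count <- field$clamp_count + sum(neg & ext)
      F[neg] <- 0
    }
    F[!ext] <- 0
    if (anyNA(F)) stop("NaN encountered in step_field")
  }
  field$step_count <- field$step_count + length(nsel) * m
  field$values <- F
  field
}

#' Bar1-dependent effective decay rate for alpha-factor
#'
#' `rate(x) = k_alpha + k_deg * B(x) / (max B + eps)`: the protease field,
#' normalised by its global maximum, adds to the basal decay wherever Bar1
#' accumulates.
#'
#' @param B Bar1 concentration matrix (or `ms_field`).
#' @param k_alpha Basal alpha-factor decay (1/time-unit).
#' @param k_deg Maximal Bar1-mediated extra decay (1/time-unit).
#' @param eps Guard against an identically zero field (default 1e-6).
#' @export
effective_alpha_decay <- function(B, k_alpha, k_deg, eps = 1e-6) {
  if (inherits(B, "ms_field")) B <- B$values
  k_alpha + k_deg * B / (max(B) + eps)
}

#' Quasi-steady-state solve of a diffusion-decay-source balance
#'
#' Solves `D Lap f - k f + S = 0` on the extracellular nodes with the same
#' no-flux boundary conditions as [step_field()], via a sparse symmetric
#' positive-definite solve. This is the fast replacement for explicitly
#' time-stepping a field whose relaxation is much faster than membrane
#' motion.
#'
#' @param grid An [ms_grid()].
#' @param ext Logical extracellular mask.
#' @param D Diffusion constant (um^2/time-unit).
#' @param rate Decay rate: scalar or matrix (must be positive somewhere;
#'   a pure-Neumann zero-decay system is singular and rejected).
#' @param source Source matrix or scalar.
#' @param op Optional prebuilt operator from [qss_operator()] for repeated
#'   solves with the same mask/rate.
#' @return Matrix of steady-state values (zero on non-exterior nodes).
#' @export
qss_solve <- function(grid, ext, D, rate, source, op = NULL) {
  if (is.null(op)) op <- qss_operator(grid, ext, D, rate)
  S <- if (length(source) == 1) matrix(source, grid$nx, grid$ny) else source
  b <- S[op$sel]
  f <- as.numeric(Matrix::solve(op$chol, b))
  out <- matrix(0, grid$nx, grid$ny)
  out[op$sel] <- pmax(f, 0)
  out
}

#' @rdname qss_solve
#' @export
qss_operator <- function(grid, ext, D, rate) {
  sel <- which(ext)
  M <- length(sel)
  if (M == 0) stop("empty extracellular mask")
  rate_v <- if (length(rate) == 1) rep(rate, M) else rate[sel]
  if (min(rate_v) <= 0)
    stop("qss_solve requires a strictly positive decay rate (pure-Neumann system is singular)")
  idx <- matrix(NA_integer_, grid$nx, grid$ny)
  idx[sel] <- seq_len(M)
  ii <- ((sel - 1L) %% grid$nx) + 1L
  jj <- ((sel - 1L) %/% grid$nx) + 1L
  edges_i <- integer(0); edges_j <- integer(0)
  for (d in list(c(1L, 0L), c(0L, 1L))) {
    i2 <- ii + d[1]; j2 <- jj + d[2]
    ok <- i2 >= 1 & i2 <= grid$nx & j2 >= 1 & j2 <= grid$ny
    nb <- idx[cbind(i2[ok], j2[ok])]
    keep <- !is.na(nb)
    edges_i <- c(edges_i, which(ok)[keep])
    edges_j <- c(edges_j, nb[keep])
  }
  w <- D / grid$h^2
  deg <- tabulate(c(edges_i, edges_j), nbins = M)
  A <- Matrix::sparseMatrix(
    i = c(seq_len(M), edges_i, edges_j),
    j = c(seq_len(M), edges_j, edges_i),
    x = c(deg * w + rate_v, rep(-w, 2 * length(edges_i))),
    dims = c(M, M), symmetric = FALSE
  )
  ch <- Matrix::Cholesky(methods::as(A, "symmetricMatrix"), LDL = FALSE)
  list(chol = ch, sel = sel)
}

#' Sample a field on a membrane and apply the dynamic-range normalisation
#'
#' Bilinearly interpolates the field at each marker using extracellular-side
#' nodes only (interior nodes hold no ligand), then normalises by the
#' membrane maximum and offsets: `f_tilde = f / max_S f + 0.1`, where S is
#' the cell's own membrane. A zero membrane maximum yields the flat guard
#' value 0.1.
#'
#' @param values Field matrix (or `ms_field`).
#' @param grid An [ms_grid()].
#' @param curve An `ms_curve`.
#' @param ext Logical extracellular mask.
#' @return List with `f` (raw per-marker samples) and `f_tilde`.
#' @export
sample_and_normalize <- function(values, grid, curve, ext) {
  if (inherits(values, "ms_field")) values <- values$values
  f <- sample_field_at(values, grid, curve, ext)
  mx <- max(f)
  f_tilde <- if (mx > 0) f / mx + 0.1 else rep(0.1, length(f))
  list(f = f, f_tilde = f_tilde)
}

# exterior-weighted bilinear sampling at the markers; markers sitting on a
# grid-tangent point with no exterior corner inherit the nearest valid sample
sample_field_at <- function(values, grid, curve, ext) {
  f <- bilinear_at(grid, values, curve$points, weights = ext * 1)
  bad <- !is.finite(f)
  if (any(bad) && !all(bad)) {
    n <- length(f)
    idx_ok <- which(!bad)
    for (i in which(bad)) {
      ring_d <- pmin(abs(idx_ok - i), n - abs(idx_ok - i))
      f[i] <- f[idx_ok[which.min(ring_d)]]
    }
  }
  f[!is.finite(f)] <- 0
  pmax(f, 0)
}
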