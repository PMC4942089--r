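#' Specification of one cell in a mating scenario
#'
#' @param id Cell identifier.
#' @param type "a" or "alpha".
#' @param center Initial centre (um).
#' @param radius Initial radius (um, default 1).
#' @param bar1 Bar1 protease secretion (a-cells only; default FALSE, i.e.
#'   bar1-delta).
#' @param supersensitive Supersensitive sensing (beta1 = 2.5 instead of 0.92).
#' @param producer For alpha-cells: whether the cell secretes alpha-factor
#'   (non-producers are the decoys of the discrimination assay). a-cells
#'   always secrete a-factor.
#' @export
cell_spec <- function(id, type = c("a", "alpha"), center, radius = 1,
                      bar1 = FALSE, supersensitive = FALSE, producer = TRUE) {
  type <- match.arg(type)
  if (bar1 && type != "a") stop("bar1 is only meaningful for a-cells")
  if (!producer && type != "alpha") stop("producer flag applies to alpha-cells")
  list(id = id, type = type, center = as.numeric(center), radius = radius,
       bar1 = bar1, supersensitive = supersensitive, producer = producer)
}

#' Build a named mating scenario
#'
#' Populates the full configuration for one of the canonical geometries:
#' \describe{
#'   \item{two_cell}{a-cell at (-2,0), alpha-cell at (2,0), domain
#'     \eqn{[-3.6,3.6]\times[-1.6,1.6]}.}
#'   \item{two_cell_close}{same, centres 2.5 um apart (0.5 um boundary gap).}
#'   \item{three_cell_discrim}{a-cell at (-2,0); alpha producer at (1,2),
#'     alpha non-producer at (1,-2), domain \eqn{[-3.6,3.6]^2} (large enough
#'     to hold every cell and its membrane band).}
#'   \item{three_cell_compete}{mirror of the discrimination triangle: one
#'     alpha producer at (-2,0); Bar1+ a-cell at (1,2) and bar1-delta a-cell
#'     at (1,-2).}
#'   \item{three_cell_offset}{two alpha producers at (1,2)/(1,-2) and the
#'     a-cell 0.1 um below the midline at (-2,-0.1).}
#'   \item{five_cell_discrim}{a-cell at the origin, four alpha-cells at
#'     (+-2,+-2) of which only (2,2) produces, domain
#'     \eqn{[-3.72,3.72]^2}.}
#' }
#'
#' @param name Scenario name.
#' @param overrides Named list of configuration overrides; `numerics` and
#'   `polarity` entries are merged element-wise.
#' @return A `ms_config` list with all model parameters (paper-default
#'   physics) and solver settings.
#' @export
build_scenario <- function(name = c("two_cell", "two_cell_close",
                                    "three_cell_discrim", "three_cell_compete",
                                    "three_cell_offset", "five_cell_discrim"),
                           overrides = list()) {
  name <- match.arg(name)
  geo <- switch(name,
    two_cell = list(
      grid = c(-3.6, 3.6, -1.6, 1.6),
      cells = list(cell_spec("a1", "a", c(-2, 0)),
                   cell_spec("alpha1", "alpha", c(2, 0)))),
    two_cell_close = list(
      grid = c(-3.6, 3.6, -1.6, 1.6),
      cells = list(cell_spec("a1", "a", c(-1.25, 0)),
                   cell_spec("alpha1", "alpha", c(1.25, 0)))),
    three_cell_discrim = list(
      grid = c(-3.6, 3.6, -3.6, 3.6),
      cells = list(cell_spec("a1", "a", c(-2, 0)),
                   cell_spec("alpha1", "alpha", c(1, 2), producer = TRUE),
                   cell_spec("alpha2", "alpha", c(1, -2), producer = FALSE))),
    three_cell_compete = list(
      grid = c(-3.6, 3.6, -3.6, 3.6),
      cells = list(cell_spec("alpha1", "alpha", c(-2, 0)),
                   cell_spec("a1", "a", c(1, 2), bar1 = TRUE),
                   cell_spec("a2", "a", c(1, -2), bar1 = FALSE))),
    three_cell_offset = list(
      grid = c(-3.6, 3.6, -3.6, 3.6),
      cells = list(cell_spec("a1", "a", c(-2, -0.1)),
                   cell_spec("alpha1", "alpha", c(1, 2)),
                   cell_spec("alpha2", "alpha", c(1, -2)))),
    five_cell_discrim = list(
      grid = c(-3.72, 3.72, -3.72, 3.72),
      cells = list(cell_spec("a1", "a", c(0, 0)),
                   cell_spec("alpha1", "alpha", c(2, 2), producer = TRUE),
                   cell_spec("alpha2", "alpha", c(-2, 2), producer = FALSE),
                   cell_spec("alpha3", "alpha", c(-2, -2), producer = FALSE),
                   cell_spec("alpha4", "alpha", c(2, -2), producer = FALSE)))
  )
  cfg <- list(
    name = name,
    grid_bounds = geo$grid,
    h = 0.04,
    cells = geo$cells,
    # extracellular physics (um^2/time-unit, 1/time-unit; 1 time-unit = 100 s)
    D_alpha = 100, D_a = 10, k_alpha = 1, k_a = 1,
    D_B = 10, k_B = 1, k_deg = 50, bar1_ratio = 1 / 50, eps_B = 1e-6,
    # noise
    kappa1 = 5, kappa2 = 3, kappa3 = 0.1,
    # growth and sources
    Vamp = 2e-4, source_mode = "polarized", background_C = 0,
    secretion_off = FALSE, exogenous_level = 0,
    # time control (seconds unless noted)
    T_end = 1800, dt_membrane = 0.01, dt_field = 4e-4, sample_interval = 50,
    time_unit = 100,
    solver_mode = "qss",
    success_threshold = NULL,   # NULL = the mesh size h (0.04 on the default grid)
    polarity = polarity_params(),
    numerics = list(
      n_markers = 400, qss_interval = 10, ls_interval = 5, reinit_every = 10,
      geom_refresh = 4, band_factor = 6, contact_gap = 0.02,
      smooth_frac = 0.08, ema_steps = 30,
      onset_ratio = 2, tau = 0.4,
      # QSS-mode emulation of the explicit scheme's membrane-level field
      # noise: relative sd = noise_coef * kappa1 / sqrt(D), angular
      # correlation length noise_corr_len um (both measured against explicit
      # Euler-Maruyama stepping on a small fixture)
      noise_coef = 0.067, noise_corr_len = 0.4
    )
  )
  apply_overrides(cfg, overrides)
}

apply_overrides <- function(cfg, overrides) {
  if (length(overrides) == 0) return(structure(cfg, class = "ms_config"))
  if (is.null(names(overrides)) || any(names(overrides) == ""))
    stop("overrides must be a fully named list")
  for (k in names(overrides)) {
    if (!k %in% names(cfg)) stop("unknown configuration key: ", k)
    if (k %in% c("numerics", "polarity")) {
      sub <- overrides[[k]]
      bad <- setdiff(names(sub), names(cfg[[k]]))
      if (length(bad)) stop("unknown ", k, " key(s): ", paste(bad, collapse = ", "))
      cfg[[k]][names(sub)] <- sub
    } else {
      cfg[[k]] <- overrides[[k]]
    }
  }
  validate_config(cfg)
  structure(cfg, class = "ms_config")
}

validate_config <- function(cfg) {
  if (cfg$Vamp < 0) stop("invalid value for Vamp: must be >= 0")
  if (cfg$background_C < 0) stop("invalid value for background_C: must be >= 0")
  if (!cfg$source_mode %in% c("polarized", "isotropic"))
    stop("source_mode must be 'polarized' or 'isotropic'")
  if (!cfg$solver_mode %in% c("qss", "explicit"))
    stop("solver_mode must be 'qss' or 'explicit'")
  for (nm in c("D_alpha", "D_a", "k_alpha", "k_a", "T_end", "dt_membrane", "h"))
    if (cfg[[nm]] <= 0) stop("invalid value for ", nm, ": must be > 0")
  invisible(cfg)
}

# genotype-resolved polarity parameters for one cell
cell_polarity_params <- function(cfg, cell) {
  p <- cfg$polarity
  p$kappa2 <- cfg$kappa2
  p$kappa3 <- cfg$kappa3
  if (isTRUE(cell$supersensitive)) p$beta1 <- 2.5
  p
}

#' Run one mating simulation
#'
#' Orchestrates the coupled system: extracellular pheromone/protease fields
#' (quasi-steady-state sparse solves, or explicit stepping), per-cell
#' membrane polarity dynamics, polarisome localisation, the normal-velocity
#' law, and level-set evolution of every membrane, with periodic
#' reinitialisation and marker resampling. Samples are collected every
#' `sample_interval` seconds and the run stops at mating success (polarisome
#' contact with an approaching trend) or at `T_end`.
#'
#' @param config An `ms_config` from [build_scenario()].
#' @param seed Integer seed; the run is deterministic given (config, seed).
#' @return An `ms_result` list: `success`, `mating_time`, `partner` (ids of
#'   the successful a/alpha pair), per-sample `samples` data frame, pairwise
#'   polarisome `pair_dist` data frame, `final_curves`, `events` counters.
#' @export
run_simulation <- function(config, seed = 1) {
  cfg <- config
  set.seed(seed)
  nm <- cfg$numerics
  g <- ms_grid(cfg$grid_bounds[1], cfg$grid_bounds[2],
               cfg$grid_bounds[3], cfg$grid_bounds[4], cfg$h)
  band_hw <- nm$band_factor * g$h
  dt_s <- cfg$dt_membrane * cfg$time_unit          # membrane step in seconds
  n_steps <- ceiling(cfg$T_end / dt_s)
  sample_every <- max(1L, round(cfg$sample_interval / dt_s))
  nodes_xy <- grid_nodes(g)

  ncell <- length(cfg$cells)
  cells <- vector("list", ncell)
  for (i in seq_len(ncell)) {
    spec <- cfg$cells[[i]]
    ls <- init_circle_levelset(spec$center, spec$radius, g, spec$id)
    curve <- extract_membrane_curve(ls, nm$n_markers)
    pp <- cell_polarity_params(cfg, spec)
    st <- polarity_state(nm$n_markers, pp)
    cells[[i]] <- list(
      spec = spec, ls = ls, curve = curve, params = pp, state = st,
      u2f = st$u2, polarized = FALSE, pol = list(found = FALSE),
      V_accum = rep(0, nm$n_markers), f_det = rep(0, nm$n_markers),
      band_sel = NULL, band_nn = NULL, ls_steps = 0L
    )
  }
  any_bar1 <- any(vapply(cells, function(cl) isTRUE(cl$spec$bar1), logical(1)))
  has_alpha_src <- any(vapply(cells, function(cl)
    cl$spec$type == "alpha" && isTRUE(cl$spec$producer), logical(1))) ||
    cfg$background_C > 0

  refresh_geometry <- function(cl) {
    sel <- which(abs(cl$ls$phi) <= band_hw)
    nn <- nearest_point(nodes_xy[sel, , drop = FALSE], cl$curve$points)
    cl$band_sel <- sel
    cl$band_nn <- nn$idx
    # angular interpolation weights from band nodes onto the marker ring
    # (smooth and symmetric, unlike nearest-marker tie-breaking)
    cen <- cl$curve$centroid
    th_m <- atan2(cl$curve$points[, 2] - cen[2], cl$curve$points[, 1] - cen[1])
    ord <- order(th_m)
    th_s <- th_m[ord]
    th_n <- atan2(nodes_xy[sel, 2] - cen[2], nodes_xy[sel, 1] - cen[1])
    pos <- findInterval(th_n, th_s)
    m <- length(ord)
    lo <- ifelse(pos == 0L, m, pos)
    hi <- ifelse(pos == m, 1L, pos + 1L)
    th_lo <- th_s[lo]; th_hi <- th_s[hi]
    gap <- (th_hi - th_lo) %% (2 * pi)
    gap[gap < 1e-12] <- 1e-12
    wfrac <- ((th_n - th_lo) %% (2 * pi)) / gap
    cl$band_i1 <- ord[lo]
    cl$band_i2 <- ord[hi]
    cl$band_w2 <- pmin(pmax(wfrac, 0), 1)
    cl
  }
  cells <- lapply(cells, refresh_geometry)

  masks <- region_masks(lapply(cells, `[[`, "ls"), g, band_hw)
  ext <- masks$exterior
  ops <- list(a = NULL, alpha = NULL, B = NULL)   # cached QSS factorisations
  f_alpha_grid <- matrix(0, g$nx, g$ny)
  f_a_grid <- matrix(0, g$nx, g$ny)
  B_grid <- matrix(0, g$nx, g$ny)
  if (cfg$solver_mode == "explicit") {
    fld_alpha <- extracellular_field(g, cfg$D_alpha, cfg$k_alpha, cfg$kappa1, "alpha_factor")
    fld_a <- extracellular_field(g, cfg$D_a, cfg$k_a, cfg$kappa1, "a_factor")
    fld_B <- extracellular_field(g, cfg$D_B, cfg$k_B, 0, "bar1")
  }

  events <- c(reinit = 0L, resample = 0L, contact = 0L, refactor = 0L,
              split = 0L)

  # membrane-band source for one cell, using cached nearest-marker indices
  cell_source <- function(cl, scale = 1) {
    S <- matrix(0, g$nx, g$ny)
    sel <- cl$band_sel
    phi_b <- cl$ls$phi[sel]
    use_polar <- cfg$source_mode == "polarized" && cl$polarized &&
      max(cl$u2f) > 0
    if (use_polar) {
      u2b <- (1 - cl$band_w2) * cl$u2f[cl$band_i1] + cl$band_w2 * cl$u2f[cl$band_i2]
      u2n <- u2b / max(cl$u2f)
      S[sel] <- scale * SOURCE_AMPLITUDE * exp(-100 * phi_b^2 - 20 * (1 - u2n)^2)
    } else {
      S[sel] <- scale * SOURCE_AMPLITUDE * exp(-100 * phi_b^2)
    }
    S
  }

  update_fields <- function(force_refactor = FALSE) {
    if (isTRUE(cfg$secretion_off)) {
      # pheromoneless control: no sources, exogenous uniform pheromone
      f_alpha_grid <<- cfg$exogenous_level * ext
      f_a_grid <<- cfg$exogenous_level * ext
      for (i in seq_len(ncell)) {
        fld <- if (cells[[i]]$spec$type == "a") f_alpha_grid else f_a_grid
        cells[[i]]$f_det <<- sample_field_at(fld, g, cells[[i]]$curve, ext)
      }
      return(invisible(NULL))
    }
    S_a <- matrix(0, g$nx, g$ny)
    S_alpha <- matrix(0, g$nx, g$ny)
    S_B <- matrix(0, g$nx, g$ny)
    for (cl in cells) {
      if (cl$spec$type == "a") {
        S_a <- S_a + cell_source(cl)
        if (isTRUE(cl$spec$bar1)) S_B <- S_B + cell_source(cl, cfg$bar1_ratio)
      } else if (isTRUE(cl$spec$producer)) {
        S_alpha <- S_alpha + cell_source(cl)
      }
    }
    if (cfg$background_C > 0) S_alpha <- S_alpha + cfg$background_C * ext

    if (cfg$solver_mode == "qss") {
      if (force_refactor) ops <<- list(a = NULL, alpha = NULL, B = NULL)
      if (is.null(ops$a)) ops$a <<- qss_operator(g, ext, cfg$D_a, cfg$k_a)
      f_a_grid <<- qss_solve(g, ext, cfg$D_a, cfg$k_a, S_a, op = ops$a)
      if (any_bar1) {
        if (is.null(ops$B)) ops$B <<- qss_operator(g, ext, cfg$D_B, cfg$k_B)
        B_grid <<- qss_solve(g, ext, cfg$D_B, cfg$k_B, S_B, op = ops$B)
        rate <- effective_alpha_decay(B_grid, cfg$k_alpha, cfg$k_deg, cfg$eps_B)
        # the Bar1-modulated decay field drifts with the slow geometry;
        # refactor the alpha operator only when it has moved appreciably
        if (is.null(ops$alpha) || is.null(ops$alpha_rate) ||
            max(abs(rate - ops$alpha_rate)) > 0.25 * cfg$k_deg) {
          ops$alpha <<- qss_operator(g, ext, cfg$D_alpha, rate)
          ops$alpha_rate <<- rate
          events["refactor"] <<- events["refactor"] + 1L
        }
      } else if (is.null(ops$alpha)) {
        ops$alpha <<- qss_operator(g, ext, cfg$D_alpha, cfg$k_alpha)
      }
      if (has_alpha_src)
        f_alpha_grid <<- qss_solve(g, ext, cfg$D_alpha, cfg$k_alpha, S_alpha,
                                   op = ops$alpha)
    } else {
      dt_tu <- cfg$dt_membrane * nm$qss_interval
      fld_a <<- step_field(fld_a, S_a, ext, dt_tu)
      f_a_grid <<- fld_a$values
      if (any_bar1) {
        fld_B <<- step_field(fld_B, S_B, ext, dt_tu)
        B_grid <<- fld_B$values
        rate <- effective_alpha_decay(B_grid, cfg$k_alpha, cfg$k_deg, cfg$eps_B)
        fld_alpha <<- step_field(fld_alpha, S_alpha, ext, dt_tu, decay_rate = rate)
      } else {
        fld_alpha <<- step_field(fld_alpha, S_alpha, ext, dt_tu)
      }
      f_alpha_grid <<- fld_alpha$values
    }
    # deterministic membrane samples (per-step noise is applied separately)
    for (i in seq_len(ncell)) {
      fld <- if (cells[[i]]$spec$type == "a") f_alpha_grid else f_a_grid
      cells[[i]]$f_det <<- sample_field_at(fld, g, cells[[i]]$curve, ext)
    }
  }
  update_fields()

  success_thr <- if (is.null(cfg$success_threshold)) g$h else cfg$success_threshold

  # sampling records
  samples <- list(); pair_rows <- list()
  success <- FALSE; mating_time <- NA_real_; partner <- c(NA_character_, NA_character_)
  a_idx <- which(vapply(cells, function(cl) cl$spec$type == "a", logical(1)))
  al_idx <- which(vapply(cells, function(cl) cl$spec$type == "alpha", logical(1)))
  pair_hist <- list()
  pair_winmin <- list()   # continuous minimum within the current sample window

  ls_counter <- 0L

  for (step in seq_len(n_steps)) {
    t_now <- step * dt_s
    if ((step - 1L) %% nm$qss_interval == 0L && step > 1L) update_fields()

    # per-cell membrane dynamics
    for (i in seq_len(ncell)) {
      cl <- cells[[i]]
      n_mk <- length(cl$f_det)
      f <- cl$f_det
      if (cfg$kappa1 > 0 && cfg$solver_mode == "qss") {
        # membrane-level external noise matching the explicit scheme's
        # stationary statistics: relative sd noise_coef*kappa1/sqrt(D),
        # smoothed to the measured angular correlation length
        D_sensed <- if (cl$spec$type == "a") cfg$D_alpha else cfg$D_a
        sig <- nm$noise_coef * cfg$kappa1 / sqrt(D_sensed)
        wn <- max(3L, round(nm$noise_corr_len / cl$curve$ds))
        z <- smooth_membrane(stats::rnorm(n_mk), wn / n_mk) * sqrt(wn)
        f <- pmax(f * (1 + sig * z), 0)
      }
      mx <- max(f)
      f_tilde <- if (mx > 0) f / mx + 0.1 else rep(0.1, n_mk)
      cl$state <- step_polarity(cl$state, f_tilde, cl$params,
                                cfg$dt_membrane, cl$curve$length)
      u2s <- smooth_membrane(cl$state$u2, nm$smooth_frac)
      cl$u2f <- cl$u2f + (u2s - cl$u2f) / nm$ema_steps
      if (!cl$polarized &&
          max(cl$state$u2) > nm$onset_ratio * mean(cl$state$u2))
        cl$polarized <- TRUE
      # the recorded polarisome follows raw u2 (its defining species);
      # the growth direction uses the filtered profile for a steady d_max
      cl$pol <- locate_polarisome(cl$state$u2, cl$curve, nm$tau)
      cl$pol_f <- locate_polarisome(cl$u2f, cl$curve, nm$tau)
      V <- if (cl$polarized) {
        membrane_velocity(cl$u2f, cl$curve, cl$pol_f, cfg$Vamp)
      } else rep(0, n_mk)
      cl$V_accum <- cl$V_accum + V
      cells[[i]] <- cl
    }

    # level-set advance on the slow cadence
    if (step %% nm$ls_interval == 0L) {
      ls_counter <- ls_counter + 1L
      geometry_changed <- FALSE
      for (i in seq_len(ncell)) {
        cl <- cells[[i]]
        V_avg <- cl$V_accum / nm$ls_interval
        cl$V_accum <- rep(0, length(cl$V_accum))
        if (max(V_avg) <= 0) { cells[[i]] <- cl; next }
        # contact handling: freeze growth where another membrane is close
        # and the outward normal points into it (markers sliding along the
        # interface keep growing, so tips can still align)
        for (j in seq_len(ncell)) {
          if (j == i) next
          # bounding-box gap rules out contact long before marker distances
          pj <- cells[[j]]$curve$points
          gap_x <- max(min(pj[, 1]) - max(cl$curve$points[, 1]),
                       min(cl$curve$points[, 1]) - max(pj[, 1]))
          gap_y <- max(min(pj[, 2]) - max(cl$curve$points[, 2]),
                       min(cl$curve$points[, 2]) - max(pj[, 2]))
          if (max(gap_x, gap_y) > 5 * nm$contact_gap) next
          nnc <- nearest_point(cl$curve$points, pj)
          toward <- rowSums(cl$curve$normals *
            (cells[[j]]$curve$points[nnc$idx, , drop = FALSE] - cl$curve$points)) > 0
          close_by <- nnc$dist < nm$contact_gap & toward
          if (any(close_by & V_avg > 0)) {
            V_avg[close_by] <- 0
            events["contact"] <- events["contact"] + 1L
          }
        }
        if (max(V_avg) <= 0) { cells[[i]] <- cl; next }
        Vg <- matrix(0, g$nx, g$ny)
        Vg[cl$band_sel] <- (1 - cl$band_w2) * V_avg[cl$band_i1] +
          cl$band_w2 * V_avg[cl$band_i2]
        dt_ls <- dt_s * nm$ls_interval
        n_sub <- max(1L, ceiling(max(abs(Vg)) * dt_ls / (0.5 * g$h)))
        for (ksub in seq_len(n_sub))
          cl$ls <- advance_levelset(cl$ls, Vg, dt_ls / n_sub)
        if (cl$ls_steps %% nm$reinit_every == nm$reinit_every - 1L) {
          cl$ls <- reinitialize_signed_distance(cl$ls, cl$curve, band_hw)
          events["reinit"] <- events["reinit"] + 1L
        }
        cl$ls_steps <- cl$ls_steps + 1L
        refresh_now <- cl$ls_steps %% nm$geom_refresh == 0L ||
          cl$ls_steps %% nm$reinit_every == 0L
        new_curve <- extract_membrane_curve(cl$ls, nm$n_markers,
                                            keep_largest = TRUE)
        if (isTRUE(new_curve$split)) {
          # a speck pinched off: rebuild phi from the main membrane so the
          # phantom island does not pollute the masks
          cl$ls$phi <- signed_distance_from_curve(g, new_curve)
          events["split"] <- events["split"] + 1L
        }
        carried <- resample_membrane_state(
          c(cl$state, list(u2f = cl$u2f)), cl$curve, new_curve)
        cl$state <- carried[c("u1", "v1", "u2", "v2")]
        cl$u2f <- carried$u2f
        cl$curve <- new_curve
        # the band mapping drifts by well under h between refreshes; rebuild
        # it on a slower cadence than the curve itself
        if (refresh_now || isTRUE(new_curve$split)) cl <- refresh_geometry(cl)
        events["resample"] <- events["resample"] + 1L
        geometry_changed <- TRUE
        cells[[i]] <- cl
      }
      if (geometry_changed) {
        new_masks <- region_masks(lapply(cells, `[[`, "ls"), g, band_hw)
        if (!identical(new_masks$exterior, ext)) {
          ext <- new_masks$exterior
          ops <- list(a = NULL, alpha = NULL, B = NULL)
          events["refactor"] <- events["refactor"] + 1L
        }
      }
    }

    # continuous tracking of pairwise polarisome distance (the success rule
    # uses the minimum distance, which can be attained between samples)
    for (ia in a_idx) for (ja in al_idx) {
      pa <- cells[[ia]]$pol; pb <- cells[[ja]]$pol
      if (pa$found && pb$found) {
        d_now <- sqrt(sum((pa$position - pb$position)^2))
        key <- paste(cells[[ia]]$spec$id, cells[[ja]]$spec$id, sep = "|")
        cur <- pair_winmin[[key]]
        if (is.null(cur) || d_now < cur) pair_winmin[[key]] <- d_now
      }
    }

    # sampling and mating detection
    if (step %% sample_every == 0L) {
      for (i in seq_len(ncell)) {
        cl <- cells[[i]]
        pl <- projection_length(cl$curve)
        samples[[length(samples) + 1L]] <- data.frame(
          time = t_now, cell_id = cl$spec$id,
          pol_found = cl$pol$found,
          pol_x = if (cl$pol$found) cl$pol$position[1] else NA_real_,
          pol_y = if (cl$pol$found) cl$pol$position[2] else NA_real_,
          pol_angle = if (cl$pol$found) cl$pol$angle else NA_real_,
          u2_max = max(cl$state$u2), u2_mean = mean(cl$state$u2),
          perimeter = cl$curve$length, proj_len = pl,
          stringsAsFactors = FALSE)
      }
      for (ia in a_idx) for (ja in al_idx) {
        pa <- cells[[ia]]$pol; pb <- cells[[ja]]$pol
        d <- if (pa$found && pb$found)
          sqrt(sum((pa$position - pb$position)^2)) else NA_real_
        key <- paste(cells[[ia]]$spec$id, cells[[ja]]$spec$id, sep = "|")
        dmin <- pair_winmin[[key]]
        if (is.null(dmin)) dmin <- d
        pair_winmin[[key]] <- NULL
        pair_hist[[key]] <- c(pair_hist[[key]], dmin)
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          time = t_now, a_id = cells[[ia]]$spec$id,
          alpha_id = cells[[ja]]$spec$id, dist = d, dist_min = dmin,
          stringsAsFactors = FALSE)
        det <- detect_mating_series(pair_hist[[key]], success_thr,
                                    current_min = dmin)
        if (det && !success) {
          success <- TRUE
          mating_time <- t_now
          partner <- c(cells[[ia]]$spec$id, cells[[ja]]$spec$id)
        }
      }
      if (success) break
    }
  }

  structure(list(
    success = success, mating_time = mating_time,
    partner = partner, seed = seed, scenario = cfg$name,
    samples = do.call(rbind, samples),
    pair_dist = do.call(rbind, pair_rows),
    final_curves = lapply(cells, function(cl)
      list(id = cl$spec$id, type = cl$spec$type, points = cl$curve$points,
           u2 = cl$state$u2, center0 = cl$spec$center,
           pol = cl$pol)),
    events = events, config = cfg
  ), class = "ms_result")
}

# success test on one pair's sampled distance series: minimum distance over
# the current sample window below threshold, and approaching on average over
# the trailing five samples
detect_mating_series <- function(d, threshold = 0.04, window = 5L,
                                 current_min = NULL) {
  k <- length(d)
  if (k < window) return(FALSE)
  recent <- d[(k - window + 1L):k]
  if (anyNA(recent)) return(FALSE)
  dmin <- if (is.null(current_min)) d[k] else current_min
  dmin < threshold && (recent[window] - recent[1]) < 0
}

#' Mating-success test on a sampled polarisome-distance series
#'
#' A pair of cells has mated at the first sample where the polarisome
#' distance is below `threshold` (default 0.04 um) and the distance has on
#' average decreased over the trailing five samples (the projections are
#' growing toward one another, not sliding past).
#'
#' @param result An `ms_result`.
#' @param threshold Distance threshold in um.
#' @return List with `success`, `time`, `a_id`, `alpha_id`.
#' @export
detect_mating <- function(result, threshold = 0.04) {
  pd <- result$pair_dist
  if (is.null(pd) || nrow(pd) == 0)
    return(list(success = FALSE, time = NA_real_,
                a_id = NA_character_, alpha_id = NA_character_))
  for (key in unique(paste(pd$a_id, pd$alpha_id, sep = "|"))) {
    ids <- strsplit(key, "|", fixed = TRUE)[[1]]
    sub <- pd[pd$a_id == ids[1] & pd$alpha_id == ids[2], ]
    sub <- sub[order(sub$time), ]
    dmin <- if ("dist_min" %in% names(sub)) sub$dist_min else sub$dist
    for (k in seq_len(nrow(sub))) {
      if (detect_mating_series(dmin[seq_len(k)], threshold,
                               current_min = dmin[k]))
        return(list(success = TRUE, time = sub$time[k],
                    a_id = ids[1], alpha_id = ids[2]))
    }
  }
  list(success = FALSE, time = NA_real_,
       a_id = NA_character_, alpha_id = NA_character_)
}

#' Mating-projection length of a membrane curve
#'
#' Distance from the initial cell centre to the farthest membrane point,
#' minus the initial radius (floored at zero): the length of the shmoo.
#'
#' @param curve An `ms_curve` (carries `center0`, `radius0`).
#' @export
projection_length <- function(curve) {
  r <- sqrt((curve$points[, 1] - curve$center0[1])^2 +
              (curve$points[, 2] - curve$center0[2])^2)
  max(max(r) - curve$radius0, 0)
}

#' @exportS3Method base::print
print.ms_result <- function(x, ...) {
  cat(sprintf("<ms_result %s seed %s: %s%s>\n", x$scenario, x$seed,
              if (x$success) "mated" else "no mating",
              if (x$success) sprintf(" at %g s (%s-%s)", x$mating_time,
                                     x$partner[1], x$partner[2]) else ""))
  invisible(x)
}
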