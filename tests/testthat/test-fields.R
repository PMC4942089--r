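test_that("membrane source matches its closed form on and off the membrane", {
  fx <- unit_circle(h = 0.04)
  A <- 1000 / sqrt(2 * pi)
  S <- membrane_source_field(fx$ls, band = abs(fx$ls$phi) <= 0.4)
  # at a node nearly on the membrane the rate approaches A
  expect_gt(max(S), A * exp(-100 * (fx$grid$h / 2)^2))
  expect_lte(max(S), A)
  # grid values follow the closed form; at phi = 0.3 um it equals A exp(-9)
  i <- which.min(abs(fx$grid$x - 1.3)); j <- which.min(abs(fx$grid$y))
  expect_equal(S[i, j], A * exp(-100 * fx$ls$phi[i, j]^2), tolerance = 1e-10)
  expect_equal(A * exp(-9), 0.04923, tolerance = 1e-3)
  # polarised mode peaks at the polarisome and is tiny at u2 = 0.2 u2max
  th <- atan2(fx$curve$points[, 2], fx$curve$points[, 1])
  u2 <- 0.2 + 0.8 * exp(-(th / 0.4)^2)
  Sp <- membrane_source_field(fx$ls, fx$curve, u2, mode = "polarized",
                              band = abs(fx$ls$phi) <= 0.4)
  front <- which.min((fx$grid$x[col(Sp) * 0 + row(Sp)] - 1)^2)  # placeholder
  i_front <- which.min(abs(fx$grid$x - 1)); j0 <- which.min(abs(fx$grid$y))
  i_back <- which.min(abs(fx$grid$x + 1))
  expect_gt(Sp[i_front, j0], 100)
  expect_lt(Sp[i_back, j0], 0.01 * Sp[i_front, j0])   # exp(-12.8) suppression
  # polarized mode with flat-zero u2 falls back to isotropic
  S0 <- membrane_source_field(fx$ls, fx$curve, u2 * 0, mode = "polarized",
                              band = abs(fx$ls$phi) <= 0.4)
  expect_equal(S0, S, tolerance = 1e-12)
})

test_that("explicit stepping reproduces pure-decay and conserves mass", {
  g <- small_grid(h = 0.1, half = 0.5)
  ext <- matrix(TRUE, g$nx, g$ny)
  f0 <- extracellular_field(g, D = 1, k_decay = 1, kappa1 = 0,
                            values = matrix(1, g$nx, g$ny))
  for (i in 1:100) f0 <- step_field(f0, 0, ext, 0.01)
  expect_equal(max(abs(f0$values - exp(-1))), 0, tolerance = 2e-3)
  # no decay, no source: mass conserved to 1e-6 relative over 1000 steps
  set.seed(7)
  f1 <- extracellular_field(g, D = 1, k_decay = 0, kappa1 = 0,
                            values = matrix(runif(g$nx * g$ny), g$nx, g$ny))
  m0 <- sum(f1$values)
  for (i in 1:1000) f1 <- step_field(f1, 0, ext, 0.005)
  expect_lt(abs(sum(f1$values) / m0 - 1), 1e-6)
})

test_that("multiplicative noise keeps the ensemble mean (martingale property)", {
  g <- small_grid(h = 0.25, half = 0.5)
  ext <- matrix(TRUE, g$nx, g$ny)
  set.seed(11)
  means <- replicate(400, {
    f <- extracellular_field(g, D = 0, k_decay = 0, kappa1 = 2,
                             values = matrix(1, g$nx, g$ny))
    for (i in 1:10) f <- step_field(f, 0, ext, 0.01)
    mean(f$values)
  })
  # mean stays at f0 = 1 within Monte-Carlo error (clamping bias is tiny)
  expect_lt(abs(mean(means) - 1), 3 * stats::sd(means) / sqrt(length(means)) + 0.02)
})

test_that("QSS solve matches the K0 Green's function and simple balances", {
  g <- ms_grid(-6, 6, -6, 6, 0.08)
  ext <- matrix(TRUE, g$nx, g$ny)
  S <- matrix(0, g$nx, g$ny)
  S[which.min(abs(g$x)), which.min(abs(g$y))] <- 1 / g$h^2
  f <- qss_solve(g, ext, D = 1, rate = 1, source = S)
  for (r in c(1, 2, 3)) {
    fa <- besselK(r, 0) / (2 * pi)
    fn <- bilinear_at(g, f, matrix(c(r, 0), 1))
    expect_lt(abs(fn / fa - 1), 0.05)
  }
  # uniform source, no obstacles: f = S/k
  fu <- qss_solve(g, ext, D = 3, rate = 2, source = 10)
  expect_equal(range(fu), c(5, 5), tolerance = 1e-8)
  # zero source: zero field
  expect_equal(max(qss_solve(g, ext, D = 3, rate = 2, source = 0)), 0)
  # zero decay is singular and refused
  expect_error(qss_solve(g, ext, D = 1, rate = 0, source = S), "positive decay")
})

test_that("Bar1-enhanced decay follows B/(max B + eps)", {
  B <- matrix(0, 5, 5)
  expect_equal(effective_alpha_decay(B, 1, 10), matrix(1, 5, 5))
  B1 <- matrix(1, 5, 5)
  expect_equal(effective_alpha_decay(B1, 1, 10)[1, 1], 11, tolerance = 1e-5)
  # pointwise monotone in B
  set.seed(3)
  Br <- matrix(runif(25), 5, 5)
  r1 <- effective_alpha_decay(Br, 1, 10)
  r2 <- effective_alpha_decay(Br * 2, 1, 10)   # same normalised shape
  expect_equal(r1, r2, tolerance = 1e-5)
  Bp <- Br; Bp[2, 2] <- max(Bp) * 1.5
  rp <- effective_alpha_decay(Bp, 1, 10)
  expect_equal(which.max(rp), which.max(Bp))
})

test_that("membrane sampling normalises to f/max + 0.1 with guards", {
  fx <- unit_circle(h = 0.04)
  ext <- fx$ls$phi > 0
  # uniform field -> f_tilde = 1.1 everywhere
  sm <- sample_and_normalize(matrix(5, fx$grid$nx, fx$grid$ny), fx$grid, fx$curve, ext)
  expect_equal(range(sm$f_tilde), c(1.1, 1.1), tolerance = 1e-9)
  # half the membrane max -> 0.6
  grad <- outer(0.5 + 0.5 * (fx$grid$x - min(fx$grid$x)) / diff(range(fx$grid$x)),
                rep(1, fx$grid$ny))
  sm2 <- sample_and_normalize(grad, fx$grid, fx$curve, ext)
  half <- which.min(abs(sm2$f - max(sm2$f) / 2))
  expect_equal(sm2$f_tilde[half], sm2$f[half] / max(sm2$f) + 0.1, tolerance = 1e-9)
  expect_lt(abs(sm2$f_tilde[half] - 0.6), 0.25)
  expect_equal(max(sm2$f_tilde), 1.1, tolerance = 1e-9)
  # zero field -> flat guard value 0.1
  sm0 <- sample_and_normalize(matrix(0, fx$grid$nx, fx$grid$ny), fx$grid, fx$curve, ext)
  expect_equal(range(sm0$f_tilde), c(0.1, 0.1))
})

test_that("QSS equals the explicit steady state on a two-cell fixture", {
  g <- ms_grid(-2, 2, -1.2, 1.2, 0.08)
  lsa <- init_circle_levelset(c(-1, 0), 0.5, g, "a")
  lsb <- init_circle_levelset(c(1, 0), 0.5, g, "b")
  m <- region_masks(list(lsa, lsb), g, 6 * g$h)
  ext <- m$exterior
  S <- membrane_source_field(lsa, band = abs(lsa$phi) <= 6 * g$h)
  fq <- qss_solve(g, ext, D = 5, rate = 1, source = S)
  fe <- extracellular_field(g, D = 5, k_decay = 1, kappa1 = 0)
  for (i in 1:600) fe <- step_field(fe, S, ext, 0.01)
  sel <- ext & fq > max(fq) * 1e-3
  expect_lt(max(abs(fe$values[sel] - fq[sel])) / max(fq), 0.01)
})
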