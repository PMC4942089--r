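# Shared fixtures: small grids and circles, built in code at test time.

small_grid <- function(h = 0.04, half = 2) ms_grid(-half, half, -half, half, h)

unit_circle <- function(h = 0.04, center = c(0, 0), grid = NULL, n = 200L) {
  if (is.null(grid)) grid <- small_grid(h)
  ls1 <- init_circle_levelset(center, 1, grid, "c1")
  list(ls = ls1, grid = grid, curve = extract_membrane_curve(ls1, n))
}

# brute-force polarisome oracle: scan all O(N^2) circular windows for the
# minimal length holding >= tau of the mass; ties resolved by maximal mass
# then smallest start (mirrors the documented rule)
brute_polarisome <- function(u2, tau = 0.4) {
  n <- length(u2)
  tot <- sum(u2)
  best <- NULL
  for (w in 1:n) {
    cand <- NULL
    for (s in 1:n) {
      idx <- ((s - 1 + 0:(w - 1)) %% n) + 1
      m <- sum(u2[idx])
      if (m >= tau * tot - 1e-9 * tot) {
        if (is.null(cand) || m > cand$mass + 1e-12 * tot) cand <- list(start = s, mass = m)
      }
    }
    if (!is.null(cand)) return(list(w = w, start = cand$start))
  }
  NULL
}

# reduced-size two-cell configuration used across simulation tests: coarse
# mesh and marker count keep one run in a few seconds
test_two_cell <- function(...) {
  build_scenario("two_cell", modifyList(
    list(h = 0.08, numerics = list(n_markers = 200)), list(...), keep.null = TRUE))
}

expect_close <- function(x, y, tol) expect_lt(abs(x - y), tol)
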