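# Simulation-level tests run on a coarsened solver mesh (h = 0.08, 200
# markers) so one full run stays in a few seconds; the physical parameters
# are the model defaults throughout.

test_that("scenario builder reproduces the canonical geometries", {
  cfg <- build_scenario("two_cell")
  centers <- t(vapply(cfg$cells, `[[`, numeric(2), "center"))
  expect_equal(centers, rbind(c(-2, 0), c(2, 0)))
  expect_equal(sqrt(sum((centers[1, ] - centers[2, ])^2)), 4)
  expect_equal(cfg$grid_bounds, c(-3.6, 3.6, -1.6, 1.6))
  expect_equal(cfg$D_a, 10); expect_equal(cfg$D_alpha, 100)
  expect_equal(cfg$kappa1, 5); expect_equal(cfg$kappa2, 3)
  expect_equal(cfg$Vamp, 2e-4); expect_equal(cfg$T_end, 1800)

  close <- build_scenario("two_cell_close")
  cc <- t(vapply(close$cells, `[[`, numeric(2), "center"))
  expect_equal(sqrt(sum((cc[1, ] - cc[2, ])^2)), 2.5)  # 0.5 um boundary gap

  five <- build_scenario("five_cell_discrim")
  expect_equal(length(five$cells), 5L)
  producers <- vapply(five$cells, function(cl)
    cl$type == "alpha" && isTRUE(cl$producer), logical(1))
  expect_equal(sum(producers), 1L)   # one producer among four alpha-cells
  expect_equal(five$grid_bounds, c(-3.72, 3.72, -3.72, 3.72))

  off <- build_scenario("three_cell_offset")
  expect_equal(off$cells[[1]]$center, c(-2, -0.1))

  expect_error(build_scenario("nonsense"))
  expect_error(build_scenario("two_cell", list(Vamp = -1)), "Vamp")
  expect_error(build_scenario("two_cell", list(made_up = 3)), "unknown")
})

test_that("mating detection needs both contact and an approaching trend", {
  # straightforward approach ending below threshold
  expect_true(detect_mating_series(c(0.5, 0.3, 0.2, 0.1, 0.03), 0.04))
  # never below threshold
  expect_false(detect_mating_series(c(2, 1.5, 1, 0.6, 0.3, 0.2), 0.04))
  # dip below threshold while the trailing trend is increasing (passing by)
  expect_false(detect_mating_series(c(0.10, 0.2, 0.3, 0.4, 0.5),
                                    0.04, current_min = 0.03))
  # too few samples
  expect_false(detect_mating_series(c(0.2, 0.03), 0.04))
})

test_that("a noise-free two-cell run mates with mirror symmetry", {
  cfg <- test_two_cell(kappa1 = 0, kappa2 = 0, kappa3 = 0)
  r <- run_simulation(cfg, seed = 1)
  expect_true(r$success)
  expect_lt(r$mating_time, cfg$T_end)
  # both polarisomes stay on the inter-cell axis to within one marker
  one_marker <- 2 * pi / 200
  s <- r$samples
  late <- s[s$time > 300, ]
  ang_a <- late$pol_angle[late$cell_id == "a1"]
  ang_al <- late$pol_angle[late$cell_id == "alpha1"]
  expect_lt(max(abs(ang_a)), 1.5 * one_marker)
  expect_lt(max(abs(abs(ang_al) - pi)), 1.5 * one_marker)
  # determinism: same seed, same trajectory
  r2 <- run_simulation(cfg, seed = 1)
  expect_identical(r$samples, r2$samples)
  expect_identical(r$mating_time, r2$mating_time)
})

test_that("projection length measures the shmoo", {
  fx <- unit_circle(h = 0.04)
  expect_equal(projection_length(fx$curve), 0, tolerance = 0.02)
  # synthetic shmoo: stretch some markers outward and compare to a direct scan
  cv <- fx$curve
  cv$points[10:20, ] <- cv$points[10:20, ] * 1.5
  expected <- max(sqrt(rowSums(cv$points^2))) - 1
  expect_equal(projection_length(cv), expected)
  expect_equal(expected, 0.5, tolerance = 1e-3)
})

test_that("pheromoneless cells with uniform exogenous pheromone do not mate", {
  cfg <- test_two_cell(secretion_off = TRUE, exogenous_level = 50)
  r <- run_simulation(cfg, seed = 4)
  expect_false(r$success)
})

test_that("batches summarise efficiency, directions and discrimination", {
  # synthetic batch assembled by hand exercises the summary path
  df <- data.frame(
    seed = 1:20, success = c(rep(TRUE, 15), rep(FALSE, 5)),
    mating_time = c(rep(1000, 15), rep(NA, 5)),
    partner_a = "a1",
    partner_alpha = c(rep("alpha1", 12), rep("alpha2", 3), rep(NA, 5)),
    theta_alpha = 0.1, theta_a = 0.15,
    proj_len_a = 1, proj_len_alpha = 1)
  me <- mating_efficiency(df)
  expect_equal(me$efficiency, 0.75)
  expect_equal(me$n_success, 15L)
  expect_equal(me$mean_time, 1000)
  fake <- structure(list(replicates = df,
                         config = build_scenario("three_cell_discrim")),
                    class = "ms_batch")
  md <- mating_discrimination(fake)
  expect_equal(md$discrimination, 12 / 15)
  expect_equal(md$producer_id, "alpha1")
  # degenerate batch: no successes -> undefined discrimination
  df0 <- df; df0$success <- FALSE
  fake0 <- structure(list(replicates = df0, config = fake$config),
                     class = "ms_batch")
  expect_true(is.na(mating_discrimination(fake0)$discrimination))
  expect_equal(mating_efficiency(df0)$efficiency, 0)
})

test_that("diagonal deviation is the perpendicular point-to-line distance", {
  # on-diagonal points deviate by zero
  expect_equal(diagonal_deviation(cbind(c(0.3, -0.2), c(0.3, -0.2))), 0)
  # single point (0, pi/4): distance (pi/4)/sqrt(2)
  expect_equal(diagonal_deviation(cbind(0, pi / 4)), (pi / 4) / sqrt(2),
               tolerance = 1e-12)
  # mirrored pairs (t, -t), (-t, t): mean distance 2|t|/sqrt(2)
  t0 <- 0.35
  got <- diagonal_deviation(cbind(c(t0, -t0), c(-t0, t0)))
  # oracle: foot-of-perpendicular computation
  d1 <- abs(-t0 - t0) / sqrt(2)
  expect_equal(got, d1, tolerance = 1e-12)
})

test_that("direction pairs use the stated sign conventions", {
  cfg <- test_two_cell(kappa1 = 0, kappa2 = 0, kappa3 = 0)
  r <- run_simulation(cfg, seed = 1)
  dp <- direction_pair(r)
  # noise-free cells point at each other: both angles ~ 0, on the diagonal
  expect_lt(abs(dp$theta_alpha), 0.05)
  expect_lt(abs(dp$theta_a), 0.05)
  expect_lt(diagonal_deviation(cbind(dp$theta_alpha, dp$theta_a)), 0.05)
})

test_that("competition tallies winners by genotype", {
  df <- data.frame(seed = 1:5, success = c(TRUE, TRUE, FALSE, TRUE, TRUE),
                   mating_time = 1, partner_a = c("a1", "a1", NA, "a2", "a1"),
                   partner_alpha = "alpha1", theta_alpha = 0, theta_a = 0,
                   proj_len_a = 1, proj_len_alpha = 1)
  fake <- structure(list(replicates = df,
                         config = build_scenario("three_cell_compete")),
                    class = "ms_batch")
  out <- competition_outcome(fake)
  expect_equal(out$a1, 3L)
  expect_equal(out$a2, 1L)
  expect_equal(out$no_mating, 1L)
})
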