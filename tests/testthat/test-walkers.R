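test_that("walker parameter records enforce model arity", {
  expect_error(walker_params("brownian", c(1, 2)), "requires 1")
  expect_error(walker_params("iheteroCRW", 1:8), "requires 9")
  expect_error(walker_params("ihomoCRW", c(10, 2, 5, 1, -1)),
               "beta must be positive")
  wp <- walker_params("heteroCRW", 1:8)
  expect_equal(unname(wp$values), as.numeric(1:8))
  expect_equal(wp$zeta_max, 25)
  expect_equal(walker_arity("levy"), 4L)
})

test_that("inverse turn scaling is exact at its anchor points", {
  expect_equal(inverse_turn_scale(25, 25, 1), 0)
  expect_equal(inverse_turn_scale(0, 25, 1), 1)
  expect_equal(inverse_turn_scale(12.5, 25, 1), 0.5)
  # speeds above the ceiling clamp inside the factor only
  expect_equal(inverse_turn_scale(40, 25, 2), 0)
  expect_true(inverse_turn_scale(12.5, 25, 3) > 0.5)  # beta>1: gentler onset
})

test_that("Brownian steps draw area-correct uniform orientations", {
  set.seed(31)
  wp <- walker_params("brownian", 6)
  st <- init_cell_states(wp, 2000)
  zs <- c(); coses <- c()
  for (k in 1:50) {
    prev <- st$heading
    out <- step_cells(st, wp, 30)
    st <- out$state
    zs <- c(zs, st$heading[, 3])
    coses <- c(coses, rowSums(prev * st$heading))
  }
  # Archimedes: z-component of a uniform orientation is uniform on [-1, 1]
  expect_lt(ks_brute(zs, stats::runif(length(zs), -1, 1)), 0.01)
  expect_lt(abs(mean(coses)), 0.01)  # no persistence
  expect_equal(step_cells(init_cell_states(walker_params("brownian", 0), 10),
                          walker_params("brownian", 0), 30)$speed, rep(0, 10))
})

test_that("Levy walkers keep heading mid-run and reorient at expiry", {
  wp <- walker_params("levy", c(alpha_t = 1.2, beta_t = 4,
                                alpha_d = 1.2, beta_d = 60))
  set.seed(32)
  st <- init_cell_states(wp, 500)
  out1 <- step_cells(st, wp, 3)     # first step draws runs
  st1 <- out1$state
  mid <- st1$run_remaining > 0
  out2 <- step_cells(st1, wp, 3)
  expect_true(any(mid))
  expect_equal(out2$state$heading[mid, ], st1$heading[mid, ])
  expect_equal(out2$speed[mid], out1$speed[mid])
  # pooled run durations are heavy-tailed for alpha_d < 2
  set.seed(33)
  d <- sample_levy(levy_params(1.2, 60), 1e4)
  expect_gt(stats::quantile(d, 0.999) / stats::quantile(d, 0.5), 50)
})

test_that("CRW rotations apply exactly the drawn turn angle", {
  set.seed(34)
  # point-mass turn speed: angle between successive headings is deterministic
  for (mu_p in c(0, 60, 360)) {
    wp <- walker_params("homoCRW", c(mu_p, 0, 10, 2))
    st <- init_cell_states(wp, 50)
    prev <- st$heading
    out <- step_cells(st, wp, 30)
    expected_deg <- mu_p * 30 / 60
    if (expected_deg > 180) expected_deg <- 360 - expected_deg
    got <- acos(pmin(1, pmax(-1, rowSums(prev * out$state$heading)))) *
      180 / pi
    expect_equal(got, rep(expected_deg, 50), tolerance = 1e-6)
  }
  # zero-turn walker produces perfectly straight tracks
  wp0 <- walker_params("homoCRW", c(0, 0, 10, 0))
  cfg <- arena_config("custom", n_cells = 5, duration = 600,
                      tracked_volume = c(1e4, 1e4, 1e4), domain_margin = 10,
                      cell_radius = 0.01)
  ds <- run_replicate(wp0, cfg, seed = 1)
  mis <- vapply(ds$tracks, meandering_index, numeric(1))
  expect_equal(unname(mis), rep(1, length(mis)), tolerance = 1e-9)
})

test_that("headings stay unit norm over long trajectories", {
  set.seed(35)
  wp <- walker_params("iheteroCRW", c(110, 45, 35, 12, 10, 4, 3.5, 1.2, 2))
  st <- init_cell_states(wp, 100)
  for (k in 1:200) st <- step_cells(st, wp, 30)$state
  expect_true(all(abs(sqrt(rowSums(st$heading^2)) - 1) < 1e-9))
})

test_that("inverse models couple speed and turn negatively, plain do not", {
  stream_rho <- function(model, vals, seed) {
    set.seed(seed)
    wp <- walker_params(model, vals)
    st <- init_cell_states(wp, 300)
    sp <- c(); td <- c()
    for (k in 1:20) {
      o <- step_cells(st, wp, 30); st <- o$state
      sp <- c(sp, o$speed); td <- c(td, o$turn_deg)
    }
    spearman_rho(sp, td)$rho
  }
  expect_lt(stream_rho("iheteroCRW",
                       c(110, 45, 35, 12, 10, 4, 3.5, 1.2, 2), 41), -0.1)
  expect_lt(stream_rho("ihomoCRW", c(110, 45, 10, 4, 1), 42), -0.1)
  expect_lt(abs(stream_rho("heteroCRW",
                           c(110, 45, 35, 12, 10, 4, 3.5, 1.2), 43)), 0.1)
  expect_lt(abs(stream_rho("homoCRW", c(110, 45, 10, 4), 44)), 0.1)
})

test_that("hetero models spread per-cell median speeds more than homo", {
  set.seed(36)
  median_spread <- function(model, vals) {
    wp <- walker_params(model, vals)
    st <- init_cell_states(wp, 200)
    speeds <- matrix(0, 200, 30)
    for (k in 1:30) { o <- step_cells(st, wp, 30); st <- o$state
      speeds[, k] <- o$speed }
    stats::sd(apply(speeds, 1, stats::median))
  }
  s_het <- median_spread("heteroCRW", c(110, 45, 35, 12, 10, 4, 3.5, 1.2))
  s_hom <- median_spread("homoCRW", c(110, 45, 10, sqrt(4^2 + 3.5^2)))
  expect_gt(s_het, 2 * s_hom)
})
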