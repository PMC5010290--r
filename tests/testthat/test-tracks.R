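test_that("track construction validates structure", {
  expect_error(track("a", t = 0, x = 0, y = 0, z = 0), "at least 2")
  expect_error(track("a", t = c(0, 30, 20), x = 1:3, y = 0, z = 0),
               "strictly increasing")
  expect_error(track("a", t = c(0, 30, 70), x = 1:3, y = 0, z = 0),
               "regularly sampled")
  expect_error(track("a", t = c(0, NA), x = 1:2, y = 0, z = 0), "finite")
  expect_error(track_dataset(list(straight_track("a"), straight_track("a"))),
               "unique")
  expect_error(track_dataset(list()), "at least one")
})

test_that("step speeds convert displacement per interval to um/min", {
  expect_equal(step_speeds(track("a", c(0, 30), x = c(0, 5), y = 0, z = 0)),
               10)
  expect_equal(step_speeds(track("a", c(0, 30), x = 3, y = 3, z = 3)), 0)
  expect_equal(step_speeds(track("a", c(0, 60, 120), x = c(0, 3, 9),
                                 y = 0, z = 0)),
               c(3, 6))
})

test_that("turn speeds are bounded by the sampling ceiling", {
  # straight continuation: zero turn
  expect_equal(as.numeric(turn_speeds(straight_track(dt = 45))),
               rep(0, 4))
  # exact reversal at 30 s: the 360 deg/min ceiling
  expect_equal(as.numeric(turn_speeds(reversal_track(dt = 30))),
               c(360, 360))
  # right angle at 60 s sampling: 90 deg per minute
  tr <- track("a", c(0, 60, 120), x = c(0, 10, 10), y = c(0, 0, 10), z = 0)
  expect_equal(as.numeric(turn_speeds(tr)), 90)
  # zero-displacement step: that turn is skipped, not imputed
  tr2 <- track("a", c(0, 30, 60, 90), x = c(0, 5, 5, 10), y = 0, z = 0)
  ts <- turn_speeds(tr2)
  expect_length(ts, 0)
  expect_equal(attr(ts, "n_skipped"), 2L)
  set.seed(1)
  for (dt in c(30, 45)) {
    tr <- random_track("a", n = 20, dt = dt)
    expect_true(all(turn_speeds(tr) <= 180 / (dt / 60) + 1e-9))
  }
})

test_that("meandering index spans straight lines to closed loops", {
  expect_equal(meandering_index(straight_track()), 1)
  closed <- track("c", seq(0, 120, 30), x = c(0, 10, 10, 0, 0),
                  y = c(0, 0, 10, 10, 0), z = 0)
  expect_equal(meandering_index(closed), 0)
  two_perp <- track("p", c(0, 30, 60), x = c(0, 10, 10), y = c(0, 0, 10),
                    z = 0)
  expect_equal(meandering_index(two_perp), sqrt(200) / 20)
  stationary <- track("z", c(0, 30), x = 1, y = 1, z = 1)
  expect_true(is.na(meandering_index(stationary)))
})

test_that("meandering index is invariant under rotation and translation", {
  set.seed(42)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  for (i in 1:5) {
    tr <- random_track("a", n = 12)
    xyz2 <- tr$xyz %*% R + matrix(c(100, -50, 3), nrow(tr$xyz), 3,
                                  byrow = TRUE)
    tr2 <- track("b", tr$t, xyz2[, 1], xyz2[, 2], xyz2[, 3])
    expect_equal(meandering_index(tr2), meandering_index(tr),
                 tolerance = 1e-12)
    expect_equal(as.numeric(turn_speeds(tr2)), as.numeric(turn_speeds(tr)),
                 tolerance = 1e-9)
  }
})

test_that("displacement filter keeps net displacement >= threshold", {
  mk <- function(id, net) track(id, c(0, 30, 60), x = c(0, net / 2, net),
                                y = 0, z = 0)
  ds <- track_dataset(list(mk("a", 10), mk("b", 26.9), mk("c", 27),
                           mk("d", 40)))
  kept <- apply_displacement_filter(ds, 27)
  expect_equal(names(kept$tracks), c("c", "d"))
  # threshold 0 is the identity on non-degenerate datasets
  expect_equal(n_tracks(apply_displacement_filter(ds, 0)), 4L)
})

test_that("motility profile pools per-step metrics with counting identities", {
  set.seed(3)
  lens <- c(5L, 8L, 12L, 20L, 9L)
  ds <- track_dataset(lapply(seq_along(lens), function(i)
    random_track(sprintf("t%d", i), n = lens[i], scale = 20)))
  p <- build_motility_profile(ds, filter_um = 0)
  expect_equal(length(p$pooled_translational_speeds), sum(lens - 1L))
  expect_true(length(p$pooled_turn_speeds) <= sum(lens - 2L))
  expect_equal(length(p$pooled_turn_speeds) + p$n_skipped_turns,
               sum(lens - 2L))
  expect_equal(length(p$meandering_indices), length(lens))
  expect_equal(length(p$median_track_translational_speeds), length(lens))
  expect_true(all(p$meandering_indices >= 0 & p$meandering_indices <= 1))
  # doubling the dataset doubles every pooled multiset
  ds2 <- track_dataset(c(ds$tracks,
                         lapply(ds$tracks, function(tr) {
                           tr$id <- paste0(tr$id, "_copy"); tr
                         })))
  p2 <- build_motility_profile(ds2, filter_um = 0)
  expect_equal(sort(p2$pooled_translational_speeds),
               sort(rep(p$pooled_translational_speeds, 2)))
  expect_equal(length(p2$meandering_indices), 2L * length(lens))
})

test_that("an all-filtered dataset raises the empty-profile error", {
  still <- track("z", c(0, 30, 60), x = c(0, 0.1, 0.2), y = 0, z = 0)
  expect_error(build_motility_profile(track_dataset(list(still)), 27),
               "empty motility profile")
})

test_that("MSD slope identifies ballistic motion exactly", {
  ds <- track_dataset(list(straight_track(n = 12, step = 5)))
  m <- msd_curve(ds)
  expect_equal(m$slope, 2, tolerance = 1e-6)
  # MSD at lag k*dt for constant speed v: (v*k*dt)^2
  expect_equal(m$msd_um2[1], 25)
  still <- track("z", seq(0, 300, 30), x = 1, y = 1, z = 1)
  expect_error(msd_curve(track_dataset(list(still))), "slope undefined")
})

test_that("displacement autocorrelation hits the persistence extremes", {
  ds <- track_dataset(list(straight_track(n = 10)))
  ac <- displacement_autocorrelation(ds)
  expect_true(all(abs(ac$median - 1) < 1e-12))
  zig <- track("z", seq(0, by = 30, length.out = 9),
               x = rep(c(0, 5), length.out = 9), y = 0, z = 0)
  acz <- displacement_autocorrelation(track_dataset(list(zig)))
  expect_equal(acz$median[acz$lag_s == 30], -1)
  expect_true(all(ac$median >= -1 & ac$median <= 1))
})

test_that("Brownian displacement directions are uncorrelated across lags", {
  set.seed(11)
  wp <- walker_params("brownian", 8)
  cfg <- arena_config("custom", n_cells = 100, duration = 900,
                      tracked_volume = c(1e5, 1e5, 1e5),
                      domain_margin = 10, cell_radius = 0.01)
  ds <- run_ensemble(wp, cfg, n_replicates = 2, seed = 5)
  ac <- displacement_autocorrelation(ds)
  expect_true(all(abs(ac$median) < 0.1))
})
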