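tiny_arena <- function() arena_config("custom", n_cells = 15,
                                      duration = 450)

tiny_target <- function(seed = 71) {
  wp <- walker_params("homoCRW", c(120, 40, 10, 3))
  run_ensemble(wp, tiny_arena(), n_replicates = 4, seed = seed)
}

test_that("calibration config validates its protocol fields", {
  expect_error(calibration_config("brownian", train_fraction = 1.2),
               "train_fraction")
  expect_error(calibration_config("brownian", population = 2), "at least 4")
  expect_equal(calibration_config("brownian")$population, 20L)
  expect_equal(calibration_config("iheteroCRW")$population, 100L)
  expect_equal(calibration_config("heteroCRW")$population, 80L)
  expect_equal(calibration_config("brownian")$generations, 40L)
  expect_equal(calibration_config("brownian")$replicates_per_eval, 10L)
  expect_equal(calibration_config("brownian")$overfit_stop, 0.8)
  b <- default_gene_bounds("iheteroCRW")
  expect_length(b$lower, 9L)
})

test_that("overfit metric counts training members shared by identity", {
  mk_front <- function(ids) {
    structure(list(members = lapply(ids, function(i)
      pareto_member(NULL, stats::runif(3), id = i))),
      class = "pareto_front")
  }
  set.seed(72)
  expect_equal(overfit_metric(mk_front(1:4), mk_front(1:6)), 0)
  expect_equal(overfit_metric(mk_front(1:4), mk_front(5:8)), 1)
  expect_equal(overfit_metric(mk_front(1:4), mk_front(c(1, 2, 9, 10))), 0.5)
})

test_that("candidate evaluation scores a self-match well and noise poorly", {
  target <- tiny_target()
  cfg <- calibration_config("homoCRW", replicates_per_eval = 4,
                            arena = tiny_arena(), filter_um = 0)
  set.seed(73)
  split <- build_motility_profile(target, 0)
  ev_self <- evaluate_candidate(walker_params("homoCRW", c(120, 40, 10, 3)),
                                split, NULL, cfg, seed = 5)
  ev_far <- evaluate_candidate(walker_params("homoCRW", c(10, 5, 45, 1)),
                               split, NULL, cfg, seed = 5)
  expect_true(all(ev_self$train < 0.25))
  expect_gt(max(ev_far$train), max(ev_self$train))
  expect_equal(attr(ev_self$train, "objective_mode"), "ks")
  # determinism under a common seed
  ev_again <- evaluate_candidate(walker_params("homoCRW", c(120, 40, 10, 3)),
                                 split, NULL, cfg, seed = 5)
  expect_equal(as.numeric(ev_self$train), as.numeric(ev_again$train))
})

test_that("a degenerate zero-motility candidate scores worst case", {
  target <- tiny_target()
  cfg <- calibration_config("homoCRW", replicates_per_eval = 2,
                            arena = tiny_arena(), filter_um = 27)
  split <- build_motility_profile(target, 27)
  ev <- evaluate_candidate(walker_params("homoCRW", c(0, 0, 0, 0)),
                           split, NULL, cfg, seed = 5)
  expect_equal(as.numeric(ev$train), c(1, 1, 1))
  expect_true(isTRUE(attr(ev$train, "degenerate")))
})

test_that("zero generations leaves the non-dominated initial population", {
  target <- tiny_target()
  cfg <- calibration_config("brownian", generations = 0, population = 6,
                            replicates_per_eval = 2, arena = tiny_arena(),
                            filter_um = 0)
  out <- nsga2_calibrate(target, cfg, seed = 74)
  expect_equal(out$n_evaluated, 6L)
  expect_true(length(out$training_front$members) >= 1)
  expect_true(length(out$training_front$members) <= 6)
  # front is internally non-dominated
  obj <- do.call(rbind, lapply(out$training_front$members,
                               function(m) m$objectives))
  expect_length(leukowalk:::nondominated_idx(obj), nrow(obj))
})

test_that("calibration is reproducible from its seed", {
  target <- tiny_target()
  cfg <- calibration_config("brownian", generations = 2, population = 6,
                            replicates_per_eval = 2, arena = tiny_arena(),
                            filter_um = 0)
  o1 <- nsga2_calibrate(target, cfg, seed = 75)
  o2 <- nsga2_calibrate(target, cfg, seed = 75)
  g1 <- do.call(rbind, lapply(o1$training_front$members,
                              function(m) m$params$values))
  g2 <- do.call(rbind, lapply(o2$training_front$members,
                              function(m) m$params$values))
  expect_equal(g1, g2)
  expect_equal(o1$overfit_trace, o2$overfit_trace)
})

test_that("the best training lambda never worsens across generations", {
  # elitism: archive fronts only gain; reflected in the stored outcome by
  # the training front dominating every evaluated candidate
  target <- tiny_target()
  cfg <- calibration_config("brownian", generations = 3, population = 6,
                            replicates_per_eval = 2, arena = tiny_arena(),
                            filter_um = 0)
  out <- nsga2_calibrate(target, cfg, seed = 76)
  front_best <- min(vapply(out$training_front$members, lambda_score,
                           numeric(1)))
  expect_true(is.finite(front_best))
  expect_true(length(out$training_front$members) >= 1)
})

test_that("model comparison reproduces trivial and oracle cases", {
  set.seed(77)
  f1 <- pareto_filter(random_members(20))
  # identical fronts: mutual 100, lambda KS masked as not significant
  cmp_same <- compare_models(list(a = f1, b = f1), n_best = 10)
  expect_equal(unname(cmp_same$nondominated_pct["a", "b"]), 100)
  expect_equal(unname(cmp_same$nondominated_pct["b", "a"]), 100)
  expect_true(is.na(cmp_same$lambda$ks["a", "b"]))
  # an elementwise-better front: 100 vs 0
  good <- pareto_filter(lapply(1:8, function(i)
    pareto_member(NULL, stats::runif(3, 0, 0.1), id = i)))
  bad <- pareto_filter(lapply(1:8, function(i)
    pareto_member(NULL, stats::runif(3, 0.5, 0.6), id = 100 + i)))
  cmp <- compare_models(list(good = good, bad = bad), n_best = 8)
  expect_equal(unname(cmp$nondominated_pct["good", "bad"]), 100)
  expect_equal(unname(cmp$nondominated_pct["bad", "good"]), 0)
  # three-model matrix equals the pairwise oracle
  fronts <- list(a = pareto_filter(random_members(10)),
                 b = pareto_filter(random_members(10)),
                 c = pareto_filter(random_members(10)))
  cmp3 <- compare_models(fronts, n_best = 5)
  for (i in names(fronts)) for (j in names(fronts)) {
    if (i != j)
      expect_equal(unname(cmp3$nondominated_pct[i, j]),
                   nondominated_proportion(fronts[[i]], fronts[[j]]))
  }
})

test_that("merged multi-run fronts are re-filtered for dominance", {
  set.seed(78)
  fa <- pareto_filter(random_members(15))
  fb <- pareto_filter(random_members(15))
  merged <- merge_fronts(list(fa, fb))
  obj <- do.call(rbind, lapply(merged$members, function(m) m$objectives))
  expect_length(leukowalk:::nondominated_idx(obj), nrow(obj))
  merged2 <- pareto_filter(merged)
  expect_equal(length(merged2$members), length(merged$members))
})

test_that("MSD-mode calibration refuses lambda and uses slope differences", {
  target <- tiny_target()
  cfg <- calibration_config("homoCRW", replicates_per_eval = 2,
                            arena = tiny_arena(), filter_um = 0,
                            objective_mode = "msd")
  split <- build_motility_profile(target, 0)
  attr(split, "msd_slope") <- msd_curve(target)$slope
  ev <- evaluate_candidate(walker_params("homoCRW", c(120, 40, 10, 3)),
                           split, NULL, cfg, seed = 9)
  expect_equal(attr(ev$train, "objective_mode"), "msd")
  expect_error(lambda_score(ev$train), "MSD")
})
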