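#' Default gene bounds for calibrating each walker model
#'
#' Biologically scaled boxes: translational speed means/SDs in um/min, turn
#' speed means/SDs in deg/min, Levy stability exponents in (0.3, 2],
#' duration scales in seconds, inverse-coupling exponents around 1.
#'
#' @param model Model name (see [walker_params()]).
#' @return List with numeric vectors `lower` and `upper` in gene order.
#' @export
default_gene_bounds <- function(model) {
  b <- switch(model,
    brownian = list(lower = 0.1, upper = 50),
    levy = list(lower = c(0.3, 0.1, 0.3, 0.1),
                upper = c(2, 50, 2, 600)),
    homoCRW = list(lower = c(0, 0.1, 0, 0.1),
                   upper = c(360, 180, 50, 30)),
    heteroCRW = list(lower = c(0, 0.1, 0, 0.1, 0, 0.1, 0, 0.1),
                     upper = c(360, 180, 180, 90, 50, 30, 30, 15)),
    ihomoCRW = list(lower = c(0, 0.1, 0, 0.1, 0.1),
                    upper = c(360, 180, 50, 30, 10)),
    iheteroCRW = list(lower = c(0, 0.1, 0, 0.1, 0, 0.1, 0, 0.1, 0.1),
                      upper = c(360, 180, 180, 90, 50, 30, 30, 15, 10)),
    stop("unknown model: ", model))
  names(b$lower) <- names(b$upper) <- walker_gene_names(model)
  b
}

#' Default NSGA-II population size per model
#'
#' Scaled with model parameter count: 20 (brownian), 50 (levy, homoCRW),
#' 60 (ihomoCRW), 80 (heteroCRW), 100 (iheteroCRW).
#'
#' @param model Model name.
#' @export
default_population <- function(model) {
  c(brownian = 20L, levy = 50L, homoCRW = 50L, heteroCRW = 80L,
    ihomoCRW = 60L, iheteroCRW = 100L)[[model]]
}

#' Calibration configuration
#'
#' @param model Walker model to calibrate.
#' @param generations Maximum NSGA-II generations (40 by default).
#' @param population Candidates per generation; defaults to
#'   [default_population()] for the model.
#' @param replicates_per_eval Arena replicates pooled per candidate
#'   evaluation (10 by default).
#' @param train_fraction Fraction of target tracks in the training split.
#' @param overfit_stop Calibration halts once the over-fitting metric (the
#'   fraction of training-front members absent from the validation front)
#'   exceeds this (0.8 by default).
#' @param gene_bounds List with `lower`/`upper`; defaults to
#'   [default_gene_bounds()].
#' @param objective_mode `"meandering"` (three KS objectives) or `"msd"`
#'   (third objective is the absolute MSD log-log slope difference).
#' @param arena An [arena_config()] describing the simulated experiment.
#' @param filter_um Net-displacement filter applied to simulated data (same
#'   threshold as the target's preprocessing).
#' @param blend Blend-crossover expansion fraction.
#' @param mutation_sd_frac Gaussian mutation SD as a fraction of each gene's
#'   box width.
#' @return An object of class `calibration_config`.
#' @export
calibration_config <- function(model,
                               generations = 40L,
                               population = NULL,
                               replicates_per_eval = 10L,
                               train_fraction = 0.7,
                               overfit_stop = 0.8,
                               gene_bounds = NULL,
                               objective_mode = c("meandering", "msd"),
                               arena = arena_config("tcell"),
                               filter_um = 27,
                               blend = 0.1,
                               mutation_sd_frac = 0.05) {
  objective_mode <- match.arg(objective_mode)
  if (is.null(population)) population <- default_population(model)
  if (is.null(gene_bounds)) gene_bounds <- default_gene_bounds(model)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (population < 4L) stop("population must be at least 4")
  if (any(gene_bounds$upper <= gene_bounds$lower))
    stop("gene upper bounds must exceed lower bounds")
  structure(list(model = model, generations = as.integer(generations),
                 population = as.integer(population),
                 replicates_per_eval = as.integer(replicates_per_eval),
                 train_fraction = train_fraction,
                 overfit_stop = overfit_stop, gene_bounds = gene_bounds,
                 objective_mode = objective_mode, arena = arena,
                 filter_um = filter_um, blend = blend,
                 mutation_sd_frac = mutation_sd_frac),
            class = "calibration_config")
}

profile_or_null <- function(ds, filter_um) {
  tryCatch(build_motility_profile(ds, filter_um), error = function(e) NULL)
}

# KS objectives of a simulated profile against a target profile
profile_objectives <- function(sim, target, mode, target_msd_slope = NULL,
                               sim_msd_slope = NULL) {
  worst <- if (mode == "msd") c(1, 1, 5) else c(1, 1, 1)
  if (is.null(sim) ||
      length(sim$pooled_turn_speeds) == 0L ||
      length(sim$meandering_indices) == 0L) {
    obj <- worst
    attr(obj, "objective_mode") <- if (mode == "msd") "msd" else "ks"
    attr(obj, "degenerate") <- TRUE
    return(obj)
  }
  o1 <- ks_two_sample(sim$pooled_translational_speeds,
                      target$pooled_translational_speeds)$statistic
  o2 <- ks_two_sample(sim$pooled_turn_speeds,
                      target$pooled_turn_speeds)$statistic
  o3 <- if (mode == "msd") {
    abs(sim_msd_slope - target_msd_slope)
  } else {
    ks_two_sample(sim$meandering_indices, target$meandering_indices)$statistic
  }
  obj <- c(o1, o2, o3)
  attr(obj, "objective_mode") <- if (mode == "msd") "msd" else "ks"
  obj
}

#' Evaluate a candidate parameterisation against training and validation
#' profiles
#'
#' Runs an ensemble of replicates, builds the simulated motility profile
#' (with the same net-displacement filter as the target preprocessing), and
#' scores the three objectives against both target profiles: KS statistics
#' on pooled translational speeds, pooled turn speeds and meandering indices
#' (or, in MSD mode, the absolute difference of MSD log-log slopes as the
#' third objective). A candidate whose simulated profile is empty after
#' filtering receives worst-case objectives.
#'
#' @param params A [walker_params()].
#' @param target_train,target_val `motility_profile` objects (validation may
#'   be `NULL`).
#' @param cfg A [calibration_config()].
#' @param seed Seed for the candidate's replicate ensemble.
#' @return List with `train` and `val` objective vectors (each length 3,
#'   attribute `objective_mode`).
#' @export
evaluate_candidate <- function(params, target_train, target_val, cfg,
                               seed = 1L) {
  ds <- run_ensemble(params, cfg$arena,
                     n_replicates = cfg$replicates_per_eval, seed = seed)
  sim <- profile_or_null(ds, cfg$filter_um)
  sim_slope <- NULL
  if (cfg$objective_mode == "msd" && !is.null(sim)) {
    fds <- apply_displacement_filter(ds, cfg$filter_um)
    sim_slope <- tryCatch(msd_curve(fds)$slope, error = function(e) NULL)
    if (is.null(sim_slope)) sim <- NULL
  }
  train <- profile_objectives(sim, target_train, cfg$objective_mode,
                              attr(target_train, "msd_slope"), sim_slope)
  val <- if (is.null(target_val)) NULL else
    profile_objectives(sim, target_val, cfg$objective_mode,
                       attr(target_val, "msd_slope"), sim_slope)
  list(train = train, val = val)
}

#' Over-fitting metric
#'
#' The proportion of training-front members that are not also members of the
#' validation front, with membership decided by candidate identity. 0 means
#' every training-optimal solution is also validation-optimal; calibration
#' halts above the configured threshold.
#'
#' @param training_front,validation_front `pareto_front` objects.
#' @return Proportion in \[0, 1\].
#' @export
overfit_metric <- function(training_front, validation_front) {
  stopifnot(inherits(training_front, "pareto_front"),
            inherits(validation_front, "pareto_front"))
  tids <- vapply(training_front$members, function(m) m$id, numeric(1))
  if (length(tids) == 0L) stop("training front must be non-empty")
  vids <- vapply(validation_front$members, function(m) m$id, numeric(1))
  1 - sum(tids %in% vids) / length(tids)
}

# ---- NSGA-II internals -----------------------------------------------------

# fast non-dominated sort; returns integer front rank per row (1 = best)
nds_ranks <- function(obj) {
  n <- nrow(obj)
  rank <- integer(n)
  dominated_by <- integer(n)
  dominates_list <- vector("list", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (all(obj[i, ] <= obj[j, ]) && any(obj[i, ] < obj[j, ]))
        dominates_list[[i]] <- c(dominates_list[[i]], j)
      else if (all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ]))
        dominated_by[i] <- dominated_by[i] + 1L
    }
  }
  current <- which(dominated_by == 0L)
  level <- 1L
  while (length(current)) {
    rank[current] <- level
    nxt <- integer(0)
    for (i in current) {
      for (j in dominates_list[[i]]) {
        dominated_by[j] <- dominated_by[j] - 1L
        if (dominated_by[j] == 0L) nxt <- c(nxt, j)
      }
    }
    current <- nxt
    level <- level + 1L
  }
  rank
}

crowding_distance <- function(obj) {
  n <- nrow(obj)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    rng <- obj[o[n], k] - obj[o[1L], k]
    d[o[1L]] <- d[o[n]] <- Inf
    if (rng > 0) {
      for (i in 2:(n - 1L))
        d[o[i]] <- d[o[i]] + (obj[o[i + 1L], k] - obj[o[i - 1L], k]) / rng
    }
  }
  d
}

# environmental selection: best `size` rows by (rank, crowding)
select_by_rank_crowding <- function(obj, size) {
  rank <- nds_ranks(obj)
  crowd <- numeric(nrow(obj))
  for (lv in unique(rank)) {
    idx <- which(rank == lv)
    crowd[idx] <- crowding_distance(obj[idx, , drop = FALSE])
  }
  ord <- order(rank, -crowd)
  list(selected = ord[seq_len(min(size, length(ord)))], rank = rank,
       crowd = crowd)
}

blx_crossover <- function(p1, p2, blend, lower, upper) {
  d <- abs(p1 - p2)
  lo <- pmin(p1, p2) - blend * d
  hi <- pmax(p1, p2) + blend * d
  pmin(pmax(stats::runif(length(p1), lo, hi), lower), upper)
}

gaussian_mutate <- function(g, rate, sd, lower, upper) {
  hit <- stats::runif(length(g)) < rate
  g[hit] <- g[hit] + stats::rnorm(sum(hit), 0, sd[hit])
  pmin(pmax(g, lower), upper)
}

#' Calibrate a walker model against a target track dataset with NSGA-II
#'
#' Splits the target's tracks once into training and validation sets (by
#' track), builds the two target motility profiles, and evolves a population
#' of candidate gene vectors for up to `generations` generations:
#' non-dominated sorting with crowding-distance truncation (elitist),
#' binary-tournament parent selection, blended crossover and Gaussian
#' mutation within the gene bounds. Every evaluated candidate updates both a
#' training and a validation Pareto front (selection is driven by training
#' performance alone; the validation front is observational). Calibration
#' stops early if the over-fitting metric exceeds its threshold.
#'
#' @param target_ds A `track_dataset` with at least 10 tracks.
#' @param cfg A [calibration_config()].
#' @param seed Master seed; the run is fully reproducible from it.
#' @return An object of class `calibration_outcome`: `training_front`,
#'   `validation_front` (both `pareto_front`s of [pareto_member()]s whose
#'   `params` are [walker_params()]), `overfit_trace`, `terminated_early`,
#'   `n_evaluated`, `cfg`, `seed`.
#' @export
nsga2_calibrate <- function(target_ds, cfg, seed = 1L) {
  stopifnot(inherits(target_ds, "track_dataset"),
            inherits(cfg, "calibration_config"))
  n_tr <- n_tracks(target_ds)
  if (n_tr < 10L) stop("target dataset must contain at least 10 tracks")
  set.seed(as.integer(seed))
  idx_train <- sample.int(n_tr, round(cfg$train_fraction * n_tr))
  train_ds <- track_dataset(target_ds$tracks[idx_train], "training")
  val_ds <- track_dataset(target_ds$tracks[-idx_train], "validation")
  target_train <- build_motility_profile(train_ds, cfg$filter_um)
  target_val <- build_motility_profile(val_ds, cfg$filter_um)
  if (cfg$objective_mode == "msd") {
    attr(target_train, "msd_slope") <-
      msd_curve(apply_displacement_filter(train_ds, cfg$filter_um))$slope
    attr(target_val, "msd_slope") <-
      msd_curve(apply_displacement_filter(val_ds, cfg$filter_um))$slope
  }
  lower <- cfg$gene_bounds$lower
  upper <- cfg$gene_bounds$upper
  ngene <- length(lower)
  mut_sd <- cfg$mutation_sd_frac * (upper - lower)
  mut_rate <- 1 / ngene
  pop_size <- cfg$population
  next_id <- 0L
  train_members <- list()
  val_members <- list()
  eval_genes <- function(genes_mat) {
    lapply(seq_len(nrow(genes_mat)), function(i) {
      next_id <<- next_id + 1L
      wp <- walker_params(cfg$model, genes_mat[i, ])
      ev <- evaluate_candidate(wp, target_train, target_val, cfg,
                               seed = sample.int(.Machine$integer.max - 1L, 1))
      train_members[[length(train_members) + 1L]] <<-
        pareto_member(wp, ev$train, origin = "training", id = next_id)
      val_members[[length(val_members) + 1L]] <<-
        pareto_member(wp, ev$val, origin = "validation", id = next_id)
      list(genes = genes_mat[i, ], train = ev$train, id = next_id)
    })
  }
  # initial population, uniform in the gene box
  genes <- matrix(stats::runif(pop_size * ngene, rep(lower, each = pop_size),
                               rep(upper, each = pop_size)),
                  nrow = pop_size)
  pop <- eval_genes(genes)
  overfit_trace <- numeric(0)
  terminated_early <- FALSE
  train_front <- pareto_filter(train_members)
  val_front <- pareto_filter(val_members)
  gen <- 0L
  while (gen < cfg$generations) {
    gen <- gen + 1L
    pop_obj <- do.call(rbind, lapply(pop, function(p) as.numeric(p$train)))
    sel <- select_by_rank_crowding(pop_obj, pop_size)
    # binary tournament on (rank, crowding)
    pick_parent <- function() {
      ij <- sample.int(length(pop), 2L)
      a <- ij[1L]; b <- ij[2L]
      if (sel$rank[a] < sel$rank[b]) a
      else if (sel$rank[b] < sel$rank[a]) b
      else if (sel$crowd[a] >= sel$crowd[b]) a else b
    }
    offspring <- matrix(0, pop_size, ngene)
    for (i in seq_len(pop_size)) {
      p1 <- pop[[pick_parent()]]$genes
      p2 <- pop[[pick_parent()]]$genes
      child <- blx_crossover(p1, p2, cfg$blend, lower, upper)
      offspring[i, ] <- gaussian_mutate(child, mut_rate, mut_sd, lower, upper)
    }
    kids <- eval_genes(offspring)
    combined <- c(pop, kids)
    comb_obj <- do.call(rbind, lapply(combined,
                                      function(p) as.numeric(p$train)))
    keep <- select_by_rank_crowding(comb_obj, pop_size)$selected
    pop <- combined[keep]
    train_front <- pareto_filter(train_members)
    val_front <- pareto_filter(val_members)
    ofm <- overfit_metric(train_front, val_front)
    overfit_trace <- c(overfit_trace, ofm)
    if (ofm > cfg$overfit_stop) { terminated_early <- TRUE; break }
  }
  structure(list(training_front = train_front,
                 validation_front = val_front,
                 overfit_trace = overfit_trace,
                 terminated_early = terminated_early,
                 n_evaluated = next_id, cfg = cfg, seed = seed),
            class = "calibration_outcome")
}

#' @export
print.calibration_outcome <- function(x, ...) {
  cat(sprintf(paste0(
    "<calibration_outcome> %s: %d candidates evaluated\n",
    "  training front %d members, validation front %d members\n",
    "  final over-fitting metric %.3f%s\n"),
    x$cfg$model, x$n_evaluated,
    length(x$training_front$members), length(x$validation_front$members),
    if (length(x$overfit_trace)) x$overfit_trace[length(x$overfit_trace)]
    else NA,
    if (x$terminated_early) " (terminated early)" else ""))
  invisible(x)
}
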