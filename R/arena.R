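#' Arena simulation configuration
#'
#' Cells move in a padded 3D continuous-space domain; only positions inside
#' the tracked (imaging) volume are recorded, reproducing the in vivo
#' observation process in which fast, persistent cells leave the volume
#' after few observations. Presets mirror the imaging protocols: T cells are
#' recorded every 30 s for 30 min, neutrophils every 45 s for 50 min, in a
#' 412 x 412 x 100 um tracked volume. Levy-walk simulations advance their
#' internal state every 3 s (run durations are shorter than the recording
#' interval) but are recorded at the preset interval like the other models.
#'
#' @param preset `"tcell"`, `"neutrophil"` or `"custom"`.
#' @param tracked_volume Numeric length-3 box dimensions, um.
#' @param domain_margin Padding around the tracked volume on every face, um;
#'   cells may roam (and re-enter) there unobserved. Boundaries of the
#'   padded domain are reflecting.
#' @param record_interval Recording interval, s.
#' @param update_interval State-update interval, s; must divide
#'   `record_interval`. Defaults to `record_interval` (3 s for Levy).
#' @param duration Simulated time, s.
#' @param n_cells Cells per replicate.
#' @param cell_radius Cell radius, um (cells are non-overlapping spheres).
#' @param levy_update Internal update interval used for the Levy model, s.
#' @return An object of class `arena_config`.
#' @export
arena_config <- function(preset = c("tcell", "neutrophil", "custom"),
                         tracked_volume = c(412, 412, 100),
                         domain_margin = 50,
                         record_interval = NULL,
                         update_interval = NULL,
                         duration = NULL,
                         n_cells = 200L,
                         cell_radius = 5,
                         levy_update = 3) {
  preset <- match.arg(preset)
  if (is.null(record_interval))
    record_interval <- switch(preset, tcell = 30, neutrophil = 45,
                              custom = 30)
  if (is.null(duration))
    duration <- switch(preset, tcell = 1800, neutrophil = 3000,
                       custom = 1800)
  if (is.null(update_interval)) update_interval <- record_interval
  if (record_interval %% update_interval > 1e-9)
    stop("record_interval must be an integer multiple of update_interval")
  if (duration < record_interval)
    stop("duration must cover at least one recording interval")
  structure(list(preset = preset, tracked_volume = tracked_volume,
                 domain_margin = domain_margin,
                 record_interval = record_interval,
                 update_interval = update_interval,
                 duration = duration, n_cells = as.integer(n_cells),
                 cell_radius = cell_radius, levy_update = levy_update),
            class = "arena_config")
}

# non-overlapping uniform initial placement in the padded domain
place_cells <- function(n, lo, hi, radius, max_tries = 200L) {
  pos <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      p <- stats::runif(3L, lo, hi)
      if (i == 1L) { placed <- TRUE }
      else {
        d2 <- rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                       matrix(p, i - 1L, 3L, byrow = TRUE))^2)
        placed <- all(d2 >= (2 * radius)^2)
      }
      if (placed) { pos[i, ] <- p; break }
    }
    if (!placed)
      stop("initial cell placement failed: domain too dense")
  }
  pos
}

# truncate a proposed move at first sphere contact with any other cell
truncate_at_contact <- function(p0, p1, others, radius) {
  delta <- p1 - p0
  len2 <- sum(delta^2)
  if (len2 == 0 || nrow(others) == 0L) return(p1)
  rel <- others - matrix(p0, nrow(others), 3L, byrow = TRUE)
  b <- as.numeric(rel %*% delta) / len2
  c0 <- rowSums(rel^2) - (2 * radius)^2
  # solve |s*delta - rel|^2 = (2r)^2 for smallest s in (0, 1]
  disc <- b^2 - c0 / len2
  s_hit <- ifelse(disc >= 0, b - sqrt(pmax(disc, 0)), Inf)
  s_hit[s_hit <= 1e-9] <- Inf
  s <- min(1, s_hit)
  if (!is.finite(s)) s <- 1
  p0 + s * delta
}

inside_volume <- function(pos, vol) {
  pos[, 1L] >= 0 & pos[, 1L] <= vol[1L] &
  pos[, 2L] >= 0 & pos[, 2L] <= vol[2L] &
  pos[, 3L] >= 0 & pos[, 3L] <= vol[3L]
}

#' Run one arena replicate
#'
#' Initialises non-overlapping cells uniformly in the padded domain and
#' advances them with the model's update rule. Proposed moves are truncated
#' at first contact with another cell (spheres cannot overlap; per-step cell
#' order is reshuffled). Domain boundaries reflect. At each recording
#' interval the positions of cells inside the tracked volume are appended to
#' their open track; a cell leaving the volume closes its track and re-entry
#' opens a new track id, as an imaging pipeline would see it.
#'
#' @param params A [walker_params()].
#' @param cfg An [arena_config()].
#' @param seed Optional seed (integer) for this replicate.
#' @param id_prefix Prefix for generated track ids.
#' @return A `track_dataset` of the recorded tracks (tracks with at least
#'   two recorded positions).
#' @export
run_replicate <- function(params, cfg, seed = NULL, id_prefix = "sim") {
  stopifnot(inherits(params, "walker_params"), inherits(cfg, "arena_config"))
  if (!is.null(seed)) set.seed(seed)
  vol <- cfg$tracked_volume
  m <- cfg$domain_margin
  lo <- rep(-m, 3L)
  hi <- vol + m
  r <- cfg$cell_radius
  n <- cfg$n_cells
  update_dt <- if (params$model == "levy") cfg$levy_update else
    cfg$update_interval
  steps_per_record <- round(cfg$record_interval / update_dt)
  n_records <- floor(cfg$duration / cfg$record_interval)
  pos <- place_cells(n, lo, hi, r)
  state <- init_cell_states(params, n)
  # open track buffers: per cell, a growing list of (t, x, y, z)
  open_t <- vector("list", n)
  open_p <- vector("list", n)
  tracks <- list()
  next_id <- 1L
  close_track <- function(i) {
    if (length(open_t[[i]]) >= 2L) {
      tt <- unlist(open_t[[i]])
      pp <- do.call(rbind, open_p[[i]])
      tracks[[length(tracks) + 1L]] <<-
        track(sprintf("%s_%04d", id_prefix, next_id), tt,
              pp[, 1L], pp[, 2L], pp[, 3L])
      next_id <<- next_id + 1L
    }
    open_t[[i]] <<- list()
    open_p[[i]] <<- list()
  }
  record <- function(t_now) {
    ins <- inside_volume(pos, vol)
    for (i in seq_len(n)) {
      if (ins[i]) {
        open_t[[i]][[length(open_t[[i]]) + 1L]] <<- t_now
        open_p[[i]][[length(open_p[[i]]) + 1L]] <<- pos[i, ]
      } else if (length(open_t[[i]])) close_track(i)
    }
  }
  record(0)
  for (rec in seq_len(n_records)) {
    for (s in seq_len(steps_per_record)) {
      out <- step_cells(state, params, update_dt)
      state <- out$state
      disp <- state$heading * (out$speed * update_dt / 60)
      proposed <- pos + disp
      # reflecting boundaries of the padded domain
      for (ax in 1:3) {
        over <- proposed[, ax] > hi[ax]
        under <- proposed[, ax] < lo[ax]
        proposed[over, ax] <- 2 * hi[ax] - proposed[over, ax]
        proposed[under, ax] <- 2 * lo[ax] - proposed[under, ax]
        flip <- over | under
        if (any(flip)) state$heading[flip, ax] <- -state$heading[flip, ax]
      }
      for (i in sample.int(n)) {
        pos[i, ] <- truncate_at_contact(pos[i, ], proposed[i, ],
                                        pos[-i, , drop = FALSE], r)
      }
    }
    record(rec * cfg$record_interval)
  }
  for (i in seq_len(n)) if (length(open_t[[i]])) close_track(i)
  if (length(tracks) == 0L)
    stop("replicate produced no tracks with >= 2 recorded positions")
  track_dataset(tracks, label = sprintf("%s:%s", params$model, cfg$preset))
}

#' Run an ensemble of independent replicates
#'
#' Pools the track datasets of `n_replicates` replicates run with distinct
#' derived seeds; track ids are unique across replicates. Candidate
#' evaluation during calibration uses 10 replicates per candidate.
#'
#' @inheritParams run_replicate
#' @param n_replicates Number of replicates.
#' @param seed Master seed.
#' @return A pooled `track_dataset`.
#' @export
run_ensemble <- function(params, cfg, n_replicates = 10L, seed = 1L) {
  seeds <- derive_seeds(seed, n_replicates)
  all_tracks <- list()
  for (k in seq_len(n_replicates)) {
    ds <- run_replicate(params, cfg, seed = seeds[k],
                        id_prefix = sprintf("rep%02d", k))
    all_tracks <- c(all_tracks, ds$tracks)
  }
  track_dataset(all_tracks,
                label = sprintf("%s:%s x%d", params$model, cfg$preset,
                                n_replicates))
}
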