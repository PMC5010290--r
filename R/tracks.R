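#' Construct a single cell track
#'
#' A track is an ordered sequence of 3D spot positions for one cell, sampled
#' at a regular interval. Positions are in micrometres, times in seconds.
#'
#' @param id Track identifier (coerced to character).
#' @param t Numeric vector of observation times in seconds, strictly
#'   increasing and regularly spaced.
#' @param x,y,z Numeric coordinate vectors in micrometres.
#' @return An object of class `cell_track`: a list with elements `id`, `t`,
#'   `xyz` (n x 3 matrix) and `dt` (sampling interval, seconds).
#' @examples
#' tr <- track("t1", t = c(0, 30, 60), x = c(0, 5, 10), y = 0, z = 0)
#' step_speeds(tr)
#' @export
track <- function(id, t, x, y, z) {
  t <- as.numeric(t)
  n <- length(t)
  if (n < 2L) stop("a track requires at least 2 points")
  xyz <- cbind(x = rep_len(as.numeric(x), n),
               y = rep_len(as.numeric(y), n),
               z = rep_len(as.numeric(z), n))
  if (!all(is.finite(t)) || !all(is.finite(xyz)))
    stop("track times and coordinates must be finite")
  if (any(t < 0)) stop("track times must be non-negative")
  dts <- diff(t)
  if (any(dts <= 0)) stop("track times must be strictly increasing")
  dt <- dts[1L]
  if (any(abs(dts - dt) > 1e-6))
    stop("track must be regularly sampled (successive time differences equal)")
  structure(list(id = as.character(id)[1L], t = t, xyz = xyz, dt = dt),
            class = "cell_track")
}

#' @export
print.cell_track <- function(x, ...) {
  cat(sprintf("<cell_track> id=%s  %d points  dt=%gs  net displacement %.2f um\n",
              x$id, nrow(x$xyz), x$dt, net_displacement(x)))
  invisible(x)
}

#' Construct a dataset of cell tracks
#'
#' @param tracks A list of [track()] objects with unique ids.
#' @param label Free-text label for the dataset.
#' @return An object of class `track_dataset`.
#' @export
track_dataset <- function(tracks, label = "") {
  if (length(tracks) == 0L) stop("a track dataset must contain at least one track")
  ok <- vapply(tracks, inherits, logical(1), what = "cell_track")
  if (!all(ok)) stop("all elements must be cell_track objects")
  ids <- vapply(tracks, function(tr) tr$id, character(1))
  if (anyDuplicated(ids)) stop("track ids must be unique")
  names(tracks) <- ids
  structure(list(tracks = tracks, label = as.character(label)[1L]),
            class = "track_dataset")
}

#' @export
print.track_dataset <- function(x, ...) {
  np <- sum(vapply(x$tracks, function(tr) nrow(tr$xyz), integer(1)))
  cat(sprintf("<track_dataset> '%s': %d tracks, %d spots\n",
              x$label, length(x$tracks), np))
  invisible(x)
}

#' Number of tracks in a dataset
#' @param ds A `track_dataset`.
#' @export
n_tracks <- function(ds) length(ds$tracks)

# displacement vectors between successive spots, one row per step
step_displacements <- function(tr) {
  diff(tr$xyz)
}

#' Per-step translational speeds of a track
#'
#' The speed over each displacement vector connecting successive spots,
#' in micrometres per minute.
#'
#' @param tr A `cell_track`.
#' @return Numeric vector of length `n_points - 1`, um/min.
#' @export
step_speeds <- function(tr) {
  stopifnot(inherits(tr, "cell_track"))
  d <- step_displacements(tr)
  sqrt(rowSums(d^2)) / (tr$dt / 60)
}

#' Per-step turn speeds of a track
#'
#' The angle between successive displacement vectors divided by the sampling
#' interval, in degrees per minute. The largest measurable turn angle is 180
#' degrees, so the maximum turn speed is `180 / (dt/60)` deg/min (360 deg/min
#' at 30 s sampling, 240 deg/min at 45 s). Steps with zero displacement leave
#' the turn angle undefined; those observations are skipped and their number
#' recorded in the `n_skipped` attribute.
#'
#' @param tr A `cell_track` with at least 3 points.
#' @return Numeric vector (deg/min) with attribute `n_skipped`.
#' @export
turn_speeds <- function(tr) {
  stopifnot(inherits(tr, "cell_track"))
  if (nrow(tr$xyz) < 3L) stop("turn speeds require at least 3 points")
  d <- step_displacements(tr)
  nrm <- sqrt(rowSums(d^2))
  m <- nrow(d)
  i <- seq_len(m - 1L)
  ok <- nrm[i] > 0 & nrm[i + 1L] > 0
  dots <- rowSums(d[i, , drop = FALSE] * d[i + 1L, , drop = FALSE])
  cosang <- pmin(1, pmax(-1, dots / (nrm[i] * nrm[i + 1L])))
  ang_deg <- acos(cosang[ok]) * 180 / pi
  out <- ang_deg / (tr$dt / 60)
  attr(out, "n_skipped") <- sum(!ok)
  out
}

#' Net (first-to-last) displacement of a track, in micrometres
#' @param tr A `cell_track`.
#' @export
net_displacement <- function(tr) {
  n <- nrow(tr$xyz)
  sqrt(sum((tr$xyz[n, ] - tr$xyz[1L, ])^2))
}

#' Meandering index of a track
#'
#' Net first-to-last displacement divided by total path length: 1 for a
#' straight monotone track, 0 for a track returning to its start. Undefined
#' (NA) for a track with zero path length.
#'
#' @param tr A `cell_track`.
#' @return A value in \[0, 1\], or `NA_real_` for a stationary track.
#' @export
meandering_index <- function(tr) {
  stopifnot(inherits(tr, "cell_track"))
  path <- sum(sqrt(rowSums(step_displacements(tr)^2)))
  if (path == 0) return(NA_real_)
  min(1, net_displacement(tr) / path)
}

#' Exclude tracks below a net-displacement threshold
#'
#' Tracks whose first-to-last net displacement is below the threshold are
#' removed. The default of 27 um reflects the empirically derived filter used
#' to exclude sessile contaminating cells and dead/dying cells from leukocyte
#' imaging data; tracks at exactly the threshold are retained.
#'
#' @param ds A `track_dataset`.
#' @param threshold_um Net displacement threshold, micrometres.
#' @return A `track_dataset`; may contain zero tracks (returned as a bare
#'   structure so callers can detect emptiness via [n_tracks()]).
#' @export
apply_displacement_filter <- function(ds, threshold_um = 27) {
  stopifnot(inherits(ds, "track_dataset"))
  keep <- vapply(ds$tracks, function(tr) net_displacement(tr) >= threshold_um,
                 logical(1))
  structure(list(tracks = ds$tracks[keep], label = ds$label),
            class = "track_dataset")
}

#' Build the motility profile of a dataset
#'
#' Applies the net-displacement filter, then pools per-step translational
#' speeds and turn speeds across all surviving tracks, and collects one
#' meandering index and one median of each speed type per track. The three
#' pooled/collected distributions (translational speeds, turn speeds,
#' meandering indices) are the calibration objectives; the per-track medians
#' are diagnostics.
#'
#' @param ds A `track_dataset`.
#' @param filter_um Net displacement filter threshold (um); 0 disables.
#' @return An object of class `motility_profile` with elements
#'   `pooled_translational_speeds`, `pooled_turn_speeds`,
#'   `meandering_indices`, `median_track_translational_speeds`,
#'   `median_track_turn_speeds`, and bookkeeping counts.
#' @export
build_motility_profile <- function(ds, filter_um = 27) {
  stopifnot(inherits(ds, "track_dataset"))
  n_before <- n_tracks(ds)
  ds <- apply_displacement_filter(ds, filter_um)
  if (n_tracks(ds) == 0L)
    stop("empty motility profile: no tracks survive the ", filter_um,
         " um displacement filter", call. = FALSE)
  trans <- list(); turn <- list(); mi <- numeric(0)
  med_trans <- numeric(0); med_turn <- numeric(0)
  n_skipped_turns <- 0L; n_stationary <- 0L
  for (tr in ds$tracks) {
    ss <- step_speeds(tr)
    trans[[length(trans) + 1L]] <- ss
    med_trans <- c(med_trans, stats::median(ss))
    if (nrow(tr$xyz) >= 3L) {
      ts <- turn_speeds(tr)
      n_skipped_turns <- n_skipped_turns + attr(ts, "n_skipped")
      if (length(ts)) {
        turn[[length(turn) + 1L]] <- as.numeric(ts)
        med_turn <- c(med_turn, stats::median(ts))
      }
    }
    m <- meandering_index(tr)
    if (is.na(m)) n_stationary <- n_stationary + 1L else mi <- c(mi, m)
  }
  structure(list(
    pooled_translational_speeds = unlist(trans, use.names = FALSE),
    pooled_turn_speeds = unlist(turn, use.names = FALSE),
    meandering_indices = mi,
    median_track_translational_speeds = med_trans,
    median_track_turn_speeds = med_turn,
    filter_um = filter_um,
    n_tracks = n_tracks(ds),
    n_excluded = n_before - n_tracks(ds),
    n_skipped_turns = n_skipped_turns,
    n_stationary = n_stationary
  ), class = "motility_profile")
}

#' @export
print.motility_profile <- function(x, ...) {
  cat(sprintf(paste0(
    "<motility_profile> %d tracks (%d excluded by %g um filter)\n",
    "  pooled translational speeds: n=%d, median %.2f um/min\n",
    "  pooled turn speeds:          n=%d, median %.1f deg/min\n",
    "  meandering indices:          n=%d, median %.3f\n"),
    x$n_tracks, x$n_excluded, x$filter_um,
    length(x$pooled_translational_speeds),
    stats::median(x$pooled_translational_speeds),
    length(x$pooled_turn_speeds),
    if (length(x$pooled_turn_speeds)) stats::median(x$pooled_turn_speeds) else NA,
    length(x$meandering_indices),
    if (length(x$meandering_indices)) stats::median(x$meandering_indices) else NA))
  invisible(x)
}

#' Mean squared displacement curve and log-log slope
#'
#' For each time lag up to `max_fraction` of the longest track duration, the
#' squared displacement over every (overlapping) pair of observations
#' separated by that lag is averaged across all tracks; lags are taken from
#' anywhere in the temporal domain, not from time zero only. The slope is the
#' least-squares gradient of log10(MSD) against log10(lag): 1 indicates
#' diffusive, 2 ballistic motion.
#'
#' @param ds A `track_dataset`.
#' @param max_fraction Largest lag as a fraction of the longest track duration.
#' @return An object of class `msd_curve`: list with `lag_s`, `msd_um2`,
#'   `n_pairs`, `slope`, `intercept`.
#' @export
msd_curve <- function(ds, max_fraction = 0.25) {
  stopifnot(inherits(ds, "track_dataset"))
  if (n_tracks(ds) == 0L) stop("msd_curve requires a non-empty dataset")
  durations <- vapply(ds$tracks, function(tr) tr$t[length(tr$t)] - tr$t[1L],
                      numeric(1))
  max_lag <- max_fraction * max(durations)
  acc <- new.env(parent = emptyenv())
  for (tr in ds$tracks) {
    n <- nrow(tr$xyz)
    kmax <- min(n - 1L, floor(max_lag / tr$dt + 1e-9))
    if (kmax < 1L) next
    for (k in seq_len(kmax)) {
      d2 <- rowSums((tr$xyz[(1L + k):n, , drop = FALSE] -
                     tr$xyz[1L:(n - k), , drop = FALSE])^2)
      key <- sprintf("%.6f", k * tr$dt)
      cur <- if (is.null(acc[[key]])) c(0, 0) else acc[[key]]
      acc[[key]] <- c(cur[1L] + sum(d2), cur[2L] + length(d2))
    }
  }
  keys <- ls(acc)
  if (length(keys) == 0L) stop("no usable lags for MSD")
  lag <- as.numeric(keys)
  ord <- order(lag)
  lag <- lag[ord]
  sums <- unname(t(vapply(keys[ord], function(k) acc[[k]], numeric(2))))
  msd <- sums[, 1L] / sums[, 2L]
  pos <- msd > 0
  if (sum(pos) < 2L)
    stop("MSD slope undefined: fewer than 2 positive-MSD lag points")
  fit <- stats::lm.fit(cbind(1, log10(lag[pos])), log10(msd[pos]))
  structure(list(lag_s = lag, msd_um2 = msd, n_pairs = sums[, 2L],
                 slope = unname(fit$coefficients[2L]),
                 intercept = unname(fit$coefficients[1L])),
            class = "msd_curve")
}

#' @export
print.msd_curve <- function(x, ...) {
  cat(sprintf("<msd_curve> %d lags (%g..%g s), log-log slope %.3f\n",
              length(x$lag_s), min(x$lag_s), max(x$lag_s), x$slope))
  invisible(x)
}

#' Displacement autocorrelation by time lag
#'
#' For each lag, the cosine of the angle between displacement vectors
#' separated by that lag is pooled across tracks; the median and interquartile
#' range per lag are reported. This is a directional-persistence diagnostic
#' (values in \[-1, 1\]); it is not used as a calibration objective.
#'
#' @param ds A `track_dataset` whose tracks have at least 3 points.
#' @return A data frame with columns `lag_s`, `median`, `q25`, `q75`, `n`.
#' @export
displacement_autocorrelation <- function(ds) {
  stopifnot(inherits(ds, "track_dataset"))
  acc <- new.env(parent = emptyenv())
  for (tr in ds$tracks) {
    d <- step_displacements(tr)
    nrm <- sqrt(rowSums(d^2))
    m <- nrow(d)
    if (m < 2L) next
    for (k in seq_len(m - 1L)) {
      i <- seq_len(m - k)
      ok <- nrm[i] > 0 & nrm[i + k] > 0
      if (!any(ok)) next
      cosv <- rowSums(d[i, , drop = FALSE] * d[i + k, , drop = FALSE])[ok] /
        (nrm[i][ok] * nrm[i + k][ok])
      key <- sprintf("%.6f", k * tr$dt)
      acc[[key]] <- c(acc[[key]], pmin(1, pmax(-1, cosv)))
    }
  }
  keys <- ls(acc)
  lag <- as.numeric(keys)
  ord <- order(lag)
  rows <- lapply(keys[ord], function(k) {
    v <- acc[[k]]
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(lag_s = as.numeric(k), median = q[2L], q25 = q[1L], q75 = q[3L],
               n = length(v))
  })
  do.call(rbind, rows)
}
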