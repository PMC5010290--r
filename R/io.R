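#' Read a track dataset from CSV
#'
#' Expects the spot-export dialect: a header row with columns `track_id`,
#' `time_s`, `x_um`, `y_um`, `z_um`, one row per spot. Rows are grouped by
#' track id and sorted by time within each track before validation, so row
#' order in the file is immaterial. Malformed tracks are reported by id.
#'
#' @param path CSV file path.
#' @param label Dataset label; defaults to the file name.
#' @return A `track_dataset`.
#' @export
read_tracks <- function(path, label = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "time_s", "x_um", "y_um", "z_um")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  tracks <- lapply(split(df, df$track_id), function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    tryCatch(track(g$track_id[1L], g$time_s, g$x_um, g$y_um, g$z_um),
             error = function(e)
               stop(sprintf("track '%s': %s", g$track_id[1L],
                            conditionMessage(e)), call. = FALSE))
  })
  track_dataset(unname(tracks), label = label)
}

#' Write a track dataset to CSV
#'
#' Emits the same dialect [read_tracks()] consumes, with values printed at 6
#' significant digits (round-trip stable at that precision).
#'
#' @param ds A `track_dataset`.
#' @param path Output file path.
#' @export
write_tracks <- function(ds, path) {
  stopifnot(inherits(ds, "track_dataset"))
  rows <- lapply(ds$tracks, function(tr) {
    data.frame(track_id = tr$id,
               time_s = signif(tr$t, 6),
               x_um = signif(tr$xyz[, 1L], 6),
               y_um = signif(tr$xyz[, 2L], 6),
               z_um = signif(tr$xyz[, 3L], 6))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Full motility report for a dataset
#'
#' Builds the motility profile, the MSD curve, the displacement
#' autocorrelation, and the two observation-bias Spearman correlations
#' (track observation count against median track translational and turn
#' speed). This is the analysis an imaging practitioner runs on an export
#' before any model fitting.
#'
#' @param ds A `track_dataset`.
#' @param filter_um Net-displacement filter threshold, um.
#' @return An object of class `motility_report`.
#' @export
motility_report <- function(ds, filter_um = 27) {
  profile <- build_motility_profile(ds, filter_um)
  fds <- apply_displacement_filter(ds, filter_um)
  counts_t <- integer(0); med_t <- numeric(0)
  counts_p <- integer(0); med_p <- numeric(0)
  for (tr in fds$tracks) {
    ss <- step_speeds(tr)
    counts_t <- c(counts_t, length(ss))
    med_t <- c(med_t, stats::median(ss))
    if (nrow(tr$xyz) >= 3L) {
      ts <- as.numeric(turn_speeds(tr))
      if (length(ts)) {
        counts_p <- c(counts_p, length(ts))
        med_p <- c(med_p, stats::median(ts))
      }
    }
  }
  bias_trans <- tryCatch(spearman_rho(counts_t, med_t),
                         error = function(e) NULL)
  bias_turn <- tryCatch(spearman_rho(counts_p, med_p),
                        error = function(e) NULL)
  structure(list(profile = profile,
                 msd = tryCatch(msd_curve(fds), error = function(e) NULL),
                 autocorrelation = displacement_autocorrelation(fds),
                 bias_translational = bias_trans,
                 bias_turn = bias_turn),
            class = "motility_report")
}

#' @export
print.motility_report <- function(x, ...) {
  print(x$profile)
  if (!is.null(x$msd))
    cat(sprintf("  MSD log-log slope: %.3f\n", x$msd$slope))
  if (!is.null(x$bias_translational))
    cat(sprintf("  Spearman(observations, median translational speed): %.3f (p=%.3g)\n",
                x$bias_translational$rho, x$bias_translational$p.value))
  if (!is.null(x$bias_turn))
    cat(sprintf("  Spearman(observations, median turn speed): %.3f (p=%.3g)\n",
                x$bias_turn$rho, x$bias_turn$p.value))
  invisible(x)
}

#' Serialise a motility profile (or report) to JSON
#'
#' Writes the five profile distributions with provenance metadata (filter
#' threshold, exclusion counts) as JSON.
#'
#' @param x A `motility_profile` or `motility_report`.
#' @param path Output file path.
#' @export
write_profile_json <- function(x, path) {
  if (inherits(x, "motility_report")) {
    out <- list(profile = unclass(x$profile),
                msd = if (!is.null(x$msd)) unclass(x$msd),
                bias_translational = x$bias_translational,
                bias_turn = x$bias_turn)
  } else if (inherits(x, "motility_profile")) {
    out <- unclass(x)
  } else stop("unsupported object")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
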