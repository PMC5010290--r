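#' Reference-dataset presets
#'
#' Presets emulating the structure of in vivo leukocyte track datasets:
#' hundreds of tracks, ~24-27 observations per track on average, 30-45 s
#' sampling, a finite imaging volume, and the observation-bias signature
#' (fast, persistent cells observed fewer times). The `"tcell"` preset
#' targets 751 tracks at 30 s sampling, `"neutrophil"` 1017 tracks at 45 s,
#' and `"smoke"` is a 5-track preset for quick end-to-end runs. The default
#' generator is an inverse heterogeneous CRW with hand-picked demonstration
#' parameters landing pooled speed medians in the leukocyte-plausible 5-15
#' um/min range; they are demo values, not estimates of any real cell
#' population.
#'
#' @param name `"tcell"`, `"neutrophil"`, `"smoke"` or `"custom"`.
#' @param n_tracks Number of tracks to bank.
#' @param generator A [walker_params()] used to generate the data.
#' @param arena An [arena_config()]; defaults to the matching preset.
#' @param seed Default seed.
#' @return An object of class `fixture_preset`.
#' @export
fixture_preset <- function(name = c("tcell", "neutrophil", "smoke",
                                    "custom"),
                           n_tracks = NULL, generator = NULL, arena = NULL,
                           seed = 1L) {
  name <- match.arg(name)
  if (is.null(n_tracks))
    n_tracks <- switch(name, tcell = 751L, neutrophil = 1017L, smoke = 5L,
                       custom = 100L)
  if (is.null(generator))
    generator <- walker_params("iheteroCRW",
                               c(mu_pm = 110, sigma_pm = 45, mu_ps = 35,
                                 sigma_ps = 12, mu_tm = 10, sigma_tm = 4,
                                 mu_ts = 3.5, sigma_ts = 1.2, beta = 2))
  if (is.null(arena))
    arena <- switch(name,
                    neutrophil = arena_config("neutrophil", n_cells = 150L),
                    arena_config("tcell", n_cells = 150L))
  structure(list(name = name, n_tracks = as.integer(n_tracks),
                 generator = generator, arena = arena,
                 seed = as.integer(seed)),
            class = "fixture_preset")
}

#' Generate a reference track dataset
#'
#' Runs arena replicates with the preset's generator until the requested
#' number of tracks has been banked, then returns the first `n_tracks`.
#' With the default inverse heterogeneous CRW generator the dataset
#' reproduces, qualitatively, the observation-bias signature of in vivo
#' data: a negative correlation between a track's observation count and its
#' median translational speed, and a negative pooled correlation between
#' step translational and turn speeds.
#'
#' @param preset A [fixture_preset()].
#' @param seed Seed (defaults to the preset's).
#' @param max_replicates Replicate budget before giving up.
#' @return A `track_dataset` with exactly `n_tracks` tracks.
#' @export
generate_reference_dataset <- function(preset, seed = preset$seed,
                                       max_replicates = 200L) {
  stopifnot(inherits(preset, "fixture_preset"))
  seeds <- derive_seeds(seed, max_replicates)
  banked <- list()
  k <- 0L
  while (length(banked) < preset$n_tracks) {
    k <- k + 1L
    if (k > max_replicates)
      stop("track budget unreachable within ", max_replicates, " replicates")
    ds <- run_replicate(preset$generator, preset$arena, seed = seeds[k],
                        id_prefix = sprintf("fx%03d", k))
    banked <- c(banked, ds$tracks)
  }
  track_dataset(banked[seq_len(preset$n_tracks)],
                label = sprintf("%s-like synthetic reference", preset$name))
}
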