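#' Walker model parameter records
#'
#' Six random-walk motility models are supported. `values` is the model's
#' gene vector in the fixed order used by calibration:
#' \describe{
#'   \item{brownian (1)}{`sigma` -- SD of the zero-mean Gaussian speed draw
#'     (um/min); a fresh uniformly random 3D orientation every step.}
#'   \item{levy (4)}{`alpha_t, beta_t` -- Levy parameters of the run speed
#'     (um/min); `alpha_d, beta_d` -- Levy parameters of the run duration
#'     (s). Cells run straight for the drawn duration, then reorient
#'     uniformly.}
#'   \item{homoCRW (4)}{`mu_p, sigma_p` -- Gaussian turn speed (deg/min);
#'     `mu_t, sigma_t` -- Gaussian translational speed (um/min). One shared
#'     distribution pair for all cells.}
#'   \item{heteroCRW (8)}{`mu_pm, sigma_pm, mu_ps, sigma_ps` -- hyperpriors
#'     of the per-cell turn-speed Gaussian; `mu_tm, sigma_tm, mu_ts,
#'     sigma_ts` -- hyperpriors of the per-cell translational-speed
#'     Gaussian. Each cell draws its bespoke pair once at creation.}
#'   \item{ihomoCRW (5)}{homoCRW genes plus `beta` -- exponent coupling turn
#'     to translational speed.}
#'   \item{iheteroCRW (9)}{heteroCRW genes plus `beta`.}
#' }
#' In the inverse models the drawn turn speed is scaled by
#' `(zeta_max^beta - zeta^beta) / zeta_max^beta` where `zeta` is the current
#' translational speed, so fast-translating cells turn slowly. `zeta_max`
#' is the maximum translational speed, 25 um/min as determined empirically
#' in vivo.
#'
#' @param model One of `"brownian"`, `"levy"`, `"homoCRW"`, `"heteroCRW"`,
#'   `"ihomoCRW"`, `"iheteroCRW"`.
#' @param values Numeric gene vector of model-specific arity (1, 4, 4, 8, 5,
#'   9 respectively).
#' @param zeta_max Maximum translational speed, um/min.
#' @return An object of class `walker_params`.
#' @export
walker_params <- function(model = c("brownian", "levy", "homoCRW",
                                    "heteroCRW", "ihomoCRW", "iheteroCRW"),
                          values, zeta_max = 25) {
  model <- match.arg(model)
  values <- as.numeric(values)
  arity <- walker_arity(model)
  if (length(values) != arity)
    stop(sprintf("model '%s' requires %d parameters, got %d",
                 model, arity, length(values)))
  if (!all(is.finite(values))) stop("walker parameters must be finite")
  if (zeta_max <= 0) stop("zeta_max must be positive")
  if (model %in% c("ihomoCRW", "iheteroCRW") && values[arity] <= 0)
    stop("inverse-model beta must be positive")
  names(values) <- walker_gene_names(model)
  structure(list(model = model, values = values, zeta_max = zeta_max),
            class = "walker_params")
}

#' Number of free parameters of each walker model
#' @param model Model name.
#' @export
walker_arity <- function(model) {
  c(brownian = 1L, levy = 4L, homoCRW = 4L, heteroCRW = 8L,
    ihomoCRW = 5L, iheteroCRW = 9L)[[model]]
}

walker_gene_names <- function(model) {
  switch(model,
    brownian = "sigma",
    levy = c("alpha_t", "beta_t", "alpha_d", "beta_d"),
    homoCRW = c("mu_p", "sigma_p", "mu_t", "sigma_t"),
    heteroCRW = c("mu_pm", "sigma_pm", "mu_ps", "sigma_ps",
                  "mu_tm", "sigma_tm", "mu_ts", "sigma_ts"),
    ihomoCRW = c("mu_p", "sigma_p", "mu_t", "sigma_t", "beta"),
    iheteroCRW = c("mu_pm", "sigma_pm", "mu_ps", "sigma_ps",
                   "mu_tm", "sigma_tm", "mu_ts", "sigma_ts", "beta"))
}

#' @export
print.walker_params <- function(x, ...) {
  cat(sprintf("<walker_params> %s: %s (zeta_max=%g um/min)\n", x$model,
              paste(sprintf("%s=%.4g", names(x$values), x$values),
                    collapse = ", "), x$zeta_max))
  invisible(x)
}

#' Turn-speed scale factor of the inverse CRW models
#'
#' `(zeta_max^beta - min(zeta, zeta_max)^beta) / zeta_max^beta`: 1 for a
#' translationally stationary cell, 0 at `zeta = zeta_max`, linear in
#' between for `beta = 1`. Translational speeds above `zeta_max` are clamped
#' inside the factor only.
#'
#' @param zeta Translational speed(s), um/min.
#' @param zeta_max Maximum translational speed, um/min.
#' @param beta Positive exponent shaping the coupling.
#' @export
inverse_turn_scale <- function(zeta, zeta_max, beta) {
  (zeta_max^beta - pmin(zeta, zeta_max)^beta) / zeta_max^beta
}

#' Initialise per-cell walker state
#'
#' Draws each cell's initial uniformly random heading and, for the
#' heterogeneous models, its bespoke translational and turn-speed Gaussians
#' (drawn once here and fixed thereafter). Levy cells start with an expired
#' run so the first step draws a fresh run.
#'
#' @param params A [walker_params()].
#' @param n Number of cells.
#' @return A walker state list (headings plus model-specific per-cell state).
#' @export
init_cell_states <- function(params, n) {
  stopifnot(inherits(params, "walker_params"))
  v <- params$values
  st <- list(model = params$model, n = n, heading = random_unit_rows(n))
  if (params$model %in% c("homoCRW", "ihomoCRW")) {
    st$turn_mu <- rep(v[["mu_p"]], n);  st$turn_sigma <- rep(v[["sigma_p"]], n)
    st$trans_mu <- rep(v[["mu_t"]], n); st$trans_sigma <- rep(v[["sigma_t"]], n)
  } else if (params$model %in% c("heteroCRW", "iheteroCRW")) {
    st$turn_mu <- stats::rnorm(n, v[["mu_pm"]], v[["sigma_pm"]])
    st$turn_sigma <- pmax(0, stats::rnorm(n, v[["mu_ps"]], v[["sigma_ps"]]))
    st$trans_mu <- stats::rnorm(n, v[["mu_tm"]], v[["sigma_tm"]])
    st$trans_sigma <- pmax(0, stats::rnorm(n, v[["mu_ts"]], v[["sigma_ts"]]))
  } else if (params$model == "levy") {
    st$run_remaining <- rep(0, n)
    st$run_speed <- rep(0, n)
  }
  st
}

#' Advance all cells by one update step
#'
#' Applies one model-specific heading/speed update to every cell:
#' \itemize{
#'   \item Brownian: fresh uniform 3D orientation, speed `|G(0, sigma)|`.
#'   \item Levy: mid-run cells keep heading and run speed; expired runs
#'     trigger a fresh uniform orientation, Levy run speed and duration.
#'   \item CRWs: a turn speed is drawn (per-cell distribution for the
#'     heterogeneous variants), converted to an angle via the step duration,
#'     and applied about a uniformly random axis perpendicular to the
#'     current heading (so successive turn planes are uncorrelated); the
#'     cell then moves forward at `|G|` translational speed. Inverse
#'     variants draw the translational speed first and scale the turn speed
#'     by [inverse_turn_scale()].
#' }
#'
#' @param state State from [init_cell_states()] (or a previous step).
#' @param params The matching [walker_params()].
#' @param dt_s Update interval, seconds.
#' @return List with `state` (updated), `speed` (um/min, per cell) and
#'   `turn_deg` (applied turn angle, degrees, per cell; `NA` for models
#'   that reorient uniformly).
#' @export
step_cells <- function(state, params, dt_s) {
  n <- state$n
  v <- params$values
  model <- state$model
  if (model == "brownian") {
    state$heading <- random_unit_rows(n)
    speed <- abs(stats::rnorm(n, 0, v[["sigma"]]))
    return(list(state = state, speed = speed, turn_deg = rep(NA_real_, n)))
  }
  if (model == "levy") {
    expired <- state$run_remaining <= 0
    k <- sum(expired)
    if (k > 0L) {
      state$heading[expired, ] <- random_unit_rows(k)
      state$run_speed[expired] <-
        sample_levy(levy_params(v[["alpha_t"]], v[["beta_t"]]), k)
      state$run_remaining[expired] <-
        sample_levy(levy_params(v[["alpha_d"]], v[["beta_d"]]), k)
    }
    state$run_remaining <- state$run_remaining - dt_s
    return(list(state = state, speed = state$run_speed,
                turn_deg = rep(NA_real_, n)))
  }
  # correlated random walks
  inverse <- model %in% c("ihomoCRW", "iheteroCRW")
  speed <- abs(stats::rnorm(n, state$trans_mu, state$trans_sigma))
  phi <- stats::rnorm(n, state$turn_mu, state$turn_sigma)
  if (inverse)
    phi <- phi * inverse_turn_scale(speed, params$zeta_max, v[["beta"]])
  turn_deg <- abs(phi) * dt_s / 60
  state$heading <- rotate_headings(state$heading, turn_deg * pi / 180)
  list(state = state, speed = speed, turn_deg = turn_deg)
}
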