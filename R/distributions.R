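#' Distribution parameter records
#'
#' Parameter constructors for the four statistical families used to model
#' pooled cell translational and turn speed data: uniform, Levy, homogeneous
#' Gaussian and heterogeneous Gaussian. A homogeneous family uses one
#' parameterised distribution for every cell; the heterogeneous Gaussian is
#' hierarchical -- each cell/group receives a bespoke Gaussian whose mean and
#' spread are themselves drawn once from Gaussians.
#'
#' Note on the spread parameters: they are standard deviations (the argument
#' passed to the normal sampler), not variances. In the hierarchical family
#' the per-group spread is itself Gaussian-distributed and can be drawn
#' negative; it is clamped at 0 (a point mass), keeping the sampler total.
#'
#' @param lam Upper bound of the uniform family, positive (contextual units,
#'   um/min or deg/min).
#' @param alpha Levy stability exponent in (0, 2].
#' @param beta Levy scale, positive.
#' @param mu,sigma Mean and standard deviation of the homogeneous Gaussian;
#'   `sigma >= 0`.
#' @param mu_m,sigma_m Mean and SD of the Gaussian generating per-group means.
#' @param mu_s,sigma_s Mean and SD of the Gaussian generating per-group SDs.
#' @return A classed parameter record.
#' @name distribution_params
NULL

#' @rdname distribution_params
#' @export
uniform_params <- function(lam) {
  if (!is.finite(lam) || lam <= 0) stop("lam must be positive")
  structure(list(lam = lam), class = c("uniform_params", "dist_params"))
}

#' @rdname distribution_params
#' @export
levy_params <- function(alpha, beta) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 2)
    stop("levy alpha must lie in (0, 2]")
  if (!is.finite(beta) || beta <= 0) stop("levy beta must be positive")
  structure(list(alpha = alpha, beta = beta),
            class = c("levy_params", "dist_params"))
}

#' @rdname distribution_params
#' @export
homo_gaussian_params <- function(mu, sigma) {
  if (!is.finite(mu) || !is.finite(sigma) || sigma < 0)
    stop("invalid homogeneous Gaussian parameters")
  structure(list(mu = mu, sigma = sigma),
            class = c("homo_gaussian_params", "dist_params"))
}

#' @rdname distribution_params
#' @export
hetero_gaussian_params <- function(mu_m, sigma_m, mu_s, sigma_s) {
  if (!all(is.finite(c(mu_m, sigma_m, mu_s, sigma_s))) ||
      sigma_m < 0 || sigma_s < 0)
    stop("invalid heterogeneous Gaussian parameters")
  structure(list(mu_m = mu_m, sigma_m = sigma_m,
                 mu_s = mu_s, sigma_s = sigma_s),
            class = c("hetero_gaussian_params", "dist_params"))
}

#' Sample from a Levy distribution
#'
#' Variates are generated from uniform and exponential transients:
#' with X uniform on \[-pi/2, pi/2\] and Y = -ln Z, Z uniform on \[0, 1\],
#' `L = beta * sin(alpha X) / cos(X)^(1/alpha) *
#' (cos((1-alpha) X) / Y)^((1-alpha)/alpha)`. L is symmetric about 0 and the
#' absolute value is returned. For `alpha = 1` this reduces to a half-Cauchy
#' with scale `beta`; `alpha = 2` gives the Gaussian (finite-variance) limit;
#' `alpha < 2` is heavy-tailed.
#'
#' @param p A [levy_params()] record.
#' @param n Number of variates.
#' @return `n` non-negative reals.
#' @export
sample_levy <- function(p, n) {
  stopifnot(inherits(p, "levy_params"))
  a <- p$alpha
  X <- stats::runif(n, -pi / 2, pi / 2)
  Y <- -log(stats::runif(n))
  L <- p$beta * sin(a * X) / cos(X)^(1 / a) *
    (cos((1 - a) * X) / Y)^((1 - a) / a)
  abs(L)
}

#' Sample from a homogeneous Gaussian
#'
#' @param p A [homo_gaussian_params()] record.
#' @param n Number of variates.
#' @param absolute If `TRUE`, return `|x|` (used for speed magnitudes:
#'   cells do not move backwards).
#' @export
sample_homo_gaussian <- function(p, n, absolute = FALSE) {
  stopifnot(inherits(p, "homo_gaussian_params"))
  x <- stats::rnorm(n, mean = p$mu, sd = p$sigma)
  if (absolute) abs(x) else x
}

#' Draw the bespoke Gaussian of one heterogeneous-Gaussian group
#'
#' Samples the group's mean and standard deviation once from the
#' hyper-distributions; the returned per-group record is then fixed for the
#' group's lifetime. A negative drawn SD is clamped at 0.
#'
#' @param p A [hetero_gaussian_params()] record.
#' @return A [homo_gaussian_params()] record for the group.
#' @export
make_hetero_gaussian_group <- function(p) {
  stopifnot(inherits(p, "hetero_gaussian_params"))
  mu_i <- stats::rnorm(1, p$mu_m, p$sigma_m)
  sigma_i <- max(0, stats::rnorm(1, p$mu_s, p$sigma_s))
  homo_gaussian_params(mu_i, sigma_i)
}

#' Sample from a uniform distribution on (0, lam]
#'
#' @param p A [uniform_params()] record.
#' @param n Number of variates.
#' @export
sample_uniform <- function(p, n) {
  stopifnot(inherits(p, "uniform_params"))
  p$lam * (1 - stats::runif(n))
}

# n draws of non-negative observations from any family; hetero draws a
# bespoke group distribution first (one call = one group)
sample_group_observations <- function(p, n) {
  if (inherits(p, "hetero_gaussian_params")) p <- make_hetero_gaussian_group(p)
  if (inherits(p, "homo_gaussian_params")) {
    sample_homo_gaussian(p, n, absolute = TRUE)
  } else if (inherits(p, "levy_params")) {
    sample_levy(p, n)
  } else if (inherits(p, "uniform_params")) {
    sample_uniform(p, n)
  } else {
    stop("unknown distribution parameter record")
  }
}
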