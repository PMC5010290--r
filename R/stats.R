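#' Two-sample Kolmogorov-Smirnov statistic
#'
#' D is the supremum of the absolute difference between the two empirical
#' CDFs; the p-value uses the asymptotic Kolmogorov distribution. Used to
#' quantify the distance between motility-profile distributions throughout
#' the calibration and model-comparison machinery.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `statistic` (D in \[0,1\]) and `p.value`.
#' @export
ks_two_sample <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) == 0L || length(b) == 0L)
    stop("ks_two_sample requires two non-empty samples")
  r <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(statistic = unname(r$statistic), p.value = r$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks with tie correction, with asymptotic
#' p-value. Used for the observation-bias diagnostics (track observation
#' count versus median track speed) and the translation/turn speed coupling.
#'
#' @param x,y Equal-length numeric vectors (length >= 3).
#' @return List with `rho` and `p.value`.
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("spearman_rho requires at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("spearman_rho undefined for constant input")
  r <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                        exact = FALSE))
  list(rho = unname(r$estimate), p.value = r$p.value)
}

#' Pareto dominance between objective vectors (minimisation)
#'
#' `a` dominates `b` iff `a <= b` elementwise and `a < b` on at least one
#' element. Exactly equal vectors do not dominate each other.
#'
#' @param a,b Numeric objective vectors of equal length.
#' @return Logical scalar.
#' @export
dominates <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  all(a <= b) && any(a < b)
}

#' Construct a Pareto-front member
#'
#' A candidate model parameterisation together with its objective scores.
#'
#' @param params Parameter record (e.g. a [walker_params()] object).
#' @param objectives Numeric objective vector (minimised). May carry an
#'   `objective_mode` attribute (`"ks"` or `"msd"`).
#' @param origin Free tag, e.g. `"training"` or `"validation"`.
#' @param id Unique candidate identity (used for front-membership tests).
#' @export
pareto_member <- function(params, objectives, origin = "training",
                          id = NULL) {
  objectives <- as.numeric(objectives)
  if (!all(is.finite(objectives))) stop("objectives must be finite")
  if (any(objectives < 0)) stop("objectives must be non-negative")
  structure(list(params = params, objectives = objectives,
                 origin = origin, id = id),
            class = "pareto_member")
}

member_objectives <- function(members) {
  do.call(rbind, lapply(members, function(m) m$objectives))
}

# indices of the non-dominated rows of an objective matrix
nondominated_idx <- function(obj) {
  n <- nrow(obj)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  which(keep)
}

#' Extract the Pareto front from a set of members
#'
#' Returns exactly the members not dominated by any other. Duplicate
#' objective vectors are mutually non-dominating and are all retained, so
#' front sizes are not silently deflated.
#'
#' @param members List of [pareto_member()] objects.
#' @return An object of class `pareto_front` (list with `members`).
#' @export
pareto_filter <- function(members) {
  if (inherits(members, "pareto_front")) members <- members$members
  if (length(members) == 0L)
    return(structure(list(members = list()), class = "pareto_front"))
  obj <- member_objectives(members)
  structure(list(members = members[nondominated_idx(obj)]),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("<pareto_front> %d members\n", length(x$members)))
  invisible(x)
}

#' Proportion of one front non-dominated by another
#'
#' The percentage of `f1`'s members that are not dominated by any member of
#' `f2`. Two models capturing the data equally well on all objectives score
#' 100 in both directions.
#'
#' @param f1,f2 `pareto_front` objects (non-empty).
#' @return Percentage in \[0, 100\].
#' @export
nondominated_proportion <- function(f1, f2) {
  stopifnot(inherits(f1, "pareto_front"), inherits(f2, "pareto_front"))
  if (length(f1$members) == 0L || length(f2$members) == 0L)
    stop("fronts must be non-empty")
  o1 <- member_objectives(f1$members)
  o2 <- member_objectives(f2$members)
  nd <- vapply(seq_len(nrow(o1)), function(i) {
    for (j in seq_len(nrow(o2))) {
      if (all(o2[j, ] <= o1[i, ]) && any(o2[j, ] < o1[i, ])) return(FALSE)
    }
    TRUE
  }, logical(1))
  100 * mean(nd)
}

#' Lambda centre-of-front score
#'
#' For a member with KS-based objective scores, Lambda = alpha * mean(KS)^2 +
#' sum((KS_o - mean(KS))^2). Low values identify solutions that perform well,
#' and equally well, on all objectives simultaneously -- the centre of the
#' Pareto front. Lambda values are only comparable for a common `alpha`.
#'
#' The score is meaningless when one objective is on a different scale (the
#' MSD-slope calibration variant), and such vectors are refused.
#'
#' @param m A [pareto_member()] or a bare numeric objective vector of KS
#'   scores in \[0, 1\].
#' @param alpha Positive weight trading the mean term against the variance
#'   term; 1 by default.
#' @return Non-negative scalar.
#' @export
lambda_score <- function(m, alpha = 1) {
  if (alpha <= 0) stop("alpha must be positive")
  obj <- if (inherits(m, "pareto_member")) m$objectives else m
  mode <- attr(obj, "objective_mode")
  obj <- as.numeric(obj)
  if (identical(mode, "msd"))
    stop("lambda_score is undefined for MSD-variant objectives: ",
         "objectives on different scales cannot be meaningfully averaged")
  if (any(obj < 0) || any(obj > 1))
    stop("lambda_score requires KS-based objectives in [0, 1]")
  mu <- mean(obj)
  alpha * mu^2 + sum((obj - mu)^2)
}
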