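#' Merge Pareto fronts from independent calibrations of one model
#'
#' Pools the members of several fronts (typically 3 independent calibration
#' runs) and re-filters for dominance, yielding one overarching front per
#' model for comparison.
#'
#' @param fronts List of `pareto_front` objects.
#' @return A `pareto_front`.
#' @export
merge_fronts <- function(fronts) {
  members <- unlist(lapply(fronts, function(f) f$members), recursive = FALSE)
  pareto_filter(members)
}

#' Contrast calibrated models via their Pareto fronts
#'
#' Three complementary analyses of two or more models' calibration fronts:
#' \enumerate{
#'   \item the full matrix of non-domination percentages (rows: the
#'     proportion of each model's front not dominated by any member of the
#'     column model's front), with front sizes;
#'   \item the distributions of each model's best (lowest) 30 Lambda values
#'     -- the centre of each front -- with pairwise KS statistics, masked
#'     `NA` where p > 0.01;
#'   \item per-objective distributions of KS scores across each front, with
#'     the same pairwise KS tables.
#' }
#' Lambda comparisons require KS-based objectives (all three on the \[0,1\]
#' scale) and a common `alpha`.
#'
#' @param fronts Named list (model name -> `pareto_front`) of at least two
#'   fronts.
#' @param alpha Lambda weight (stored with the report).
#' @param n_best Number of lowest Lambda values contrasted per model.
#' @param p_mask Pairwise KS values with p above this are masked `NA`.
#' @param objective_names Labels of the three objectives.
#' @return An object of class `model_comparison`.
#' @export
compare_models <- function(fronts, alpha = 1, n_best = 30L, p_mask = 0.01,
                           objective_names = c("translational", "turn",
                                               "meandering")) {
  if (length(fronts) < 2L) stop("compare_models requires at least 2 fronts")
  if (is.null(names(fronts)) || any(!nzchar(names(fronts))))
    stop("fronts must be a named list")
  models <- names(fronts)
  k <- length(models)
  sizes <- vapply(fronts, function(f) length(f$members), integer(1))
  nondom <- matrix(NA_real_, k, k, dimnames = list(models, models))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j)
      nondom[i, j] <- nondominated_proportion(fronts[[i]], fronts[[j]])
  }
  lambda_vals <- lapply(fronts, function(f) {
    lv <- vapply(f$members, lambda_score, numeric(1), alpha = alpha)
    sort(lv)[seq_len(min(n_best, length(lv)))]
  })
  pairwise_ks <- function(samples) {
    D <- matrix(NA_real_, k, k, dimnames = list(models, models))
    P <- D
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i < j) {
        r <- ks_two_sample(samples[[i]], samples[[j]])
        P[i, j] <- P[j, i] <- r$p.value
        D[i, j] <- D[j, i] <-
          if (r$p.value > p_mask) NA_real_ else r$statistic
      }
    }
    list(D = D, p = P)
  }
  lambda_ks <- pairwise_ks(lambda_vals)
  obj_scores <- lapply(seq_along(objective_names), function(o) {
    lapply(fronts, function(f)
      vapply(f$members, function(m) m$objectives[o], numeric(1)))
  })
  names(obj_scores) <- objective_names
  per_objective <- lapply(obj_scores, pairwise_ks)
  structure(list(models = models, front_sizes = sizes,
                 nondominated_pct = nondom,
                 lambda = list(alpha = alpha, best = lambda_vals,
                               ks = lambda_ks$D, p = lambda_ks$p),
                 objective_scores = obj_scores,
                 per_objective_ks = per_objective),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  cat("Non-dominated % (rows vs columns), front sizes in parentheses:\n")
  m <- x$nondominated_pct
  rownames(m) <- sprintf("%s (%d)", x$models, x$front_sizes)
  print(round(m, 1))
  cat(sprintf("\nBest-%d Lambda (alpha=%g) medians:\n",
              length(x$lambda$best[[1L]]), x$lambda$alpha))
  print(vapply(x$lambda$best, stats::median, numeric(1)))
  cat("\nPairwise Lambda KS (NA = not significant at p<=0.01):\n")
  print(round(x$lambda$ks, 3))
  invisible(x)
}

#' Write a Pareto front to CSV
#'
#' One row per member: model, gene values, the three objective scores,
#' Lambda (when objectives are KS-based) and the origin tag.
#'
#' @param front A `pareto_front` of members with [walker_params()] params.
#' @param path Output file.
#' @param alpha Lambda weight.
#' @export
write_front_csv <- function(front, path, alpha = 1) {
  stopifnot(inherits(front, "pareto_front"))
  rows <- lapply(front$members, function(m) {
    lam <- tryCatch(lambda_score(m, alpha = alpha),
                    error = function(e) NA_real_)
    as.data.frame(c(list(model = m$params$model),
                    as.list(m$params$values),
                    list(objective_1 = m$objectives[1L],
                         objective_2 = m$objectives[2L],
                         objective_3 = m$objectives[3L],
                         lambda = lam, alpha = alpha,
                         origin = m$origin, id = m$id)))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
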