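# small programmatic fixtures shared across test files

straight_track <- function(id = "s", n = 6, dt = 30, step = 5) {
  track(id, t = seq(0, by = dt, length.out = n),
        x = seq(0, by = step, length.out = n), y = 0, z = 0)
}

reversal_track <- function(id = "r", dt = 30, step = 10) {
  # out-and-back along x: every interior turn is an exact 180-degree reversal
  track(id, t = seq(0, by = dt, length.out = 4),
        x = c(0, step, 0, step), y = 0, z = 0)
}

random_track <- function(id, n = 10, dt = 30, scale = 5) {
  steps <- matrix(stats::rnorm(3 * (n - 1), sd = scale), ncol = 3)
  xyz <- rbind(0, apply(steps, 2, cumsum))
  track(id, t = seq(0, by = dt, length.out = n),
        x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
}

random_dataset <- function(n_tracks = 10, n = 10, dt = 30, scale = 5) {
  track_dataset(lapply(seq_len(n_tracks), function(i)
    random_track(sprintf("t%02d", i), n = n, dt = dt, scale = scale)))
}

# brute-force two-sample KS oracle: explicit ECDF sweep over all points
ks_brute <- function(a, b) {
  g <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(g) - stats::ecdf(b)(g)))
}

# O(n^2) non-dominated scan oracle on an objective matrix
nondominated_brute <- function(obj) {
  n <- nrow(obj)
  keep <- logical(n)
  for (i in seq_len(n)) {
    dominated <- FALSE
    for (j in seq_len(n)) {
      if (j != i && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])) {
        dominated <- TRUE; break
      }
    }
    keep[i] <- !dominated
  }
  which(keep)
}

random_members <- function(n, k = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i)
    pareto_member(params = NULL, objectives = stats::runif(k), id = i))
}

# a small bias target with heterogeneous structure and a coupled rho
make_hetero_target <- function(n_groups = 50, seed = 7, rho = -0.5,
                               gen = hetero_gaussian_params(9, 3, 2.5, 0.8)) {
  set.seed(seed)
  counts <- sample(5:30, n_groups, replace = TRUE)
  shell <- bias_target(counts, stats::rnorm(n_groups), 30,
                       mode = "translation", target_rho = rho)
  gd <- suppressWarnings(synthesize_grouped_dataset(gen, shell))
  tgt <- bias_target(gd$counts,
                     vapply(gd$groups, stats::median, numeric(1)),
                     30, mode = "translation")
  tgt$pooled <- unlist(gd$groups, use.names = FALSE)
  tgt
}
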