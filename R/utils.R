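# derive n reproducible sub-seeds (< 2^31) from a master seed
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                   sample.int(.Machine$integer.max - 1L, n))
}

# random unit 3-vectors, one per row (uniform on the sphere)
random_unit_rows <- function(n) {
  v <- matrix(stats::rnorm(3L * n), ncol = 3L)
  nrm <- sqrt(rowSums(v^2))
  zero <- nrm < 1e-12
  if (any(zero)) {
    v[zero, ] <- matrix(rep(c(1, 0, 0), sum(zero)), ncol = 3L, byrow = TRUE)
    nrm[zero] <- 1
  }
  v / nrm
}

# rotate each row of unit-heading matrix h by angle_rad[i] about a uniformly
# random axis perpendicular to it: new = cos(a) h + sin(a) u, u _|_ h
rotate_headings <- function(h, angle_rad) {
  n <- nrow(h)
  u <- matrix(stats::rnorm(3L * n), ncol = 3L)
  u <- u - rowSums(u * h) * h
  nrm <- sqrt(rowSums(u^2))
  bad <- nrm < 1e-9
  if (any(bad)) {
    # degenerate draw: build a perpendicular deterministically
    for (i in which(bad)) {
      e <- if (abs(h[i, 1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      w <- e - sum(e * h[i, ]) * h[i, ]
      u[i, ] <- w
      nrm[i] <- sqrt(sum(w^2))
    }
  }
  u <- u / nrm
  out <- cos(angle_rad) * h + sin(angle_rad) * u
  out / sqrt(rowSums(out^2))
}
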