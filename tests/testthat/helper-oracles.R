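# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# Cox-de Boor recursion for B-splines on simple knots, half-open intervals
# [knot_i, knot_{i+1}).  Returns length(knots) - ord basis functions.
cdb_basis <- function(t, knots, ord = 4) {
  nb <- length(knots) - 1L
  B <- vapply(seq_len(nb), function(i) {
    as.numeric(t >= knots[i] & t < knots[i + 1L])
  }, numeric(length(t)))
  B <- matrix(B, nrow = length(t))
  for (k in 2:ord) {
    nb <- length(knots) - k
    Bk <- matrix(0, length(t), nb)
    for (i in seq_len(nb)) {
      d1 <- knots[i + k - 1L] - knots[i]
      d2 <- knots[i + k] - knots[i + 1L]
      a <- if (d1 > 0) (t - knots[i]) / d1 else 0
      b <- if (d2 > 0) (knots[i + k] - t) / d2 else 0
      Bk[, i] <- a * B[, i] + b * B[, i + 1L]
    }
    B <- Bk
  }
  B
}

# per-base brute-force coverage scan of an interval set over a window
brute_coverage <- function(ivs, a, b) {
  pos <- seq(a, b)
  cov <- rep(0, length(pos))
  for (r in seq_len(nrow(ivs))) {
    cov[pos >= ivs$start[r] & pos < ivs$end[r]] <- 1
  }
  cov
}

# central finite-difference gradient of a scalar function
fd_gradient <- function(f, theta, h = 1e-5) {
  vapply(seq_along(theta), function(j) {
    hj <- h * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + hj
    tm <- theta; tm[j] <- tm[j] - hj
    (f(tp) - f(tm)) / (2 * hj)
  }, numeric(1))
}

# fine-grid Bernoulli discretization simulator: independent check of the
# thinning sampler for non-explosive (inhibitory/neutral) models
bernoulli_simulate <- function(a, b, marks, params, spec, dt = 1) {
  grid <- seq(a + dt / 2, b, by = dt)
  pts <- setNames(lapply(marks, function(k) numeric(0)), marks)
  lag_max <- spec$knots[length(spec$knots)]
  for (t in grid) {
    for (k in marks) {
      a0 <- params$alpha[[k]]$baseline
      eta <- if (length(a0) > 1L) a0[1L] else a0
      for (m in marks) {
        beta <- params$beta[[m]][[k]]
        if (all(beta == 0)) next
        s <- pts[[m]]
        s <- s[s < t & t - s <= lag_max]
        if (length(s) > 0L) eta <- eta + sum(evaluate_h(t - s, beta, spec))
      }
      if (runif(1) < exp(eta) * dt) pts[[k]] <- c(pts[[k]], t)
    }
  }
  pts
}

# small deterministic dataset builders
tiny_windows <- function(n = 1, L = 2000, chrom = "chrT") {
  make_windows(data.frame(chrom = paste0(chrom, seq_len(n)),
                          start = 0, end = L))
}

tiny_dataset <- function(points, n_windows = 1, L = 2000,
                         covariates = NULL) {
  new_dataset(tiny_windows(n_windows, L), points, covariates)
}
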