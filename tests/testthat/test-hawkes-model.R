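spec <- spline_spec()

test_that("design rows and columns follow the stated layout", {
  # empty dataset, one window of length 1000, r = 10: 100 grid rows
  d <- tiny_dataset(list(list(A = numeric(0))), L = 1000)
  des <- build_design(d, "A", spec, r = 10)
  expect_equal(nrow(des$X), 100L)
  expect_equal(sum(des$is_event), 0L)
  expect_equal(sum(des$w), 1000)

  # 8 marks, 2 covariates, per-window baselines over 44 windows:
  # 44 + 2 + 8 * 4 = 78 columns
  w44 <- tiny_windows(44, 5000)
  pts <- rep(list(setNames(lapply(1:8, function(m) numeric(0)),
                           paste0("M", 1:8))), 44)
  pts[[1]]$M1 <- c(100, 700)
  covs <- rep(list(list(c1 = cbind(start = 10, end = 60),
                        c2 = cbind(start = 200, end = 900))), 44)
  d8 <- new_dataset(w44, pts, covs)
  des8 <- build_design(d8, "M1", spec, r = 10,
                       baseline_mode = "per_window")
  expect_equal(ncol(des8$X), 78L)
  expect_error(build_design(d8, "M1", spec, r = 6000), "resolution")
})

test_that("spline-block entries equal the basis at the event lag", {
  d <- tiny_dataset(list(list(S = 100, T = 600)), L = 2000)
  des <- build_design(d, "T", spec, r = 10)
  ev <- which(des$is_event)
  expect_length(ev, 1L)
  x <- as.numeric(des$X[ev, des$col_map$beta[["S"]]])
  expect_equal(x, as.numeric(evaluate_basis(500, spec)), tolerance = 1e-12)
  # the target's own event does not excite itself
  expect_equal(as.numeric(des$X[ev, des$col_map$beta[["T"]]]), rep(0, 4))
})

test_that("log-likelihood reduces to the Poisson closed form when flat", {
  set.seed(21)
  pts <- list(list(A = sort(sample(1:9999, 37))))
  d <- tiny_dataset(pts, L = 10000)
  des <- build_design(d, "A", spec, r = 10)
  a0 <- log(37 / 10000) + 0.3
  theta <- c(a0, rep(0, 4))
  expect_equal(hawkes_loglik(theta, des), 37 * a0 - 10000 * exp(a0),
               tolerance = 1e-12)
})

test_that("gradient matches finite differences; Hessian is concave", {
  set.seed(22)
  sim <- make_synthetic_dataset("one_pair_excitation", seed = 5,
                                n_windows = 2, window_length = 5e4)
  des <- build_design(sim$dataset, "B", spec, r = 10)
  for (rep in 1:3) {
    theta <- c(log(1e-4) + rnorm(1, 0, 0.3), rnorm(8, 0, 0.3))
    g <- hawkes_gradient(theta, des)
    gfd <- fd_gradient(function(th) hawkes_loglik(th, des), theta)
    expect_lt(max(abs(g - gfd) / pmax(abs(gfd), 1e-8)), 1e-6)
    H <- hawkes_hessian(theta, des)
    expect_lt(max(eigen(H, symmetric = TRUE, only.values = TRUE)$values),
              1e-8)
    expect_equal(H, t(H))
  }
})

test_that("log-likelihood is additive over windows and translation invariant", {
  set.seed(23)
  p1 <- list(A = sort(sample(1:1990, 12)), B = sort(sample(1:1990, 9)))
  p2 <- list(A = sort(sample(1:1990, 7)), B = sort(sample(1:1990, 14)))
  d12 <- tiny_dataset(list(p1, p2), n_windows = 2, L = 2000)
  d1 <- tiny_dataset(list(p1), L = 2000)
  d2 <- tiny_dataset(list(p2), L = 2000)
  theta <- c(log(8 / 2000), 0.2, -0.4, 0.1, 0.3, -0.2, 0.5, 0, 0.1)
  ll <- function(d) hawkes_loglik(theta, build_design(d, "A", spec, r = 5))
  expect_equal(ll(d12), ll(d1) + ll(d2), tolerance = 1e-10)

  # translate all coordinates by a constant
  shift <- 5000
  p1s <- lapply(p1, function(p) p + shift)
  dshift <- new_dataset(make_windows(data.frame(chrom = "chrT1",
                                                start = shift,
                                                end = 2000 + shift)),
                        list(p1s))
  expect_equal(ll(d1),
               hawkes_loglik(theta, build_design(dshift, "A", spec, r = 5)),
               tolerance = 1e-10)
})

test_that("linear predictor composes baseline and upstream g factors", {
  d <- tiny_dataset(list(list(S = c(300, 450), T = numeric(0))), L = 2000)
  beta <- c(0.5, -0.3, 0.8, 0.2)
  params <- null_params(c("S", "T"), log(2e-4), spec = spec)
  # no upstream points: lambda equals the baseline
  expect_equal(exp(linear_predictor(100, "T", 1, d, params, spec)), 2e-4)
  params$beta[["S"]][["T"]] <- beta
  # one upstream point at lag s: lambda = baseline * g(s)
  lam1 <- exp(linear_predictor(400, "T", 1, d, params, spec))
  expect_equal(lam1, 2e-4 * g_function(100, beta, spec))
  # two upstream points: the g factors multiply
  lam2 <- exp(linear_predictor(700, "T", 1, d, params, spec))
  expect_equal(lam2,
               2e-4 * g_function(400, beta, spec) *
                 g_function(250, beta, spec))
  # a point never contributes at its own position
  expect_equal(exp(linear_predictor(300, "T", 1, d, params, spec)),
               2e-4 * 1)
})

test_that("g equals exponentiated spline values and is 1 when flat", {
  beta <- c(0.4, -1, 0.3, 0.9)
  s <- seq(0, 1200, by = 25)
  expect_equal(g_function(s, beta, spec),
               exp(drop(cdb_basis(s, spec$knots, 4) %*% beta)))
  expect_equal(g_function(s, rep(0, 4), spec), rep(1, length(s)))
  expect_equal(g_function(1200, beta, spec), 1)
})
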