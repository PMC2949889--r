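spec <- spline_spec()

# small fitted object reused across several tests
sim_small <- make_synthetic_dataset("one_pair_excitation", seed = 31,
                                    n_windows = 4, window_length = 1e5)
fit_small <- suppressWarnings(hawkes_fit(sim_small$dataset, spec, r = 10))

test_that("flat-model MLE recovers the homogeneous Poisson rate exactly", {
  sim <- make_synthetic_dataset("null_independent", seed = 32,
                                n_windows = 2, window_length = 1e5)
  d <- sim$dataset
  fz <- expand.grid(m = d$marks, k = d$marks, stringsAsFactors = FALSE)
  f0 <- hawkes_fit(d, spec, r = 10, fixed_zero = fz, targets = "A")
  n <- sum(vapply(d$points, function(p) length(p$A), integer(1)))
  L <- sum(d$windows$b - d$windows$a)
  expect_equal(exp(f0$fits$A$theta[1]), n / L, tolerance = 1e-6)
  expect_true(f0$fits$A$converged)
})

test_that("concavity: different starts reach the same optimum", {
  d <- sim_small$dataset
  des <- fit_small$fits$B$design
  set.seed(33)
  lls <- replicate(2, {
    start <- c(log(1e-4), rep(0, 8)) + rnorm(9, 0, 0.5)
    opt <- optim(start, fn = hawkes_loglik, gr = hawkes_gradient,
                 design = des, method = "BFGS",
                 control = list(fnscale = -1, maxit = 500,
                                reltol = 1e-10))
    opt$value
  })
  expect_lt(abs(diff(lls)), 1e-6 * max(1, abs(lls[1])))
  expect_equal(lls[1], fit_small$fits$B$loglik,
               tolerance = 1e-6)
})

test_that("confidence bands follow the Wald formula on the log scale", {
  band <- g_confidence_band(fit_small, "A", "B", lags = c(0, 200, 650))
  expect_true(all(band$lower <= band$estimate + 1e-12))
  expect_true(all(band$estimate <= band$upper + 1e-12))
  expect_true(all(band$lower > 0))
  # independent recomputation at one lag
  beta <- coef_beta(fit_small, "A", "B")
  cols <- fit_small$fits$B$col_map$beta[["A"]]
  pos <- match(cols, fit_small$fits$B$free)
  Sig <- fit_small$fits$B$vcov[pos, pos]
  Bt <- as.numeric(cdb_basis(200, spec$knots, 4))
  h <- sum(Bt * beta)
  se <- sqrt(drop(t(Bt) %*% Sig %*% Bt))
  z <- qnorm(0.975)
  expect_equal(band$estimate[2], exp(h), tolerance = 1e-10)
  expect_equal(band$lower[2], exp(h - z * se), tolerance = 1e-10)
  expect_equal(band$upper[2], exp(h + z * se), tolerance = 1e-10)
})

test_that("degenerate covariance collapses the band to the estimate", {
  fake <- fit_small
  fake$fits$B$vcov[] <- 0
  band <- g_confidence_band(fake, "A", "B", lags = seq(0, 1000, 100))
  expect_equal(band$lower, band$estimate, tolerance = 1e-12)
  expect_equal(band$upper, band$estimate, tolerance = 1e-12)
  # flat fitted beta gives a band symmetric on the log scale around 1
  fake2 <- fit_small
  pos <- match(fake2$fits$B$col_map$beta[["A"]], fake2$fits$B$free)
  fake2$fits$B$theta[pos] <- 0
  band2 <- g_confidence_band(fake2, "A", "B", lags = c(100, 500))
  expect_equal(band2$estimate, c(1, 1))
  expect_equal(log(band2$upper), -log(band2$lower), tolerance = 1e-10)
})

test_that("covariate fold-changes exponentiate the Wald interval", {
  sim <- make_synthetic_dataset("with_covariates", seed = 34)
  fitc <- hawkes_fit(sim$dataset, spec, r = 10, targets = "A")
  fc <- covariate_fold_change(fitc, "A", "cov1")
  expect_true(fc["lower"] < fc["estimate"] & fc["estimate"] < fc["upper"])
  # independent recomputation
  fk <- fitc$fits$A
  col <- fk$col_map$covariate[1]
  a <- fk$theta[match(col, fk$free)]
  se <- sqrt(fk$vcov[match(col, fk$free), match(col, fk$free)])
  expect_equal(unname(fc["estimate"]), exp(a))
  expect_equal(unname(fc["upper"]), exp(a + qnorm(0.975) * se))
  expect_error(covariate_fold_change(fitc, "A", "nope"), "not in model")
})

test_that("Holm decisions match the hand-executed step-down rule", {
  # thresholds 0.05/3, 0.05/2, 0.05: all three rejected
  expect_equal(holm_adjust(c(0.01, 0.02, 0.04), 0.05),
               c(TRUE, TRUE, TRUE))
  expect_equal(holm_adjust(c(0.5, 0.6), 0.05), c(FALSE, FALSE))
  expect_equal(holm_adjust(0.04, 0.05), TRUE)
  # step-down stops at the first failure even if later p are small enough
  expect_equal(holm_adjust(c(0.030, 0.026, 0.04), 0.05),
               c(FALSE, FALSE, FALSE))
  # decisions are monotone in the raw p-values
  set.seed(35)
  p <- runif(12)
  dec <- holm_adjust(p, 0.05)
  expect_true(all(p[dec] <= min(c(p[!dec], Inf))))
})

test_that("the LRT is chi-squared referenced with d_beta df", {
  lr <- lrt_local_independence(fit_small, "A", "B")
  expect_equal(lr$df, 4)
  expect_gte(lr$Q, 0)
  expect_equal(lr$p, pchisq(lr$Q, 4, lower.tail = FALSE))
  expect_true(lr$valid)
  # the planted A -> B excitation is detected on this data
  expect_lt(lr$p, 0.01)
  # constrained pairs cannot be tested
  fz <- cbind("A", "B")
  f0 <- hawkes_fit(sim_small$dataset, spec, r = 10, targets = "B",
                   fixed_zero = fz)
  expect_error(lrt_local_independence(f0, "A", "B"), "constrained")
})

test_that("test_all_pairs covers all K^2 ordered pairs with joint Holm", {
  tab <- test_all_pairs(sim_small$dataset, spec, r = 10)
  expect_s3_class(tab, "TestTable")
  expect_equal(nrow(tab), 4L)  # K = 2
  expect_setequal(paste(tab$m, tab$k),
                  c("A A", "A B", "B A", "B B"))
  expect_equal(tab$holm_reject, holm_adjust(tab$p_raw, 0.05))
  expect_true(tab$holm_reject[tab$m == "A" & tab$k == "B"])
  f <- withr::local_tempfile(fileext = ".tsv")
  write_test_table(tab, f)
  re <- read.delim(f)
  expect_equal(nrow(re), 4L)
  expect_equal(re$Q, tab$Q, tolerance = 1e-12)
})

test_that("forward and reverse fits agree on the strong planted pair", {
  tab_f <- test_all_pairs(sim_small$dataset, spec, r = 10)
  tab_r <- test_all_pairs(reverse_dataset(sim_small$dataset), spec, r = 10)
  # effect of A on B fitted forward should appear as B on A in reverse
  expect_true(tab_f$holm_reject[tab_f$m == "A" & tab_f$k == "B"])
  expect_true(tab_r$holm_reject[tab_r$m == "B" & tab_r$k == "A"])
})
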