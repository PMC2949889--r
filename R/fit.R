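#' Maximum-likelihood fit of the multivariate Hawkes model
#'
#' Each target mark's parameters enter only its own term of the joint
#' log-likelihood, so the K marks are fitted independently.  Optimization
#' uses \code{optim(method = "BFGS")} with the analytic gradient, starting
#' from the zero-interaction model (all spline coefficients 0, baseline at
#' the event-rate log-MLE, covariate coefficients 0).  The log-likelihood
#' is concave, so any local maximum reached is the global one and fits are
#' reproducible without seeds.  The per-mark covariance is the inverse of
#' the negative Hessian at the optimum.
#'
#' @param d A \code{MarkedPointDataset}.
#' @param spec A [spline_spec()].
#' @param r Quadrature resolution in bp.
#' @param baseline_mode \code{"shared"} or \code{"per_window"}.
#' @param targets Marks to fit (default all); cross-mark transfer
#'   functions into non-target marks are simply not estimated.
#' @param fixed_zero Optional two-column matrix or data.frame of
#'   (source, target) mark-name pairs whose transfer functions are
#'   constrained to zero.
#' @param keep_design Keep each target's design in the fit object
#'   (reused by [lrt_local_independence()]; turn off to save memory).
#' @param control Passed to \code{optim} (merged over sensible defaults).
#' @return An object of class \code{HawkesFit}: per-target list with
#'   \code{theta} (free coordinates), \code{free} column indices,
#'   \code{col_map}, \code{vcov}, \code{loglik}, \code{converged}; plus
#'   the shared configuration.
#' @export
hawkes_fit <- function(d, spec = spline_spec(), r = 10,
                       baseline_mode = c("shared", "per_window"),
                       targets = d$marks, fixed_zero = NULL,
                       keep_design = TRUE, control = list()) {
  stopifnot(inherits(d, "MarkedPointDataset"), all(targets %in% d$marks))
  baseline_mode <- match.arg(baseline_mode)
  fits <- setNames(vector("list", length(targets)), targets)
  for (k in targets) {
    design <- build_design(d, k, spec, r, baseline_mode, collapse = TRUE)
    zero_src <- fixed_zero_sources(fixed_zero, k)
    fits[[k]] <- fit_one_mark(d, design, zero_src, control)
    if (keep_design) fits[[k]]$design <- design
  }
  structure(list(fits = fits, marks = d$marks, targets = targets,
                 spec = spec, r = r, baseline_mode = baseline_mode,
                 cov_names = d$cov_names, n_windows = nrow(d$windows)),
            class = "HawkesFit")
}

fixed_zero_sources <- function(fixed_zero, k) {
  if (is.null(fixed_zero)) return(character(0))
  fz <- as.matrix(fixed_zero)
  if (ncol(fz) != 2L) stop("fixed_zero needs two columns (source, target)")
  fz[fz[, 2L] == k, 1L]
}

fit_one_mark <- function(d, design, zero_src = character(0),
                         control = list(), start = NULL) {
  free <- setdiff(seq_len(ncol(design$X)),
                  unlist(design$col_map$beta[zero_src]))
  if (is.null(start)) {
    start <- numeric(ncol(design$X))
    L <- d$windows$b - d$windows$a
    n_ik <- vapply(d$points, function(p) length(p[[design$k]]), integer(1))
    if (design$baseline_mode == "per_window") {
      start[design$col_map$baseline] <- log((n_ik + 0.5) / L)
    } else {
      start[design$col_map$baseline] <- log((sum(n_ik) + 0.5) / sum(L))
    }
    start <- start[free]
  }
  ctl <- modifyList(list(maxit = 500L, reltol = 1e-9, fnscale = -1,
                         optimizer = "newton"),
                    control)
  opt <- if (identical(ctl$optimizer, "newton")) {
    newton_maximize(start, design, free, reltol = ctl$reltol)
  } else {
    stats::optim(start, fn = hawkes_loglik, gr = hawkes_gradient,
                 design = design, free = free, method = "BFGS",
                 control = ctl[c("maxit", "reltol", "fnscale")])
  }
  H <- hawkes_hessian(opt$par, design, free)
  vc <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(vc)) {
    # directions the data leave flat (coefficients drifting to -Inf)
    # make the Hessian numerically singular; a small ridge yields a
    # covariance that is essentially unchanged in identified directions
    # and honestly enormous in the flat ones
    ridge <- 1e-10 * max(1, max(abs(diag(H))))
    vc <- tryCatch(solve(-H + diag(ridge, nrow(H))),
                   error = function(e) NULL)
    if (is.null(vc)) {
      warning("singular Hessian for mark ", design$k,
              "; covariance unavailable")
    } else {
      warning("numerically singular Hessian for mark ", design$k,
              "; covariance from a ridge-regularized inverse")
    }
  }
  list(k = design$k, theta = opt$par, free = free,
       col_map = design$col_map, vcov = vc, loglik = opt$value,
       converged = opt$convergence == 0L, zero_src = zero_src)
}

# Damped Newton ascent with step halving.  Concavity of the
# log-likelihood makes this globally convergent and far cheaper than a
# quasi-Newton method here, since the analytic Hessian costs little more
# than a gradient on the sparse design; a small ridge handles directions
# left flat by the data (coefficients unbounded below are simply stopped
# by the relative-tolerance rule).
newton_maximize <- function(start, design, free, reltol = 1e-9,
                            maxit = 60L) {
  # subset the free columns once up front
  if (!is.null(free) && length(free) < ncol(design$X)) {
    design$X <- design$X[, free, drop = FALSE]
  }
  free <- NULL
  theta <- start
  ll <- hawkes_loglik(theta, design, free)
  conv <- 1L
  for (it in seq_len(maxit)) {
    g <- hawkes_gradient(theta, design, free)
    H <- hawkes_hessian(theta, design, free)
    step <- tryCatch(solve(-H, g), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      ridge <- 1e-8 * max(1, -min(diag(H)))
      step <- solve(-H + diag(ridge, nrow(H)), g)
    }
    t_ls <- 1
    repeat {
      cand <- theta + t_ls * step
      llc <- suppressWarnings(hawkes_loglik(cand, design, free))
      if (is.finite(llc) && llc >= ll) break
      t_ls <- t_ls / 2
      if (t_ls < 1e-10) { llc <- ll; cand <- theta; break }
    }
    done <- (llc - ll) < reltol * (abs(ll) + 1e-3)
    theta <- cand
    ll <- llc
    if (done) { conv <- 0L; break }
  }
  list(par = theta, value = ll, convergence = conv)
}

#' Extract a fitted spline coefficient vector
#'
#' @param fit A \code{HawkesFit}.
#' @param m Source mark name.
#' @param k Target mark name.
#' @return Coefficient vector \eqn{\hat\beta^{mk}} (zeros if the pair was
#'   constrained out).
#' @export
coef_beta <- function(fit, m, k) {
  fk <- fit$fits[[k]]
  if (is.null(fk)) stop("mark ", k, " was not a fit target")
  cols <- fk$col_map$beta[[m]]
  beta <- numeric(length(cols))
  pos <- match(cols, fk$free)
  beta[!is.na(pos)] <- fk$theta[pos[!is.na(pos)]]
  beta
}

vcov_block <- function(fit, k, cols) {
  fk <- fit$fits[[k]]
  if (is.null(fk$vcov)) stop("covariance unavailable for mark ", k)
  pos <- match(cols, fk$free)
  if (anyNA(pos)) stop("requested parameters were constrained to zero")
  fk$vcov[pos, pos, drop = FALSE]
}

#' Pointwise confidence band for a g-function
#'
#' The band for \eqn{h} at lag \eqn{t} is
#' \eqn{\hat h(t) \pm z_{0.975}\sqrt{B(t)^T \hat\Sigma B(t)}} with
#' \eqn{\hat\Sigma} the covariance block of \eqn{\hat\beta^{mk}}; it is
#' mapped through the exponential to a band for
#' \eqn{g = e^h}.
#'
#' @param fit A \code{HawkesFit} with available covariance.
#' @param m,k Source and target mark names.
#' @param lags Lag grid in bp (default 0:1000).
#' @param level Confidence level.
#' @return Data frame with columns \code{lag}, \code{estimate},
#'   \code{lower}, \code{upper} (all strictly positive).
#' @export
g_confidence_band <- function(fit, m, k, lags = 0:1000, level = 0.95) {
  beta <- coef_beta(fit, m, k)
  B <- evaluate_basis(lags, fit$spec)
  h <- drop(B %*% beta)
  Sig <- vcov_block(fit, k, fit$fits[[k]]$col_map$beta[[m]])
  se <- sqrt(pmax(rowSums((B %*% Sig) * B), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(lag = lags, estimate = exp(h),
             lower = exp(h - z * se), upper = exp(h + z * se))
}

#' Covariate fold-change of the baseline intensity
#'
#' The multiplicative effect of covariate \eqn{j} on mark \eqn{k} is
#' \eqn{\gamma_j^k = e^{\alpha_j^k}}; its confidence interval is the
#' exponentiated Wald interval for \eqn{\alpha_j^k}.
#'
#' @param fit A \code{HawkesFit}.
#' @param k Target mark name.
#' @param j Covariate name or index.
#' @param level Confidence level.
#' @return Named vector with \code{estimate}, \code{lower}, \code{upper}.
#' @export
covariate_fold_change <- function(fit, k, j, level = 0.95) {
  if (is.character(j)) j <- match(j, fit$cov_names)
  if (is.na(j) || j < 1L || j > length(fit$cov_names)) {
    stop("covariate not in model")
  }
  fk <- fit$fits[[k]]
  col <- fk$col_map$covariate[j]
  a <- fk$theta[match(col, fk$free)]
  se <- sqrt(diag(vcov_block(fit, k, col)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(estimate = exp(a), lower = exp(a - z * se), upper = exp(a + z * se))
}

#' @exportS3Method base::print
print.HawkesFit <- function(x, ...) {
  cat("HawkesFit:", length(x$targets), "target mark(s) of",
      length(x$marks), ";", x$baseline_mode, "baseline(s), r =", x$r,
      "bp\n")
  ll <- vapply(x$fits, `[[`, numeric(1), "loglik")
  conv <- vapply(x$fits, `[[`, logical(1), "converged")
  for (k in x$targets) {
    cat(sprintf("  %s: loglik = %.3f, converged = %s\n", k, ll[[k]],
                conv[[k]]))
  }
  invisible(x)
}
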