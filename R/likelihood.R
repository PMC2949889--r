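#' Log-likelihood, gradient and Hessian on a discretized design
#'
#' With row linear predictors \eqn{\eta = X\theta}, the discretized
#' log-likelihood for the target mark is
#' \deqn{l(\theta) = \sum_{\mathrm{event\ rows}} \eta
#'   - \sum_{\mathrm{grid\ rows}} w\, e^{\eta},}
#' its gradient is \eqn{X_{ev}^T 1 - X^T (w e^{\eta})} and its Hessian is
#' \eqn{-X^T \mathrm{diag}(w e^{\eta}) X}, which is negative semidefinite:
#' the log-likelihood is concave in \eqn{\theta}.  Linear predictors above
#' an internal clamp are truncated inside the exponential (with a warning)
#' to keep optimization iterates finite; the clamp never binds at
#' realistic parameter values.
#'
#' @param theta Parameter vector (baseline block, covariate block, spline
#'   coefficient blocks; see [build_design()]).
#' @param design A \code{HawkesDesign}.
#' @param free Optional integer vector of free column indices; columns not
#'   listed are constrained to zero and \code{theta} is given in the free
#'   coordinates.  Used for the reduced models of the local-independence
#'   tests.
#' @return \code{hawkes_loglik}: scalar log-likelihood;
#'   \code{hawkes_gradient}: vector of length \code{length(theta)};
#'   \code{hawkes_hessian}: dense symmetric matrix.
#' @export
hawkes_loglik <- function(theta, design, free = NULL) {
  X <- design_free(design, free)
  eta <- as.numeric(X %*% theta)
  sum(eta[design$is_event]) - sum(design$w * exp(clamp_eta(eta)))
}

#' @rdname hawkes_loglik
#' @export
hawkes_gradient <- function(theta, design, free = NULL) {
  X <- design_free(design, free)
  eta <- as.numeric(X %*% theta)
  mu <- design$w * exp(clamp_eta(eta))
  as.numeric(Matrix::crossprod(X, as.numeric(design$is_event) - mu))
}

#' @rdname hawkes_loglik
#' @export
hawkes_hessian <- function(theta, design, free = NULL) {
  X <- design_free(design, free)
  eta <- as.numeric(X %*% theta)
  mu <- design$w * exp(clamp_eta(eta))
  Xw <- X
  Xw@x <- X@x * mu[X@i + 1L]   # row scaling on the dgCMatrix slots
  H <- -as.matrix(Matrix::crossprod(X, Xw))
  (H + t(H)) / 2
}

design_free <- function(design, free) {
  if (is.null(free)) design$X else design$X[, free, drop = FALSE]
}

clamp_eta <- function(eta) {
  if (any(eta > .ETA_CLAMP)) {
    warning("linear predictor clamped at ", .ETA_CLAMP,
            " in the likelihood; estimates near the clamp are unreliable")
    eta <- pmin(eta, .ETA_CLAMP)
  }
  eta
}

#' Linear predictor of the conditional log-intensity at a position
#'
#' Direct (non-discretized) evaluation of
#' \eqn{\log\lambda_k^{(i)}(t) = (\alpha^{(i)k})^T X_i(t) +
#'   \sum_m \sum_{s < t} h^{mk}(t - s)}, summing transfer-function
#' contributions of all strictly upstream points within the basis range.
#' A point never contributes to its own intensity.
#'
#' @param t Position (scalar).
#' @param k Target mark name.
#' @param i Window index.
#' @param d A \code{MarkedPointDataset}.
#' @param params A [hawkes_params()] object.
#' @param spec A [spline_spec()].
#' @return The scalar linear predictor \eqn{\eta}; the intensity is
#'   \eqn{e^\eta} (or its capped version during simulation).
#' @export
linear_predictor <- function(t, k, i, d, params, spec = spline_spec()) {
  a0 <- params$alpha[[k]]$baseline
  eta <- if (length(a0) > 1L) a0[i] else a0
  if (length(params$alpha[[k]]$covariate) > 0L) {
    for (j in seq_along(d$cov_names)) {
      eta <- eta + params$alpha[[k]]$covariate[j] *
        covariate_value(d$covariates[[i]][[d$cov_names[j]]], t)
    }
  }
  lag_max <- spec$knots[length(spec$knots)]
  for (m in d$marks) {
    beta <- params$beta[[m]][[k]]
    if (all(beta == 0)) next
    s <- d$points[[i]][[m]]
    s <- s[s < t & t - s <= lag_max]
    if (length(s) > 0L) {
      eta <- eta + sum(evaluate_h(t - s, beta, spec))
    }
  }
  eta
}

#' The multiplicative transfer function g
#'
#' \eqn{g_{m,k}(s) = e^{h^{mk}(s)}} is the factor by which a mark-m point
#' changes the intensity of mark k at downstream distance \eqn{s}.  It
#' equals 1 identically when \eqn{\beta^{mk} = 0} (local independence) and
#' beyond the basis range.
#'
#' @param s Lags in bp (vectorized), \code{s >= 0}.
#' @param beta Spline coefficient vector for the (m, k) pair.
#' @param spec A [spline_spec()].
#' @return Vector of fold-changes, strictly positive.
#' @export
g_function <- function(s, beta, spec = spline_spec()) {
  stopifnot(all(s >= 0))
  exp(evaluate_h(s, beta, spec))
}

#' Parameter container for the Hawkes model
#'
#' @param marks Mark names.
#' @param alpha Named list per mark: list with \code{baseline} (scalar, or
#'   vector over windows for per-window baselines, on the log scale) and
#'   \code{covariate} (vector of log fold-changes, possibly empty).
#' @param beta Named list-of-lists: \code{beta[[m]][[k]]} is the spline
#'   coefficient vector for the effect of source mark m on target mark k.
#' @return An object of class \code{HawkesParams}.
#' @export
hawkes_params <- function(marks, alpha, beta) {
  stopifnot(all(marks %in% names(alpha)), all(marks %in% names(beta)))
  structure(list(marks = marks, alpha = alpha, beta = beta),
            class = "HawkesParams")
}

#' Zero-interaction parameters (all transfer functions flat)
#'
#' @param marks Mark names.
#' @param log_baseline Log baseline intensity, scalar or per-window
#'   vector, recycled across marks.
#' @param n_cov Number of covariates (coefficients set to 0).
#' @param spec A [spline_spec()].
#' @return A \code{HawkesParams} with all \code{beta} zero.
#' @export
null_params <- function(marks, log_baseline, n_cov = 0,
                        spec = spline_spec()) {
  alpha <- setNames(lapply(marks, function(k) {
    list(baseline = log_baseline, covariate = rep(0, n_cov))
  }), marks)
  beta <- setNames(lapply(marks, function(m) {
    setNames(lapply(marks, function(k) rep(0, spec$d_beta)), marks)
  }), marks)
  hawkes_params(marks, alpha, beta)
}
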