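#' Likelihood-ratio test of local independence for one ordered pair
#'
#' Tests \eqn{H_0: g_{m,k} = 1}, i.e. that the intensity of mark k does
#' not depend on upstream occurrences of mark m given the remaining
#' marks.  The reduced model refits all remaining parameters of mark k
#' with \eqn{\beta^{mk}} fixed at zero; the statistic is
#' \eqn{Q = 2(l_1 - l_0)}, referred to the \eqn{\chi^2} distribution with
#' \code{d_beta} degrees of freedom (4 for the default basis).  A
#' marginally negative Q from optimizer tolerance is clipped to zero with
#' a warning.
#'
#' @param fit A \code{HawkesFit} containing target \code{k} (fitted with
#'   \code{keep_design = TRUE}, otherwise the design is rebuilt and
#'   \code{d} must be supplied).
#' @param m,k Source and target mark names.
#' @param d The dataset (only needed when the design was not kept).
#' @return List with \code{Q}, \code{df}, \code{p} and \code{valid}
#'   (FALSE if the reduced fit failed to converge).
#' @export
lrt_local_independence <- function(fit, m, k, d = NULL) {
  fk <- fit$fits[[k]]
  if (is.null(fk)) stop("mark ", k, " was not a fit target")
  if (m %in% fk$zero_src) {
    stop("pair (", m, ", ", k, ") was already constrained to zero")
  }
  design <- fk$design
  if (is.null(design)) {
    if (is.null(d)) stop("fit has no stored design; supply the dataset")
    design <- build_design(d, k, fit$spec, fit$r, fit$baseline_mode)
  }
  # warm start: the full optimum with the tested block removed
  drop_cols <- fk$col_map$beta[[m]]
  keep <- !(fk$free %in% drop_cols)
  red <- fit_one_mark(NULL, design, zero_src = union(fk$zero_src, m),
                      start = fk$theta[keep])
  Q <- 2 * (fk$loglik - red$loglik)
  if (Q < 0) {
    if (Q < -1e-4) {
      warning(sprintf("negative LRT statistic %.3g for (%s, %s) %s", Q, m,
                      k, "clipped to 0; check convergence"))
    }
    Q <- 0
  }
  df <- fit$spec$d_beta
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE),
       valid = red$converged && fk$converged)
}

#' Holm step-down multiple-testing decisions
#'
#' Controls the family-wise error rate across a family of tests: the
#' ordered p-values \eqn{p_{(1)} \le \dots \le p_{(m)}} are rejected
#' while \eqn{p_{(i)} \le \alpha / (m - i + 1)}, stopping at the first
#' failure.
#'
#' @param p Vector of raw p-values in [0, 1].
#' @param alpha Family-wise level.
#' @return Logical vector of rejections, in the original order.
#' @export
holm_adjust <- function(p, alpha = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm") <= alpha
}

#' Test local independence for all ordered mark pairs
#'
#' Runs the [lrt_local_independence()] test for every ordered pair
#' (m, k), including the self-pairs m = k (self-dependence), and applies
#' Holm's correction jointly over all \eqn{K^2} raw p-values.
#'
#' @param d A \code{MarkedPointDataset}.
#' @param spec A [spline_spec()].
#' @param r Quadrature resolution in bp.
#' @param baseline_mode \code{"shared"} or \code{"per_window"}.
#' @param alpha Family-wise level for the Holm decisions.
#' @param fit Optionally, a precomputed full \code{HawkesFit} (all marks,
#'   designs kept) to reuse.
#' @return A data.frame of class \code{TestTable} with one row per
#'   ordered pair: \code{m}, \code{k}, \code{Q}, \code{df}, \code{p_raw},
#'   \code{holm_reject}, \code{valid}.  The full fit is attached as
#'   attribute \code{"fit"}.
#' @export
test_all_pairs <- function(d, spec = spline_spec(), r = 10,
                           baseline_mode = c("shared", "per_window"),
                           alpha = 0.05, fit = NULL) {
  baseline_mode <- match.arg(baseline_mode)
  if (is.null(fit)) {
    fit <- hawkes_fit(d, spec, r, baseline_mode, keep_design = TRUE)
  }
  marks <- d$marks
  grid <- expand.grid(m = marks, k = marks, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(idx) {
    lrt_local_independence(fit, grid$m[idx], grid$k[idx], d = d)
  })
  tab <- data.frame(m = grid$m, k = grid$k,
                    Q = vapply(res, `[[`, numeric(1), "Q"),
                    df = vapply(res, `[[`, numeric(1), "df"),
                    p_raw = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  tab$holm_reject <- holm_adjust(tab$p_raw, alpha)
  tab$valid <- vapply(res, `[[`, logical(1), "valid")
  class(tab) <- c("TestTable", "data.frame")
  attr(tab, "fit") <- fit
  attr(tab, "alpha") <- alpha
  tab
}

#' Write a test table as TSV
#'
#' @param tab A \code{TestTable}.
#' @param path Output file path.
#' @export
write_test_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab)[, c("m", "k", "Q", "df", "p_raw",
                                            "holm_reject")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
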