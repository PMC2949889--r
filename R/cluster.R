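#' Integrated absolute transfer-function weight
#'
#' The strength of the (m, k) interaction is summarized by
#' \eqn{H^{mk} = \int_0^{T} |h^{mk}(t)|\,dt} with \eqn{T} the last knot
#' (1000 bp by default), evaluated by a midpoint rule at 1 bp.  The
#' absolute value prevents excitatory and inhibitory stretches from
#' cancelling, so mutually repressive pairs also score high.
#'
#' @param beta Spline coefficient vector.
#' @param spec A [spline_spec()].
#' @return Nonnegative scalar in bp x log-fold-change units; exactly 0
#'   when \code{beta} is zero.
#' @export
interaction_weight <- function(beta, spec = spline_spec()) {
  if (all(beta == 0)) return(0)
  upper <- spec$knots[length(spec$knots)]
  grid <- seq(0.5, upper - 0.5, by = 1)
  sum(abs(evaluate_h(grid, beta, spec)))
}

#' Matrix of pairwise interaction weights from a fit
#'
#' @param fit A \code{HawkesFit} with all marks as targets.
#' @return K x K matrix \code{H} with \code{H[m, k]} the weight of the
#'   effect of source mark m on target mark k.
#' @export
interaction_matrix <- function(fit) {
  marks <- fit$marks
  stopifnot(all(marks %in% fit$targets))
  H <- matrix(0, length(marks), length(marks),
              dimnames = list(marks, marks))
  for (m in marks) {
    for (k in marks) {
      H[m, k] <- interaction_weight(coef_beta(fit, m, k), fit$spec)
    }
  }
  H
}

#' Ward clustering of TREs by interaction strength
#'
#' Each mark is represented by the concatenation of its row (outgoing
#' weights) and column (incoming weights) of the interaction matrix,
#' including the self-weight; marks are grouped by hierarchical
#' clustering with Ward's minimum-variance criterion on Euclidean
#' distances.  Marks whose transfer functions are strong within a group
#' and weak across groups cluster together.
#'
#' @param H Interaction weight matrix from [interaction_matrix()].
#' @param k_groups Number of flat groups to cut (default 2).
#' @return List with \code{hclust} (the dendrogram), \code{groups}
#'   (named integer vector from \code{cutree}) and \code{newick}
#'   (Newick string with merge heights).
#' @export
cluster_tres <- function(H, k_groups = 2) {
  stopifnot(is.matrix(H), nrow(H) == ncol(H))
  if (nrow(H) < 2L) stop("clustering needs at least 2 marks")
  features <- cbind(H, t(H))
  rownames(features) <- rownames(H)
  hc <- stats::hclust(stats::dist(features, method = "euclidean"),
                      method = "ward.D2")
  groups <- stats::cutree(hc, k = min(k_groups, nrow(H)))
  phy <- ape::as.phylo(hc)
  list(hclust = hc, groups = groups,
       newick = ape::write.tree(phy))
}
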