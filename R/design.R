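#' Sparse discretized design for one target mark
#'
#' The log-likelihood of the conditional-intensity model involves an
#' integral of the intensity over every window; it is approximated by a
#' midpoint Riemann sum at resolution \code{r}.  Rows of the design are
#' quadrature nodes \code{a_i + r/2, a_i + 3r/2, ...} with weight \code{r}
#' (a shorter final cell is used when the window length is not a multiple
#' of \code{r}), plus one zero-weight row per event of the target mark,
#' carrying the \eqn{\sum_j \log\lambda(t_j)} term.  Columns are the
#' baseline block (one column, or one per window), the covariate block,
#' and \code{d_beta} spline columns per source mark holding
#' \eqn{\sum_j B_l(t - t_j^m)} over source events strictly upstream within
#' the basis range (lags beyond the last knot contribute nothing, hence
#' the matrix is sparse).
#'
#' @param d A \code{MarkedPointDataset}.
#' @param k Target mark name.
#' @param spec A [spline_spec()].
#' @param r Quadrature resolution in bp (>= 1).
#' @param baseline_mode \code{"shared"} (one baseline for all windows) or
#'   \code{"per_window"}.
#' @param collapse Aggregate quadrature rows whose only nonzero entry is
#'   the baseline column (positions beyond the reach of every event and
#'   covariate) into a single row per baseline column with the summed
#'   weight.  The intensity is constant across such rows, so the
#'   log-likelihood, gradient and Hessian are unchanged to machine
#'   precision while the row count drops substantially at low event
#'   densities.  [hawkes_fit()] enables this.
#' @return A list of class \code{HawkesDesign}: sparse matrix \code{X},
#'   quadrature weights \code{w} (0 on event rows), logical
#'   \code{is_event}, the column map \code{col_map} (indices of the
#'   baseline, covariate and per-source-mark spline blocks), and the
#'   configuration.
#' @export
build_design <- function(d, k, spec = spline_spec(), r = 10,
                         baseline_mode = c("shared", "per_window"),
                         collapse = FALSE) {
  stopifnot(inherits(d, "MarkedPointDataset"), k %in% d$marks, r >= 1)
  baseline_mode <- match.arg(baseline_mode)
  M <- nrow(d$windows)
  L <- d$windows$b - d$windows$a
  if (r > min(L)) stop("resolution r exceeds the shortest window length")
  marks <- d$marks
  K <- length(marks)
  J <- length(d$cov_names)
  db <- spec$d_beta
  n_base <- if (baseline_mode == "per_window") M else 1L
  p <- n_base + J + db * K
  col_map <- list(
    baseline = seq_len(n_base),
    covariate = if (J > 0L) n_base + seq_len(J) else integer(0),
    beta = setNames(lapply(seq_len(K), function(m) {
      n_base + J + (m - 1L) * db + seq_len(db)
    }), marks)
  )
  lag_max <- spec$knots[length(spec$knots)]

  rows_i <- vector("list", M)
  trip <- vector("list", M)
  w_i <- vector("list", M)
  ev_i <- vector("list", M)
  row_off <- 0L
  for (i in seq_len(M)) {
    a <- d$windows$a[i]; b <- d$windows$b[i]
    n_full <- floor(L[i] / r)
    rem <- L[i] - n_full * r
    grid <- a + r / 2 + r * (seq_len(n_full) - 1L)
    wts <- rep(r, n_full)
    if (rem > 1e-9) {
      grid <- c(grid, a + n_full * r + rem / 2)
      wts <- c(wts, rem)
    }
    ev <- d$points[[i]][[k]]
    pos <- c(grid, ev)
    wts <- c(wts, rep(0, length(ev)))
    is_ev <- c(rep(FALSE, length(grid)), rep(TRUE, length(ev)))
    o <- order(pos)
    pos <- pos[o]; wts <- wts[o]; is_ev <- is_ev[o]
    nr <- length(pos)

    ti <- list()
    # baseline column(s)
    bcol <- if (baseline_mode == "per_window") i else 1L
    ti[[length(ti) + 1L]] <- cbind(row_off + seq_len(nr), bcol, 1)
    # covariate columns
    if (J > 0L) {
      for (j in seq_len(J)) {
        x <- covariate_value(d$covariates[[i]][[d$cov_names[j]]], pos)
        nz <- which(x != 0)
        if (length(nz) > 0L) {
          ti[[length(ti) + 1L]] <- cbind(row_off + nz, col_map$covariate[j],
                                         x[nz])
        }
      }
    }
    # spline blocks: rows strictly downstream of each source event within
    # the basis range, vectorized over the window's source events
    for (m in seq_len(K)) {
      src <- d$points[[i]][[marks[m]]]
      if (length(src) == 0L) next
      cols <- col_map$beta[[m]]
      lo <- findInterval(src, pos) + 1L            # first row with pos > s
      hi <- findInterval(src + lag_max, pos)       # last row, lag <= max
      len <- pmax(hi - lo + 1L, 0L)
      if (sum(len) == 0L) next
      rr <- sequence(len, from = lo)
      lags <- pos[rr] - rep.int(src, len)
      Bm <- evaluate_basis(lags, spec)
      nz <- which(Bm != 0, arr.ind = TRUE)
      if (nrow(nz) > 0L) {
        ti[[length(ti) + 1L]] <- cbind(row_off + rr[nz[, 1L]],
                                       cols[nz[, 2L]], Bm[nz])
      }
    }
    trip[[i]] <- do.call(rbind, ti)
    w_i[[i]] <- wts
    ev_i[[i]] <- is_ev
    row_off <- row_off + nr
  }
  tr <- do.call(rbind, trip)
  w_all <- unlist(w_i)
  ev_all <- unlist(ev_i)
  if (collapse) {
    # rows whose only entry is the baseline column have a constant
    # predictor per baseline column; pool their quadrature weight
    other <- rep(FALSE, row_off)
    other[tr[tr[, 2L] > n_base, 1L]] <- TRUE
    bare <- !other & !ev_all
    if (any(bare)) {
      bcol <- integer(row_off)
      bcol[tr[tr[, 2L] <= n_base, 1L]] <- tr[tr[, 2L] <= n_base, 2L]
      w_pool <- vapply(seq_len(n_base), function(j) {
        sum(w_all[bare & bcol == j])
      }, numeric(1))
      keep <- which(!bare)
      new_id <- integer(row_off)
      new_id[keep] <- seq_along(keep)
      sel <- new_id[tr[, 1L]] > 0L
      tr <- cbind(new_id[tr[sel, 1L]], tr[sel, 2L], tr[sel, 3L])
      nz <- which(w_pool > 0)
      tr <- rbind(tr, cbind(length(keep) + seq_along(nz), nz,
                            rep(1, length(nz))))
      w_all <- c(w_all[keep], w_pool[nz])
      ev_all <- c(ev_all[keep], rep(FALSE, length(nz)))
      row_off <- length(keep) + length(nz)
    }
  }
  X <- Matrix::sparseMatrix(i = tr[, 1L], j = tr[, 2L], x = tr[, 3L],
                            dims = c(row_off, p))
  structure(list(X = X, w = w_all, is_event = ev_all,
                 col_map = col_map, k = k, marks = marks,
                 cov_names = d$cov_names, spec = spec, r = r,
                 baseline_mode = baseline_mode, n_windows = M),
            class = "HawkesDesign")
}
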