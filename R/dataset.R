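#' Define analysis windows
#'
#' Windows are the bounded intervals \code{[a_i, b_i]} on which the point
#' process is observed: whole chromosomes for genome-wide data, or region
#' files (ENCODE-style pilot regions) read with [read_intervals()].
#'
#' @param x Either an interval data.frame (one row per window) or the
#'   string \code{"chromosomes"}, in which case windows spanning
#'   \code{[0, max(end)]} are derived per chromosome from \code{ivs}.
#' @param ivs Interval data.frame used when \code{x == "chromosomes"}
#'   (typically all mark and covariate intervals combined).
#' @return Window data.frame with columns \code{id}, \code{chrom},
#'   \code{a}, \code{b}.
#' @export
make_windows <- function(x, ivs = NULL) {
  if (is.character(x) && length(x) == 1L && x == "chromosomes") {
    if (is.null(ivs) || nrow(ivs) == 0L) {
      stop("deriving chromosome windows requires intervals")
    }
    chroms <- sort(unique(ivs$chrom))
    b <- vapply(chroms, function(ch) max(ivs$end[ivs$chrom == ch]),
                numeric(1))
    w <- data.frame(id = seq_along(chroms), chrom = chroms,
                    a = 0, b = b, stringsAsFactors = FALSE)
  } else {
    stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
    w <- data.frame(id = seq_len(nrow(x)), chrom = x$chrom,
                    a = x$start, b = x$end, stringsAsFactors = FALSE)
  }
  if (any(w$b <= w$a)) stop("windows must satisfy b > a")
  rownames(w) <- NULL
  w
}

#' Assemble a marked point dataset
#'
#' Reduces each mark's enriched regions to midpoint proxies
#' ([interval_midpoint()]), assigns them to windows, sorts and removes
#' duplicate positions within a mark (the process is simple), and builds
#' the 0/1 covariate tracks per window.  Midpoints falling outside every
#' window are dropped and their count reported via \code{message()}.
#'
#' @param tre_intervals Named list of interval data.frames, one per mark.
#' @param cov_intervals Named list of interval data.frames, one per
#'   covariate (may be empty).
#' @param windows Window data.frame from [make_windows()].
#' @return An object of class \code{MarkedPointDataset}: a list with
#'   \code{windows}, \code{marks}, \code{cov_names},
#'   \code{points[[i]][[mark]]} (sorted positions per window and mark) and
#'   \code{covariates[[i]][[cov]]} (segment matrices).
#' @export
assemble_dataset <- function(tre_intervals, cov_intervals = list(),
                             windows) {
  stopifnot(length(tre_intervals) > 0L, !is.null(names(tre_intervals)))
  marks <- names(tre_intervals)
  cov_names <- names(cov_intervals)
  M <- nrow(windows)
  pts <- vector("list", M)
  covs <- vector("list", M)
  dropped <- 0L
  for (i in seq_len(M)) {
    w <- windows[i, ]
    pts[[i]] <- lapply(tre_intervals, function(iv) {
      iv <- iv[iv$chrom == w$chrom, , drop = FALSE]
      if (nrow(iv) == 0L) return(numeric(0))
      mid <- interval_midpoint(iv$start, iv$end)
      sort(unique(mid[mid >= w$a & mid <= w$b]))
    })
    names(pts[[i]]) <- marks
    covs[[i]] <- lapply(cov_intervals, build_covariate_track, window = w)
    names(covs[[i]]) <- cov_names
  }
  # count midpoints not contained in any window
  for (k in marks) {
    iv <- tre_intervals[[k]]
    if (nrow(iv) == 0L) next
    mid <- interval_midpoint(iv$start, iv$end)
    inside <- rep(FALSE, length(mid))
    for (i in seq_len(M)) {
      w <- windows[i, ]
      inside <- inside | (iv$chrom == w$chrom & mid >= w$a & mid <= w$b)
    }
    dropped <- dropped + sum(!inside)
  }
  if (dropped > 0L) {
    message(dropped, " midpoint(s) outside every window were dropped")
  }
  empty <- marks[vapply(marks, function(k) {
    all(vapply(pts, function(p) length(p[[k]]) == 0L, logical(1)))
  }, logical(1))]
  if (length(empty) > 0L) {
    warning("mark(s) with zero points in all windows retained: ",
            paste(empty, collapse = ", "))
  }
  structure(list(windows = windows, marks = marks, cov_names = cov_names,
                 points = pts, covariates = covs),
            class = "MarkedPointDataset")
}

#' Construct a dataset directly from point positions
#'
#' Lower-level companion to [assemble_dataset()] used by the simulator and
#' in tests, taking already-extracted point positions per window and mark.
#'
#' @param windows Window data.frame.
#' @param points List (over windows) of named lists (over marks) of
#'   positions.
#' @param covariates Optional list (over windows) of named lists of
#'   segment matrices.
#' @param marks Mark names; defaults to the names found in \code{points}.
#' @return A \code{MarkedPointDataset}.
#' @export
new_dataset <- function(windows, points, covariates = NULL, marks = NULL) {
  if (is.null(marks)) marks <- names(points[[1L]])
  M <- nrow(windows)
  stopifnot(length(points) == M)
  if (is.null(covariates)) {
    covariates <- rep(list(setNames(list(), character(0))), M)
  }
  cov_names <- names(covariates[[1L]])
  if (is.null(cov_names)) cov_names <- character(0)
  pts <- lapply(seq_len(M), function(i) {
    p <- lapply(marks, function(k) {
      v <- points[[i]][[k]]
      if (is.null(v)) v <- numeric(0)
      sort(unique(as.numeric(v)))
    })
    names(p) <- marks
    p
  })
  structure(list(windows = windows, marks = marks, cov_names = cov_names,
                 points = pts, covariates = covariates),
            class = "MarkedPointDataset")
}

#' Reverse the genomic direction of a dataset
#'
#' Maps every position \code{t} in window \code{i} to \code{a_i + b_i - t}
#' and mirrors covariate segments, so the model can be estimated in the
#' reverse direction of the genome.  Applying the function twice returns
#' the original dataset.
#'
#' @param d A \code{MarkedPointDataset}.
#' @return The reversed \code{MarkedPointDataset}.
#' @export
reverse_dataset <- function(d) {
  stopifnot(inherits(d, "MarkedPointDataset"))
  for (i in seq_len(nrow(d$windows))) {
    s <- d$windows$a[i] + d$windows$b[i]
    d$points[[i]] <- lapply(d$points[[i]], function(p) sort(s - p))
    d$covariates[[i]] <- lapply(d$covariates[[i]], function(tr) {
      if (nrow(tr) == 0L) return(tr)
      out <- cbind(start = s - tr[, 2L], end = s - tr[, 1L])
      out[order(out[, 1L]), , drop = FALSE]
    })
  }
  d
}

#' @exportS3Method base::print
print.MarkedPointDataset <- function(x, ...) {
  n <- vapply(x$marks, function(k) {
    sum(vapply(x$points, function(p) length(p[[k]]), integer(1)))
  }, integer(1))
  cat("MarkedPointDataset:", nrow(x$windows), "window(s),",
      length(x$marks), "mark(s)\n")
  cat("  total length:", sum(x$windows$b - x$windows$a), "bp\n")
  cat("  points per mark:",
      paste(sprintf("%s=%d", x$marks, n), collapse = ", "), "\n")
  if (length(x$cov_names) > 0L) {
    cat("  covariates:", paste(x$cov_names, collapse = ", "), "\n")
  }
  invisible(x)
}
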