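#' Read genomic intervals from a BED-like file
#'
#' Parses a whitespace- or tab-delimited file whose first three columns are
#' chromosome, start and end in the BED dialect (0-based, half-open).
#' Additional columns are ignored.  Lines starting with \code{#},
#' \code{track} or \code{browser} are skipped.
#'
#' @param path Path to the file.
#' @param label Name attached to every interval (the mark or covariate the
#'   file represents).  Defaults to the file name without extension.
#' @return A data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   and \code{label}.  Empty files yield a zero-row data.frame.
#' @export
read_intervals <- function(path, label = NULL) {
  if (!file.exists(path)) {
    stop("input file not found: ", path)
  }
  if (is.null(label)) {
    label <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*($|#|track\\b|browser\\b)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), label = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(trimws(lines[idx]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    bad <- idx[which(nf < 3L)[1L]]
    stop("malformed line ", bad, " in ", path,
         ": expected at least 3 columns (chrom, start, end)")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1L]]
    stop("malformed line ", bad, " in ", path,
         ": start/end not numeric")
  }
  if (any(start < 0)) {
    bad <- idx[which(start < 0)[1L]]
    stop("invalid interval at line ", bad, " in ", path, ": start < 0")
  }
  if (any(end <= start)) {
    bad <- idx[which(end <= start)[1L]]
    stop("invalid interval at line ", bad, " in ", path, ": end <= start")
  }
  data.frame(chrom = chrom, start = start, end = end, label = label,
             stringsAsFactors = FALSE)
}

#' Midpoint of an enriched region
#'
#' Reduces ChIP enriched regions to single-base binding-site proxies.  With
#' the BED interval \code{[start, end)} viewed as the 1-based inclusive span
#' \code{[start + 1, end]}, the midpoint is \code{floor((start + 1 + end) / 2)}:
#' for even-length regions, where the midpoint falls between two base pairs,
#' the lesser of the two central bases is returned.
#'
#' @param start,end BED coordinates (0-based half-open); vectorized.
#' @return Integer-valued midpoint position(s), 1-based.
#' @export
interval_midpoint <- function(start, end) {
  if (any(end <= start)) stop("end must exceed start")
  floor((start + 1 + end) / 2)
}

#' Build a 0/1 covariate track on a window
#'
#' Covariates that cannot be regarded as point-like (e.g. histone
#' modifications) enter the model through their whole enriched sequence as
#' indicator functions.  Overlapping or touching intervals are unioned and
#' the result is clipped to the window.
#'
#' @param ivs Interval data.frame as returned by [read_intervals()].
#' @param window A single-row window data.frame with columns \code{chrom},
#'   \code{a}, \code{b}.
#' @return A two-column matrix of disjoint \code{[start, end]} segments on
#'   which the indicator is 1 (zero rows if the window is uncovered).
#' @export
build_covariate_track <- function(ivs, window) {
  stopifnot(nrow(window) == 1L)
  out <- matrix(numeric(0), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  if (nrow(ivs) == 0L) return(out)
  ivs <- ivs[ivs$chrom == window$chrom &
               ivs$end > window$a & ivs$start < window$b, , drop = FALSE]
  if (nrow(ivs) == 0L) return(out)
  s <- pmax(ivs$start, window$a)
  e <- pmin(ivs$end, window$b)
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  # merge a sorted interval list in one pass
  ms <- s[1L]; me <- e[1L]
  starts <- numeric(0); ends <- numeric(0)
  for (j in seq_along(s)[-1L]) {
    if (s[j] <= me) {
      me <- max(me, e[j])
    } else {
      starts <- c(starts, ms); ends <- c(ends, me)
      ms <- s[j]; me <- e[j]
    }
  }
  starts <- c(starts, ms); ends <- c(ends, me)
  cbind(start = starts, end = ends)
}

#' Evaluate a covariate track at positions
#'
#' @param track Two-column segment matrix from [build_covariate_track()].
#' @param t Positions (vectorized).
#' @return 0/1 vector; 1 where \code{t} lies in a covered segment
#'   (half-open, matching the BED dialect: \code{start <= t < end}).
#' @export
covariate_value <- function(track, t) {
  if (nrow(track) == 0L) return(numeric(length(t)))
  idx <- findInterval(t, track[, 1L])
  ifelse(idx >= 1L & t < track[pmax(idx, 1L), 2L], 1, 0)
}
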