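## Static functional connectivity: Pearson adjacency matrices and
## within-network FC strength.

## Internal fast path shared with the sliding-window code: plain matrix in,
## plain matrix out. Errors name the offending ROI so that QC can report it.
.pearsonMatrix <- function(x, transform = FALSE, context = "") {
  ss <- .colCenterSS(x)
  if (any(ss == 0)) {
    stop("zero-variance ROI time series", context, ": ",
         paste(colnames(x)[ss == 0], collapse = ", "))
  }
  r <- cor(x)
  r <- (r + t(r)) / 2          # enforce exact symmetry
  diag(r) <- 1
  if (transform) {
    off <- upper.tri(r) | lower.tri(r)
    v <- r[off]
    if (any(abs(v) > 1 - 1e-7)) {
      warning("off-diagonal |r| = 1 clipped to 1 - 1e-7 before atanh")
      v <- .clip(v, -(1 - 1e-7), 1 - 1e-7)
    }
    r[off] <- atanh(v)
  }
  r
}

#' Pearson functional-connectivity matrix
#'
#' Computes the weighted adjacency matrix of pairwise Pearson correlations
#' between ROI time courses. With `transform = TRUE`, Fisher's r-to-z
#' (`atanh`) is applied elementwise to the off-diagonal entries (the
#' validation variant; the main analysis uses raw r). Off-diagonal values
#' with |r| = 1 are clipped to 1 - 1e-7 with a warning before `atanh`.
#'
#' @param ts a [TimeSeriesMatrix-class] or a plain volumes x ROIs matrix.
#' @param transform apply Fisher r-to-z to off-diagonals?
#' @return An [FcMatrix-class].
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
#' fcValues(fcMatrix(x))["a", "b"]  # 1
#' @export
fcMatrix <- function(ts, transform = FALSE) {
  x <- if (is(ts, "TimeSeriesMatrix")) tsMatrix(ts) else as.matrix(ts)
  new("FcMatrix", values = .pearsonMatrix(x, transform),
      transformed = isTRUE(transform))
}

#' Number of unordered ROI pairs
#'
#' `n * (n - 1) / 2`; with the 58-region default-mode set this is 1653, the
#' number of connections averaged into within-network FC strength.
#'
#' @param nRois number of regions (>= 2).
#' @return Integer pair count.
#' @examples
#' countPairs(58)  # 1653
#' @export
countPairs <- function(nRois) {
  if (!is.numeric(nRois) || length(nRois) != 1L || !.isWholeNumber(nRois) ||
      nRois < 2) {
    stop("nRois must be a single integer >= 2")
  }
  as.integer(round(nRois * (nRois - 1) / 2))
}

#' Within-network FC strength
#'
#' The mean of all pairwise connectivity values, i.e. the average over the
#' strict upper triangle of the FC matrix (diagonal excluded).
#'
#' @param fc an [FcMatrix-class] or a symmetric numeric matrix.
#' @return A single number; for raw r matrices it lies in `[-1, 1]`.
#' @export
withinNetworkStrength <- function(fc) {
  v <- if (is(fc, "FcMatrix")) fcValues(fc) else as.matrix(fc)
  off <- v[upper.tri(v)]
  if (any(!is.finite(off))) {
    stop("FC matrix has non-finite off-diagonal entries")
  }
  mean(off)
}
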