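## Sliding-window dynamic FC and the temporal-variability statistic.
##
## For region k, F(i, k) is its connectivity profile in window i: row k of
## the i-th windowed FC matrix with the self-entry removed. Node-wise
## variability is
##   V_k = 1 - mean_{i < j} cor(F(i, k), F(j, k)),
## the mean running over all T(T-1)/2 unordered window pairs (equal to the
## i != j average by symmetry), and network variability V is the mean of
## V_k over regions. Both lie in [0, 2]: 0 for perfectly stable profiles,
## 2 for perfectly anti-correlated ones.

#' Plan a sliding-window segmentation
#'
#' Converts width and step from seconds to volumes and enumerates the
#' maximal set of full windows; trailing volumes that do not fill a window
#' are dropped. The defaults (width 100 s, step 6 s) follow common practice
#' for resting-state dynamic connectivity; the validation grid varies width
#' over 80/100/120 s and step over 6/8/10 s.
#'
#' @param nVolumes number of volumes in the series.
#' @param trS repetition time in seconds.
#' @param widthS window width in seconds (must be an exact multiple of `trS`).
#' @param stepS step length in seconds (must be an exact multiple of `trS`).
#' @return A [WindowSpec-class] with `T = floor((nVolumes - widthVol) /`
#'   `stepVol) + 1` windows; an error if `T < 2`.
#' @examples
#' windowCount(windowPlan(200, trS = 2, widthS = 100, stepS = 6))  # 51
#' @export
windowPlan <- function(nVolumes, trS, widthS = 100, stepS = 6) {
  if (trS <= 0 || widthS <= 0 || stepS <= 0) {
    stop("trS, widthS and stepS must be positive")
  }
  widthVol <- widthS / trS
  stepVol <- stepS / trS
  if (!.isWholeNumber(widthVol)) {
    stop("window width ", widthS, " s is not a whole number of volumes at TR = ",
         trS, " s")
  }
  if (!.isWholeNumber(stepVol)) {
    stop("step length ", stepS, " s is not a whole number of volumes at TR = ",
         trS, " s")
  }
  widthVol <- as.integer(round(widthVol))
  stepVol <- as.integer(round(stepVol))
  if (widthVol > nVolumes) {
    stop("window of ", widthVol, " volumes exceeds series length ", nVolumes)
  }
  nWin <- (nVolumes - widthVol) %/% stepVol + 1L
  if (nWin < 2L) {
    stop("only ", nWin, " full window(s) fit; need at least 2 for a ",
         "variability estimate")
  }
  new("WindowSpec", widthS = widthS, stepS = stepS, trS = trS,
      widthVol = widthVol, stepVol = stepVol,
      starts = as.integer(seq(0L, by = stepVol, length.out = nWin)))
}

#' Windowed connectivity stack
#'
#' Computes the FC matrix of every windowed segment of a subject's time
#' series. Windows use 0-based half-open index ranges
#' `[start, start + widthVol)`.
#'
#' @param ts a [TimeSeriesMatrix-class].
#' @param spec a [WindowSpec-class]; built from `widthS`/`stepS` when `NULL`.
#' @param widthS,stepS window parameters in seconds, used when `spec` is
#'   `NULL`.
#' @param transform apply Fisher r-to-z within every window (validation
#'   variant)?
#' @return A [DfcStack-class].
#' @export
dfcStack <- function(ts, spec = NULL, widthS = 100, stepS = 6,
                     transform = FALSE) {
  stopifnot(is(ts, "TimeSeriesMatrix"))
  if (is.null(spec)) {
    spec <- windowPlan(nVolumes(ts), trSeconds(ts), widthS, stepS)
  }
  if (spec@trS != trSeconds(ts)) {
    stop("WindowSpec TR (", spec@trS, " s) does not match the series TR (",
         trSeconds(ts), " s)")
  }
  x <- tsMatrix(ts)
  if (max(windowStarts(spec)) + spec@widthVol > nrow(x)) {
    stop("WindowSpec extends beyond the series length")
  }
  k <- ncol(x)
  nWin <- windowCount(spec)
  vals <- array(NA_real_, dim = c(k, k, nWin),
                dimnames = list(colnames(x), colnames(x), NULL))
  for (i in seq_len(nWin)) {
    s <- windowStarts(spec)[i]
    seg <- x[(s + 1L):(s + spec@widthVol), , drop = FALSE]
    vals[, , i] <- .pearsonMatrix(seg, transform,
                                  context = sprintf(" in window %d", i))
  }
  new("DfcStack", subjectId = subjectId(ts), spec = spec, values = vals,
      transformed = isTRUE(transform))
}

## Profiles of region k across windows: (nRois - 1) x T matrix, self-entry
## removed.
.nodeProfiles <- function(stack, k) {
  stack@values[k, -k, , drop = TRUE]
}

#' Node-wise temporal variability of dynamic FC
#'
#' For region `k`, one minus the mean Pearson correlation between its
#' windowed connectivity profiles over all unordered window pairs. With
#' `k = NULL`, the full vector over regions is returned.
#'
#' @param stack a [DfcStack-class] with `T >= 2` windows.
#' @param k region index (1-based) or `NULL` for all regions.
#' @return Numeric value(s) in `[0, 2]`.
#' @export
nodeVariability <- function(stack, k = NULL) {
  stopifnot(is(stack, "DfcStack"))
  ks <- if (is.null(k)) seq_len(nRois(stack)) else k
  out <- vapply(ks, function(kk) {
    prof <- .nodeProfiles(stack, kk)            # (nRois-1) x T
    m <- nrow(prof)
    nT <- ncol(prof)
    pc <- prof - matrix(colMeans(prof), m, nT, byrow = TRUE)
    ss <- colSums(pc^2)
    if (any(ss == 0)) {
      stop("zero-variance connectivity profile for ROI ", kk, " in window(s) ",
           paste(which(ss == 0), collapse = ", "))
    }
    z <- pc / matrix(sqrt(ss), m, nT, byrow = TRUE)
    cc <- crossprod(z)                          # T x T profile correlations
    .clip(1 - (sum(cc) - nT) / (nT * (nT - 1)), 0, 2)
  }, numeric(1))
  dn <- dimnames(stack@values)[[1]]
  if (!is.null(dn)) names(out) <- dn[ks]
  if (is.null(k)) out else unname(out)
}

#' Network-level temporal variability of dynamic FC
#'
#' The arithmetic mean of [nodeVariability()] over all regions.
#'
#' @param stack a [DfcStack-class].
#' @return A single value in `[0, 2]`.
#' @export
networkVariability <- function(stack) {
  mean(nodeVariability(stack))
}

#' Per-subject connectivity outcomes
#'
#' Convenience wrapper computing both outcomes for one subject: static
#' within-network FC strength and dynamic FC temporal variability at the
#' given window parameters.
#'
#' @param ts a [TimeSeriesMatrix-class].
#' @param widthS,stepS sliding-window parameters in seconds.
#' @param transform Fisher r-to-z variant?
#' @return A one-row data.frame with columns `subject_id`, `fc_strength`,
#'   `dfc_variability`, `window_width_s`, `step_s`.
#' @export
subjectMetrics <- function(ts, widthS = 100, stepS = 6, transform = FALSE) {
  fc <- fcMatrix(ts, transform = transform)
  stack <- dfcStack(ts, widthS = widthS, stepS = stepS, transform = transform)
  data.frame(subject_id = subjectId(ts),
             fc_strength = withinNetworkStrength(fc),
             dfc_variability = networkVariability(stack),
             window_width_s = widthS, step_s = stepS,
             stringsAsFactors = FALSE)
}
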