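## small internal helpers shared across modules

.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Run `code` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  force(code)
}

## Detect the field separator of a delimited text file: tab preferred,
## comma accepted (common connectome exports use either).
.sniffSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) {
    stop("file is empty: ", path)
  }
  if (grepl("\t", first)) "\t" else ","
}

## Column sums of squares about the column mean; values indistinguishable
## from a constant column at double precision are snapped to exact zero.
.colCenterSS <- function(x) {
  cm <- colMeans(x)
  ss <- colSums((x - matrix(cm, nrow(x), ncol(x), byrow = TRUE))^2)
  tol <- nrow(x) * (1e-12 * (1 + abs(cm)))^2
  ss[ss <= tol] <- 0
  ss
}

.isWholeNumber <- function(x, tol = 1e-8) {
  abs(x - round(x)) < tol
}

## Format numeric columns so that write/read round-trips are exact
## (17 significant digits suffice for IEEE doubles).
.formatFull <- function(x) {
  if (is.double(x)) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- NA_character_
    trimws(out)
  } else {
    x
  }
}
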