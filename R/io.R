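## File I/O: ROI definitions, time series, phenotypes, metrics tables.
## Dialect: tab-separated UTF-8 with a header row; comma accepted by sniffing.
## Missing clinical values are empty fields, never sentinel numbers.

#' Read a ROI definition table
#'
#' Reads a delimited table with columns `label`, `x`, `y`, `z` (MNI mm).
#' With no argument, returns the packaged default: a 58-region default-mode
#' set matching the size of the Power-atlas DMN used in large consortium
#' analyses. The packaged coordinates are a *synthetic* stand-in placed
#' around canonical DMN hubs; they are metadata only and never enter any
#' computation in this package.
#'
#' @param path path to a TSV/CSV file; `NULL` for the packaged default.
#' @return A [RoiSet-class], rows in file order.
#' @examples
#' nRois(readRoiSet())  # 58
#' @export
readRoiSet <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dmn58_synthetic_rois.tsv",
                        package = "dmnAging", mustWork = TRUE)
  }
  tab <- read.table(path, header = TRUE, sep = .sniffSep(path),
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("ROI file must have columns label, x, y, z; missing: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  }
  if (anyDuplicated(tab$label)) {
    stop("duplicated ROI labels: ",
         paste(unique(tab$label[duplicated(tab$label)]), collapse = ", "))
  }
  xyz <- tab[, c("x", "y", "z")]
  bad <- !vapply(xyz, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric coordinate column(s): ",
         paste(c("x", "y", "z")[bad], collapse = ", "))
  }
  RoiSet(tab$label, as.matrix(xyz))
}

#' Read one subject's ROI time-series matrix
#'
#' Expects a delimited text file with a header row of ROI labels and one row
#' per volume. Columns are canonicalized to the `roiSet` label order at read
#' time, so all downstream indexing can assume one fixed order.
#'
#' @param path path to a TSV/CSV file.
#' @param trS repetition time in seconds.
#' @param roiSet a [RoiSet-class] to match columns against, or `NULL` to
#'   accept the file's own column set.
#' @param subjectId identifier; defaults to the file name without extension.
#' @return A [TimeSeriesMatrix-class].
#' @export
readTimeSeries <- function(path, trS, roiSet = NULL, subjectId = NULL) {
  if (is.null(subjectId)) {
    subjectId <- sub("\\.[^.]*$", "", basename(path))
  }
  tab <- read.table(path, header = TRUE, sep = .sniffSep(path),
                    stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(tab)
  if (!is.numeric(mat)) stop("time-series file contains non-numeric values")
  if (anyNA(mat)) stop("time-series file contains missing values")
  if (nrow(mat) < 2L) stop("need at least 2 volumes, got ", nrow(mat))
  if (!is.null(roiSet)) {
    want <- roiLabels(roiSet)
    if (!setequal(colnames(mat), want)) {
      stop("time-series columns do not match the RoiSet labels ",
           "(missing: ", paste(setdiff(want, colnames(mat)), collapse = ", "),
           "; extra: ", paste(setdiff(colnames(mat), want), collapse = ", "),
           ")")
    }
    mat <- mat[, want, drop = FALSE]
  }
  TimeSeriesMatrix(subjectId, mat, trS)
}

#' Write one subject's time-series matrix
#'
#' Tab-separated, full floating precision; [readTimeSeries()] on the result
#' reproduces the matrix exactly.
#'
#' @param ts a [TimeSeriesMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTimeSeries <- function(ts, path) {
  df <- as.data.frame(tsMatrix(ts), check.names = FALSE)
  df[] <- lapply(df, .formatFull)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.requiredPhenotypeCols <- c("subject_id", "diagnosis", "age", "sex",
                            "education", "site", "mean_fd")
.numericPhenotypeCols <- c("age", "education", "mean_fd",
                           "illness_duration", "hamd", "hama")

#' Read a phenotype table
#'
#' Required columns: `subject_id`, `diagnosis` (MDD/HC), `age` (years),
#' `sex` (male/female), `education` (years), `site`, `mean_fd` (mm).
#' Optional clinical columns (`illness_duration` in months, `hamd`, `hama`,
#' `episodicity` first/recurrent) may be blank; blanks become `NA`.
#'
#' @param path path to a TSV/CSV file.
#' @return A data.frame, one row per subject.
#' @export
readPhenotypeTable <- function(path) {
  tab <- read.table(path, header = TRUE, sep = .sniffSep(path),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("", "NA"), colClasses = "character")
  missing <- setdiff(.requiredPhenotypeCols, names(tab))
  if (length(missing)) {
    stop("phenotype table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  for (cc in intersect(.numericPhenotypeCols, names(tab))) {
    raw <- tab[[cc]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- !is.na(raw) & is.na(num)
    if (any(bad)) {
      stop("unparseable numeric value(s) in column ", cc, ": ",
           paste(unique(raw[bad]), collapse = ", "))
    }
    tab[[cc]] <- num
  }
  tab
}

#' Write a phenotype table
#'
#' @param table data.frame of subject records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePhenotypeTable <- function(table, path) {
  out <- as.data.frame(table)
  out[] <- lapply(out, .formatFull)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Write a subject-metrics table
#'
#' Tab-separated with a stable column order and full floating precision so
#' that [readMetrics()] returns an identical table.
#'
#' @param table a metrics data.frame (one row per subject).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetrics <- function(table, path) {
  out <- as.data.frame(table)
  out[] <- lapply(out, .formatFull)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read a subject-metrics table written by [writeMetrics()]
#'
#' @param path path to the TSV file.
#' @return A data.frame.
#' @export
readMetrics <- function(path) {
  read.table(path, header = TRUE, sep = .sniffSep(path),
             stringsAsFactors = FALSE, check.names = FALSE,
             na.strings = c("", "NA"))
}
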