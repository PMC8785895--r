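## Group-level inference: diagnosis-by-age interaction regression,
## comparison of independent correlations, clinical associations, and
## tests recomputable from published summary statistics.

## Build the fixed design used by the interaction model. Coding follows the
## reporting conventions of the analysis it implements:
##   diagnosis: MDD = 0, HC = 1
##   sex:       male = 0, female = 1
##   site:      treatment dummies, lexicographically first site = reference
##   interaction regressor: diagnosis x mean-centered age
.interactionDesign <- function(table) {
  need <- c("diagnosis", "age", "sex", "education", "site", "mean_fd")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("metrics table lacks model column(s): ",
         paste(missing, collapse = ", "))
  }
  if (!all(table$diagnosis %in% c("MDD", "HC"))) {
    stop("diagnosis must be 'MDD' or 'HC'")
  }
  if (!all(table$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  diag01 <- as.numeric(table$diagnosis == "HC")
  sex01 <- as.numeric(table$sex == "female")
  ageC <- table$age - mean(table$age)
  df <- data.frame(diagnosis = diag01,
                   age = table$age,
                   diagnosis_x_age = diag01 * ageC,
                   sex = sex01,
                   education = table$education,
                   mean_fd = table$mean_fd)
  sites <- sort(unique(as.character(table$site)))
  if (length(sites) > 1L) {
    for (s in sites[-1L]) {
      df[[paste0("site_", s)]] <- as.numeric(as.character(table$site) == s)
    }
  }
  df
}

#' Fit the diagnosis-by-age interaction model
#'
#' Ordinary least squares of an outcome on diagnosis (MDD = 0, HC = 1),
#' age, their interaction (diagnosis times mean-centered age), sex
#' (male = 0, female = 1), education, acquisition-site dummies
#' (lexicographically first site as reference) and mean framewise
#' displacement. Standardized coefficients are computed per term as
#' `b * SD(x) / SD(y)` (dummies included), matching the convention of
#' common statistical GUIs. Centering age before forming the product leaves
#' the interaction t and p unchanged when both main effects are present.
#'
#' @param table a metrics data.frame: one row per subject with phenotype
#'   columns and the outcome.
#' @param outcome name of the outcome column.
#' @return A [RegressionResult-class].
#' @export
fitInteractionModel <- function(table, outcome) {
  table <- as.data.frame(table)
  if (!outcome %in% names(table)) {
    stop("outcome column not found: ", outcome)
  }
  design <- .interactionDesign(table)
  y <- as.numeric(table[[outcome]])
  if (anyNA(y) || anyNA(design)) {
    stop("missing values in model columns; run QC / subset first")
  }
  n <- length(y)
  if (n <= ncol(design) + 1L) {
    stop("n = ", n, " subjects for ", ncol(design) + 1L, " model terms")
  }
  fit <- lm(y ~ ., data = cbind(y = y, design))
  b <- coef(fit)
  if (anyNA(b)) {
    stop("rank-deficient design; offending column(s): ",
         paste(names(b)[is.na(b)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  terms <- rownames(sm)
  terms[terms == "(Intercept)"] <- "intercept"
  sdY <- sd(y)
  betaStd <- vapply(rownames(sm), function(tt) {
    if (tt == "(Intercept)") return(NA_real_)
    unname(sm[tt, 1L]) * sd(design[[tt]]) / sdY
  }, numeric(1))
  cf <- data.frame(term = terms, b = unname(sm[, 1L]),
                   beta_std = unname(betaStd), t = unname(sm[, 3L]),
                   p = unname(sm[, 4L]), stringsAsFactors = FALSE)
  new("RegressionResult", coefficients = cf,
      residuals = unname(stats::residuals(fit)), n = as.integer(n),
      outcomeName = outcome, logTransformed = FALSE,
      moderators = data.frame(age = table$age))
}

#' Within-group correlation between age and an outcome
#'
#' @param table metrics data.frame.
#' @param outcome outcome column name.
#' @param group `"MDD"` or `"HC"`.
#' @return Pearson r.
#' @export
groupAgeCorrelation <- function(table, outcome, group) {
  sub <- table[table$diagnosis == group, , drop = FALSE]
  if (nrow(sub) < 4L) stop("need at least 4 subjects in group ", group)
  x <- sub$age
  y <- sub[[outcome]]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("zero variance in age or ", outcome, " within group ", group)
  }
  cor(x, y)
}

#' Compare two independent Pearson correlations (Fisher r-to-z)
#'
#' The classical large-sample test for equality of correlations observed in
#' independent groups:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-tailed standard-normal p-value.
#'
#' @param r1,r2 group correlations, strictly inside (-1, 1).
#' @param n1,n2 group sizes (> 3).
#' @return A list with `r1`, `n1`, `r2`, `n2`, `z`, `p`.
#' @examples
#' compareIndependentCorrelations(-0.310, 971, -0.216, 902)$z  # about -2.18
#' @export
compareIndependentCorrelations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  if (n1 <= 3 || n2 <= 3) stop("group sizes must exceed 3")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
       z = z, p = 2 * pnorm(-abs(z)))
}

#' Heteroscedasticity diagnostic for a fitted model
#'
#' Spearman rank correlation between a moderator (age, by default the one
#' stored with the fit) and the absolute residuals, with a two-tailed
#' p-value. A significant correlation indicates residual spread changing
#' along the moderator.
#'
#' @param result a [RegressionResult-class].
#' @param moderator numeric vector aligned with the residuals; defaults to
#'   the age values stored in the fit.
#' @return A list with `rho` and `p`.
#' @export
heteroscedasticityCheck <- function(result, moderator = NULL) {
  stopifnot(is(result, "RegressionResult"))
  if (is.null(moderator)) moderator <- result@moderators$age
  if (length(moderator) != length(result@residuals)) {
    stop("moderator length must match the residual vector")
  }
  if (length(unique(moderator)) < 2L) {
    stop("moderator must take at least 2 distinct values")
  }
  absres <- abs(result@residuals)
  if (sd(absres) == 0) {
    stop("absolute residuals are constant; rank correlation undefined")
  }
  ct <- suppressWarnings(
    cor.test(moderator, absres, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Refit the interaction model on the natural log of the outcome
#'
#' The standard mitigation when the heteroscedasticity diagnostic is
#' significant. All outcome values must be strictly positive; the transform
#' is undefined otherwise and no silent shifting is performed.
#'
#' @param table metrics data.frame.
#' @param outcome outcome column name (strictly positive values).
#' @return A [RegressionResult-class] with `logTransformed = TRUE`.
#' @export
logTransformRefit <- function(table, outcome) {
  y <- table[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  if (any(is.na(y)) || any(y <= 0)) {
    stop("logarithmic transform undefined: ", outcome,
         " contains values <= 0 (or NA); no shifting is applied")
  }
  tab2 <- as.data.frame(table)
  logname <- paste0(".log_", outcome)
  tab2[[logname]] <- log(y)
  fit <- fitInteractionModel(tab2, logname)
  fit@outcomeName <- outcome
  fit@logTransformed <- TRUE
  fit
}

#' Partial Pearson correlation controlling for covariates
#'
#' Correlation between the OLS residuals of `x` and `y` after regression on
#' the covariates plus an intercept; the p-value uses
#' `df = n - 2 - k` where `k` is the number of covariate columns. With no
#' covariates this reduces to the plain Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data.frame (n x k) or `NULL`.
#' @return A list with `r`, `p`, `df`, `n`.
#' @export
partialCorrelation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (is.null(covariates) || NCOL(covariates) == 0L ||
      NROW(covariates) == 0L) {
    k <- 0L
    rx <- x - mean(x)
    ry <- y - mean(y)
  } else {
    cm <- as.matrix(as.data.frame(covariates))
    if (nrow(cm) != n) stop("covariates must have one row per observation")
    k <- ncol(cm)
    X <- cbind(1, cm)
    qx <- qr(X)
    if (qx$rank < ncol(X)) stop("rank-deficient covariate matrix")
    rx <- qr.resid(qx, x)
    ry <- qr.resid(qx, y)
  }
  if (n <= k + 3L) stop("need n > k + 3 observations")
  r <- cor(rx, ry)
  df <- n - 2L - k
  tstat <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tstat), df), df = df, n = n)
}

#' ANCOVA for a binary factor with covariates
#'
#' OLS of the outcome on the two-level factor plus covariates; reports the
#' factor's F statistic (the square of its t) and p-value.
#'
#' @param table data.frame.
#' @param outcome outcome column name.
#' @param factorName two-level factor column name.
#' @param covariateNames character vector of covariate column names
#'   (categorical columns are expanded to dummies by the model).
#' @return A list with `F`, `p`, `df1`, `df2`, and the factor contrast `level`.
#' @export
ancovaBinary <- function(table, outcome, factorName,
                         covariateNames = character()) {
  cols <- c(outcome, factorName, covariateNames)
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    stop("column(s) not found: ", paste(missing, collapse = ", "))
  }
  dat <- table[stats::complete.cases(table[, cols, drop = FALSE]),
               cols, drop = FALSE]
  f <- factor(dat[[factorName]])
  if (nlevels(droplevels(f)) != 2L) {
    stop("factor ", factorName, " must have exactly 2 levels present, got ",
         nlevels(droplevels(f)))
  }
  dat[[factorName]] <- droplevels(f)
  for (cc in covariateNames) {
    if (is.character(dat[[cc]])) dat[[cc]] <- factor(dat[[cc]])
  }
  fml <- stats::reformulate(c(factorName, covariateNames), response = outcome)
  fit <- lm(fml, data = dat)
  sm <- summary(fit)$coefficients
  frow <- grep(paste0("^", factorName), rownames(sm))[1L]
  tstat <- sm[frow, 3L]
  list(F = unname(tstat^2), p = unname(sm[frow, 4L]),
       df1 = 1L, df2 = fit$df.residual,
       level = sub(paste0("^", factorName), "", rownames(sm)[frow]))
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Recomputes a group comparison from published means, SDs and sizes:
#' `t = (m1 - m2) / (sp * sqrt(1/n1 + 1/n2))` with
#' `sp^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`.
#'
#' @param m1,sd1,n1 first group's mean, SD, size.
#' @param m2,sd2,n2 second group's mean, SD, size.
#' @return A list with `t`, `df`, `p`.
#' @export
pooledTFromSummary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be non-negative")
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) stop("t undefined: both SDs zero and means equal")
    return(list(t = Inf * sign(m1 - m2), df = n1 + n2 - 2, p = 0))
  }
  tstat <- (m1 - m2) / (sqrt(sp2) * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df))
}

#' Pearson chi-square test for a 2 x 2 contingency table
#'
#' Without continuity correction (df = 1), as used for sex-by-diagnosis
#' comparisons of counts.
#'
#' @param a,b first row (e.g. males per group).
#' @param c,d second row (e.g. females per group).
#' @return A list with `chi2` and `p`.
#' @examples
#' chiSquare2x2(344, 627, 368, 534)$chi2  # about 5.72
#' @export
chiSquare2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(!.isWholeNumber(cells))) {
    stop("cells must be non-negative integers")
  }
  m <- matrix(cells, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("all table margins must be positive")
  }
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = ct$p.value)
}
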