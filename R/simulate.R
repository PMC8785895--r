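## Seeded multi-site cohort simulator.
##
## Subject-level signal model: a one-factor design with slowly drifting,
## region-specific coupling. At volume t, region k gets
##   x[t, k] = sqrt(rho_k(t)) * c_t + sqrt(1 - rho_k(t)) * e[t, k],
## with c_t a shared standard-normal factor and e independent noise, so the
## instantaneous correlation between two regions is sqrt(rho_j(t) rho_k(t))
## and, with constant rho, exactly rho. Coupling drifts sinusoidally,
##   rho_k(t) = clip(rhoTarget + alphaTarget * sin(2 pi t/P + phi + psi_k)),
## with one subject-level phase phi and independent region phases psi_k, so
## the *shape* of each region's connectivity profile changes over time and
## the temporal-variability statistic responds to alphaTarget. The drift
## period (default 200 s) deliberately exceeds the analysis window width:
## fluctuation faster than the window averages out inside each window and
## is invisible to windowed estimates. Each series finally passes an AR(1)
## filter (hemodynamic-like autocorrelation) and is re-standardized, which
## leaves zero-lag correlations of the white factor model unchanged.

## Per-site scan lengths and TR emulating a 20-centre consortium
## acquisition table (volumes 150-250, TR 2 s); sampling weights follow the
## centres' relative sample sizes.
.defaultSiteTable <- function() {
  data.frame(
    site = sprintf("s%02d", c(1, 2, 3, 6, 7, 8, 9, 10, 11, 12, 15, 16, 17,
                              18, 20, 21, 22, 23, 24, 25)),
    n_volumes = c(210, 200, 150, 180, 184, 200, 200, 240, 200, 240, 240,
                  200, 240, 200, 242, 240, 250, 240, 160, 240),
    tr_s = 2,
    weight = c(142, 55, 57, 28, 72, 94, 95, 39, 55, 35, 88, 57, 74, 38,
               506, 146, 42, 56, 52, 142),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Collects the generator parameters with defaults that emulate the study
#' conditions the pipeline targets: two diagnostic groups scanned at
#' multiple sites (150-250 volumes at TR = 2 s), a within-network coupling
#' level that declines with age faster in the patient group (the
#' interaction of interest), and a temporal-fluctuation amplitude that
#' rises with age. Slopes are free parameters in generator-native units;
#' the defaults make the interaction detectable at the default desk-scale
#' cohort of 150 subjects per group.
#'
#' @param nPerGroup subjects per diagnostic group.
#' @param ageRange min/max age in years (uniform sampling).
#' @param rho0 baseline coupling (mid-age within-network correlation).
#' @param slopeHc,slopeMdd change in target coupling per year of age;
#'   `slopeMdd` more negative emulates accelerated decline in patients.
#' @param alpha0 baseline fluctuation amplitude of the coupling.
#' @param alphaAgeSlope amplitude change per year of age.
#' @param subjectNoiseSd between-subject SD added to both targets.
#' @param arCoef AR(1) coefficient of the temporal smoothing, in `[0, 1)`.
#' @param driftPeriodS coupling drift period in seconds (longer than the
#'   analysis window width so the drift survives window averaging).
#' @param nRois number of regions to simulate.
#' @param siteTable data.frame with columns `site`, `n_volumes`, `tr_s`,
#'   `weight`.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nPerGroup = 150,
                             ageRange = c(18, 65),
                             rho0 = 0.40,
                             slopeHc = -0.0015,
                             slopeMdd = -0.0030,
                             alpha0 = 0.15,
                             alphaAgeSlope = 0.002,
                             subjectNoiseSd = 0.05,
                             arCoef = 0.3,
                             driftPeriodS = 200,
                             nRois = 58,
                             siteTable = .defaultSiteTable()) {
  stopifnot(rho0 > 0, rho0 < 1, alpha0 >= 0, subjectNoiseSd >= 0,
            arCoef >= 0, arCoef < 1, nPerGroup >= 1, nRois >= 2,
            length(ageRange) == 2L, ageRange[1] < ageRange[2],
            all(c("site", "n_volumes", "tr_s", "weight") %in%
                  names(siteTable)))
  structure(list(nPerGroup = nPerGroup, ageRange = ageRange, rho0 = rho0,
                 slopeHc = slopeHc, slopeMdd = slopeMdd, alpha0 = alpha0,
                 alphaAgeSlope = alphaAgeSlope,
                 subjectNoiseSd = subjectNoiseSd, arCoef = arCoef,
                 driftPeriodS = driftPeriodS, nRois = nRois,
                 siteTable = siteTable,
                 rhoClip = c(0.05, 0.90)),
            class = "SimulationConfig")
}

#' Simulate one subject's ROI time series
#'
#' @param rhoTarget target within-network coupling, in (0, 1).
#' @param alphaTarget fluctuation amplitude (>= 0);
#'   `rhoTarget +/- alphaTarget` must stay inside (0, 1).
#' @param nVolumes scan length in volumes.
#' @param trS repetition time in seconds.
#' @param nRois number of regions.
#' @param arCoef AR(1) smoothing coefficient in `[0, 1)`.
#' @param seed integer seed; identical arguments give identical output.
#' @param subjectId identifier stored on the result.
#' @param roiLabels column labels; autogenerated when `NULL`.
#' @param driftPeriodS coupling drift period in seconds.
#' @return A [TimeSeriesMatrix-class], `nVolumes x nRois`, each column
#'   standardized.
#' @export
simulateSubject <- function(rhoTarget, alphaTarget, nVolumes, trS = 2,
                            nRois = 58, arCoef = 0.3, seed = 1,
                            subjectId = "sim", roiLabels = NULL,
                            driftPeriodS = 200) {
  if (rhoTarget <= 0 || rhoTarget >= 1) stop("rhoTarget must be in (0, 1)")
  if (alphaTarget < 0) stop("alphaTarget must be >= 0")
  if (rhoTarget - alphaTarget <= 0 || rhoTarget + alphaTarget >= 1) {
    stop("rhoTarget +/- alphaTarget must stay inside (0, 1)")
  }
  if (arCoef < 0 || arCoef >= 1) stop("arCoef must be in [0, 1)")
  if (is.null(roiLabels)) {
    roiLabels <- sprintf("DMN_%02d", seq_len(nRois))
  }
  withSeed(seed, {
    phi <- runif(1, 0, 2 * pi)
    psi <- runif(nRois, 0, 2 * pi)
    pVol <- driftPeriodS / trS
    tt <- seq_len(nVolumes)
    rho <- outer(tt, psi, function(t, p) {
      .clip(rhoTarget + alphaTarget * sin(2 * pi * t / pVol + phi + p),
            0.001, 0.999)
    })
    cvec <- rnorm(nVolumes)
    e <- matrix(rnorm(nVolumes * nRois), nVolumes, nRois)
    x <- sqrt(rho) * cvec + sqrt(1 - rho) * e
    if (arCoef > 0) {
      x <- apply(x, 2L, function(col) {
        as.numeric(stats::filter(col, arCoef, method = "recursive"))
      })
    }
    x <- scale(x)
    attr(x, "scaled:center") <- NULL
    attr(x, "scaled:scale") <- NULL
    colnames(x) <- roiLabels
    TimeSeriesMatrix(subjectId, x, trS)
  })
}

## Truncated-normal draw by rejection (bounds assumed to hold decent mass).
.rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lo | out > hi)
  }
  out
}

#' Simulate a multi-site cohort
#'
#' Draws phenotypes (age uniform over the configured range, sex Bernoulli
#' 0.5, education truncated normal(12, 4) above 0, mean FD truncated
#' normal(0.07, 0.03) in `[0, 0.2]`, site multinomial by consortium
#' weights) and, per subject, a coupling target
#' `rho = clip(rho0 + slopeGroup * (age - midpoint) + noise)` and a
#' fluctuation target
#' `alpha = clip(alpha0 + alphaAgeSlope * (age - midpoint) + noise)`, then
#' generates the ROI time series with [simulateSubject()]. Patient-only
#' clinical columns (HAMD, HAMA, illness duration, episodicity) are drawn
#' with realistic availability gaps and are unrelated to the connectivity
#' targets. Fully reproducible from `seed`.
#'
#' @param config a [simulationConfig()] list.
#' @param seed integer root seed; per-subject seeds are derived from it.
#' @param timeSeries generate the time series (`TRUE`) or phenotypes and
#'   targets only (`FALSE`, for fast large-scale statistical simulations)?
#' @return A [DmnCohort-class]; phenotypes carry the generator targets
#'   (`rho_target`, `alpha_target`) and the per-site scan length.
#' @export
simulateCohort <- function(config = simulationConfig(), seed = 1,
                           timeSeries = TRUE) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(seed, {
    nG <- config$nPerGroup
    n <- 2L * nG
    diagnosis <- rep(c("MDD", "HC"), each = nG)
    ids <- c(sprintf("MDD_%04d", seq_len(nG)), sprintf("HC_%04d", seq_len(nG)))
    age <- runif(n, config$ageRange[1], config$ageRange[2])
    mid <- mean(config$ageRange)
    sex <- sample(c("male", "female"), n, replace = TRUE)
    education <- .rtruncnorm(n, 12, 4, lo = 0)
    meanFd <- .rtruncnorm(n, 0.07, 0.03, lo = 0, hi = 0.2)
    siteIdx <- sample.int(nrow(config$siteTable), n, replace = TRUE,
                          prob = config$siteTable$weight)
    slope <- ifelse(diagnosis == "MDD", config$slopeMdd, config$slopeHc)
    rhoT <- .clip(config$rho0 + slope * (age - mid) +
                    rnorm(n, 0, config$subjectNoiseSd),
                  config$rhoClip[1], config$rhoClip[2])
    alphaT <- config$alpha0 + config$alphaAgeSlope * (age - mid) +
      rnorm(n, 0, config$subjectNoiseSd)
    ## keep rho +/- alpha strictly inside (0, 1)
    alphaT <- .clip(alphaT, 0, pmin(rhoT - 0.02, 0.98 - rhoT))
    ## patient-only clinical measures, with availability gaps as seen in
    ## consortium phenotype tables
    hamd <- hama <- dur <- rep(NA_real_, n)
    episodicity <- rep(NA_character_, n)
    isMdd <- diagnosis == "MDD"
    nM <- sum(isMdd)
    hamd[isMdd] <- ifelse(runif(nM) < 0.84,
                          .rtruncnorm(nM, 20.6, 7.8, lo = 0), NA)
    hama[isMdd] <- ifelse(runif(nM) < 0.58,
                          .rtruncnorm(nM, 19.4, 8.9, lo = 0), NA)
    dur[isMdd] <- ifelse(runif(nM) < 0.77,
                         stats::rlnorm(nM, meanlog = 3.03, sdlog = 1.12), NA)
    episodicity[isMdd] <- sample(c("first", "recurrent", NA), nM,
                                 replace = TRUE,
                                 prob = c(364, 234, 373) / 971)
    st <- config$siteTable
    ph <- data.frame(subject_id = ids, diagnosis = diagnosis, age = age,
                     sex = sex, education = education,
                     site = st$site[siteIdx], mean_fd = meanFd,
                     illness_duration = dur, hamd = hamd, hama = hama,
                     episodicity = episodicity,
                     n_volumes = st$n_volumes[siteIdx],
                     tr_s = st$tr_s[siteIdx],
                     rho_target = rhoT, alpha_target = alphaT,
                     stringsAsFactors = FALSE)
    subjectSeeds <- sample.int(.Machine$integer.max - 1L, n)
    tsList <- list()
    if (timeSeries) {
      labels <- sprintf("DMN_%02d", seq_len(config$nRois))
      tsList <- lapply(seq_len(n), function(i) {
        simulateSubject(rhoT[i], alphaT[i], ph$n_volumes[i], ph$tr_s[i],
                        nRois = config$nRois, arCoef = config$arCoef,
                        seed = subjectSeeds[i], subjectId = ids[i],
                        roiLabels = labels,
                        driftPeriodS = config$driftPeriodS)
      })
      names(tsList) <- ids
    }
    rs <- if (config$nRois == 58) readRoiSet() else {
      RoiSet(sprintf("DMN_%02d", seq_len(config$nRois)),
             matrix(0, config$nRois, 3))
    }
    DmnCohort(ph, tsList, rs)
  })
}
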