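test_that("noise-free linear outcome is recovered exactly", {
  tab <- randomMetricsTable(40, seed = 1, nSites = 1)
  tab$y <- 3 + 2 * tab$age
  fit <- suppressWarnings(fitInteractionModel(tab, "y"))  # exact fit warns
  cf <- coefTable(fit)
  expect_equal(cf$b[cf$term == "age"], 2, tolerance = 1e-8)
  expect_equal(cf$b[cf$term == "diagnosis_x_age"], 0, tolerance = 1e-8)
  expect_equal(cf$b[cf$term == "intercept"], 3, tolerance = 1e-6)
  expect_equal(sum(residuals(fit)), 0, tolerance = 1e-8)
})

test_that("simulated interaction parameters fall inside their 95% CIs", {
  tab <- randomMetricsTable(500, seed = 2, nSites = 3)
  d01 <- as.numeric(tab$diagnosis == "HC")
  ageC <- tab$age - mean(tab$age)
  set.seed(3)
  tab$y <- 10 + 1.5 * d01 - 0.5 * tab$age + 0.3 * d01 * ageC + rnorm(500)
  fit <- fitInteractionModel(tab, "y")
  cf <- coefTable(fit)
  for (tm in c("age", "diagnosis_x_age")) {
    b <- cf$b[cf$term == tm]
    se <- b / cf$t[cf$term == tm]
    true <- if (tm == "age") -0.5 else 0.3
    expect_lt(abs(b - true), 1.96 * abs(se))
  }
})

test_that("coefficients match the normal-equations oracle", {
  tab <- randomMetricsTable(30, seed = 4, nSites = 2)
  set.seed(5)
  tab$y <- rnorm(30)
  fit <- fitInteractionModel(tab, "y")
  # independent design construction + closed-form solve
  d01 <- as.numeric(tab$diagnosis == "HC")
  s01 <- as.numeric(tab$sex == "female")
  ageC <- tab$age - mean(tab$age)
  site2 <- as.numeric(tab$site == sort(unique(tab$site))[2])
  X <- cbind(1, d01, tab$age, d01 * ageC, s01, tab$education, tab$mean_fd,
             site2)
  bWant <- drop(solve(crossprod(X), crossprod(X, tab$y)))
  cf <- coefTable(fit)
  bGot <- cf$b[match(c("intercept", "diagnosis", "age", "diagnosis_x_age",
                       "sex", "education", "mean_fd",
                       paste0("site_", sort(unique(tab$site))[2])), cf$term)]
  expect_equal(unname(bGot), unname(bWant), tolerance = 1e-10)
})

test_that("interaction t is unchanged by centering age in the product", {
  tab <- randomMetricsTable(120, seed = 6, nSites = 2)
  set.seed(7)
  tab$y <- 0.5 * tab$age + rnorm(120)
  fit <- fitInteractionModel(tab, "y")
  # uncentered-product fit, built independently
  d01 <- as.numeric(tab$diagnosis == "HC")
  s01 <- as.numeric(tab$sex == "female")
  site2 <- as.numeric(tab$site == sort(unique(tab$site))[2])
  raw <- lm(y ~ d01 + age + I(d01 * age) + s01 + education + mean_fd + site2,
            data = cbind(tab, d01 = d01, s01 = s01, site2 = site2))
  tRaw <- summary(raw)$coefficients["I(d01 * age)", 3]
  cf <- coefTable(fit)
  expect_equal(cf$t[cf$term == "diagnosis_x_age"], unname(tRaw),
               tolerance = 1e-10)
})

test_that("standardized betas ignore positive rescaling of a predictor", {
  tab <- randomMetricsTable(150, seed = 8, nSites = 2)
  set.seed(9)
  tab$y <- 0.2 * tab$education - 0.1 * tab$age + rnorm(150)
  b1 <- coefTable(fitInteractionModel(tab, "y"))
  tab2 <- tab
  tab2$education <- tab2$education * 10
  b2 <- coefTable(fitInteractionModel(tab2, "y"))
  expect_equal(b1$beta_std[-1], b2$beta_std[-1], tolerance = 1e-10)
})

test_that("degenerate designs are rejected with informative errors", {
  tab <- randomMetricsTable(40, seed = 10, nSites = 2)
  tab$y <- rnorm(40)
  tab$education <- tab$age  # collinear
  expect_error(fitInteractionModel(tab, "y"), "rank-deficient")
  tab2 <- randomMetricsTable(6, seed = 11, nSites = 1)
  tab2$y <- rnorm(6)
  expect_error(fitInteractionModel(tab2, "y"), "model terms")
  tab3 <- randomMetricsTable(40, seed = 12)
  tab3$y <- rnorm(40)
  tab3$age[3] <- NA
  expect_error(fitInteractionModel(tab3, "y"), "missing values")
})

test_that("group age correlations behave as expected", {
  tab <- randomMetricsTable(2000, seed = 13, nSites = 1)
  tab$same <- tab$age
  expect_equal(groupAgeCorrelation(tab, "same", "MDD"), 1)
  set.seed(14)
  tab$indep <- rnorm(2000)
  expect_lt(abs(groupAgeCorrelation(tab, "indep", "MDD")), 0.08)
  tab$neg <- -tab$age + rnorm(2000, sd = 0.1)
  expect_lt(groupAgeCorrelation(tab, "neg", "HC"), -0.99)
  expect_error(groupAgeCorrelation(tab[1:6, ], "same", "MDD"), "4 subjects")
})

test_that("Fisher z comparison reproduces published group comparisons", {
  c1 <- compareIndependentCorrelations(-0.310, 971, -0.216, 902)
  expect_equal(c1$z, -2.183, tolerance = 0.002)
  expect_lt(c1$p, 0.05)
  c2 <- compareIndependentCorrelations(0.434, 971, 0.394, 902)
  expect_equal(c2$z, 1.043, tolerance = 0.002)
  expect_gt(c2$p, 0.05)
})

test_that("Fisher z comparison is antisymmetric and null at equality", {
  for (seed in 1:5) {
    set.seed(seed)
    r1 <- runif(1, -0.9, 0.9); r2 <- runif(1, -0.9, 0.9)
    n1 <- sample(10:500, 1); n2 <- sample(10:500, 1)
    a <- compareIndependentCorrelations(r1, n1, r2, n2)
    b <- compareIndependentCorrelations(r2, n2, r1, n1)
    expect_equal(a$z, -b$z, tolerance = 1e-12)
    expect_equal(a$p, b$p, tolerance = 1e-12)
  }
  eq <- compareIndependentCorrelations(0.3, 50, 0.3, 50)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  expect_error(compareIndependentCorrelations(1, 50, 0.3, 50), "< 1")
  expect_error(compareIndependentCorrelations(0.5, 3, 0.3, 50), "exceed 3")
})

test_that("heteroscedasticity diagnostic separates flat from scaled noise", {
  tab <- randomMetricsTable(1000, seed = 15, nSites = 2)
  set.seed(16)
  tab$flat <- 0.3 - 0.1 * tab$age + rnorm(1000)
  homo <- heteroscedasticityCheck(fitInteractionModel(tab, "flat"))
  expect_lt(abs(homo$rho), 0.08)
  tab$scaled <- 0.3 - 0.1 * tab$age + rnorm(1000) * (tab$age / 20)
  het <- heteroscedasticityCheck(fitInteractionModel(tab, "scaled"))
  expect_gt(het$rho, 0.3)
  expect_lt(het$p, 1e-6)
  fit <- fitInteractionModel(tab, "flat")
  expect_error(heteroscedasticityCheck(fit, moderator = rep(1, 1000)),
               "distinct")
})

test_that("log refit inverts an exponential outcome exactly", {
  tab <- randomMetricsTable(60, seed = 17, nSites = 1)
  tab$y <- exp(1 + 0.02 * tab$age)
  fit <- suppressWarnings(logTransformRefit(tab, "y"))  # exact fit warns
  cf <- coefTable(fit)
  expect_true(fit@logTransformed)
  expect_equal(cf$b[cf$term == "age"], 0.02, tolerance = 1e-8)
  expect_equal(cf$b[cf$term == "intercept"], 1, tolerance = 1e-6)

  set.seed(18)
  tab$pos <- exp(0.5 + 0.03 * tab$age + rnorm(60, sd = 0.1))
  raw <- coefTable(fitInteractionModel(tab, "pos"))
  logd <- coefTable(logTransformRefit(tab, "pos"))
  expect_equal(sign(logd$t[logd$term == "age"]),
               sign(raw$t[raw$term == "age"]))

  tab$zero <- tab$y; tab$zero[1] <- 0
  expect_error(logTransformRefit(tab, "zero"), "undefined")
})

test_that("partial correlation matches the inverse-correlation-matrix oracle", {
  set.seed(19)
  n <- 50
  Z <- matrix(rnorm(n * 4), n, 4)
  x <- 0.4 * Z[, 1] + rnorm(n)
  y <- -0.3 * Z[, 1] + 0.2 * Z[, 2] + rnorm(n)
  got <- partialCorrelation(x, y, Z)
  Pinv <- solve(cor(cbind(x, y, Z)))
  want <- -Pinv[1, 2] / sqrt(Pinv[1, 1] * Pinv[2, 2])
  expect_equal(got$r, want, tolerance = 1e-10)
  expect_equal(got$df, n - 2 - 4)

  # no covariates -> plain Pearson, p as in cor.test
  plain <- partialCorrelation(x, y)
  expect_equal(plain$r, cor(x, y), tolerance = 1e-12)
  expect_equal(plain$p, cor.test(x, y)$p.value, tolerance = 1e-10)

  # outcome explained by covariates plus noise independent of x:
  # the partial association vanishes up to sampling error
  set.seed(23)
  n2 <- 2000
  Z2 <- matrix(rnorm(n2 * 4), n2, 4)
  x2 <- Z2 %*% c(0.5, -0.2, 0, 1) + rnorm(n2)
  y2 <- Z2 %*% c(1, -2, 0.5, 3) + rnorm(n2)
  ortho <- partialCorrelation(drop(x2), drop(y2), Z2)
  expect_lt(abs(ortho$r), 0.06)
  expect_gt(ortho$p, 0.01)

  expect_error(partialCorrelation(x, y, cbind(Z, Z[, 1])), "rank-deficient")
})

test_that("binary ANCOVA reports F equal to the squared factor t", {
  tab <- randomMetricsTable(200, seed = 20, nSites = 2)
  tab <- tab[tab$diagnosis == "MDD", ]
  set.seed(21)
  tab$episodicity <- sample(c("first", "recurrent"), nrow(tab), TRUE)
  tab$y <- 0.3 - 0.01 * tab$age + rnorm(nrow(tab), sd = 0.05)
  res <- ancovaBinary(tab, "y", "episodicity",
                      c("age", "sex", "education", "site", "mean_fd"))
  # identity against a direct lm fit of the same model
  ref <- lm(y ~ episodicity + age + sex + education + site + mean_fd,
            data = tab)
  tRef <- summary(ref)$coefficients["episodicityrecurrent", 3]
  expect_equal(res$F, unname(tRef^2), tolerance = 1e-10)
  expect_equal(res$p, unname(summary(ref)$coefficients["episodicityrecurrent", 4]),
               tolerance = 1e-12)
  expect_gt(res$p, 0.001)  # no true effect injected

  tab$y2 <- tab$y + (tab$episodicity == "recurrent") * 1
  strong <- ancovaBinary(tab, "y2", "episodicity",
                         c("age", "sex", "education", "site", "mean_fd"))
  expect_gt(strong$F, 100)
  expect_lt(strong$p, 1e-6)

  tab$one <- "first"
  expect_error(ancovaBinary(tab, "y", "one", "age"), "2 levels")
})

test_that("pooled t from summaries reproduces the published education gap", {
  ed <- pooledTFromSummary(11.43, 4.09, 971, 12.47, 4.90, 902)
  expect_equal(ed$t, -4.996, tolerance = abs(-4.996) * 0.005)
  expect_equal(ed$df, 1871)
  expect_lt(ed$p, 0.001)

  expect_equal(pooledTFromSummary(5, 1, 10, 5, 2, 12)$t, 0)

  # matches a raw-data t on a dataset constructed to the same summaries
  set.seed(22)
  mk <- function(n, m, s) { v <- rnorm(n); m + s * (v - mean(v)) / sd(v) }
  g1 <- mk(40, 11.43, 4.09); g2 <- mk(35, 12.47, 4.90)
  want <- t.test(g1, g2, var.equal = TRUE)
  got <- pooledTFromSummary(11.43, 4.09, 40, 12.47, 4.90, 35)
  expect_equal(got$t, unname(want$statistic), tolerance = 1e-10)
  expect_equal(got$p, want$p.value, tolerance = 1e-10)

  expect_error(pooledTFromSummary(5, 0, 10, 5, 0, 10), "undefined")
})

test_that("2x2 chi-square matches the published sex table and closed form", {
  sex <- chiSquare2x2(344, 627, 368, 534)
  expect_equal(sex$chi2, 5.724, tolerance = 0.001)
  expect_lt(sex$p, 0.05)

  expect_equal(chiSquare2x2(10, 20, 30, 60)$chi2, 0, tolerance = 1e-12)

  cells <- c(10, 20, 20, 10)
  nTot <- sum(cells)
  want <- nTot * (10 * 10 - 20 * 20)^2 / (30 * 30 * 30 * 30)
  expect_equal(chiSquare2x2(10, 20, 20, 10)$chi2, want, tolerance = 1e-12)

  expect_error(chiSquare2x2(0, 0, 3, 4), "margins")
  expect_error(chiSquare2x2(1.5, 2, 3, 4), "integers")
})
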