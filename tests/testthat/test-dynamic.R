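test_that("window arithmetic gives the maximal set of full windows", {
  spec <- windowPlan(200, trS = 2, widthS = 100, stepS = 6)
  expect_equal(spec@widthVol, 50L)
  expect_equal(spec@stepVol, 3L)
  expect_equal(windowCount(spec), 51L)          # floor((200 - 50) / 3) + 1
  expect_equal(windowStarts(spec)[1], 0L)
  expect_equal(max(windowStarts(spec)) + spec@widthVol, 200L)  # no overrun

  expect_error(windowPlan(50, 2, 100, 6), "at least 2")     # T would be 1
  expect_error(windowPlan(52, 2, 100, 6), "at least 2")     # only one window
  expect_error(windowPlan(200, 2, 101, 6), "whole number")  # 50.5 volumes
  expect_error(windowPlan(200, 2, 100, 7), "whole number")
})

test_that("dfcStack equals per-window brute-force Pearson loops", {
  ts <- randomTs(48, 6, seed = 21)
  spec <- windowPlan(48, 2, widthS = 20, stepS = 8)
  stack <- dfcStack(ts, spec)
  want <- bfWindowMatrices(ts, widthVol = 10, stepVol = 4)
  expect_equal(windowCount(stack), length(want))
  for (i in seq_along(want)) {
    expect_lt(max(abs(unname(dfcMatrix(stack, i)) - want[[i]])), 1e-12)
  }
  # every windowed matrix is symmetric with unit diagonal
  for (i in seq_len(windowCount(stack))) {
    m <- dfcMatrix(stack, i)
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, 6))
  }
})

test_that("a flat ROI inside one window is reported with window and region", {
  x <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("A", "B", "C")))
  x[11:20, 2] <- 0.5                      # constant inside window 2 only
  ts <- TimeSeriesMatrix("s", x, 2)
  expect_error(dfcStack(ts, widthS = 20, stepS = 20), "window 2.*B")
})

# Build a stack directly from a list of symmetric matrices.
stackFromMats <- function(mats) {
  spec <- new("WindowSpec", widthS = 20, stepS = 10, trS = 2,
              widthVol = 10L, stepVol = 5L,
              starts = as.integer(seq(0, by = 5, length.out = length(mats))))
  new("DfcStack", subjectId = "toy", spec = spec,
      values = array(unlist(mats),
                     dim = c(nrow(mats[[1]]), nrow(mats[[1]]), length(mats))),
      transformed = FALSE)
}

symFromProfile <- function(p, fill = 0.2) {
  k <- length(p) + 1
  m <- matrix(fill, k, k)
  m[1, 2:k] <- m[2:k, 1] <- p
  diag(m) <- 1
  m
}

test_that("node variability hits its exact extremes", {
  base <- symFromProfile(c(0.9, 0.1, 0.5))
  expect_equal(nodeVariability(stackFromMats(list(base, base, base)), 1), 0)

  # perfectly anti-correlated profiles: cor(p, 1 - p) = -1 -> V_k = 2
  p <- c(0.9, 0.1, 0.5)
  anti <- stackFromMats(list(symFromProfile(p), symFromProfile(1 - p)))
  expect_equal(nodeVariability(anti, 1), 2)
})

test_that("three-window node variability equals the pairwise-correlation oracle", {
  set.seed(5)
  profs <- replicate(3, runif(5, -0.5, 0.9), simplify = FALSE)
  mats <- lapply(profs, symFromProfile)
  stack <- stackFromMats(mats)
  r12 <- bfPearson(profs[[1]], profs[[2]])
  r13 <- bfPearson(profs[[1]], profs[[3]])
  r23 <- bfPearson(profs[[2]], profs[[3]])
  expect_equal(nodeVariability(stack, 1), 1 - mean(c(r12, r13, r23)),
               tolerance = 1e-12)
})

test_that("variability equals the double-loop oracle and stays in [0, 2]", {
  for (seed in 1:5) {
    set.seed(seed)
    nRoi <- sample(4:10, 1)
    nVol <- sample(30:60, 1)
    ts <- randomTs(nVol, nRoi, seed = seed + 100)
    widthVol <- sample(8:12, 1)
    spec <- windowPlan(nVol, 2, widthS = 2 * widthVol,
                       stepS = 2 * sample(3:6, 1))
    stack <- dfcStack(ts, spec)
    mats <- lapply(seq_len(windowCount(stack)),
                   function(i) unname(dfcMatrix(stack, i)))
    vk <- nodeVariability(stack)
    expect_true(all(vk >= 0 & vk <= 2))
    for (k in seq_len(nRoi)) {
      expect_equal(unname(vk[k]), bfNodeVariability(mats, k),
                   tolerance = 1e-12)
    }
    expect_equal(networkVariability(stack), mean(vk), tolerance = 1e-12)
  }
})

test_that("variability is invariant to a common affine map of the profiles", {
  ts <- randomTs(60, 6, seed = 77)
  stack <- dfcStack(ts, widthS = 24, stepS = 12)
  shifted <- stack
  shifted@values <- 3.2 * stack@values - 0.4
  expect_equal(nodeVariability(shifted), nodeVariability(stack),
               tolerance = 1e-10)
})

test_that("median variability rises with the injected fluctuation amplitude", {
  meds <- sapply(c(0, 0.2, 0.4), function(alpha) {
    vs <- sapply(1:20, function(s) {
      ts <- simulateSubject(0.5, alpha, nVolumes = 200, trS = 2, nRois = 20,
                            seed = 5000 + s)
      networkVariability(dfcStack(ts, widthS = 100, stepS = 6))
    })
    median(vs)
  })
  expect_true(all(diff(meds) > 0))
})
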