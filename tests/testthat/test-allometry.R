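## build an aligned_dataset by hand from coordinates and sizes
manualAligned <- function(coords, sizes, scheme = NULL) {
  k <- dim(coords)[1]
  if (is.null(scheme)) scheme <- landmarkScheme(sprintf("lm%02d", seq_len(k)))
  n <- dim(coords)[3]
  for (s in seq_len(n)) {
    coords[, , s] <- sweep(coords[, , s], 2, colMeans(coords[, , s]))
    coords[, , s] <- coords[, , s] / sqrt(sum(coords[, , s]^2))
  }
  cons <- apply(coords, c(1, 2), mean)
  structure(list(coords = coords, size = sizes,
                 moduleSize = NULL, consensus = cons / sqrt(sum(cons^2)),
                 scheme = scheme, specimens = sprintf("s%02d", seq_len(n)),
                 iterations = 0L, delta = numeric(0), variant = "raw"),
            class = "aligned_dataset")
}

## noiseless allometric population: shape = base + (log cs - mean) * field
linearAllometric <- function(n = 12, k = 10, seed = 41, noise = 0) {
  set.seed(seed)
  base <- 5 * toyConfig(k, seed = seed)
  field <- matrix(rnorm(3 * k, 0, 0.05), k, 3)
  x <- seq(log(2), log(8), length.out = n)
  arr <- array(NA_real_, c(k, 3, n))
  for (s in seq_len(n)) {
    cfg <- base + (x[s] - mean(x)) * field
    if (noise > 0) cfg <- cfg + matrix(rnorm(3 * k, 0, noise), k, 3)
    cfg <- sweep(cfg, 2, colMeans(cfg))
    arr[, , s] <- cfg * exp(x[s]) / centroidSize(cfg)
  }
  list(arr = arr, x = x, base = base, field = field)
}

test_that("noiseless linear allometry gives R2 = 1 and CAC along the field", {
  ## data exactly linear in log size, analysed in the frame they are given
  set.seed(40)
  k <- 10; n <- 12
  base <- 5 * toyConfig(k, seed = 40)
  field <- matrix(rnorm(3 * k, 0, 0.05), k, 3)
  x <- seq(log(2), log(8), length.out = n)
  arr <- array(NA_real_, c(k, 3, n))
  for (s in seq_len(n)) arr[, , s] <- base + (x[s] - mean(x)) * field
  al <- structure(list(coords = arr, size = exp(x), moduleSize = NULL,
                       consensus = base,
                       scheme = landmarkScheme(sprintf("lm%02d", 1:k)),
                       specimens = sprintf("s%02d", 1:n), iterations = 0L,
                       delta = numeric(0), variant = "raw"),
                  class = "aligned_dataset")
  fit <- fitShapeSizeRegression(al, nPerm = 0)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  ## CAC direction is the (normalised) planted field
  cac <- matrix(fit$cac, k, 3, byrow = TRUE)
  cosang <- abs(sum(cac * field)) / sqrt(sum(field^2))
  expect_gt(cosang, 1 - 1e-10)
  ## predicted shape at an observed size equals that specimen exactly
  pr <- predictShapeAtSize(fit, x[n])
  expect_equal(unname(pr), unname(arr[, , n]), tolerance = 1e-10)
  ## CAC scores correlate perfectly with the fitted shape scores
  fitted <- (fit$logSize - fit$meanLogSize) * fit$cacSlope
  expect_equal(cor(fit$cacScores, fitted), 1, tolerance = 1e-10)
  ## the full Procrustes route still recovers the structure to high order
  lin <- linearAllometric()
  fit2 <- fitShapeSizeRegression(gpa(lin$arr), nPerm = 0)
  expect_gt(fit2$r2, 0.999)
})

test_that("permuting sizes destroys the association and p is calibrated", {
  lin <- linearAllometric(n = 14)
  al <- gpa(lin$arr)
  set.seed(42)
  r2p <- replicate(60, {
    alp <- al
    alp$size <- sample(al$size)
    fitShapeSizeRegression(alp, nPerm = 0)$r2
  })
  expect_lt(median(r2p), 0.35)
  ## permutation p under a true null is roughly uniform
  set.seed(43)
  noise <- manualAligned(array(rnorm(10 * 3 * 12), c(10, 3, 12)),
                         exp(runif(12, 0, 2)))
  ps <- vapply(1:40, function(i) {
    al2 <- noise
    al2$size <- sample(noise$size)
    fitShapeSizeRegression(al2, nPerm = 49, seed = i)$p
  }, numeric(1))
  expect_gt(mean(ps > 0.1), 0.6)
  expect_lt(mean(ps <= 0.05), 0.25)
})

test_that("residual shape components are orthogonal to the CAC scores", {
  sc <- makeScheme(kPerModule = 8, nModules = 3)
  sim <- simulateDataset(syntheticTruth(sc), nSpecimens = 15, seed = 44)
  fit <- fitShapeSizeRegression(gpa(sim$dataset), nPerm = 0)
  expect_equal(sqrt(sum(fit$cac^2)), 1, tolerance = 1e-12)
  for (j in seq_len(min(5, ncol(fit$rscScores)))) {
    expect_lt(abs(cor(fit$rscScores[, j], fit$cacScores)), 1e-8)
  }
  G <- crossprod(fit$rsc[, 1:5])
  expect_equal(G, diag(5), tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(fit$r2 >= 0 && fit$r2 <= 1)
})

test_that("allometry correction removes all size-correlated shape", {
  set.seed(51)
  k <- 8; n <- 10
  base <- 4 * toyConfig(k, seed = 51)
  field <- matrix(rnorm(3 * k, 0, 0.05), k, 3)
  x <- seq(0, 1.5, length.out = n)
  arr <- array(NA_real_, c(k, 3, n))
  for (s in seq_len(n)) arr[, , s] <- base + (x[s] - mean(x)) * field
  al <- structure(list(coords = arr, size = exp(x), moduleSize = NULL,
                       consensus = base,
                       scheme = landmarkScheme(sprintf("lm%02d", 1:k)),
                       specimens = sprintf("s%02d", 1:n), iterations = 0L,
                       delta = numeric(0), variant = "raw"),
                  class = "aligned_dataset")
  corr <- allometryCorrect(al)
  ## noiseless case: every corrected specimen equals the mean shape
  pv <- procrustesVariance(corr)
  expect_lt(pv$total, 1e-12)
  ## refit on corrected data explains nothing
  sc <- makeScheme(kPerModule = 8, nModules = 3)
  sim <- simulateDataset(syntheticTruth(sc), nSpecimens = 15, seed = 45)
  al2 <- gpa(sim$dataset)
  corr2 <- allometryCorrect(al2)
  refit <- fitShapeSizeRegression(corr2, nPerm = 0)
  expect_lt(refit$r2, 1e-10)
})

test_that("corrected disparity matches hand-computed residual variances on a toy", {
  k <- 5; n <- 6
  set.seed(46)
  base <- 3 * toyConfig(k, seed = 3)
  field <- matrix(rnorm(3 * k, 0, 0.04), k, 3)
  x <- seq(0, 1, length.out = n)
  noise <- array(rnorm(k * 3 * n, 0, 0.02), c(k, 3, n))
  arr <- array(NA_real_, c(k, 3, n))
  for (s in seq_len(n)) arr[, , s] <- base + (x[s] - mean(x)) * field +
    noise[, , s]
  al <- manualAligned(arr, exp(x))
  corr <- allometryCorrect(al)
  pv <- procrustesVariance(corr)
  ## hand computation: residuals of each coordinate on centred log size
  Y <- t(apply(al$coords, 3, function(m) as.numeric(t(m))))
  Y <- sweep(Y, 2, colMeans(Y))
  xc <- x - mean(x)
  R <- Y - outer(xc, drop(crossprod(Y, xc)) / sum(xc^2))
  vhand <- vapply(seq_len(k), function(i) {
    sum(R[, 3 * (i - 1) + 1:3]^2) / (n - 1)
  }, numeric(1))
  expect_equal(pv$landmark$variance, vhand, tolerance = 1e-10)
})

test_that("module size slopes recover constructed scaling exponents exactly", {
  sc <- tinyScheme(nMid = 2, nPair = 3, module = "a")
  sc2 <- tinyScheme(nMid = 2, nPair = 3, module = "b")
  sc2$id <- paste0("b.", sc2$id)
  sc2$pair <- ifelse(is.na(sc2$pair), NA, paste0("b.", sc2$pair))
  scheme <- rbind(sc, sc2)
  class(scheme) <- c("landmark_scheme", "data.frame")
  k <- nrow(scheme)
  set.seed(47)
  baseA <- toyConfig(8, seed = 5); baseB <- toyConfig(8, seed = 6) + 4
  n <- 10
  whole <- exp(seq(0, 1.5, length.out = n))
  arr <- array(NA_real_, c(k, 3, n))
  for (s in seq_len(n)) {
    ## module a scales with (whole CS)^1.5, module b isometrically
    arr[1:8, , s] <- sweep(baseA, 2, colMeans(baseA)) * whole[s]^1.5
    arr[9:16, , s] <- sweep(baseB, 2, colMeans(baseB)) * whole[s] +
      matrix(10, 8, 3)
  }
  ds <- specimenDataset(arr, scheme)
  al <- gpa(ds)
  ## overwrite the size bookkeeping with the constructed whole sizes
  al$size <- whole * al$size[1] / whole[1]
  tab <- suppressWarnings(moduleSizeAllometry(al))
  expect_equal(tab$slope[tab$module == "a"], 1.5, tolerance = 1e-8)
  expect_equal(tab$slope[tab$module == "b"], 1.0, tolerance = 1e-8)
})

test_that("module CAC slope is zero without size-correlated shape change", {
  sc <- makeScheme(kPerModule = 8, nModules = 2)
  k <- nrow(sc)
  n <- 12
  set.seed(48)
  cons <- consensusFromScheme(sc)
  x <- seq(0, 1, length.out = n)
  arr <- array(NA_real_, c(k, 3, n))
  fieldB <- matrix(0, k, 3)
  fieldB[sc$module == "snout", ] <- matrix(rnorm(sum(sc$module == "snout") * 3,
                                                 0, 0.03), ncol = 3)
  for (s in seq_len(n)) {
    arr[, , s] <- cons + (x[s] - mean(x)) * fieldB   # only snout changes
  }
  ## aligned container built directly: the frill block is constant across
  ## specimens, so its allometric slope must vanish identically
  al <- structure(list(coords = arr, size = exp(x), moduleSize = NULL,
                       consensus = cons, scheme = sc,
                       specimens = sprintf("s%02d", seq_len(n)),
                       iterations = 0L, delta = numeric(0), variant = "raw"),
                  class = "aligned_dataset")
  tab <- cacSlopePerModule(al)
  expect_lt(abs(tab$slope[tab$module == "frill"]), 1e-8)
  expect_gt(tab$slope[tab$module == "snout"], 0.01)
  ## whole-skull slope equals the coefficient norm of the global fit
  fit <- fitShapeSizeRegression(al, nPerm = 0)
  expect_equal(tab$slope[tab$module == "whole"], fit$cacSlope,
               tolerance = 1e-8)
})

test_that("pairwise ANCOVA separates different slopes and not identical data", {
  x <- rep(seq(0, 1, length.out = 10), 2)
  g <- rep(c("a", "b"), each = 10)
  yid <- c(1 + 2 * x[1:10], 1 + 2 * x[1:10])
  set.seed(49)
  yid <- yid + rep(rnorm(10, 0, 0.01), 2)       # same noise in both groups
  tabid <- compareSlopesAncova(x, yid, g)
  expect_equal(tabid$p, 1, tolerance = 1e-6)
  ysep <- ifelse(g == "a", 1 + 1 * x, 1 + 2 * x) + rnorm(20, 0, 1e-4)
  tab2 <- compareSlopesAncova(x, ysep, g)
  expect_lt(tab2$p, 1e-6)
  expect_error(compareSlopesAncova(x[1:4], ysep[1:4], c("a", "a", "a", "b")),
               "at least 3")
})

test_that("shape prediction interpolates and extrapolates the fitted trajectory", {
  lin <- linearAllometric()
  al <- gpa(lin$arr)
  fit <- fitShapeSizeRegression(al, nPerm = 0)
  atMean <- predictShapeAtSize(fit, fit$meanLogSize)
  expect_equal(unname(atMean), unname(fit$consensus), tolerance = 1e-12)
  ## arithmetic oracle at an extrapolated size
  target <- fit$meanLogSize + 1.7
  pr <- predictShapeAtSize(fit, target)
  byHand <- fit$consensus + 1.7 * matrix(fit$coef, nrow(fit$consensus), 3,
                                         byrow = TRUE)
  expect_equal(unname(pr), unname(byHand), tolerance = 1e-12)
})

test_that("R2 is invariant to a global rotation of the aligned data", {
  sc <- makeScheme(kPerModule = 8, nModules = 2)
  sim <- simulateDataset(syntheticTruth(sc), nSpecimens = 10, seed = 50)
  al <- gpa(sim$dataset)
  fit <- fitShapeSizeRegression(al, nPerm = 0)
  R <- rrot()
  al2 <- al
  for (s in seq_along(al$specimens)) al2$coords[, , s] <- al$coords[, , s] %*% R
  al2$consensus <- al$consensus %*% R
  fit2 <- fitShapeSizeRegression(al2, nPerm = 0)
  expect_equal(fit2$r2, fit$r2, tolerance = 1e-10)
})
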