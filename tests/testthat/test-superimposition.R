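test_that("centroid size is the root summed squared deviation from the centroid", {
  sq <- rbind(c(1, 1, 0), c(1, -1, 0), c(-1, 1, 0), c(-1, -1, 0))
  expect_equal(centroidSize(sq), sqrt(8), tolerance = 1e-12)
  x <- toyConfig(10)
  expect_equal(centroidSize(3 * x), 3 * centroidSize(x), tolerance = 1e-12)
  expect_error(centroidSize(matrix(1, 5, 3)), "coincident")
  expect_error(centroidSize(matrix(1, 1, 3)), "at least 2")
})

test_that("pairwise superimposition recovers exact rigid motions", {
  x <- toyConfig(9, seed = 1)
  R <- rrot()
  y <- sweep(2.5 * x %*% R, 2, c(3, -1, 2), `+`)
  fit <- alignPair(y, x)
  expect_lt(fit$residual, 1e-20)
  expect_equal(fit$aligned, x, tolerance = 1e-10)
  ## chirality: a reflected copy cannot be aligned without reflection
  xr <- x; xr[, 1] <- -xr[, 1]
  fitNoRef <- alignPair(xr, x, allowReflection = FALSE)
  fitRef <- alignPair(xr, x, allowReflection = TRUE)
  expect_gt(fitNoRef$residual, 1e-3)
  expect_lt(fitRef$residual, 1e-20)
  expect_equal(det(fitNoRef$rotation), 1, tolerance = 1e-10)
})

test_that("pairwise residual matches the rotation-grid brute force", {
  set.seed(5)
  for (rep in 1:3) {
    x <- matrix(rnorm(30), 10, 3)
    y <- matrix(rnorm(30), 10, 3)
    fit <- alignPair(x, y)
    oracle <- gridAlignResidual(x, y)
    expect_equal(fit$residual, oracle, tolerance = 1e-3)
    expect_lte(fit$residual, oracle + 1e-9)
  }
})

test_that("GPA is exact for copies of one shape under random similarity maps", {
  x <- toyConfig(12, seed = 4)
  set.seed(8)
  arr <- array(NA_real_, c(12, 3, 6))
  for (s in 1:6) {
    arr[, , s] <- sweep(runif(1, 0.5, 3) * x %*% rrot(), 2, rnorm(3, 0, 5), `+`)
  }
  al <- gpa(arr)
  pv <- procrustesVariance(al)
  expect_lt(pv$total, 1e-12)
  for (s in 1:6) {
    expect_equal(unname(colMeans(al$coords[, , s])), c(0, 0, 0),
                 tolerance = 1e-8)
    expect_equal(sqrt(sum(al$coords[, , s]^2)), 1, tolerance = 1e-8)
  }
})

test_that("GPA output is invariant to specimen order and per-specimen motions", {
  sc <- makeScheme(kPerModule = 8, nModules = 2)
  sim <- simulateDataset(syntheticTruth(sc), nSpecimens = 8, seed = 21)
  al <- gpa(sim$dataset, tol = 1e-13)
  ## permuted input order
  perm <- c(5, 1, 8, 2, 7, 3, 6, 4)
  al2 <- gpa(subsetDataset(sim$dataset, specimens = perm), tol = 1e-13)
  expect_equal(al2$consensus, al$consensus, tolerance = 1e-9)
  expect_equal(al2$coords[, , match(1, perm)], al$coords[, , 1],
               tolerance = 1e-8)
  ## extra rigid motions and rescalings change nothing
  set.seed(9)
  ds3 <- sim$dataset
  for (s in seq_along(ds3$specimens)) {
    ds3$coords[, , s] <- sweep(runif(1, 0.3, 4) * ds3$coords[, , s] %*% rrot(),
                               2, rnorm(3, 0, 10), `+`)
  }
  al3 <- gpa(ds3, tol = 1e-13)
  expect_equal(al3$coords, al$coords, tolerance = 1e-8)
  expect_equal(al3$consensus, al$consensus, tolerance = 1e-8)
})

test_that("two-specimen GPA matches the pairwise superimposition residual", {
  x <- toyConfig(10, seed = 2)
  set.seed(3)
  y <- x + matrix(rnorm(30, 0, 0.1), 10, 3)
  arr <- array(c(x, y), c(10, 3, 2))
  al <- gpa(arr)
  Q <- sum(sweep(al$coords, c(1, 2), apply(al$coords, c(1, 2), mean))^2)
  ## after mutual scaling to unit centroid size the GPA residual is half the
  ## pairwise squared distance
  xu <- sweep(x, 2, colMeans(x)); xu <- xu / sqrt(sum(xu^2))
  yu <- sweep(y, 2, colMeans(y)); yu <- yu / sqrt(sum(yu^2))
  fit <- alignPair(xu, yu, scale = FALSE)
  expect_equal(Q, fit$residual / 2, tolerance = 1e-9)
})

test_that("midline plane estimation is a total-least-squares fit", {
  set.seed(6)
  m <- cbind(0, rnorm(8), rnorm(8))
  pl <- estimateMidlinePlane(m)
  expect_equal(abs(pl$normal), c(1, 0, 0), tolerance = 1e-12)
  expect_lt(pl$rmsResidual, 1e-12)
  ## perturbation: plane moves O(sigma)
  for (sg in c(1e-4, 1e-3)) {
    mm <- m; mm[, 1] <- rnorm(8, 0, sg)
    pl2 <- estimateMidlinePlane(mm)
    ang <- acos(min(1, abs(sum(pl2$normal * c(1, 0, 0)))))
    expect_lt(ang, 10 * sg)
  }
  expect_error(estimateMidlinePlane(cbind(1:5, 2 * (1:5), 3 * (1:5))),
               "collinear")
})

test_that("reflection-augmented GPA equals plain GPA for symmetric shapes", {
  sc <- tinyScheme(nMid = 4, nPair = 4)
  set.seed(13)
  arr <- array(NA_real_, c(nrow(sc), 3, 6))
  base <- tinySymmetricConfig(sc, seed = 1)
  for (s in 1:6) {
    dev <- matrix(rnorm(nrow(sc) * 3, 0, 0.03), ncol = 3)
    dev[sc$midline, 1] <- 0
    left <- which(sc$side == "left"); p <- match(sc$pair[left], sc$id)
    dev[left, ] <- dev[p, ]; dev[left, 1] <- -dev[p, 1]
    cfg <- base + dev
    arr[, , s] <- sweep(runif(1, .5, 2) * cfg %*% rrot(), 2, rnorm(3), `+`)
  }
  ds <- specimenDataset(arr, sc)
  alS <- symmetricGPA(ds)
  alP <- gpa(ds)
  expect_lt(procDist(alS$consensus, alP$consensus), 1e-7)
  ## original-scale centroid sizes are reported
  expect_equal(unname(alS$size), apply(arr, 3, centroidSize),
               tolerance = 1e-12)
})

test_that("reflection augmentation keeps the consensus midline on a plane", {
  ## width-heterogeneous population: plain GPA lets the midline drift
  sc <- tinyScheme(nMid = 5, nPair = 6)
  base <- tinySymmetricConfig(sc, seed = 10)
  set.seed(14)
  n <- 10
  arr <- array(NA_real_, c(nrow(sc), 3, n))
  for (s in seq_len(n)) {
    cfg <- base
    w <- runif(1, 0.6, 1.8)                 # width variation
    cfg[, 1] <- cfg[, 1] * w
    cfg <- cfg + matrix(rnorm(nrow(sc) * 3, 0, 0.02), ncol = 3)
    arr[, , s] <- cfg
  }
  ds <- specimenDataset(arr, sc)
  alS <- symmetricGPA(ds)
  alP <- gpa(ds)
  spread <- function(al) {
    pl <- estimateMidlinePlane(al$consensus, al$scheme$midline)
    mean(abs(sweep(al$consensus[al$scheme$midline, ], 2, pl$point) %*%
               pl$normal))
  }
  expect_lte(spread(alS), spread(alP) + 1e-10)
})

test_that("single-specimen symmetric GPA returns the centred, scaled input", {
  sc <- tinyScheme()
  cfg <- tinySymmetricConfig(sc, seed = 3)
  ds <- specimenDataset(cfg, sc)
  al <- symmetricGPA(ds)
  expect_lt(procDist(al$coords[, , 1], cfg), 1e-10)
})

test_that("retrodeformation symmetrises mildly sheared specimens and refuses others", {
  sc <- tinyScheme(nMid = 4, nPair = 5)
  cfg <- tinySymmetricConfig(sc, seed = 5)
  ## already symmetric: fixed point
  out0 <- symmetrizeRetrodeform(cfg, sc)
  expect_equal(unname(out0), unname(cfg), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(attr(out0, "obliquityDeg"), 1e-6)
  shear <- function(cfg, deg) {
    ctr <- colMeans(cfg)
    cfg[, 1] <- cfg[, 1] + tan(deg * pi / 180) * (cfg[, 3] - ctr[3])
    cfg
  }
  sheared5 <- shear(cfg, 5)
  out <- symmetrizeRetrodeform(sheared5, sc)
  expect_gt(attr(out, "obliquityDeg"), 2)
  ## output is exactly mirror symmetric about its own sagittal plane
  pl <- estimateMidlinePlane(out, sc$midline)
  refl <- out - 2 * as.numeric(sweep(out, 2, pl$point) %*% pl$normal) %*%
    t(pl$normal)
  left <- which(sc$side == "left"); p <- match(sc$pair[left], sc$id)
  expect_equal(unname(out[left, ]), unname(refl[p, ]), tolerance = 1e-9)
  ## idempotent
  out2 <- symmetrizeRetrodeform(out, sc)
  expect_equal(unname(out2), unname(out), tolerance = 1e-9,
               ignore_attr = TRUE)
  ## too oblique: refused
  expect_error(symmetrizeRetrodeform(shear(cfg, 15), sc),
               "not retrodeformable")
})
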