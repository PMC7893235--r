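#' Centroid size of a configuration
#'
#' The standard geometric-morphometric size measure: the square root of the
#' summed squared distances of all (present) landmarks from their centroid.
#' Scaling the coordinates by a factor c scales centroid size by c.
#'
#' @param x k x 3 coordinate matrix; rows with `NA` are ignored.
#' @return positive scalar.
#' @export
centroidSize <- function(x) {
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 2) stop("centroid size needs at least 2 present landmarks")
  cs <- sqrt(sum(scale(x, scale = FALSE)^2))
  if (cs <= .Machine$double.eps^0.5 * nrow(x)) {
    stop("degenerate configuration: all landmarks coincident")
  }
  cs
}

## centroid of present rows
.centroid <- function(x) colMeans(x[stats::complete.cases(x), , drop = FALSE])

#' Least-squares superimposition of one configuration onto another
#'
#' Finds the translation, rotation and (optionally) uniform scale minimising
#' the summed squared distances between the transformed `target` and the
#' `reference` (ordinary / full Procrustes superimposition). Reflections are
#' excluded unless `allowReflection = TRUE`; anatomical chirality is treated
#' as meaningful throughout the package, so mirroring only ever happens
#' through the explicit reflection operations.
#'
#' @param target,reference k x 3 matrices over the same landmarks.
#' @param scale fit a uniform scale factor (default `TRUE`).
#' @param allowReflection permit an improper rotation.
#' @return list with `rotation` (3 x 3, det +1 unless reflection allowed),
#'   `translation` (length-3; applied after rotation and scaling),
#'   `scale`, `residual` (summed squared distances), and `aligned`
#'   (the transformed target).
#' @export
alignPair <- function(target, reference, scale = TRUE,
                      allowReflection = FALSE) {
  stopifnot(all(dim(target) == dim(reference)))
  ok <- stats::complete.cases(target) & stats::complete.cases(reference)
  X <- target[ok, , drop = FALSE]
  Y <- reference[ok, , drop = FALSE]
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  M <- crossprod(Xc, Yc)            # 3x3 cross-covariance
  sv <- svd(M)
  d <- diag(3)
  if (!allowReflection && det(sv$u %*% t(sv$v)) < 0) d[3, 3] <- -1
  R <- sv$u %*% d %*% t(sv$v)
  s <- if (scale) sum(diag(d) * sv$d) / sum(Xc^2) else 1
  aligned_c <- s * Xc %*% R
  resid <- sum((aligned_c - Yc)^2)
  full <- matrix(NA_real_, nrow(target), 3)
  full[ok, ] <- sweep(aligned_c, 2, cy, `+`)
  list(rotation = R, translation = cy - s * as.numeric(cx %*% R),
       scale = s, residual = resid, aligned = full)
}

## deterministic orientation: rotate so the consensus lies on its principal
## axes with a sign convention (largest-|coordinate| entry positive per axis,
## proper rotation enforced on the last axis)
.canonicalOrientation <- function(consensus) {
  cc <- sweep(consensus, 2, colMeans(consensus))
  e <- eigen(crossprod(cc), symmetric = TRUE)
  R <- e$vectors
  for (j in 1:2) {
    v <- cc %*% R[, j]
    if (v[which.max(abs(v))] < 0) R[, j] <- -R[, j]
  }
  ## third axis sign fixed by right-handedness
  cr <- c(R[2, 1] * R[3, 2] - R[3, 1] * R[2, 2],
          R[3, 1] * R[1, 2] - R[1, 1] * R[3, 2],
          R[1, 1] * R[2, 2] - R[2, 1] * R[1, 2])
  if (sum(cr * R[, 3]) < 0) R[, 3] <- -R[, 3]
  R
}

#' Generalized Procrustes alignment
#'
#' Translates every configuration to the origin, scales it to unit centroid
#' size (when `scale = TRUE`), and iteratively rotates all configurations to
#' their evolving consensus until the summed squared residual changes by
#' less than `tol`. The final solution is put in a deterministic canonical
#' orientation (principal axes of the consensus), which makes the result
#' invariant, to numerical precision, to the input order and to arbitrary
#' rigid motions or rescalings of individual specimens.
#'
#' Whole-configuration and per-module centroid sizes are recorded from the
#' original (unaligned, unscaled) coordinates before superimposition; these
#' are the size variables used by the allometry operations.
#'
#' @param dataset a [specimenDataset()], or a k x 3 x n array.
#' @param scale scale configurations to unit centroid size (default TRUE).
#' @param tol convergence tolerance on the change in summed squared
#'   residuals.
#' @param maxIter maximum number of alignment sweeps.
#' @return an object of class `aligned_dataset`: list with `coords`
#'   (k x 3 x n aligned array), `size` (whole centroid sizes, original
#'   scale), `moduleSize` (modules x n matrix, `NA` where a module is
#'   incomplete), `consensus` (mean shape rescaled to unit centroid size),
#'   `scheme`, `specimens`, `iterations`, `delta` (per-iteration change),
#'   `variant`.
#' @export
gpa <- function(dataset, scale = TRUE, tol = 1e-10, maxIter = 100) {
  if (!inherits(dataset, "specimen_dataset")) {
    dataset <- specimenDataset(dataset, landmarkScheme(
      sprintf("lm%03d", seq_len(dim(dataset)[1]))))
  }
  if (!all(dataset$present)) {
    stop("gpa needs a shared complete landmark set; subset to complete ",
         "specimens or to one module first")
  }
  A <- dataset$coords
  k <- dim(A)[1]; n <- dim(A)[3]
  sizes <- apply(A, 3, centroidSize)
  modSize <- .moduleSizes(dataset)

  ## centre and (optionally) scale to unit centroid size
  for (s in seq_len(n)) {
    A[, , s] <- sweep(A[, , s], 2, colMeans(A[, , s]))
    if (scale) A[, , s] <- A[, , s] / sqrt(sum(A[, , s]^2))
  }
  consensus <- A[, , 1]                       # deterministic initialisation
  Qold <- Inf; deltas <- numeric(0)
  for (it in seq_len(maxIter)) {
    for (s in seq_len(n)) {
      M <- crossprod(A[, , s], consensus)
      sv <- svd(M)
      d <- diag(3)
      if (det(sv$u %*% t(sv$v)) < 0) d[3, 3] <- -1
      A[, , s] <- A[, , s] %*% (sv$u %*% d %*% t(sv$v))
    }
    consensus <- apply(A, c(1, 2), mean)
    if (scale) consensus <- consensus / sqrt(sum(consensus^2))
    Q <- sum(sweep(A, c(1, 2), consensus)^2)
    deltas <- c(deltas, abs(Qold - Q))
    if (abs(Qold - Q) < tol) break
    Qold <- Q
  }
  if (it == maxIter && abs(Qold - Q) >= tol) {
    stop("gpa did not converge in ", maxIter,
         " iterations (last change ", signif(deltas[length(deltas)], 3), ")")
  }
  ## canonical orientation from the consensus
  R <- .canonicalOrientation(consensus)
  for (s in seq_len(n)) A[, , s] <- A[, , s] %*% R
  consensus <- consensus %*% R
  structure(list(
    coords = A, size = sizes, moduleSize = modSize,
    consensus = consensus / sqrt(sum(sweep(consensus, 2,
                                           colMeans(consensus))^2)),
    scheme = dataset$scheme, specimens = dataset$specimens,
    iterations = it, delta = deltas, variant = "raw"
  ), class = "aligned_dataset")
}

.moduleSizes <- function(dataset) {
  mods <- schemeModules(dataset$scheme)
  n <- nSpecimens(dataset)
  out <- matrix(NA_real_, length(mods), n, dimnames = list(mods, dataset$specimens))
  pres <- modulePresence(dataset)
  for (m in seq_along(mods)) {
    idx <- dataset$scheme$module == mods[m]
    for (s in seq_len(n)) {
      if (pres[m, s]) out[m, s] <- centroidSize(dataset$coords[idx, , s])
    }
  }
  out
}

#' @export
print.aligned_dataset <- function(x, ...) {
  cat("Procrustes-aligned dataset (", x$variant, "): ",
      length(x$specimens), " specimens, ", dim(x$coords)[1],
      " landmarks, ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' Total-least-squares sagittal plane from midline landmarks
#'
#' Fits the plane minimising orthogonal distances to the midline landmarks.
#' The normal is the eigenvector of the smallest eigenvalue of the centred
#' cross-product matrix, oriented so its x-component is positive (first
#' non-zero component if x is zero).
#'
#' @param config k x 3 matrix.
#' @param midline logical or integer index of midline landmarks; if missing
#'   and `config` has scheme row names, all rows are used.
#' @return list with `point` (centroid of midline landmarks), `normal`
#'   (unit), `rmsResidual`.
#' @export
estimateMidlinePlane <- function(config, midline = NULL) {
  m <- if (is.null(midline)) config else config[midline, , drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  if (nrow(m) < 3) stop("midline plane needs at least 3 midline landmarks")
  ctr <- colMeans(m)
  mc <- sweep(m, 2, ctr)
  e <- eigen(crossprod(mc), symmetric = TRUE)
  if (e$values[2] < max(e$values[1], .Machine$double.eps) * 1e-10) {
    stop("midline landmarks are collinear; plane is undefined")
  }
  nrm <- e$vectors[, 3]
  piv <- which(abs(nrm) > 1e-12)[1]
  if (nrm[piv] < 0) nrm <- -nrm
  list(point = ctr, normal = nrm,
       rmsResidual = sqrt(max(0, e$values[3]) / nrow(m)))
}

## reflect coordinates across plane (point p0, unit normal nv)
reflectAcrossPlane <- function(x, point, normal) {
  d <- sweep(x, 2, point) %*% normal
  x - 2 * as.numeric(d) %*% t(normal)
}

#' Mirror a configuration digitised on the wrong side
#'
#' Specimens preserved only on the left side are digitised there and then
#' reflected across the estimated sagittal plane into the canonical
#' right-side configuration, swapping the coordinates of each bilateral
#' pair. Midline landmarks are reflected in place (unchanged up to their
#' off-plane residual). Applying the operation twice recovers the original
#' coordinates.
#'
#' @param config k x 3 coordinate matrix in scheme order (NA = absent).
#' @param scheme the [landmarkScheme()].
#' @return mirrored k x 3 matrix.
#' @export
mirrorIncompleteSide <- function(config, scheme) {
  plane <- estimateMidlinePlane(config, scheme$midline)
  refl <- reflectAcrossPlane(config, plane$point, plane$normal)
  out <- refl
  paired <- which(!is.na(scheme$pair))
  out[paired, ] <- refl[match(scheme$pair[paired], scheme$id), ]
  dimnames(out) <- dimnames(config)
  out
}

#' Reflection-augmented (symmetric) generalized Procrustes alignment
#'
#' Specimens of different widths can pull a plain Procrustes alignment away
#' from the midline of a bilaterally symmetric skull. To guard against this,
#' each configuration is augmented with its own mirror image across its
#' estimated sagittal plane (midline landmarks are duplicated at their
#' reflected positions), GPA is run on the doubled configurations, and the
#' mirrored half is then discarded. The retained halves are re-centred and
#' rescaled to unit centroid size so the result satisfies the usual
#' aligned-dataset invariants; reported centroid sizes are those of the
#' original, non-augmented configurations.
#'
#' @inheritParams gpa
#' @return an `aligned_dataset` (see [gpa()]), `variant = "symmetric"`.
#' @export
symmetricGPA <- function(dataset, scale = TRUE, tol = 1e-10, maxIter = 100) {
  stopifnot(inherits(dataset, "specimen_dataset"))
  if (!any(dataset$scheme$midline)) {
    stop("symmetric GPA needs midline landmarks in the scheme")
  }
  if (!all(dataset$present)) {
    stop("symmetric GPA needs complete specimens")
  }
  k <- nrow(dataset$scheme); n <- nSpecimens(dataset)
  aug <- array(NA_real_, c(2 * k, 3, n))
  for (s in seq_len(n)) {
    x <- dataset$coords[, , s]
    pl <- estimateMidlinePlane(x, dataset$scheme$midline)
    aug[, , s] <- rbind(x, reflectAcrossPlane(x, pl$point, pl$normal))
  }
  augScheme <- landmarkScheme(c(dataset$scheme$id,
                                paste0(dataset$scheme$id, ".mirror")))
  al <- gpa(specimenDataset(aug, augScheme, dataset$specimens),
            scale = scale, tol = tol, maxIter = maxIter)
  A <- al$coords[seq_len(k), , , drop = FALSE]
  for (s in seq_len(n)) {
    A[, , s] <- sweep(A[, , s], 2, colMeans(A[, , s]))
    if (scale) A[, , s] <- A[, , s] / sqrt(sum(A[, , s]^2))
  }
  consensus <- apply(A, c(1, 2), mean)
  consensus <- sweep(consensus, 2, colMeans(consensus))
  if (scale) consensus <- consensus / sqrt(sum(consensus^2))
  dimnames(A) <- dimnames(dataset$coords)
  structure(list(
    coords = A, size = apply(dataset$coords, 3, centroidSize),
    moduleSize = .moduleSizes(dataset),
    consensus = consensus, scheme = dataset$scheme,
    specimens = dataset$specimens, iterations = al$iterations,
    delta = al$delta, variant = "symmetric"
  ), class = "aligned_dataset")
}

#' Landmark-level retrodeformation by bilateral symmetrisation
#'
#' Removes small amounts of asymmetric taphonomic deformation by averaging
#' each landmark with the reflection of its bilateral partner across the
#' estimated sagittal plane; midline landmarks are projected onto the plane.
#' Landmarks without a present partner are taken from a mirrored copy of the
#' configuration, which leaves them unchanged. The output is exactly
#' mirror-symmetric and the operation is idempotent.
#'
#' Obliquity — the deviation of the sagittal plane from the skull's symmetry
#' direction — is measured as the angle between the fitted midline-plane
#' normal and the dominant direction of the bilateral pair differences.
#' Specimens more oblique than `maxObliquityDeg` are refused, mirroring the
#' practice of only retrodeforming mildly distorted material (less than 10
#' degrees).
#'
#' @param config k x 3 matrix in scheme order.
#' @param scheme the [landmarkScheme()].
#' @param maxObliquityDeg refusal threshold in degrees (default 10).
#' @return symmetrised k x 3 matrix with attribute `obliquityDeg`.
#' @export
symmetrizeRetrodeform <- function(config, scheme, maxObliquityDeg = 10) {
  plane <- estimateMidlinePlane(config, scheme$midline)
  paired <- which(!is.na(scheme$pair))
  partner <- match(scheme$pair[paired], scheme$id)
  havePair <- paired[stats::complete.cases(config[paired, , drop = FALSE]) &
                     stats::complete.cases(config[partner, , drop = FALSE])]
  obl <- 0
  if (length(havePair) >= 2) {
    diffs <- config[havePair, , drop = FALSE] -
      config[match(scheme$pair[havePair], scheme$id), , drop = FALSE]
    e <- eigen(crossprod(diffs), symmetric = TRUE)
    dirv <- e$vectors[, 1]
    cosang <- abs(sum(dirv * plane$normal))
    obl <- acos(min(1, cosang)) * 180 / pi
  }
  if (obl > maxObliquityDeg) {
    stop("specimen is not retrodeformable: sagittal obliquity ",
         sprintf("%.1f", obl), " deg exceeds ", maxObliquityDeg, " deg")
  }
  refl <- reflectAcrossPlane(config, plane$point, plane$normal)
  out <- config
  ## midline: average with own reflection = orthogonal projection on plane
  mid <- which(scheme$midline)
  out[mid, ] <- (config[mid, , drop = FALSE] + refl[mid, , drop = FALSE]) / 2
  ## paired (partner present): average with the reflected partner
  if (length(havePair)) {
    p2 <- match(scheme$pair[havePair], scheme$id)
    avg <- (config[havePair, , drop = FALSE] + refl[p2, , drop = FALSE]) / 2
    out[havePair, ] <- avg
    ## enforce exact mirror symmetry on the partners
    out[p2, ] <- reflectAcrossPlane(avg, plane$point, plane$normal)
  }
  attr(out, "obliquityDeg") <- obl
  out
}
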