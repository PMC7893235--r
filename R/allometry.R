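## shape matrix: specimens x 3k, landmark-major column order (x1,y1,z1,x2,...)
.shapeMatrix <- function(aligned) {
  A <- aligned$coords
  k <- dim(A)[1]; n <- dim(A)[3]
  t(matrix(aperm(A, c(2, 1, 3)), 3 * k, n))
}

.matrixToConfig <- function(v, k) {
  matrix(v, k, 3, byrow = TRUE)
}

#' Regression of shape on log centroid size
#'
#' Multivariate regression of the mean-centred Procrustes coordinates on
#' centred natural-log centroid size. R-squared is the explained fraction of
#' the total summed squared coordinate variation; its significance comes
#' from permutation of the size labels. The normalised coefficient vector is
#' the common allometric component (CAC), the single shape direction most
#' closely aligned with size; projecting specimens onto it gives the
#' standardized shape (allometry) scores. Residual shape components (RSC)
#' are the principal directions of the shape data after the CAC-score
#' direction is partialled out, so RSC scores are exactly uncorrelated with
#' the CAC scores.
#'
#' @param aligned an `aligned_dataset`.
#' @param nPerm permutations for the R-squared p-value (default 999).
#' @param seed RNG seed for the permutations.
#' @return object of class `allometry_model`: list with `coef` (3k), `r2`,
#'   `p`, `cac` (unit vector), `cacScores`, `cacSlope` (slope of CAC score
#'   on centred log size, equal to the coefficient norm), `rsc`
#'   (directions, columns), `rscScores`, `logSize`, `meanLogSize`,
#'   `consensus`, `scheme`, `variant`.
#' @export
fitShapeSizeRegression <- function(aligned, nPerm = 999, seed = 1) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  n <- length(aligned$specimens)
  if (n < 3) stop("shape-size regression needs at least 3 specimens")
  Y <- .shapeMatrix(aligned)
  mu <- colMeans(Y)
  Y <- sweep(Y, 2, mu)
  x <- log(aligned$size)
  if (stats::sd(x) < 1e-12) stop("no centroid-size variation")
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  b <- drop(crossprod(Y, xc)) / sxx
  sst <- sum(Y^2)
  fitted <- outer(xc, b)
  sse <- sum(fitted^2)
  r2 <- sse / sst
  ## permutation p for the size-shape association
  p <- NA_real_
  if (nPerm > 0) {
    if (!is.null(seed)) set.seed(seed)
    cnt <- 0L
    for (i in seq_len(nPerm)) {
      xp <- sample(xc)
      r2p <- sum((drop(crossprod(Y, xp)) / sum(xp^2))^2) * sum(xp^2) / sst
      if (r2p >= r2 - 1e-12) cnt <- cnt + 1L
    }
    p <- (cnt + 1) / (nPerm + 1)
  }
  nb <- sqrt(sum(b^2))
  cac <- b / nb
  s <- drop(Y %*% cac)                      # CAC / allometry shape scores
  ## residual shape components: principal directions after removing the
  ## CAC-score direction from the data (scores exactly uncorrelated with s)
  W <- Y - outer(s, drop(crossprod(Y, s)) / sum(s^2))
  pc <- stats::prcomp(W, center = FALSE)
  keep <- which(pc$sdev > max(pc$sdev) * 1e-10)
  structure(list(
    coef = b, r2 = r2, p = p, cac = cac, cacScores = s,
    cacSlope = nb, rsc = pc$rotation[, keep, drop = FALSE],
    rscScores = pc$x[, keep, drop = FALSE],
    logSize = x, meanLogSize = mean(x), center = mu,
    consensus = .matrixToConfig(mu, dim(aligned$coords)[1]),
    scheme = aligned$scheme,
    specimens = aligned$specimens, variant = aligned$variant
  ), class = "allometry_model")
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf("Shape ~ log(centroid size): R2 = %.3f (p = %s), n = %d\n",
              x$r2, format(x$p), length(x$logSize)))
  invisible(x)
}

#' Remove the allometric component from an aligned dataset
#'
#' Replaces each specimen's coordinates by the residual from the
#' shape-on-size regression plus the consensus, i.e. the shape the specimen
#' would have at the mean log size. The corrected dataset is accepted by
#' the modularity, disparity and dimorphism operations.
#'
#' @param aligned an `aligned_dataset`.
#' @param model optionally a pre-fitted [fitShapeSizeRegression()] model.
#' @param nPerm,seed passed to [fitShapeSizeRegression()] when `model` is
#'   `NULL`; the correction itself needs no permutations, so `nPerm = 0`
#'   by default.
#' @return an `aligned_dataset` with `variant = "allometry-corrected"`.
#' @export
allometryCorrect <- function(aligned, model = NULL, nPerm = 0, seed = 1) {
  if (is.null(model)) {
    model <- fitShapeSizeRegression(aligned, nPerm = nPerm, seed = seed)
  }
  Y <- .shapeMatrix(aligned)
  Y <- sweep(Y, 2, model$center)
  xc <- model$logSize - model$meanLogSize
  R <- Y - outer(xc, model$coef)
  k <- dim(aligned$coords)[1]
  out <- aligned
  for (s in seq_len(nrow(R))) {
    out$coords[, , s] <- .matrixToConfig(model$center + R[s, ], k)
  }
  out$consensus <- .matrixToConfig(model$center, k)
  out$variant <- paste0(aligned$variant, "+allometry-corrected")
  out
}

#' Per-module centroid-size allometry
#'
#' Ordinary least-squares regression of log module centroid size on log
#' whole-configuration centroid size, one slope per module. A slope of 1 is
#' isometry; socio-sexual signal structures are expected to exceed it
#' clearly. Module centroid sizes come from the original-scale
#' configurations recorded at alignment time; partial specimens contribute
#' to every module they preserve completely.
#'
#' @param aligned an `aligned_dataset` (its `moduleSize` matrix may include
#'   columns for partial specimens when built from a combined dataset).
#' @return data frame: module, slope, se, r2, n.
#' @export
moduleSizeAllometry <- function(aligned) {
  ms <- aligned$moduleSize
  if (is.null(ms)) stop("aligned dataset carries no module sizes")
  wh <- log(aligned$size)
  out <- lapply(rownames(ms), function(m) {
    ok <- !is.na(ms[m, ])
    if (sum(ok) < 3) stop("module ", m, " present in fewer than 3 specimens")
    fit <- stats::lm(log(ms[m, ok]) ~ wh[ok])
    sm <- summary(fit)
    data.frame(module = m, slope = unname(coef(fit)[2]),
               se = sm$coefficients[2, 2], r2 = sm$r.squared,
               n = sum(ok), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-module allometric shape change (CAC slope)
#'
#' For each module, the globally aligned coordinates are restricted to the
#' module's landmarks, the module's own common allometric component is
#' extracted, and the module CAC score is regressed on log whole-skull
#' centroid size. The CAC direction is signed so scores correlate
#' positively with size, making all slopes non-negative at fit; a module
#' whose shape does not change with size has slope 0. The whole-skull slope
#' is reported alongside and equals the coefficient norm of
#' [fitShapeSizeRegression()].
#'
#' @param aligned an `aligned_dataset`.
#' @return data frame: module ("whole" first), slope, se, r2, n.
#' @export
cacSlopePerModule <- function(aligned) {
  x <- log(aligned$size)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slopeRow <- function(label, Y) {
    Y <- sweep(Y, 2, colMeans(Y))
    b <- drop(crossprod(Y, xc)) / sxx
    nb <- sqrt(sum(b^2))
    if (nb < 1e-300) {
      return(data.frame(module = label, slope = 0, se = 0, r2 = 0,
                        n = length(x), stringsAsFactors = FALSE))
    }
    s <- drop(Y %*% (b / nb))
    if (stats::cor(s, xc) < 0) s <- -s        # sign convention
    fit <- stats::lm(s ~ xc)
    sm <- summary(fit)
    data.frame(module = label, slope = unname(coef(fit)[2]),
               se = sm$coefficients[2, 2], r2 = sm$r.squared,
               n = length(x), stringsAsFactors = FALSE)
  }
  Y <- .shapeMatrix(aligned)
  scores <- list()
  slopeRow2 <- function(label, Y) {
    r <- slopeRow(label, Y)
    Yc <- sweep(Y, 2, colMeans(Y))
    b <- drop(crossprod(Yc, xc)) / sxx
    nb <- sqrt(sum(b^2))
    s <- if (nb < 1e-300) rep(0, nrow(Y)) else drop(Yc %*% (b / nb))
    if (length(s) > 1 && stats::sd(s) > 0 && stats::cor(s, xc) < 0) s <- -s
    scores[[label]] <<- s
    r
  }
  out <- list(slopeRow2("whole", Y))
  for (m in schemeModules(aligned$scheme)) {
    idx <- which(aligned$scheme$module == m)
    cols <- as.vector(t(outer(idx - 1, 1:3, function(i, d) 3 * i + d)))
    out[[length(out) + 1]] <- slopeRow2(m, Y[, cols, drop = FALSE])
  }
  res <- do.call(rbind, out)
  attr(res, "scores") <- do.call(cbind, scores)
  res
}

#' Pairwise ANCOVA comparison of regression slopes
#'
#' For every pair of groups, fits `y ~ x * group` and reports the F-test
#' p-value of the interaction term — the test that the two slopes differ.
#'
#' @param x predictor values.
#' @param y response values.
#' @param group group labels (same length).
#' @return data frame: group1, group2, F, df1, df2, p.
#' @export
compareSlopesAncova <- function(x, y, group) {
  stopifnot(length(x) == length(y), length(x) == length(group))
  group <- as.character(group)
  gs <- unique(group)
  if (any(table(group) < 3)) stop("every group needs at least 3 points")
  out <- list()
  for (i in seq_along(gs)) {
    for (j in seq_along(gs)) {
      if (j <= i) next
      sel <- group %in% c(gs[i], gs[j])
      g <- factor(group[sel])
      fit <- stats::lm(y[sel] ~ x[sel] * g)
      an <- stats::anova(fit)
      row <- an[rownames(an) == "x[sel]:g", ]
      if (!nrow(row) || !is.finite(row$`F value`)) {
        stop("singular ANCOVA design for groups ", gs[i], " / ", gs[j])
      }
      out[[length(out) + 1]] <- data.frame(
        group1 = gs[i], group2 = gs[j],
        F = row$`F value`, df1 = row$Df, df2 = an["Residuals", "Df"],
        p = row$`Pr(>F)`, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Predict the shape at a given log centroid size
#'
#' Evaluates the fitted allometric trajectory: consensus plus coefficient
#' vector times the centred log size. At the training mean log size this is
#' exactly the consensus; projected shapes at the minimum and maximum
#' observed sizes visualise ontogenetic shape change.
#'
#' @param model an [fitShapeSizeRegression()] model.
#' @param logSize natural-log centroid size at which to evaluate.
#' @return k x 3 configuration matrix.
#' @export
predictShapeAtSize <- function(model, logSize) {
  k <- nrow(model$consensus)
  v <- model$center + (logSize - model$meanLogSize) * model$coef
  cfg <- .matrixToConfig(v, k)
  dimnames(cfg) <- list(model$scheme$id, c("x", "y", "z"))
  cfg
}
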