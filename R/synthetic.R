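#' Build a synthetic landmark scheme
#'
#' Generates a bilaterally symmetric landmark scheme of `nModules` modules
#' with `kPerModule` landmarks each: a fraction on the midline, the rest as
#' left/right bilateral pairs. Within each module the right-side landmarks
#' are typed deterministically: a few fixed anatomical points, one ordered
#' curve of semilandmarks when the module is large enough, and surface
#' semilandmarks for the remainder (mirrored on the left). The same
#' arguments always produce the identical scheme.
#'
#' @param kPerModule landmarks per module (>= 3), counting both sides.
#' @param nModules number of modules (default 5).
#' @param midlineFraction fraction of each module's landmarks on the
#'   midline; rounded so the remainder splits into pairs.
#' @param moduleNames optional module labels; defaults to the five skull
#'   regions of the ceratopsian analysis (frill, snout, jugal, maxilla,
#'   postorbital).
#' @return a [landmarkScheme()].
#' @export
makeScheme <- function(kPerModule = 20, nModules = 5, midlineFraction = 0.2,
                       moduleNames = NULL) {
  if (kPerModule < 3) stop("kPerModule must be at least 3")
  if (nModules < 1) stop("need at least one module")
  if (is.null(moduleNames)) {
    base <- c("frill", "snout", "jugal", "maxilla", "postorbital")
    moduleNames <- if (nModules <= 5) base[seq_len(nModules)] else
      c(base, sprintf("module%02d", 6:nModules))
  }
  rows <- list()
  for (m in seq_len(nModules)) {
    mod <- moduleNames[m]
    nMid <- round(kPerModule * midlineFraction)
    if ((kPerModule - nMid) %% 2 == 1) nMid <- nMid + 1
    if (nMid > kPerModule) nMid <- kPerModule - kPerModule %% 2
    nR <- (kPerModule - nMid) / 2
    ## right-side types: >=7 per side gets 2 fixed + a 4-curve + surfaces
    if (nR >= 7) {
      typesR <- c(rep("fixed", 2), rep("curve", 4),
                  rep("surface", nR - 6))
      curveR <- c(rep(NA, 2), rep(paste0(mod, ".curve"), 4),
                  rep(NA, nR - 6))
      cposR <- c(rep(NA, 2), 1:4, rep(NA, nR - 6))
    } else {
      typesR <- rep("fixed", nR)
      curveR <- rep(NA_character_, nR)
      cposR <- rep(NA_integer_, nR)
    }
    if (nMid > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        id = sprintf("%s.mid%02d", mod, seq_len(nMid)),
        type = "fixed", module = mod, midline = TRUE,
        pair = NA_character_, side = "mid",
        curve = NA_character_, curve_pos = NA_integer_,
        stringsAsFactors = FALSE)
    }
    if (nR > 0) {
      idR <- sprintf("%s.r%02d", mod, seq_len(nR))
      idL <- sprintf("%s.l%02d", mod, seq_len(nR))
      rows[[length(rows) + 1]] <- data.frame(
        id = idR, type = typesR, module = mod, midline = FALSE,
        pair = idL, side = "right", curve = curveR, curve_pos = cposR,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        id = idL, type = typesR, module = mod, midline = FALSE,
        pair = idR, side = "left",
        curve = ifelse(is.na(curveR), NA, paste0(curveR, ".L")),
        curve_pos = cposR, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  landmarkScheme(tab$id, tab$type, tab$module, tab$midline, tab$pair,
                 tab$side, tab$curve, tab$curve_pos)
}

## deterministic consensus geometry: module centres on a skull-like arc,
## midline landmarks exactly at x = 0, right landmarks at x > 0, left
## landmarks their exact mirror. Pure formulas, no RNG.
consensusFromScheme <- function(scheme) {
  mods <- schemeModules(scheme)
  M <- length(mods)
  k <- nrow(scheme)
  out <- matrix(NA_real_, k, 3, dimnames = list(scheme$id, c("x", "y", "z")))
  phi <- 2.399963                       # golden angle, spreads points evenly
  ## arc slots are assigned centre-out (1st module in the middle): central
  ## modules have the shortest rotation lever, which keeps their planted
  ## deviations most faithful under Procrustes alignment
  slots <- order(abs(seq_len(M) - (M + 1) / 2))
  for (m in seq_along(mods)) {
    th <- pi * (slots[m] - 0.5) / M
    ctr <- c(0, 1.6 * cos(th), 0.6 * sin(th))
    idx <- which(scheme$module == mods[m] & scheme$side != "left")
    for (jj in seq_along(idx)) {
      i <- idx[jj]
      r <- 0.12 + 0.05 * ((jj * phi) %% 1)
      a1 <- jj * phi; a2 <- jj * 1.7 + m
      if (scheme$type[i] == "curve") {
        t <- (scheme$curve_pos[i] - 1) / 4          # along an arc
        p <- ctr + c(0.22, 0, 0) +
          0.18 * c(0.25 * sin(pi * t), cos(pi * t), sin(pi * t) - 0.5)
      } else if (scheme$midline[i]) {
        p <- ctr + 0.15 * c(0, cos(a1), sin(a1))
        p[1] <- 0
      } else {
        p <- ctr + c(0.25 + 0.06 * cos(a2), r * cos(a1), r * sin(a1))
      }
      out[i, ] <- p
    }
  }
  ## left landmarks: exact mirror of their right partner
  left <- which(scheme$side == "left")
  out[left, ] <- out[match(scheme$pair[left], scheme$id), , drop = FALSE]
  out[left, 1] <- -out[left, 1]
  out
}

## deterministic smooth unit "deformation fields" used for planted effects;
## variant selects different smooth patterns so the fields are linearly
## independent between modules and effects. Symmetric across the midline.
.moduleField <- function(scheme, consensus, module, variant = 0) {
  idx <- which(scheme$module == module)
  ctr <- colMeans(consensus[idx, , drop = FALSE])
  F <- matrix(0, nrow(scheme), 3)
  for (i in idx) {
    d <- consensus[i, ] - ctr
    w <- switch((variant %% 3) + 1,
                d,                                    # radial expansion
                c(d[2], -d[1] * 0.5, d[3] * 0.8),      # shear/twist
                c(0.2 * d[1], d[3], -d[2]))            # roll
    F[i, ] <- w + 0.1 * sin(variant + seq(0.3, 2.9, length.out = 3))
  }
  ## enforce bilateral symmetry: left row = mirrored right row
  left <- which(scheme$side == "left" & scheme$module == module)
  if (length(left)) {
    p <- match(scheme$pair[left], scheme$id)
    F[left, ] <- F[p, , drop = FALSE]
    F[left, 1] <- -F[left, 1]
  }
  ## midline rows: no x component, keeps configurations symmetric
  F[scheme$midline & scheme$module == module, 1] <- 0
  F / sqrt(sum(F^2))
}

## projector onto the orthogonal complement of the similarity tangent
## space at a configuration: translations, infinitesimal rotations, scaling
.similarityBasis <- function(cons) {
  k <- nrow(cons)
  cc <- sweep(cons, 2, colMeans(cons))
  basis <- cbind(
    as.numeric(matrix(rep(c(1, 0, 0), each = k), k, 3)),
    as.numeric(matrix(rep(c(0, 1, 0), each = k), k, 3)),
    as.numeric(matrix(rep(c(0, 0, 1), each = k), k, 3)),
    as.numeric(cbind(0, -cc[, 3], cc[, 2])),     # rotation about x
    as.numeric(cbind(cc[, 3], 0, -cc[, 1])),     # rotation about y
    as.numeric(cbind(-cc[, 2], cc[, 1], 0)),     # rotation about z
    as.numeric(cc))                              # scaling
  qr.Q(qr(basis))
}

.similarityProjector <- function(cons) {
  k <- nrow(cons)
  Q <- .similarityBasis(cons)
  function(Fm) {
    v <- as.numeric(Fm)
    v <- v - Q %*% crossprod(Q, v)
    out <- matrix(v, k, 3)
    out / sqrt(sum(out^2))
  }
}

#' Ground truth for the synthetic generator
#'
#' Collects the planted parameters of [simulateDataset()]. The defaults are
#' the paper-like study conditions: five modules, about half of the shape
#' variance explained by size, a frill analogue with the steepest
#' centroid-size allometry (slope 1.4), three times the allometric shape
#' magnitude and the largest size-independent variance, moderate modular
#' covariance (within-module congruence 0.6, between 0.25), and no
#' dimorphism (the open question the dip scan asks).
#'
#' @param scheme a [makeScheme()] scheme (default: 5 x 20 landmarks).
#' @param withinCor,betweenCor congruence targets (within must exceed
#'   between).
#' @param beta per-module centroid-size allometric exponents.
#' @param cacRel per-module relative allometric shape magnitudes.
#' @param devScale per-module relative deviation scales (size-independent
#'   variance enters with the square of these).
#' @param allometricFraction target share of shape variance explained by
#'   size.
#' @param noiseSigma iid coordinate noise standard deviation.
#' @param factorScale per-landmark factor standard deviation used in the
#'   noiseless (`noiseSigma = 0`) mode, where the congruence ratio no longer
#'   pins the factor variance.
#' @param dimorphismDelta dimorphic shape offset between the sexes
#'   (0 = off): each landmark of `dimorphismModule` is displaced by, in
#'   root mean square, `dimorphismDelta` times the module's total
#'   within-sex per-coordinate deviation sd (factors plus noise), along a
#'   direction orthogonal to the factor fields.
#' @param dimorphismModule module carrying the dimorphic shape offset.
#' @param logSizeRange range of log centroid size (natural log).
#' @param sizeDistribution `"uniform"` or `"bimodal"` (a juvenile cluster
#'   separated from the adults).
#' @param juvenileFraction fraction of juveniles under `"bimodal"`.
#' @param compressionRange taphonomic dorsoventral dilation factor range
#'   (`c(1, 1)` = off).
#' @param rigidMotions randomly rotate/translate each specimen (default
#'   TRUE; alignment is then non-trivial).
#' @return object of class `synthetic_truth` (a list).
#' @export
syntheticTruth <- function(scheme = makeScheme(),
                           withinCor = 0.6, betweenCor = 0.25,
                           beta = NULL, cacRel = NULL, devScale = NULL,
                           allometricFraction = 0.5, noiseSigma = 0.01,
                           factorScale = 0.01,
                           dimorphismDelta = 0, dimorphismModule = NULL,
                           logSizeRange = c(log(0.5), log(2)),
                           sizeDistribution = c("uniform", "bimodal"),
                           juvenileFraction = 0.2,
                           compressionRange = c(1, 1),
                           rigidMotions = TRUE) {
  sizeDistribution <- match.arg(sizeDistribution)
  mods <- schemeModules(scheme)
  M <- length(mods)
  if (withinCor <= betweenCor) {
    stop("unsatisfiable congruence targets: within must exceed between")
  }
  dflt <- function(x, vals) {
    if (!is.null(x)) {
      if (is.null(names(x))) names(x) <- mods[seq_along(x)]
      return(x[mods])
    }
    setNames(rep_len(vals, M), mods)
  }
  beta <- dflt(beta, c(1.4, 1.1, 1.0, 1.0, 0.9))
  cacRel <- dflt(cacRel, c(3, 1, 1, 1, 1))
  devScale <- dflt(devScale, c(2.2, 1.2, 1.6, 1.2, 1.0))
  if (is.null(dimorphismModule)) dimorphismModule <- mods[1]
  structure(list(
    scheme = scheme, consensus = consensusFromScheme(scheme),
    withinCor = withinCor, betweenCor = betweenCor,
    beta = beta, cacRel = cacRel, devScale = devScale,
    allometricFraction = allometricFraction,
    noiseSigma = noiseSigma, factorScale = factorScale,
    dimorphismDelta = dimorphismDelta,
    dimorphismModule = dimorphismModule,
    logSizeRange = logSizeRange,
    sizeDistribution = sizeDistribution,
    juvenileFraction = juvenileFraction,
    compressionRange = compressionRange,
    rigidMotions = rigidMotions
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("Synthetic ground truth:", nrow(x$scheme), "landmarks,",
      length(x$beta), "modules\n")
  cat("  beta:", paste(sprintf("%s=%.2f", names(x$beta), x$beta),
                       collapse = ", "), "\n")
  cat(sprintf("  allometric fraction %.2f, within/between congruence %.2f/%.2f, dimorphism delta %.1f\n",
              x$allometricFraction, x$withinCor, x$betweenCor,
              x$dimorphismDelta))
  invisible(x)
}

## random proper rotation (QR of a normal matrix, det +1)
.randomRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

#' Simulate a landmark dataset with known ground truth
#'
#' Draws specimens from the linear factor model the analysis pipeline
#' assumes: shape = consensus + (centred log size) x allometric fields +
#' module factors + global factor + sex offset + iid noise, after which
#' each module is rescaled about its centroid by size^(beta - 1), optional
#' dorsoventral compression is applied, and the specimen is scaled to its
#' target centroid size and (optionally) randomly rotated and translated.
#' Factor scores are orthonormalised in-sample against the size axis, so
#' the planted variance fractions and congruence targets hold exactly in
#' the noiseless limit.
#'
#' @param truth a [syntheticTruth()].
#' @param nSpecimens number of complete specimens (>= 4).
#' @param nPartial additional partial specimens carrying a random subset
#'   of 2-3 complete modules each.
#' @param seed RNG seed (same seed, same dataset, bit for bit).
#' @return list with `dataset` (a [specimenDataset()]) and `truth` (the
#'   input truth augmented with the per-specimen draws: `logSize`, `sex`,
#'   `juvenile`, `compression`, `partialModules`).
#' @export
simulateDataset <- function(truth, nSpecimens = 30, nPartial = 0, seed = 1) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (nSpecimens < 4) stop("need at least 4 complete specimens")
  set.seed(seed)
  scheme <- truth$scheme
  mods <- names(truth$beta)
  M <- length(mods)
  k <- nrow(scheme)
  cons <- truth$consensus
  n <- nSpecimens + nPartial

  ## --- sizes ------------------------------------------------------------
  lo <- truth$logSizeRange[1]; hi <- truth$logSizeRange[2]
  juvenile <- rep(FALSE, n)
  if (truth$sizeDistribution == "bimodal") {
    juvenile <- stats::runif(n) < truth$juvenileFraction
    if (sum(juvenile) < 2) juvenile[sample(n, 2)] <- TRUE
    x <- numeric(n)
    x[juvenile] <- stats::runif(sum(juvenile), lo, lo + 0.2 * (hi - lo))
    x[!juvenile] <- stats::runif(sum(!juvenile), lo + 0.55 * (hi - lo), hi)
  } else {
    x <- stats::runif(n, lo, hi)
  }
  xc <- x - mean(x)

  ## --- latent factors, exactly orthogonal to size and each other --------
  raw <- cbind(1, xc, matrix(stats::rnorm(n * (M + 1)), n))
  Q <- qr.Q(qr(raw))
  xq <- Q[, 2] * sign(sum(Q[, 2] * xc))           # the size direction
  xcs <- xq * sqrt(sum(xc^2))                     # = centred x exactly
  g <- Q[, 3] * sqrt(n - 1)                       # global factor, sd 1
  f <- Q[, 3 + seq_len(M), drop = FALSE] * sqrt(n - 1)

  ## --- per-landmark deviation magnitudes --------------------------------
  ## congruence targets fix the factor-to-noise variance ratio; in the
  ## noiseless limit a fixed pure-factor scale is used instead
  sig <- truth$noiseSigma
  rw <- truth$withinCor; rb <- truth$betweenCor
  Tfac <- if (sig > 0) 3 * sig^2 * rw / (1 - rw) else truth$factorScale^2
  c2 <- Tfac * rb / rw                            # global-factor variance
  a2 <- Tfac - c2                                 # module-factor variance
  s_m <- truth$devScale / max(truth$devScale)
  km <- vapply(mods, function(m) sum(scheme$module == m), numeric(1))

  ## --- deformation fields -----------------------------------------------
  ## all planted fields are projected orthogonal to the similarity tangent
  ## space at the consensus (translations, rotations, scaling), so Procrustes
  ## alignment leaves the planted variances intact at first order
  P <- .similarityProjector(cons)
  ## allometric fields are additionally made neutral to each module's own
  ## centroid size, so they do not bias the planted beta exponents
  csNeutral <- function(Fm) {
    for (m in seq_len(M)) {
      idx <- scheme$module == mods[m]
      Sm <- sweep(cons[idx, , drop = FALSE], 2,
                  colMeans(cons[idx, , drop = FALSE]))
      Fm[idx, ] <- Fm[idx, ] - sum(Fm[idx, ] * Sm) / sum(Sm^2) * Sm
    }
    Fm
  }
  allo <- lapply(seq_len(M), function(m) {
    Fm <- .moduleField(scheme, cons, mods[m], variant = m)
    ## alternating projections: converge to a field orthogonal to both the
    ## similarity tangent space and every module's own scaling direction
    for (i in 1:25) Fm <- P(csNeutral(Fm))
    Fm
  })
  ## factor fields: one common unit 3-vector per module (so within-module
  ## congruence is near its target), projected as above
  Qsim <- .similarityBasis(cons)
  facF <- lapply(seq_len(M), function(m) {
    idx <- scheme$module == mods[m]
    ## mirror-symmetric constant field in direction v over the module: the
    ## left side carries the reflected vector, the midline no x-component,
    ## so bilateral symmetrisation preserves the factor variance
    mkF <- function(v) {
      Fm <- matrix(0, k, 3)
      Fm[idx, ] <- matrix(v, sum(idx), 3, byrow = TRUE)
      Fm[idx & scheme$side == "left", 1] <- -v[1]
      Fm[idx & scheme$midline, 1] <- 0
      Fm
    }
    ## candidate directions are screened by how coherent the module's rows
    ## remain after projecting out the similarity tangent space and the
    ## module scaling direction: the projections must not turn the common
    ## deviation direction (which the congruence targets assume) into a
    ## landmark-dependent one
    A <- vapply(1:3, function(d) as.numeric(mkF(diag(3)[d, ])),
                numeric(3 * k))
    Sm <- matrix(0, k, 3)
    Sm[idx, ] <- sweep(cons[idx, , drop = FALSE], 2,
                       colMeans(cons[idx, , drop = FALSE]))
    Cb <- qr.Q(qr(cbind(Qsim, as.numeric(Sm))))
    Mv <- crossprod(crossprod(Cb, A))
    ev <- eigen(Mv, symmetric = TRUE)$vectors
    cands <- list(ev[, 3], ev[, 2], c(0, 1, 0), c(0, 0, 1),
                  c(0, 1, 1) / sqrt(2), c(0, 1, -1) / sqrt(2))
    best <- NULL; bestScore <- -Inf
    for (u in cands) {
      Fm <- matrix(A %*% u, k, 3)
      for (i in 1:5) Fm <- P(csNeutral(Fm))
      rn <- sqrt(rowSums(Fm[idx, , drop = FALSE]^2))
      R <- Fm[idx, , drop = FALSE] / rn
      cosm <- abs(tcrossprod(R))
      score <- mean(cosm[upper.tri(cosm)]) - stats::sd(rn) / mean(rn)
      if (score > bestScore + 1e-12) { bestScore <- score; best <- Fm }
    }
    Fm <- best
    ## unit per-landmark RMS over the module, so a unit factor score adds
    ## unit variance per landmark (the scale the congruence targets assume)
    Fm / sqrt(mean(rowSums(Fm[idx, , drop = FALSE]^2)))
  })
  dimDir <- P(.moduleField(scheme, cons, truth$dimorphismModule,
                           variant = 2 * M + 1))
  ## the dimorphic contrast is a direction of its own: orthogonalise it
  ## against the factor fields so the between-sex shift is not confounded
  ## with (or hidden by) the ordinary within-sex factor variation
  for (it in 1:3) {
    for (m in seq_len(M)) {
      fh <- facF[[m]] / sqrt(sum(facF[[m]]^2))
      dimDir <- dimDir - sum(dimDir * fh) * fh
    }
    dimDir <- P(dimDir)
  }
  sex <- rep(c(-0.5, 0.5), length.out = n)[sample(n)]

  ## --- predraw noise and taphonomy so calibration sees the real draws ---
  sland <- s_m[match(scheme$module, mods)]
  E <- lapply(seq_len(n), function(s) {
    if (sig > 0) matrix(stats::rnorm(k * 3), k, 3) * (sland * sig) else
      matrix(0, k, 3)
  })
  compression <- stats::runif(n, truth$compressionRange[1],
                              truth$compressionRange[2])

  ## --- dimorphism offset ------------------------------------------------
  ## the offset displaces each landmark of the target module by (on root
  ## mean square) delta times the module's within-sex per-coordinate
  ## deviation sd (factors plus noise), along a smooth module field;
  ## delta = 4 plants a clearly bimodal shift
  sigEff <- if (sig > 0) sig else truth$factorScale
  mDim <- match(truth$dimorphismModule, mods)
  sdPerCoord <- sqrt(s_m[mDim]^2 * (a2 + c2 + 3 * sigEff^2) / 3)
  dimd <- which(scheme$module == truth$dimorphismModule)
  dimRms <- sqrt(mean(rowSums(dimDir[dimd, , drop = FALSE]^2)))
  delta <- truth$dimorphismDelta * sdPerCoord / max(dimRms, 1e-12)

  ## --- specimen shapes as a function of the allometric magnitude --------
  bRel <- truth$cacRel * sqrt(km)
  bRel <- bRel / sqrt(sum(bRel^2))
  Ballo <- Reduce(`+`, lapply(seq_len(M), function(m) bRel[m] * allo[[m]]))
  modIdx <- lapply(mods, function(m) which(scheme$module == m))
  buildShape <- function(s, kappa) {
    X <- cons + kappa * xcs[s] * Ballo + E[[s]]
    for (m in seq_len(M)) {
      dev <- s_m[m] * (sqrt(a2) * f[s, m] + sqrt(c2) * g[s])
      X <- X + dev * facF[[m]]
    }
    if (delta > 0) X <- X + sex[s] * delta * dimDir
    ## module-specific size scaling about the module centroid
    for (m in seq_len(M)) {
      idx <- modIdx[[m]]
      ctr <- colMeans(X[idx, , drop = FALSE])
      X[idx, ] <- sweep(X[idx, , drop = FALSE], 2, ctr) *
        exp((truth$beta[m] - 1) * xc[s])
      X[idx, ] <- sweep(X[idx, , drop = FALSE], 2, ctr, `+`)
    }
    ## symmetric taphonomic dilation (dorsoventral compression)
    if (compression[s] != 1) {
      ctr <- colMeans(X)
      X[, 3] <- ctr[3] + compression[s] * (X[, 3] - ctr[3])
    }
    X <- sweep(X, 2, colMeans(X))
    X * centroidSize(cons) / centroidSize(X)
  }

  ## --- calibrate the allometric shape magnitude --------------------------
  ## the beta exponents already move shape with size; the extra allometric
  ## fields are scaled so the realised share of shape variance explained by
  ## size matches the requested fraction
  r2At <- function(kappa) {
    V <- vapply(seq_len(n), function(s) as.numeric(buildShape(s, kappa)),
                numeric(3 * k))
    V <- V - rowMeans(V)
    fitted <- outer(drop(V %*% xcs) / sum(xcs^2), xcs)
    sum(fitted^2) / sum(V^2)
  }
  fr <- truth$allometricFraction
  kappa <- 0
  if (fr > 0) {
    if (r2At(0) >= fr) {
      warning("planted beta exponents alone explain at least the requested ",
              "allometric fraction; extra allometric shape change disabled")
    } else {
      hi2 <- 0.05
      while (r2At(hi2) < fr && hi2 < 1e3) hi2 <- hi2 * 2
      kappa <- stats::uniroot(function(kk) r2At(kk) - fr, c(0, hi2),
                              tol = 1e-12)$root
    }
  }

  ## --- assemble specimens -----------------------------------------------
  coords <- array(NA_real_, c(k, 3, n))
  for (s in seq_len(n)) {
    X <- buildShape(s, kappa) * exp(x[s])
    if (truth$rigidMotions) {
      X <- X %*% .randomRotation()
      X <- sweep(X, 2, stats::rnorm(3, 0, 2), `+`)
    }
    coords[, , s] <- X
  }

  ## --- partial specimens keep a random 2-3 module subset ----------------
  partialModules <- vector("list", n)
  if (nPartial > 0) {
    for (s in nSpecimens + seq_len(nPartial)) {
      keepM <- sample(mods, sample(2:min(3, M), 1))
      partialModules[[s]] <- keepM
      drop <- !(scheme$module %in% keepM)
      coords[drop, , s] <- NA_real_
    }
  }
  ids <- c(sprintf("sim%03d", seq_len(nSpecimens)),
           if (nPartial > 0) sprintf("part%02d", seq_len(nPartial)))
  dataset <- specimenDataset(coords, scheme, ids)
  truth$logSize <- x
  truth$sex <- ifelse(sex > 0, "f", "m")
  truth$juvenile <- juvenile
  truth$compression <- compression
  truth$partialModules <- partialModules
  truth$kappa <- kappa
  truth$seed <- seed
  list(dataset = dataset, truth = truth)
}

#' Apply taphonomic deformation to a dataset
#'
#' Dilation is the symmetric component of burial deformation: a per-specimen
#' anisotropic compression along the dorsoventral (z) axis about the
#' centroid. An optional small shear about the midline adds the asymmetric
#' component that [symmetrizeRetrodeform()] is designed to remove.
#' Deformation acts in the coordinates as stored, so it is intended for
#' synthetic datasets before any random rigid motion.
#'
#' @param dataset a [specimenDataset()].
#' @param compressionRange dorsoventral scale factor range (e.g.
#'   `c(0.7, 1)`).
#' @param shearDegRange shear angle range in degrees about the midline.
#' @param seed RNG seed.
#' @return the deformed dataset; attribute `taphonomyLog` records the
#'   factor and shear drawn per specimen.
#' @export
applyTaphonomy <- function(dataset, compressionRange = c(0.7, 1),
                           shearDegRange = c(0, 0), seed = 1) {
  stopifnot(inherits(dataset, "specimen_dataset"))
  if (diff(range(compressionRange)) < 0 || any(compressionRange <= 0)) {
    stop("invalid compression range")
  }
  set.seed(seed)
  n <- nSpecimens(dataset)
  fac <- stats::runif(n, compressionRange[1], compressionRange[2])
  shear <- stats::runif(n, shearDegRange[1], shearDegRange[2])
  out <- dataset
  for (s in seq_len(n)) {
    X <- dataset$coords[, , s]
    ok <- stats::complete.cases(X)
    ctr <- colMeans(X[ok, , drop = FALSE])
    X[ok, 3] <- ctr[3] + fac[s] * (X[ok, 3] - ctr[3])
    if (shear[s] != 0) {
      X[ok, 1] <- X[ok, 1] + tan(shear[s] * pi / 180) * (X[ok, 3] - ctr[3])
    }
    out$coords[, , s] <- X
  }
  attr(out, "taphonomyLog") <- data.frame(
    specimen = dataset$specimens, compression = fac, shearDeg = shear)
  out
}

#' The paper-like synthetic preset
#'
#' Study conditions mirroring the scale of the fossil analysis: 30 complete
#' plus 14 partial specimens, five modules, allometric fraction 0.5, a
#' frill analogue with the steepest size slope (1.4 versus 1.1, 1.0, 1.0,
#' 0.9), three-fold allometric shape magnitude and the largest
#' size-independent variance; no planted dimorphism.
#'
#' @param kPerModule landmarks per module in the scheme (default 20,
#'   i.e. 60 analysis-side landmarks over 5 modules).
#' @param ... overrides passed to [syntheticTruth()].
#' @return a `synthetic_truth`.
#' @export
paperLikePreset <- function(kPerModule = 20, ...) {
  syntheticTruth(scheme = makeScheme(kPerModule = kPerModule), ...)
}
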