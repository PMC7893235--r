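#' Landmark congruence matrix
#'
#' Pairwise congruence coefficients between landmarks: for each landmark the
#' 3D deviations from its mean position are stacked across specimens into a
#' 3n-vector, and entry (i, j) is the normalised inner product of the two
#' vectors. Exactly co-varying landmarks score 1, anti-covarying landmarks
#' -1, independent landmarks scatter around 0. This is the correlation
#' matrix that the maximum-likelihood modularity analysis models.
#'
#' @param aligned an `aligned_dataset` (raw or allometry-corrected) or a
#'   k x 3 x n array.
#' @return k x k symmetric matrix, unit diagonal.
#' @export
congruenceMatrix <- function(aligned) {
  A <- if (inherits(aligned, "aligned_dataset")) aligned$coords else aligned
  k <- dim(A)[1]; n <- dim(A)[3]
  if (n < 4) stop("congruence needs at least 4 specimens")
  ids <- dimnames(A)[[1]]
  if (is.null(ids)) ids <- sprintf("lm%03d", seq_len(k))
  ## k x 3n deviation matrix, centred per landmark and coordinate
  D <- matrix(NA_real_, k, 3 * n)
  for (s in seq_len(n)) D[, 3 * (s - 1) + 1:3] <- A[, , s]
  ctr <- vapply(1:3, function(d) rowMeans(D[, seq(d, 3 * n, 3), drop = FALSE]),
                numeric(k))
  for (s in seq_len(n)) D[, 3 * (s - 1) + 1:3] <- D[, 3 * (s - 1) + 1:3] - ctr
  rs <- sqrt(rowSums(D^2))
  zero <- rs < 1e-14
  if (any(zero)) {
    stop("zero-variance landmark(s): ", paste(ids[zero], collapse = ", "))
  }
  C <- tcrossprod(D / rs)
  C[C > 1] <- 1; C[C < -1] <- -1
  diag(C) <- 1
  dimnames(C) <- list(ids, ids)
  C
}

## pair classes for a hypothesis: returns integer class id per upper-tri pair
## and the class labels; separate = one between-class per module pair,
## pooled = single between class
.pairClasses <- function(assign, ids, separate) {
  a <- assign[ids]
  if (anyNA(a)) stop("hypothesis leaves landmarks unassigned")
  k <- length(ids)
  ut <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  m1 <- a[ut[, 1]]; m2 <- a[ut[, 2]]
  within <- m1 == m2
  lab <- character(nrow(ut))
  lab[within] <- paste0("within.", m1[within])
  if (separate) {
    lo <- pmin(m1, m2)[!within]; hi <- pmax(m1, m2)[!within]
    lab[!within] <- paste0("between.", lo, ".", hi)
  } else {
    lab[!within] <- "between"
  }
  lab
}

#' Maximum-likelihood comparison of module hypotheses
#'
#' EMMLi-style model comparison over a congruence matrix. Each hypothesis
#' partitions the landmark pairs into correlation classes (one class per
#' within-module set; between-module pairs either pooled into one class or
#' kept separate per module pair — both variants are evaluated). Within a
#' class the absolute congruence coefficients share one parameter rho,
#' estimated by the class mean; the likelihood is Gaussian on the Fisher-z
#' scale with sampling variance 1/(n-3). Models are ranked by AICc with
#' parameter count = number of rho classes + 1 and sample size = number of
#' landmark pairs; Akaike weights quantify relative support.
#'
#' @param corr congruence matrix from [congruenceMatrix()].
#' @param hypotheses named list of assignments (named character vector
#'   landmark id -> module). A single-rho null model is always included.
#' @param nSpecimens number of specimens behind `corr` (must exceed 3).
#' @return object of class `modularity_result`: list with `table` (model,
#'   logL, k, AICc, dAICc, weight), `rho` (named list of fitted class
#'   means), `best` (best model name), `bestHypothesis` (its assignment),
#'   `corr`, `nSpecimens`, `hypotheses`.
#' @export
emmliFit <- function(corr, hypotheses, nSpecimens) {
  if (nSpecimens <= 3) stop("likelihood undefined for n <= 3 specimens")
  ids <- rownames(corr)
  if (is.null(ids)) stop("congruence matrix needs landmark ids as dimnames")
  if (is.null(names(hypotheses)) || any(!nzchar(names(hypotheses)))) {
    stop("hypotheses must be a named list")
  }
  r <- abs(corr[upper.tri(corr)])
  r <- pmin(r, 0.999999)
  z <- atanh(r)
  sdz <- 1 / sqrt(nSpecimens - 3)
  N <- length(r)

  models <- list()
  addModel <- function(name, lab, hypName) {
    rho <- tapply(r, lab, mean)
    mu <- atanh(pmin(rho, 0.999999))[lab]
    ll <- sum(stats::dnorm(z, mu, sdz, log = TRUE))
    p <- length(rho) + 1
    if (N - p - 1 <= 0) stop("more parameters than landmark pairs supports")
    aicc <- -2 * ll + 2 * p + 2 * p * (p + 1) / (N - p - 1)
    models[[name]] <<- list(logL = ll, k = p, AICc = aicc,
                            rho = rho, hypothesis = hypName)
  }
  addModel("null.single.rho", rep("all", N), NA_character_)
  for (nm in names(hypotheses)) {
    a <- hypotheses[[nm]]
    mods <- unique(a[ids])
    if (length(mods) < 2) next                # duplicate of the null
    addModel(paste0(nm, ".sep.between"), .pairClasses(a, ids, TRUE), nm)
    addModel(paste0(nm, ".pooled.between"), .pairClasses(a, ids, FALSE), nm)
  }
  aicc <- vapply(models, `[[`, numeric(1), "AICc")
  daicc <- aicc - min(aicc)
  w <- exp(-daicc / 2); w <- w / sum(w)
  tab <- data.frame(model = names(models),
                    logL = vapply(models, `[[`, numeric(1), "logL"),
                    k = vapply(models, `[[`, numeric(1), "k"),
                    AICc = aicc, dAICc = daicc, weight = w,
                    stringsAsFactors = FALSE, row.names = NULL)
  tab <- tab[order(tab$AICc), ]
  best <- tab$model[1]
  bestHyp <- models[[best]]$hypothesis
  structure(list(
    table = tab,
    rho = lapply(models, `[[`, "rho"),
    best = best,
    bestHypothesis = if (!is.na(bestHyp)) hypotheses[[bestHyp]] else
      setNames(rep("all", length(ids)), ids),
    corr = corr, nSpecimens = nSpecimens, hypotheses = hypotheses
  ), class = "modularity_result")
}

#' @export
print.modularity_result <- function(x, ...) {
  cat("Maximum-likelihood modularity comparison (", nrow(x$table),
      " models )\nbest:", x$best, "\n")
  print(utils::head(x$table, 5), row.names = FALSE)
  invisible(x)
}

#' Merge weakly separated modules
#'
#' High-density landmark data tend to support many small modules; to
#' compensate, modules whose between-module correlation comes within
#' `threshold` of the lowest within-module correlation are merged
#' (transitively, as connected components). Between-module correlations
#' are the class means of the best hypothesis computed directly from the
#' congruence matrix, so the rule works whether the AICc-best variant
#' pooled its between classes or not.
#'
#' @param result a [emmliFit()] result.
#' @param threshold merge margin (default 0.1).
#' @return list with `assignment` (landmark id -> merged module label),
#'   `mapping` (old module -> merged label), `nModules`, `rhoWithin`,
#'   `rhoBetween` (matrix).
#' @export
mergeModules <- function(result, threshold = 0.1) {
  stopifnot(inherits(result, "modularity_result"))
  a <- result$bestHypothesis
  ids <- rownames(result$corr)
  a <- a[ids]
  mods <- unique(a)
  m <- length(mods)
  r <- abs(result$corr)
  rhoW <- setNames(numeric(m), mods)
  for (mod in mods) {
    sel <- which(a == mod)
    rr <- r[sel, sel]
    rhoW[mod] <- mean(rr[upper.tri(rr)])
  }
  rhoB <- matrix(NA_real_, m, m, dimnames = list(mods, mods))
  if (m > 1) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      rhoB[i, j] <- rhoB[j, i] <-
        mean(r[a == mods[i], a == mods[j]])
    }
  }
  rhoMin <- min(rhoW)
  ## union-find over mergeable pairs
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (m > 1) {
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (rhoB[i, j] >= rhoMin - threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(m), find, integer(1))
  newLab <- vapply(seq_len(m), function(i) {
    paste(sort(mods[comp == comp[i]]), collapse = "+")
  }, character(1))
  mapping <- setNames(newLab, mods)
  assignment <- setNames(mapping[a], ids)
  list(assignment = assignment, mapping = mapping,
       nModules = length(unique(newLab)),
       rhoWithin = rhoW, rhoBetween = rhoB)
}

## squared-covariance landmark matrix: S[i,j] = sum over the 3x3
## cross-covariance block of squared entries (basis of the CR statistic)
.squaredCovLandmarks <- function(aligned) {
  Y <- .shapeMatrix(aligned)
  Y <- sweep(Y, 2, colMeans(Y))
  V <- crossprod(Y) / (nrow(Y) - 1)
  k <- ncol(Y) / 3
  S <- matrix(0, k, k)
  for (d1 in 1:3) for (d2 in 1:3) {
    S <- S + V[seq(d1, 3 * k, 3), seq(d2, 3 * k, 3), drop = FALSE]^2
  }
  S
}

.crFromS <- function(S, modIdx) {
  mods <- unique(modIdx)
  m <- length(mods)
  within <- numeric(m)
  for (i in seq_len(m)) {
    sel <- modIdx == mods[i]
    ss <- S[sel, sel]
    within[i] <- sum(ss) - sum(diag(ss))
  }
  crs <- c()
  for (i in 1:(m - 1)) for (j in (i + 1):m) {
    bet <- sum(S[modIdx == mods[i], modIdx == mods[j]])
    crs <- c(crs, sqrt(bet / sqrt(within[i] * within[j])))
  }
  mean(crs)
}

#' Covariance ratio test of modularity
#'
#' The covariance ratio (CR) compares between-module to within-module
#' covariation of the Procrustes coordinates: for each module pair, the
#' root of the summed squared between-block covariances over the geometric
#' mean of the summed squared within-block covariances (diagonal cells
#' excluded); the overall CR is the mean over module pairs. Values below 1
#' indicate modular structure. Significance comes from permuting whole
#' landmarks (keeping x, y, z together) across modules, preserving module
#' sizes; the p-value is the smoothed proportion of permuted CRs at or
#' below the observed one.
#'
#' @param aligned an `aligned_dataset` (raw or allometry-corrected).
#' @param partition named character vector landmark id -> module, or `NULL`
#'   to use the scheme's module labels.
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `cr`, `p`, `crPairs` hidden in `attr`, `perm` (the
#'   permuted values), `nPerm`.
#' @export
covarianceRatio <- function(aligned, partition = NULL, nPerm = 999,
                            seed = 1) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  n <- length(aligned$specimens)
  if (n < 3) stop("covariance ratio needs at least 3 specimens")
  ids <- aligned$scheme$id
  if (is.null(partition)) {
    partition <- setNames(aligned$scheme$module, ids)
  }
  modIdx <- as.integer(factor(partition[ids]))
  if (length(unique(modIdx)) < 2) stop("need at least 2 modules")
  if (any(table(modIdx) < 2)) stop("every module needs at least 2 landmarks")
  S <- .squaredCovLandmarks(aligned)
  cr <- .crFromS(S, modIdx)
  if (!is.null(seed)) set.seed(seed)
  perm <- numeric(nPerm)
  for (i in seq_len(nPerm)) {
    perm[i] <- .crFromS(S, sample(modIdx))
  }
  p <- (sum(perm <= cr) + 1) / (nPerm + 1)
  list(cr = cr, p = p, perm = perm, nPerm = nPerm)
}
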