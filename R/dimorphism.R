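#' Hartigans' dip statistic
#'
#' The dip measures departure from unimodality: the smallest sup-norm
#' distance between the empirical distribution function of the sample and
#' any unimodal distribution function (convex up to a mode, concave after
#' it). It is location- and scale-invariant, bounded between 1/(2n) and
#' 0.25, and large for well-separated mixtures. Computed in closed form by
#' scanning candidate mode positions with convex-minorant / concave-majorant
#' geometry (see `src/dip.cpp`).
#'
#' @param values numeric vector, at least 2 finite values.
#' @return the dip statistic D.
#' @export
dipStatistic <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("dip needs at least 2 finite values")
  dip_cpp(as.numeric(values))
}

#' Dip test of unimodality
#'
#' Monte-Carlo test against the uniform null, the asymptotically least
#' favourable unimodal distribution: the p-value is the smoothed proportion
#' of dip statistics from `nMc` uniform samples of the same size that reach
#' or exceed the observed dip.
#'
#' @param values numeric sample (n >= 4).
#' @param nMc number of Monte-Carlo null samples (default 10000).
#' @param seed RNG seed (`NULL` = leave the RNG state alone).
#' @param null optional precomputed null dips for this sample size (e.g.
#'   from [dipNull()]), reused to avoid re-simulation in scans.
#' @return object of class `dip_result`: list with `n`, `statistic`, `p`,
#'   `nMc`.
#' @export
dipTest <- function(values, nMc = 10000, seed = NULL, null = NULL) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4) stop("dip test needs at least 4 values")
  D <- dipStatistic(values)
  if (is.null(null)) {
    if (!is.null(seed)) set.seed(seed)
    null <- dip_null_cpp(n, as.integer(nMc))
  } else if (!is.null(attr(null, "n")) && attr(null, "n") != n) {
    stop("precomputed null is for a different sample size")
  }
  p <- (sum(null >= D) + 1) / (length(null) + 1)
  structure(list(n = n, statistic = D, p = p, nMc = length(null)),
            class = "dip_result")
}

#' @export
print.dip_result <- function(x, ...) {
  cat(sprintf("Hartigans' dip: D = %.4f, n = %d, Monte-Carlo p = %.4g\n",
              x$statistic, x$n, x$p))
  invisible(x)
}

#' Null distribution of the dip for a given sample size
#'
#' @param n sample size.
#' @param nMc number of uniform samples.
#' @param seed RNG seed.
#' @return numeric vector of null dips with attribute `n`.
#' @export
dipNull <- function(n, nMc = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  structure(dip_null_cpp(as.integer(n), as.integer(nMc)), n = n)
}

#' Flag the smallest specimens as juveniles by their size gap
#'
#' Very young individuals form a cluster well below the adults on the
#' allometry (log centroid size) axis. The rule is deterministic: sort the
#' log sizes, find the largest adjacent gap, and flag everything below it
#' as juvenile when that gap exceeds `gapFactor` times the median adjacent
#' gap. With evenly spread sizes nothing is flagged.
#'
#' @param aligned an `aligned_dataset`, or a numeric vector of centroid
#'   sizes.
#' @param gapFactor multiple of the median gap required (default 2).
#' @return list with `juvenile` (logical per specimen, input order),
#'   `threshold` (log-size midpoint of the gap, `NA` if none), `gap`,
#'   `medianGap`.
#' @export
excludeJuveniles <- function(aligned, gapFactor = 2) {
  sizes <- if (inherits(aligned, "aligned_dataset")) aligned$size else aligned
  n <- length(sizes)
  if (n < 4) stop("refusing to split fewer than 4 specimens")
  ls <- log(sizes)
  o <- order(ls)
  gaps <- diff(ls[o])
  gi <- which.max(gaps)
  medGap <- stats::median(gaps)
  juv <- rep(FALSE, n)
  threshold <- NA_real_
  if (gaps[gi] > gapFactor * medGap && medGap > 0) {
    threshold <- (ls[o][gi] + ls[o][gi + 1]) / 2
    juv <- ls < threshold
  }
  list(juvenile = juv, threshold = threshold,
       gap = gaps[gi], medianGap = medGap)
}

#' Dimorphism scan: dip tests over residual shape components
#'
#' Sexual shape dimorphism in a pooled sample should surface as bimodality
#' in some direction of size-independent shape space. For every supplied
#' dataset variant the scan removes allometry, extracts the residual shape
#' components (principal components of the corrected coordinates), and dip
#' tests the first `nComponents` of them; the whole scan is repeated with
#' the juvenile specimens excluded. No multiple-testing correction is
#' applied — the per-component p-values are reported raw, together with the
#' number of flags expected by chance at the 5% level.
#'
#' @param variants named list of `aligned_dataset` objects (e.g. whole
#'   skull plus per-module globally- and separately-aligned datasets).
#' @param nComponents components to test per variant (default 8; truncated
#'   with a warning when fewer are available).
#' @param nMc Monte-Carlo samples per dip test.
#' @param seed RNG seed (null distributions are cached per sample size).
#' @param juvenileSubset also run with juveniles excluded (default TRUE).
#' @param gapFactor passed to [excludeJuveniles()].
#' @return data frame with class `dimorphism_scan`: variant, subset,
#'   component, n, statistic, p, flag; attributes `alpha`,
#'   `expectedFalseFlags`.
#' @export
dimorphismScan <- function(variants, nComponents = 8, nMc = 10000,
                           seed = 1, juvenileSubset = TRUE, gapFactor = 2) {
  if (is.null(names(variants))) {
    names(variants) <- sprintf("variant%02d", seq_along(variants))
  }
  if (!is.null(seed)) set.seed(seed)
  nullCache <- new.env(parent = emptyenv())
  getNull <- function(n) {
    key <- as.character(n)
    if (is.null(nullCache[[key]])) {
      nullCache[[key]] <- structure(dip_null_cpp(n, as.integer(nMc)), n = n)
    }
    nullCache[[key]]
  }
  rows <- list()
  scanOne <- function(aligned, label, subset) {
    model <- fitShapeSizeRegression(aligned, nPerm = 0)
    corr <- allometryCorrect(aligned, model)
    Y <- .shapeMatrix(corr)
    Y <- sweep(Y, 2, colMeans(Y))
    pc <- stats::prcomp(Y, center = FALSE)
    avail <- sum(pc$sdev > max(pc$sdev) * 1e-8)
    nc <- min(nComponents, avail)
    if (nc < nComponents) {
      warning("variant ", label, " (", subset, "): only ", nc,
              " residual components available; scan truncated")
    }
    for (comp in seq_len(nc)) {
      sc <- pc$x[, comp]
      dt <- dipTest(sc, null = getNull(length(sc)))
      rows[[length(rows) + 1]] <<- data.frame(
        variant = label, subset = subset, component = comp,
        n = dt$n, statistic = dt$statistic, p = dt$p,
        flag = dt$p < 0.05, stringsAsFactors = FALSE)
    }
  }
  for (nm in names(variants)) {
    al <- variants[[nm]]
    scanOne(al, nm, "all")
    if (juvenileSubset) {
      ex <- excludeJuveniles(al, gapFactor)
      if (any(ex$juvenile) && sum(!ex$juvenile) >= 4) {
        keep <- which(!ex$juvenile)
        sub <- al
        sub$coords <- al$coords[, , keep, drop = FALSE]
        sub$size <- al$size[keep]
        sub$moduleSize <- al$moduleSize[, keep, drop = FALSE]
        sub$specimens <- al$specimens[keep]
        scanOne(sub, nm, "juveniles-removed")
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- 0.05
  attr(out, "expectedFalseFlags") <- 0.05 * nrow(out)
  class(out) <- c("dimorphism_scan", "data.frame")
  out
}
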