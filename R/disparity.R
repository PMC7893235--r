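#' Procrustes variance per landmark and per module
#'
#' Morphological disparity: for every landmark, the mean squared 3D
#' deviation (divisor n - 1) of the aligned coordinates from the mean
#' configuration; per module, the sum of its landmarks' variances and the
#' landmark-count-normalised value (sum / number of landmarks), which makes
#' modules of different landmark density comparable. The landmark variances
#' add up exactly to the total Procrustes variance of the dataset.
#'
#' @param aligned an `aligned_dataset` (raw or allometry-corrected; the
#'   variant tag is carried through).
#' @param partition named character vector landmark id -> module, or `NULL`
#'   for the scheme's modules.
#' @return object of class `disparity_table`: list with `landmark` (data
#'   frame id, module, variance), `module` (data frame module,
#'   n_landmarks, variance, normalized), `total`, `variant`.
#' @export
procrustesVariance <- function(aligned, partition = NULL) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  A <- aligned$coords
  n <- dim(A)[3]
  if (n < 2) stop("Procrustes variance needs at least 2 specimens")
  mn <- apply(A, c(1, 2), mean)
  dev2 <- apply(sweep(A, c(1, 2), mn)^2, c(1, 3), sum)   # k x n
  v <- rowSums(dev2) / (n - 1)
  ids <- aligned$scheme$id
  if (is.null(partition)) partition <- setNames(aligned$scheme$module, ids)
  mod <- partition[ids]
  lm_tab <- data.frame(id = ids, module = mod, variance = v,
                       stringsAsFactors = FALSE, row.names = NULL)
  agg <- lapply(split(lm_tab$variance, lm_tab$module), function(x) {
    c(n = length(x), sum = sum(x))
  })
  mod_tab <- data.frame(
    module = names(agg),
    n_landmarks = vapply(agg, `[[`, numeric(1), "n"),
    variance = vapply(agg, `[[`, numeric(1), "sum"),
    stringsAsFactors = FALSE, row.names = NULL)
  mod_tab$normalized <- mod_tab$variance / mod_tab$n_landmarks
  structure(list(landmark = lm_tab, module = mod_tab,
                 total = sum(v), variant = aligned$variant),
            class = "disparity_table")
}

#' @export
print.disparity_table <- function(x, ...) {
  cat("Procrustes variance (", x$variant, "), total =",
      format(x$total, digits = 4), "\n")
  print(x$module[order(-x$module$normalized), ], row.names = FALSE)
  invisible(x)
}

#' Regression of module disparity on a covariate
#'
#' Tests, across modules, whether disparity tracks a covariate such as the
#' module growth rate (centroid-size allometric slope) or the within-module
#' correlation from the maximum-likelihood modularity fit. Ordinary least
#' squares with a two-sided t-test on the slope.
#'
#' @param moduleDisparity numeric vector of per-module (normalised)
#'   disparities, named by module.
#' @param covariate numeric vector over the same modules (matched by name
#'   when both are named).
#' @return list with `slope`, `r`, `p`, `n`.
#' @export
disparityCovariateTest <- function(moduleDisparity, covariate) {
  if (!is.null(names(moduleDisparity)) && !is.null(names(covariate))) {
    covariate <- covariate[names(moduleDisparity)]
  }
  ok <- is.finite(moduleDisparity) & is.finite(covariate)
  y <- moduleDisparity[ok]; x <- covariate[ok]
  if (length(y) < 3) stop("need at least 3 modules")
  if (stats::sd(x) < 1e-14) stop("covariate has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]),
       r = unname(stats::cor(x, y)),
       p = sm$coefficients[2, 4],
       n = length(y))
}
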