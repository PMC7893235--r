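## Test fixtures and independent oracles, built in code.

## random proper rotation
rrot <- function() {
  R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## Procrustes distance between two configurations (after full superimposition)
procDist <- function(a, b) {
  a <- sweep(a, 2, colMeans(a)); a <- a / sqrt(sum(a^2))
  b <- sweep(b, 2, colMeans(b)); b <- b / sqrt(sum(b^2))
  sv <- svd(crossprod(a, b))
  d <- diag(3); if (det(sv$u %*% t(sv$v)) < 0) d[3, 3] <- -1
  sqrt(max(0, sum((a %*% (sv$u %*% d %*% t(sv$v)) - b)^2)))
}

## a small irregular (non-degenerate) 3D configuration
toyConfig <- function(k = 8, seed = 7) {
  set.seed(seed)
  matrix(rnorm(3 * k), k, 3)
}

## tiny bilateral scheme: nMid midline + nPair left/right pairs, one module
tinyScheme <- function(nMid = 4, nPair = 3, module = "all") {
  ids <- c(sprintf("m%02d", seq_len(nMid)),
           sprintf("r%02d", seq_len(nPair)), sprintf("l%02d", seq_len(nPair)))
  landmarkScheme(
    ids,
    type = "fixed", module = module,
    midline = c(rep(TRUE, nMid), rep(FALSE, 2 * nPair)),
    pair = c(rep(NA, nMid), sprintf("l%02d", seq_len(nPair)),
             sprintf("r%02d", seq_len(nPair))),
    side = c(rep("mid", nMid), rep("right", nPair), rep("left", nPair)))
}

## symmetric configuration on a tiny scheme (midline exactly at x = 0)
tinySymmetricConfig <- function(scheme, seed = 11) {
  set.seed(seed)
  k <- nrow(scheme)
  x <- matrix(rnorm(3 * k), k, 3)
  x[scheme$midline, 1] <- 0
  left <- which(scheme$side == "left")
  p <- match(scheme$pair[left], scheme$id)
  x[which(scheme$side == "right"), 1] <-
    abs(x[which(scheme$side == "right"), 1]) + 0.5
  x[left, ] <- x[p, ]
  x[left, 1] <- -x[left, 1]
  dimnames(x) <- list(scheme$id, c("x", "y", "z"))
  x
}

## brute-force pairwise superimposition: coarse-to-fine grid over rotations
## (Euler angles), translation and scale closed-form given the rotation
gridAlignResidual <- function(target, reference, scale = TRUE) {
  Xc <- sweep(target, 2, colMeans(target))
  Yc <- sweep(reference, 2, colMeans(reference))
  rotz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                               0, 0, 1), 3, 3)
  roty <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                               sin(a), 0, cos(a)), 3, 3)
  resid <- function(ang) {
    R <- rotz(ang[1]) %*% roty(ang[2]) %*% rotz(ang[3])
    Xr <- Xc %*% R
    s <- if (scale) max(0, sum(Xr * Yc) / sum(Xr^2)) else 1
    sum((s * Xr - Yc)^2)
  }
  best <- c(0, 0, 0); bestv <- resid(best)
  for (a1 in seq(0, 2 * pi, by = 0.25)) {
    for (a2 in seq(0, pi, by = 0.25)) {
      for (a3 in seq(0, 2 * pi, by = 0.25)) {
        v <- resid(c(a1, a2, a3))
        if (v < bestv) { bestv <- v; best <- c(a1, a2, a3) }
      }
    }
  }
  step <- 0.125
  while (step > 1e-5) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (i in 1:3) for (s in c(-step, step)) {
        cand <- best; cand[i] <- cand[i] + s
        v <- resid(cand)
        if (v < bestv - 1e-15) { bestv <- v; best <- cand; improved <- TRUE }
      }
    }
    step <- step / 2
  }
  bestv
}

## direct-solve TPS bending energy oracle: fit the interpolating 3D TPS
## (kernel U(r) = -r) and evaluate its energy as sum_d w_d' K w_d
tpsEnergyDirect <- function(reference, target) {
  k <- nrow(reference)
  K <- -as.matrix(dist(reference))
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  e <- 0
  for (d in 1:3) {
    rhs <- c(target[, d] - reference[, d], rep(0, 4))
    sol <- solve(L, rhs)
    w <- sol[seq_len(k)]
    e <- e + drop(crossprod(w, K %*% w))
  }
  e
}

## dip oracle: minimum sup-distance to a piecewise-linear unimodal CDF,
## solved as linear programs over candidate mode positions (data points
## with an atom, plus a grid of positions inside each gap)
dipOracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  X <- unique(x)
  G <- length(X)
  cnt <- as.numeric(table(match(x, X)))
  hi <- cumsum(cnt) / n
  lo <- c(0, hi[-G])
  if (G == 1) return(0.5 / n)
  best <- Inf
  solveLP <- function(nv, cons) {
    A1 <- do.call(rbind, lapply(cons$le, `[[`, 1))
    b1 <- vapply(cons$le, `[[`, numeric(1), 2)
    A2 <- do.call(rbind, lapply(cons$ge, `[[`, 1))
    b2 <- vapply(cons$ge, `[[`, numeric(1), 2)
    obj <- rep(0, nv); obj[nv] <- 1
    sol <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                         maxi = FALSE)
    if (sol$solved == 1) sol$value else Inf
  }
  newCons <- function() list(le = list(), ge = list())
  addLE <- function(cons, row, rhs) { cons$le[[length(cons$le) + 1]] <- list(row, rhs); cons }
  addGE <- function(cons, row, rhs) { cons$ge[[length(cons$ge) + 1]] <- list(row, rhs); cons }
  convexRows <- function(cons, cols, xs, z, sign = 1) {
    if (length(cols) >= 3) {
      for (i in 2:(length(cols) - 1)) {
        h1 <- xs[i] - xs[i - 1]; h2 <- xs[i + 1] - xs[i]
        r <- z
        r[cols[i - 1]] <- r[cols[i - 1]] + sign / h1
        r[cols[i]] <- r[cols[i]] - sign * (1 / h1 + 1 / h2)
        r[cols[i + 1]] <- r[cols[i + 1]] + sign / h2
        cons <- addGE(cons, r, 0)
      }
    }
    cons
  }
  ## atom at data point t
  for (t in seq_len(G)) {
    nv <- G + 2
    di <- nv; iL <- t; iR <- t + 1
    pos <- function(j) if (j < t) j else j + 1
    z <- rep(0, nv)
    cons <- newCons()
    for (j in seq_len(G)) {
      if (j == t) {
        r <- z; r[iL] <- 1; r[di] <- 1; cons <- addGE(cons, r, lo[t])
        r <- z; r[iL] <- 1; r[di] <- -1; cons <- addLE(cons, r, lo[t])
        r <- z; r[iR] <- 1; r[di] <- 1; cons <- addGE(cons, r, hi[t])
        r <- z; r[iR] <- 1; r[di] <- -1; cons <- addLE(cons, r, hi[t])
      } else {
        r <- z; r[pos(j)] <- 1; r[di] <- 1; cons <- addGE(cons, r, hi[j])
        r <- z; r[pos(j)] <- 1; r[di] <- -1; cons <- addLE(cons, r, lo[j])
      }
    }
    cols <- c(if (t > 1) vapply(1:(t - 1), pos, 0), iL, iR,
              if (t < G) vapply((t + 1):G, pos, 0))
    for (i in seq_len(length(cols) - 1)) {
      r <- z; r[cols[i]] <- -1; r[cols[i + 1]] <- 1; cons <- addGE(cons, r, 0)
    }
    cons <- convexRows(cons, c(if (t > 1) vapply(1:(t - 1), pos, 0), iL),
                       c(X[seq_len(t - 1)], X[t]), z, 1)
    cons <- convexRows(cons, c(iR, if (t < G) vapply((t + 1):G, pos, 0)),
                       c(X[t], if (t < G) X[(t + 1):G]), z, -1)
    best <- min(best, solveLP(nv, cons))
  }
  ## mode inside a gap
  for (s in seq_len(G - 1)) {
    for (frac in c(0.15, 0.3, 0.5, 0.7, 0.85)) {
      m <- X[s] + frac * (X[s + 1] - X[s])
      nv <- G + 3
      iL <- G + 1; iR <- G + 2; di <- G + 3
      z <- rep(0, nv)
      cons <- newCons()
      for (j in seq_len(G)) {
        r <- z; r[j] <- 1; r[di] <- 1; cons <- addGE(cons, r, hi[j])
        r <- z; r[j] <- 1; r[di] <- -1; cons <- addLE(cons, r, lo[j])
      }
      for (ii in c(iL, iR)) {
        r <- z; r[ii] <- 1; r[di] <- 1; cons <- addGE(cons, r, hi[s])
        r <- z; r[ii] <- 1; r[di] <- -1; cons <- addLE(cons, r, hi[s])
      }
      cols <- c(seq_len(s), iL, iR, if (s < G) (s + 1):G)
      for (i in seq_len(length(cols) - 1)) {
        r <- z; r[cols[i]] <- -1; r[cols[i + 1]] <- 1; cons <- addGE(cons, r, 0)
      }
      cons <- convexRows(cons, c(seq_len(s), iL), c(X[seq_len(s)], m), z, 1)
      cons <- convexRows(cons, c(iR, (s + 1):G), c(m, X[(s + 1):G]), z, -1)
      best <- min(best, solveLP(nv, cons))
    }
  }
  max(best, 0.5 / n)
}
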