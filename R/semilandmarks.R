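#' Thin-plate-spline bending energy model
#'
#' Builds the 3D thin-plate-spline system for a reference configuration,
#' kernel U(r) = -r, and extracts the bending-energy matrix: the upper-left
#' k x k block of the inverted TPS system. The quadratic form
#' \eqn{\sum_d v_d' B v_d} over displacement fields v measures the
#' non-affine ("bending") part of the deformation taking the reference to
#' reference + v; it is zero for every affine map and positive otherwise.
#'
#' @param reference k x 3 matrix with pairwise-distinct rows.
#' @return object of class `tps_model`: list with `reference` and `energy`
#'   (k x k symmetric positive semidefinite matrix).
#' @export
bendingEnergyMatrix <- function(reference) {
  k <- nrow(reference)
  if (k < 5) stop("3D TPS needs at least 5 reference landmarks")
  D <- as.matrix(stats::dist(reference))
  if (any(D[upper.tri(D)] < 1e-12)) {
    stop("coincident reference landmarks make the TPS kernel singular")
  }
  ## 3D kernel U(r) = -r: distance matrices are conditionally negative
  ## definite, so this sign makes the bending quadratic form positive
  ## semidefinite on the non-affine subspace
  K <- -D
  P <- cbind(1, reference)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  Li <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system: ", conditionMessage(e)))
  B <- Li[seq_len(k), seq_len(k), drop = FALSE]
  B <- (B + t(B)) / 2
  structure(list(reference = reference, energy = B), class = "tps_model")
}

#' Bending energy of a target configuration relative to a TPS model
#'
#' @param model a [bendingEnergyMatrix()] result.
#' @param target k x 3 matrix over the same landmarks.
#' @return non-negative scalar (numerically, >= -1e-10).
#' @export
bendingEnergy <- function(model, target) {
  v <- target - model$reference
  sum(vapply(1:3, function(d) drop(crossprod(v[, d], model$energy %*% v[, d])),
             numeric(1)))
}

## tangent directions per landmark: list with $idx (landmark row), $U (3 x q_i)
## curves: central difference along the stated curve order (one-sided at ends)
## surfaces: first two principal directions of the 8-nearest-neighbour cloud;
## neighbour sets are fixed from the reference so the operation is
## deterministic, directions are evaluated on the configuration itself.
.tangentBases <- function(config, scheme, neighbours) {
  out <- list()
  for (i in seq_len(nrow(scheme))) {
    if (scheme$type[i] == "curve") {
      ids <- which(scheme$curve == scheme$curve[i])
      ids <- ids[order(scheme$curve_pos[ids])]
      pos <- which(ids == i)
      lo <- ids[max(1, pos - 1)]; hi <- ids[min(length(ids), pos + 1)]
      t1 <- config[hi, ] - config[lo, ]
      nrmv <- sqrt(sum(t1^2))
      if (nrmv < 1e-12) stop("degenerate curve tangent at landmark ", scheme$id[i])
      out[[length(out) + 1]] <- list(idx = i, U = matrix(t1 / nrmv, 3, 1))
    } else if (scheme$type[i] == "surface") {
      nb <- neighbours[[i]]
      cloud <- config[c(i, nb), , drop = FALSE]
      cloud <- sweep(cloud, 2, colMeans(cloud))
      e <- eigen(crossprod(cloud), symmetric = TRUE)
      out[[length(out) + 1]] <- list(idx = i, U = e$vectors[, 1:2])
    }
  }
  out
}

.surfaceNeighbours <- function(reference, scheme, nNeighbours = 8) {
  D <- as.matrix(stats::dist(reference))
  lapply(seq_len(nrow(scheme)), function(i) {
    if (scheme$type[i] != "surface") return(NULL)
    ord <- order(D[i, ])
    utils::head(setdiff(ord, i), nNeighbours)
  })
}

#' Slide semilandmarks to minimise bending energy
#'
#' Curve and surface semilandmarks have no exact anatomical position along
#' their structure; their spacing is a digitisation artefact. Sliding
#' displaces each semilandmark within its local tangent space (a 1D tangent
#' for curve points, a 2D tangent plane for surface points) so that the
#' thin-plate-spline bending energy of the deformation from the current
#' consensus to each specimen is minimised, using the closed-form
#' constrained least-squares solution. Fixed landmarks never move. The
#' cycle slide -> re-superimpose -> update consensus is repeated
#' `iterations` times; three passes are ample in practice since the energy
#' drop is sharp in the first pass.
#'
#' @param aligned an `aligned_dataset` from [gpa()] or [symmetricGPA()].
#' @param iterations number of slide/re-align cycles (default 3).
#' @param ridge small diagonal stabiliser for the tangent normal equations.
#' @return an `aligned_dataset` with slid coordinates; attribute
#'   `energyLog` records total bending energy before and after the slide of
#'   each iteration (non-increasing within each iteration by construction).
#' @export
slideSemilandmarks <- function(aligned, iterations = 3, ridge = 1e-10) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  scheme <- aligned$scheme
  semi <- scheme$type %in% c("curve", "surface")
  if (!any(semi)) return(aligned)
  if (any(scheme$type == "surface")) {
    ## guard: a surface semilandmark needs neighbours to define its tangent
    if (nrow(scheme) < 4) stop("isolated semilandmark: tangent undefined")
  }
  A <- aligned$coords
  k <- dim(A)[1]; n <- dim(A)[3]
  neighbours <- .surfaceNeighbours(aligned$consensus, scheme)
  energyLog <- data.frame(iteration = integer(0), before = numeric(0),
                          after = numeric(0))
  consensus <- aligned$consensus
  for (it in seq_len(iterations)) {
    model <- bendingEnergyMatrix(consensus)
    B <- model$energy
    ebefore <- eafter <- 0
    for (s in seq_len(n)) {
      X <- A[, , s]
      ebefore <- ebefore + bendingEnergy(model, X)
      bases <- .tangentBases(X, scheme, neighbours)
      q <- sum(vapply(bases, function(b) ncol(b$U), integer(1)))
      idx <- unlist(lapply(bases, function(b) rep(b$idx, ncol(b$U))))
      U <- matrix(0, 3, q)
      j <- 0
      for (b in bases) {
        U[, j + seq_len(ncol(b$U))] <- b$U
        j <- j + ncol(b$U)
      }
      ## normal equations for tangential displacements t:
      ##   A_ab = B[i_a, i_b] (u_a . u_b),  rhs_a = -u_a . (B Y)[i_a, ]
      Y <- X - consensus
      BY <- B %*% Y
      Amat <- B[idx, idx] * crossprod(U)
      rhs <- -vapply(seq_len(q), function(a) sum(U[, a] * BY[idx[a], ]),
                     numeric(1))
      diag(Amat) <- diag(Amat) + ridge * max(diag(Amat), 1e-300)
      tvec <- tryCatch(solve(Amat, rhs), error = function(e) {
        drop(.pinv(Amat) %*% rhs)
      })
      for (a in seq_len(q)) X[idx[a], ] <- X[idx[a], ] + tvec[a] * U[, a]
      eafter <- eafter + bendingEnergy(model, X)
      A[, , s] <- X
    }
    energyLog <- rbind(energyLog,
                       data.frame(iteration = it, before = ebefore,
                                  after = eafter))
    ## re-superimpose and update the consensus
    re <- gpa(specimenDataset(A, scheme, aligned$specimens))
    A <- re$coords
    consensus <- re$consensus
  }
  out <- aligned
  out$coords <- A
  out$consensus <- consensus
  attr(out, "energyLog") <- energyLog
  out
}

## SVD pseudo-inverse fallback for an exactly singular tangent system

.pinv <- function(X, tol = 1e-12) {
  s <- svd(X)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}
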