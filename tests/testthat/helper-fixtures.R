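## landmark array with factor-structured deviations: landmarks in the same
## module share a scalar factor (plus iid noise), across modules a global
## factor induces weaker correlation. Used for congruence/EMMLi/CR tests.
modularArray <- function(k = 30, nModules = 3, n = 50, rhoWithin = 0.7,
                         rhoBetween = 0.2, seed = 1) {
  set.seed(seed)
  mod <- rep(seq_len(nModules), length.out = k)[order(rep(seq_len(nModules),
                                                          length.out = k))]
  mod <- sort(rep_len(seq_len(nModules), k))
  base <- matrix(rnorm(3 * k, 0, 4), k, 3)
  fvar <- rhoWithin - rhoBetween
  gvar <- rhoBetween
  evar <- 1 - rhoWithin
  fm <- matrix(rnorm(n * nModules), n)
  gg <- rnorm(n)
  ## one common deviation direction: the congruence targets are then exact
  u <- c(0.4, -0.7, 0.59); u <- u / sqrt(sum(u^2))
  dirs <- matrix(u, k, 3, byrow = TRUE)
  arr <- array(NA_real_, c(k, 3, n))
  for (s in seq_len(n)) {
    amp <- sqrt(fvar) * fm[s, mod] + sqrt(gvar) * gg[s]
    dev <- dirs * amp + matrix(rnorm(3 * k, 0, sqrt(evar / 3)), k, 3)
    arr[, , s] <- base + 0.05 * dev
  }
  dimnames(arr) <- list(sprintf("lm%03d", seq_len(k)), NULL, NULL)
  list(arr = arr, module = setNames(paste0("mod", mod), dimnames(arr)[[1]]))
}

asAligned <- function(arr, module) {
  k <- dim(arr)[1]
  scheme <- landmarkScheme(dimnames(arr)[[1]], module = module)
  structure(list(coords = arr, size = rep(1, dim(arr)[3]), moduleSize = NULL,
                 consensus = apply(arr, c(1, 2), mean), scheme = scheme,
                 specimens = sprintf("s%03d", seq_len(dim(arr)[3])),
                 iterations = 0L, delta = numeric(0), variant = "raw"),
            class = "aligned_dataset")
}

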