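## Independent numerical oracles and small fixture builders used across the
## test files. The oracles deliberately avoid the package's own solvers.

## Closed-form LTI step response via the matrix exponential:
## x(t) = e^{At} x0 + A^{-1} (e^{At} - I) B u   (A invertible, u constant)
expmStepOracle <- function(A, B, u, times, x0 = rep(0, nrow(A))) {
  n <- nrow(A)
  t(vapply(times, function(t) {
    E <- as.matrix(Matrix::expm(A * t))
    as.numeric(E %*% x0 + solve(A, (E - diag(n)) %*% B %*% u))
  }, numeric(n)))
}

## Exact chain response to piecewise-linear forcing via an augmented matrix
## exponential: state [x; g; slope], d/dt g = slope.
chainExpmOracle <- function(a, r, times, g) {
  Ac <- diag(a, r)
  if (r > 1) for (j in 2:r) Ac[j, j - 1] <- 1
  M <- matrix(0, r + 2, r + 2)
  M[1:r, 1:r] <- Ac
  M[1, r + 1] <- 1
  M[r + 1, r + 2] <- 1
  x <- numeric(r + 2)
  out <- numeric(length(times))
  for (k in seq_along(times)[-1]) {
    h <- times[k] - times[k - 1]
    x[r + 1] <- g[k - 1]
    x[r + 2] <- (g[k] - g[k - 1]) / h
    x <- as.numeric(Matrix::expm(M * h) %*% x)
    out[k] <- x[r]
  }
  out
}

## Weighted least squares through the pseudo-inverse (oracle for regressInit)
pinvRegressOracle <- function(H, w, y) {
  sw <- sqrt(w)
  as.numeric(MASS::ginv(H * sw) %*% (y * sw))
}

## Brute-force position-by-position confusion counting (oracle for
## evaluateStructure); tol matches the package's edge-coding tolerance
bruteConfusionOracle <- function(Ai, Bi, At, Bt, tol = 1e-6) {
  code <- function(x) if (abs(x) <= tol) 0 else sign(x)
  cnt <- c(TP = 0, TN = 0, FPn = 0, FPs = 0, FN = 0)
  all_t <- cbind(At, Bt)
  all_i <- cbind(Ai, Bi)
  for (i in seq_len(nrow(all_t))) for (j in seq_len(ncol(all_t))) {
    ct <- code(all_t[i, j])
    ci <- code(all_i[i, j])
    k <- if (ct != 0 && ci == ct) "TP"
         else if (ct != 0 && ci != 0) "FPs"
         else if (ct == 0 && ci != 0) "FPn"
         else if (ct != 0) "FN"
         else "TN"
    cnt[k] <- cnt[k] + 1
  }
  cnt
}

## One- or two-experiment dataset simulated from a given small model,
## optionally noisy; measured grid with exponentially increasing intervals.
makeSimulatedDataset <- function(model, inputLevels = list(c(1, 0), c(0, 1)),
                                 times = c(0, 1, 2, 4, 8, 16), noiseSd = 0,
                                 seed = 1) {
  set.seed(seed)
  sn <- stimulusNames(model)
  exps <- lapply(seq_along(inputLevels), function(e) {
    u <- inputLevels[[e]]
    sim <- simulateGRN(model, u, times)
    Y <- sim + matrix(rnorm(length(sim), sd = noiseSd), nrow(sim))
    U <- matrix(rep(u, each = length(times)), length(times),
                dimnames = list(NULL, sn))
    grnExperiment(times, Y, U, name = paste0("E", e))
  })
  standardiseDataset(grnDataset(exps))
}

## Random stable gene-level model with negative diagonal, used by property
## tests.
randomStableModel <- function(n, m, seed) {
  set.seed(seed)
  A <- matrix(0, n, n)
  diag(A) <- -runif(n, 0.3, 2)
  off <- which(upper.tri(A) | lower.tri(A))
  pick <- sample(off, min(length(off), n))
  A[pick] <- runif(length(pick), -1, 1)
  B <- matrix(0, n, m)
  B[sample(seq_len(n * m), min(n, n * m))] <- runif(min(n, n * m), 0.3, 1.5)
  grnModel(A, B)
}
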