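# Fixtures use dyadic values (multiples of 2^-6) so that sums compared
# between the DP and the enumeration oracle are exact in doubles.
randomDyadicMatrix <- function(M, N, seed) {
  set.seed(seed)
  matrix(sample(0:64, M * N, replace = TRUE) / 64, M, N)
}

randomDyadicVolume <- function(M, N, P, seed) {
  set.seed(seed)
  array(sample(0:64, M * N * P, replace = TRUE) / 64, c(M, N, P))
}

# Independent re-implementation of the through-plane accumulation,
# written as plain elementwise loops (no vectorised shift trick) so it
# shares no code path with dp3dPass2.
referencePass2 <- function(c1, R, d2, alpha2, init = "featureVolume") {
  M <- dim(R)[1]; N <- dim(R)[2]; P <- dim(R)[3]
  c2 <- array(NA_real_, c(M, P, N))
  for (x in seq_len(N)) {
    for (y in seq_len(M)) {
      c2[y, 1, x] <- if (init == "featureVolume") R[y, x, 1] else c1[y, x, 1]
    }
    if (P >= 2) {
      for (z in 2:P) {
        for (y in seq_len(M)) {
          best <- Inf
          for (i in -d2:d2) {
            if (y + i >= 1 && y + i <= M) {
              v <- c2[y + i, z - 1, x] + alpha2 * abs(i)
              if (v < best) best <- v
            }
          }
          c2[y, z, x] <- best + c1[y, x, z]
        }
      }
    }
  }
  c2
}

# Exhaustive minimum over all d2-constrained z-paths of the per-angle
# second-pass objective (init term + c1 terms + alpha2 jump penalties).
bruteForceBestZPath <- function(c1, R, x, d2, alpha2, init = "featureVolume") {
  M <- dim(R)[1]; P <- dim(R)[3]
  initCol <- if (init == "featureVolume") R[, x, 1] else c1[, x, 1]
  best <- Inf
  grid <- expand.grid(rep(list(seq_len(M)), P))
  for (k in seq_len(nrow(grid))) {
    rows <- as.integer(grid[k, ])
    if (P >= 2 && any(abs(diff(rows)) > d2)) next
    cst <- initCol[rows[1]]
    if (P >= 2) {
      for (z in 2:P)
        cst <- cst + c1[rows[z], x, z] + alpha2 * abs(rows[z] - rows[z - 1])
    }
    if (cst < best) best <- cst
  }
  best
}

# cost of a traced per-angle z-path under the same objective
tracedZPathCost <- function(c1, R, x, rows, d2, alpha2,
                            init = "featureVolume") {
  P <- dim(R)[3]
  initCol <- if (init == "featureVolume") R[, x, 1] else c1[, x, 1]
  cst <- initCol[rows[1]]
  if (P >= 2) {
    for (z in 2:P)
      cst <- cst + c1[rows[z], x, z] + alpha2 * abs(rows[z] - rows[z - 1])
  }
  cst
}
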