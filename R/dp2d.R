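# Candidate jumps ordered by preference: smallest |j| first, and the
# negative jump before the positive one when |j| ties.  Combined with a
# strict-improvement update this makes every arg-min deterministic.
jumpOrder <- function(d) {
  js <- seq.int(-d, d)
  js[order(abs(js), js)]
}

# One column update of the jump-constrained minimum:
#   best[y] = min_{j in [-d,d], 1 <= y+j <= M} prev[y + j] + alpha * |j|
# The neighbourhood is clipped at the first and last row (no padding,
# no wraparound).  Returns the minima and the arg-min source rows.
minOverJumps <- function(prev, d, alpha) {
  M <- length(prev)
  best <- rep.int(Inf, M)
  arg <- integer(M)
  for (j in jumpOrder(d)) {
    src <- seq_len(M) + j
    ok <- src >= 1L & src <= M
    cand <- rep.int(Inf, M)
    cand[ok] <- prev[src[ok]] + alpha * abs(j)
    upd <- cand < best
    best[upd] <- cand[upd]
    arg[upd] <- src[upd]
  }
  list(min = best, arg = arg)
}

#' 2D dynamic-programming cost accumulation
#'
#' Builds the cost map \eqn{C} and predecessor pointers for the
#' left-to-right minimal-cost path through a feature matrix:
#' \deqn{C(x, y) = \min_{|j| \le d} C(x-1, y+j) + \alpha |j| + F(x, y)}
#' with the boundary condition \eqn{C(1, y) = F(1, y)}.  Rows are
#' candidate boundary positions, columns the search direction;
#' \eqn{\alpha} weights path smoothness and \eqn{d} caps the row jump
#' between adjacent columns.
#'
#' @param F numeric matrix (M rows x N columns) of finite feature
#'   values; low values attract the path.
#' @param d non-negative integer, maximum row jump between adjacent
#'   columns; must be smaller than \code{nrow(F)}.
#' @param alpha non-negative smoothness weight.
#' @return list with components \code{cost} (M x N matrix), \code{pointer}
#'   (M x N integer matrix of predecessor rows; column 1 points to
#'   itself), and the parameters \code{d}, \code{alpha}.
#' @seealso [dp2dTraceback()], [dp2dPath()], [oracleMinPath()]
#' @examples
#' F <- rbind(c(0.5, 0.3), c(0.1, 0.4))
#' dp2dAccumulate(F, d = 1, alpha = 0)$cost
#' @export
dp2dAccumulate <- function(F, d, alpha) {
  F <- as.matrix(F)
  if (!is.numeric(F) || !all(is.finite(F)))
    stop("feature matrix must be numeric and finite")
  M <- nrow(F)
  N <- ncol(F)
  d <- checkJump(d, M, "d")
  alpha <- checkWeight(alpha, "alpha")
  cost <- matrix(0, M, N)
  pointer <- matrix(0L, M, N)
  cost[, 1L] <- F[, 1L]
  pointer[, 1L] <- seq_len(M)
  if (N > 1L) {
    for (x in 2:N) {
      mj <- minOverJumps(cost[, x - 1L], d, alpha)
      cost[, x] <- mj$min + F[, x]
      pointer[, x] <- mj$arg
    }
  }
  list(cost = cost, pointer = pointer, d = d, alpha = alpha)
}

#' Trace the optimal 2D path backwards
#'
#' Starts at the global minimum of the last cost column (smallest row
#' index on ties) and follows the predecessor pointers back to the first
#' column.
#'
#' @param state result of [dp2dAccumulate()].
#' @return list with \code{path} (integer vector of row indices, one per
#'   column) and \code{cost} (the attained minimum).
#' @export
dp2dTraceback <- function(state) {
  cost <- state$cost
  pointer <- state$pointer
  N <- ncol(cost)
  path <- integer(N)
  path[N] <- which.min(cost[, N])
  if (N > 1L) {
    for (x in N:2) path[x - 1L] <- pointer[path[x], x]
  }
  list(path = path, cost = cost[path[N], N])
}

#' Minimal-cost 2D boundary path
#'
#' Convenience wrapper running [dp2dAccumulate()] followed by
#' [dp2dTraceback()].
#'
#' @inheritParams dp2dAccumulate
#' @return as [dp2dTraceback()].
#' @export
dp2dPath <- function(F, d, alpha) {
  dp2dTraceback(dp2dAccumulate(F, d, alpha))
}

#' Exhaustive-enumeration path oracle
#'
#' Computes the exact minimum of the jump-constrained path objective by
#' enumerating every start row and every sequence of column-to-column
#' jumps.  Exponential in the number of columns; intended as an
#' independent reference for testing the dynamic programme on small
#' instances.
#'
#' @inheritParams dp2dAccumulate
#' @param maxCandidates explosion guard: error if
#'   \code{M * (2d+1)^(N-1)} exceeds this.
#' @return list with \code{cost} (the exact minimum) and \code{path}
#'   (one attaining row sequence).
#' @export
oracleMinPath <- function(F, d, alpha, maxCandidates = 1e7) {
  F <- as.matrix(F)
  M <- nrow(F)
  N <- ncol(F)
  d <- checkJump(d, M, "d")
  alpha <- checkWeight(alpha, "alpha")
  nCand <- M * (2 * d + 1)^(N - 1)
  if (nCand > maxCandidates)
    stop("enumeration would examine ", nCand, " candidates; refusing")
  if (N == 1L) {
    y <- which.min(F[, 1L])
    return(list(cost = F[y, 1L], path = y))
  }
  jumps <- as.matrix(expand.grid(rep(list(seq.int(-d, d)), N - 1L)))
  bestCost <- Inf
  bestPath <- NULL
  for (y1 in seq_len(M)) {
    for (k in seq_len(nrow(jumps))) {
      rows <- cumsum(c(y1, jumps[k, ]))
      if (any(rows < 1L | rows > M)) next
      cst <- sum(F[cbind(rows, seq_len(N))]) + alpha * sum(abs(jumps[k, ]))
      if (cst < bestCost) {
        bestCost <- cst
        bestPath <- rows
      }
    }
  }
  list(cost = bestCost, path = as.integer(bestPath))
}

checkJump <- function(d, M, name) {
  if (length(d) != 1L || !is.finite(d) || d < 0 || d != round(d))
    stop(name, " must be a single non-negative integer")
  if (d >= M)
    stop(name, " (", d, ") must be smaller than the number of rows (", M, ")")
  as.integer(d)
}

checkWeight <- function(a, name) {
  if (length(a) != 1L || !is.finite(a) || a < 0)
    stop(name, " must be a single non-negative number")
  as.numeric(a)
}
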