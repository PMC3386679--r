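test_that("accumulation reproduces hand-worked costs and paths", {
  # zero feature: every constrained path costs zero, tie-break row 1
  st <- dp2dAccumulate(matrix(0, 3, 3), d = 1, alpha = 0)
  expect_equal(st$cost, matrix(0, 3, 3))
  tb <- dp2dTraceback(st)
  expect_equal(tb$cost, 0)
  expect_equal(tb$path, c(1L, 1L, 1L))

  # two-column example, enumerable by hand: 4 constrained paths
  F <- cbind(c(0.5, 0.1), c(0.3, 0.4))
  st <- dp2dAccumulate(F, d = 1, alpha = 0)
  expect_equal(st$cost[, 1], c(0.5, 0.1))
  expect_equal(st$cost[, 2], c(0.4, 0.5))
  tb <- dp2dTraceback(st)
  expect_equal(tb$path, c(2L, 1L))
  expect_equal(tb$cost, 0.4)
  expect_equal(oracleMinPath(F, d = 1, alpha = 0)$cost, 0.4)
})

test_that("a uniquely zero row captures the whole path", {
  F <- matrix(1, 5, 6)
  F[3, ] <- 0
  tb <- dp2dPath(F, d = 1, alpha = 0)
  expect_equal(tb$path, rep(3L, 6))
  expect_equal(tb$cost, 0)
})

test_that("dp equals the exhaustive-path oracle on random instances", {
  cases <- expand.grid(seed = 1:25, d = 1:2, alpha = c(0, 0.125, 0.25))
  for (k in seq_len(nrow(cases))) {
    F <- randomDyadicMatrix(5, 5, seed = 1000 + cases$seed[k] +
                              100 * cases$d[k])
    tb <- dp2dPath(F, d = cases$d[k], alpha = cases$alpha[k])
    or <- oracleMinPath(F, d = cases$d[k], alpha = cases$alpha[k])
    expect_identical(tb$cost, or$cost)
    # the traced path must satisfy the jump constraint and attain the cost
    expect_true(all(abs(diff(tb$path)) <= cases$d[k]))
    expect_identical(sum(F[cbind(tb$path, 1:5)]) +
                       cases$alpha[k] * sum(abs(diff(tb$path))), tb$cost)
  }
})

test_that("non-square instances agree with the oracle", {
  F <- randomDyadicMatrix(4, 5, seed = 42)
  tb <- dp2dPath(F, d = 1, alpha = 0.1)
  expect_equal(tb$cost, oracleMinPath(F, d = 1, alpha = 0.1)$cost)
})

test_that("minimal cost is non-decreasing in the smoothness weight", {
  for (seed in 1:10) {
    F <- randomDyadicMatrix(5, 5, seed = 2000 + seed)
    costs <- vapply(c(0, 0.05, 0.1, 0.2, 0.5),
                    function(a) dp2dPath(F, d = 1, alpha = a)$cost, 0)
    expect_true(all(diff(costs) >= 0))
  }
})

test_that("adding a constant shifts every cost by N*c, not the arg-min", {
  F <- randomDyadicMatrix(5, 4, seed = 7)
  tb0 <- dp2dPath(F, d = 1, alpha = 0.125)
  tb1 <- dp2dPath(F + 0.5, d = 1, alpha = 0.125)
  expect_equal(tb1$cost, tb0$cost + 4 * 0.5)
  expect_identical(tb1$path, tb0$path)
})

test_that("degenerate and invalid inputs are rejected cleanly", {
  expect_error(dp2dAccumulate(matrix(0, 3, 3), d = 3, alpha = 0),
               "smaller than the number of rows")
  expect_error(dp2dAccumulate(matrix(c(0, NA, 0, 0), 2, 2), d = 1,
                              alpha = 0), "finite")
  expect_error(dp2dAccumulate(matrix(0, 3, 3), d = 1, alpha = -1),
               "non-negative")
  # single-column problem degenerates to the column minimum
  F1 <- matrix(c(0.5, 0.25, 0.75), 3, 1)
  expect_equal(oracleMinPath(F1, d = 1, alpha = 0)$cost, 0.25)
  expect_equal(dp2dPath(F1, d = 1, alpha = 0)$cost, 0.25)
  # enumeration guard
  expect_error(oracleMinPath(matrix(0, 4, 20), d = 2, alpha = 0),
               "refusing")
})

test_that("ties break to the smallest jump, negative before positive", {
  # two equal minima in the previous column: pointer must prefer j = 0,
  # then j = -1 over j = +1
  F <- cbind(c(0.5, 0.5, 0.5), c(0, 0, 0))
  st <- dp2dAccumulate(F, d = 1, alpha = 0)
  expect_equal(st$pointer[, 2], c(1L, 2L, 3L))        # j = 0 wins
  F2 <- cbind(c(0.25, 0.5, 0.25), c(0, 0, 0))
  st2 <- dp2dAccumulate(F2, d = 1, alpha = 0)
  expect_equal(st2$pointer[2, 2], 1L)                 # -1 before +1
})
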