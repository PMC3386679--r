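test_that("zero volumes accumulate to zero under both initialisations", {
  R <- array(0, c(3, 4, 3))
  p1 <- dp3dPass1(R, d1 = 1, alpha1 = 0)
  expect_equal(p1$c1, array(0, c(3, 4, 3)))
  for (init in c("featureVolume", "pass1")) {
    p2 <- dp3dPass2(p1$c1, R, d2 = 1, alpha2 = 0, c2Init = init)
    expect_equal(p2$c2, array(0, c(3, 3, 4)))
    surf <- dp3dTraceback(p2$c2, p2$y2)
    expect_equal(totalCost(surf), 0)
    expect_true(all(surfaceHeights(surf) == 1L))   # smallest-row tie-break
  }
})

test_that("first pass equals the 2D accumulation slice by slice", {
  R <- randomDyadicVolume(4, 4, 3, seed = 11)
  p1 <- dp3dPass1(R, d1 = 1, alpha1 = 0.125)
  for (z in 1:3) {
    st <- dp2dAccumulate(R[, , z], d = 1, alpha = 0.125)
    expect_identical(p1$c1[, , z], st$cost)
    expect_identical(p1$y1[, , z], st$pointer)
  }
})

test_that("a single-frame volume reduces to the 2D programme", {
  R <- randomDyadicVolume(5, 6, 1, seed = 3)
  p1 <- dp3dPass1(R, d1 = 1, alpha1 = 0.1)
  st <- dp2dAccumulate(R[, , 1], d = 1, alpha = 0.1)
  expect_identical(matrix(p1$c1[, , 1], 5, 6), st$cost)
  surf <- dp3dDetect(R, d1 = 1, d2 = 1, alpha1 = 0.1, traceC1 = TRUE)
  tb <- dp2dTraceback(st)
  expect_identical(as.integer(surfaceHeights(surf)[, 1]), tb$path)
  expect_equal(totalCost(surf), tb$cost)
})

test_that("second pass matches an independently written recursion", {
  for (init in c("featureVolume", "pass1")) {
    R <- randomDyadicVolume(4, 4, 3, seed = 17)
    p1 <- dp3dPass1(R, d1 = 1, alpha1 = 0.0625)
    p2 <- dp3dPass2(p1$c1, R, d2 = 2, alpha2 = 0.0625, c2Init = init)
    expect_equal(p2$c2, referencePass2(p1$c1, R, 2, 0.0625, init))
  }
})

test_that("two frames with an unconstrained jump give the closed form", {
  # P = 2, alpha2 = 0, d2 = M - 1: second depth column is the slice cost
  # plus the global minimum of the initial column
  R <- randomDyadicVolume(4, 3, 2, seed = 23)
  p1 <- dp3dPass1(R, d1 = 1, alpha1 = 0)
  p2 <- dp3dPass2(p1$c1, R, d2 = 3, alpha2 = 0)
  for (x in 1:3) {
    expect_equal(p2$c2[, 2, x], p1$c1[, x, 2] + min(R[, x, 1]))
  }
})

test_that("shape mismatch between passes is rejected", {
  R <- array(0, c(3, 3, 2))
  expect_error(dp3dPass2(array(0, c(3, 3, 3)), R, d2 = 1, alpha2 = 0),
               "identical dimensions")
})

test_that("a zero-valued plane is detected exactly", {
  R <- array(1, c(6, 9, 4))
  R[4, , ] <- 0
  surf <- dp3dDetect(R, d1 = 1, d2 = 1, alpha1 = 0.05)
  expect_true(all(surfaceHeights(surf) == 4L))
})

test_that("traced surfaces attain the per-angle exhaustive optimum", {
  cases <- list(list(dim = c(3, 3, 2), d2 = 1, a = 0.05),
                list(dim = c(4, 4, 4), d2 = 1, a = 0.125),
                list(dim = c(4, 4, 4), d2 = 2, a = 0.0625))
  for (ci in seq_along(cases)) {
    cs <- cases[[ci]]
    for (seed in 1:5) {
      R <- randomDyadicVolume(cs$dim[1], cs$dim[2], cs$dim[3],
                              seed = 400 + 20 * ci + seed)
      p1 <- dp3dPass1(R, d1 = 1, alpha1 = cs$a)
      p2 <- dp3dPass2(p1$c1, R, d2 = cs$d2, alpha2 = cs$a)
      surf <- dp3dTraceback(p2$c2, p2$y2)
      h <- surfaceHeights(surf)
      for (x in seq_len(cs$dim[2])) {
        traced <- tracedZPathCost(p1$c1, R, x, h[x, ], cs$d2, cs$a)
        brute <- bruteForceBestZPath(p1$c1, R, x, cs$d2, cs$a)
        expect_identical(traced, brute)
        expect_identical(traced, min(p2$c2[, cs$dim[3], x]))
      }
    }
  }
})

test_that("traced surfaces always satisfy the frame-direction constraint", {
  for (seed in 1:10) {
    R <- randomDyadicVolume(6, 5, 4, seed = 900 + seed)
    for (d2 in 1:2) {
      h <- surfaceHeights(dp3dDetect(R, d1 = 1, d2 = d2, alpha1 = 0.05))
      expect_true(all(abs(h[, -1] - h[, -4]) <= d2))
    }
  }
})

test_that("a ruined slice is bridged when its neighbours agree", {
  # row 3 is a zero-cost valley in every frame except the middle one,
  # which carries no evidence at all (all ones); with a small d2 the
  # surface must stay within d2 of the valley across the ruined frame
  R <- array(1, c(6, 8, 5))
  R[3, , c(1, 2, 4, 5)] <- 0
  h <- surfaceHeights(dp3dDetect(R, d1 = 1, d2 = 1, alpha1 = 0.05))
  expect_true(all(h[, c(1, 2, 4, 5)] == 3L))
  expect_true(all(abs(h[, 3] - 3L) <= 1L))
})

test_that("tracing on the first pass reproduces per-slice 2D detection", {
  R <- randomDyadicVolume(5, 7, 3, seed = 77)
  surf <- dp3dDetect(R, d1 = 1, d2 = 2, alpha1 = 0.1, traceC1 = TRUE)
  for (z in 1:3) {
    tb <- dp2dPath(R[, , z], d = 1, alpha = 0.1)
    expect_identical(as.integer(surfaceHeights(surf)[, z]), tb$path)
  }
})
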