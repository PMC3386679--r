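test_that("radial gradient is zero on constant images and ~a on cones", {
  img <- matrix(0.7, 21, 21)
  expect_equal(radialGradient(img, c(11, 11)), matrix(0, 21, 21))

  # intensity linear in radius: outward derivative is the slope a
  a <- 0.03
  ctr <- c(11, 11)
  r <- sqrt(outer((1:21 - 11)^2, (1:21 - 11)^2, "+"))
  cone <- a * r
  g <- radialGradient(cone, ctr)
  interior <- r > 2 & r < 7         # away from the apex and borders
  expect_true(all(abs(g[interior] - a) < 0.01))

  expect_error(radialGradient(img, c(30, 11)), "outside")
})

test_that("the disc boundary is the gradient minimum on every ray", {
  ph <- generatePhantom(phantomSpec(radii = rep(10, 1)))
  g <- radialGradient(frames(ph)[, , 1], c(21, 21))
  angles <- 2 * pi * (0:35) / 36
  radii <- seq(2, 18, by = 0.5)
  xs <- 21 + outer(radii, cos(angles))
  ys <- 21 + outer(radii, sin(angles))
  prof <- bilinearSample(g, xs, ys)
  argminR <- radii[apply(prof, 2, which.min)]
  expect_true(all(abs(argminR - 10) <= 1))
})

test_that("bilinear sampling interpolates exactly on a bilinear surface", {
  img <- outer(1:6, 1:5, function(i, j) 2 * i + 3 * j - 1)
  expect_equal(bilinearSample(img, x = 3, y = 4), img[4, 3])
  expect_equal(bilinearSample(img, x = 2.5, y = 3.25),
               2 * 3.25 + 3 * 2.5 - 1)
  # clamping outside the support
  expect_equal(bilinearSample(img, x = 99, y = -5), img[1, 5])
})

test_that("bicubic resize reproduces affine images and the centre map", {
  ramp <- outer(1:10, rep(1, 12))
  out <- resizeBicubic(ramp, 2)
  expect_equal(dim(out), c(20L, 24L))
  # cubic convolution is exact on linear data away from the clamped
  # borders; pixel-centre convention maps output row k to input
  # position (k - 0.5)/2 + 0.5
  pred <- (1:20 - 0.5) / 2 + 0.5
  expect_equal(out[4:17, 5], pred[4:17], tolerance = 1e-12)
  expect_equal(out[c(1:3, 18:20), 5], pmin(pmax(pred, 1), 10)[c(1:3, 18:20)],
               tolerance = 0.15)
  expect_equal(resizeBicubic(matrix(0.3, 8, 8), 1.6),
               matrix(0.3, 13, 13))
})

test_that("gaussian smoothing preserves constants and total mass", {
  img <- matrix(0.42, 15, 15)
  expect_equal(gaussianSmooth(img, 0.5), img)
  set.seed(1)
  noise <- matrix(runif(225), 15, 15)
  sm <- gaussianSmooth(noise, 1)
  # reflective boundaries conserve the mean exactly for symmetric kernels
  expect_equal(mean(sm), mean(noise), tolerance = 1e-12)
  expect_lt(stats::sd(sm), stats::sd(noise))
})

test_that("shoelace area matches the regular-polygon closed form", {
  for (N in c(8, 72)) {
    th <- 2 * pi * (0:(N - 1)) / N
    R <- 10
    expect_equal(shoelaceArea(R * cos(th), R * sin(th)),
                 0.5 * N * R^2 * sin(2 * pi / N))
  }
  # 72 vertices approximate the disc area to well under 0.5%
  th <- 2 * pi * (0:71) / 72
  expect_lt(abs(shoelaceArea(10 * cos(th), 10 * sin(th)) - 100 * pi) /
              (100 * pi), 0.005)
})

test_that("feature frames are min-max normalised unless degenerate", {
  ph <- generatePhantom()
  fv <- buildFeatureVolume(ph, polarGrid(c(21, 21), resizeFactor = 1.6))
  v <- featureValues(fv)
  for (z in seq_len(dim(v)[3])) {
    expect_equal(min(v[, , z]), 0)
    expect_equal(max(v[, , z]), 1)
  }
  flat <- lapply(1:3, function(i) matrix(0.5, 41, 41))
  w <- capture_warnings(fvFlat <- buildFeatureVolume(flat,
                                                     polarGrid(c(21, 21))))
  expect_length(w, 3L)
  expect_match(w, "no gradient contrast", all = TRUE)
  expect_true(all(featureValues(fvFlat) == 0.5))
})

test_that("phantom feature minima map back to the disc radius", {
  ph <- generatePhantom(phantomSpec(radii = rep(10, 2)))
  for (f in c(1, 2)) {
    fv <- buildFeatureVolume(ph, polarGrid(c(21, 21), resizeFactor = f))
    v <- featureValues(fv)
    s <- mean(fv@scale)
    am <- apply(v[, , 1], 2, which.min)
    rBack <- fv@radiiRes[am] / s
    expect_true(all(abs(rBack - 10) <= 1))
  }
})

test_that("surface-to-contour inverts the polar geometry", {
  ph <- generatePhantom(phantomSpec(radii = rep(10, 1)))
  fv <- buildFeatureVolume(ph, polarGrid(c(21, 21), nAngles = 72L))
  # constant surface at the row closest to radius 10
  row <- which.min(abs(fv@radiiRes / mean(fv@scale) - 10))
  surf <- new("DPSurface",
              heights = matrix(row, 72, 1), totalCost = 0)
  cs <- surfaceToContours(surf, fv, pixelSize = 0.625)
  R <- fv@radiiRes[row] / mean(fv@scale)
  expect_equal(cs@areaPx2[1], 0.5 * 72 * R^2 * sin(2 * pi / 72))
  expect_equal(cs@areaMm2[1], cs@areaPx2[1] * 0.625^2)
  expect_lt(abs(cs@areaPx2[1] - pi * R^2) / (pi * R^2), 0.005)
})

test_that("detected geometry is stable under resize (noise free)", {
  ph <- generatePhantom()
  radiiOf <- function(det) {
    vapply(seq_len(8), function(z) {
      p <- contourPoints(det$contours)[[z]]
      mean(sqrt((p[, 1] - 21)^2 + (p[, 2] - 21)^2))
    }, 0)
  }
  r1 <- radiiOf(detectSequence(ph, s = 0.01, resizeFactor = 1))
  r16 <- radiiOf(detectSequence(ph, s = 0.01, resizeFactor = 1.6))
  expect_lt(mean(abs(r1 - r16)), 0.5)
})

test_that("grid validation catches out-of-range search radii", {
  ph <- generatePhantom()
  expect_error(buildFeatureVolume(ph, polarGrid(c(21, 21), rMax = 25)),
               "border")
  expect_error(polarGrid(c(21, 21), nAngles = 4), "at least 8")
})
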