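#' Derive a reproducible sub-seed from a master seed
#'
#' Folds a master seed and a sequence of indices (e.g., noise-level
#' index, repetition number) into a single 32-bit seed with a
#' multiplicative congruential scheme, so that any cell of a larger
#' experiment can be re-run independently of the others.
#'
#' @param seed integer master seed.
#' @param ... integer indices identifying the cell.
#' @return an integer below 2^31.
#' @export
deriveSeed <- function(seed, ...) {
  v <- as.double(seed) %% 2147483647
  for (k in c(...)) v <- (v * 69069 + as.double(k)) %% 2147483647
  as.integer(v)
}

#' Detect closed contours through an image sequence
#'
#' End-to-end detection: build the polar feature volume
#' ([buildFeatureVolume()]), extract the minimal-cost surface
#' ([dp3dDetect()]) and map it back to Cartesian closed contours with
#' areas ([surfaceToContours()]).  Deterministic given inputs and
#' configuration.
#'
#' @param images image sequence (3D array, list of matrices, or
#'   [PhantomSequence-class]).
#' @param center contour centre \code{c(x, y)}; defaults to the image
#'   centre.
#' @param pixelSize mm per pixel (for physical areas).
#' @param d1,d2 jump bounds along the angle and frame axes.
#' @param s smoothness weight, applied to both axes
#'   (\eqn{\alpha_1 = \alpha_2 = s}).
#' @param resizeFactor bilinear upsampling factor (radial refinement).
#' @param nAngles,rMin,rMax polar grid parameters, see [polarGrid()].
#' @param invert detect a dark object on a bright background.
#' @param c2Init initialisation of the through-plane pass, see
#'   [dp3dPass2()].
#' @param traceC1 trace each frame independently (traditional 2D DP).
#' @return list with components \code{surface} ([DPSurface-class]),
#'   \code{contours} ([ContourSet-class]), \code{areas} (data.frame
#'   \code{frame, areaPx2, areaMm2}) and \code{featureVolume}.
#' @examples
#' ph <- generatePhantom()
#' det <- detectSequence(ph, s = 0.01, resizeFactor = 1.6)
#' det$areas
#' @export
detectSequence <- function(images, center = NULL, pixelSize = 1,
                           d1 = 1L, d2 = 2L, s = 0.1, resizeFactor = 1.6,
                           nAngles = 72L, rMin = 2, rMax = NULL,
                           invert = FALSE,
                           c2Init = c("featureVolume", "pass1"),
                           traceC1 = FALSE) {
  fr <- asFrameList(images)
  H <- nrow(fr[[1L]])
  W <- ncol(fr[[1L]])
  if (is.null(center)) center <- c((W + 1) / 2, (H + 1) / 2)
  grid <- polarGrid(center = center, nAngles = nAngles, rMin = rMin,
                    rMax = rMax, resizeFactor = resizeFactor)
  fv <- buildFeatureVolume(fr, grid, invert = invert)
  surf <- dp3dDetect(featureValues(fv), d1 = d1, d2 = d2,
                     alpha1 = s, alpha2 = s,
                     c2Init = match.arg(c2Init), traceC1 = traceC1)
  cs <- surfaceToContours(surf, fv, pixelSize = pixelSize)
  list(surface = surf, contours = cs, areas = areaTable(cs),
       featureVolume = fv)
}

#' Relative unsigned area error
#'
#' \deqn{\varepsilon = |A_{manual} - A_{auto}| / A_{manual} \times 100}
#' in percent, vectorised over frame pairs.
#'
#' @param autoArea,manualArea numeric vectors of equal length; the
#'   manual (reference) areas must be positive.
#' @return percentage errors.
#' @examples
#' relativeUnsignedError(97.6, 100)   # 2.4
#' @export
relativeUnsignedError <- function(autoArea, manualArea) {
  if (length(autoArea) != length(manualArea))
    stop("area vectors must have equal length")
  if (any(manualArea <= 0))
    stop("reference areas must be positive")
  abs(manualArea - autoArea) / manualArea * 100
}

#' Bland-Altman agreement statistics
#'
#' Differences \code{auto - manual}, their mean and standard deviation
#' (n-1 denominator), and the limits of agreement
#' \code{mean +/- 1.96 * SD}, plus the pairwise means needed for the
#' usual plot.
#'
#' @param autoArea,manualArea paired measurements, equal length >= 2.
#' @return list with \code{meanDiff}, \code{sdDiff}, \code{loaLow},
#'   \code{loaHigh}, \code{n} and a data.frame \code{data} with columns
#'   \code{mean} and \code{diff}.
#' @export
blandAltman <- function(autoArea, manualArea) {
  if (length(autoArea) != length(manualArea))
    stop("paired vectors must have equal length")
  if (length(autoArea) < 2L)
    stop("at least two pairs required")
  diffs <- autoArea - manualArea
  m <- mean(diffs)
  s <- stats::sd(diffs)
  list(meanDiff = m, sdDiff = s,
       loaLow = m - 1.96 * s, loaHigh = m + 1.96 * s,
       n = length(diffs),
       data = data.frame(mean = (autoArea + manualArea) / 2, diff = diffs))
}

# per-frame area errors of one detection run against the phantom truth
phantomRunErrors <- function(noisySeq, s, resizeFactor, d1 = 1L, d2 = 2L,
                             nAngles = 72L, rMin = 2, rMax = NULL,
                             c2Init = "featureVolume", traceC1 = FALSE) {
  det <- detectSequence(noisySeq, d1 = d1, d2 = d2, s = s,
                        resizeFactor = resizeFactor, nAngles = nAngles,
                        rMin = rMin, rMax = rMax, c2Init = c2Init,
                        traceC1 = traceC1)
  relativeUnsignedError(det$areas$areaPx2, trueAreasPx2(noisySeq))
}

#' Accuracy sweep over smoothness weight and resize factor
#'
#' For each combination of noise level, smoothness weight \code{s} and
#' resize factor, generates seeded noisy phantom sequences, runs the
#' full detection and averages the relative unsigned area errors
#' against the analytic disc areas over all frames and repetitions.
#' Noise amplitudes are calibrated once per SNR with
#' [calibrateNLevel()]; repetition seeds come from [deriveSeed()], so
#' any cell can be reproduced in isolation.
#'
#' @param spec a [phantomSpec()].
#' @param snrDb numeric vector of target SNRs in dB.
#' @param sGrid numeric vector of smoothness weights.
#' @param resizeFactors numeric vector of resize factors.
#' @param reps repetitions (independent noise draws) per cell.
#' @param seed master seed.
#' @param d1,d2,nAngles,rMin,rMax detection parameters, see
#'   [detectSequence()].
#' @return data.frame with one row per (snrDb, s, resizeFactor):
#'   \code{meanErrorPct}, \code{sdErrorPct} over frames x repetitions,
#'   and \code{n} (number of frame errors averaged).
#' @export
parameterSweep <- function(spec = phantomSpec(), snrDb = c(14, 20),
                           sGrid = seq(0.01, 0.21, by = 0.01),
                           resizeFactors = c(1, 1.6), reps = 10L,
                           seed = 1L, d1 = 1L, d2 = 2L, nAngles = 72L,
                           rMin = 2, rMax = NULL) {
  if (!length(snrDb) || !length(sGrid) || !length(resizeFactors))
    stop("snrDb, sGrid and resizeFactors must be non-empty")
  clean <- generatePhantom(spec)
  res <- expand.grid(snrDb = snrDb, s = sGrid, resizeFactor = resizeFactors,
                     KEEP.OUT.ATTRS = FALSE)
  acc <- vector("list", nrow(res))
  for (si in seq_along(snrDb)) {
    nLevel <- calibrateNLevel(spec, snrDb[si], seed = seed)
    for (rep in seq_len(reps)) {
      noisy <- addNoise(clean, nLevel, seed = deriveSeed(seed, si, rep))
      for (fi in seq_along(resizeFactors)) {
        for (ki in seq_along(sGrid)) {
          row <- which(res$snrDb == snrDb[si] & res$s == sGrid[ki] &
                       res$resizeFactor == resizeFactors[fi])
          err <- phantomRunErrors(noisy, s = sGrid[ki],
                                  resizeFactor = resizeFactors[fi],
                                  d1 = d1, d2 = d2, nAngles = nAngles,
                                  rMin = rMin, rMax = rMax)
          acc[[row]] <- c(acc[[row]], err)
        }
      }
    }
  }
  res$meanErrorPct <- vapply(acc, mean, 0)
  res$sdErrorPct <- vapply(acc, stats::sd, 0)
  res$n <- vapply(acc, length, 0L)
  res
}

#' Ruined-frame robustness experiment
#'
#' Replaces one frame of a noisy phantom sequence by pure noise and
#' compares how far the detected contour on that frame drifts from the
#' mean of its two neighbours, for the surface search (which bridges
#' the gap through the frame-direction constraint) versus independent
#' per-frame 2D detection (which has no information linking frames).
#' The deviation is the mean over angles of
#' \code{|row(ruined) - (row(prev) + row(next)) / 2|} in radial
#' samples.
#'
#' @param spec a [phantomSpec()].
#' @param snrDb target SNR of the intact frames.
#' @param ruinIndex frame to ruin; default is the middle frame.
#' @param nSeeds number of independent repetitions.
#' @param seed master seed.
#' @param s,resizeFactor,d1,d2 detection parameters; \code{d2} is the
#'   frame-direction bound that does the bridging.
#' @return data.frame with one row per repetition: \code{dev3d} (surface
#'   search) and \code{dev2d} (per-frame baseline), in radial samples.
#' @export
ruinedSliceExperiment <- function(spec = phantomSpec(), snrDb = 14,
                                  ruinIndex = NULL, nSeeds = 10L,
                                  seed = 1L, s = 0.1, resizeFactor = 1.6,
                                  d1 = 1L, d2 = 1L) {
  clean <- generatePhantom(spec)
  P <- dim(frames(clean))[3L]
  if (P < 3L) stop("need at least 3 frames")
  if (is.null(ruinIndex)) ruinIndex <- (P + 1L) %/% 2L
  if (ruinIndex < 2L || ruinIndex > P - 1L)
    stop("ruinIndex must have two neighbours")
  nLevel <- calibrateNLevel(spec, snrDb, seed = seed)
  dev <- function(h) {
    mean(abs(h[, ruinIndex] -
             (h[, ruinIndex - 1L] + h[, ruinIndex + 1L]) / 2))
  }
  out <- data.frame(rep = seq_len(nSeeds), dev3d = NA_real_,
                    dev2d = NA_real_)
  for (k in seq_len(nSeeds)) {
    noisy <- addNoise(clean, nLevel, seed = deriveSeed(seed, 11L, k))
    noisy <- ruinFrame(noisy, ruinIndex, seed = deriveSeed(seed, 13L, k))
    det3 <- detectSequence(noisy, d1 = d1, d2 = d2, s = s,
                           resizeFactor = resizeFactor)
    det2 <- detectSequence(noisy, d1 = d1, d2 = d2, s = s,
                           resizeFactor = resizeFactor, traceC1 = TRUE)
    out$dev3d[k] <- dev(surfaceHeights(det3$surface))
    out$dev2d[k] <- dev(surfaceHeights(det2$surface))
  }
  out
}
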