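#' Phantom generation parameters
#'
#' Bundles the parameters of the synthetic disc phantom: a bright disc
#' (the simulated artery lumen) on a darker background, Gaussian
#' pre-smoothing, and the per-frame radius schedule.  The defaults give
#' an eight-frame 41x41 sequence with radii stepping 9..12 and back down
#' to 8, foreground 1.0 and background 0.4, smoothed with sigma 0.5 --
#' a plausible stand-in for a vessel lumen pulsating over one cardiac
#' cycle.
#'
#' @param imageSize side length of the square frames, pixels.
#' @param fg,bg foreground (disc) and background intensities;
#'   \code{fg > bg > 0} required.
#' @param radii per-frame disc radii in pixels; every radius must be at
#'   least 1 and smaller than \code{imageSize/2 - 1}.
#' @param smoothSigma Gaussian smoothing sigma in pixels, applied before
#'   any noise.
#' @return a validated list of class \code{"PhantomSpec"}.
#' @export
phantomSpec <- function(imageSize = 41L, fg = 1, bg = 0.4,
                        radii = c(9, 10, 11, 12, 11, 10, 9, 8),
                        smoothSigma = 0.5) {
  if (imageSize < 8) stop("imageSize must be at least 8")
  if (!(fg > bg && bg > 0)) stop("need fg > bg > 0")
  if (!length(radii) || any(radii < 1))
    stop("radii must all be at least 1 pixel")
  if (max(radii) >= imageSize / 2 - 1)
    stop("largest radius (", max(radii), ") too big for a ", imageSize,
         "-pixel canvas")
  if (smoothSigma < 0) stop("smoothSigma must be non-negative")
  structure(list(imageSize = as.integer(imageSize), fg = fg, bg = bg,
                 radii = as.numeric(radii), smoothSigma = smoothSigma),
            class = "PhantomSpec")
}

#' Generate a noise-free phantom sequence
#'
#' Rasterises one disc per frame (a pixel belongs to the disc iff its
#' centre lies within the radius of the image centre) and applies
#' Gaussian smoothing.  The gold standard recorded alongside is the
#' analytic area \eqn{\pi r^2}: the ideal circle is the boundary being
#' sought, and smoothing does not move it.
#'
#' @param spec a [phantomSpec()].
#' @return a [PhantomSequence-class] with per-frame true radii and
#'   areas; the SNR slot is \code{NA} (no noise yet).
#' @seealso [addNoise()], [calibrateNLevel()]
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  if (!inherits(spec, "PhantomSpec")) stop("spec must come from phantomSpec()")
  n <- spec$imageSize
  ctr <- (n + 1) / 2          # exact image centre, 1-based
  dx <- matrix(seq_len(n), n, n, byrow = TRUE) - ctr
  dy <- matrix(seq_len(n), n, n) - ctr
  dist <- sqrt(dx^2 + dy^2)
  P <- length(spec$radii)
  fr <- array(0, c(n, n, P))
  for (z in seq_len(P)) {
    img <- matrix(spec$bg, n, n)
    img[dist <= spec$radii[z]] <- spec$fg
    fr[, , z] <- gaussianSmooth(img, spec$smoothSigma)
  }
  new("PhantomSequence", frames = fr, trueRadii = spec$radii,
      trueAreasPx2 = pi * spec$radii^2,
      measuredSnrDb = rep(NA_real_, P), nLevel = NA_real_,
      spec = unclass(spec))
}

#' Per-pixel logarithmic signal-to-noise ratio
#'
#' The SNR of a noisy image is measured as the image average of the
#' per-pixel ratio in decibels:
#' \deqn{\mathrm{SNR} = \frac{1}{HW} \sum_{x,y}
#'   20 \log_{10} \frac{g(x,y)}{|n(x,y)|}}
#' where \eqn{g} is the clean image and \eqn{n} the added noise.
#' Pixels with exactly zero noise are excluded with a warning (a
#' probability-zero event for continuous noise).
#'
#' @param clean positive numeric matrix, the noise-free image.
#' @param noise numeric matrix of the same shape, the added noise.
#' @return the SNR in dB.
#' @export
measureSNR <- function(clean, noise) {
  if (!identical(dim(clean), dim(noise)))
    stop("clean and noise must have the same shape")
  if (any(clean <= 0))
    stop("clean image must be strictly positive for the log ratio")
  nz <- noise != 0
  if (!all(nz))
    warning(sum(!nz), " zero-noise pixel(s) excluded from the SNR average")
  mean(20 * log10(clean[nz] / abs(noise[nz])))
}

#' Calibrate the uniform-noise amplitude to a target SNR
#'
#' Finds by bisection the amplitude \code{nLevel} of zero-mean uniform
#' noise on \code{[-nLevel, nLevel]} such that the expected per-pixel
#' log-SNR of the phantom, estimated over a fixed set of seeded noise
#' draws, hits the target.  Deterministic given \code{seed}.
#'
#' @param spec a [phantomSpec()].
#' @param targetSnrDb target SNR in dB.
#' @param nDraws number of Monte-Carlo noise draws in the estimate.
#' @param tol convergence tolerance in dB.
#' @param seed integer seed for the calibration draws.
#' @return the calibrated \code{nLevel} in (0, 1).
#' @export
calibrateNLevel <- function(spec = phantomSpec(), targetSnrDb,
                            nDraws = 50L, tol = 0.1, seed = 1L) {
  clean <- frames(generatePhantom(spec))
  npx <- length(clean)
  # with n = L * u, u ~ U(-1,1):  SNR(L) = base - 20*log10(L), where the
  # Monte-Carlo base averages 20*log10(g / |u|) over pixels and draws
  base <- 0
  for (k in seq_len(nDraws)) {
    set.seed(deriveSeed(seed, 7L, k))
    u <- stats::runif(npx, -1, 1)
    u[u == 0] <- 1e-12
    base <- base + mean(20 * log10(as.vector(clean) / abs(u)))
  }
  base <- base / nDraws
  lo <- 1e-6
  hi <- 1 - 1e-6
  snrAt <- function(L) base - 20 * log10(L)
  if (targetSnrDb > snrAt(lo) || targetSnrDb < snrAt(hi))
    stop(sprintf(
      "target %.1f dB unachievable; achievable range is %.1f..%.1f dB",
      targetSnrDb, snrAt(hi), snrAt(lo)))
  for (it in seq_len(200L)) {
    mid <- sqrt(lo * hi)    # bisect in log space; SNR is linear in log L
    err <- snrAt(mid) - targetSnrDb
    if (abs(err) <= tol) break
    if (err > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Add calibrated uniform noise to a phantom sequence
#'
#' Adds independent zero-mean uniform noise on \code{[-nLevel, nLevel]}
#' to every pixel of every frame (after the smoothing already baked into
#' the sequence) and records the per-frame measured SNR.  Values are not
#' clipped to [0, 1]: the SNR definition presumes the raw signal and
#' noise, and clipping would bias it.  Fully reproducible from the seed.
#'
#' @param pseq a [PhantomSequence-class] (normally noise free).
#' @param nLevel uniform noise amplitude in \code{[0, 1)}.
#' @param seed integer seed.
#' @return a new [PhantomSequence-class] with noisy frames and measured
#'   per-frame SNR.
#' @export
addNoise <- function(pseq, nLevel, seed = 1L) {
  if (!is(pseq, "PhantomSequence")) stop("pseq must be a PhantomSequence")
  if (nLevel < 0 || nLevel >= 1) stop("nLevel must lie in [0, 1)")
  fr <- frames(pseq)
  d <- dim(fr)
  P <- d[3L]
  if (nLevel == 0) {
    warning("nLevel is 0: frames unchanged; SNR reported as 1e6 dB")
    return(initialize(pseq, measuredSnrDb = rep(1e6, P), nLevel = 0))
  }
  set.seed(as.integer(seed))
  snr <- numeric(P)
  for (z in seq_len(P)) {
    n <- matrix(stats::runif(d[1L] * d[2L], -nLevel, nLevel), d[1L], d[2L])
    snr[z] <- measureSNR(zSlice(fr, z), n)
    fr[, , z] <- fr[, , z] + n
  }
  initialize(pseq, frames = fr, measuredSnrDb = snr, nLevel = nLevel)
}

#' Replace one frame by pure noise
#'
#' Destroys all boundary evidence in one frame by overwriting it with
#' i.i.d. uniform noise on [0, 1].  Used to demonstrate that the
#' through-plane continuity constraint bridges a ruined frame.
#'
#' @param pseq a [PhantomSequence-class].
#' @param index frame to ruin (1-based).
#' @param seed integer seed.
#' @return the sequence with the frame replaced.
#' @export
ruinFrame <- function(pseq, index, seed = 1L) {
  if (!is(pseq, "PhantomSequence")) stop("pseq must be a PhantomSequence")
  fr <- frames(pseq)
  d <- dim(fr)
  if (index < 1 || index > d[3L]) stop("frame index out of range")
  set.seed(as.integer(seed))
  fr[, , index] <- stats::runif(d[1L] * d[2L])
  initialize(pseq, frames = fr)
}
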