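#' Read a grayscale image sequence
#'
#' Accepts a multipage TIFF, a directory of PNG/TIFF frames (ordered by
#' file name), or an RDS file holding a 3D array.  Multi-channel frames
#' are converted to grayscale by channel averaging; intensities are
#' rescaled to [0, 1] per stack (min-max), with the applied rescale
#' recorded in the \code{"rescale"} attribute.
#'
#' @param path file or directory.
#' @param pixelSize mm per pixel; stored in the \code{"pixelSize"}
#'   attribute of the result.  TIFF and PNG carry no physical pixel
#'   size, so the default of 1 is used with a message unless the caller
#'   supplies one.
#' @return a 3D numeric array (H x W x P) with attributes
#'   \code{pixelSize} and \code{rescale = c(offset, scale)} such that
#'   \code{stored = (raw - offset) * scale}.
#' @export
readSequence <- function(path, pixelSize = NULL) {
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (is.null(pixelSize)) {
    message("no pixel size supplied; assuming 1 mm/pixel")
    pixelSize <- 1
  }
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no PNG/TIFF frames found in ", path)
    fr <- lapply(files, readFrame)
  } else if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    fr <- tiff::readTIFF(path, all = TRUE)
    fr <- lapply(fr, toGray)
  } else if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    a <- readRDS(path)
    if (!is.array(a) || length(dim(a)) != 3L)
      stop("RDS container must hold a 3D array")
    fr <- asFrameList(a)
  } else {
    stop("unsupported input: ", path,
         " (use a multipage TIFF, a PNG/TIFF directory, or an RDS array)")
  }
  if (!length(fr)) stop("empty image stack: ", path)
  dims <- vapply(fr, dim, integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L]))
    stop("frames have mixed shapes")
  a <- array(unlist(fr), c(dim(fr[[1L]]), length(fr)))
  rng <- range(a)
  if (rng[2L] > rng[1L]) {
    sc <- 1 / (rng[2L] - rng[1L])
    a <- (a - rng[1L]) * sc
    rescale <- c(offset = rng[1L], scale = sc)
  } else {
    rescale <- c(offset = 0, scale = 1)
  }
  message(sprintf("read %d frame(s) of %dx%d; rescale offset %.4g scale %.4g",
                  dim(a)[3L], dim(a)[1L], dim(a)[2L],
                  rescale[1L], rescale[2L]))
  attr(a, "pixelSize") <- pixelSize
  attr(a, "rescale") <- rescale
  a
}

readFrame <- function(file) {
  img <- tryCatch({
    if (grepl("\\.png$", file, ignore.case = TRUE)) png::readPNG(file)
    else tiff::readTIFF(file)
  }, error = function(e) stop("cannot read frame ", file, ": ",
                              conditionMessage(e)))
  toGray(img)
}

toGray <- function(img) {
  if (length(dim(img)) == 3L) {
    message("multi-channel frame converted to grayscale by channel average")
    img <- apply(img, c(1L, 2L), mean)
  }
  as.matrix(img)
}

#' Write an image sequence as a multipage TIFF
#'
#' Writes 32-bit float frames.  TIFF storage requires values in [0, 1];
#' a stack outside that range is min-max rescaled first (with a
#' message), which is immaterial to detection because feature frames are
#' re-normalised per frame anyway.
#'
#' @param images 3D array, list of matrices, or [PhantomSequence-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSequenceTIFF <- function(images, path) {
  fr <- asFrameList(images)
  rng <- range(unlist(fr))
  if (rng[1L] < 0 || rng[2L] > 1) {
    message(sprintf("rescaling stack from [%.3f, %.3f] to [0, 1] for TIFF",
                    rng[1L], rng[2L]))
    fr <- lapply(fr, function(m) (m - rng[1L]) / (rng[2L] - rng[1L]))
  }
  tiff::writeTIFF(fr, path, bits.per.sample = 32L)
  invisible(path)
}

#' Write a detected surface to CSV or JSON
#'
#' The CSV has one row per (angle, frame) node with columns \code{x}
#' (angle index), \code{z} (frame index) and \code{y} (radial row
#' index); JSON stores the height matrix plus the total cost.
#'
#' @param surface a [DPSurface-class].
#' @param path output file; format chosen by extension (.csv or .json).
#' @return the path, invisibly.
#' @export
writeSurface <- function(surface, path) {
  h <- surfaceHeights(surface)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(heights = h, totalCost = totalCost(surface)),
                         path, digits = NA)
  } else {
    df <- data.frame(x = as.vector(row(h)), z = as.vector(col(h)),
                     y = as.vector(h))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Write contours and areas to CSV
#'
#' \code{writeContoursCSV} emits one row per vertex (columns
#' \code{frame, vertex, x_px, y_px}); \code{writeAreasCSV} one row per
#' frame (columns \code{frame, area_px2, area_mm2}).
#'
#' @param contours a [ContourSet-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeContoursCSV <- function(contours, path) {
  pts <- contourPoints(contours)
  df <- do.call(rbind, lapply(seq_along(pts), function(z) {
    data.frame(frame = z, vertex = seq_len(nrow(pts[[z]])),
               x_px = pts[[z]][, 1L], y_px = pts[[z]][, 2L])
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeContoursCSV
#' @export
writeAreasCSV <- function(contours, path) {
  at <- areaTable(contours)
  names(at) <- c("frame", "area_px2", "area_mm2")
  utils::write.csv(at, path, row.names = FALSE)
  invisible(path)
}

#' Round-trip a phantom specification through JSON
#'
#' @param spec a [phantomSpec()].
#' @param path JSON file.
#' @return \code{writePhantomSpec} returns the path invisibly;
#'   \code{readPhantomSpec} the validated [phantomSpec()].
#' @export
writePhantomSpec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePhantomSpec
#' @export
readPhantomSpec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  phantomSpec(imageSize = x$imageSize, fg = x$fg, bg = x$bg,
              radii = x$radii, smoothSigma = x$smoothSigma)
}
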