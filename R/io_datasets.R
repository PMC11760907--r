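## Reading and writing images, masks and probability maps; DRIVE/STARE-style
## directory handling and train/test splitting.
##
## Pixel convention: arrays are H x W (x C), row-major, origin top-left,
## 1-based in R.  8-bit rasters are scaled to [0, 1] on read.

#' Read a raster image as an H x W (x C) array in [0, 1]
#'
#' PNG, JPEG and TIFF are decoded with EBImage; PPM/PGM (both ASCII and
#' binary) with a built-in reader.  GIF is not decodable with the packages
#' this package builds on; convert such masks to PNG first.
#'
#' @param path image file.
#' @return numeric array, values in `[0, 1]`.
#' @export
readRaster <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read '", path, "'")
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = , jpg = , jpeg = , tif = , tiff = {
      img <- as.array(EBImage::readImage(path))
      # EBImage is W x H (x C); transpose to H x W (x C)
      if (length(dim(img)) == 2L) t(img) else aperm(img, c(2, 1, 3))
    },
    ppm = , pgm = readPNM(path),
    gif = stop("I/O error: GIF decoding is unsupported; convert '", path,
               "' to PNG (e.g. with ImageMagick) first"),
    stop("I/O error: unsupported raster format '", ext, "' for '", path, "'"))
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  pmin(pmax(x, 0), 1)
}

## Minimal Netpbm reader: P2/P5 (grayscale), P3/P6 (RGB)
readPNM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("I/O error: truncated PNM file '", path, "'")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
      } else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch) || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("I/O error: unsupported PNM magic '", magic, "' in '", path, "'")
  w <- as.integer(tok()); h <- as.integer(tok()); maxv <- as.integer(tok())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else {
    v <- numeric(0)
    while (length(v) < n) v <- c(v, as.numeric(tok()))
    v
  }
  # PNM is row-major (pixels left-to-right, top-to-bottom), channels interleaved
  if (nch == 3L) {
    arr <- aperm(array(vals, c(3L, w, h)), c(3, 2, 1))
  } else {
    arr <- t(matrix(vals, w, h))
    dim(arr) <- c(h, w)
  }
  arr / maxv
}

#' Resize an H x W (x C) array
#'
#' @param x image array.
#' @param targetSize `c(H, W)` output size.
#' @param method `"bilinear"` (images) or `"nearest"` (masks).
#' @return resized array.
#' @export
resizeArray <- function(x, targetSize, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  d <- dim(x)
  if (all(d[1:2] == targetSize)) return(x)
  is3 <- length(d) == 3L
  xe <- if (is3) aperm(x, c(2, 1, 3)) else t(x)
  img <- EBImage::resize(EBImage::Image(xe,
                                        colormode = if (is3) "Color" else "Grayscale"),
                         w = targetSize[2], h = targetSize[1],
                         filter = if (method == "nearest") "none" else "bilinear")
  y <- as.array(img)
  y <- if (is3) aperm(y, c(2, 1, 3)) else t(y)
  pmin(pmax(y, 0), 1)
}

#' Load one image/mask pair
#'
#' Reads a fundus image and its manual vessel annotation, checks that their
#' raster sizes agree, resizes the image with bilinear interpolation and the
#' mask with nearest-neighbour to `targetSize`, and re-binarizes the mask at
#' 0.5 (nearest-neighbour on a clean 0/1 mask cannot create intermediate
#' values; the threshold only guards against anti-aliased source files).
#'
#' @param imagePath path to the fundus image.
#' @param maskPath path to the binary vessel annotation.
#' @param targetSize `c(H, W)`; the reference protocol uses 256 x 256.
#' @param id sample identifier; defaults to the image file stem.
#' @return A [FundusSample-class] with `source = "real"`.
#' @export
loadPair <- function(imagePath, maskPath, targetSize = c(256L, 256L),
                     id = tools::file_path_sans_ext(basename(imagePath))) {
  img <- readRaster(imagePath)
  msk <- readRaster(maskPath)
  if (length(dim(msk)) == 3L) msk <- msk[, , 1]
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (!identical(dim(img)[1:2], dim(msk)[1:2]))
    stop(sprintf("dimension mismatch: image is %d x %d but mask is %d x %d",
                 dim(img)[1], dim(img)[2], dim(msk)[1], dim(msk)[2]))
  img <- resizeArray(img, targetSize, "bilinear")
  msk <- resizeArray(msk, targetSize, "nearest")
  msk <- (msk >= 0.5) * 1
  fundusSample(id, img, matrix(msk, targetSize[1], targetSize[2]), "real")
}

#' Load a paired image/mask directory
#'
#' Pairs files by shared stem (exact stem match, falling back to the leading
#' token before the first underscore, which matches the DRIVE naming of
#' e.g. `21_training` / `21_manual1`).
#'
#' @param imagesDir,masksDir directories of images and annotations.
#' @param targetSize `c(H, W)` passed to [loadPair()].
#' @param pattern optional filename filter regexp.
#' @return list of [FundusSample-class] objects, ordered by stem.
#' @export
loadDataset <- function(imagesDir, masksDir, targetSize = c(256L, 256L),
                        pattern = NULL) {
  imgs <- sort(list.files(imagesDir, pattern = pattern, full.names = TRUE))
  msks <- sort(list.files(masksDir, pattern = pattern, full.names = TRUE))
  if (!length(imgs)) stop("I/O error: no images found in '", imagesDir, "'")
  stem <- function(f) tools::file_path_sans_ext(basename(f))
  key <- function(f) sub("_.*$", "", stem(f))
  mk <- if (setequal(stem(imgs), stem(msks))) stem else key
  mi <- match(mk(imgs), mk(msks))
  if (anyNA(mi) || anyDuplicated(mk(imgs)))
    stop("cannot pair images and masks by shared stem in '", imagesDir, "'")
  mapply(function(ip, mp) loadPair(ip, mp, targetSize),
         imgs, msks[mi], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Split samples into train and test sets
#'
#' With `shuffle = FALSE` the input order is preserved (the fixed DRIVE
#' 20/20 convention: first `nTrain` samples train, the rest test); with
#' `shuffle = TRUE` the permutation is drawn deterministically from `seed`.
#'
#' @param samples list of [FundusSample-class] objects.
#' @param nTrain number of training samples, `0 < nTrain < length(samples)`.
#' @param seed permutation seed (used when shuffling).
#' @param shuffle permute before splitting.
#' @return A [DatasetSplit-class].
#' @export
splitDataset <- function(samples, nTrain, seed = 42L, shuffle = FALSE) {
  n <- length(samples)
  if (nTrain <= 0L || nTrain >= n)
    stop("argument error: nTrain must satisfy 0 < nTrain < length(samples)")
  ord <- if (shuffle) withr::with_seed(seed, sample.int(n)) else seq_len(n)
  new("DatasetSplit", train = samples[ord[seq_len(nTrain)]],
      test = samples[ord[(nTrain + 1L):n]])
}

#' Write a probability map as a PNG
#'
#' With `threshold = NULL` the map is written as 8-bit grayscale
#' `round(255 * p)`; with a threshold it is binarized first (`p >= t` maps
#' to 255, else 0), so a binary map written without threshold round-trips
#' exactly through [loadProbabilityMap()].
#'
#' @param prob H x W matrix of probabilities in `[0, 1]`.
#' @param path output PNG path.
#' @param threshold optional binarization threshold.
#' @return the path, invisibly.
#' @export
writeProbabilityMap <- function(prob, path, threshold = NULL) {
  if (min(prob) < 0 || max(prob) > 1)
    stop("prob values must lie in [0, 1]")
  x <- if (is.null(threshold)) round(255 * prob) / 255 else (prob >= threshold) * 1
  ok <- tryCatch({ png::writePNG(x, path); TRUE },
                 error = function(e) FALSE)
  if (!ok) stop("I/O error: cannot write '", path, "'")
  invisible(path)
}

#' @rdname writeProbabilityMap
#' @export
loadProbabilityMap <- function(path) {
  if (!file.exists(path)) stop("I/O error: cannot read '", path, "'")
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1]
  x
}

#' Write a split manifest
#'
#' Two-column CSV (`id`, `partition`) recording which samples went where.
#'
#' @param split a [DatasetSplit-class].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeSplitManifest <- function(split, path) {
  df <- data.frame(
    id = c(vapply(split@train, sampleId, character(1)),
           vapply(split@test, sampleId, character(1))),
    partition = c(rep("train", length(split@train)),
                  rep("test", length(split@test))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
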