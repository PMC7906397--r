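#' Construct an intensity image
#'
#' The basic container used throughout the package: a 2-D matrix of real
#' grey levels together with its physical pixel spacing and the declared
#' grayscale range \eqn{[q_{min}, q_{max}]} (the "standard scale" onto which
#' normalized images are mapped).
#'
#' @param pixels numeric matrix (rows = y, columns = x) of grey levels.
#' @param spacing_mm numeric vector of per-axis spacing in millimetres,
#'   recycled to length 2. Must be strictly positive.
#' @param q_min,q_max integers delimiting the grayscale range. Default 0/255
#'   (8-bit convention).
#' @return An object of class `intensity_image`: a list with elements
#'   `pixels`, `spacing_mm`, `q_min`, `q_max`.
#' @examples
#' img <- intensity_image(matrix(0:255, 16, 16))
#' range(img$pixels)
#' @export
intensity_image <- function(pixels, spacing_mm = c(1, 1), q_min = 0L, q_max = 255L) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  if (any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("`spacing_mm` must be strictly positive on every axis", call. = FALSE)
  if (!(q_min < q_max))
    stop("`q_min` must be < `q_max`", call. = FALSE)
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm,
         q_min = as.numeric(q_min), q_max = as.numeric(q_max)),
    class = "intensity_image"
  )
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %d x %d, spacing %.3g x %.3g mm, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels),
              x$spacing_mm[1], x$spacing_mm[2], x$q_min, x$q_max))
  cat(sprintf("  pixel values in [%.4g, %.4g]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.intensity_image <- function(x) dim(x$pixels)

#' Construct a binary mask
#'
#' A 0/1 raster aligned to an [intensity_image()] grid, used for overlap
#' (Dice) evaluation and volume counting.
#'
#' @param pixels matrix of values that are exactly 0 or 1 (logical accepted).
#' @param spacing_mm per-axis spacing in millimetres.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, spacing_mm = c(1, 1)) {
  if (is.logical(pixels)) storage.mode(pixels) <- "integer"
  if (!is.matrix(pixels) || !all(pixels %in% c(0, 1)))
    stop("mask pixels must be a matrix of 0/1 values", call. = FALSE)
  spacing_mm <- rep_len(as.numeric(spacing_mm), 2L)
  if (any(spacing_mm <= 0))
    stop("`spacing_mm` must be strictly positive", call. = FALSE)
  structure(list(pixels = pixels, spacing_mm = spacing_mm), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d, %d foreground pixels\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

clip_range <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## ITU-R 601 luminance weights for RGB -> grey conversion
luminance <- function(arr) {
  if (length(dim(arr)) == 2L) return(arr)
  ch <- dim(arr)[3]
  if (ch >= 3L)
    0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  else
    arr[, , 1]
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  switch(ext,
         nii = "nifti",
         mha = , mhd = "metaimage",
         png = "png",
         jpg = , jpeg = "jpeg",
         stop("cannot infer image format from extension of ", path, call. = FALSE))
}

#' Read a grayscale image
#'
#' Reads NIfTI-1, MetaImage (`.mha` or `.mhd` + `.raw`), PNG or JPEG into an
#' [intensity_image()]. Multi-channel rasters are converted to luminance
#' grayscale using the ITU-R 601 weights. Spacing is taken from the header
#' for NIfTI/MetaImage and defaults to 1 mm isotropic for PNG/JPEG. Pixel
#' values are kept in the file's native integer scale (8-bit PNG/JPEG data
#' become 0..255), never rescaled.
#'
#' For 3-D volumes the central axial slice is returned; full volumes are out
#' of scope for the normalization pipeline, which operates on 2-D slices.
#'
#' @param path file path.
#' @param format one of `"auto"` (default, by extension), `"nifti"`,
#'   `"metaimage"`, `"png"`, `"jpeg"`.
#' @param q_min,q_max declared grayscale range of the returned image.
#' @return An [intensity_image()].
#' @export
read_image <- function(path, format = c("auto", "nifti", "metaimage", "png", "jpeg"),
                       q_min = 0L, q_max = 255L) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("cannot read image: no such file: ", path, call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nifti = {
      vol <- RNifti::readNifti(path)
      pix <- as.array(vol)
      sp <- RNifti::pixdim(vol)
      if (length(dim(pix)) == 3L) {
        k <- max(1L, ceiling(dim(pix)[3] / 2))
        pix <- pix[, , k]
      }
      intensity_image(as.matrix(pix), spacing_mm = sp[1:2],
                      q_min = q_min, q_max = q_max)
    },
    metaimage = {
      mi <- read_metaimage(path)
      intensity_image(mi$pixels, spacing_mm = mi$spacing,
                      q_min = q_min, q_max = q_max)
    },
    png = {
      arr <- png::readPNG(path)
      intensity_image(luminance(arr) * 255, spacing_mm = c(1, 1),
                      q_min = q_min, q_max = q_max)
    },
    jpeg = {
      arr <- jpeg::readJPEG(path)
      intensity_image(luminance(arr) * 255, spacing_mm = c(1, 1),
                      q_min = q_min, q_max = q_max)
    })
}

#' Write a grayscale image
#'
#' Counterpart of [read_image()]. NIfTI and MetaImage preserve grey values
#' and spacing; PNG stores values scaled from `[q_min, q_max]` to the 8-bit
#' file range.
#'
#' @param img an [intensity_image()].
#' @param path destination path; the format is inferred from the extension
#'   unless `format` is given.
#' @param format `"auto"`, `"nifti"`, `"metaimage"` or `"png"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = c("auto", "nifti", "metaimage", "png")) {
  stopifnot(inherits(img, "intensity_image"))
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  switch(format,
    nifti = {
      vol <- RNifti::asNifti(img$pixels)
      RNifti::pixdim(vol) <- img$spacing_mm
      RNifti::writeNifti(vol, path)
    },
    metaimage = write_metaimage(img$pixels, path, spacing = img$spacing_mm),
    png = {
      scaled <- (img$pixels - img$q_min) / (img$q_max - img$q_min)
      png::writePNG(clip_range(scaled, 0, 1), path)
    })
  invisible(path)
}

## ---- MetaImage (.mha / .mhd + .raw) ---------------------------------------
## Plain ASCII header followed by (or pointing to) a raw little-endian pixel
## block. Only the scalar 2-D/3-D subset needed here is supported.

meta_types <- data.frame(
  met = c("MET_UCHAR", "MET_CHAR", "MET_USHORT", "MET_SHORT", "MET_FLOAT", "MET_DOUBLE"),
  what = c("integer", "integer", "integer", "integer", "numeric", "numeric"),
  size = c(1L, 1L, 2L, 2L, 4L, 8L),
  signed = c(FALSE, TRUE, FALSE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  data_offset <- NULL
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop("truncated MetaImage header in ", path, call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed MetaImage header line: ", line, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") { data_offset <- seek(con); break }
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else rep(1, length(dims))
  tinfo <- meta_types[meta_types$met == hdr$ElementType, ]
  if (nrow(tinfo) != 1L)
    stop("unsupported MetaImage ElementType: ", hdr$ElementType, call. = FALSE)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = "little")
  } else {
    raw_path <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(raw_path))
      stop("cannot read MetaImage payload: no such file: ", raw_path, call. = FALSE)
    rcon <- file(raw_path, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, tinfo$what, n = n, size = tinfo$size,
                    signed = tinfo$signed, endian = "little")
  }
  if (length(vals) < n)
    stop("truncated MetaImage payload for ", path,
         ": expected ", n, " values, got ", length(vals), call. = FALSE)
  ## MetaImage raster order is x-fastest; matrix(nrow = nx) then transpose
  ## yields the package's row-major (y, x) layout.
  if (length(dims) == 3L && dims[3] > 1L) {
    k <- max(1L, ceiling(dims[3] / 2))
    vals <- vals[((k - 1L) * dims[1] * dims[2] + 1L):(k * dims[1] * dims[2])]
  }
  pix <- t(matrix(as.numeric(vals), nrow = dims[1], ncol = dims[2]))
  ## header spacing is (x, y); package convention is (row, col) = (y, x)
  list(pixels = pix, spacing = spacing[c(2, 1)])
}

write_metaimage <- function(pixels, path, spacing = c(1, 1)) {
  ext <- tolower(tools::file_ext(path))
  integral <- all(pixels == round(pixels))
  if (integral && min(pixels) >= 0 && max(pixels) <= 255) {
    met <- "MET_UCHAR"; size <- 1L; what <- as.integer(round(pixels))
  } else if (integral && min(pixels) >= -32768 && max(pixels) <= 32767) {
    met <- "MET_SHORT"; size <- 2L; what <- as.integer(round(pixels))
  } else {
    met <- "MET_DOUBLE"; size <- 8L; what <- as.numeric(pixels)
  }
  ## back to x-fastest order
  ordered <- as.vector(t(pixels))
  hdr <- c("ObjectType = Image",
           "NDims = 2",
           sprintf("DimSize = %d %d", ncol(pixels), nrow(pixels)),
           sprintf("ElementSpacing = %g %g", spacing[2], spacing[1]),
           sprintf("ElementType = %s", met))
  if (ext == "mha") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(hdr, "ElementDataFile = LOCAL"), con)
    writeBin(if (size <= 2L) as.integer(ordered) else as.numeric(ordered),
             con, size = size, endian = "little")
  } else {
    raw_name <- paste0(tools::file_path_sans_ext(basename(path)), ".raw")
    writeLines(c(hdr, paste("ElementDataFile =", raw_name)), path)
    rcon <- file(file.path(dirname(path), raw_name), "wb")
    on.exit(close(rcon))
    writeBin(if (size <= 2L) as.integer(ordered) else as.numeric(ordered),
             rcon, size = size, endian = "little")
  }
  invisible(path)
}

#' Resize an image by bilinear interpolation
#'
#' Output spacing is rescaled so the physical extent of the image is
#' preserved; values are clipped to the image's grayscale range. Used to
#' bring extracted patches to a classifier's input size (e.g. 64 to 117 or
#' 224 pixels).
#'
#' @param img an [intensity_image()].
#' @param target_shape integer pair `(rows, cols)`, both at least 1.
#' @return The resized [intensity_image()].
#' @export
resize <- function(img, target_shape) {
  stopifnot(inherits(img, "intensity_image"))
  target_shape <- as.integer(rep_len(target_shape, 2L))
  if (any(target_shape < 1L))
    stop("target dimensions must be >= 1", call. = FALSE)
  src <- img$pixels
  h <- nrow(src); w <- ncol(src)
  th <- target_shape[1]; tw <- target_shape[2]
  if (th == h && tw == w) return(img)
  ## centre-aligned sampling: output pixel centres mapped into source grid
  ry <- (seq_len(th) - 0.5) * h / th - 0.5
  rx <- (seq_len(tw) - 0.5) * w / tw - 0.5
  y0 <- clip_range(floor(ry), 0, h - 1); y1 <- clip_range(y0 + 1, 0, h - 1)
  x0 <- clip_range(floor(rx), 0, w - 1); x1 <- clip_range(x0 + 1, 0, w - 1)
  fy <- ry - floor(ry); fx <- rx - floor(rx)
  fy[ry < 0] <- 0; fy[ry > h - 1] <- 1
  fx[rx < 0] <- 0; fx[rx > w - 1] <- 1
  A <- src[y0 + 1, x0 + 1, drop = FALSE]; B <- src[y0 + 1, x1 + 1, drop = FALSE]
  C <- src[y1 + 1, x0 + 1, drop = FALSE]; D <- src[y1 + 1, x1 + 1, drop = FALSE]
  wy <- matrix(fy, th, tw); wx <- matrix(fx, th, tw, byrow = TRUE)
  out <- (1 - wy) * ((1 - wx) * A + wx * B) + wy * ((1 - wx) * C + wx * D)
  intensity_image(clip_range(out, img$q_min, img$q_max),
                  spacing_mm = img$spacing_mm * c(h / th, w / tw),
                  q_min = img$q_min, q_max = img$q_max)
}

## Run code under a temporary RNG state; the caller's stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
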