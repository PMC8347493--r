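#' Fundus image and mask containers
#'
#' A `fundus_image` holds the red, green and blue channels of an optic nerve
#' head photograph as numeric matrices (rows = image rows, origin top-left),
#' together with a camera identifier and the eye laterality. Intensities are
#' linear sensor values on the native bit-depth scale (0..255 for 8-bit,
#' 0..65535 for 16-bit); no gamma handling is applied anywhere in the
#' pipeline, which only ever uses the gain-invariant ratio (R-G)/R.
#'
#' @param red,green,blue Numeric matrices of identical dimensions with
#'   non-negative entries.
#' @param camera_id Character label identifying the fundus camera model
#'   (used to look up calibrations).
#' @param eye One of `"right"`, `"left"`, `"unknown"`.
#' @param bit_depth Nominal bit depth (8 or 16); informational, used only
#'   when writing files.
#' @return An object of class `fundus_image`.
#' @export
fundus_image <- function(red, green, blue, camera_id = "unknown",
                         eye = c("unknown", "right", "left"), bit_depth = 8) {
  eye <- match.arg(eye)
  red <- as.matrix(red); green <- as.matrix(green); blue <- as.matrix(blue)
  if (!identical(dim(red), dim(green)) || !identical(dim(red), dim(blue))) {
    stop("red, green and blue channels must share dimensions", call. = FALSE)
  }
  if (min(red, green, blue) < 0) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  structure(
    list(red = red, green = green, blue = blue,
         camera_id = camera_id, eye = eye, bit_depth = bit_depth),
    class = "fundus_image"
  )
}

#' @export
print.fundus_image <- function(x, ...) {
  cat(sprintf("<fundus_image> %d x %d px, camera '%s', eye %s, %d-bit\n",
              nrow(x$red), ncol(x$red), x$camera_id, x$eye, x$bit_depth))
  invisible(x)
}

#' @export
dim.fundus_image <- function(x) dim(x$red)

#' Disc and vessel masks
#'
#' Boolean rasters delimiting the optic disc (inner edge of Elschnig's
#' scleral ring) and the reference vessels. Vessel pixels used as the
#' colorimetric reference must lie inside the disc region, optionally
#' extended by a margin (see [vessel_reference()]).
#'
#' @param disc_mask,vessel_mask Logical matrices of identical dimensions.
#' @return An object of class `disc_masks`.
#' @export
disc_masks <- function(disc_mask, vessel_mask) {
  disc_mask <- as.matrix(disc_mask); vessel_mask <- as.matrix(vessel_mask)
  storage.mode(disc_mask) <- "logical"
  storage.mode(vessel_mask) <- "logical"
  if (!identical(dim(disc_mask), dim(vessel_mask))) {
    stop("disc and vessel masks must share dimensions", call. = FALSE)
  }
  structure(list(disc_mask = disc_mask, vessel_mask = vessel_mask),
            class = "disc_masks")
}

#' @export
print.disc_masks <- function(x, ...) {
  cat(sprintf("<disc_masks> %d x %d px, disc %d px, vessels %d px\n",
              nrow(x$disc_mask), ncol(x$disc_mask),
              sum(x$disc_mask), sum(x$vessel_mask)))
  invisible(x)
}

# Internal: read a PNG/TIFF into an array in [0,1]; returns list(data, depth).
read_raster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png")) {
    a <- png::readPNG(path)
    depth <- 8L
  } else if (ext %in% c("tif", "tiff")) {
    a <- tiff::readTIFF(path)
    depth <- 8L
  } else {
    stop("unsupported image format: '", ext, "' (use PNG or TIFF)",
         call. = FALSE)
  }
  list(data = a, depth = depth)
}

#' Read a fundus photograph
#'
#' Reads an RGB PNG or TIFF into a [fundus_image()]. File values in \[0,1\]
#' are rescaled to the 8-bit range; single-channel files are refused.
#'
#' @param path Path to a PNG or TIFF file.
#' @inheritParams fundus_image
#' @return A `fundus_image`.
#' @export
read_fundus_image <- function(path, camera_id = "unknown",
                              eye = c("unknown", "right", "left")) {
  eye <- match.arg(eye)
  r <- read_raster(path)
  a <- r$data
  if (length(dim(a)) != 3 || dim(a)[3] < 3) {
    stop("expected an RGB image: ", path, call. = FALSE)
  }
  scale <- 2^r$depth - 1
  fundus_image(a[, , 1] * scale, a[, , 2] * scale, a[, , 3] * scale,
               camera_id = camera_id, eye = eye, bit_depth = r$depth)
}

#' Write a fundus image as PNG
#'
#' @param image A [fundus_image()].
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_fundus_image <- function(image, path) {
  scale <- 2^image$bit_depth - 1
  a <- array(0, c(nrow(image$red), ncol(image$red), 3))
  a[, , 1] <- pmin(image$red / scale, 1)
  a[, , 2] <- pmin(image$green / scale, 1)
  a[, , 3] <- pmin(image$blue / scale, 1)
  png::writePNG(a, path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Nonzero pixels are `TRUE`.
#'
#' @param path Path to a PNG file.
#' @return A logical matrix.
#' @export
read_mask <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) a <- a[, , 1]
  a > 0
}

#' Write a binary mask as a single-channel PNG
#'
#' @param mask Logical matrix.
#' @param path Output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask * 1, path)
  invisible(path)
}
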