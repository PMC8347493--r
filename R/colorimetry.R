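#' Haemoglobin ratio of a pixel
#'
#' Haemoglobin absorbs green light and reflects most of the red, so the
#' contrast between the red (R) and green (G) channel of a pixel indexes how
#' much haemoglobin the imaged tissue carries. The ratio is `(R - G) / R`:
#' 1 for a pixel reflecting no green at all, 0 when R = G, negative when
#' green exceeds red. Pixels with `R = 0` carry no colour information and
#' are returned as `NA` (callers must exclude them).
#'
#' The ratio is invariant to a common positive gain on both channels, which
#' is what makes the downstream map robust to exposure differences.
#'
#' @param red,green Numeric vectors/matrices of channel intensities
#'   (`red >= 0`, `green >= 0`), recycled to a common shape.
#' @return `(red - green) / red`, `NA` where `red == 0`.
#' @examples
#' hb_ratio(100, 50)   # 0.5
#' hb_ratio(200, 200)  # 0
#' hb_ratio(50, 100)   # -1
#' @export
hb_ratio <- function(red, green) {
  out <- (red - green) / red
  out[red == 0] <- NA_real_
  out
}

#' Vessel reference ratio
#'
#' The central retinal vessels are the most haemoglobin-rich structure in
#' the image, so their colour anchors the haemoglobin scale: the tissue map
#' is expressed relative to a robust central tendency of [hb_ratio()] over
#' the vessel pixels. The median is the default (robust to specular
#' highlights along vessel centrelines); the mean is available.
#'
#' Only vessel pixels inside the disc region — optionally dilated by
#' `margin` pixels — contribute, so that peripheral vessels with different
#' illumination do not pull the reference.
#'
#' @param image A [fundus_image()].
#' @param masks A [disc_masks()].
#' @param statistic `"median"` (default) or `"mean"`.
#' @param margin Non-negative integer: the disc mask is dilated by this many
#'   pixels before intersecting the vessel mask. Default 2.
#' @return The reference ratio, a positive scalar.
#' @export
vessel_reference <- function(image, masks, statistic = c("median", "mean"),
                             margin = 2) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(image, "fundus_image"), inherits(masks, "disc_masks"))
  region <- masks$disc_mask
  if (margin > 0) {
    brush <- EBImage::makeBrush(2 * margin + 1, shape = "disc")
    region <- EBImage::dilate(EBImage::Image(region * 1), brush) > 0
  }
  use <- masks$vessel_mask & region
  ratios <- hb_ratio(image$red[use], image$green[use])
  ratios <- ratios[!is.na(ratios)]
  if (length(ratios) == 0) {
    stop("no usable vessel pixels inside the disc region ",
         "(empty vessel mask or all R = 0)", call. = FALSE)
  }
  ref <- if (statistic == "median") median(ratios) else mean(ratios)
  if (ref <= 0) {
    stop(sprintf(paste0(
      "non-positive vessel reference ratio (%.4f over %d pixels): vessels ",
      "should be the most haemoglobin-rich pixels; check the vessel mask ",
      "and channel order"), ref, length(ratios)), call. = FALSE)
  }
  ref
}

#' Per-pixel haemoglobin percentage map
#'
#' Applies the camera calibration, computes the vessel reference ratio, and
#' expresses the [hb_ratio()] of every disc tissue pixel as a percentage of
#' that reference: `100 * ratio / reference`. The map is defined exactly on
#' disc pixels that are not vessel pixels and have `R > 0`; everything else
#' is `NA`. Values are not clipped — tissue redder than the vessels exceeds
#' 100, tissue with G > R goes negative; display ranges are a downstream
#' concern.
#'
#' @inheritParams vessel_reference
#' @param calib A [camera_calibration()] or `NULL`.
#' @param ... Passed to [vessel_reference()].
#' @return An object of class `hb_map`: list with `hb` (numeric matrix,
#'   `NA` off-support), `reference_ratio`, `n_tissue`.
#' @export
hb_percentage_map <- function(image, masks, calib = NULL, ...) {
  stopifnot(inherits(image, "fundus_image"), inherits(masks, "disc_masks"))
  if (!identical(dim(image$red), dim(masks$disc_mask))) {
    stop("image and masks must share dimensions", call. = FALSE)
  }
  image <- apply_calibration(image, calib)
  ref <- vessel_reference(image, masks, ...)
  tissue <- masks$disc_mask & !masks$vessel_mask
  hb <- matrix(NA_real_, nrow(image$red), ncol(image$red))
  hb[tissue] <- 100 * hb_ratio(image$red[tissue], image$green[tissue]) / ref
  structure(
    list(hb = hb, reference_ratio = ref, n_tissue = sum(!is.na(hb))),
    class = "hb_map"
  )
}

#' @export
print.hb_map <- function(x, ...) {
  v <- x$hb[!is.na(x$hb)]
  cat(sprintf(
    "<hb_map> %d tissue px, reference ratio %.4f, Hb%% median %.1f [%.1f, %.1f]\n",
    x$n_tissue, x$reference_ratio,
    median(v), min(v), max(v)))
  invisible(x)
}

#' Write a haemoglobin map
#'
#' 32-bit float TIFF plus a JSON sidecar with the reference ratio, tissue
#' pixel count and the affine encoding. TIFF float storage is only defined
#' on \[0, 1\], so Hb values (unbounded in principle) are rescaled affinely
#' into (0, 1\] with off-support pixels stored as exactly 0; the sidecar
#' records the transform so [read_hb_map()] inverts it losslessly (to
#' float32 precision).
#'
#' @param hb An `hb_map`.
#' @param path Output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_hb_map <- function(hb, path) {
  v <- hb$hb[!is.na(hb$hb)]
  lo <- min(v); hi <- max(v)
  pad <- 1 / 16                       # keep valid pixels clear of the 0 = missing code
  m <- matrix(0, nrow(hb$hb), ncol(hb$hb))
  ok <- !is.na(hb$hb)
  m[ok] <- if (hi > lo) pad + (1 - pad) * (hb$hb[ok] - lo) / (hi - lo) else 0.5
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(reference_ratio = hb$reference_ratio, n_tissue = hb$n_tissue,
         encoding = list(lo = lo, hi = hi, pad = pad,
                         missing = "stored value 0")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a haemoglobin map written by [write_hb_map()]
#'
#' @param path TIFF path (sidecar `<path>.json` must exist).
#' @return An `hb_map`.
#' @export
read_hb_map <- function(path) {
  m <- tiff::readTIFF(path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  enc <- side$encoding
  out <- matrix(NA_real_, nrow(m), ncol(m))
  ok <- !is.nan(m) & m > enc$pad / 2
  out[ok] <- if (enc$hi > enc$lo)
    enc$lo + (m[ok] - enc$pad) / (1 - enc$pad) * (enc$hi - enc$lo)
  else enc$lo
  structure(list(hb = out, reference_ratio = side$reference_ratio,
                 n_tissue = sum(ok)),
            class = "hb_map")
}

#' Plot a haemoglobin map
#'
#' Pseudo-colour raster of the haemoglobin percentage over the disc.
#'
#' @param object An `hb_map`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot hb_map
#' @export
autoplot.hb_map <- function(object, ...) {
  df <- tibble::tibble(
    row = as.vector(row(object$hb)),
    col = as.vector(col(object$hb)),
    hb = as.vector(object$hb)
  ) |> dplyr::filter(!is.na(.data$hb))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$hb)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "Hb %") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Haemoglobin map (vessel-referenced)") +
    ggplot2::theme_void()
}
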