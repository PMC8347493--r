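# Fixture-grade deterministic segmentation. These routines exist so the
# colorimetric pipeline can run end-to-end on synthetic phantoms without any
# externally supplied masks; for real retinographies users are expected to
# provide disc and vessel masks from whatever segmentation tool they trust.

#' Locate the optic disc
#'
#' The disc is the brightest compact structure in an optic-nerve-head
#' photograph. Detection: threshold the luminance at a high percentile,
#' close small gaps, keep the largest connected component, and fill the
#' ellipse recovered from its second moments (semi-axes = 2 * sqrt of the
#' eigenvalues of the pixel covariance, the exact relation for a filled
#' ellipse).
#'
#' The luminance percentile is scale-free, so the result is invariant to a
#' common positive gain on all channels, and translation-equivariant.
#'
#' @param image A [fundus_image()].
#' @param luminance_percentile Percentile of luminance above which pixels
#'   are disc candidates; default 0.90.
#' @param closing_radius Closing brush radius in px; default 5.
#' @param min_area Minimum component area (px) below which detection fails;
#'   default 50.
#' @return A logical disc mask.
#' @export
locate_disc <- function(image, luminance_percentile = 0.90,
                        closing_radius = 5, min_area = 50) {
  stopifnot(inherits(image, "fundus_image"))
  lum <- (image$red + image$green + image$blue) / 3
  cut <- quantile(lum, luminance_percentile, names = FALSE)
  cand <- lum > cut                       # strict: a flat image yields nothing
  if (!any(cand)) stop("no disc found: no pixels above the luminance percentile",
                       call. = FALSE)
  # select the largest bright component first (scattered noise pixels above
  # the cut must not be merged into it by the closing), then smooth it
  lab <- as.integer(EBImage::bwlabel(EBImage::Image(cand * 1)))
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes) || max(sizes) < min_area) {
    stop("no disc found: largest bright component below ", min_area, " px",
         call. = FALSE)
  }
  comp <- matrix(lab == which.max(sizes), nrow(lum), ncol(lum))
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    # opening first: it shaves off thin bright structures (vessel segments)
    # protruding from the disc, which would otherwise skew the moment-based
    # ellipse fit — and must run before the closing can merge neighbouring
    # segments into slabs too wide to remove; the closing then bridges any
    # gaps inside the disc body
    opened <- EBImage::opening(EBImage::Image(comp * 1), brush) > 0
    if (any(opened)) comp <- opened
    comp <- EBImage::closing(EBImage::Image(comp * 1), brush) > 0
  }
  moment_ellipse_fill(comp)
}

#' Segment the reference vessels
#'
#' Vessels are the most haemoglobin-rich pixels, i.e. the highest
#' [hb_ratio()] values in the disc neighbourhood. An adaptive (Otsu) cut on
#' the ratio separates them from rim/cup tissue; speckle components below
#' `min_component` px are removed. The search region is the disc mask
#' dilated by `margin` px. The ratio is gain-invariant, so the mask is too.
#'
#' @param image A [fundus_image()].
#' @param disc_mask Logical matrix from [locate_disc()] or supplied
#'   externally; must be non-empty.
#' @param margin Dilation of the disc mask delimiting the search region
#'   (px); default 10.
#' @param min_component Minimum component size kept (px); default 10.
#' @param cut Ratio threshold; `NULL` (default) = adaptive two-stage Otsu:
#'   a first split removes the low-ratio background/cup mass, and if the
#'   upper class is too large to plausibly be vessels (more than
#'   `max_vessel_fraction` of the region, i.e. it still contains rim
#'   tissue), a second split within it isolates the vessel mode.
#' @param max_vessel_fraction Upper-class size above which the second split
#'   is applied; default 0.35.
#' @param gap_floor Minimum separation (in ratio units) between the vessel
#'   class and the tissue class for the adaptive cut to be accepted; a
#'   split whose classes touch is bisecting noise, not finding vessels.
#'   Default 0.05.
#' @return A logical vessel mask (with a warning if empty).
#' @export
segment_vessels <- function(image, disc_mask, margin = 10,
                            min_component = 10, cut = NULL,
                            max_vessel_fraction = 0.35, gap_floor = 0.05) {
  stopifnot(inherits(image, "fundus_image"))
  if (!any(disc_mask)) stop("empty disc mask", call. = FALSE)
  region <- disc_mask
  if (margin > 0) {
    brush <- EBImage::makeBrush(2 * margin + 1, shape = "disc")
    region <- EBImage::dilate(EBImage::Image(disc_mask * 1), brush) > 0
  }
  ratio <- hb_ratio(image$red, image$green)
  rvals <- ratio[region & !is.na(ratio)]
  adaptive <- is.null(cut)
  if (adaptive) {
    cut <- otsu_threshold(rvals)
    if (mean(rvals > cut) > max_vessel_fraction) {
      cut <- otsu_threshold(rvals[rvals > cut])
    }
    # a genuine vessel mode is separated from the tissue ratios; if the
    # split only bisects one noisy mode the two classes touch and there
    # are no vessels to find
    if (any(rvals > cut) && any(rvals <= cut) &&
        min(rvals[rvals > cut]) - max(rvals[rvals <= cut]) < gap_floor) {
      cut <- Inf
    }
  }
  vess <- region & !is.na(ratio) & ratio > cut
  if (any(vess)) {
    lab <- as.integer(EBImage::bwlabel(EBImage::Image(vess * 1)))
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_component)
    vess <- matrix(lab %in% keep, nrow(vess), ncol(vess))
  }
  if (!any(vess)) {
    warning("no vessels found in the disc neighbourhood; returning empty mask",
            call. = FALSE)
  }
  vess
}

#' Basic image sanity gate
#'
#' Plumbing check for gross exposure/contrast problems before analysis
#' (quality grading proper is out of scope: callers with a quality score
#' should gate on it upstream).
#'
#' @param image A [fundus_image()].
#' @param min_mean,max_mean Acceptable mean luminance band, as a fraction of
#'   full scale; defaults 0.02 and 0.98.
#' @param min_sd Minimum luminance SD as a fraction of full scale; default 0.005.
#' @return `TRUE` if the image passes, otherwise `FALSE` with a message
#'   attribute `"reason"`.
#' @export
image_sanity <- function(image, min_mean = 0.02, max_mean = 0.98,
                         min_sd = 0.005) {
  scale <- 2^image$bit_depth - 1
  lum <- (image$red + image$green + image$blue) / 3 / scale
  m <- mean(lum); s <- sd(lum)
  reason <- NULL
  if (m < min_mean) reason <- "underexposed"
  else if (m > max_mean) reason <- "overexposed"
  else if (s < min_sd) reason <- "no contrast"
  ok <- is.null(reason)
  if (!ok) attr(ok, "reason") <- reason
  ok
}
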