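# End-to-end single-image analysis: calibration -> Hb map -> sectors ->
# cup -> per-eye feature vector (the inputs of the reference classifier and
# of the GDF components).

#' Analyse one fundus image
#'
#' Runs the full colorimetric pipeline on an image: calibration, vessel
#' reference, haemoglobin map, sector profile, cup estimate and the per-eye
#' feature vector. Masks are supplied externally or, failing that, come
#' from the fixture-grade classical segmentation ([locate_disc()],
#' [segment_vessels()]).
#'
#' @param image A [fundus_image()].
#' @param masks A [disc_masks()], or `NULL` to auto-segment.
#' @param calib A [camera_calibration()] or `NULL`.
#' @param n_sectors Sector count for the profile; default 24.
#' @param cup_args List of extra arguments for [estimate_cup()].
#' @param seg_args List of extra arguments for [locate_disc()] /
#'   [segment_vessels()] when auto-segmenting.
#' @return A list of class `onhe_analysis`: `hb_map`, `sectors`, `cup`,
#'   `features` (one-row tibble), `masks`.
#' @export
analyze_fundus <- function(image, masks = NULL, calib = NULL, n_sectors = 24,
                           cup_args = list(), seg_args = list()) {
  stopifnot(inherits(image, "fundus_image"))
  if (is.null(masks)) {
    disc <- do.call(locate_disc, c(list(image), seg_args[
      intersect(names(seg_args), names(formals(locate_disc)))]))
    vess <- do.call(segment_vessels, c(list(image, disc), seg_args[
      intersect(names(seg_args), names(formals(segment_vessels)))]))
    masks <- disc_masks(disc, vess)
  }
  hb <- hb_percentage_map(image, masks, calib)
  eye <- if (image$eye == "unknown") "right" else image$eye
  sectors <- sectorize(hb, masks, n_sectors = n_sectors, eye = eye)
  cup <- do.call(estimate_cup, c(list(hb, masks), cup_args))
  structure(list(hb_map = hb, sectors = sectors, cup = cup,
                 features = disc_features(hb, sectors, cup), masks = masks),
            class = "onhe_analysis")
}

#' @export
print.onhe_analysis <- function(x, ...) {
  cat("<onhe_analysis>\n")
  print(x$hb_map); print(x$cup)
  print(x$features)
  invisible(x)
}

#' Per-eye morphology/perfusion feature vector
#'
#' The features feeding the reference classifier and the default GDF
#' component set: mean disc tissue Hb%, vertical and area cup/disc ratios,
#' and the mean Hb% of the inferotemporal sector span (angle centres within
#' 22.5–67.5 degrees from the temporal horizontal, midway between temporal
#' at 0 and inferior at 90 — the region most vulnerable in early glaucoma).
#'
#' @param hb An `hb_map`.
#' @param sectors A `sector_profile`.
#' @param cup A `cup_estimate`.
#' @return One-row tibble: `mean_hb`, `vertical_cd`, `area_cd`,
#'   `inferotemporal_hb`.
#' @export
disc_features <- function(hb, sectors, cup) {
  it <- sectors$angle_center >= 22.5 & sectors$angle_center <= 67.5
  tibble::tibble(
    mean_hb = mean(hb$hb, na.rm = TRUE),
    vertical_cd = cup$vertical_cd,
    area_cd = cup$area_cd,
    inferotemporal_hb = stats::weighted.mean(
      sectors$mean_hb[it], sectors$n_pixels[it], na.rm = TRUE))
}

#' GDF for an analysed image
#'
#' Convenience wrapper: z-normalizes the classifier score and the default
#' component features against the reference cohort and composes the GDF.
#'
#' @param analysis An `onhe_analysis`.
#' @param classifier An `onhe_lda` (or any object with a `predict` method
#'   returning larger-is-worse scores).
#' @param stats A [reference_cohort_stats()] covering `classifier_score`
#'   and the component features.
#' @param components Component feature names; default [gdf_components()].
#' @param w Classifier weight; default 0.45.
#' @return GDF value (lower = more glaucomatous).
#' @export
gdf_for_analysis <- function(analysis, classifier, stats,
                             components = gdf_components(), w = 0.45) {
  score <- predict(classifier, analysis$features)
  cz <- z_normalize(score, "classifier_score", stats)
  comp <- vapply(components, function(cp)
    z_normalize(analysis$features[[cp]], cp, stats), numeric(1))
  gdf(cz, comp, w = w)
}
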