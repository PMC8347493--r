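# Disc morphology: angular sector decomposition of the Hb map, cup
# estimation from the haemoglobin distribution, cup/disc ratios and
# normative percentiles.

# Otsu's bimodal histogram split on a numeric vector: threshold maximising
# between-class variance over `levels` equal-width bins. Returns a value on
# the input scale (bin upper edge of the background class).
otsu_threshold <- function(x, levels = 256L) {
  x <- x[!is.na(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(
    findInterval(x, seq(rng[1], rng[2], length.out = levels + 1L),
                 rightmost.closed = TRUE), 1L), levels), nbins = levels)
  p <- h / sum(h)
  mids <- seq(rng[1], rng[2], length.out = levels + 1L)[-1L] -
    diff(rng) / (2 * levels)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  between <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- 0
  # with well-separated modes the criterion is flat between them: take the
  # centre of the argmax plateau, not its lower edge
  mean(mids[between >= max(between) - 1e-12])
}

# Fill a pixel component with the ellipse given by its second moments
# (semi-axes = 2 * sqrt(eigenvalues): exact for a filled ellipse).
moment_ellipse_fill <- function(comp) {
  idx <- which(comp, arr.ind = TRUE)
  if (nrow(idx) < 8) return(comp)
  ctr <- colMeans(idx)
  cv <- stats::cov(idx)
  if (det(cv) <= .Machine$double.eps) return(comp)
  inv <- solve(cv)
  rows <- row(comp) - ctr[1]
  cols <- col(comp) - ctr[2]
  d2 <- inv[1, 1] * rows^2 + 2 * inv[1, 2] * rows * cols + inv[2, 2] * cols^2
  d2 <= 4
}

# Angle of each pixel about the disc centroid, in degrees in [0, 360),
# 0 = temporal horizontal, advancing counterclockwise as viewed (through
# inferior at 90, nasal at 180, superior at 270). The temporal side is
# taken to be the image-left edge for right eyes and image-right for left
# eyes (left-eye geometry is the mirror image of right-eye geometry), so the
# same sector index means the same anatomical sector in both eyes.
disc_angles <- function(disc_mask, eye = "right") {
  idx <- which(disc_mask, arr.ind = TRUE)
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  dx <- idx[, 2] - cx
  dy <- idx[, 1] - cy            # raster rows grow downwards
  if (identical(eye, "left")) dx <- -dx
  ang <- (atan2(-dy, dx) * 180 / pi - 180) %% 360
  list(angle = ang, idx = idx, centroid = c(row = cy, col = cx))
}

#' Sector decomposition of a haemoglobin map
#'
#' Divides the disc into `n_sectors` equal angular wedges about the disc
#' centroid and reports, per sector, the mean haemoglobin percentage over
#' defined tissue pixels and the sector area as a percentage of the disc
#' area. Sector 1 is centred on the temporal horizontal; sectors advance
#' counterclockwise as viewed (inferior at 90 degrees, nasal at 180,
#' superior at 270) for right eyes and mirrored for left eyes, so sector
#' indices are anatomically comparable across eyes.
#'
#' @param hb An `hb_map` from [hb_percentage_map()].
#' @param masks A [disc_masks()].
#' @param n_sectors Number of angular sectors (>= 4; default 24).
#' @param eye `"right"`, `"left"` or `"unknown"` (treated as right).
#' @return A tibble of class `sector_profile` with columns `sector`,
#'   `angle_center` (degrees from temporal horizontal), `mean_hb`
#'   (`NA` if the sector has no defined Hb pixel), `area_pct`, `n_pixels`.
#' @export
sectorize <- function(hb, masks, n_sectors = 24, eye = "right") {
  stopifnot(inherits(hb, "hb_map"), inherits(masks, "disc_masks"))
  if (n_sectors < 4) stop("n_sectors must be >= 4", call. = FALSE)
  if (!any(masks$disc_mask)) stop("empty disc mask", call. = FALSE)
  da <- disc_angles(masks$disc_mask, eye)
  width <- 360 / n_sectors
  sec <- floor(((da$angle + width / 2) %% 360) / width) + 1L
  hbv <- hb$hb[da$idx]
  out <- tibble::tibble(sector = sec, hb = hbv) |>
    dplyr::group_by(.data$sector) |>
    dplyr::summarise(
      mean_hb = if (all(is.na(.data$hb))) NA_real_ else
        mean(.data$hb, na.rm = TRUE),
      n_pixels = dplyr::n(), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(sector = seq_len(n_sectors)),
                      by = "sector") |>
    dplyr::arrange(.data$sector) |>
    dplyr::mutate(
      n_pixels = dplyr::coalesce(.data$n_pixels, 0L),
      area_pct = 100 * .data$n_pixels / sum(.data$n_pixels),
      angle_center = (.data$sector - 1) * width) |>
    dplyr::select("sector", "angle_center", "mean_hb", "area_pct", "n_pixels")
  attr(out, "n_sectors") <- n_sectors
  attr(out, "eye") <- eye
  attr(out, "angular_convention") <-
    "0 deg = temporal horizontal, 90 = inferior, 270 = superior; left eyes mirrored"
  class(out) <- c("sector_profile", class(out))
  out
}

#' Plot a sector profile
#'
#' Polar bar chart of per-sector mean haemoglobin.
#'
#' @param object A `sector_profile`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot sector_profile
#' @export
autoplot.sector_profile <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$angle_center, y = .data$mean_hb,
                               fill = .data$mean_hb)) +
    ggplot2::geom_col(width = 360 / nrow(object)) +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "Hb %") +
    ggplot2::labs(x = "angle from temporal horizontal (deg)",
                  y = "mean Hb %", title = "Sector haemoglobin profile")
}

#' Estimate the cup from the haemoglobin distribution
#'
#' The cup is the pale, excavated centre of the disc: its tissue carries
#' less haemoglobin than the neuroretinal rim, so it appears as the low mode
#' of the disc Hb distribution. The estimator thresholds the Hb map at a
#' bimodal histogram split (Otsu; overridable), bridges the gaps left by
#' vessels with a morphological closing, and keeps the largest connected
#' component. A minimum-contrast gate returns an empty cup when the disc Hb
#' range is below `contrast_floor` (a near-uniform disc has no detectable
#' cup, and a histogram split on noise would be meaningless).
#'
#' @param hb An `hb_map`.
#' @param masks A [disc_masks()].
#' @param threshold Hb% cut below which tissue is cup candidate; `NULL`
#'   (default) uses the Otsu split of the disc Hb values.
#' @param contrast_floor Minimum disc Hb range (max - min, in Hb points) for
#'   a cup to be estimable; default 15.
#' @param closing_radius Radius (px) of the closing brush that bridges
#'   vessel shadows across the cup; default 5.
#' @param min_tissue Minimum number of defined Hb pixels required; default 100.
#' @param vertical_rule `"centroid_column"` (default) measures vertical
#'   extents on the column through the disc centroid; `"max_column"` takes
#'   the maximum extent ratio over all columns.
#' @param regularize `"ellipse"` (default) replaces the selected component
#'   by its moment ellipse (clipped to the disc), which restores the parts
#'   of the cup occluded by vessels — occlusions at the cup's vertical caps
#'   are unrecoverable by closing alone and would bias the vertical C/D
#'   low; `"none"` keeps the raw component.
#' @return An object of class `cup_estimate`: `cup_mask`, `vertical_cd`,
#'   `area_cd`, `threshold_used`.
#' @export
estimate_cup <- function(hb, masks, threshold = NULL, contrast_floor = 15,
                         closing_radius = 5, min_tissue = 100,
                         vertical_rule = c("centroid_column", "max_column"),
                         regularize = c("ellipse", "none")) {
  vertical_rule <- match.arg(vertical_rule)
  regularize <- match.arg(regularize)
  stopifnot(inherits(hb, "hb_map"), inherits(masks, "disc_masks"))
  vals <- hb$hb[!is.na(hb$hb)]
  if (length(vals) < min_tissue) {
    stop("Hb map defined on fewer than ", min_tissue, " pixels", call. = FALSE)
  }
  empty <- function(thr) {
    structure(list(cup_mask = matrix(FALSE, nrow(hb$hb), ncol(hb$hb)),
                   vertical_cd = 0, area_cd = 0, threshold_used = thr),
              class = "cup_estimate")
  }
  if (diff(range(vals)) < contrast_floor) return(empty(NA_real_))
  thr <- threshold %||% otsu_threshold(vals)
  cand <- !is.na(hb$hb) & hb$hb < thr
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    cand <- EBImage::closing(EBImage::Image(cand * 1), brush) > 0
  }
  cand <- cand & masks$disc_mask
  if (!any(cand)) return(empty(thr))
  lab <- EBImage::bwlabel(EBImage::Image(cand * 1))
  sizes <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  cup <- matrix(as.integer(lab) == which.max(sizes),
                nrow(hb$hb), ncol(hb$hb))
  # union with the moment ellipse: restores cup parts occluded by vessels
  # without discarding observed cup pixels outside the fitted ellipse
  if (regularize == "ellipse") cup <- cup | moment_ellipse_fill(cup)
  cup <- cup & masks$disc_mask
  cd <- cup_disc_ratios(cup, masks$disc_mask, vertical_rule)
  structure(list(cup_mask = cup, vertical_cd = cd[["vertical_cd"]],
                 area_cd = cd[["area_cd"]], threshold_used = thr),
            class = "cup_estimate")
}

#' @export
print.cup_estimate <- function(x, ...) {
  cat(sprintf(
    "<cup_estimate> vertical C/D %.3f, area C/D %.3f (threshold %s, %d px)\n",
    x$vertical_cd, x$area_cd,
    if (is.na(x$threshold_used)) "none: contrast gate"
    else sprintf("%.1f Hb%%", x$threshold_used),
    sum(x$cup_mask)))
  invisible(x)
}

#' Cup/disc ratios from masks
#'
#' Vertical C/D is the ratio of the vertical extents of cup and disc
#' measured along the column through the disc centroid (or the maximum such
#' ratio over columns); area C/D is the pixel-count ratio.
#'
#' @param cup_mask,disc_mask Logical matrices; `cup_mask` must be a subset
#'   of `disc_mask`.
#' @param vertical_rule See [estimate_cup()].
#' @return Named numeric vector `c(vertical_cd =, area_cd =)`, both in \[0,1\].
#' @export
cup_disc_ratios <- function(cup_mask, disc_mask,
                            vertical_rule = c("centroid_column", "max_column")) {
  vertical_rule <- match.arg(vertical_rule)
  if (!any(disc_mask)) stop("empty disc mask", call. = FALSE)
  if (any(cup_mask & !disc_mask)) {
    stop("cup mask must be contained in the disc mask", call. = FALSE)
  }
  area_cd <- sum(cup_mask) / sum(disc_mask)
  if (!any(cup_mask)) return(c(vertical_cd = 0, area_cd = 0))
  if (vertical_rule == "centroid_column") {
    ccol <- round(mean(which(disc_mask, arr.ind = TRUE)[, 2]))
    vert <- sum(cup_mask[, ccol]) / sum(disc_mask[, ccol])
  } else {
    cols <- which(colSums(disc_mask) > 0)
    vert <- max(colSums(cup_mask[, cols, drop = FALSE]) /
                  colSums(disc_mask[, cols, drop = FALSE]))
  }
  c(vertical_cd = min(vert, 1), area_cd = min(area_cd, 1))
}

#' Build a normative reference from a cohort of normal eyes
#'
#' Stores, per feature, the mean, SD and the sorted empirical values, so
#' that new measurements can be placed on the normal distribution
#' ([normative_percentile()]).
#'
#' @param data Data frame of normal-eye measurements.
#' @param features Character vector of column names to reference (default:
#'   all numeric columns).
#' @return An object of class `normative_reference`.
#' @export
normative_reference <- function(data, features = NULL) {
  data <- tibble::as_tibble(data)
  features <- features %||%
    names(data)[vapply(data, is.numeric, logical(1))]
  missing <- setdiff(features, names(data))
  if (length(missing)) stop("features not in data: ",
                            paste(missing, collapse = ", "), call. = FALSE)
  values <- purrr::map(rlang::set_names(features), function(f) {
    v <- sort(data[[f]][!is.na(data[[f]])])
    if (length(v) < 20) {
      warning("normative reference for '", f, "' built from only ",
              length(v), " values (< 20)", call. = FALSE)
    }
    v
  })
  stats <- tibble::tibble(
    feature = features,
    mean = vapply(values, mean, numeric(1)),
    sd = vapply(values, sd, numeric(1)),
    n = vapply(values, length, integer(1)))
  if (any(stats$sd <= 0 | is.na(stats$sd))) {
    stop("every referenced feature needs positive SD", call. = FALSE)
  }
  structure(list(stats = stats, values = values),
            class = "normative_reference")
}

#' @export
print.normative_reference <- function(x, ...) {
  cat("<normative_reference>\n")
  print(x$stats)
  invisible(x)
}

#' Empirical percentile of a value in the normal population
#'
#' Midrank convention: `100 * (#below + 0.5 * #equal) / n`. A value below
#' the reference minimum scores 0, above the maximum 100, and the reference
#' median scores 50.
#'
#' @param value Numeric vector of new measurements.
#' @param feature Feature name present in `ref`.
#' @param ref A [normative_reference()].
#' @return Percentiles in \[0, 100\], same length as `value`.
#' @export
normative_percentile <- function(value, feature, ref) {
  stopifnot(inherits(ref, "normative_reference"))
  v <- ref$values[[feature]]
  if (is.null(v)) stop("feature '", feature, "' not in reference", call. = FALSE)
  vapply(value, function(x) {
    if (is.na(x)) return(NA_real_)
    100 * (sum(v < x) + 0.5 * sum(v == x)) / length(v)
  }, numeric(1))
}

#' Persist / load a normative reference as CSV
#'
#' Two plain-text files: `<stem>_stats.csv` (feature, mean, sd, n) and
#' `<stem>_values.csv` (feature, value) with the sorted reference samples.
#'
#' @param ref A [normative_reference()].
#' @param stem Path stem (no extension).
#' @return `stem` invisibly; `read_normative_reference()` returns the object.
#' @export
write_normative_reference <- function(ref, stem) {
  write.csv(ref$stats, paste0(stem, "_stats.csv"), row.names = FALSE)
  long <- purrr::imap(ref$values, ~tibble::tibble(feature = .y, value = .x)) |>
    purrr::list_rbind()
  write.csv(long, paste0(stem, "_values.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_normative_reference
#' @export
read_normative_reference <- function(stem) {
  long <- read.csv(paste0(stem, "_values.csv"))
  wide <- split(long$value, long$feature)
  normative_reference(
    tibble::as_tibble(lapply(wide, function(v) {
      length(v) <- max(lengths(wide)); v
    })),
    features = names(wide))
}
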