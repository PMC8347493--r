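# Perimetric indices: mean deviation (MD), pattern standard deviation
# (PSD / sLV), the rectified PSDr restoring a linear response in advanced
# loss, and the threshold coefficient of variation (TCV), an
# age-independent harmony index.

#' Standard 24-2-like test point grid
#'
#' The 54-point grid at 6-degree spacing offset 3 degrees from the
#' meridians, in right-eye convention (temporal field = positive x, blind
#' spot at (15, +/-3)). The two blind-spot locations are excluded, leaving
#' 52 points.
#'
#' @param include_blind_spot Keep the two blind-spot points; default `FALSE`.
#' @return Tibble with columns `x`, `y` (degrees).
#' @export
grid_242 <- function(include_blind_spot = FALSE) {
  rows <- list(`21` = seq(-9, 9, 6), `15` = seq(-15, 15, 6),
               `9` = seq(-21, 21, 6), `3` = seq(-27, 21, 6))
  g <- purrr::imap(rows, function(xs, y) {
    y <- as.numeric(y)
    tibble::tibble(x = rep(xs, 2), y = rep(c(y, -y), each = length(xs)))
  }) |> purrr::list_rbind()
  if (!include_blind_spot) g <- dplyr::filter(g, !(.data$x == 15 & abs(.data$y) == 3))
  dplyr::arrange(g, dplyr::desc(.data$y), .data$x)
}

#' Construct a visual field
#'
#' Thresholds in dB at visual-field locations, with the metadata the
#' indices need. Left-eye fields are mirrored about the vertical midline on
#' ingest (x -> -x) so that a single right-eye-convention location set
#' serves both eyes. Blind-spot locations (15, +/-3 after mirroring) are
#' dropped with a message if present.
#'
#' @param data Data frame with columns `x`, `y` (degrees) and `threshold`
#'   (dB, >= 0).
#' @param age Subject age in years.
#' @param eye `"right"`, `"left"` or `"unknown"`.
#' @param perimeter Device family label, e.g. `"easyfield"`, `"octopus"`,
#'   `"humphrey"`.
#' @param md_sign_convention How the *device* reports MD:
#'   `"negative-is-loss"` (Humphrey-style, the internal convention) or
#'   `"positive-is-loss"` (Octopus mean defect). Used by [harmonize_md()]
#'   when ingesting device-reported MD values.
#' @return A tibble of class `visual_field` with attributes `age`, `eye`,
#'   `perimeter`, `md_sign_convention`.
#' @export
visual_field <- function(data, age = 50, eye = c("unknown", "right", "left"),
                         perimeter = "generic",
                         md_sign_convention = c("negative-is-loss",
                                                "positive-is-loss")) {
  eye <- match.arg(eye)
  md_sign_convention <- match.arg(md_sign_convention)
  vf <- tibble::as_tibble(data)
  stopifnot(all(c("x", "y", "threshold") %in% names(vf)))
  if (any(vf$threshold < 0)) stop("thresholds must be >= 0 dB", call. = FALSE)
  if (identical(eye, "left")) vf$x <- -vf$x
  bs <- vf$x == 15 & abs(vf$y) == 3
  if (any(bs)) {
    message("dropping ", sum(bs), " blind-spot location(s)")
    vf <- vf[!bs, , drop = FALSE]
  }
  if (anyDuplicated(vf[c("x", "y")])) {
    stop("duplicate visual-field locations", call. = FALSE)
  }
  attr(vf, "age") <- age
  attr(vf, "eye") <- eye
  attr(vf, "perimeter") <- perimeter
  attr(vf, "md_sign_convention") <- md_sign_convention
  class(vf) <- c("visual_field", class(vf))
  vf
}

#' Normative visual-field model
#'
#' Expected (age-corrected) threshold per location: a hill-of-vision
#' `height - ecc_slope * eccentricity` at the reference age, declining by
#' `age_slope` dB per decade. Defaults (33 dB apex, 0.15 dB/deg fall-off,
#' 0.6 dB/decade) are in the range reported for white-on-white perimetry in
#' normal adults.
#'
#' @param age Age (years) for which expected thresholds are produced.
#' @param locations Location tibble (`x`, `y`); default [grid_242()].
#' @param height Apex sensitivity (dB) at `ref_age`.
#' @param ecc_slope Fall-off (dB per degree of eccentricity).
#' @param age_slope Decline (dB per decade of age).
#' @param ref_age Reference age (years).
#' @return A tibble (`x`, `y`, `expected`) of class `normative_vf`.
#' @export
normative_vf <- function(age = 50, locations = grid_242(), height = 33,
                         ecc_slope = 0.15, age_slope = 0.6, ref_age = 45) {
  out <- dplyr::mutate(
    tibble::as_tibble(locations),
    expected = pmax(height - ecc_slope * sqrt(.data$x^2 + .data$y^2) -
                      age_slope * (age - ref_age) / 10, 0))
  if (any(out$expected <= 0)) {
    stop("normative model produced non-positive expected thresholds",
         call. = FALSE)
  }
  class(out) <- c("normative_vf", class(out))
  out
}

# Internal: pointwise deviations threshold - expected, after checking that
# the location sets match exactly.
vf_deviations <- function(vf, norm) {
  j <- dplyr::inner_join(vf, norm, by = c("x", "y"))
  if (nrow(j) != nrow(vf) || nrow(j) != nrow(norm)) {
    stop("visual field and normative model cover different locations (",
         nrow(vf), " vs ", nrow(norm), ", ", nrow(j), " shared)",
         call. = FALSE)
  }
  j$threshold - j$expected
}

#' Mean deviation (MD)
#'
#' Mean of the pointwise differences between measured thresholds and the
#' age-expected values. Internal convention throughout the package:
#' negative MD = loss (Humphrey-style). Octopus devices report the mean
#' *defect* with the opposite sign; use [harmonize_md()] when ingesting
#' device-reported values.
#'
#' @param vf A [visual_field()].
#' @param norm A [normative_vf()] on the same locations.
#' @return MD in dB (negative = loss).
#' @export
mean_deviation <- function(vf, norm) mean(vf_deviations(vf, norm))

#' Harmonize a device-reported MD to the internal sign convention
#'
#' The Octopus family reports mean defect with positive values for loss;
#' for joint analysis its sign is inverted so that every device speaks the
#' internal negative-is-loss convention.
#'
#' @param md Device-reported MD value(s), dB.
#' @param convention `"negative-is-loss"` or `"positive-is-loss"`.
#' @return MD in the internal convention (negative = loss).
#' @export
harmonize_md <- function(md, convention = c("negative-is-loss",
                                            "positive-is-loss")) {
  convention <- match.arg(convention)
  if (convention == "positive-is-loss") -md else md
}

#' Pattern standard deviation (PSD / sLV)
#'
#' Sample standard deviation (n - 1 denominator) of the pointwise
#' deviations: the irregularity of the field relative to its age-expected
#' shape. Location weighting used by commercial devices is not applied.
#'
#' @inheritParams mean_deviation
#' @return PSD in dB (>= 0).
#' @export
pattern_sd <- function(vf, norm) {
  dev <- vf_deviations(vf, norm)
  if (length(dev) < 2) stop("PSD needs at least 2 locations", call. = FALSE)
  sd(dev)
}

#' Rectified PSD (PSDr)
#'
#' PSD grows with defect depth in early and moderate loss but collapses
#' again in advanced loss, when many points reach 0 dB and the field turns
#' uniformly blind. The rectification restores a linear response: once
#' |MD| exceeds 16.33 dB, the excess is added back at a rate of 1/0.84 dB
#' of PSD per dB of MD:
#' \deqn{PSDr = PSD + (|MD| - 16.33)/0.84 \quad \mathrm{if}\ |MD| > 16.33,}
#' and PSDr = PSD otherwise. The transformation is continuous at the
#' boundary and monotone in |MD|. `op = "multiply"` selects the alternative
#' reading `PSD + (|MD| - 16.33) * 0.84`.
#'
#' @param psd PSD in dB (>= 0).
#' @param md MD in dB (either sign convention: only |MD| is used).
#' @param op `"divide"` (default) or `"multiply"`.
#' @return PSDr in dB.
#' @export
rectify_psd <- function(psd, md, op = c("divide", "multiply")) {
  op <- match.arg(op)
  stopifnot(all(psd >= 0))
  excess <- pmax(abs(md) - 16.33, 0)
  psd + if (op == "divide") excess / 0.84 else excess * 0.84
}

#' Default TCV positions
#'
#' The 16 locations of the 24-2-like grid with |x| and |y| in {3, 9}
#' degrees: the four innermost rings, symmetric in fours about both
#' meridians. The set ships as an editable CSV
#' (`system.file("extdata", "tcv_positions.csv", package = "hbdisc")`).
#'
#' @return Tibble with columns `x`, `y` (16 rows).
#' @export
tcv_positions <- function() {
  p <- read.csv(system.file("extdata", "tcv_positions.csv",
                            package = "hbdisc"))
  tibble::as_tibble(p)
}

#' Threshold coefficient of variation (TCV)
#'
#' Harmony index of the field taken on its own, with no normative
#' comparison and no age term: 100 times the sample SD of the thresholds at
#' 16 symmetric positions divided by their mean. A harmonious field — close
#' to or far from normal average sensitivity — scores low; an irregular one
#' scores high, and a uniform scaling of all thresholds leaves TCV
#' unchanged.
#'
#' When absolute scotomas (0 dB points) are present both the SD and the
#' mean are adjusted: the default strategy excludes 0 dB points from both
#' (`"exclude"`); `"inflate"` instead computes TCV over the non-zero points
#' and scales it by 16/n_used. The number of points actually used is
#' attached as attribute `n_used`.
#'
#' @param vf A [visual_field()].
#' @param positions Tibble of the 16 positions (`x`, `y`); default
#'   [tcv_positions()].
#' @param scotoma_strategy `"exclude"` (default) or `"inflate"`.
#' @return TCV in percent, with attribute `n_used`; `NA` (flagged with a
#'   warning) if every used point is an absolute scotoma.
#' @export
tcv <- function(vf, positions = tcv_positions(),
                scotoma_strategy = c("exclude", "inflate")) {
  scotoma_strategy <- match.arg(scotoma_strategy)
  j <- dplyr::inner_join(tibble::as_tibble(positions), vf, by = c("x", "y"))
  if (nrow(j) != nrow(positions)) {
    stop("visual field is missing ", nrow(positions) - nrow(j),
         " of the TCV positions", call. = FALSE)
  }
  th <- j$threshold
  used <- th[th > 0]
  n_used <- length(used)
  if (n_used < 2 || mean(used) == 0) {
    warning("TCV undefined: fewer than 2 non-zero thresholds", call. = FALSE)
    return(structure(NA_real_, n_used = n_used))
  }
  val <- 100 * sd(used) / mean(used)
  if (scotoma_strategy == "inflate" && n_used < nrow(positions)) {
    val <- val * nrow(positions) / n_used
  }
  structure(val, n_used = n_used)
}

#' All perimetric indices of a field
#'
#' @inheritParams mean_deviation
#' @param positions TCV positions; default [tcv_positions()].
#' @param ... Passed to [tcv()] and [rectify_psd()].
#' @return One-row tibble: `md`, `psd`, `psdr`, `tcv`, `tcv_n_used`.
#' @export
vf_indices <- function(vf, norm = NULL, positions = tcv_positions(), ...) {
  norm <- norm %||% normative_vf(age = attr(vf, "age"),
                                 locations = vf[c("x", "y")])
  md <- mean_deviation(vf, norm)
  psd <- pattern_sd(vf, norm)
  tv <- tcv(vf, positions, ...)
  tibble::tibble(md = md, psd = psd, psdr = rectify_psd(psd, md),
                 tcv = as.numeric(tv), tcv_n_used = attr(tv, "n_used"))
}

#' Read a visual field from CSV (+ optional JSON header)
#'
#' The CSV must have columns `x`, `y`, `threshold`; the JSON header (if
#' present at `<path>.json` or given explicitly) may carry `age`, `eye`,
#' `perimeter`, `md_sign_convention`.
#'
#' @param path CSV path.
#' @param header Optional path to the JSON header.
#' @return A [visual_field()].
#' @export
read_visual_field <- function(path, header = NULL) {
  df <- read.csv(path)
  header <- header %||% if (file.exists(paste0(path, ".json")))
    paste0(path, ".json") else NULL
  meta <- if (!is.null(header)) jsonlite::read_json(header) else list()
  visual_field(df,
               age = meta$age %||% 50,
               eye = meta$eye %||% "unknown",
               perimeter = meta$perimeter %||% "generic",
               md_sign_convention = meta$md_sign_convention %||%
                 "negative-is-loss")
}

#' Plot a visual field
#'
#' Greyscale-style map of thresholds at their field locations.
#'
#' @param object A `visual_field`.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot visual_field
#' @export
autoplot.visual_field <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$threshold),
                       width = 5.5, height = 5.5) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "dB", limits = c(0, NA)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (deg)", y = "y (deg)",
                  title = "Visual field thresholds")
}
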