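# Seeded generators: disc phantoms with known cup geometry and vessel
# trees, 24-2-like visual fields with template defects, and binormal
# two-group cohorts with stated effect sizes. Every generator takes an
# explicit seed and is bit-reproducible; adequacy is defined by the
# recovery tests, not by photorealism.

#' Phantom specification
#'
#' Geometry and photometry of a synthetic optic-nerve-head image. Defaults
#' describe a 256 px square frame with a disc of radius 40 px, a concentric
#' pale cup covering half the disc radius, rim tissue at 65% of the vessel
#' haemoglobin signal and cup tissue at 30%, six vessels crossing the disc
#' vertically, and mild sensor noise (SD 1 on the 8-bit scale).
#'
#' @param size Image side, px.
#' @param disc_center `(row, col)` of the disc centre; default image centre.
#' @param disc_radius Disc radius, px.
#' @param cup_fraction Cup radius as a fraction of disc radius in \[0, 1).
#' @param rim_hb,cup_hb Tissue haemoglobin, % of the vessel reference.
#' @param vessel_ratio Haemoglobin ratio of vessel pixels; default 0.75.
#' @param n_vessels Number of vessel strokes crossing the disc.
#' @param vessel_width Stroke width, px.
#' @param tortuosity Lateral wander of vessel control points, as a fraction
#'   of the disc radius.
#' @param noise_sd Per-channel Gaussian noise SD (8-bit units).
#' @param background RGB of the fundus background (8-bit).
#' @param seed Mandatory RNG seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(size = 256, disc_center = NULL, disc_radius = 40,
                         cup_fraction = 0.5, rim_hb = 65, cup_hb = 30,
                         vessel_ratio = 0.75, n_vessels = 6, vessel_width = 3,
                         tortuosity = 0.25, noise_sd = 1,
                         background = c(60, 50, 30), seed) {
  if (missing(seed)) stop("phantom_spec requires an explicit seed", call. = FALSE)
  if (cup_fraction < 0 || cup_fraction >= 1) {
    stop("cup_fraction must be in [0, 1)", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(size = size,
                 disc_center = disc_center %||% c(size / 2, size / 2),
                 disc_radius = disc_radius, cup_fraction = cup_fraction,
                 rim_hb = rim_hb, cup_hb = cup_hb,
                 vessel_ratio = vessel_ratio, n_vessels = n_vessels,
                 vessel_width = vessel_width, tortuosity = tortuosity,
                 noise_sd = noise_sd, background = background, seed = seed),
            class = "phantom_spec")
}

# Rasterize a quadratic Bezier stroke of the given width into a logical mask.
bezier_stroke <- function(mask, p0, p1, p2, width) {
  t <- seq(0, 1, length.out = 4 * max(dim(mask)))
  pts <- outer((1 - t)^2, p0) + outer(2 * t * (1 - t), p1) + outer(t^2, p2)
  half <- width / 2
  rr <- nrow(mask); cc <- ncol(mask)
  for (k in seq_along(t)) {
    r0 <- max(1, ceiling(pts[k, 1] - half)); r1 <- min(rr, floor(pts[k, 1] + half))
    c0 <- max(1, ceiling(pts[k, 2] - half)); c1 <- min(cc, floor(pts[k, 2] + half))
    if (r0 <= r1 && c0 <= c1) mask[r0:r1, c0:c1] <- TRUE
  }
  mask
}

#' Render a disc phantom
#'
#' Produces a [fundus_image()] together with ground-truth [disc_masks()]
#' and the true cup geometry. The cup is rendered paler (higher R, lower
#' (R-G)/R contrast is *reduced* relative to rim — less haemoglobin), the
#' rim carries intermediate haemoglobin, and the vessels have the highest
#' ratio of all. Deterministic given the spec's seed.
#'
#' @param spec A [phantom_spec()].
#' @return List: `image` (`fundus_image`), `masks` (`disc_masks`, truth),
#'   `cup` (list `cup_mask`, `vertical_cd`, `area_cd` — geometric truth),
#'   `spec`.
#' @export
make_disc_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  n <- spec$size
  cy <- spec$disc_center[1]; cx <- spec$disc_center[2]
  R <- spec$disc_radius
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dist <- sqrt((rows - cy)^2 + (cols - cx)^2)
  disc <- dist <= R
  cup <- dist <= spec$cup_fraction * R

  red <- matrix(spec$background[1], n, n)
  green <- matrix(spec$background[2], n, n)
  blue <- matrix(spec$background[3], n, n)

  ref <- spec$vessel_ratio
  # rim tissue: moderately bright, Hb at rim_hb% of the vessel reference
  red[disc] <- 220
  green[disc] <- 220 * (1 - ref * spec$rim_hb / 100)
  blue[disc] <- 90
  # cup: paler (brighter red, much weaker red/green contrast)
  red[cup] <- 235
  green[cup] <- 235 * (1 - ref * spec$cup_hb / 100)
  blue[cup] <- 110

  vessel <- matrix(FALSE, n, n)
  if (spec$n_vessels > 0) {
    for (v in seq_len(spec$n_vessels)) {
      o <- runif(3, -0.6, 0.6) * R
      wig <- rnorm(1, 0, spec$tortuosity * R)
      p0 <- c(cy - R - 8, cx + o[1])
      p1 <- c(cy, cx + o[2] + wig)
      p2 <- c(cy + R + 8, cx + o[3])
      vessel <- bezier_stroke(vessel, p0, p1, p2, spec$vessel_width)
    }
    red[vessel] <- 180
    green[vessel] <- 180 * (1 - ref)
    blue[vessel] <- 40
  }
  if (spec$noise_sd > 0) {
    red <- pmax(red + rnorm(n * n, 0, spec$noise_sd), 0)
    green <- pmax(green + rnorm(n * n, 0, spec$noise_sd), 0)
    blue <- pmax(blue + rnorm(n * n, 0, spec$noise_sd), 0)
  }
  ncol_disc <- sum(disc[, round(cx)])
  vert <- if (any(cup)) sum(cup[, round(cx)]) / ncol_disc else 0
  list(
    image = fundus_image(red, green, blue, camera_id = "phantom",
                         eye = "right"),
    masks = disc_masks(disc, vessel),
    cup = list(cup_mask = cup,
               vertical_cd = vert,
               area_cd = sum(cup) / sum(disc)),
    spec = spec
  )
}

#' Visual-field defect templates
#'
#' Deterministic location sets on the 24-2-like grid:
#' * `none` — empty;
#' * `arcuate` — a superior Bjerrum-region sweep (eccentricity 9–22
#'   degrees, superior hemifield, sparing the far nasal edge);
#' * `nasal_step` — superior nasal wedge (x <= -15);
#' * `advanced` — the whole field (use depth >= 17 dB so |MD| crosses the
#'   16.33 dB rectification knee).
#'
#' @param defect Template name.
#' @param locations Location tibble; default [grid_242()].
#' @return Logical vector marking template membership per location row.
#' @export
vf_defect_template <- function(defect = c("none", "arcuate", "nasal_step",
                                          "advanced"),
                               locations = grid_242()) {
  defect <- match.arg(defect)
  x <- locations$x; y <- locations$y
  ecc <- sqrt(x^2 + y^2)
  switch(defect,
         none = rep(FALSE, nrow(locations)),
         arcuate = y >= 3 & ecc >= 9 & ecc <= 22 & x <= 9,
         nasal_step = x <= -15 & y >= 3,
         advanced = rep(TRUE, nrow(locations)))
}

#' Generate a synthetic visual field
#'
#' Thresholds are the age-expected normative surface minus `depth` dB on
#' the defect template minus Gaussian noise, floored at 0 dB. With zero
#' noise, MD equals exactly `-depth * (template size / number of
#' locations)` provided no point is floored.
#'
#' @param defect Template name (see [vf_defect_template()]).
#' @param depth Defect depth, dB (>= 0).
#' @param noise_sd Per-point threshold noise SD, dB.
#' @param age Subject age, years.
#' @param seed Mandatory RNG seed.
#' @param eye `"right"` or `"left"`.
#' @param locations Location tibble; default [grid_242()].
#' @return List: `vf` (a [visual_field()]), `true_deviation` (tibble `x`,
#'   `y`, `deviation` — the noise-free deviation map), `template`.
#' @export
make_vf <- function(defect = "none", depth = 10, noise_sd = 1, age = 55,
                    seed, eye = "right", locations = grid_242()) {
  if (missing(seed)) stop("make_vf requires an explicit seed", call. = FALSE)
  if (depth < 0) stop("depth must be >= 0", call. = FALSE)
  set.seed(seed)
  norm <- normative_vf(age = age, locations = locations)
  tmpl <- vf_defect_template(defect, locations)
  dev_true <- -depth * tmpl
  th <- pmax(norm$expected + dev_true + rnorm(nrow(norm), 0, noise_sd), 0)
  df <- tibble::tibble(x = locations$x, y = locations$y, threshold = th)
  if (identical(eye, "left")) df$x <- -df$x   # ingest mirrors it back
  list(vf = visual_field(df, age = age, eye = eye),
       true_deviation = tibble::tibble(x = locations$x, y = locations$y,
                                       deviation = dev_true),
       template = tmpl)
}

#' Cohort specification
#'
#' @param n_normal,n_case Group sizes (>= 2 each; default 100 per group).
#' @param d Per-index case shift in normal-SD units (recycled over
#'   `indices`). The analytic single-index AUC is `pnorm(d / sqrt(2))`.
#' @param indices Index column names; default `c("GDF", "TCV", "PSDr")`.
#' @param rho Exchangeable inter-index correlation (ignored when `Sigma`
#'   given); default 0.5, about what related structural/functional
#'   glaucoma indices show.
#' @param Sigma Optional full correlation matrix.
#' @param n_suspect,d_suspect Optional third group of glaucoma suspects
#'   with its own (usually smaller) shift; default none.
#' @param seed Mandatory RNG seed.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 100, n_case = 100, d = 1,
                        indices = c("GDF", "TCV",
                                                             "PSDr"),
                        rho = 0.5, Sigma = NULL, n_suspect = 0,
                        d_suspect = 0, seed) {
  if (missing(seed)) stop("cohort_spec requires an explicit seed", call. = FALSE)
  if (n_normal < 2 || n_case < 2) stop("need n >= 2 per group", call. = FALSE)
  p <- length(indices)
  Sigma <- Sigma %||% ((1 - rho) * diag(p) + rho)
  if (!isSymmetric(unname(Sigma)) || min(eigen(Sigma, TRUE, TRUE)$values) < -1e-8) {
    stop("correlation matrix must be symmetric positive semi-definite",
         call. = FALSE)
  }
  structure(list(n_normal = n_normal, n_case = n_case,
                 d = rep_len(d, p), indices = indices, Sigma = Sigma,
                 n_suspect = n_suspect, d_suspect = rep_len(d_suspect, p),
                 seed = seed),
            class = "cohort_spec")
}

#' Generate a binormal two-group cohort
#'
#' Normals are standard multivariate normal over the index columns; cases
#' (and optional suspects) are shifted by `d` normal-SDs per index, under
#' the spec's correlation structure. Shifts are applied in the disease
#' direction of each index (an index where lower raw values mean disease,
#' such as GDF or MD, is shifted downwards), so generated cohorts carry
#' realistic orientations. The analytic AUC of a single index is
#' `pnorm(d / sqrt(2))`.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble: `eye_id`, `subject_id`, `group` (`normal` /
#'   `confirmed` / `suspect`), and one column per index.
#' @export
make_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  p <- length(spec$indices)
  sgn <- vapply(spec$indices, function(ix)
    if (default_higher_is_worse(ix, quiet = TRUE)) 1 else -1, numeric(1))
  draw <- function(n, shift) {
    X <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = spec$Sigma)
    X <- sweep(X, 2, shift * sgn, `+`)
    colnames(X) <- spec$indices
    tibble::as_tibble(X)
  }
  blocks <- list(
    dplyr::mutate(draw(spec$n_normal, 0), group = "normal"),
    dplyr::mutate(draw(spec$n_case, spec$d), group = "confirmed"))
  if (spec$n_suspect > 0) {
    blocks <- c(blocks, list(
      dplyr::mutate(draw(spec$n_suspect, spec$d_suspect), group = "suspect")))
  }
  out <- purrr::list_rbind(blocks)
  dplyr::bind_cols(
    tibble::tibble(eye_id = sprintf("eye%04d", seq_len(nrow(out))),
                   subject_id = sprintf("subj%04d", seq_len(nrow(out)))),
    out)
}
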