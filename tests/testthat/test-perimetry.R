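test_that("the 24-2-like grid has 52 points, symmetric, blind spot excluded", {
  g <- grid_242()
  expect_equal(nrow(g), 52)
  expect_false(any(g$x == 15 & abs(g$y) == 3))
  expect_equal(nrow(grid_242(include_blind_spot = TRUE)), 54)
  # vertical symmetry of the retained set
  expect_setequal(paste(g$x, g$y), paste(g$x, -g$y))
})

test_that("MD is the mean pointwise deviation, linear in uniform depression", {
  norm <- normative_vf(age = 50)
  vf0 <- visual_field(data.frame(x = norm$x, y = norm$y,
                                 threshold = norm$expected), age = 50)
  expect_equal(mean_deviation(vf0, norm), 0)
  expect_equal(pattern_sd(vf0, norm), 0)
  for (c in c(2, 5, 11.5)) {
    vfc <- visual_field(data.frame(x = norm$x, y = norm$y,
                                   threshold = pmax(norm$expected - c, 0)),
                        age = 50)
    expect_equal(mean_deviation(vfc, norm), -c)
    expect_equal(pattern_sd(vfc, norm), 0, tolerance = 1e-12)
  }
  bad <- normative_vf(age = 50, locations = grid_242()[1:30, ])
  expect_error(mean_deviation(vf0, bad), "different locations")
})

test_that("Octopus-style MD values are sign-inverted on harmonization", {
  expect_equal(harmonize_md(5, "positive-is-loss"), -5)
  expect_equal(harmonize_md(-5, "negative-is-loss"), -5)
  expect_equal(harmonize_md(c(0, 3.2), "positive-is-loss"), c(0, -3.2))
})

test_that("PSD matches closed-form sample SDs on constructed deviation sets", {
  norm <- normative_vf(age = 50)
  # 26 points at 0 deviation, 26 at -8
  dev <- rep(c(0, -8), each = 26)
  vf <- visual_field(data.frame(x = norm$x, y = norm$y,
                                threshold = norm$expected + dev), age = 50)
  expect_equal(pattern_sd(vf, norm), sqrt(26 * 2 * 16 / 51), tolerance = 1e-12)
  expect_equal(pattern_sd(vf, norm), 4.039, tolerance = 1e-3)
  # one -20 point among 51 zeros: ss = 400 * 51/52
  dev2 <- c(-20, rep(0, 51))
  vf2 <- visual_field(data.frame(x = norm$x, y = norm$y,
                                 threshold = norm$expected + dev2), age = 50)
  expect_equal(pattern_sd(vf2, norm), sqrt(400 / 52), tolerance = 1e-12)
  expect_equal(pattern_sd(vf2, norm), 2.772, tolerance = 1e-3)
})

test_that("rectify_psd applies the linearising correction beyond 16.33 dB", {
  expect_equal(rectify_psd(5, -10), 5)
  expect_equal(rectify_psd(5, -16.33), 5)        # boundary: no jump
  expect_equal(rectify_psd(8, -20), 8 + (20 - 16.33) / 0.84, tolerance = 1e-12)
  expect_equal(rectify_psd(8, -20), 12.369, tolerance = 1e-3)
  expect_equal(rectify_psd(8, 20), rectify_psd(8, -20))   # |MD| only
  # continuity and monotonicity in |MD|
  eps <- 1e-9
  expect_equal(rectify_psd(4, -(16.33 + eps)), rectify_psd(4, -16.33),
               tolerance = 1e-6)
  mds <- seq(0, 30, by = 0.25)
  expect_true(all(diff(rectify_psd(3, -mds)) >= 0))
  # PSDr = PSD whenever |MD| <= 16.33, exactly
  expect_identical(rectify_psd(seq(0, 10), -16.33), as.numeric(seq(0, 10)))
  # the alternative multiplicative reading
  expect_equal(rectify_psd(8, -20, op = "multiply"), 8 + (20 - 16.33) * 0.84)
})

test_that("TCV is 100*SD/mean over 16 positions, scale-invariant, age-free", {
  expect_equal(as.numeric(tcv(tcv_field(rep(30, 16)))), 0)
  v <- rep(c(28, 32), each = 8)
  expect_equal(as.numeric(tcv(tcv_field(v))), 100 * sd(v) / 30,
               tolerance = 1e-12)
  expect_equal(as.numeric(tcv(tcv_field(v))), 6.885, tolerance = 1e-3)
  # scale invariance
  set.seed(51)
  for (i in 1:10) {
    w <- runif(16, 5, 35)
    k <- runif(1, 0.5, 3)
    expect_equal(as.numeric(tcv(tcv_field(w * k))),
                 as.numeric(tcv(tcv_field(w))), tolerance = 1e-9)
  }
  # no normative argument exists: the index is structurally age-independent
  expect_false("norm" %in% names(formals(tcv)))
})

test_that("TCV scotoma handling adjusts both SD and mean", {
  v <- c(rep(30, 12), rep(0, 4))
  t_ex <- tcv(tcv_field(v))
  expect_equal(attr(t_ex, "n_used"), 12)
  expect_equal(as.numeric(t_ex), 0)       # the 12 surviving points are flat
  t_in <- tcv(tcv_field(c(runif(12, 20, 30), rep(0, 4))),
              scotoma_strategy = "inflate")
  expect_equal(attr(t_in, "n_used"), 12)
  # inflation scales by 16/n_used
  v2 <- c(runif(12, 20, 30), rep(0, 4))
  expect_equal(as.numeric(tcv(tcv_field(v2), scotoma_strategy = "inflate")),
               as.numeric(tcv(tcv_field(v2))) * 16 / 12, tolerance = 1e-12)
  expect_warning(t_all0 <- tcv(tcv_field(rep(0, 16))), "undefined")
  expect_true(is.na(t_all0))
})

test_that("left-eye fields are mirrored on ingest", {
  norm <- normative_vf(age = 50)
  # a defect confined to x = -27 (nasal edge) of a left-eye report appears
  # at x = +27 pre-mirroring in device coordinates
  dev <- ifelse(norm$x == -27, -10, 0)
  right <- visual_field(data.frame(x = norm$x, y = norm$y,
                                   threshold = norm$expected + dev),
                        age = 50, eye = "right")
  left_raw <- data.frame(x = -norm$x, y = norm$y,
                         threshold = norm$expected + dev)
  left <- visual_field(left_raw, age = 50, eye = "left")
  expect_equal(mean_deviation(left, norm), mean_deviation(right, norm))
  expect_equal(sort(left$x), sort(right$x))
})

test_that("vf_indices bundles MD/PSD/PSDr/TCV and the CSV reader works", {
  sim <- make_vf("advanced", depth = 22, noise_sd = 0, seed = 52)
  idx <- vf_indices(sim$vf)
  expect_equal(idx$md, -22)
  expect_gt(abs(idx$md), 16.33)
  expect_gt(idx$psdr, idx$psd)
  expect_gte(idx$psd, 0)

  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(as.data.frame(sim$vf), f, row.names = FALSE)
  jsonlite::write_json(list(age = 55, eye = "right", perimeter = "octopus",
                            md_sign_convention = "positive-is-loss"),
                       paste0(f, ".json"), auto_unbox = TRUE)
  vf2 <- read_visual_field(f)
  expect_equal(attr(vf2, "md_sign_convention"), "positive-is-loss")
  expect_equal(vf_indices(vf2)$md, -22)
})

test_that("visual_field enforces its invariants", {
  expect_error(visual_field(data.frame(x = 3, y = 3, threshold = -1)),
               ">= 0 dB")
  expect_message(
    vf <- visual_field(data.frame(x = c(15, 3), y = c(3, 3),
                                  threshold = c(10, 20))),
    "blind-spot")
  expect_equal(nrow(vf), 1)
  expect_error(visual_field(data.frame(x = c(3, 3), y = c(3, 3),
                                       threshold = c(1, 2))),
               "duplicate")
})
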