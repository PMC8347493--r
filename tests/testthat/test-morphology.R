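test_that("sector profile partitions the disc and averages Hb per wedge", {
  # uniform disc (no cup, no real vessels): the reference pixels carry the
  # same colour as the tissue, so every defined pixel sits at exactly 100%
  ph <- make_disc_phantom(phantom_spec(seed = 21, n_vessels = 0,
                                       noise_sd = 0, cup_fraction = 0,
                                       cup_hb = 65))
  masks <- disc_masks(ph$masks$disc_mask, circle_mask(256, 128, 128, 3))
  hb <- hb_percentage_map(ph$image, masks)
  for (k in c(4, 12, 24)) {
    s <- sectorize(hb, masks, n_sectors = k)
    expect_equal(nrow(s), k)
    expect_equal(sum(s$area_pct), 100, tolerance = 1e-6)
    expect_equal(s$mean_hb, rep(100, k), tolerance = 1e-9)
  }
  expect_error(sectorize(hb, masks, n_sectors = 3), ">= 4")
})

test_that("hemifield contrast lands in the right sectors, mirrored across eyes", {
  # upper half of the disc Hb 40, lower half Hb 80 (image rows above/below
  # centre); no vessels so every pixel is defined
  n <- 128
  disc <- circle_mask(n, 64, 64, 40)
  ref <- 0.75
  red <- matrix(200, n, n)
  green <- matrix(200 * (1 - ref * 0.60), n, n)
  up <- row(red) < 64
  green[up] <- 200 * (1 - ref * 0.40)
  green[!up] <- 200 * (1 - ref * 0.80)
  vess <- matrix(FALSE, n, n); vess[64, 30:98] <- TRUE
  green[vess] <- 200 * (1 - ref)        # vessel pixels at the reference colour
  img <- px_image(red, green, matrix(50, n, n))
  hb <- hb_percentage_map(img, disc_masks(disc, vess))
  s <- sectorize(hb, disc_masks(disc, vess), n_sectors = 4, eye = "right")
  # superior (upper image half) is at 270 deg, inferior at 90
  expect_equal(s$mean_hb[s$angle_center == 270], 40, tolerance = 2)
  expect_equal(s$mean_hb[s$angle_center == 90], 80, tolerance = 2)
  # a left eye mirrors about the vertical axis: superior stays superior
  sl <- sectorize(hb, disc_masks(disc, vess), n_sectors = 4, eye = "left")
  expect_equal(sl$mean_hb[sl$angle_center == 270], 40, tolerance = 2)
})

test_that("cup_disc_ratios handles the degenerate and exact geometric cases", {
  disc <- circle_mask(64, 32, 32, 20)
  none <- matrix(FALSE, 64, 64)
  expect_equal(unname(cup_disc_ratios(none, disc)), c(0, 0))
  expect_equal(unname(cup_disc_ratios(disc, disc)), c(1, 1))
  cup <- circle_mask(64, 32, 32, 10)
  cd <- cup_disc_ratios(cup, disc)
  expect_lt(abs(cd[["vertical_cd"]] - 0.5), 0.02)
  expect_lt(abs(cd[["area_cd"]] - 0.25), 0.02)
  expect_error(cup_disc_ratios(none, none), "empty disc")
  expect_error(cup_disc_ratios(disc, cup), "contained")
})

test_that("estimate_cup recovers a concentric pale core and gates on contrast", {
  # phantom with cup radius 0.6 x disc radius, zero noise
  ph <- make_disc_phantom(phantom_spec(cup_fraction = 0.6, noise_sd = 0,
                                       seed = 5))
  hb <- hb_percentage_map(ph$image, ph$masks)
  cup <- estimate_cup(hb, ph$masks)
  expect_lt(abs(cup$vertical_cd - 0.60), 0.05)
  expect_lt(abs(cup$area_cd - 0.36), 0.05)
  expect_true(all(cup$cup_mask <= ph$masks$disc_mask))

  # uniform disc -> contrast gate -> empty cup
  ph0 <- make_disc_phantom(phantom_spec(cup_fraction = 0, cup_hb = 65,
                                        noise_sd = 0, seed = 5))
  hb0 <- hb_percentage_map(ph0$image, ph0$masks)
  cup0 <- estimate_cup(hb0, ph0$masks)
  expect_equal(cup0$vertical_cd, 0)
  expect_equal(cup0$area_cd, 0)
  expect_false(any(cup0$cup_mask))

  tiny_disc <- circle_mask(64, 32, 32, 4)
  tiny_vess <- matrix(FALSE, 64, 64); tiny_vess[32, 29:35] <- TRUE
  tiny_img <- px_image(matrix(200, 64, 64), matrix(80, 64, 64))
  tiny_hb <- hb_percentage_map(tiny_img, disc_masks(tiny_disc, tiny_vess))
  expect_error(estimate_cup(tiny_hb, disc_masks(tiny_disc, tiny_vess)),
               "fewer than")
})

test_that("cup grows monotonically with the threshold", {
  ph <- make_disc_phantom(phantom_spec(cup_fraction = 0.5, seed = 6))
  hb <- hb_percentage_map(ph$image, ph$masks)
  thr <- c(35, 45, 55, 75)
  ests <- lapply(thr, function(t) estimate_cup(hb, ph$masks, threshold = t))
  vcd <- vapply(ests, `[[`, numeric(1), "vertical_cd")
  acd <- vapply(ests, `[[`, numeric(1), "area_cd")
  expect_true(all(diff(vcd) >= 0))
  expect_true(all(diff(acd) >= 0))
})

test_that("estimate_cup inherits gain invariance from the colorimetry", {
  ph <- make_disc_phantom(phantom_spec(seed = 8))
  img2 <- ph$image
  for (ch in c("red", "green", "blue")) img2[[ch]] <- img2[[ch]] * 2.3
  c1 <- estimate_cup(hb_percentage_map(ph$image, ph$masks), ph$masks)
  c2 <- estimate_cup(hb_percentage_map(img2, ph$masks), ph$masks)
  expect_identical(c1$cup_mask, c2$cup_mask)
  expect_equal(c1$vertical_cd, c2$vertical_cd)
})

test_that("normative percentiles use midranks", {
  ref <- normative_reference(
    data.frame(v = c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)), "v") |>
    suppressWarnings()
  expect_equal(normative_percentile(55, "v", ref), 50)   # reference median
  expect_equal(normative_percentile(5, "v", ref), 0)     # below minimum
  expect_equal(normative_percentile(30, "v", ref), 25)   # 3rd smallest of 10
  expect_equal(normative_percentile(101, "v", ref), 100)
  expect_error(normative_percentile(1, "nope", ref), "not in reference")
})

test_that("normative reference warns on small cohorts and round-trips via CSV", {
  small <- data.frame(a = rnorm(10))
  expect_warning(normative_reference(small, "a"), "only 10")
  set.seed(9)
  big <- data.frame(a = rnorm(50), b = runif(50))
  ref <- normative_reference(big)
  stem <- withr::local_tempfile()
  write_normative_reference(ref, stem)
  back <- read_normative_reference(stem)
  expect_equal(back$stats$mean, ref$stats$mean, tolerance = 1e-12)
  expect_equal(back$values$a, ref$values$a, tolerance = 1e-12)
})
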