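test_that("zero contrast gives a spatially constant cube at the mean level", {
  sc <- generate_scene(scene_model(size = 16, contrast = 0, mean_level = 3),
                       seed = 1)
  expect_equal(dim(sc$cube), c(16, 16, 33))
  expect_true(all(sc$cube == 3))
})

test_that("scene generation is deterministic under a fixed seed", {
  m <- scene_model(size = 24)
  expect_identical(generate_scene(m, seed = 7)$cube,
                   generate_scene(m, seed = 7)$cube)
  expect_false(identical(generate_scene(m, seed = 7)$cube,
                         generate_scene(m, seed = 8)$cube))
})

test_that("invalid scene parameters are rejected", {
  expect_conelearn_error(scene_model(size = 1), "conelearn_invalid_parameter")
  expect_conelearn_error(scene_model(spectral_corr_scale = 0),
                         "conelearn_invalid_parameter")
})

test_that("ensemble correlations decay with distance and wavelength gap", {
  # Monte-Carlo version of the generator's two decay axes over 50 scenes:
  # corr falls with pixel distance at fixed band, and with band separation
  # (0 vs 320 nm) at fixed distance 1.
  n_sc <- 50
  m <- scene_model(size = 32)
  p0 <- c(); p1 <- c(); p8 <- c(); p1_far <- c()
  for (s in seq_len(n_sc)) {
    sc <- generate_scene(m, seed = s)
    b1 <- sc$cube[, , 1]
    p0 <- c(p0, b1[1:20, 16])
    p1 <- c(p1, b1[1:20 + 1, 16])
    p8 <- c(p8, b1[1:20 + 8, 16])
    p1_far <- c(p1_far, sc$cube[1:20 + 1, 16, 33])  # 320 nm away
  }
  c_d1 <- cor(p0, p1); c_d8 <- cor(p0, p8); c_d1_320 <- cor(p0, p1_far)
  expect_gt(c_d1, c_d8)          # spatial decay
  expect_gt(c_d1, c_d1_320)      # spectral decay at fixed distance
  expect_gt(c_d8, 0)
})

test_that("quadratic band extrapolation recovers quadratic spectra exactly", {
  wl <- standard_wavelengths()
  cube <- quadratic_cube()
  full <- hyperspectral_image(cube, wl)
  trunc <- hyperspectral_image(cube[, , 3:33], wl[3:33])  # drop 400, 410
  out <- extrapolate_bands(trunc)
  expect_equal(out$wavelengths, wl)
  expect_equal(out$cube[, , 3:33], cube[, , 3:33])  # existing bands untouched
  expect_equal(out$cube, full$cube, tolerance = 1e-10)
})

test_that("extrapolation continues constants and lines exactly, at either end", {
  wl <- standard_wavelengths()
  const <- hyperspectral_image(array(2.5, c(3, 3, 31)), wl[1:31])
  out <- extrapolate_bands(const)
  expect_true(all(abs(out$cube - 2.5) < 1e-10))
  lin <- array(rep(0.01 * wl[3:33], each = 9), c(3, 3, 31))
  out2 <- extrapolate_bands(hyperspectral_image(lin, wl[3:33]))
  expect_equal(out2$cube[1, 1, 1:2], 0.01 * wl[1:2], tolerance = 1e-10)
})

test_that("extrapolated negatives are clamped to zero", {
  wl <- standard_wavelengths()
  # steeply falling line hits zero below 420 nm
  vals <- pmax(0.001 * (standard_wavelengths()[3:33] - 430), 0)
  vals[1:3] <- c(0.001 * 10, 0.001 * 20, 0.001 * 30) # increasing from 420
  lin <- array(rep(vals, each = 4), c(2, 2, 31))
  out <- extrapolate_bands(hyperspectral_image(lin, wl[3:33]))
  expect_true(all(out$cube >= 0))
})

test_that("blur is the identity at sigma zero and preserves constants", {
  sc <- generate_scene(scene_model(size = 24), seed = 2)
  expect_identical(blur_image(sc, 0)$cube, sc$cube)
  const <- hyperspectral_image(array(1.5, c(16, 16, 33)))
  expect_equal(blur_image(const, 4)$cube, const$cube, tolerance = 1e-12)
  expect_conelearn_error(blur_image(sc, -1), "conelearn_invalid_parameter")
})

test_that("blurring a delta image spreads mass with the kernel's moments", {
  cube <- array(0, c(65, 65, 33))
  cube[33, 33, ] <- 1
  out <- blur_image(hyperspectral_image(cube), 4)
  spot <- out$cube[, , 5]
  expect_equal(sum(spot), 1, tolerance = 1e-8)          # mass preserved
  xs <- rowSums(spot)
  mu <- sum(xs * seq_len(65))
  sdv <- sqrt(sum(xs * (seq_len(65) - mu)^2))
  expect_equal(mu, 33, tolerance = 1e-6)
  expect_equal(sdv, 4, tolerance = 0.02)                # sample sd ~ sigma
})

test_that("blur commutes with band permutation (spatial-only operator)", {
  sc <- generate_scene(scene_model(size = 16), seed = 5)
  perm <- c(17:33, 1:16)
  blurred_then_perm <- blur_image(sc, 2)$cube[, , perm]
  perm_img <- hyperspectral_image(sc$cube[, , perm])
  expect_equal(blur_image(perm_img, 2)$cube, blurred_then_perm,
               tolerance = 1e-12)
})

test_that("patch sampling honors its contracts", {
  imgs <- small_scenes(2, size = 32)
  expect_equal(length(sample_patches(imgs, 8, 0, seed = 1)), 0)
  # single image, patch = image size: every patch is the whole image
  one <- small_scenes(1, size = 20)
  st <- sample_patches(one, 20, 5, seed = 1)
  for (i in 1:5) expect_identical(get_patch(st, i), one[[1]]$cube)
  # seeded reproducibility
  s1 <- sample_patches(imgs, 8, 100, seed = 9)
  s2 <- sample_patches(imgs, 8, 100, seed = 9)
  expect_identical(s1$draws, s2$draws)
  expect_conelearn_error(sample_patches(imgs, 64, 10, seed = 1),
                         "conelearn_size_error")
})

test_that("cubes round-trip losslessly through ENVI and CSV containers", {
  sc <- generate_scene(scene_model(size = 9), seed = 3)
  tmp <- withr::local_tempdir()
  hdr <- write_cube(sc, file.path(tmp, "scene"))
  back <- read_cube(hdr)
  expect_equal(back$cube, sc$cube)
  expect_equal(back$wavelengths, sc$wavelengths)
  csv <- file.path(tmp, "scene.csv")
  write_cube(sc, csv)
  back2 <- read_cube(csv)
  expect_equal(back2$cube, sc$cube, tolerance = 1e-12)
})

test_that("a 420-720 nm cube reads back flagged for extrapolation", {
  wl <- standard_wavelengths()
  img <- hyperspectral_image(quadratic_cube()[, , 3:33], wl[3:33])
  tmp <- withr::local_tempdir()
  p <- write_cube(img, file.path(tmp, "trunc"))
  back <- read_cube(p)
  expect_true(attr(back, "needs_extrapolation"))
  full <- read_cube(write_cube(generate_scene(scene_model(size = 4), 1),
                               file.path(tmp, "full")))
  expect_false(attr(full, "needs_extrapolation"))
})

test_that("corrupt or incomplete headers give parse errors", {
  tmp <- withr::local_tempdir()
  sc <- generate_scene(scene_model(size = 4), seed = 1)
  p <- write_cube(sc, file.path(tmp, "x"))
  hdr <- readLines(p)
  writeLines(hdr[!grepl("^wavelength =", hdr)], p)
  expect_conelearn_error(read_cube(p), "conelearn_parse_error")
  expect_conelearn_error(read_cube(file.path(tmp, "nope")),
                         "conelearn_parse_error")
})
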