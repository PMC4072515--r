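test_that("raw responses are spectral inner products at each cone's pixel", {
  m <- tiny_mosaic()
  sens <- lm_s_sensitivities()
  zero <- array(0, c(10, 10, 33))
  expect_true(all(raw_response(zero, m, sens) == 0))
  # spectrally flat unit patch: response = sum of the sensitivity
  flat <- array(1, c(10, 10, 33))
  r <- raw_response(flat, m, sens)
  for (cl in c("L", "M", "S"))
    expect_equal(unname(r[m$labels == cl]),
                 rep(sum(sens[[cl]]$sensitivity), sum(m$labels == cl)))
  # linearity
  sc <- small_scenes(1, size = 12)[[1]]
  r1 <- raw_response(sc$cube, m, sens)
  r3 <- raw_response(hyperspectral_image(3 * sc$cube)$cube, m, sens)
  expect_equal(r3, 3 * r1, tolerance = 1e-12)
})

test_that("same-class cones seeing identical spectra respond identically", {
  m <- tiny_mosaic()
  sens <- lm_s_sensitivities()
  cube <- array(rep(runif(33), each = 100), c(10, 10, 33))
  r <- raw_response(cube, m, sens)
  for (cl in unique(m$labels))
    expect_equal(diff(range(r[m$labels == cl])), 0)
})

test_that("uniform surround weights of interior cones sum to the default 0.25", {
  m <- build_mosaic(20, standard_lm_classes(), c(1, 1), seed = 4)
  spec <- surround_spec("uniform")
  w <- surround_weights(m, c(10, 10), spec)
  expect_equal(sum(w$weight), 0.25, tolerance = 1e-12)
  # Gaussian symmetry: mirrored offsets get equal weights
  w1 <- w$weight[w$drow == 2 & w$dcol == 1]
  w2 <- w$weight[w$drow == -2 & w$dcol == 1]
  expect_equal(w1, w2)
  # boundary cones are renormalized to the same total
  wb <- surround_weights(m, c(1, 1), spec)
  expect_equal(sum(wb$weight), 0.25, tolerance = 1e-12)
})

test_that("cone-selective surrounds use only other-class neighbors, possibly none", {
  # build a mosaic that is all L except one M far away: L cones near the
  # center have no eligible neighbor and get an empty surround
  m <- build_mosaic(12, standard_lm_classes(), c(1e6, 1), s_fraction = 0,
                    seed = 8)
  m$labels[] <- "L"; m$labels[1] <- "M"
  spec <- surround_spec("cone_selective")
  w_center <- surround_weights(m, c(7, 7), spec)
  expect_equal(nrow(w_center), 0)
  # the M cone in the corner sees only L neighbors
  w_m <- surround_weights(m, 1, spec)
  expect_true(nrow(w_m) > 0)
  expect_true(all(m$labels[w_m$index] == "L"))
  expect_equal(sum(w_m$weight), 0.25, tolerance = 1e-12)
})

test_that("opponency subtracts the weighted neighborhood and respects mode none", {
  m <- tiny_mosaic()
  x <- matrix(rnorm(100 * 7), 100, 7)
  expect_identical(opponent_response(x, m, surround_spec("none")), x)
  # uniform input to a one-class mosaic: every interior cone scaled by 0.75
  m1 <- build_mosaic(12, list(cone_class("L", 558.9)), 1, s_fraction = 0,
                     seed = 2)
  u <- rep(2, 144)
  out <- opponent_response(u, m1, surround_spec("uniform"))
  expect_equal(unname(out), rep(2 * 0.75, 144), tolerance = 1e-12)
})

test_that("surround weight sums hold for every cone with eligible neighbors", {
  m <- tiny_mosaic(seed = 9)
  W <- surround_matrix(m, surround_spec("uniform"))
  expect_equal(unname(Matrix::rowSums(W)), rep(0.25, 100), tolerance = 1e-12)
})

test_that("response noise scales with the mean response and is seeded", {
  x <- matrix(rexp(50 * 2000, rate = 0.1), 50, 2000)
  expect_identical(add_noise(x, 0), x)
  expect_conelearn_error(add_noise(x, -0.1), "conelearn_invalid_parameter")
  y1 <- add_noise(x, 0.05, seed = 3)
  y2 <- add_noise(x, 0.05, seed = 3)
  expect_identical(y1, y2)
  # empirical sd of the added noise approaches 5% of the per-patch mean
  noise <- y1 - x
  ratio <- apply(noise, 2, sd) / colMeans(x)
  expect_equal(mean(ratio), 0.05, tolerance = 0.005)
})

test_that("uniform opponency sharpens the class contrast of neighbor correlations", {
  # over seeds: subtracting the surround removes wide-field signal shared
  # by all cones, widening the gap between same-class and different-class
  # nearest-neighbor correlations -- the signal the classifier feeds on
  gap_raw <- c(); gap_opp <- c()
  for (seed in 1:12) {
    m <- tiny_mosaic(seed = seed)
    imgs <- small_scenes(2, size = 32, seed = seed)
    sens <- lm_s_sensitivities()
    st <- sample_patches(imgs, 10, 2500, seed = seed)
    resp <- vapply(seq_len(2500),
                   function(i) raw_response(get_patch(st, i), m, sens),
                   numeric(100))
    W <- surround_matrix(m, surround_spec("uniform"))
    opp <- as.matrix(resp - W %*% resp)
    d <- as.matrix(dist(m$coords))
    ns <- m$labels != "S"
    same <- outer(m$labels, m$labels, "==") & d == 1 & ns & upper.tri(d)
    diff_lm <- (!outer(m$labels, m$labels, "==")) & d == 1 &
      outer(ns, ns, "&") & upper.tri(d)
    gap <- function(x) {
      rho <- cor(t(x))
      mean(rho[same]) - mean(rho[diff_lm])
    }
    gap_raw <- c(gap_raw, gap(resp))
    gap_opp <- c(gap_opp, gap(opp))
  }
  expect_gt(mean(gap_opp), mean(gap_raw))
})
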