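test_that("classical MDS reproduces Euclidean configurations exactly", {
  set.seed(6)
  x <- matrix(rnorm(36), 12, 3)
  rec <- classical_mds(as.matrix(dist(x)), 3)
  pro <- vegan::procrustes(scale(x, scale = FALSE), rec, scale = FALSE)
  expect_lt(sqrt(sum(pro$residuals^2)), 1e-8)
})

test_that("classical MDS handles canonical tiny cases", {
  two <- matrix(c(0, 2, 2, 0), 2, 2)
  xy <- classical_mds(two, 1)
  expect_equal(sort(xy[, 1]), c(-1, 1), tolerance = 1e-12)
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  xt <- classical_mds(tri, 2)
  dd <- dist(xt)
  expect_equal(max(dd) - min(dd), 0, tolerance = 1e-12)
  # deterministic sign: repeated calls identical
  expect_identical(classical_mds(tri, 2), classical_mds(tri, 2))
})

test_that("rank-deficient input pads with zeros under a warning", {
  line <- as.matrix(dist(cbind(1:5)))
  expect_warning(x <- classical_mds(line, 3), "padding")
  expect_equal(ncol(x), 3)
  expect_true(all(x[, 3] == 0))
})

test_that("NMDS attains near-zero stress on exact Euclidean input", {
  set.seed(7)
  x <- matrix(rnorm(30), 10, 3)
  fit <- nmds(as.matrix(dist(x)), dim = 3)
  expect_lt(fit$stress, 1e-4)
  expect_true(all(diff(fit$stress_history) <= 1e-12))
})

test_that("NMDS improves on its classical start and never increases stress", {
  set.seed(8)
  for (rep in 1:4) {
    dm <- as.matrix(dist(matrix(rnorm(20), 10, 2))) +
      0.4 * as.matrix(dist(matrix(rnorm(20), 10, 2)))
    dm <- (dm + t(dm)) / 2; diag(dm) <- 0
    init <- classical_mds(dm, 3)
    low <- lower.tri(dm)
    dv <- as.matrix(dist(init))[low]
    ord <- order(dm[low], seq_along(dm[low]))
    disp <- numeric(length(dv)); disp[ord] <- sort(dv[ord])  # upper bound only
    fit <- nmds(dm, dim = 3)
    init_stress <- fit$stress_history[1]
    expect_lte(fit$stress, init_stress)
    expect_true(all(diff(fit$stress_history) <= 1e-12))
  }
})

test_that("NMDS stress is invariant to monotone transforms of the input", {
  set.seed(9)
  dm <- as.matrix(dist(matrix(rnorm(24), 12, 2))) +
    0.3 * as.matrix(dist(matrix(rnorm(24), 12, 2)))
  dm <- (dm + t(dm)) / 2; diag(dm) <- 0
  s1 <- nmds(dm, max_iter = 1000, tol = 1e-8)$stress
  s2 <- nmds(dm^2, max_iter = 1000, tol = 1e-8)$stress
  expect_lt(abs(s1 - s2), 1e-3)
})

test_that("NMDS stress agrees with the Kruskal reference at its own solution", {
  # definition check: STRESS1 evaluated at an isoMDS solution equals the
  # stress isoMDS reports (the full multi-restart oracle comparison runs
  # with the end-to-end suite)
  skip_if_not_installed("MASS")
  set.seed(33)
  dm <- as.matrix(dist(matrix(rnorm(20), 10, 2))) +
    0.3 * as.matrix(dist(matrix(rnorm(20), 10, 2)))
  dm <- (dm + t(dm)) / 2; diag(dm) <- 0
  s <- MASS::isoMDS(dm, k = 3, trace = FALSE, maxit = 200)
  low <- lower.tri(dm)
  dv <- as.matrix(dist(s$points))[low]
  ord <- order(dm[low], seq_along(dm[low]))
  disp <- numeric(length(dv))
  disp[ord] <- conelearn:::pav_increasing(dv[ord])
  my_stress <- sqrt(sum((disp - dv)^2) / sum(dv^2))
  expect_equal(my_stress, s$stress / 100, tolerance = 1e-6)
})

test_that("S cones are found as the smaller k-means cluster", {
  set.seed(10)
  big <- matrix(rnorm(376 * 3, sd = 0.3), 376, 3)
  small <- matrix(rnorm(24 * 3, sd = 0.3), 24, 3) +
    matrix(c(-6, 0, 0), 24, 3, byrow = TRUE)
  emb <- rbind(big, small)
  s <- identify_s_cones(emb, seed = 1)
  expect_setequal(s, 377:400)
  expect_identical(identify_s_cones(emb, seed = 1),
                   identify_s_cones(emb, seed = 1))
})

test_that("an even split raises an ambiguity error instead of guessing", {
  pts <- rbind(matrix(rnorm(10 * 3, sd = 0.1), 10, 3),
               matrix(rnorm(10 * 3, sd = 0.1), 10, 3) +
                 matrix(c(5, 0, 0), 10, 3, byrow = TRUE))
  expect_conelearn_error(identify_s_cones(pts, seed = 1),
                         "conelearn_ambiguous_cluster")
})

test_that("rotation puts the S/non-S separation on a negative first axis", {
  set.seed(11)
  base <- matrix(rnorm(60 * 3), 60, 3)
  s_set <- 1:6
  base[s_set, 3] <- base[s_set, 3] + 9     # separation along axis 3
  emb <- structure(list(coords = base, stress = 0.1, iterations = 1,
                        converged = TRUE, stress_history = 0.1),
                   class = "cone_embedding")
  rot <- rotate_embedding(emb, s_set)
  v <- colMeans(rot$coords[s_set, ]) - colMeans(rot$coords[-s_set, ])
  expect_lt(max(abs(v[2:3])), 1e-10)
  expect_lt(v[1], 0)
  # rigid: pairwise distances preserved
  expect_equal(as.matrix(dist(rot$coords)), as.matrix(dist(base)),
               tolerance = 1e-12)
  # already-aligned input: rotation is (numerically) the identity
  rot2 <- rotate_embedding(rot, s_set)
  expect_equal(rot2$coords, rot$coords, tolerance = 1e-8)
  # degenerate separation errors out
  expect_conelearn_error(
    rotate_embedding(structure(list(coords = matrix(0, 10, 3)),
                               class = "cone_embedding"), 1:2),
    "conelearn_rotation_error")
})
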