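test_that("the skew-normal density obeys its closed forms", {
  x <- seq(-4, 4, by = 0.25)
  expect_equal(skew_normal_pdf(x, 1, 2, 0), dnorm(x, 1, 2), tolerance = 1e-14)
  expect_equal(skew_normal_pdf(0.5, 0.5, 1.3, 0), 1 / (1.3 * sqrt(2 * pi)))
  q <- integrate(function(t) skew_normal_pdf(t, 0, 1, 4), -20, 20,
                 rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-8)
  expect_conelearn_error(skew_normal_pdf(0, 0, -1, 0), "conelearn_domain_error")
})

test_that("the skew-normal CDF matches quadrature of the density", {
  for (al in c(-3, 0, 1, 4)) {
    qs <- c(-2, -0.5, 0, 1, 2.5)
    direct <- skew_normal_cdf(qs, 0.2, 1.1, al)
    ref <- vapply(qs, function(q)
      integrate(function(t) skew_normal_pdf(t, 0.2, 1.1, al), -16, q,
                rel.tol = 1e-11)$value, 0)
    expect_equal(direct, ref, tolerance = 1e-8)
  }
  expect_equal(skew_normal_cdf(c(-1, 0, 2), 0, 1, 0), pnorm(c(-1, 0, 2)),
               tolerance = 1e-12)
})

test_that("mixture fits recover generating parameters", {
  # single component: point estimates land near the truth at n = 5000
  # (the bootstrap-calibrated version of this check runs with the
  # end-to-end suite)
  set.seed(12)
  vals <- rskewnorm(5000, 0, 1, 3)
  fit <- fit_mixture(vals, 1, restarts = 10, seed = 1)
  est <- unlist(fit$components[c("xi", "omega", "alpha")])
  expect_equal(unname(est), c(0, 1, 3), tolerance = 0.15)
  # two equal components at +-5: weights within 0.05 of one half
  set.seed(13)
  v2 <- c(rskewnorm(2500, -5, 1, 0), rskewnorm(2500, 5, 1, 0))
  f2 <- fit_mixture(v2, 2, restarts = 10, seed = 1)
  expect_true(all(abs(f2$components$weight - 0.5) < 0.05))
  expect_equal(f2$components$xi, c(-5, 5), tolerance = 0.5)
  # fitting normal data with K = 1: the shape is statistically
  # indistinguishable from zero (likelihood ratio against the alpha = 0
  # fit far below the 1% chi-square bound; the direct parametrization has
  # a flat ridge near alpha = 0, so the point estimate itself is noisy)
  set.seed(14)
  v <- rnorm(4000)
  f3 <- fit_mixture(v, 1, restarts = 10, seed = 1)
  nll0 <- -sum(dnorm(v, mean(v), sd(v) * sqrt(3999 / 4000), log = TRUE))
  expect_lt(2 * (nll0 + f3$loglik), qchisq(0.99, 1))
})

test_that("the KS statistic and p-value behave as specified", {
  mix <- structure(list(components = data.frame(xi = 0, omega = 1, alpha = 0,
                                                weight = 1),
                        K = 1, n = 0, loglik = 0), class = "skew_mixture")
  # points at the (i - 0.5)/n quantiles give D = 0.5/n exactly
  n <- 40
  qs <- qnorm((seq_len(n) - 0.5) / n)
  ks <- ks_pvalue(qs, mix)
  expect_equal(ks$D, 0.5 / n, tolerance = 1e-10)
  # a shifted sample is rejected decisively at n = 376
  set.seed(15)
  expect_lt(ks_pvalue(rnorm(376, mean = 0.4), mix)$p, 0.01)
  expect_conelearn_error(ks_pvalue(numeric(0), mix), "conelearn_input_error")
})

test_that("KS p-values are approximately uniform under the null", {
  mix <- data.frame(xi = c(-2, 2), omega = c(1, 1.5), alpha = c(2, -1),
                    weight = c(0.4, 0.6))
  set.seed(16)
  ps <- replicate(500, {
    n <- 150
    comp <- sample(1:2, n, TRUE, mix$weight)
    x <- rskewnorm(n, 0, 1, 0)  # placeholder, filled per component below
    for (k in 1:2) {
      sel <- comp == k
      x[sel] <- rskewnorm(sum(sel), mix$xi[k], mix$omega[k], mix$alpha[k])
    }
    ks_pvalue(x, mix)$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
  expect_equal(mean(ps), 0.5, tolerance = 0.06)
})

test_that("class-count selection finds 1, 2 and 3 separated modes", {
  set.seed(17)
  one <- rskewnorm(400, 0, 1, 1.5)
  expect_equal(select_k(one, seed = 1, restarts = 10)$K, 1)
  two <- c(rnorm(200, -4, 0.7), rnorm(200, 4, 0.7))
  expect_equal(select_k(two, seed = 1, restarts = 10)$K, 2)
  three <- c(rnorm(130, -6, 0.6), rnorm(130, 0, 0.6), rnorm(130, 6, 0.6))
  sel3 <- select_k(three, seed = 1, restarts = 10)
  expect_equal(sel3$K, 3)
  expect_false(sel3$no_adequate_fit)
  # selection proceeds smallest-first: the K = 1 fit must have been rejected
  expect_lt(sel3$table$p[1], 0.01)
})

test_that("class assignment follows the highest density and the S-anchored order", {
  # symmetric equal components at +-a: threshold at 0, labels split by sign
  mix <- structure(list(components = data.frame(xi = c(-3, 3),
                                                omega = c(1, 1),
                                                alpha = c(0, 0),
                                                weight = c(0.5, 0.5)),
                        K = 2, n = 0, loglik = 0), class = "skew_mixture")
  vals <- setNames(seq(-5, 5, by = 0.5), seq_along(seq(-5, 5, by = 0.5)))
  cls <- assign_classes(vals, mix)
  expect_equal(unname(cls$threshold), 0, tolerance = 1e-8)
  expect_true(all(cls$labels[vals < 0] == "M"))
  expect_true(all(cls$labels[vals > 0] == "L"))
  # farther from the S side means longer lambda-max: with S on the positive
  # side instead, ordering flips
  cls_flip <- assign_classes(vals, mix, s_side = "positive")
  expect_true(all(cls_flip$labels[vals < 0] == "L"))
  # permutation invariance of per-cone labels
  perm <- sample(length(vals))
  cls_perm <- assign_classes(vals[perm], mix)
  expect_identical(cls_perm$labels[as.character(seq_along(vals))],
                   cls$labels[as.character(seq_along(vals))])
})

test_that("fitted mixture densities integrate to one", {
  set.seed(18)
  v <- c(rnorm(150, -2), rnorm(150, 2))
  f <- fit_mixture(v, 2, restarts = 5, seed = 3)
  q <- integrate(function(x) mixture_pdf(x, f), -30, 30, rel.tol = 1e-9)
  expect_equal(q$value, 1, tolerance = 1e-6)
})
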