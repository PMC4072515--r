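# Shared fixtures, all built in code at test time.

standard_lm_classes <- function() {
  list(cone_class("L", 558.9), cone_class("M", 530))
}

tiny_mosaic <- function(side = 10, seed = 3, ratio = c(1, 1)) {
  build_mosaic(side, standard_lm_classes(), ratio, seed = seed)
}

small_scenes <- function(n = 2, size = 64, seed = 1, ...) {
  model <- scene_model(size = size, ...)
  lapply(derive_test_seeds(seed, n), function(s) generate_scene(model, s))
}

derive_test_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(1e6, n))
}

# deterministic cube with a quadratic per-pixel spectrum, for extrapolation
# oracles: I(r, c, l) = a(r,c) + b(r,c) l + c2(r,c) l^2, kept positive
quadratic_cube <- function(nr = 4, nc = 5, wavelengths = standard_wavelengths()) {
  a <- outer(seq_len(nr), seq_len(nc), function(r, c) 50 + r + c)
  b <- outer(seq_len(nr), seq_len(nc), function(r, c) 0.02 * r - 0.01 * c)
  c2 <- outer(seq_len(nr), seq_len(nc), function(r, c) 1e-5 * (r + c))
  cube <- array(0, c(nr, nc, length(wavelengths)))
  for (i in seq_along(wavelengths)) {
    l <- wavelengths[i]
    cube[, , i] <- pmax(a + b * l + c2 * l^2, 0)
  }
  cube
}

# a small full-sensitivity set covering the classes of tiny_mosaic
lm_s_sensitivities <- function(filter = TRUE) {
  list(L = cone_fundamental(558.9, filter = filter),
       M = cone_fundamental(530, filter = filter),
       S = cone_fundamental(420.7, filter = filter))
}

expect_conelearn_error <- function(expr, subclass) {
  expect_error(expr, class = subclass)
}
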