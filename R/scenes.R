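# Hyperspectral scene container, synthetic scene generator, and image-level
# transforms (band extrapolation, Gaussian blur, patch sampling).

#' Construct a hyperspectral image
#'
#' @param cube Numeric array (rows x cols x bands), nonnegative intensities.
#' @param wavelengths Strictly increasing, uniformly spaced wavelength grid in
#'   nm, one entry per band.
#' @param meta Optional provenance tag (character).
#' @return Object of class `hyperspectral_image`.
#' @export
hyperspectral_image <- function(cube, wavelengths = standard_wavelengths(),
                                meta = "unspecified") {
  if (!is.array(cube) || length(dim(cube)) != 3)
    cl_stop("conelearn_invalid_parameter", "cube must be a 3-d array")
  if (dim(cube)[3] != length(wavelengths))
    cl_stop("conelearn_wavelength_grid_error",
            "band count (%d) != wavelength count (%d)",
            dim(cube)[3], length(wavelengths))
  dl <- diff(wavelengths)
  if (length(wavelengths) > 1 &&
      (any(dl <= 0) || max(abs(dl - dl[1])) > 1e-8))
    cl_stop("conelearn_wavelength_grid_error",
            "wavelength grid must be strictly increasing and uniform")
  if (any(!is.finite(cube)) || any(cube < 0))
    cl_stop("conelearn_invalid_parameter", "intensities must be finite and >= 0")
  structure(list(cube = cube, wavelengths = as.numeric(wavelengths),
                 meta = meta),
            class = "hyperspectral_image")
}

#' @export
print.hyperspectral_image <- function(x, ...) {
  d <- dim(x$cube)
  cat(sprintf("hyperspectral image: %d x %d px, %d bands (%g-%g nm) [%s]\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$meta))
  invisible(x)
}

#' Synthetic scene model
#'
#' Parameters of the synthetic hyperspectral scene generator. Scenes are
#' lognormal textures built from Gaussian random fields with a power-law
#' spatial amplitude spectrum, correlated across wavelength bands by a
#' squared-exponential kernel in wavelength separation. The two decay axes —
#' pixel-pixel correlation falling with spatial distance, band-band
#' correlation falling with wavelength separation — mimic the key statistics
#' of natural hyperspectral image databases.
#'
#' @param size Side of the square scene in pixels.
#' @param spatial_exponent Slope of the spatial amplitude spectrum
#'   (amplitude ~ f^-spatial_exponent). The default 1.5 reproduces the
#'   natural-image regime of high short-range and slowly decaying long-range
#'   pixel correlation.
#' @param spectral_corr_scale Length scale (nm) of the squared-exponential
#'   inter-band correlation kernel; must be > 0.
#' @param mean_level Mean radiance level (arbitrary units).
#' @param contrast Log-domain contrast (sd of the Gaussian exponent); 0 gives
#'   a spatially constant cube at `mean_level`.
#' @param wavelengths Wavelength grid.
#' @return Object of class `scene_model`.
#' @export
scene_model <- function(size = 128, spatial_exponent = 1.5,
                        spectral_corr_scale = 120, mean_level = 1,
                        contrast = 0.35,
                        wavelengths = standard_wavelengths()) {
  if (size < 2) cl_stop("conelearn_invalid_parameter", "size must be >= 2")
  if (spectral_corr_scale <= 0)
    cl_stop("conelearn_invalid_parameter", "spectral_corr_scale must be > 0")
  if (mean_level <= 0)
    cl_stop("conelearn_invalid_parameter", "mean_level must be > 0")
  if (contrast < 0)
    cl_stop("conelearn_invalid_parameter", "contrast must be >= 0")
  structure(list(size = as.integer(size),
                 spatial_exponent = spatial_exponent,
                 spectral_corr_scale = spectral_corr_scale,
                 mean_level = mean_level, contrast = contrast,
                 wavelengths = wavelengths),
            class = "scene_model")
}

# One Gaussian random field with power-law amplitude spectrum. The field is
# synthesized on a 4x larger periodic domain and cropped, so the scene keeps
# long-range correlation (scenes are windows onto a larger world) and a
# scene-level mean offset (ensemble luminance variation): normalization to
# zero mean / unit variance happens on the full domain, not the crop.
.field_pad <- 4L

# nf independent fields as columns of an (n*n x nf) matrix. Synthesis is in
# the frequency domain: complex white noise shaped by the amplitude
# envelope; the real and imaginary parts of one inverse FFT are two
# independent real fields with the target spectrum.
powerlaw_fields <- function(n, exponent, nf) {
  N <- n * .field_pad
  f1 <- c(0, pmin(1:(N - 1), N - (1:(N - 1)))) / N
  fr <- sqrt(outer(f1^2, f1^2, "+"))
  amp <- ifelse(fr > 0, fr^(-exponent), 0)
  out <- matrix(0, n * n, nf)
  keep <- as.vector(outer(seq_len(n), (seq_len(n) - 1) * N, "+"))
  for (j in seq_len(ceiling(nf / 2))) {
    w <- matrix(complex(real = stats::rnorm(N * N),
                        imaginary = stats::rnorm(N * N)), N, N)
    x <- stats::fft(amp * w, inverse = TRUE)
    re <- Re(x); im <- Im(x)
    re <- (re - mean(re)) / stats::sd(re)
    out[, 2 * j - 1] <- re[keep]
    if (2 * j <= nf) {
      im <- (im - mean(im)) / stats::sd(im)
      out[, 2 * j] <- im[keep]
    }
  }
  out
}

powerlaw_field <- function(n, exponent) {
  matrix(powerlaw_fields(n, exponent, 1L), n, n)
}

#' Generate a synthetic hyperspectral scene
#'
#' @param model A [scene_model()].
#' @param seed Integer seed; fixed seed gives a bit-identical cube.
#' @return A [hyperspectral_image()].
#' @export
generate_scene <- function(model, seed = 1) {
  stopifnot(inherits(model, "scene_model"))
  old_rng <- save_rng(); on.exit(restore_rng(old_rng))
  set.seed(as.integer(seed))
  n <- model$size
  nb <- length(model$wavelengths)
  if (model$contrast == 0) {
    cube <- array(model$mean_level, c(n, n, nb))
    return(hyperspectral_image(cube, model$wavelengths, meta = "synthetic"))
  }
  # independent power-law fields, one per band, as columns of (npix x nb)
  g <- powerlaw_fields(n, model$spatial_exponent, nb)
  # impose band-band correlation K = exp(-dl^2 / (2 scale^2))
  dl <- outer(model$wavelengths, model$wavelengths, "-")
  K <- exp(-dl^2 / (2 * model$spectral_corr_scale^2))
  z <- g %*% chol(K + diag(1e-10, nb))
  cube <- array(model$mean_level * exp(model$contrast * z -
                                         model$contrast^2 / 2),
                c(n, n, nb))
  hyperspectral_image(cube, model$wavelengths, meta = "synthetic")
}

#' Extrapolate missing end bands quadratically
#'
#' Extends a cube recorded on a truncated wavelength grid (missing bands at
#' one end, as in databases covering 420-700 nm) to a full target grid. Each
#' pixel's spectrum is continued with the quadratic through its three bands
#' nearest the gap; negative extrapolations are clamped to zero.
#'
#' @param image A [hyperspectral_image()] whose grid is a contiguous
#'   sub-grid of `target_grid`, short only at the ends.
#' @param target_grid Full wavelength grid (default
#'   [standard_wavelengths()]).
#' @return A [hyperspectral_image()] on `target_grid`; pre-existing bands are
#'   unchanged.
#' @export
extrapolate_bands <- function(image, target_grid = standard_wavelengths()) {
  stopifnot(inherits(image, "hyperspectral_image"))
  wl <- image$wavelengths
  idx <- match(wl, target_grid)
  if (any(is.na(idx)))
    cl_stop("conelearn_wavelength_grid_error",
            "image grid is not a sub-grid of the target grid")
  if (any(diff(idx) != 1) ||
      !identical(target_grid[idx], wl))
    cl_stop("conelearn_unsupported_layout",
            "missing bands must be contiguous at the grid ends")
  if (length(wl) < 3)
    cl_stop("conelearn_invalid_parameter",
            "need at least 3 bands to extrapolate")
  d <- dim(image$cube)
  out <- array(0, c(d[1], d[2], length(target_grid)))
  out[, , idx] <- image$cube
  quad_extend <- function(missing_idx, anchor_idx) {
    # exact quadratic through the three anchor bands, per pixel
    lam <- target_grid[anchor_idx]
    y <- matrix(image$cube[, , match(target_grid[anchor_idx], wl)],
                ncol = 3)
    v <- cbind(1, lam, lam^2)
    coef <- y %*% t(solve(v))              # npix x 3: c0, c1, c2
    for (m in missing_idx) {
      lm <- target_grid[m]
      vals <- coef[, 1] + coef[, 2] * lm + coef[, 3] * lm^2
      out[, , m] <<- matrix(pmax(vals, 0), d[1], d[2])
    }
  }
  lo <- setdiff(seq_len(min(idx) - 1), integer(0))
  hi <- setdiff(seq(max(idx) + 1, length.out = length(target_grid) - max(idx)),
                integer(0))
  if (length(lo)) quad_extend(lo, idx[1:3])
  if (length(hi)) quad_extend(hi, idx[length(idx) - 2:0])
  hyperspectral_image(out, target_grid,
                      meta = paste0(image$meta, "+extrapolated"))
}

#' Gaussian spatial blur, band by band
#'
#' Separable 2-D Gaussian convolution applied independently to every band;
#' boundaries use reflect padding. `sigma_px = 0` is the identity.
#'
#' @param image A [hyperspectral_image()].
#' @param sigma_px Gaussian standard deviation in pixels, >= 0.
#' @return Blurred [hyperspectral_image()].
#' @export
blur_image <- function(image, sigma_px) {
  stopifnot(inherits(image, "hyperspectral_image"))
  if (!is.numeric(sigma_px) || length(sigma_px) != 1 || sigma_px < 0)
    cl_stop("conelearn_invalid_parameter", "sigma_px must be a single value >= 0")
  if (sigma_px == 0) return(image)
  r <- ceiling(4 * sigma_px)
  k <- stats::dnorm(-r:r, sd = sigma_px)
  k <- k / sum(k)
  conv1 <- function(m) {
    # reflect-pad rows, convolve columns of m with k
    n <- nrow(m)
    pad <- rbind(m[r:1, , drop = FALSE], m, m[n:(n - r + 1), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[(j - 1) + seq_len(n), , drop = FALSE]
    }
    out
  }
  cube <- image$cube
  for (b in seq_len(dim(cube)[3])) {
    cube[, , b] <- t(conv1(t(conv1(cube[, , b]))))
  }
  hyperspectral_image(cube, image$wavelengths,
                      meta = paste0(image$meta, "+blur"))
}

#' Sample image patches with replacement
#'
#' Draws `n_patches` square patches i.i.d. with replacement over (image,
#' offset) from a list of hyperspectral images, mirroring random patch
#' presentation to a retinal mosaic.
#'
#' @param images List of [hyperspectral_image()] objects on a common grid.
#' @param patch_size Patch side in pixels.
#' @param n_patches Number of draws.
#' @param seed Integer seed.
#' @return Object of class `patch_stream`: the images plus an `n_patches` x 3
#'   draw table (image index, row offset, col offset). Use [get_patch()] to
#'   materialize a patch cube.
#' @export
sample_patches <- function(images, patch_size, n_patches, seed = 1) {
  if (!length(images)) cl_stop("conelearn_invalid_parameter", "no images given")
  dims <- vapply(images, function(im) dim(im$cube)[1:2], numeric(2))
  if (patch_size > min(dims))
    cl_stop("conelearn_size_error",
            "patch_size %d exceeds smallest image dimension %d",
            patch_size, min(dims))
  old_rng <- save_rng(); on.exit(restore_rng(old_rng))
  set.seed(as.integer(seed))
  n_patches <- as.integer(n_patches)
  img <- if (n_patches > 0) sample.int(length(images), n_patches, replace = TRUE) else integer(0)
  row0 <- integer(n_patches); col0 <- integer(n_patches)
  for (g in seq_along(images)) {
    sel <- which(img == g)
    if (!length(sel)) next
    row0[sel] <- sample.int(dims[1, g] - patch_size + 1L, length(sel), replace = TRUE)
    col0[sel] <- sample.int(dims[2, g] - patch_size + 1L, length(sel), replace = TRUE)
  }
  structure(list(images = images, patch_size = as.integer(patch_size),
                 draws = cbind(image = img, row = row0, col = col0)),
            class = "patch_stream")
}

#' Materialize one patch from a patch stream
#'
#' @param stream A [sample_patches()] result.
#' @param i Patch index.
#' @return Numeric array `patch_size x patch_size x bands`.
#' @export
get_patch <- function(stream, i) {
  stopifnot(inherits(stream, "patch_stream"))
  d <- stream$draws[i, ]
  ps <- stream$patch_size
  stream$images[[d["image"]]]$cube[d["row"] + 0:(ps - 1),
                                   d["col"] + 0:(ps - 1), , drop = FALSE]
}

#' @export
length.patch_stream <- function(x) nrow(x$draws)
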