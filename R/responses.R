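# Cone responses to image patches: spectral integration at each cone's
# pixel, optional center-surround opponency (uniform or cone-selective),
# optional additive Gaussian noise.

#' Surround specification
#'
#' Antagonistic surround of each cone: a 2-D Gaussian over grid neighbors,
#' normalized so the weights sum to `total_weight` (0.25 by default, matching
#' the suppressive-surround strength used throughout). In `cone_selective`
#' mode only opposite-type longer-wavelength neighbors are eligible (L
#' surrounds draw on M and vice versa; S surrounds draw on all non-S
#' classes); a cone with no eligible neighbor gets an empty surround.
#'
#' @param mode One of "none", "uniform", "cone_selective".
#' @param sigma Gaussian sd in inter-cone units (default 2).
#' @param total_weight Summed surround weight in (0, 1) (default 0.25).
#' @param support_radius Chebyshev radius of the surround support (default 5).
#' @return Object of class `surround_spec`.
#' @export
surround_spec <- function(mode = c("uniform", "none", "cone_selective"),
                          sigma = 2, total_weight = 0.25, support_radius = 5) {
  mode <- match.arg(mode)
  if (mode != "none" && sigma <= 0)
    cl_stop("conelearn_invalid_parameter", "sigma must be > 0")
  if (total_weight <= 0 || total_weight >= 1)
    cl_stop("conelearn_invalid_parameter", "total_weight must be in (0, 1)")
  structure(list(mode = mode, sigma = sigma, total_weight = total_weight,
                 support_radius = as.integer(support_radius)),
            class = "surround_spec")
}

#' Raw spectral responses of a mosaic to one patch
#'
#' Each cone's raw response is the inner product of its spectral sensitivity
#' with the spectrum at its assigned pixel: `r = sum_lambda S(lambda) *
#' I(lambda)`. The cone at grid position (i, j) reads the patch pixel
#' (1 + (i-1)*stride, 1 + (j-1)*stride); `stride` > 1 spaces the cones
#' further apart relative to the image scale.
#'
#' @param patch Array `rows x cols x bands` on the standard grid.
#' @param mosaic A [build_mosaic()] result.
#' @param sensitivities Named list of [cone_fundamental()] objects covering
#'   every class in the mosaic (including "S" when present).
#' @param stride Cone spacing in image pixels (default 1).
#' @return Numeric vector, one response per cone (column-major grid order).
#' @export
raw_response <- function(patch, mosaic, sensitivities, stride = 1L) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  need <- (mosaic$side - 1L) * stride + 1L
  if (dim(patch)[1] < need || dim(patch)[2] < need)
    cl_stop("conelearn_size_error",
            "patch (%d x %d) smaller than mosaic footprint (%d)",
            dim(patch)[1], dim(patch)[2], need)
  smat <- sensitivity_matrix(mosaic, sensitivities, n_bands = dim(patch)[3])
  px_r <- 1L + (mosaic$coords[, 1] - 1L) * stride
  px_c <- 1L + (mosaic$coords[, 2] - 1L) * stride
  npix <- dim(patch)[1] * dim(patch)[2]
  flat <- matrix(patch, nrow = npix)          # pixel x band
  spectra <- flat[(px_c - 1L) * dim(patch)[1] + px_r, , drop = FALSE]
  unname(rowSums(spectra * smat))
}

# cones x bands matrix of per-cone sensitivities; validates class coverage.
sensitivity_matrix <- function(mosaic, sensitivities, n_bands) {
  classes <- unique(mosaic$labels)
  missing <- setdiff(classes, names(sensitivities))
  if (length(missing))
    cl_stop("conelearn_invalid_parameter",
            "no sensitivity given for class(es): %s",
            paste(missing, collapse = ", "))
  nb <- length(sensitivities[[classes[1]]]$sensitivity)
  if (nb != n_bands)
    cl_stop("conelearn_wavelength_grid_error",
            "sensitivity has %d bands but patch has %d", nb, n_bands)
  s_by_class <- t(vapply(sensitivities[classes],
                         function(s) s$sensitivity, numeric(nb)))
  s_by_class[match(mosaic$labels, classes), , drop = FALSE]
}

#' Surround weights of one cone
#'
#' Gaussian weights `exp(-(dx^2+dy^2)/(2 sigma^2))` over the eligible
#' neighbors within the support radius, normalized to sum to
#' `spec$total_weight`. Boundary cones (and cone-selective cones with few
#' eligible neighbors) are renormalized over the neighbors they have; a cone
#' with no eligible neighbor gets an empty surround.
#'
#' @param mosaic A [build_mosaic()] result.
#' @param cone Cone index or `c(row, col)`.
#' @param spec A [surround_spec()]; mode must not be "none".
#' @return Data frame `index`, `drow`, `dcol`, `weight`.
#' @export
surround_weights <- function(mosaic, cone, spec) {
  stopifnot(inherits(spec, "surround_spec"))
  if (spec$mode == "none")
    cl_stop("conelearn_invalid_parameter", "surround mode is 'none'")
  if (length(cone) == 2) cone <- (cone[2] - 1L) * mosaic$side + cone[1]
  nb <- neighbor_offsets(mosaic, cone, spec$support_radius)
  if (spec$mode == "cone_selective") {
    ctr <- mosaic$labels[cone]
    elig <- if (ctr == "S") mosaic$labels[nb$index] != "S"
            else mosaic$labels[nb$index] != ctr & mosaic$labels[nb$index] != "S"
    nb <- nb[elig, , drop = FALSE]
  }
  if (!nrow(nb)) return(cbind(nb, weight = numeric(0)))
  w <- exp(-(nb$drow^2 + nb$dcol^2) / (2 * spec$sigma^2))
  nb$weight <- w * spec$total_weight / sum(w)
  nb[c("index", "drow", "dcol", "weight")]
}

#' Sparse surround weight matrix for a whole mosaic
#'
#' Row i holds the surround weights of cone i over all other cones;
#' `(I - W) %*% responses` applies the opponency in one step.
#'
#' @inheritParams surround_weights
#' @return A `dgCMatrix` (cones x cones); the zero matrix for mode "none".
#' @export
surround_matrix <- function(mosaic, spec) {
  n <- mosaic$side^2
  if (spec$mode == "none")
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  ii <- vector("list", n)
  for (k in seq_len(n)) {
    w <- surround_weights(mosaic, k, spec)
    if (nrow(w)) ii[[k]] <- cbind(k, w$index, w$weight)
  }
  trip <- do.call(rbind, ii)
  Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
                       dims = c(n, n))
}

#' Apply center-surround opponency to a response batch
#'
#' Subtracts from each cone's response the Gaussian-weighted sum of its
#' neighbors' raw responses: `r' = r - W r`. Mode "none" is the identity.
#'
#' @param batch Numeric matrix, cones x patches (or a vector for one patch).
#' @param mosaic A [build_mosaic()] result.
#' @param spec A [surround_spec()].
#' @param W Optional precomputed [surround_matrix()] (saves rebuilding it
#'   per batch).
#' @return Matrix (or vector) of opponent responses, same shape as `batch`.
#' @export
opponent_response <- function(batch, mosaic, spec, W = NULL) {
  if (spec$mode == "none") return(batch)
  vec <- is.null(dim(batch))
  if (vec) batch <- matrix(batch, ncol = 1)
  if (is.null(W)) W <- surround_matrix(mosaic, spec)
  out <- as.matrix(batch - W %*% batch)
  if (vec) out[, 1] else out
}

#' Add response noise
#'
#' Adds i.i.d. Gaussian noise to every cone's response. For each patch the
#' noise sd is `fraction` times the mean response over cones to that patch
#' (`per_patch = TRUE`, default); alternatively one global sd computed from
#' the grand mean response of the whole batch (`per_patch = FALSE`).
#'
#' @param batch Cones x patches response matrix.
#' @param fraction Noise sd as a fraction of the mean response, >= 0.
#' @param seed Integer seed.
#' @param per_patch Use per-patch means (default) or the grand mean.
#' @return Noisy batch, same shape.
#' @export
add_noise <- function(batch, fraction, seed = 1, per_patch = TRUE) {
  if (fraction < 0)
    cl_stop("conelearn_invalid_parameter", "fraction must be >= 0")
  if (fraction == 0) return(batch)
  old_rng <- save_rng(); on.exit(restore_rng(old_rng))
  set.seed(as.integer(seed))
  sd_per_patch <- if (per_patch) fraction * colMeans(batch)
                  else rep(fraction * mean(batch), ncol(batch))
  batch + matrix(stats::rnorm(length(batch)), nrow(batch), ncol(batch)) *
    rep(sd_per_patch, each = nrow(batch))
}
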