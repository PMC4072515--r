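# Streaming cone x cone Pearson correlation over a patch stream, and the
# -log transform that turns it into the MDS dissimilarity.

#' Accumulate the cone correlation matrix over a patch stream
#'
#' Single-pass streaming computation of the cone x cone Pearson correlation
#' matrix from running sums of x and x x' accumulated batch by batch, so
#' arbitrarily many patches can be processed at fixed memory.
#'
#' @param patches A [sample_patches()] stream, or an integer patch count when
#'   `responder` generates its own inputs.
#' @param responder Function taking a vector of patch indices and returning
#'   the cones x length(indices) response matrix for those patches.
#' @param batch_size Patches per accumulation step (default 1000).
#' @return Object of class `cone_correlation`: `rho` (symmetric, unit
#'   diagonal), `n_patches`.
#' @export
accumulate_correlation <- function(patches, responder, batch_size = 1000) {
  n_patches <- if (inherits(patches, "patch_stream")) length(patches)
               else as.integer(patches)
  if (n_patches < 2)
    cl_stop("conelearn_invalid_parameter", "need at least 2 patches")
  s1 <- NULL; s2 <- NULL
  for (start in seq(1, n_patches, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n_patches)
    x <- responder(idx)
    if (is.null(s1)) {
      s1 <- numeric(nrow(x)); s2 <- matrix(0, nrow(x), nrow(x))
    }
    s1 <- s1 + rowSums(x)
    s2 <- s2 + tcrossprod(x)
  }
  m <- s1 / n_patches
  cov <- s2 / n_patches - tcrossprod(m)
  v <- diag(cov)
  scale <- mean(abs(s2)) / n_patches + 1e-300
  bad <- which(v <= 1e-12 * scale)
  if (length(bad))
    cl_stop("conelearn_degenerate_cone",
            "cone(s) with zero response variance: %s",
            paste(utils::head(bad, 10), collapse = ", "))
  rho <- cov / sqrt(tcrossprod(v))
  rho <- (rho + t(rho)) / 2
  rho[rho > 1] <- 1; rho[rho < -1] <- -1
  diag(rho) <- 1
  structure(list(rho = rho, n_patches = n_patches),
            class = "cone_correlation")
}

#' Correlation to MDS dissimilarity
#'
#' `d = -log(rho)`, the approximate inter-cone distance used for the
#' embedding. Correlations at or below `floor` are clamped to `floor` before
#' the log (the transform is undefined for nonpositive correlations, which
#' center-surround opponency can produce); the diagonal is forced to zero.
#'
#' @param corr A [accumulate_correlation()] result (or a plain correlation
#'   matrix).
#' @param floor Clamp value in (0, 1] (default 1e-6).
#' @return Object of class `cone_dissimilarity`: symmetric nonnegative `d`
#'   with zero diagonal; attribute `n_clamped` counts clamped off-diagonal
#'   entries.
#' @export
to_dissimilarity <- function(corr, floor = 1e-6) {
  if (floor <= 0)
    cl_stop("conelearn_invalid_parameter", "floor must be > 0")
  rho <- if (inherits(corr, "cone_correlation")) corr$rho else as.matrix(corr)
  n_clamped <- sum(rho < floor) - sum(diag(rho) < floor)
  d <- -log(pmax(rho, floor))
  diag(d) <- 0
  structure(list(d = d, n_clamped = n_clamped),
            class = "cone_dissimilarity")
}
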