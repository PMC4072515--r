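# Flattening of the curved surface(s) on which non-S cones embed: fit a
# quadratic surface z1 = q(z2, z3) over embedding dimensions 2-3 by
# minimizing the *standard deviation* of the point-to-surface distances,
# then convert each cone to a signed distance (the flattened spectral
# coordinate).

quad_eval <- function(cf, u, v) {
  cf[1] + cf[2] * u + cf[3] * v + cf[4] * u^2 + cf[5] * u * v + cf[6] * v^2
}

# Perpendicular Euclidean distances from points (x,y,z) to the surface
# z1 = q(z2,z3): per-point Newton solve of the foot-point normal equations,
# vectorized across points; falls back to the z1-residual distance where the
# inner solve fails. Returns the distances plus the fallback count.
surface_distances <- function(cf, x, y, z, max_newton = 25) {
  u <- x; v <- y
  conv <- rep(FALSE, length(x))
  for (it in seq_len(max_newton)) {
    q <- quad_eval(cf, u, v)
    qu <- cf[2] + 2 * cf[4] * u + cf[5] * v
    qv <- cf[3] + cf[5] * u + 2 * cf[6] * v
    r <- q - z
    g1 <- (u - x) + r * qu
    g2 <- (v - y) + r * qv
    h11 <- 1 + qu^2 + r * 2 * cf[4]
    h12 <- qu * qv + r * cf[5]
    h22 <- 1 + qv^2 + r * 2 * cf[6]
    det <- h11 * h22 - h12^2
    bad <- !is.finite(det) | abs(det) < 1e-12
    det[bad] <- 1
    du <- (h22 * g1 - h12 * g2) / det
    dv <- (h11 * g2 - h12 * g1) / det
    du[bad] <- 0; dv[bad] <- 0
    # damp large steps for stability
    step <- sqrt(du^2 + dv^2)
    damp <- ifelse(step > 1, 1 / step, 1)
    u <- u - damp * du
    v <- v - damp * dv
    conv <- sqrt(g1^2 + g2^2) < 1e-10
    if (all(conv)) break
  }
  q <- quad_eval(cf, u, v)
  dist <- sqrt((u - x)^2 + (v - y)^2 + (q - z)^2)
  # fallback: z1 residual where Newton failed or wandered
  fail <- !conv | !is.finite(dist)
  if (any(fail)) {
    q0 <- quad_eval(cf, x[fail], y[fail])
    dist[fail] <- abs(z[fail] - q0)
  }
  list(dist = dist, n_fallback = sum(fail))
}

#' Fit the flattening surface
#'
#' Fits the 6 coefficients of `z1 = c0 + c1 z2 + c2 z3 + c3 z2^2 +
#' c4 z2 z3 + c5 z3^2` to the non-S cones of an embedding by minimizing the
#' standard deviation (not the sum) of the point-to-surface distances —
#' favoring a surface equally distant from every cone over one merely close
#' to most. Nonlinear minimization (Nelder-Mead) is initialized from the
#' least-squares quadratic regression of dim 1 on dims 2-3.
#'
#' @param embedding A [nmds()] (typically rotated) result.
#' @param non_s_set Indices of the non-S cones (>= 7 of them).
#' @param n_starts Number of optimizer starts (default 8).
#' @return Object of class `quadratic_surface`: `coefficients`, `objective`
#'   (the achieved distance sd), `n_fallback` (points where the perpendicular
#'   foot-point solve fell back to the dim-1 residual).
#' @export
fit_surface <- function(embedding, non_s_set, n_starts = 8) {
  pts <- if (inherits(embedding, "cone_embedding")) embedding$coords else as.matrix(embedding)
  pts <- pts[non_s_set, , drop = FALSE]
  if (nrow(pts) < 7)
    cl_stop("conelearn_input_error", "need >= 7 non-S cones to fit 6 coefficients")
  z <- pts[, 1]; u <- pts[, 2]; v <- pts[, 3]
  basis <- cbind(1, u, v, u^2, u * v, v^2)
  if (qr(basis)$rank < 6)
    cl_stop("conelearn_rank_error",
            "(dim2, dim3) support is degenerate; quadratic basis is rank deficient")
  init <- qr.solve(basis, z)
  obj <- function(cf) {
    sd <- surface_distances(cf, u, v, z)
    if (!all(is.finite(sd$dist))) return(.Machine$double.xmax)
    stats::sd(sd$dist)
  }
  # The sd-of-distances objective is non-convex with nearby local basins;
  # multi-start Nelder-Mead (least-squares init plus seeded jitters, each
  # run polished by a restart from its incumbent) finds the global basin
  # reliably and makes the fit frame-invariant in practice.
  resid_scale <- stats::sd(z - basis %*% init)
  old_rng <- save_rng(); on.exit(restore_rng(old_rng))
  set.seed(271828L)
  fit <- NULL
  for (s in seq_len(n_starts)) {
    p0 <- if (s == 1) init
          else init + stats::rnorm(6, sd = resid_scale *
                                     c(1, 0.5, 0.5, 0.3, 0.3, 0.3))
    f <- stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-9))
    f <- stats::optim(f$par, obj, method = "Nelder-Mead",
                      control = list(maxit = 10000, reltol = 1e-10))
    if (is.null(fit) || f$value < fit$value) fit <- f
  }
  if (!is.finite(fit$value))
    cl_stop("conelearn_fit_error", "surface fit failed (non-finite objective)")
  final <- surface_distances(fit$par, u, v, z)
  structure(list(coefficients = unname(fit$par), objective = fit$value,
                 n_fallback = final$n_fallback,
                 optim_convergence = fit$convergence),
            class = "quadratic_surface")
}

#' Flattened spectral positions
#'
#' Converts each non-S cone's embedded position to its signed perpendicular
#' distance from the fitted surface: the flattened spectral coordinate.
#' The sign is negative on the side of the surface where the S cones lie
#' (taken from the mean S-cone residual), positive on the other side. For
#' tritanope runs with no S cones, supply `s_side_sign` directly (the
#' manual-rotation hook).
#'
#' @param embedding The (rotated) [nmds()] result the surface was fit on.
#' @param surface A [fit_surface()] result.
#' @param s_set Indices of the S cones; may be empty if `s_side_sign` given.
#' @param s_side_sign Optional +1/-1: the sign of the dim-1 residual on the
#'   S side, overriding the S-cone-derived convention.
#' @return Object of class `flattened_positions`: `values` (named by cone
#'   index, one per non-S cone), `non_s_set`, `s_side_sign`.
#' @export
flatten <- function(embedding, surface, s_set, s_side_sign = NULL) {
  stopifnot(inherits(surface, "quadratic_surface"))
  pts <- if (inherits(embedding, "cone_embedding")) embedding$coords else as.matrix(embedding)
  cf <- surface$coefficients
  if (is.null(s_side_sign)) {
    if (!length(s_set))
      cl_stop("conelearn_invalid_parameter",
              "empty s_set: supply s_side_sign for mosaics without S cones")
    s_resid <- mean(pts[s_set, 1] -
                      quad_eval(cf, pts[s_set, 2], pts[s_set, 3]))
    if (abs(s_resid) < 1e-12)
      cl_stop("conelearn_sign_ambiguity",
              "mean S-cone position lies exactly on the surface")
    s_side_sign <- sign(s_resid)
  }
  non_s <- setdiff(seq_len(nrow(pts)), s_set)
  u <- pts[non_s, 2]; v <- pts[non_s, 3]; z <- pts[non_s, 1]
  sd <- surface_distances(cf, u, v, z)
  resid <- z - quad_eval(cf, u, v)
  side <- ifelse(resid >= 0, 1, -1)
  vals <- sd$dist * ifelse(side == s_side_sign, -1, 1)
  structure(list(values = stats::setNames(vals, non_s),
                 non_s_set = non_s, s_side_sign = s_side_sign),
            class = "flattened_positions")
}
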