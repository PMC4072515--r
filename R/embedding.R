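# Non-metric MDS of the cone dissimilarity matrix into 3-D, plus S-cone
# identification and the rotation that puts the spectral axis on dimension 1.

as_dissim_matrix <- function(d) {
  m <- if (inherits(d, "cone_dissimilarity")) d$d else as.matrix(d)
  if (any(!is.finite(m)))
    cl_stop("conelearn_input_error", "dissimilarities must be finite")
  if (max(abs(m - t(m))) > 1e-8 || any(abs(diag(m)) > 1e-12))
    cl_stop("conelearn_input_error",
            "dissimilarity matrix must be symmetric with zero diagonal")
  (m + t(m)) / 2
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centered Gram eigendecomposition via [stats::cmdscale()], with two
#' conventions on top: axes whose eigenvalues are not positive are padded
#' with zeros (with a warning), and each axis' sign is fixed so its first
#' nonzero loading is positive, making the result fully deterministic.
#'
#' @param d Dissimilarity matrix (or [to_dissimilarity()] result).
#' @param dim Embedding dimension (default 3).
#' @return Numeric matrix, points x dim.
#' @export
classical_mds <- function(d, dim = 3) {
  m <- as_dissim_matrix(d)
  fit <- stats::cmdscale(m, k = dim, eig = TRUE)
  x <- fit$points
  if (ncol(x) < dim) x <- cbind(x, matrix(0, nrow(x), dim - ncol(x)))
  # columns carried by (numerically) non-positive eigenvalues are noise:
  # zero them and warn
  eigs <- fit$eig[seq_len(dim)]
  weak <- !is.finite(eigs) | eigs <= max(fit$eig) * 1e-8
  if (any(weak)) {
    warning(sprintf("only %d positive eigenvalue(s); padding to %d dims with zeros",
                    sum(!weak), dim))
    x[, weak] <- 0
  }
  for (j in seq_len(ncol(x))) {
    nz <- which(abs(x[, j]) > 1e-12)
    if (length(nz) && x[nz[1], j] < 0) x[, j] <- -x[, j]
  }
  unname(x)
}

# STRESS1 given configuration distances and disparities.
stress1 <- function(dist_vec, disp_vec) {
  sqrt(sum((disp_vec - dist_vec)^2) / sum(dist_vec^2))
}

# Isotonic regression of configuration distances on the rank order of the
# dissimilarities (ties broken by index), via the compiled
# pool-adjacent-violators kernel.
isotonic_disparities <- function(dist_vec, ord) {
  disp <- numeric(length(ord))
  disp[ord] <- pav_increasing(dist_vec[ord])
  disp
}

#' Non-metric MDS by SMACOF with isotonic disparities
#'
#' Embeds a dissimilarity matrix in `dim` dimensions by minimizing STRESS1
#' (`sqrt(sum((dhat - dist)^2) / sum(dist^2))`), alternating isotonic
#' regression of the configuration distances on the rank order of the input
#' dissimilarities (the monotone disparities `dhat`) with Guttman-transform
#' coordinate updates. Starts from [classical_mds()] by default. Iteration
#' keeps the best configuration seen and stops as soon as the stress fails
#' to decrease, so the recorded stress history is non-increasing.
#'
#' @param d Dissimilarity matrix (or [to_dissimilarity()] result).
#' @param dim Embedding dimension (default 3).
#' @param init Optional starting configuration (points x dim).
#' @param max_iter Maximum iterations (default 300).
#' @param tol Relative stress-change convergence tolerance (default 1e-6).
#' @return Object of class `cone_embedding`: `coords`, final `stress`,
#'   `iterations`, `converged`, `stress_history`.
#' @export
nmds <- function(d, dim = 3, init = NULL, max_iter = 300, tol = 1e-6) {
  m <- as_dissim_matrix(d)
  n <- nrow(m)
  low <- lower.tri(m)
  delta <- m[low]
  ord <- order(delta, seq_along(delta))
  x <- if (is.null(init)) classical_mds(m, dim) else as.matrix(init)
  pair_dist <- function(x) {
    dm <- as.matrix(stats::dist(x))
    list(mat = dm, vec = dm[low])
  }
  pd <- pair_dist(x)
  disp <- isotonic_disparities(pd$vec, ord)
  s <- stress1(pd$vec, disp)
  history <- s
  best_x <- x; best_s <- s
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    # Guttman transform with current disparities
    dhat <- matrix(0, n, n)
    dhat[low] <- disp
    dhat <- dhat + t(dhat)
    ratio <- ifelse(pd$mat > 1e-12, dhat / pd$mat, 0)
    b <- -ratio
    diag(b) <- 0
    diag(b) <- -rowSums(b)
    x <- (b %*% x) / n
    pd <- pair_dist(x)
    disp <- isotonic_disparities(pd$vec, ord)
    s_new <- stress1(pd$vec, disp)
    if (s_new > best_s + 1e-12) { converged <- TRUE; break }
    rel <- (best_s - s_new) / max(best_s, .Machine$double.eps)
    best_x <- x; best_s <- s_new
    history <- c(history, s_new)
    if (rel < tol) { converged <- TRUE; break }
  }
  structure(list(coords = unname(best_x), stress = best_s,
                 iterations = iter, converged = converged,
                 stress_history = history),
            class = "cone_embedding")
}

#' @export
print.cone_embedding <- function(x, ...) {
  cat(sprintf("cone embedding: %d points in %d-d, STRESS1 = %.5f (%d iter%s)\n",
              nrow(x$coords), ncol(x$coords), x$stress, x$iterations,
              if (x$converged) ", converged" else ", NOT converged"))
  invisible(x)
}

#' Identify the S cones in an embedding
#'
#' 2-means clustering on the embedded coordinates (10 seeded restarts); the
#' members of the smaller cluster are taken to be the S cones, whose large
#' spectral separation isolates them in the embedding.
#'
#' @param embedding A [nmds()] result (or a coordinate matrix).
#' @param seed Integer seed for the k-means restarts.
#' @return Integer vector of S-cone indices.
#' @export
identify_s_cones <- function(embedding, seed = 1) {
  x <- if (inherits(embedding, "cone_embedding")) embedding$coords else as.matrix(embedding)
  if (nrow(x) < 3)
    cl_stop("conelearn_input_error", "need at least 3 cones")
  old_rng <- save_rng(); on.exit(restore_rng(old_rng))
  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = 2, nstart = 10)
  sizes <- km$size
  if (sizes[1] == sizes[2])
    cl_stop("conelearn_ambiguous_cluster",
            "k-means clusters have equal size (%d); retry with another seed",
            sizes[1])
  which(km$cluster == which.min(sizes))
}

#' Rotate an embedding so the spectral axis is dimension 1
#'
#' Applies the rigid rotation that aligns the vector from the mean of the
#' non-S cone positions to the mean of the S cone positions with the
#' negative first axis, so S cones sit at negative dimension-1 values.
#' Pairwise distances are preserved exactly.
#'
#' @param embedding A [nmds()] result.
#' @param s_set Integer indices of the S cones (nonempty proper subset).
#' @param rotation Optional user-supplied orthogonal matrix applied instead
#'   of the automatic alignment — the manual-rotation hook used for
#'   tritanope mosaics, where no S cones anchor the axis.
#' @return Rotated `cone_embedding` (stress and history carried over).
#' @export
rotate_embedding <- function(embedding, s_set, rotation = NULL) {
  stopifnot(inherits(embedding, "cone_embedding"))
  x <- embedding$coords
  if (is.null(rotation)) {
    if (!length(s_set) || length(s_set) >= nrow(x))
      cl_stop("conelearn_invalid_parameter",
              "s_set must be a nonempty proper subset of the cones")
    v <- colMeans(x[s_set, , drop = FALSE]) -
      colMeans(x[-s_set, , drop = FALSE])
    nv <- sqrt(sum(v^2))
    if (nv < 1e-12)
      cl_stop("conelearn_rotation_error",
              "S / non-S mean separation is degenerate (zero vector)")
    # minimal proper rotation taking a = v/|v| onto b = -e1, leaving the
    # orthogonal complement of span(a, b) fixed; identity when already
    # aligned
    a <- v / nv
    b <- c(-1, rep(0, length(v) - 1))
    if (sum(a * b) < -1 + 1e-12) {
      rotation <- diag(c(rep(-1, 2), rep(1, length(v) - 2)))  # 180 degrees
    } else {
      ab <- a + b
      r <- diag(length(v)) - tcrossprod(ab) / (1 + sum(a * b)) +
        2 * tcrossprod(b, a)
      rotation <- t(r)      # coords %*% rotation applies r to row vectors
    }
  }
  out <- embedding
  out$coords <- unname(x %*% rotation)
  out
}
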