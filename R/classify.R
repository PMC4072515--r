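# Skew-normal mixture classification of the flattened spectral positions:
# ML fits for K = 1..3 components, Kolmogorov-Smirnov goodness-of-fit model
# selection at the 0.01 criterion, and per-cone class assignment.

# -- skew-normal distribution ------------------------------------------------

#' Skew-normal density
#'
#' `2/omega * dnorm(z) * pnorm(alpha * z)` with `z = (x - xi)/omega`;
#' `alpha = 0` reduces to the normal density.
#'
#' @param x Evaluation points.
#' @param xi Location.
#' @param omega Scale, > 0.
#' @param alpha Shape (skewness direction/strength).
#' @return Density values.
#' @export
skew_normal_pdf <- function(x, xi = 0, omega = 1, alpha = 0) {
  if (omega <= 0)
    cl_stop("conelearn_domain_error", "omega must be > 0")
  z <- (x - xi) / omega
  2 / omega * stats::dnorm(z) * stats::pnorm(alpha * z)
}

# Owen's T function T(h, a) by fixed Gauss-Legendre quadrature on [0, a];
# antisymmetric in a. Accurate to ~1e-12 for |a| <= 60, ample for the
# bounded shapes used in fitting.
owens_t <- function(h, a) {
  if (a == 0) return(rep(0, length(h)))
  s <- sign(a); a <- abs(a)
  gl <- gauss_legendre_64
  x <- a / 2 * (gl$nodes + 1)
  w <- a / 2 * gl$weights
  integrand <- exp(-0.5 * outer(h^2, 1 + x^2)) /
    rep(1 + x^2, each = length(h))
  s * as.vector(integrand %*% w) / (2 * pi)
}

# 64-point Gauss-Legendre rule on [-1, 1] (Golub-Welsch).
gauss_legendre_rule <- function(n) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}
gauss_legendre_64 <- gauss_legendre_rule(64)

#' Skew-normal cumulative distribution function
#'
#' `pnorm(z) - 2 T(z, alpha)` with Owen's T evaluated by quadrature.
#'
#' @inheritParams skew_normal_pdf
#' @param q Quantiles.
#' @return CDF values in [0, 1].
#' @export
skew_normal_cdf <- function(q, xi = 0, omega = 1, alpha = 0) {
  if (omega <= 0)
    cl_stop("conelearn_domain_error", "omega must be > 0")
  z <- (q - xi) / omega
  p <- stats::pnorm(z) - 2 * owens_t(z, alpha)
  pmin(pmax(p, 0), 1)
}

#' Draw from a skew-normal distribution
#'
#' Uses the half-normal convolution representation
#' `xi + omega * (delta |U0| + sqrt(1 - delta^2) U1)`.
#'
#' @inheritParams skew_normal_pdf
#' @param n Number of draws.
#' @return Numeric vector of draws.
#' @export
rskewnorm <- function(n, xi = 0, omega = 1, alpha = 0) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- abs(stats::rnorm(n)); u1 <- stats::rnorm(n)
  xi + omega * (delta * u0 + sqrt(1 - delta^2) * u1)
}

skew_normal_mean <- function(xi, omega, alpha) {
  xi + omega * alpha / sqrt(1 + alpha^2) * sqrt(2 / pi)
}

# -- mixtures ----------------------------------------------------------------

#' Mixture density / CDF of a fitted skew-normal mixture
#'
#' @param x,q Evaluation points.
#' @param mixture A `skew_mixture` (see [fit_mixture()]) or its `components`
#'   data frame (`xi`, `omega`, `alpha`, `weight`).
#' @return Density / CDF values.
#' @export
mixture_pdf <- function(x, mixture) {
  comps <- mixture_components(mixture)
  rowSums(vapply(seq_len(nrow(comps)), function(k)
    comps$weight[k] * skew_normal_pdf(x, comps$xi[k], comps$omega[k],
                                      comps$alpha[k]),
    numeric(length(x))))
}

#' @rdname mixture_pdf
#' @export
mixture_cdf <- function(q, mixture) {
  comps <- mixture_components(mixture)
  rowSums(vapply(seq_len(nrow(comps)), function(k)
    comps$weight[k] * skew_normal_cdf(q, comps$xi[k], comps$omega[k],
                                      comps$alpha[k]),
    numeric(length(q))))
}

mixture_components <- function(mixture) {
  if (inherits(mixture, "skew_mixture")) mixture$components
  else as.data.frame(mixture)
}

# parameter vector <-> component table (weights by softmax over K logits
# with the last fixed at 0)
par_to_components <- function(par, K) {
  xi <- par[seq(1, 3 * K, by = 3)]
  omega <- exp(par[seq(2, 3 * K, by = 3)])
  alpha <- par[seq(3, 3 * K, by = 3)]
  logits <- c(if (K > 1) par[3 * K + seq_len(K - 1)], 0)
  w <- exp(logits - max(logits)); w <- w / sum(w)
  data.frame(xi = xi, omega = omega, alpha = pmax(pmin(alpha, 50), -50),
             weight = w)
}

#' Fit a skew-normal mixture by maximum likelihood
#'
#' Fits `K` skew-normal components to the flattened spectral positions by
#' direct nonlinear minimization of the negative log-likelihood
#' (Nelder-Mead), with multi-restart initialization from quantile splits of
#' the data plus seeded jitter. Component scales are floored at
#' `1e-4 * range(values)`; restarts collapsing below the floor are rejected.
#'
#' @param values Numeric data (>= 5K points).
#' @param K Number of components (1-3 in normal use).
#' @param restarts Number of restarts (default 20).
#' @param seed Integer seed (restart jitter).
#' @return Object of class `skew_mixture`: `components` (sorted by
#'   location), `loglik`, `K`, `n`.
#' @export
fit_mixture <- function(values, K, restarts = 20, seed = 1) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 5 * K)
    cl_stop("conelearn_fit_error", "need >= %d points to fit K = %d", 5 * K, K)
  old_rng <- save_rng(); on.exit(restore_rng(old_rng))
  set.seed(as.integer(seed))
  floor_omega <- 1e-4 * max(diff(range(values)), .Machine$double.eps)
  ix <- seq(1, 3 * K, by = 3)
  nll <- function(par) {
    if (any(!is.finite(par))) return(1e10)
    xi <- par[ix]; omega <- exp(par[ix + 1])
    alpha <- pmax(pmin(par[ix + 2], 50), -50)
    if (any(omega < floor_omega) || any(!is.finite(omega))) return(1e10)
    logits <- c(if (K > 1) par[3 * K + seq_len(K - 1)], 0)
    w <- exp(logits - max(logits)); w <- w / sum(w)
    dens <- 0
    for (k in seq_len(K)) {
      z <- (values - xi[k]) / omega[k]
      dens <- dens + w[k] * 2 / omega[k] * stats::dnorm(z) *
        stats::pnorm(alpha[k] * z)
    }
    -sum(log(pmax(dens, 1e-300)))
  }
  # quantile-split initialization: K contiguous blocks
  qs <- stats::quantile(values, probs = seq(0, 1, length.out = K + 1))
  block <- cut(values, breaks = unique(c(-Inf, qs[-c(1, K + 1)], Inf)),
               labels = FALSE)
  base_par <- numeric(0)
  for (k in seq_len(K)) {
    vk <- values[block == min(k, max(block))]
    m <- mean(vk); s <- max(stats::sd(vk), floor_omega, na.rm = TRUE)
    if (!is.finite(s)) s <- max(stats::sd(values), floor_omega)
    sk <- mean(((vk - m) / s)^3)
    base_par <- c(base_par, m, log(s), sign(sk) * 1)
  }
  if (K > 1) base_par <- c(base_par, rep(0, K - 1))
  spread <- stats::sd(values)
  best <- NULL
  for (r in seq_len(restarts)) {
    par0 <- base_par
    if (r > 1) {
      jit <- stats::rnorm(length(par0))
      par0[seq(1, 3 * K, by = 3)] <- par0[seq(1, 3 * K, by = 3)] +
        0.3 * spread * jit[seq(1, 3 * K, by = 3)]
      par0[seq(2, 3 * K, by = 3)] <- par0[seq(2, 3 * K, by = 3)] +
        0.3 * jit[seq(2, 3 * K, by = 3)]
      par0[seq(3, 3 * K, by = 3)] <- par0[seq(3, 3 * K, by = 3)] +
        1.5 * jit[seq(3, 3 * K, by = 3)]
    }
    fit <- tryCatch(
      stats::optim(par0, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000 * (3 * K - 1),
                                  reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    cl_stop("conelearn_fit_error", "all %d mixture restarts failed", restarts)
  comps <- par_to_components(best$par, K)
  comps <- comps[order(comps$xi), , drop = FALSE]
  rownames(comps) <- NULL
  structure(list(components = comps, loglik = -best$value, K = K, n = n),
            class = "skew_mixture")
}

#' @export
print.skew_mixture <- function(x, ...) {
  cat(sprintf("skew-normal mixture, K = %d (n = %d, logLik = %.2f)\n",
              x$K, x$n, x$loglik))
  print(format(x$components, digits = 4), ...)
  invisible(x)
}

#' Kolmogorov-Smirnov goodness of fit of a mixture
#'
#' Two-sided one-sample KS test of the data against the fitted mixture CDF:
#' `D = sup |ECDF - F|`, p-value from the asymptotic Kolmogorov
#' distribution. No correction is applied for the parameters having been
#' estimated from the same data (anti-conservative; retained deliberately as
#' part of the selection procedure).
#'
#' @param values Numeric data.
#' @param mixture A [fit_mixture()] result.
#' @return List with `D` and `p`.
#' @export
ks_pvalue <- function(values, mixture) {
  if (!length(values))
    cl_stop("conelearn_input_error", "empty values")
  ks <- suppressWarnings(
    stats::ks.test(values, function(q) mixture_cdf(q, mixture),
                   exact = FALSE))
  list(D = unname(ks$statistic), p = unname(ks$p.value))
}

#' Select the number of cone classes
#'
#' Fits mixtures of K = 1, 2, ... `k_max` skew normals to the flattened
#' positions in order and returns the first (fewest-parameter) fit whose KS
#' p-value reaches `alpha` — the smallest class count the data cannot
#' reject. If none passes, the K with the largest p-value is returned with
#' `no_adequate_fit = TRUE`.
#'
#' @param values Flattened spectral positions of the non-S cones.
#' @param k_max Largest class count tried (default 3).
#' @param alpha Acceptance criterion on the KS p-value (default 0.01).
#' @param restarts,seed Passed to [fit_mixture()].
#' @return Object of class `k_selection`: `K`, `fit` (the selected
#'   `skew_mixture`), `fits` (all tried, with `D`/`p` attached), `table`
#'   (K, D, p), `no_adequate_fit`.
#' @export
select_k <- function(values, k_max = 3, alpha = 0.01, restarts = 20,
                     seed = 1) {
  seeds <- derive_seeds(seed, k_max)
  fits <- vector("list", k_max)
  tab <- data.frame(K = seq_len(k_max), D = NA_real_, p = NA_real_)
  selected <- NA_integer_
  for (K in seq_len(k_max)) {
    fit <- fit_mixture(values, K, restarts = restarts, seed = seeds[K])
    ks <- ks_pvalue(values, fit)
    fit$D <- ks$D; fit$p <- ks$p
    fits[[K]] <- fit
    tab$D[K] <- ks$D; tab$p[K] <- ks$p
    if (ks$p >= alpha) { selected <- K; break }
  }
  no_fit <- is.na(selected)
  if (no_fit) selected <- tab$K[which.max(tab$p)]
  structure(list(K = selected, fit = fits[[selected]], fits = fits,
                 table = tab[!is.na(tab$D), ], alpha = alpha,
                 no_adequate_fit = no_fit),
            class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("selected K = %d%s (criterion p >= %.2g)\n", x$K,
              if (x$no_adequate_fit) " [no adequate fit; best available]" else "",
              x$alpha))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Assign a spectral class to every cone
#'
#' Labels each flattened position with the mixture component whose weighted
#' density is highest there (exact ties broken toward the component with the
#' larger mean). Components are ordered by how far their means lie from the
#' S side — farther from the S cones means a longer peak wavelength — and
#' named accordingly: "L" alone for K = 1, M/L for K = 2, M/A/L for K = 3
#' (override with `class_names`, shortest wavelength first). For K = 2 the
#' point between the two component means where the weighted densities are
#' equal is also reported as the classification threshold.
#'
#' @param values Flattened positions (named by cone index, as produced by
#'   [flatten()]).
#' @param mixture The selected [fit_mixture()] result.
#' @param s_side Which sign of the flattened axis the S cones occupy
#'   ("negative", the [flatten()] convention, or "positive").
#' @param class_names Optional class names, ordered from nearest to the S
#'   side (shortest lambda-max) to farthest.
#' @return Object of class `cone_classification`: `labels` (one per value,
#'   names preserved), `K`, `class_names`, `threshold` (K = 2 only),
#'   `mixture`.
#' @export
assign_classes <- function(values, mixture, s_side = c("negative", "positive"),
                           class_names = NULL) {
  s_side <- match.arg(s_side)
  comps <- mixture_components(mixture)
  K <- nrow(comps)
  mk <- skew_normal_mean(comps$xi, comps$omega, comps$alpha)
  # distance from the S side: larger values are farther when S is negative
  far <- if (s_side == "negative") mk else -mk
  ord <- order(far)                       # nearest S (shortest lambda) first
  if (is.null(class_names)) {
    class_names <- switch(as.character(K), "1" = "L", "2" = c("M", "L"),
                          "3" = c("M", "A", "L"),
                          paste0("class", seq_len(K)))
  }
  if (length(class_names) != K)
    cl_stop("conelearn_invalid_parameter",
            "class_names must have %d entries", K)
  dens <- vapply(ord, function(k)
    comps$weight[k] * skew_normal_pdf(as.numeric(values), comps$xi[k],
                                      comps$omega[k], comps$alpha[k]),
    numeric(length(values)))
  dens <- matrix(dens, ncol = K)
  pick <- max.col(dens, ties.method = "last")   # ties -> larger-mean class
  labels <- stats::setNames(class_names[pick], names(values))
  threshold <- NA_real_
  if (K == 2) {
    f <- function(x) comps$weight[ord[1]] *
      skew_normal_pdf(x, comps$xi[ord[1]], comps$omega[ord[1]], comps$alpha[ord[1]]) -
      comps$weight[ord[2]] *
      skew_normal_pdf(x, comps$xi[ord[2]], comps$omega[ord[2]], comps$alpha[ord[2]])
    lo <- min(mk); hi <- max(mk)
    if (hi > lo && is.finite(f(lo)) && is.finite(f(hi)) &&
        sign(f(lo)) != sign(f(hi))) {
      threshold <- stats::uniroot(f, c(lo, hi))$root
    }
  }
  structure(list(labels = labels, K = K, class_names = class_names,
                 threshold = threshold, mixture = mixture),
            class = "cone_classification")
}
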