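# End-to-end orchestration: config -> scenes -> mosaic -> responses ->
# correlation -> embedding -> flattening -> classification -> evaluation.

#' Pipeline configuration
#'
#' Collects every parameter of an end-to-end run with the package defaults:
#' a 20x20 mosaic with 6% S cones, L and M classes peaking at 558.9 and
#' 530 nm in a 1:1 ratio, a uniform Gaussian surround summing to 0.25, and
#' 1e5 synthetic-scene patches (the full-scale simulations in the field use
#' ~2e6; learning is near asymptotic well below that).
#'
#' @param side Mosaic side (cones).
#' @param classes List of [cone_class()] for the non-S classes, shortest to
#'   longest peak wavelength ordering not required.
#' @param ratio Positive abundance ratios, one per non-S class.
#' @param s_fraction S-cone proportion (0 for a tritanope mosaic).
#' @param s_lambda_max,min_s_spacing S-cone parameters (see
#'   [build_mosaic()]).
#' @param n_scenes,scene_size,spatial_exponent,spectral_corr_scale,mean_level,contrast
#'   Synthetic scene ensemble parameters (see [scene_model()]).
#' @param blur_sigma Optical blur sd in pixels applied to every scene
#'   (0 = none).
#' @param n_patches Number of image patches presented.
#' @param stride Cone spacing in image pixels.
#' @param surround A [surround_spec()].
#' @param noise_fraction Response noise sd as a fraction of the mean
#'   response (0 = none); `noise_per_patch` picks the per-patch or grand
#'   mean convention.
#' @param noise_per_patch Logical (default TRUE).
#' @param corr_floor Correlation clamp before the -log transform.
#' @param nmds_max_iter,nmds_tol Embedding optimizer settings.
#' @param alpha KS acceptance criterion for class-count selection.
#' @param k_max Largest class count tried.
#' @param assume_k Skip selection and fit exactly this K (as in the
#'   robustness simulations that assume two classes); NULL selects K.
#' @param restarts Mixture fit restarts.
#' @param surface_starts Multi-start count for the flattening surface fit.
#' @param prereceptoral_filter Apply lens+macular filtering to the
#'   fundamentals.
#' @param batch_size Patches per streaming batch.
#' @param seed Master seed; every stage seed derives from it.
#' @return Object of class `cone_run_config`.
#' @export
run_config <- function(side = 20,
                       classes = list(cone_class("L", 558.9),
                                      cone_class("M", 530)),
                       ratio = c(1, 1),
                       s_fraction = 0.06, s_lambda_max = 420.7,
                       min_s_spacing = 2.5,
                       n_scenes = 8, scene_size = 128,
                       spatial_exponent = 1.5, spectral_corr_scale = 120,
                       mean_level = 1, contrast = 0.35,
                       blur_sigma = 0,
                       n_patches = 1e5, stride = 1,
                       surround = surround_spec("uniform"),
                       noise_fraction = 0, noise_per_patch = TRUE,
                       corr_floor = 1e-6,
                       nmds_max_iter = 300, nmds_tol = 1e-6,
                       alpha = 0.01, k_max = 3, assume_k = NULL,
                       restarts = 20, surface_starts = 8,
                       prereceptoral_filter = TRUE,
                       batch_size = 2000, seed = 1) {
  cfg <- list(side = as.integer(side), classes = classes, ratio = ratio,
              s_fraction = s_fraction, s_lambda_max = s_lambda_max,
              min_s_spacing = min_s_spacing,
              n_scenes = as.integer(n_scenes),
              scene_size = as.integer(scene_size),
              spatial_exponent = spatial_exponent,
              spectral_corr_scale = spectral_corr_scale,
              mean_level = mean_level, contrast = contrast,
              blur_sigma = blur_sigma,
              n_patches = as.integer(n_patches), stride = as.integer(stride),
              surround = surround, noise_fraction = noise_fraction,
              noise_per_patch = noise_per_patch, corr_floor = corr_floor,
              nmds_max_iter = nmds_max_iter, nmds_tol = nmds_tol,
              alpha = alpha, k_max = as.integer(k_max), assume_k = assume_k,
              restarts = restarts, surface_starts = surface_starts,
              prereceptoral_filter = prereceptoral_filter,
              batch_size = as.integer(batch_size), seed = as.integer(seed))
  if (length(cfg$ratio) != length(cfg$classes) || any(cfg$ratio <= 0))
    cl_stop("conelearn_invalid_parameter",
            "ratio must be positive, one entry per non-S class")
  needed <- (cfg$side - 1L) * cfg$stride + 1L
  if (needed > cfg$scene_size)
    cl_stop("conelearn_invalid_parameter",
            "mosaic footprint (%d px) exceeds scene size (%d px)",
            needed, cfg$scene_size)
  structure(cfg, class = "cone_run_config")
}

# per-scene per-class response planes: plane[[g]][[class]] = H x W matrix of
# the inner product of the scene spectrum with that class' sensitivity.
class_response_planes <- function(images, sens) {
  lapply(images, function(im) {
    d <- dim(im$cube)
    flat <- matrix(im$cube, nrow = d[1] * d[2])
    lapply(sens, function(s) matrix(flat %*% s$sensitivity, d[1], d[2]))
  })
}

#' Run the full unsupervised cone-classification pipeline
#'
#' Executes every stage in order with seeded determinism: synthetic scene
#' generation (or caller-supplied images), mosaic construction, spectral
#' responses with optional surround opponency and noise, streaming cone
#' correlation, -log dissimilarity, 3-D non-metric MDS, S-cone
#' identification and rotation, quadratic-surface flattening, skew-normal
#' mixture class-count selection and per-cone classification, and the
#' evaluation metrics against the generating mosaic.
#'
#' @param config A [run_config()].
#' @param images Optional list of [hyperspectral_image()] to use instead of
#'   generated scenes.
#' @param manual_rotation Optional orthogonal 3x3 matrix applied to the raw
#'   embedding for mosaics without S cones (the tritanope hook), together
#'   with `manual_s_side` (+1/-1) fixing the flattened sign convention.
#' @param manual_s_side See `manual_rotation`.
#' @param verbose Print per-stage progress.
#' @return Object of class `cone_run_report`: selected `K`, `detection`,
#'   `balanced`/`overall` accuracy, `per_class` accuracies, `confusion`,
#'   `s_cone_accuracy`, `spatial_residual`, `stress`, plus an `artifacts`
#'   list (mosaic, correlation, embedding, flattened values, classification,
#'   selection table) and the full `config`.
#' @export
run_pipeline <- function(config, images = NULL, manual_rotation = NULL,
                         manual_s_side = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "cone_run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  sds <- derive_seeds(config$seed, 7)
  scene_seeds <- derive_seeds(sds[1], max(config$n_scenes, 1))

  # -- stimuli ---------------------------------------------------------------
  if (is.null(images)) {
    say("generating %d synthetic scenes (%d px)", config$n_scenes,
        config$scene_size)
    model <- scene_model(size = config$scene_size,
                         spatial_exponent = config$spatial_exponent,
                         spectral_corr_scale = config$spectral_corr_scale,
                         mean_level = config$mean_level,
                         contrast = config$contrast)
    images <- lapply(scene_seeds, function(s) generate_scene(model, seed = s))
  }
  if (config$blur_sigma > 0) {
    say("blurring scenes (sigma = %g px)", config$blur_sigma)
    images <- lapply(images, blur_image, sigma_px = config$blur_sigma)
  }

  # -- mosaic & spectra ------------------------------------------------------
  mosaic <- build_mosaic(config$side, config$classes, config$ratio,
                         s_fraction = config$s_fraction,
                         s_lambda_max = config$s_lambda_max,
                         min_s_spacing = config$min_s_spacing,
                         seed = sds[2])
  say("mosaic: %s", paste(capture_labels(mosaic), collapse = ", "))
  all_classes <- unique(mosaic$labels)
  lmax_of <- function(cl) mosaic$lambda_max[match(cl, mosaic$labels)]
  sens <- stats::setNames(lapply(all_classes, function(cl)
    cone_fundamental(lmax_of(cl), filter = config$prereceptoral_filter)),
    all_classes)

  # -- responses -> correlation (streaming fast path) ------------------------
  planes <- class_response_planes(images, sens)
  ps <- (config$side - 1L) * config$stride + 1L
  stream <- sample_patches(images, ps, config$n_patches, seed = sds[3])
  dims <- vapply(images, function(im) dim(im$cube)[1:2], numeric(2))
  if (any(dims != dims[1]))
    cl_stop("conelearn_invalid_parameter",
            "all images must share one size for the streaming fast path")
  H <- dims[1]
  base_off <- (mosaic$coords[, 2] - 1L) * config$stride * H +
    (mosaic$coords[, 1] - 1L) * config$stride
  W <- surround_matrix(mosaic, config$surround)
  use_surround <- config$surround$mode != "none"
  n_batches <- ceiling(config$n_patches / config$batch_size)
  noise_seeds <- if (config$noise_fraction > 0) derive_seeds(sds[4], n_batches)
  class_rows <- lapply(all_classes, function(cl) which(mosaic$labels == cl))
  responder <- function(idx) {
    dr <- stream$draws[idx, , drop = FALSE]
    patch_base <- (dr[, "col"] - 1L) * H + dr[, "row"]
    x <- matrix(0, length(base_off), length(idx))
    for (g in unique(dr[, "image"])) {
      sel <- which(dr[, "image"] == g)
      lin <- outer(base_off, patch_base[sel], "+")
      for (ci in seq_along(all_classes)) {
        rows <- class_rows[[ci]]
        x[rows, sel] <- planes[[g]][[all_classes[ci]]][lin[rows, , drop = FALSE]]
      }
    }
    if (use_surround) x <- as.matrix(x - W %*% x)
    if (config$noise_fraction > 0) {
      b <- (idx[1] - 1L) %/% config$batch_size + 1L
      x <- add_noise(x, config$noise_fraction, seed = noise_seeds[b],
                     per_patch = config$noise_per_patch)
    }
    x
  }
  say("accumulating correlations over %d patches", config$n_patches)
  corr <- accumulate_correlation(stream, responder,
                                 batch_size = config$batch_size)
  dis <- to_dissimilarity(corr, floor = config$corr_floor)

  # -- embedding -------------------------------------------------------------
  say("non-metric MDS (3-d)")
  emb <- nmds(dis, dim = 3, max_iter = config$nmds_max_iter,
              tol = config$nmds_tol)
  true_s <- which(mosaic$labels == "S")
  if (config$s_fraction > 0) {
    s_hat <- identify_s_cones(emb, seed = sds[5])
    emb_rot <- rotate_embedding(emb, s_hat)
    s_side <- NULL
  } else {
    s_hat <- integer(0)
    emb_rot <- if (!is.null(manual_rotation))
      rotate_embedding(emb, integer(0), rotation = manual_rotation) else emb
    s_side <- manual_s_side %||% -1
  }

  # -- flatten & classify ----------------------------------------------------
  non_s_hat <- setdiff(seq_len(config$side^2), s_hat)
  surf <- fit_surface(emb_rot, non_s_hat, n_starts = config$surface_starts)
  flat <- flatten(emb_rot, surf, s_hat, s_side_sign = s_side)
  vals <- flat$values
  say("classifying %d longer-wavelength cones", length(vals))
  if (!is.null(config$assume_k)) {
    fit <- fit_mixture(vals, config$assume_k, restarts = config$restarts,
                       seed = sds[6])
    ks <- ks_pvalue(vals, fit)
    fit$D <- ks$D; fit$p <- ks$p
    selection <- structure(list(K = fit$K, fit = fit, fits = list(fit),
                                table = data.frame(K = fit$K, D = ks$D,
                                                   p = ks$p),
                                alpha = config$alpha,
                                no_adequate_fit = FALSE),
                           class = "k_selection")
  } else {
    selection <- select_k(vals, k_max = config$k_max, alpha = config$alpha,
                          restarts = config$restarts, seed = sds[6])
  }
  s_side_used <- if (flat$s_side_sign < 0) "negative" else "positive"
  cls <- assign_classes(vals, selection$fit, s_side = s_side_used)

  # -- evaluation ------------------------------------------------------------
  pred <- character(config$side^2)
  pred[s_hat] <- "S"
  pred[flat$non_s_set] <- cls$labels
  truth <- mosaic$labels
  true_k <- length(config$classes)
  non_s_names <- mosaic$class_names[order(mosaic$class_lambda_max)]
  acc <- balanced_accuracy(truth, pred, classes = non_s_names)
  s_acc <- if (length(true_s))
    mean((seq_along(truth) %in% s_hat) == (truth == "S")) else NA_real_
  # spatial recovery on the true non-S cones, embedding pre-scaled to the
  # grid's overall spread (MDS units are arbitrary)
  truly_ns <- which(truth != "S")
  exy <- emb_rot$coords[truly_ns, 2:3, drop = FALSE]
  gxy <- mosaic$coords[truly_ns, , drop = FALSE]
  scale_fac <- sqrt(sum(scale(gxy, scale = FALSE)^2) /
                      max(sum(scale(exy, scale = FALSE)^2), 1e-300))
  spat <- tryCatch(spatial_recovery(exy * scale_fac, gxy),
                   error = function(e) list(residual = NA_real_))
  structure(list(K = selection$K,
                 detection = detection_outcome(selection$K, true_k),
                 true_k = true_k,
                 balanced = acc$balanced, overall = acc$overall,
                 per_class = acc$per_class, confusion = acc$confusion,
                 s_cone_accuracy = s_acc,
                 spatial_residual = spat$residual,
                 stress = emb$stress,
                 no_adequate_fit = selection$no_adequate_fit,
                 artifacts = list(mosaic = mosaic, correlation = corr,
                                  dissimilarity = dis, embedding = emb_rot,
                                  surface = surf, flattened = flat,
                                  selection = selection,
                                  classification = cls,
                                  predicted_labels = pred),
                 config = config),
            class = "cone_run_report")
}

capture_labels <- function(mosaic) {
  tb <- table(mosaic$labels)
  sprintf("%s=%d", names(tb), as.integer(tb))
}

#' @export
print.cone_run_report <- function(x, ...) {
  cat("cone-class discovery report\n")
  cat(sprintf("  mosaic: %dx%d, true longer-wavelength classes: %d\n",
              x$config$side, x$config$side, x$true_k))
  cat(sprintf("  selected K = %d (%s)%s\n", x$K, x$detection,
              if (x$no_adequate_fit) " [no adequate fit]" else ""))
  cat(sprintf("  balanced accuracy = %.1f%%, overall = %.1f%%\n",
              100 * x$balanced, 100 * x$overall))
  cat(sprintf("  per-class: %s\n",
              paste(sprintf("%s %.1f%%", names(x$per_class),
                            100 * x$per_class), collapse = ", ")))
  if (!is.na(x$s_cone_accuracy))
    cat(sprintf("  S-cone identification accuracy = %.1f%%\n",
                100 * x$s_cone_accuracy))
  cat(sprintf("  embedding STRESS1 = %.4f, spatial RMS residual = %.2f cone units\n",
              x$stress, x$spatial_residual))
  invisible(x)
}

#' Write a run report and its artifacts to disk
#'
#' Persists the report as JSON plus the per-cone label table, correlation
#' matrix, embedding and flattened positions as CSV.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_report <- function(report, dir) {
  stopifnot(inherits(report, "cone_run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  core <- report[c("K", "detection", "true_k", "balanced", "overall",
                   "per_class", "s_cone_accuracy", "spatial_residual",
                   "stress", "no_adequate_fit")]
  core$selection_table <- report$artifacts$selection$table
  jsonlite::write_json(core, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  m <- report$artifacts$mosaic
  utils::write.csv(data.frame(row = m$coords[, 1], col = m$coords[, 2],
                              true_class = m$labels,
                              predicted = report$artifacts$predicted_labels),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  utils::write.csv(report$artifacts$correlation$rho,
                   file.path(dir, "correlation.csv"), row.names = FALSE)
  emb <- report$artifacts$embedding$coords
  utils::write.csv(data.frame(cone = seq_len(nrow(emb)), dim1 = emb[, 1],
                              dim2 = emb[, 2], dim3 = emb[, 3]),
                   file.path(dir, "embedding.csv"), row.names = FALSE)
  fl <- report$artifacts$flattened
  utils::write.csv(data.frame(cone = as.integer(names(fl$values)),
                              flat_lambda = unname(fl$values)),
                   file.path(dir, "flattened.csv"), row.names = FALSE)
  invisible(dir)
}
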