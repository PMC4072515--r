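# Evaluation metrics: class-averaged accuracy, detection correctness, and
# rigid-alignment spatial recovery.

#' Class-averaged (balanced) accuracy
#'
#' Mean over classes of the per-class fraction correct — the accuracy
#' convention used throughout: with 354/354 L cones and 1/22 M cones
#' correct, the balanced accuracy is 52% while the overall fraction correct
#' is 94%.
#'
#' @param labels_true,labels_pred Equal-length label vectors.
#' @param classes Classes to average over (default: the classes present in
#'   `labels_true`). Every listed class must occur in `labels_true`.
#' @return List: `balanced`, `overall`, `per_class`, `confusion` (true x
#'   predicted table over all labels).
#' @export
balanced_accuracy <- function(labels_true, labels_pred, classes = NULL) {
  if (length(labels_true) != length(labels_pred))
    cl_stop("conelearn_invalid_parameter", "label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(labels_true))
  if (!length(classes))
    cl_stop("conelearn_undefined_class", "no classes to average over")
  per <- vapply(classes, function(cl) {
    in_cl <- labels_true == cl
    if (!any(in_cl))
      cl_stop("conelearn_undefined_class",
              "class '%s' absent from labels_true", cl)
    mean(labels_pred[in_cl] == cl)
  }, numeric(1))
  list(balanced = mean(per),
       overall = mean(labels_true == labels_pred),
       per_class = per,
       confusion = table(true = labels_true, predicted = labels_pred))
}

#' Detection outcome
#'
#' Compares the selected number of longer-wavelength classes with the true
#' count.
#'
#' @param selected_k,true_k Positive integers.
#' @return "correct", "under_detected" or "over_detected".
#' @export
detection_outcome <- function(selected_k, true_k) {
  stopifnot(selected_k >= 1, true_k >= 1)
  if (selected_k == true_k) "correct"
  else if (selected_k < true_k) "under_detected"
  else "over_detected"
}

#' Rigid least-squares spatial recovery
#'
#' Aligns the embedded (dim 2, dim 3) cone positions to the true mosaic grid
#' with an orthogonal Procrustes transformation — rotation, reflection and
#' translation, no scaling (the alignment is relative-distance-preserving) —
#' and reports the root-mean-square residual. The rotation is delegated to
#' [vegan::procrustes()].
#'
#' @param embedding_xy Embedded positions, cones x 2.
#' @param mosaic_xy True grid positions, cones x 2.
#' @return List: `aligned` (embedding mapped onto the grid), `residual`
#'   (RMS Euclidean residual per cone, in grid units), `rotation`.
#' @export
spatial_recovery <- function(embedding_xy, mosaic_xy) {
  X <- as.matrix(mosaic_xy); Y <- as.matrix(embedding_xy)
  if (nrow(X) != nrow(Y) || nrow(X) < 3)
    cl_stop("conelearn_invalid_parameter",
            "need matching coordinate sets with >= 3 cones")
  if (max(apply(Y, 2, stats::sd)) < 1e-12)
    cl_stop("conelearn_alignment_error", "embedded positions are degenerate")
  pro <- vegan::procrustes(X, Y, scale = FALSE, symmetric = FALSE)
  aligned <- Y %*% pro$rotation +
    matrix(pro$translation, nrow(Y), ncol(Y), byrow = TRUE)
  res <- sqrt(mean(rowSums((aligned - X)^2)))
  list(aligned = aligned, residual = res, rotation = pro$rotation)
}
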