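# Simulated retinal cone mosaics: rectangular grid, quasi-regular S-cone
# placement by rejection sampling, ratio-driven assignment of the
# longer-wavelength classes.

#' Cone class specification
#'
#' @param name Class name (e.g. "L", "M", "S").
#' @param lambda_max Peak sensitivity wavelength in nm, in [400, 720].
#' @return Object of class `cone_class`.
#' @export
cone_class <- function(name, lambda_max) {
  if (lambda_max < 400 || lambda_max > 720)
    cl_stop("conelearn_invalid_parameter",
            "lambda_max must be in [400, 720] nm")
  structure(list(name = as.character(name), lambda_max = lambda_max),
            class = "cone_class")
}

#' Build a simulated cone mosaic
#'
#' Constructs a `side` x `side` rectangular mosaic. S cones are placed first
#' at quasi-regular positions: candidate cells are drawn uniformly and
#' rejected if closer than `min_s_spacing` (Euclidean, in inter-cone units)
#' to an already placed S cone. The S count is exact:
#' `round(s_fraction * side^2)`. Every remaining cell is then assigned one of
#' the non-S classes independently with probability proportional to the ratio
#' vector.
#'
#' @param side Grid side (cones).
#' @param class_specs List of [cone_class()] for the non-S classes, e.g.
#'   `list(cone_class("L", 558.9), cone_class("M", 530))`.
#' @param ratio_vector Positive relative abundances, one per non-S class
#'   (e.g. `c(4, 1)` for an L:M ratio of 4:1).
#' @param s_fraction Proportion of S cones in [0, 1); 0 builds a tritanope
#'   mosaic with no S cones.
#' @param s_lambda_max Peak wavelength of S cones (default 420.7 nm).
#' @param min_s_spacing Minimum Euclidean distance between S cones in
#'   inter-cone units (default 2.5).
#' @param max_tries Rejection-sampling attempts per S cone before a
#'   placement error (default 1000).
#' @param seed Integer seed.
#' @return Object of class `cone_mosaic`: grid of labels, per-cone
#'   coordinates and lambda_max, the generating parameters.
#' @export
build_mosaic <- function(side, class_specs, ratio_vector,
                         s_fraction = 0.06, s_lambda_max = 420.7,
                         min_s_spacing = 2.5, max_tries = 1000, seed = 1) {
  if (!length(class_specs) || !all(vapply(class_specs, inherits, TRUE, "cone_class")))
    cl_stop("conelearn_invalid_parameter",
            "class_specs must be a non-empty list of cone_class objects")
  if (length(ratio_vector) != length(class_specs) || any(ratio_vector <= 0))
    cl_stop("conelearn_invalid_parameter",
            "ratio_vector must be positive, one entry per non-S class")
  if (s_fraction < 0 || s_fraction >= 1)
    cl_stop("conelearn_invalid_parameter", "s_fraction must be in [0, 1)")
  old_rng <- save_rng(); on.exit(restore_rng(old_rng))
  set.seed(as.integer(seed))
  n <- as.integer(side)^2
  n_s <- round(s_fraction * n)
  coords <- cbind(row = rep(seq_len(side), side),
                  col = rep(seq_len(side), each = side))
  s_cells <- integer(0)
  if (n_s > 0) {
    for (k in seq_len(n_s)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- sample.int(n, 1)
        if (cand %in% s_cells) next
        if (!length(s_cells)) { ok <- TRUE } else {
          dd <- sqrt((coords[s_cells, 1] - coords[cand, 1])^2 +
                       (coords[s_cells, 2] - coords[cand, 2])^2)
          ok <- all(dd >= min_s_spacing)
        }
        if (ok) { s_cells <- c(s_cells, cand); placed <- TRUE; break }
      }
      if (!placed)
        cl_stop("conelearn_placement_error",
                "could not place S cone %d of %d with spacing %.2f after %d tries",
                k, n_s, min_s_spacing, max_tries)
    }
  }
  names_ns <- vapply(class_specs, `[[`, "", "name")
  lmax_ns <- vapply(class_specs, `[[`, 0, "lambda_max")
  labels <- character(n)
  non_s <- setdiff(seq_len(n), s_cells)
  labels[non_s] <- sample(names_ns, length(non_s), replace = TRUE,
                          prob = ratio_vector / sum(ratio_vector))
  labels[s_cells] <- "S"
  lmax <- stats::setNames(c(lmax_ns, S = s_lambda_max), c(names_ns, "S"))[labels]
  structure(list(side = as.integer(side), labels = labels,
                 coords = coords, lambda_max = unname(lmax),
                 class_names = names_ns, class_lambda_max = lmax_ns,
                 ratio_vector = ratio_vector, s_fraction = s_fraction,
                 s_lambda_max = s_lambda_max,
                 min_s_spacing = min_s_spacing, seed = seed),
            class = "cone_mosaic")
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat(sprintf("cone mosaic %dx%d: %s\n", x$side, x$side,
              paste(sprintf("%s=%d", names(table(x$labels)),
                            as.integer(table(x$labels))), collapse = ", ")))
  invisible(x)
}

#' Grid neighbors of a cone
#'
#' Neighbors of a cone within a Chebyshev radius, as integer offsets in
#' inter-cone units; the center cone is excluded and boundary cones return
#' truncated lists.
#'
#' @param mosaic A [build_mosaic()] result.
#' @param cone Cone index (column-major over the grid) or `c(row, col)`.
#' @param radius Chebyshev radius (integer >= 0).
#' @return Data frame with `index`, `drow`, `dcol`, `dist` (Euclidean).
#' @export
neighbor_offsets <- function(mosaic, cone, radius) {
  stopifnot(inherits(mosaic, "cone_mosaic"))
  if (length(cone) == 2) cone <- (cone[2] - 1L) * mosaic$side + cone[1]
  if (cone < 1 || cone > mosaic$side^2)
    cl_stop("conelearn_invalid_parameter", "cone index out of range")
  r0 <- mosaic$coords[cone, 1]; c0 <- mosaic$coords[cone, 2]
  if (radius < 1) return(data.frame(index = integer(0), drow = integer(0),
                                    dcol = integer(0), dist = numeric(0)))
  dr <- mosaic$coords[, 1] - r0
  dc <- mosaic$coords[, 2] - c0
  keep <- pmax(abs(dr), abs(dc)) <= radius & !(dr == 0 & dc == 0)
  data.frame(index = which(keep), drow = dr[keep], dcol = dc[keep],
             dist = sqrt(dr[keep]^2 + dc[keep]^2))
}
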