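#' @keywords internal
#' @useDynLib conelearn, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' The standard wavelength grid
#'
#' Wavelength sampling used throughout the package: 400 to 720 nm in 10 nm
#' steps (33 bands).
#'
#' @return Numeric vector of 33 wavelengths in nm.
#' @export
standard_wavelengths <- function() seq(400, 720, by = 10)

# Structured condition helper; every package error carries a subclass so
# callers (and tests) can match on it.
cl_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(subclass, "conelearn_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Derive independent stage seeds from one master seed (all < 2^31).
derive_seeds <- function(seed, n) {
  old_rng <- save_rng(); on.exit(restore_rng(old_rng))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seeded package functions snapshot and restore the caller's RNG state so
# they never perturb the surrounding random stream:
#   old <- save_rng(); on.exit(restore_rng(old)); set.seed(seed)
save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
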