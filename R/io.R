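# Hyperspectral cube I/O: ENVI header + flat binary (BSQ, little-endian
# doubles) as the primary container, and a plain-text CSV table as the
# secondary, lossless in both directions.

#' Write a hyperspectral cube
#'
#' ENVI format writes `<path>.hdr` (text header with the wavelength grid)
#' plus `<path>.raw` (band-sequential doubles, little-endian, rows within
#' band in reading order). CSV format writes one text table: `row`, `col`,
#' then one column per band named `wl_<nm>`.
#'
#' @param image A [hyperspectral_image()].
#' @param path Output path; for ENVI, the common stem of the `.hdr`/`.raw`
#'   pair (a trailing `.hdr`/`.raw` is stripped).
#' @param format "envi" or "csv"; "auto" (default) picks CSV for a `.csv`
#'   path.
#' @return The header or csv path, invisibly.
#' @export
write_cube <- function(image, path, format = c("auto", "envi", "csv")) {
  stopifnot(inherits(image, "hyperspectral_image"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path)) "csv" else "envi"
  d <- dim(image$cube)
  if (format == "csv") {
    flat <- matrix(aperm(image$cube, c(2, 1, 3)), nrow = d[1] * d[2])
    df <- data.frame(row = rep(seq_len(d[1]), each = d[2]),
                     col = rep(seq_len(d[2]), d[1]), flat)
    names(df)[-(1:2)] <- paste0("wl_", image$wavelengths)
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  stem <- sub("\\.(hdr|raw)$", "", path)
  hdr <- c("ENVI",
           sprintf("samples = %d", d[2]),
           sprintf("lines = %d", d[1]),
           sprintf("bands = %d", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bsq",
           "byte order = 0",
           sprintf("meta = {%s}", image$meta),
           "wavelength units = Nanometers",
           sprintf("wavelength = {%s}",
                   paste(format(image$wavelengths, trim = TRUE),
                         collapse = ", ")))
  writeLines(hdr, paste0(stem, ".hdr"))
  con <- file(paste0(stem, ".raw"), "wb")
  on.exit(close(con))
  for (b in seq_len(d[3]))
    writeBin(as.vector(t(image$cube[, , b])), con, size = 8,
             endian = "little")
  invisible(paste0(stem, ".hdr"))
}

#' Read a hyperspectral cube
#'
#' Reads a cube written by [write_cube()] (either format). A cube on a
#' truncated grid that is a contiguous end-trimmed sub-grid of the standard
#' 400-720 nm grid is readable and returned with attribute
#' `needs_extrapolation = TRUE`, to be completed with
#' [extrapolate_bands()].
#'
#' @param path `.hdr` (or stem) for ENVI, `.csv` for CSV.
#' @param format See [write_cube()].
#' @return A [hyperspectral_image()].
#' @export
read_cube <- function(path, format = c("auto", "envi", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path)) "csv" else "envi"
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE)
    wl_cols <- grep("^wl_", names(df))
    if (!length(wl_cols))
      cl_stop("conelearn_parse_error", "no wl_* band columns in %s", path)
    wl <- as.numeric(sub("^wl_", "", names(df)[wl_cols]))
    nr <- max(df$row); nc <- max(df$col)
    cube <- array(0, c(nr, nc, length(wl)))
    for (b in seq_along(wl_cols))
      cube[cbind(df$row, df$col, b)] <- df[[wl_cols[b]]]
    return(flag_grid(hyperspectral_image(cube, wl, meta = basename(path))))
  }
  stem <- sub("\\.(hdr|raw)$", "", path)
  hdr_path <- paste0(stem, ".hdr")
  if (!file.exists(hdr_path))
    cl_stop("conelearn_parse_error", "header not found: %s", hdr_path)
  hdr <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(hdr, regexec(sprintf("%s *= *([0-9]+)", key), hdr))[[1]]
    if (length(m) < 2)
      cl_stop("conelearn_parse_error", "corrupt header: missing '%s'", key)
    as.integer(m[2])
  }
  samples <- get_num("samples"); lines_n <- get_num("lines")
  bands <- get_num("bands")
  wm <- regmatches(hdr, regexec("wavelength *= *\\{([^}]*)\\}", hdr))[[1]]
  if (length(wm) < 2)
    cl_stop("conelearn_parse_error", "missing wavelength metadata in %s",
            hdr_path)
  wl <- as.numeric(strsplit(wm[2], ",")[[1]])
  if (any(is.na(wl)) || length(wl) != bands)
    cl_stop("conelearn_parse_error",
            "wavelength list does not match band count in %s", hdr_path)
  meta <- regmatches(hdr, regexec("meta *= *\\{([^}]*)\\}", hdr))[[1]]
  raw <- readBin(paste0(stem, ".raw"), "double",
                 n = samples * lines_n * bands, size = 8, endian = "little")
  if (length(raw) != samples * lines_n * bands)
    cl_stop("conelearn_parse_error", "truncated data file for %s", stem)
  cube <- array(0, c(lines_n, samples, bands))
  for (b in seq_len(bands)) {
    seg <- raw[(b - 1) * samples * lines_n + seq_len(samples * lines_n)]
    cube[, , b] <- t(matrix(seg, samples, lines_n))
  }
  flag_grid(hyperspectral_image(cube, wl,
                                meta = if (length(meta) >= 2) meta[2]
                                       else basename(stem)))
}

# mark cubes on an end-trimmed standard grid as needing extrapolation
flag_grid <- function(image) {
  full <- standard_wavelengths()
  idx <- match(image$wavelengths, full)
  attr(image, "needs_extrapolation") <-
    !any(is.na(idx)) && length(idx) < length(full) && all(diff(idx) == 1)
  image
}
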