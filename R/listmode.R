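# Readers and writers for the two list-mode text formats and for
# reconstructed volumes.
#
# Both list-mode formats are header-less whitespace-delimited text, one event
# per row, written with a single space separator and fixed 6-decimal
# formatting (C locale). Readers accept arbitrary whitespace.

fmt_rows <- function(m) {
  do.call(sprintf, c(list(paste(rep("%.6f", ncol(m)), collapse = " ")),
                     lapply(seq_len(ncol(m)), function(j) m[, j])))
}

parse_lm <- function(path, ncol_expect, what) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(matrix(numeric(), 0, ncol_expect))
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf != ncol_expect)) {
    bad <- which(nf != ncol_expect)[1]
    stop(sprintf("%s: line %d has %d columns, expected %d",
                 what, bad, nf[bad], ncol_expect))
  }
  vals <- suppressWarnings(as.numeric(unlist(toks)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1] / ncol_expect)
    stop(sprintf("%s: line %d is not numeric", what, bad))
  }
  matrix(vals, ncol = ncol_expect, byrow = TRUE)
}

#' Write / read the PET list-mode format
#'
#' One line of response per row, columns `x1 y1 z1 x2 y2 z2` (mm): the
#' coordinates of the two annihilation-photon detection points.
#'
#' @param records data.frame with columns `x1, y1, z1, x2, y2, z2`.
#' @param path file path.
#' @return `write_pet_lm`: the path, invisibly. `read_pet_lm`: the records
#'   data.frame.
#' @export
write_pet_lm <- function(records, path) {
  m <- as.matrix(records[, c("x1", "y1", "z1", "x2", "y2", "z2"), drop = FALSE])
  stopifnot(all(is.finite(m)) || nrow(m) == 0)
  writeLines(fmt_rows(m), path)
  invisible(path)
}

#' @rdname write_pet_lm
#' @export
read_pet_lm <- function(path) {
  m <- parse_lm(path, 6L, "read_pet_lm")
  stats::setNames(as.data.frame(m), c("x1", "y1", "z1", "x2", "y2", "z2"))
}

#' Write / read the Compton-camera list-mode format
#'
#' One cone of response per row, columns `xs ys zs E1 xa ya za E2`: Compton
#' scatter position (mm) and transferred energy (keV), then photoelectric
#' absorption position and its deposited energy.
#'
#' On read, rows with `E1 <= 0` or `E2 <= 0` are kept but flagged (logical
#' column `valid`), with a warning.
#'
#' @param records data.frame with columns `xs, ys, zs, E1, xa, ya, za, E2`.
#' @param path file path.
#' @return `write_cc_lm`: the path, invisibly. `read_cc_lm`: the records
#'   data.frame (with a `valid` flag column).
#' @export
write_cc_lm <- function(records, path) {
  m <- as.matrix(records[, c("xs", "ys", "zs", "E1", "xa", "ya", "za", "E2"),
                         drop = FALSE])
  stopifnot(all(is.finite(m)) || nrow(m) == 0)
  writeLines(fmt_rows(m), path)
  invisible(path)
}

#' @rdname write_cc_lm
#' @export
read_cc_lm <- function(path) {
  m <- parse_lm(path, 8L, "read_cc_lm")
  d <- stats::setNames(as.data.frame(m),
                       c("xs", "ys", "zs", "E1", "xa", "ya", "za", "E2"))
  d$valid <- d$E1 > 0 & d$E2 > 0
  if (nrow(d) && any(!d$valid)) {
    warning(sprintf("read_cc_lm: %d record(s) with nonpositive energy flagged",
                    sum(!d$valid)))
  }
  d
}

#' Write / read a reconstructed volume
#'
#' Raw little-endian 32-bit float voxel block in x-fastest order, with a JSON
#' sidecar (`<path>.json`) recording grid dims, voxel size and origin.
#' Round-trips losslessly at 32-bit precision.
#'
#' @param volume an [image_volume()].
#' @param path path of the raw block; the sidecar is written next to it.
#' @return `write_volume`: the path, invisibly. `read_volume`: the
#'   [image_volume()].
#' @export
write_volume <- function(volume, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(volume$values), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(dims = volume$dims, voxel_mm = volume$voxel_mm,
         origin = volume$origin, dtype = "float32", order = "x-fastest"),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(side$dims)
  n <- prod(dims)
  if (file.info(path)$size != 4 * n) {
    stop(sprintf("read_volume: block size %d does not match sidecar dims (%s)",
                 file.info(path)$size, paste(dims, collapse = "x")))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, numeric(), n = n, size = 4L, endian = "little")
  image_volume(array(v, dim = dims), dims = dims,
               voxel_mm = side$voxel_mm, origin = side$origin)
}

#' Validate a list-mode file
#'
#' Reports the row count and any validation failures for a PET or CC
#' list-mode file.
#' @param path file path.
#' @param mode `"pet"` or `"cc"`.
#' @return list with `rows` and `valid` counts.
#' @export
lm_validate <- function(path, mode = c("pet", "cc")) {
  mode <- match.arg(mode)
  d <- if (mode == "pet") read_pet_lm(path) else suppressWarnings(read_cc_lm(path))
  list(rows = nrow(d),
       valid = if (mode == "cc") sum(d$valid) else nrow(d))
}
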