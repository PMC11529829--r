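# Dual-panel edge-on CZT crystal tiling, point location, readout quantization.
#
# Coordinate frame: origin at the phantom center. y is the panel-normal axis
# (panels at y in [100, 140] and [-140, -100] mm for the default separation);
# x spans the 200 mm panel width; z the 150 mm stacking axis. Each 40x40x5 mm
# crystal presents its 40 mm depth edge-on along y; the 5 mm dimension stacks
# along z.

#' Build the dual-panel detector geometry
#'
#' Tiles each panel exactly with crystals and returns the crystal index map
#' plus readout pitches. Defaults are the two-panel configuration: 20 x 15 cm
#' panel faces, 4 cm depth, 20 cm between inner faces, 4 x 4 x 0.5 cm
#' crystals (150 per panel: 5 columns of 30 edge-on stacked crystals), and
#' cross-strip readout pitches of 1 mm along x, 5 mm along y (depth) and
#' 1 mm along z.
#'
#' @param config optional list overriding any of `panel_separation_mm`,
#'   `panel_width_mm`, `panel_height_mm`, `panel_depth_mm`,
#'   `crystal_dims_mm` (length-3: x, y, z extents of one crystal) and
#'   `readout_pitch_mm` (length-3; a 0 entry disables quantization on that
#'   axis). Panel dimensions must be integer multiples of the crystal
#'   dimensions on each tiling axis.
#' @return an object of class `detector_geometry` with the panel specs, a
#'   `crystals` data.frame (id, panel, col, slab, xmin..zmax) and the readout
#'   pitches.
#' @export
build_geometry <- function(config = list()) {
  cfg <- utils::modifyList(list(
    panel_separation_mm = 200,
    panel_width_mm = 200,
    panel_height_mm = 150,
    panel_depth_mm = 40,
    crystal_dims_mm = c(40, 40, 5),
    readout_pitch_mm = c(1, 5, 1)
  ), config)
  cd <- cfg$crystal_dims_mm
  stopifnot(length(cd) == 3, all(cd > 0), all(cfg$readout_pitch_mm >= 0))
  ntile <- c(cfg$panel_width_mm / cd[1], cfg$panel_depth_mm / cd[2],
             cfg$panel_height_mm / cd[3])
  for (ax in 1:3) {
    if (abs(ntile[ax] - round(ntile[ax])) > 1e-9) {
      stop(sprintf("build_geometry: panel dimension not an integer multiple of the crystal dimension on the %s axis",
                   c("x", "y", "z")[ax]))
    }
  }
  ntile <- round(ntile)
  ncol_ <- ntile[1]; nslab <- ntile[3]
  y0 <- cfg$panel_separation_mm / 2
  x0 <- -cfg$panel_width_mm / 2
  z0 <- -cfg$panel_height_mm / 2

  grid <- expand.grid(col = seq_len(ncol_), slab = seq_len(nslab),
                      panel = c(1L, 2L))
  xmin <- x0 + (grid$col - 1) * cd[1]
  zmin <- z0 + (grid$slab - 1) * cd[3]
  ymin <- ifelse(grid$panel == 1L, y0, -y0 - cfg$panel_depth_mm)
  crystals <- data.frame(
    id = seq_len(nrow(grid)),
    panel = grid$panel, col = grid$col, slab = grid$slab,
    xmin = xmin, xmax = xmin + cd[1],
    ymin = ymin, ymax = ymin + cfg$panel_depth_mm,
    zmin = zmin, zmax = zmin + cd[3]
  )
  structure(list(config = cfg, crystals = crystals,
                 n_per_panel = ncol_ * nslab,
                 readout_pitch = cfg$readout_pitch_mm),
            class = "detector_geometry")
}

#' Locate points in detector crystals
#'
#' Maps each point to the unique crystal whose half-open box (boundaries
#' half-open toward increasing coordinate) contains it, by index arithmetic.
#'
#' @param geometry a [build_geometry()] result.
#' @param points `n x 3` matrix (or length-3 vector) of positions, mm.
#' @return integer vector of crystal ids, `NA` where no crystal contains the
#'   point.
#' @export
locate_point <- function(geometry, points) {
  p <- to_mat3(points)
  cfg <- geometry$config
  cd <- cfg$crystal_dims_mm
  y0 <- cfg$panel_separation_mm / 2
  x0 <- -cfg$panel_width_mm / 2
  z0 <- -cfg$panel_height_mm / 2
  ncol_ <- round(cfg$panel_width_mm / cd[1])
  nslab <- round(cfg$panel_height_mm / cd[3])

  panel <- ifelse(p[, 2] >= y0 & p[, 2] < y0 + cfg$panel_depth_mm, 1L,
           ifelse(p[, 2] >= -y0 - cfg$panel_depth_mm & p[, 2] < -y0, 2L, NA_integer_))
  col <- floor((p[, 1] - x0) / cd[1]) + 1
  slab <- floor((p[, 3] - z0) / cd[3]) + 1
  ok <- !is.na(panel) & col >= 1 & col <= ncol_ & slab >= 1 & slab <= nslab &
    p[, 1] >= x0 & p[, 3] >= z0
  id <- rep(NA_integer_, nrow(p))
  # id layout must match build_geometry's expand.grid(col, slab, panel)
  id[ok] <- (as.integer(panel[ok]) - 1L) * geometry$n_per_panel +
    (as.integer(slab[ok]) - 1L) * ncol_ + as.integer(col[ok])
  id
}

#' Quantize interaction positions to the readout pitch
#'
#' Snaps each coordinate to the center of its readout bin within the crystal
#' (bin index from the crystal's low edge). A pitch of 0 on an axis leaves
#' that coordinate unchanged. Quantized points remain inside the crystal.
#'
#' @param geometry a [build_geometry()] result.
#' @param points `n x 3` matrix of positions, mm.
#' @param crystal_id integer vector of containing crystals (from
#'   [locate_point()]).
#' @return `n x 3` matrix of quantized positions.
#' @export
quantize_position <- function(geometry, points, crystal_id) {
  p <- to_mat3(points)
  cry <- geometry$crystals[crystal_id, , drop = FALSE]
  lo <- as.matrix(cry[, c("xmin", "ymin", "zmin")])
  hi <- as.matrix(cry[, c("xmax", "ymax", "zmax")])
  if (any(p < lo - 1e-9 | p > hi + 1e-9)) {
    stop("quantize_position: point outside its crystal")
  }
  out <- p
  pitch <- geometry$readout_pitch
  for (ax in 1:3) {
    if (pitch[ax] > 0) {
      i <- floor((p[, ax] - lo[, ax]) / pitch[ax])
      ctr <- lo[, ax] + (i + 0.5) * pitch[ax]
      out[, ax] <- pmin(pmax(ctr, lo[, ax]), hi[, ax])
    }
  }
  out
}

#' Write the crystal boxes as CSV
#'
#' Inspection dump of the crystal index map (id, panel, col, slab,
#' xmin..zmax).
#' @param geometry a [build_geometry()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
geometry_dump <- function(geometry, path) {
  utils::write.csv(geometry$crystals, path, row.names = FALSE)
  invisible(path)
}

to_mat3 <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  stopifnot(ncol(p) == 3)
  p
}
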