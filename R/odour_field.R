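## Odour landscapes -----------------------------------------------------------
##
## A field is a list(kind, p, grid, noise, label) understood by the compiled
## evaluator; the same evaluator serves both the simulation engine and the
## analysis side, so concentrations agree bit-for-bit.

new_odour_field <- function(kind, p, grid = NULL, noise = NULL, label = "") {
  structure(list(kind = as.integer(kind), p = as.double(p),
                 grid = grid, noise = noise, label = label),
            class = "odour_field")
}

unit2 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("direction vector must be nonzero")
  v / n
}

#' Uniform (zero-gradient) odour field
#'
#' @param value constant concentration (dimensionless, >= 0).
#' @return an `odour_field` object.
#' @export
odour_field_uniform <- function(value = 1) {
  stopifnot(value >= 0)
  new_odour_field(0L, value, label = "uniform")
}

#' Gaussian odour field
#'
#' Concentration `peak_value * exp(-|p - peak|^2 / (2 sigma^2))`, the standard
#' surrogate for a point odour source. Peak concentration is normalised to
#' `peak_value` (default 1).
#'
#' @param peak source position, `c(x, y)` in mm.
#' @param sigma length scale of the Gaussian, mm.
#' @param peak_value concentration at the peak.
#' @return an `odour_field` object.
#' @export
odour_field_gaussian <- function(peak = c(0, 0), sigma = 30, peak_value = 1) {
  stopifnot(sigma > 0, peak_value >= 0)
  new_odour_field(1L, c(peak, sigma, peak_value), label = "gaussian")
}

#' Linear odour gradient
#'
#' Concentration interpolates from `low` at point `from` to `high` at point
#' `to` along the axis joining them, clamped to `[low, high]` beyond the
#' endpoints.
#'
#' @param from,to points `c(x, y)` in mm defining the gradient axis.
#' @param low,high concentrations at `from` and `to`.
#' @return an `odour_field` object.
#' @export
odour_field_linear <- function(from, to, low = 0, high = 1) {
  stopifnot(low >= 0, high >= 0, any(from != to))
  new_odour_field(2L, c(from, to, low, high), label = "linear")
}

#' Exponential odour gradient
#'
#' Concentration `peak_value * exp(s / scale)` where `s <= 0` is the signed
#' distance along `direction` from the peak position (capped at `peak_value`
#' beyond the peak). Gives a constant relative gradient `1/scale`, so a larva
#' running straight up-gradient perceives a constant signal `v / scale`.
#'
#' @param peak position of the concentration maximum, `c(x, y)` mm.
#' @param scale length constant in mm.
#' @param direction up-gradient axis (need not be unit length).
#' @param peak_value concentration at the peak.
#' @return an `odour_field` object.
#' @export
odour_field_exponential <- function(peak, scale, direction = c(1, 0), peak_value = 1) {
  stopifnot(scale > 0, peak_value >= 0)
  u <- unit2(direction)
  new_odour_field(3L, c(peak, u, scale, peak_value), label = "exponential")
}

#' Step odour field with a linear ramp
#'
#' Concentration `low` on one side of a line through `centre`, `high` on the
#' other, joined by a linear ramp of the given `width`.
#'
#' @param centre point on the mid-line of the ramp, `c(x, y)` mm.
#' @param direction axis pointing towards the `high` side.
#' @param width ramp width, mm.
#' @param low,high concentrations on the two sides.
#' @return an `odour_field` object.
#' @export
odour_field_step <- function(centre = c(0, 0), direction = c(1, 0), width = 5,
                             low = 0, high = 1) {
  stopifnot(width > 0, low >= 0, high >= 0)
  u <- unit2(direction)
  new_odour_field(4L, c(centre, u, width, low, high), label = "step")
}

#' Gridded odour field
#'
#' A matrix of concentrations on a regular grid: bilinear interpolation inside
#' the grid hull, constant extrapolation outside. Row index runs along y
#' (row 1 = minimum y), column index along x.
#'
#' @param values numeric matrix of concentrations (all >= 0), `nrow` = number
#'   of y nodes, `ncol` = number of x nodes.
#' @param origin position `c(x, y)` in mm of the `values[1, 1]` node.
#' @param cell grid spacing in mm.
#' @return an `odour_field` object.
#' @export
odour_field_grid <- function(values, origin = c(0, 0), cell = 1) {
  values <- as.matrix(values)
  if (length(values) == 0) stop("grid odour field has an empty matrix")
  stopifnot(cell > 0, all(is.finite(values)), all(values >= 0))
  storage.mode(values) <- "double"
  new_odour_field(5L, numeric(0),
                  grid = list(values = values, origin = as.double(origin),
                              cell = as.double(cell)),
                  label = "grid")
}

as_points <- function(p) {
  if (is.matrix(p)) {
    storage.mode(p) <- "double"
    p
  } else {
    matrix(as.double(p), ncol = 2, byrow = TRUE)
  }
}

#' Odour concentration at a point
#'
#' @param field an `odour_field`.
#' @param p a point `c(x, y)` in mm or an n x 2 matrix of points.
#' @return numeric vector of concentrations (>= 0), one per point.
#' @export
concentration <- function(field, p) {
  stopifnot(inherits(field, "odour_field"))
  pts <- as_points(p)
  stopifnot(all(is.finite(pts)))
  field_eval_cpp(field, pts)
}

#' Finite-difference odour gradient
#'
#' Central finite difference of the concentration with step `h` (default
#' 0.1 mm), used to define the local up-gradient direction for bearing
#' statistics.
#'
#' @param field an `odour_field`.
#' @param p a point or n x 2 matrix of points, mm.
#' @param h finite-difference step, mm.
#' @return n x 2 matrix of gradient components (concentration / mm).
#' @export
field_gradient <- function(field, p, h = 0.1) {
  pts <- as_points(p)
  gx <- (concentration(field, cbind(pts[, 1] + h, pts[, 2])) -
         concentration(field, cbind(pts[, 1] - h, pts[, 2]))) / (2 * h)
  gy <- (concentration(field, cbind(pts[, 1], pts[, 2] + h)) -
         concentration(field, cbind(pts[, 1], pts[, 2] - h))) / (2 * h)
  cbind(gx = gx, gy = gy)
}

#' Local up-gradient direction
#'
#' @inheritParams field_gradient
#' @return direction of maximal concentration increase in degrees
#'   anticlockwise from +x; `NA` where the gradient vanishes.
#' @export
gradient_direction <- function(field, p, h = 0.1) {
  g <- field_gradient(field, p, h)
  out <- unname(atan2(g[, 2], g[, 1]) * 180 / pi)
  out[g[, 1] == 0 & g[, 2] == 0] <- NA_real_
  out
}

#' Overlay multiplicative grid noise on an odour field
#'
#' Divides the covered extent into square cells of side `cell` and multiplies
#' the concentration in each cell by an independent draw from
#' Normal(1, `variance`), clamped at zero so concentrations stay
#' non-negative. The same seed always reproduces the same field.
#'
#' @param field an `odour_field`.
#' @param extent either an `arena` (its bounding box is used) or
#'   `c(xmin, xmax, ymin, ymax)` in mm.
#' @param cell noise cell side, mm (default 0.08).
#' @param variance variance of the multiplier distribution (>= 0).
#' @param seed integer seed for the multiplier draws.
#' @return an `odour_field` with the noise grid attached.
#' @export
apply_multiplicative_noise <- function(field, extent, cell = 0.08,
                                       variance = 0.04, seed = 1) {
  stopifnot(inherits(field, "odour_field"), cell > 0)
  if (variance < 0) stop("noise variance must be >= 0")
  if (variance == 0) return(field)
  if (inherits(extent, "arena")) extent <- arena_bbox(extent)
  stopifnot(length(extent) == 4, extent[2] > extent[1], extent[4] > extent[3])
  nx <- ceiling((extent[2] - extent[1]) / cell)
  ny <- ceiling((extent[4] - extent[3]) / cell)
  m <- with_seed(seed, matrix(pmax(0, rnorm(nx * ny, mean = 1, sd = sqrt(variance))),
                              nrow = ny, ncol = nx))
  field$noise <- list(values = m, origin = as.double(c(extent[1], extent[3])),
                      cell = as.double(cell))
  field
}

#' @export
print.odour_field <- function(x, ...) {
  cat("<odour_field>", x$label, "\n")
  if (!is.null(x$grid))
    cat("  grid:", nrow(x$grid$values), "x", ncol(x$grid$values),
        "nodes, cell", x$grid$cell, "mm\n")
  if (!is.null(x$noise))
    cat("  multiplicative noise:", nrow(x$noise$values), "x",
        ncol(x$noise$values), "cells of", x$noise$cell, "mm\n")
  invisible(x)
}

## Grid landscape file format: three header lines giving the origin and cell
## size, then the concentration matrix row-major with row 1 = minimum y.

#' Write a gridded odour landscape to a TSV file
#'
#' @param field a grid-kind `odour_field` (see [odour_field_grid()] or
#'   [sample_field_to_grid()]).
#' @param path output file path.
#' @export
write_odour_grid <- function(field, path) {
  stopifnot(inherits(field, "odour_field"), field$kind == 5L)
  g <- field$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# origin_x_mm %.17g", g$origin[1]),
               sprintf("# origin_y_mm %.17g", g$origin[2]),
               sprintf("# cell_mm %.17g", g$cell)), con)
  write.table(format(g$values, digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a gridded odour landscape from a TSV file
#'
#' @param path file written by [write_odour_grid()].
#' @return a grid-kind `odour_field`.
#' @export
read_odour_grid <- function(path) {
  lines <- readLines(path)
  hdr <- lines[seq_len(3)]
  val <- function(key) {
    ln <- hdr[grepl(paste0("^# ", key), hdr)]
    if (length(ln) != 1) stop("malformed grid file header: missing ", key)
    as.numeric(sub(paste0("# ", key, " "), "", ln))
  }
  m <- as.matrix(read.table(text = lines[-seq_len(3)], sep = "\t"))
  dimnames(m) <- NULL
  odour_field_grid(m, origin = c(val("origin_x_mm"), val("origin_y_mm")),
                   cell = val("cell_mm"))
}

#' Sample any odour field onto a regular grid
#'
#' @param field an `odour_field`.
#' @param extent `c(xmin, xmax, ymin, ymax)` mm or an `arena`.
#' @param cell grid spacing, mm.
#' @return a grid-kind `odour_field` holding the sampled concentrations.
#' @export
sample_field_to_grid <- function(field, extent, cell = 1) {
  if (inherits(extent, "arena")) extent <- arena_bbox(extent)
  xs <- seq(extent[1], extent[2], by = cell)
  ys <- seq(extent[3], extent[4], by = cell)
  pts <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  v <- matrix(concentration(field, pts), nrow = length(ys), ncol = length(xs))
  odour_field_grid(v, origin = c(xs[1], ys[1]), cell = cell)
}
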