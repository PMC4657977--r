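## Arenas, walls and regions of interest --------------------------------------

new_arena <- function(kind, p, label) {
  structure(list(kind = as.integer(kind), p = as.double(p), label = label),
            class = "arena")
}

#' Circular arena (Petri dish)
#'
#' @param radius dish radius, mm.
#' @param centre dish centre, `c(x, y)` mm.
#' @return an `arena` object.
#' @export
arena_circle <- function(radius = 45, centre = c(0, 0)) {
  stopifnot(radius > 0)
  new_arena(1L, c(centre, radius), "circle")
}

#' Rectangular arena
#'
#' @param width extent along x, mm.
#' @param height extent along y, mm.
#' @param centre arena centre, `c(x, y)` mm.
#' @return an `arena` object.
#' @export
arena_rectangle <- function(width, height, centre = c(0, 0)) {
  stopifnot(width > 0, height > 0)
  new_arena(2L, c(centre, width, height), "rectangle")
}

#' Unbounded arena (no walls)
#' @return an `arena` object with no wall geometry.
#' @export
arena_none <- function() new_arena(0L, numeric(0), "none")

#' Arena bounding box
#' @param arena an `arena`.
#' @return `c(xmin, xmax, ymin, ymax)` in mm.
#' @export
arena_bbox <- function(arena) {
  stopifnot(inherits(arena, "arena"))
  p <- arena$p
  switch(as.character(arena$kind),
         "1" = c(p[1] - p[3], p[1] + p[3], p[2] - p[3], p[2] + p[3]),
         "2" = c(p[1] - p[3] / 2, p[1] + p[3] / 2, p[2] - p[4] / 2, p[2] + p[4] / 2),
         stop("unbounded arena has no bounding box"))
}

#' Wall contact report
#'
#' A point on or outside the wall is in contact; the report includes the
#' inward unit normal (the direction back into the arena) and the distance by
#' which the point lies outside.
#'
#' @param arena an `arena`.
#' @param p point `c(x, y)` or n x 2 matrix, mm.
#' @return data.frame with columns `contact` (logical), `nx`, `ny` (inward
#'   normal) and `pen` (penetration depth, mm).
#' @export
wall_contact <- function(arena, p) {
  stopifnot(inherits(arena, "arena"))
  res <- arena_contact_cpp(arena, as_points(p))
  data.frame(contact = res$contact, nx = res$nx, ny = res$ny, pen = res$pen)
}

#' Is a point strictly inside the arena walls?
#' @inheritParams wall_contact
#' @return logical vector.
#' @export
point_in_arena <- function(arena, p) {
  if (arena$kind == 0L) return(rep(TRUE, nrow(as_points(p))))
  !wall_contact(arena, p)$contact
}

#' @export
print.arena <- function(x, ...) {
  cat("<arena>", x$label)
  if (x$kind == 1L) cat(" radius", x$p[3], "mm")
  if (x$kind == 2L) cat(" ", x$p[3], "x", x$p[4], "mm")
  cat("\n")
  invisible(x)
}

## Regions of interest ---------------------------------------------------------

#' Circular region of interest
#' @param centre circle centre, mm.
#' @param radius circle radius, mm.
#' @return an `roi` object usable with [in_roi()] and [chemotaxis_index()].
#' @export
roi_circle <- function(centre, radius) {
  stopifnot(radius > 0)
  structure(list(kind = "circle", centre = centre, radius = radius), class = "roi")
}

#' Half-plane region of interest
#'
#' Contains the points whose projection on `direction` is at least `offset`
#' (projections taken from the coordinate origin).
#'
#' @param direction axis defining the half-plane normal.
#' @param offset signed threshold along the axis, mm.
#' @return an `roi` object.
#' @export
roi_halfplane <- function(direction, offset = 0) {
  structure(list(kind = "halfplane", u = unit2(direction), offset = offset),
            class = "roi")
}

#' Band region of interest
#'
#' Points whose projection on `direction` lies in `[lo, hi]`.
#'
#' @inheritParams roi_halfplane
#' @param lo,hi band limits along the axis, mm.
#' @return an `roi` object.
#' @export
roi_band <- function(direction, lo, hi) {
  stopifnot(hi > lo)
  structure(list(kind = "band", u = unit2(direction), lo = lo, hi = hi),
            class = "roi")
}

#' Region-of-interest membership
#' @param roi an `roi` object.
#' @param p point or n x 2 matrix, mm.
#' @return logical vector.
#' @export
in_roi <- function(roi, p) {
  stopifnot(inherits(roi, "roi"))
  pts <- as_points(p)
  switch(roi$kind,
         circle = sqrt((pts[, 1] - roi$centre[1])^2 +
                       (pts[, 2] - roi$centre[2])^2) <= roi$radius,
         halfplane = pts %*% roi$u >= roi$offset,
         band = {
           s <- drop(pts %*% roi$u)
           s >= roi$lo & s <= roi$hi
         })
}

#' Choice-assay partition
#'
#' Splits the dish into two sides about a line through the arena centre, with
#' a centre-exclusion band: larvae inside the band are excluded from the side
#' counts but still count towards the total in the preference index.
#'
#' @param direction axis pointing towards side 1 (default: the left,
#'   odour-bearing side of the standard assay).
#' @param exclude_halfwidth half-width of the centre exclusion band, mm
#'   (default 5, a 1 cm band).
#' @return a `choice_partition` object for [preference_index()].
#' @export
choice_partition <- function(direction = c(-1, 0), exclude_halfwidth = 5) {
  stopifnot(exclude_halfwidth >= 0)
  structure(list(u = unit2(direction), half = exclude_halfwidth),
            class = "choice_partition")
}
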