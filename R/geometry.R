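# Pouch geometry: crypt-villus unit templates and the cylindrical unit lattice.
#
# The pouch is a cylinder tiled by crypt-villus units on an axial x
# circumferential lattice. Each unit carries two square prisms (a crypt
# invagination and a villus projection) whose four lateral faces are
# unwrapped into 2D grids; the prism tips/valleys are closed by a single cap
# row. The geometry object is lazy: it stores per-unit heights only, so an
# anatomic-scale pouch (tens of millions of sites) can be constructed and
# size-accounted without allocating per-site arrays.

#' Crypt-villus unit template
#'
#' Describes one crypt-villus unit: the number of grid rows in the villus and
#' crypt components, the width of each lateral prism face, and the number of
#' faces. The default template is calibrated so that the villus:crypt site
#' ratio at full occupancy is approximately 4:1, matching small-intestinal
#' histology.
#'
#' @param villus_height integer, villus rows per face (row 0 = villus base).
#' @param crypt_depth integer, crypt rows per face (row 0 = crypt base).
#' @param face_width integer, columns per lateral face.
#' @param n_faces integer, lateral faces per prism. Only 4 (square prisms) is
#'   supported: the fold adjacency maps each face onto one of the four unit
#'   lattice directions.
#' @param cap_rows integer, rows closing the villus tip / crypt valley
#'   (currently always 1: a single fold line joining opposite faces).
#' @return An object of class `cv_unit`.
#' @export
crypt_villus_unit <- function(villus_height = 50L, crypt_depth = 12L,
                              face_width = 6L, n_faces = 4L, cap_rows = 1L) {
  villus_height <- as.integer(villus_height)
  crypt_depth <- as.integer(crypt_depth)
  face_width <- as.integer(face_width)
  if (is.na(villus_height) || villus_height < 1L)
    stop("villus_height must be an integer >= 1", call. = FALSE)
  if (is.na(crypt_depth) || crypt_depth < 1L)
    stop("crypt_depth must be an integer >= 1", call. = FALSE)
  if (is.na(face_width) || face_width < 1L)
    stop("face_width must be an integer >= 1", call. = FALSE)
  if (as.integer(n_faces) != 4L)
    stop("only n_faces = 4 (square prisms) is supported by the fold adjacency",
         call. = FALSE)
  if (as.integer(cap_rows) != 1L)
    stop("only cap_rows = 1 (single fold-line closure) is supported",
         call. = FALSE)
  structure(list(villus_height = villus_height, crypt_depth = crypt_depth,
                 face_width = face_width, n_faces = 4L, cap_rows = 1L),
            class = "cv_unit")
}

#' @export
print.cv_unit <- function(x, ...) {
  cat(sprintf("<cv_unit> villus %d rows, crypt %d rows, %d faces x %d cols\n",
              x$villus_height, x$crypt_depth, x$n_faces, x$face_width))
  invisible(x)
}

.unit_table <- function(n_axial, n_circ, template) {
  n_units <- n_axial * n_circ
  u <- seq_len(n_units) - 1L
  data.frame(unit = u,
             axial = u %/% n_circ,
             circ = u %% n_circ,
             villus_height = rep(template$villus_height, n_units),
             crypt_depth = rep(template$crypt_depth, n_units))
}

.new_pouch <- function(diameter_cm, length_cm, unit_spacing_mm,
                       n_axial, n_circ, template) {
  structure(list(diameter_cm = diameter_cm, length_cm = length_cm,
                 unit_spacing_mm = unit_spacing_mm,
                 n_axial = as.integer(n_axial), n_circ = as.integer(n_circ),
                 template = template,
                 units = .unit_table(n_axial, n_circ, template)),
            class = "pouch_geometry")
}

#' Build a cylindrical pouch tiled with crypt-villus units
#'
#' Places `n_axial x n_circ` copies of the unit template on a cylinder, with
#' `n_circ = floor(pi * diameter_cm * 10 / unit_spacing_mm)` and
#' `n_axial = floor(length_cm * 10 / unit_spacing_mm)`. The unit lattice wraps
#' circumferentially (cylinder) but not axially. Construction is lazy: no
#' per-site arrays are allocated, so anatomic dimensions (e.g. a 3.5 cm x 6 cm
#' pouch, ~26k units) are cheap to build and size-account.
#'
#' @param diameter_cm,length_cm pouch dimensions in centimetres (> 0).
#' @param unit_spacing_mm centre-to-centre spacing of units in millimetres.
#' @param template a [crypt_villus_unit()].
#' @return A `pouch_geometry` object.
#' @examples
#' geom <- build_pouch(3.5, 6, 0.5)
#' geom$n_circ  # 219
#' geom$n_axial # 120
#' @export
build_pouch <- function(diameter_cm, length_cm, unit_spacing_mm = 0.5,
                        template = crypt_villus_unit()) {
  if (!is.numeric(diameter_cm) || length(diameter_cm) != 1 || diameter_cm <= 0)
    stop("diameter_cm must be a single positive number", call. = FALSE)
  if (!is.numeric(length_cm) || length(length_cm) != 1 || length_cm <= 0)
    stop("length_cm must be a single positive number", call. = FALSE)
  if (!is.numeric(unit_spacing_mm) || length(unit_spacing_mm) != 1 ||
      unit_spacing_mm <= 0)
    stop("unit_spacing_mm must be a single positive number", call. = FALSE)
  stopifnot(inherits(template, "cv_unit"))
  # tiny epsilon so that exact-fit spacings are not lost to float round-off
  n_circ <- floor(pi * diameter_cm * 10 / unit_spacing_mm + 1e-9)
  n_axial <- floor(length_cm * 10 / unit_spacing_mm + 1e-9)
  if (n_circ < 1L)
    stop("unit_spacing_mm exceeds the pouch circumference: no unit fits",
         call. = FALSE)
  if (n_axial < 1L)
    stop("unit_spacing_mm exceeds the pouch length: no unit fits",
         call. = FALSE)
  .new_pouch(diameter_cm, length_cm, unit_spacing_mm, n_axial, n_circ, template)
}

#' Build a pouch directly from a unit lattice
#'
#' Desk-scale convenience constructor: specifies the unit lattice explicitly
#' (e.g. 8 x 8 units) and derives nominal cylinder dimensions from the
#' spacing, so that coordinate mapping and axial positions remain defined.
#'
#' @param n_axial,n_circ unit lattice dimensions (>= 1).
#' @param template a [crypt_villus_unit()].
#' @param unit_spacing_mm centre-to-centre unit spacing in millimetres.
#' @return A `pouch_geometry` object.
#' @export
lattice_pouch <- function(n_axial, n_circ, template = crypt_villus_unit(),
                          unit_spacing_mm = 0.5) {
  n_axial <- as.integer(n_axial); n_circ <- as.integer(n_circ)
  stopifnot(n_axial >= 1L, n_circ >= 1L, inherits(template, "cv_unit"))
  .new_pouch(diameter_cm = n_circ * unit_spacing_mm / (10 * pi),
             length_cm = n_axial * unit_spacing_mm / 10,
             unit_spacing_mm = unit_spacing_mm,
             n_axial = n_axial, n_circ = n_circ, template = template)
}

#' @export
print.pouch_geometry <- function(x, ...) {
  cat(sprintf(paste0("<pouch_geometry> %.3g cm diameter x %.3g cm length, ",
                     "%d x %d units (axial x circ), %s sites\n"),
              x$diameter_cm, x$length_cm, x$n_axial, x$n_circ,
              format(n_sites(x), big.mark = ",")))
  invisible(x)
}

#' Total number of lattice sites in a geometry
#'
#' Computed arithmetically from per-unit heights (faces x width x rows for
#' both components plus one cap row per component), without building a site
#' index; usable for size accounting of anatomic-scale geometries.
#'
#' @param geom a `pouch_geometry`.
#' @return total site count (numeric, exact).
#' @export
n_sites <- function(geom) {
  stopifnot(inherits(geom, "pouch_geometry"))
  W <- geom$template$n_faces * geom$template$face_width
  sum((geom$units$villus_height + geom$units$crypt_depth + 1) * W)
}

#' Axial position of a unit
#'
#' Distance in millimetres of a unit's axial lattice row from the proximal
#' (inflow) end of the pouch; the terminal pouch is at maximal axial position.
#'
#' @param geom a `pouch_geometry`.
#' @param unit_index 0-based unit index (row-major, axial-then-circumferential).
#' @return numeric vector of axial positions in mm.
#' @export
axial_position_mm <- function(geom, unit_index) {
  stopifnot(inherits(geom, "pouch_geometry"))
  unit_index <- as.integer(unit_index)
  if (any(is.na(unit_index)) || any(unit_index < 0L) ||
      any(unit_index >= nrow(geom$units)))
    stop("invalid unit_index", call. = FALSE)
  (unit_index %/% geom$n_circ) * geom$unit_spacing_mm
}

# Neighbouring unit of `unit` in lattice direction `dir` (0 = axial-, 1 =
# circ+, 2 = axial+, 3 = circ-). Circumferential wraps; axial does not
# (returns NA beyond the pouch ends).
.unit_neighbor <- function(geom, unit, dir) {
  ax <- unit %/% geom$n_circ
  ci <- unit %% geom$n_circ
  if (dir == 0L) { ax <- ax - 1L }
  else if (dir == 2L) { ax <- ax + 1L }
  else if (dir == 1L) { ci <- (ci + 1L) %% geom$n_circ }
  else { ci <- (ci - 1L + geom$n_circ) %% geom$n_circ }
  if (ax < 0L || ax >= geom$n_axial) return(NA_integer_)
  ax * geom$n_circ + ci
}
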