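#' Micromagnet footprint specification
#'
#' Describes the lateral shape and magnetic-layer thickness of a single
#' micromagnet. Four footprints are supported, matching the lithographically
#' convenient designs studied for NLM transport: circle, square, equilateral
#' triangle and rectangle.
#'
#' The triangle is equilateral with one side parallel to the y axis; the
#' opposite vertex points along +x by default (the transport direction).
#' The field landscape of a triangular magnet is not mirror-symmetric in x,
#' so the vertex direction is an explicit, configurable choice.
#'
#' @param kind One of `"circle"`, `"square"`, `"triangle"`, `"rectangle"`.
#' @param size_um Lateral dimension(s) in micrometers: diameter for circle,
#'   side for square and triangle, `c(x_side, y_side)` for rectangle.
#' @param thickness_nm Magnetic layer thickness in nanometers (default 100,
#'   a sputtered cobalt layer).
#' @param triangle_vertex `"+x"` or `"-x"`: direction the triangle vertex
#'   points (ignored for other kinds).
#' @return An object of class `nlm_shape`.
#' @examples
#' shape_spec("circle", 5)
#' shape_spec("rectangle", c(5, 12.5))
#' @export
shape_spec <- function(kind = c("circle", "square", "triangle", "rectangle"),
                       size_um, thickness_nm = 100,
                       triangle_vertex = c("+x", "-x")) {
  kind <- match.arg(kind)
  triangle_vertex <- match.arg(triangle_vertex)
  if (kind == "rectangle") {
    if (length(size_um) != 2) stop("rectangle needs size_um = c(x_side, y_side)")
  } else {
    if (length(size_um) != 1) stop(sprintf("%s needs a single lateral dimension", kind))
  }
  if (any(size_um <= 0) || thickness_nm <= 0) stop("all dimensions must be > 0")
  structure(
    list(kind = kind, size_um = as.numeric(size_um),
         thickness_nm = as.numeric(thickness_nm),
         triangle_vertex = triangle_vertex),
    class = "nlm_shape")
}

#' @export
print.nlm_shape <- function(x, ...) {
  cat(sprintf("<nlm_shape> %s, %s um lateral, %g nm thick\n",
              x$kind, paste(x$size_um, collapse = " x "), x$thickness_nm))
  invisible(x)
}

#' Closed-form footprint area of a micromagnet
#'
#' @param shape An [shape_spec()] object.
#' @return Area in um^2.
#' @examples
#' footprint_area(shape_spec("circle", 5))    # pi * 2.5^2
#' footprint_area(shape_spec("triangle", 5))  # sqrt(3)/4 * 25
#' @export
footprint_area <- function(shape) {
  stopifnot(inherits(shape, "nlm_shape"))
  s <- shape$size_um
  switch(shape$kind,
    circle    = pi * (s / 2)^2,
    square    = s^2,
    triangle  = sqrt(3) / 4 * s^2,
    rectangle = s[1] * s[2],
    stop("unknown shape kind: ", shape$kind))
}

# lateral half-extents (um) of the footprint bounding box, centered on the
# footprint centroid
.shape_extent <- function(shape) {
  s <- shape$size_um
  switch(shape$kind,
    circle    = c(s / 2, s / 2),
    square    = c(s / 2, s / 2),
    ## centroid at origin: vertex at 2h/3, base at -h/3 (h = height)
    triangle  = c(sqrt(3) / 2 * s * 2 / 3, s / 2),
    rectangle = c(s[1] / 2, s[2] / 2))
}

#' Point-in-footprint test
#'
#' Membership test for points in the footprint of a micromagnet centered at
#' the origin. Used by the rasterizer and by dimer-overhang geometry.
#'
#' @param shape An [shape_spec()] object.
#' @param x_um,y_um Coordinates in micrometers (vectorized).
#' @return Logical vector.
#' @export
point_in_footprint <- function(shape, x_um, y_um) {
  stopifnot(inherits(shape, "nlm_shape"))
  s <- shape$size_um
  switch(shape$kind,
    circle = x_um^2 + y_um^2 <= (s / 2)^2,
    square = abs(x_um) <= s / 2 & abs(y_um) <= s / 2,
    rectangle = abs(x_um) <= s[1] / 2 & abs(y_um) <= s[2] / 2,
    triangle = {
      h <- sqrt(3) / 2 * s           # height
      xx <- if (shape$triangle_vertex == "+x") x_um else -x_um
      ## centroid at origin: base edge at x = -h/3, vertex at x = 2h/3
      (xx >= -h / 3) & (abs(y_um) <= (2 * h / 3 - xx) / sqrt(3))
    },
    stop("unknown shape kind"))
}

#' Rasterize a micromagnet footprint into dipole cells
#'
#' Tiles the footprint with square cells of side `cell_um`. Each cell
#' carries a coverage fraction estimated from a 6 x 6 midpoint subgrid
#' (cells fully inside have fraction 1; boundary cells fractional; cells
#' fully outside are dropped), a 3-D center (z at magnet mid-thickness,
#' with z = 0 the magnet top surface) and a volume
#' `cell_um^2 * thickness * fraction`. The cell list is the discrete
#' source distribution summed by the magnetostatic solver; it stands in
#' for a finite-element representation of the magnet.
#'
#' @param shape An [shape_spec()] object.
#' @param cell_um Cell side in micrometers; must be at most 1/8 of the
#'   smallest lateral dimension so the footprint is resolved.
#' @return A data.frame with columns `x_um`, `y_um`, `z_um`, `volume_um3`.
#' @examples
#' cells <- rasterize_footprint(shape_spec("square", 5), 0.25)
#' nrow(cells)            # 400: the square tiles exactly
#' sum(cells$volume_um3)  # 25 um^2 x 0.1 um
#' @export
rasterize_footprint <- function(shape, cell_um = 0.25) {
  stopifnot(inherits(shape, "nlm_shape"))
  if (cell_um <= 0) stop("cell_um must be > 0")
  min_dim <- min(shape$size_um)
  if (cell_um > min_dim / 8)
    stop(sprintf("cell_um = %g too coarse: must be <= min lateral dimension / 8 = %g um",
                 cell_um, min_dim / 8))
  ext <- .shape_extent(shape)
  nx <- ceiling(2 * ext[1] / cell_um)
  ny <- ceiling(2 * ext[2] / cell_um)
  cx <- (seq_len(nx) - (nx + 1) / 2) * cell_um
  cy <- (seq_len(ny) - (ny + 1) / 2) * cell_um
  g <- expand.grid(x_um = cx, y_um = cy, KEEP.OUT.ATTRS = FALSE)
  ## coverage fraction from a midpoint subgrid within each cell
  n_sub <- 6L
  off <- ((seq_len(n_sub) - 0.5) / n_sub - 0.5) * cell_um
  sub <- expand.grid(dx = off, dy = off, KEEP.OUT.ATTRS = FALSE)
  frac <- rowMeans(vapply(seq_len(nrow(sub)), function(k) {
    point_in_footprint(shape, g$x_um + sub$dx[k], g$y_um + sub$dy[k])
  }, logical(nrow(g))))
  keep <- frac > 0
  g <- g[keep, , drop = FALSE]
  thick_um <- shape$thickness_nm / 1000
  g$z_um <- -thick_um / 2    # single dipole layer at mid-thickness
  g$volume_um3 <- cell_um^2 * thick_um * frac[keep]
  rownames(g) <- NULL
  attr(g, "cell_um") <- cell_um
  g
}

#' Micromagnet array (lattice) specification
#'
#' A rectilinear lattice of identical micromagnets on a chip, magnetized
#' along +x, planarized with a spin-on-glass layer. Coordinates are
#' right-handed with x the transport/magnetization axis, z the chip normal,
#' and z = 0 at the top surface of the magnetic layer; the glass occupies
#' `[0, glass_nm]`.
#'
#' Defaults follow the reference chip: 8 um pitch, 80 kA/m magnetization,
#' 600 nm spin-on glass over a 100 nm magnetic layer.
#'
#' @param shape An [shape_spec()] object.
#' @param pitch_x_um,pitch_y_um Center-to-center lattice spacings in um.
#' @param n_x,n_y Number of magnets along x and y.
#' @param magnetization_A_m Uniform magnetization along +x, A/m.
#' @param glass_nm Spin-on-glass thickness in nm.
#' @param origin_um Position of magnet (1, 1) center, `c(x, y)` in um.
#' @return An object of class `nlm_array`.
#' @export
array_spec <- function(shape, pitch_x_um = 8, pitch_y_um = pitch_x_um,
                       n_x = 11, n_y = 11, magnetization_A_m = 80e3,
                       glass_nm = 600, origin_um = c(0, 0)) {
  stopifnot(inherits(shape, "nlm_shape"))
  ext <- .shape_extent(shape)
  if (pitch_x_um < 2 * ext[1])
    stop("pitch_x_um smaller than the magnet x-extent: magnets would overlap")
  if (n_x < 1 || n_y < 1) stop("n_x and n_y must be >= 1")
  if (magnetization_A_m <= 0) stop("magnetization must be > 0")
  structure(
    list(shape = shape, pitch_x_um = pitch_x_um, pitch_y_um = pitch_y_um,
         n_x = as.integer(n_x), n_y = as.integer(n_y),
         magnetization_A_m = magnetization_A_m, glass_nm = glass_nm,
         origin_um = as.numeric(origin_um)),
    class = "nlm_array")
}

#' @export
print.nlm_array <- function(x, ...) {
  cat(sprintf("<nlm_array> %d x %d %s magnets, pitch %g x %g um, M = %g kA/m\n",
              x$n_x, x$n_y, x$shape$kind, x$pitch_x_um, x$pitch_y_um,
              x$magnetization_A_m / 1000))
  invisible(x)
}

#' Reference micromagnet arrays
#'
#' The four array geometries characterized for NLM separation: circular (C),
#' square (S) and triangular (T) magnets with 5 um lateral dimension on an
#' 8 um square lattice, and rectangular (R) magnets of 5 x 12.5 um on an
#' 8 x 16 um lattice. All are 100 nm thick, magnetized at 80 kA/m along +x,
#' under 600 nm of spin-on glass.
#'
#' @param geometry One of `"C"`, `"S"`, `"T"`, `"R"`.
#' @param n_x,n_y Lattice size (default 11 x 11: large enough that the
#'   center of the array is effectively periodic).
#' @return An [array_spec()] object.
#' @examples
#' default_array("C")
#' default_array("R")$pitch_y_um   # 16
#' @export
default_array <- function(geometry = c("C", "S", "T", "R"), n_x = 11, n_y = 11) {
  geometry <- match.arg(geometry)
  switch(geometry,
    C = array_spec(shape_spec("circle", 5), 8, 8, n_x, n_y),
    S = array_spec(shape_spec("square", 5), 8, 8, n_x, n_y),
    T = array_spec(shape_spec("triangle", 5), 8, 8, n_x, n_y),
    R = array_spec(shape_spec("rectangle", c(5, 12.5)), 8, 16, n_x, n_y))
}

#' Magnet placements of an array
#'
#' @param array An [array_spec()] object.
#' @return A data.frame with columns `i`, `j` (1-based lattice indices) and
#'   `x_um`, `y_um` (magnet centers).
#' @export
build_lattice <- function(array) {
  stopifnot(inherits(array, "nlm_array"))
  g <- expand.grid(i = seq_len(array$n_x), j = seq_len(array$n_y),
                   KEEP.OUT.ATTRS = FALSE)
  g$x_um <- array$origin_um[1] + (g$i - 1) * array$pitch_x_um
  g$y_um <- array$origin_um[2] + (g$j - 1) * array$pitch_y_um
  g
}

# All dipole cells of a set of magnet placements, in SI.
# Returns list(points = n x 3 matrix in m, moment = A m^2 per cell).
.array_dipoles <- function(array, placements, cell_um = 0.25) {
  cells <- rasterize_footprint(array$shape, cell_um)
  ncell <- nrow(cells)
  nmag <- nrow(placements)
  px <- rep(cells$x_um, times = nmag) + rep(placements$x_um, each = ncell)
  py <- rep(cells$y_um, times = nmag) + rep(placements$y_um, each = ncell)
  pz <- rep(cells$z_um, times = nmag)
  pts <- cbind(px, py, pz) * 1e-6
  mom <- rep(array$magnetization_A_m * cells$volume_um3 * 1e-18, nmag)
  list(points = pts, moment = mom)
}

#' Read or write an array specification
#'
#' Array specs serialize to YAML or JSON (chosen by file extension). Sizes
#' are stored in micrometers/nanometers, magnetization in A/m.
#'
#' @param array An [array_spec()] object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_array_spec` returns an `nlm_array`; `write_array_spec`
#'   returns `path` invisibly.
#' @export
write_array_spec <- function(array, path) {
  stopifnot(inherits(array, "nlm_array"))
  doc <- list(
    shape = list(kind = array$shape$kind, size_um = array$shape$size_um,
                 thickness_nm = array$shape$thickness_nm,
                 triangle_vertex = array$shape$triangle_vertex),
    pitch_x_um = array$pitch_x_um, pitch_y_um = array$pitch_y_um,
    n_x = array$n_x, n_y = array$n_y,
    magnetization_A_m = array$magnetization_A_m,
    glass_nm = array$glass_nm, origin_um = array$origin_um)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  } else stop("unrecognized extension (use .yaml/.yml/.json): ", path)
  invisible(path)
}

#' @rdname write_array_spec
#' @export
read_array_spec <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unrecognized extension (use .yaml/.yml/.json): ", path)
  sh <- doc$shape
  shape <- shape_spec(sh$kind, unlist(sh$size_um), sh$thickness_nm,
                      if (!is.null(sh$triangle_vertex)) sh$triangle_vertex else "+x")
  array_spec(shape, doc$pitch_x_um, doc$pitch_y_um, doc$n_x, doc$n_y,
             doc$magnetization_A_m, doc$glass_nm,
             if (!is.null(doc$origin_um)) unlist(doc$origin_um) else c(0, 0))
}

#' Export rasterized cells as CSV
#'
#' @param shape An [shape_spec()] object.
#' @param path Output CSV path.
#' @param cell_um Cell side in um.
#' @return `path`, invisibly.
#' @export
write_cells_csv <- function(shape, path, cell_um = 0.25) {
  cells <- rasterize_footprint(shape, cell_um)
  write.csv(cells, path, row.names = FALSE)
  invisible(path)
}
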