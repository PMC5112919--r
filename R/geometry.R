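# Convex cell shapes, the periodic microdomain, exact ray-shape
# intersection, and global/local (tile) coordinate bookkeeping.

#' Define a cell shape
#'
#' A bacterial cell is modeled as a capsule (spherocylinder): a cylinder of
#' radius `radius` and length `cylinder_length` capped by two hemispheres.
#' A zero cylinder length gives a sphere.
#'
#' @param kind `"capsule"` or `"sphere"`.
#' @param radius cap/cylinder radius [um], > 0.
#' @param cylinder_length cylinder length [um], >= 0 (forced 0 for spheres).
#' @return object of class `cell_shape`.
#' @examples
#' cell_shape("capsule", 0.5, 2)    # the E. coli rod model
#' cell_shape("sphere", 1.5)        # the D. radiodurans model
#' @export
cell_shape <- function(kind = c("capsule", "sphere"), radius, cylinder_length = 0) {
  kind <- match.arg(kind)
  if (!is.numeric(radius) || length(radius) != 1 || !is.finite(radius) || radius <= 0)
    stop("invalid shape: radius must be a positive number")
  if (cylinder_length < 0) stop("invalid shape: cylinder_length must be >= 0")
  if (kind == "sphere") cylinder_length <- 0
  structure(list(kind = kind, radius = radius, cylinder_length = cylinder_length),
            class = "cell_shape")
}

#' Closed-form geometric properties of a cell shape
#'
#' Volume, surface area, orientation-averaged projected area (Cauchy's
#' formula: surface/4) and mean chord length (4 volume/surface) of a capsule
#' or sphere.
#'
#' @param shape a [cell_shape()].
#' @return list with `volume` [um^3], `surface` [um^2],
#'   `mean_projected_area` [um^2], `mean_chord` [um].
#' @examples
#' shape_properties(cell_shape("capsule", 0.5, 2))
#' @export
shape_properties <- function(shape) {
  stopifnot(inherits(shape, "cell_shape"))
  r <- shape$radius; L <- shape$cylinder_length
  volume <- pi * r^2 * L + 4 / 3 * pi * r^3
  surface <- 2 * pi * r * L + 4 * pi * r^2
  list(volume = volume, surface = surface,
       mean_projected_area = surface / 4,
       mean_chord = 4 * volume / surface)
}

#' Exact ray-capsule (or ray-sphere) chord
#'
#' Intersects an infinite ray with a posed capsule and returns the chord, or
#' `NULL` when the ray misses. Used by the chord-based transport instead of
#' fixed small-step tracking.
#'
#' @param origin ray origin [um], length-3.
#' @param direction ray direction (normalized internally, with a warning if
#'   not unit length).
#' @param shape a [cell_shape()].
#' @param center capsule center [um].
#' @param axis capsule axis unit vector (ignored for spheres).
#' @return list with `entry_point`, `exit_point`, `length` [um], and `t_entry`,
#'   `t_exit` (ray parameters), or `NULL` if no intersection ahead of the
#'   origin. Tangential grazing returns a zero-length chord.
#' @export
ray_chord <- function(origin, direction, shape, center = c(0, 0, 0),
                      axis = c(0, 0, 1)) {
  stopifnot(inherits(shape, "cell_shape"))
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-9) {
    warning("direction was not a unit vector; normalizing")
    direction <- direction / nrm
  }
  axis <- axis / sqrt(sum(axis^2))
  tt <- ray_capsule_cpp(as.numeric(origin), as.numeric(direction),
                        as.numeric(center), as.numeric(axis),
                        shape$radius, shape$cylinder_length / 2)
  if (tt[1] > tt[2]) return(NULL)       # miss
  if (tt[2] < 0) return(NULL)           # entirely behind the origin
  t0 <- tt[1]; t1 <- tt[2]
  list(entry_point = origin + t0 * direction,
       exit_point = origin + t1 * direction,
       length = t1 - t0, t_entry = t0, t_exit = t1)
}

#' Place cells in the periodic microdomain
#'
#' Uniform-random centers and isotropic random orientations inside a cube of
#' side `edge`, by default with non-overlapping rejection sampling (the cell
#' volume fraction at the experimental density is ~1e-3, so rejection is
#' cheap). Reproducible under a fixed seed.
#'
#' @param n number of cells (default 4000).
#' @param edge domain edge [um] (default 200).
#' @param shape a [cell_shape()] (default the E. coli capsule r=0.5, L=2).
#' @param seed integer seed.
#' @param overlap_policy `"reject"` (non-overlapping) or `"allow"`.
#' @param well_extent optional list(min=, max=) [um] giving the virtual well
#'   box in the global frame (used to terminate tracks; see [in_well()]).
#' @return object of class `microdomain`: list with `edge`, `n`, `centers`
#'   (n x 3), `orientations` (n x 3 unit vectors), `shape`, `well_extent`.
#' @export
place_cells <- function(n = 4000, edge = 200,
                        shape = cell_shape("capsule", 0.5, 2),
                        seed = 1L, overlap_policy = c("reject", "allow"),
                        well_extent = NULL) {
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(n >= 0, edge > 0)
  pf <- n * shape_properties(shape)$volume / edge^3
  if (overlap_policy == "reject" && pf > 0.2)
    stop(sprintf("packing fraction %.3g > 0.2: rejection sampling would stall; use overlap_policy = 'allow'", pf))
  if (n == 0) {
    out <- list(centers = matrix(numeric(0), 0, 3), axes = matrix(numeric(0), 0, 3))
  } else {
    out <- place_cells_cpp(as.integer(n), edge, shape$radius,
                           shape$cylinder_length / 2,
                           overlap_policy == "reject", as.numeric(seed))
  }
  structure(list(edge = edge, n = n, centers = out$centers,
                 orientations = out$axes, shape = shape,
                 well_extent = well_extent),
            class = "microdomain")
}

#' @export
print.microdomain <- function(x, ...) {
  cat(sprintf("<microdomain> %d %s cells in a %g um cube (density %.3g um^-3)\n",
              x$n, x$shape$kind, x$edge, x$n / x$edge^3))
  invisible(x)
}

#' Tile coordinate
#'
#' A position in the periodic microdomain: integer tile index plus local
#' position in `[0, edge)^3`. The global position `tile * edge + local` is
#' continuous across boundary crossings.
#'
#' @param tile integer triple.
#' @param local numeric triple in `[0, edge)`.
#' @param edge domain edge [um].
#' @export
tile_coordinate <- function(tile = c(0L, 0L, 0L), local = c(0, 0, 0), edge = 200) {
  stopifnot(length(tile) == 3, length(local) == 3, all(local >= 0), all(local < edge))
  structure(list(tile = as.integer(tile), local = as.numeric(local), edge = edge),
            class = "tile_coordinate")
}

#' Global position of a tile coordinate [um]
#' @param coord a [tile_coordinate()].
#' @export
global_position <- function(coord) {
  coord$tile * coord$edge + coord$local
}

#' Advance a tile coordinate by a displacement
#'
#' Wraps the local position back into `[0, edge)^3` and updates the tile
#' index for every face crossed, so that the global position advances exactly
#' by `displacement`.
#'
#' @param coord a [tile_coordinate()].
#' @param displacement numeric triple [um].
#' @return updated [tile_coordinate()].
#' @export
advance_periodic <- function(coord, displacement) {
  stopifnot(all(is.finite(displacement)))
  g <- global_position(coord) + displacement
  tile <- floor(g / coord$edge)
  local <- g - tile * coord$edge
  # numeric safety at the upper face
  hi <- local >= coord$edge
  tile[hi] <- tile[hi] + 1
  local[hi] <- local[hi] - coord$edge
  tile_coordinate(as.integer(tile), local, coord$edge)
}

#' Is a tile coordinate (or global position) inside the virtual well?
#'
#' Tracks are killed when their global coordinates leave the well box that
#' the periodic tiling virtually fills.
#'
#' @param coord a [tile_coordinate()] or a numeric global position [um].
#' @param well_extent list(min=, max=) numeric triples [um].
#' @export
in_well <- function(coord, well_extent) {
  g <- if (inherits(coord, "tile_coordinate")) global_position(coord) else coord
  all(g >= well_extent$min) && all(g <= well_extent$max)
}

#' Serialize a microdomain to a columnar text file
#'
#' One row per cell: `id cx cy cz ox oy oz`; header comment lines carry the
#' edge length and shape so the file round-trips.
#'
#' @param domain a `microdomain`.
#' @param path output path.
#' @export
write_microdomain <- function(domain, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# microdosim microdomain v1",
    sprintf("# edge_um %.9g", domain$edge),
    sprintf("# shape %s %.9g %.9g", domain$shape$kind, domain$shape$radius,
            domain$shape$cylinder_length),
    sprintf("# n %d", domain$n),
    "# id cx cy cz ox oy oz"), con)
  if (domain$n > 0) {
    df <- data.frame(id = seq_len(domain$n), domain$centers, domain$orientations)
    write.table(format(df, digits = 12), con, row.names = FALSE,
                col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a microdomain written by [write_microdomain()]
#' @param path input path.
#' @export
read_microdomain <- function(path) {
  hdr <- readLines(path, n = 5)
  if (!grepl("^# microdosim microdomain", hdr[1]))
    stop("not a microdomain file: ", path)
  edge <- as.numeric(strsplit(hdr[2], " ")[[1]][3])
  sh <- strsplit(hdr[3], " ")[[1]]
  shape <- cell_shape(sh[3], as.numeric(sh[4]), as.numeric(sh[5]))
  n <- as.integer(strsplit(hdr[4], " ")[[1]][3])
  if (n > 0) {
    df <- read.table(path, skip = 5)
    centers <- as.matrix(df[, 2:4]); axes <- as.matrix(df[, 5:7])
  } else {
    centers <- matrix(numeric(0), 0, 3); axes <- matrix(numeric(0), 0, 3)
  }
  dimnames(centers) <- NULL; dimnames(axes) <- NULL
  structure(list(edge = edge, n = n, centers = centers, orientations = axes,
                 shape = shape, well_extent = NULL), class = "microdomain")
}

#' Number of cells the virtual well represents
#'
#' The periodic microdomain models the final cell density; tiling it through
#' the well volume represents `density * V_well` cells, the denominator of
#' the per-cell hit frequency.
#'
#' @param domain a `microdomain`.
#' @param well_volume_cm3 well liquid volume [cm^3] (default 1.5).
#' @export
cells_considered <- function(domain, well_volume_cm3 = 1.5) {
  density_um3 <- domain$n / domain$edge^3
  density_um3 * well_volume_cm3 * 1e12
}
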