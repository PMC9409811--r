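# Grid construction: axisymmetric (r,z) tensor grids, optionally graded
# (fine spacing near the electrode, geometrically stretched toward the
# far-field boundary), plus uniform cartesian 3D label grids used for
# lesion rasterization. All grid coordinates are in mm.

#' Build a 1D axis of cell faces with optional local refinement
#'
#' Produces face coordinates covering \code{lim}. Inside
#' \code{fine_window} the spacing is \code{h_fine}; outside it grows
#' geometrically by \code{growth} per cell up to \code{h_max}. With no
#' window the axis is uniform with spacing \code{h_max}.
#'
#' @param lim Numeric length-2: axis limits, mm.
#' @param h_max Coarse (maximum) spacing, mm.
#' @param fine_window Optional length-2 range to refine, mm.
#' @param h_fine Fine spacing inside the window, mm.
#' @param growth Geometric growth factor for the transition (> 1).
#' @return Increasing numeric vector of face coordinates starting at
#'   \code{lim[1]} and ending at \code{lim[2]}.
#' @keywords internal
axis_faces <- function(lim, h_max, fine_window = NULL, h_fine = h_max,
                       growth = 1.3) {
  stopifnot(length(lim) == 2L, lim[2] > lim[1], h_max > 0, h_fine > 0,
            growth > 1)
  if (is.null(fine_window)) {
    n <- max(1L, round(diff(lim) / h_max))
    return(seq(lim[1], lim[2], length.out = n + 1L))
  }
  fw <- c(max(lim[1], min(fine_window)), min(lim[2], max(fine_window)))
  if (fw[2] <= fw[1]) return(axis_faces(lim, h_max))
  # uniform fine block covering the window
  nf <- max(1L, ceiling((fw[2] - fw[1]) / h_fine))
  fine <- seq(fw[1], fw[2], length.out = nf + 1L)
  grade <- function(from, to, sign) {
    # geometric spacings from |h_fine| growing to h_max, then uniform
    out <- numeric(0)
    pos <- from
    h <- h_fine
    while ((to - pos) * sign > 1e-12) {
      h <- min(h * growth, h_max, abs(to - pos))
      pos <- pos + sign * h
      out <- c(out, pos)
    }
    if (length(out)) out[length(out)] <- to
    out
  }
  up <- grade(fw[2], lim[2], +1)
  down <- rev(grade(fw[1], lim[1], -1))
  unique(c(down, fine, up))
}

#' Axisymmetric simulation grid
#'
#' Constructs an empty axisymmetric (r,z) grid: the arena for the field
#' and bioheat solvers. The electrode axis is r = 0. Cells are annular
#' rings; the grid may be graded so that a fine spacing is used near the
#' electrode tip and a coarser one toward the far-field boundary.
#'
#' @param r_extent Domain radius, mm.
#' @param z_extent Length-2 axial limits, mm.
#' @param spacing Coarse grid spacing, mm.
#' @param fine_window Optional list with elements \code{r} and \code{z}
#'   (each a length-2 range, mm) to refine near the electrode.
#' @param h_fine Fine spacing inside the window, mm (default \code{spacing}).
#' @param growth Geometric growth factor of the grading.
#' @param labels Integer label for every cell (recycled), or a full
#'   nr x nz matrix.
#' @param properties Tissue property table (see [brain_tissue_table()]).
#' @return An object of class \code{phantom_grid} with fields \code{mode},
#'   \code{rf, zf} (face coordinates, mm), \code{rc, zc} (cell centers),
#'   \code{labels} (nr x nz integer matrix) and \code{properties}.
#' @export
axisymmetric_grid <- function(r_extent = 50, z_extent = c(-50, 50),
                              spacing = 0.5, fine_window = NULL,
                              h_fine = spacing, growth = 1.3,
                              labels = 1L,
                              properties = brain_tissue_table()) {
  if (!(r_extent > 0)) stop("geometry error: r_extent must be > 0")
  if (!(spacing > 0) || !(h_fine > 0)) stop("spacing must be > 0")
  rf <- axis_faces(c(0, r_extent), spacing,
                   fine_window = fine_window$r, h_fine = h_fine,
                   growth = growth)
  zf <- axis_faces(z_extent, spacing,
                   fine_window = fine_window$z, h_fine = h_fine,
                   growth = growth)
  nr <- length(rf) - 1L
  nz <- length(zf) - 1L
  lab <- matrix(as.integer(labels), nr, nz)
  g <- structure(list(mode = "axisymmetric-rz",
                      rf = rf, zf = zf,
                      rc = (rf[-1] + rf[-length(rf)]) / 2,
                      zc = (zf[-1] + zf[-length(zf)]) / 2,
                      labels = lab,
                      properties = properties),
                 class = "phantom_grid")
  validate_grid(g)
  g
}

#' Uniform cartesian 3D label grid
#'
#' A voxelized 3D tissue-label domain, used for multi-trajectory lesion
#' rasterization and synthetic post-ablation images.
#'
#' @param extent List or length-3 list/vector of length-2 axis limits
#'   (mm); a single length-2 vector is reused for x, y, z.
#' @param spacing Isotropic voxel size, mm.
#' @inheritParams axisymmetric_grid
#' @return \code{phantom_grid} in mode \code{"cartesian-3d"} with face
#'   and center coordinates per axis and a 3D integer label array.
#' @export
cartesian_grid <- function(extent = c(-50, 50), spacing = 1,
                           labels = 1L,
                           properties = brain_tissue_table()) {
  if (!(spacing > 0)) stop("spacing must be > 0")
  if (!is.list(extent)) extent <- list(extent, extent, extent)
  faces <- lapply(extent, function(lim) axis_faces(lim, spacing))
  n <- vapply(faces, function(f) length(f) - 1L, integer(1))
  centers <- lapply(faces, function(f) (f[-1] + f[-length(f)]) / 2)
  g <- structure(list(mode = "cartesian-3d",
                      xf = faces[[1]], yf = faces[[2]], zf = faces[[3]],
                      xc = centers[[1]], yc = centers[[2]],
                      zc = centers[[3]],
                      spacing = spacing,
                      labels = array(as.integer(labels), dim = n),
                      properties = properties),
                 class = "phantom_grid")
  validate_grid(g)
  g
}

validate_grid <- function(grid) {
  stopifnot(inherits(grid, "phantom_grid"))
  validate_tissue_table(grid$properties)
  used <- unique(as.vector(grid$labels))
  unknown <- setdiff(used, grid$properties$label)
  if (length(unknown))
    stop("configuration error: label(s) without properties: ",
         paste(unknown, collapse = ", "))
  invisible(grid)
}

#' Cell volumes of a grid
#'
#' @param grid A \code{phantom_grid}.
#' @return Volumes in mm^3: an nr x nz matrix (full 2*pi revolution of
#'   each annular cell) for axisymmetric grids, or a scalar voxel volume
#'   for cartesian grids.
#' @export
cell_volumes <- function(grid) {
  if (grid$mode == "axisymmetric-rz") {
    ring <- pi * diff(grid$rf^2)            # mm^2 (annulus area)
    outer(ring, diff(grid$zf))              # mm^3
  } else {
    prod(vapply(list(grid$xf, grid$yf, grid$zf),
                function(f) f[2] - f[1], numeric(1)))
  }
}

# per-cell lookup of one property column, same shape as grid$labels
property_field <- function(grid, field) {
  i <- match(grid$labels, grid$properties$label)
  vals <- grid$properties[[field]][i]
  if (is.matrix(grid$labels)) {
    matrix(vals, nrow(grid$labels), ncol(grid$labels))
  } else {
    array(vals, dim = dim(grid$labels))
  }
}

# ---- layered phantom construction -------------------------------------

region_mask <- function(grid, region) {
  type <- region$type
  if (grid$mode == "axisymmetric-rz") {
    R <- matrix(grid$rc, length(grid$rc), length(grid$zc))
    Z <- matrix(grid$zc, length(grid$rc), length(grid$zc), byrow = TRUE)
    switch(type,
      all = R == R,
      slab = Z >= region$z[1] & Z <= region$z[2],
      sphere = {
        ctr <- region$center   # z coordinate on the axis
        if (length(ctr) != 1L)
          stop("geometry error: axisymmetric sphere center is a single ",
               "z coordinate on the axis")
        sqrt(R^2 + (Z - ctr)^2) <= region$radius
      },
      cylinder = R <= region$radius & Z >= region$z[1] & Z <= region$z[2],
      stop("configuration error: unknown region type: ", type)
    )
  } else {
    X <- array(grid$xc, dim = dim(grid$labels))
    Y <- aperm(array(grid$yc, dim = dim(grid$labels)[c(2, 1, 3)]),
               c(2, 1, 3))
    Z <- aperm(array(grid$zc, dim = dim(grid$labels)[c(3, 1, 2)]),
               c(2, 3, 1))
    switch(type,
      all = X == X,
      slab = Z >= region$z[1] & Z <= region$z[2],
      sphere = {
        ctr <- region$center
        if (length(ctr) != 3L)
          stop("geometry error: 3D sphere center needs x, y, z")
        sqrt((X - ctr[1])^2 + (Y - ctr[2])^2 + (Z - ctr[3])^2) <=
          region$radius
      },
      stop("configuration error: unknown region type: ", type)
    )
  }
}

region_fits <- function(grid, region) {
  if (is.null(region$radius)) return(TRUE)
  if (grid$mode == "axisymmetric-rz") {
    lo <- c(0, grid$zf[1]); hi <- c(max(grid$rf), max(grid$zf))
    ctr <- c(0, region$center)
  } else {
    lo <- c(grid$xf[1], grid$yf[1], grid$zf[1])
    hi <- c(max(grid$xf), max(grid$yf), max(grid$zf))
    ctr <- region$center
  }
  all(ctr + region$radius <= hi + 1e-9) &&
    all(ctr - region$radius >= lo - 1e-9 |
          (grid$mode == "axisymmetric-rz" & seq_along(ctr) == 1))
}

#' Build a layered tissue phantom
#'
#' Fills a grid with tissue labels from a list of geometric regions,
#' painted in order (later regions overwrite earlier ones). This is the
#' synthetic stand-in for a segmented head model with grey matter, white
#' matter and hippocampus classes.
#'
#' Supported region types: \code{all} (whole domain), \code{slab}
#' (\code{z} range), \code{sphere} (\code{center}, \code{radius}; in
#' axisymmetric mode the center is a z coordinate on the axis),
#' \code{cylinder} (axisymmetric only: \code{radius} and \code{z} range).
#'
#' @param layers List of layers, each \code{list(label =, region =)}
#'   where the region is \code{list(type =, ...)}.
#' @param spacing Grid spacing, mm.
#' @param extent For axisymmetric mode a list
#'   \code{list(r = , z = c(,))}; for cartesian a length-2 limit vector
#'   or list of three.
#' @param mode \code{"axisymmetric-rz"} or \code{"cartesian-3d"}.
#' @param properties Tissue property table; every layer label must have
#'   an entry.
#' @param ... Passed to the grid constructor (e.g. \code{fine_window},
#'   \code{h_fine}).
#' @return A labelled \code{phantom_grid}.
#' @examples
#' ph <- build_layered_phantom(
#'   list(list(label = 2L, region = list(type = "all")),
#'        list(label = 3L, region = list(type = "sphere",
#'                                       center = 0, radius = 10))),
#'   spacing = 1, extent = list(r = 30, z = c(-30, 30)))
#' table(ph$labels)
#' @export
build_layered_phantom <- function(layers, spacing, extent,
                                  mode = c("axisymmetric-rz",
                                           "cartesian-3d"),
                                  properties = brain_tissue_table(),
                                  ...) {
  mode <- match.arg(mode)
  if (!(spacing > 0)) stop("spacing must be > 0")
  if (!length(layers)) stop("configuration error: no layers given")
  labs <- vapply(layers, function(l) as.integer(l$label), integer(1))
  unknown <- setdiff(labs, properties$label)
  if (length(unknown))
    stop("configuration error: layer label(s) not in property table: ",
         paste(unknown, collapse = ", "))
  grid <- if (mode == "axisymmetric-rz") {
    axisymmetric_grid(r_extent = extent$r, z_extent = extent$z,
                      spacing = spacing, labels = labs[1],
                      properties = properties, ...)
  } else {
    cartesian_grid(extent = extent, spacing = spacing, labels = labs[1],
                   properties = properties, ...)
  }
  for (l in layers) {
    if (!region_fits(grid, l$region))
      stop("geometry error: region of label ", l$label,
           " does not fit inside the domain")
    m <- region_mask(grid, l$region)
    grid$labels[m] <- as.integer(l$label)
  }
  validate_grid(grid)
  grid
}

#' @export
print.phantom_grid <- function(x, ...) {
  cat("<phantom_grid>", x$mode, "\n")
  if (x$mode == "axisymmetric-rz") {
    cat(sprintf("  %d x %d cells, r <= %.1f mm, z in [%.1f, %.1f] mm\n",
                nrow(x$labels), ncol(x$labels), max(x$rf),
                min(x$zf), max(x$zf)))
  } else {
    cat(sprintf("  %s voxels, %.2f mm spacing\n",
                paste(dim(x$labels), collapse = " x "), x$spacing))
  }
  counts <- table(x$labels)
  nm <- x$properties$label_name[match(as.integer(names(counts)),
                                      x$properties$label)]
  cat("  labels:",
      paste(sprintf("%s (%s)", nm, format(as.vector(counts))),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.phantom_grid <- function(x, ...) {
  if (x$mode != "axisymmetric-rz")
    stop("plotting implemented for axisymmetric grids")
  graphics::image(x$rc, x$zc, x$labels, xlab = "r (mm)", ylab = "z (mm)",
                  main = "tissue labels", useRaster = FALSE, ...)
  invisible(x)
}
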