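#' Unipolar RF electrode specification
#'
#' Describes the ablation electrode on the grid axis (r = 0 of an
#' axisymmetric grid). The default is the clinical needle: 1.6 mm shaft
#' diameter with a 3 mm active cautery tip (cylinder with a hemispherical
#' cap at the deep end). The insulated shaft continues from the top of the
#' active tip to the top of the domain. An idealized spherical electrode
#' is available for validation against closed-form solutions.
#'
#' @param shaft_diameter Shaft (and tip) diameter, mm.
#' @param tip_length Active tip length including the hemispherical cap, mm.
#' @param tip_position Axial coordinate (mm) of the electrode's deepest
#'   point (the cap apex).
#' @param type \code{"needle"} (default) or \code{"sphere"}.
#' @param radius Sphere radius, mm (sphere type only).
#' @param center Axial coordinate of the sphere center, mm.
#' @param k_metal,rho_metal,c_metal Thermal conductivity (W/(m K)),
#'   density (kg/m^3) and specific heat (J/(kg K)) of the electrode
#'   body, used by the conducting electrode thermal model (defaults:
#'   stainless steel).
#' @return Object of class \code{electrode_spec}.
#' @examples
#' electrode_spec()                      # the clinical 1.6 mm / 3 mm needle
#' electrode_spec(type = "sphere", radius = 1)
#' @export
electrode_spec <- function(shaft_diameter = 1.6, tip_length = 3.0,
                           tip_position = -1.5,
                           type = c("needle", "sphere"),
                           radius = 1, center = 0,
                           k_metal = 15, rho_metal = 7900,
                           c_metal = 500) {
  type <- match.arg(type)
  if (type == "needle") {
    if (!(shaft_diameter > 0)) stop("shaft_diameter must be > 0")
    if (!(tip_length > 0)) stop("tip_length must be > 0")
    if (tip_length < shaft_diameter / 2)
      stop("geometry error: tip_length shorter than the hemispherical cap")
  } else {
    if (!(radius > 0)) stop("radius must be > 0")
  }
  if (!(k_metal > 0) || !(rho_metal > 0) || !(c_metal > 0))
    stop("electrode metal properties must be > 0")
  structure(list(type = type, shaft_diameter = shaft_diameter,
                 tip_length = tip_length, tip_position = tip_position,
                 radius = radius, center = center,
                 k_metal = k_metal, rho_metal = rho_metal,
                 c_metal = c_metal),
            class = "electrode_spec")
}

#' @export
print.electrode_spec <- function(x, ...) {
  if (x$type == "needle") {
    cat(sprintf(
      "<electrode_spec> needle: %.2f mm diameter, %.1f mm active tip, apex at z = %.1f mm\n",
      x$shaft_diameter, x$tip_length, x$tip_position))
  } else {
    cat(sprintf("<electrode_spec> sphere: radius %.2f mm at z = %.1f mm\n",
                x$radius, x$center))
  }
  invisible(x)
}

# Cell classification on an axisymmetric grid:
# 0 = tissue, 1 = active electrode (Dirichlet equipotential),
# 2 = insulated shaft (blocked). A cell belongs to the electrode if its
# center lies inside the electrode solid.
classify_cells <- function(grid, electrode) {
  stopifnot(grid$mode == "axisymmetric-rz")
  nr <- length(grid$rc); nz <- length(grid$zc)
  R <- matrix(grid$rc, nr, nz)
  Z <- matrix(grid$zc, nr, nz, byrow = TRUE)
  type <- matrix(0L, nr, nz)
  if (is.null(electrode)) return(type)
  if (electrode$type == "sphere") {
    inside <- sqrt(R^2 + (Z - electrode$center)^2) <= electrode$radius
    type[inside] <- 1L
    return(type)
  }
  a <- electrode$shaft_diameter / 2
  z0 <- electrode$tip_position          # apex
  zc_cap <- z0 + a                      # cap center
  z_top <- z0 + electrode$tip_length    # top of active tip
  active <- (R <= a & Z >= zc_cap & Z <= z_top) |
    (sqrt(R^2 + (Z - zc_cap)^2) <= a)
  shaft <- R <= a & Z > z_top
  type[shaft] <- 2L
  type[active] <- 1L
  type
}

# Signed distance (mm) from cell centers to the active-tip surface
# (negative inside). Used for the tip-adjacent temperature proxy shell.
surface_distance <- function(grid, electrode) {
  nr <- length(grid$rc); nz <- length(grid$zc)
  R <- matrix(grid$rc, nr, nz)
  Z <- matrix(grid$zc, nr, nz, byrow = TRUE)
  if (electrode$type == "sphere") {
    return(sqrt(R^2 + (Z - electrode$center)^2) - electrode$radius)
  }
  a <- electrode$shaft_diameter / 2
  zc_cap <- electrode$tip_position + a
  z_top <- electrode$tip_position + electrode$tip_length
  d <- matrix(NA_real_, nr, nz)
  mid <- Z >= zc_cap & Z <= z_top
  d[mid] <- R[mid] - a
  below <- Z < zc_cap
  d[below] <- sqrt(R[below]^2 + (Z[below] - zc_cap)^2) - a
  above <- Z > z_top
  d[above] <- sqrt(pmax(R[above] - a, 0)^2 + (Z[above] - z_top)^2)
  d
}

# Active-tip clearance to the outer boundary, mm (needle and sphere).
tip_clearance <- function(grid, electrode) {
  if (electrode$type == "sphere") {
    lo <- electrode$center - electrode$radius
    hi <- electrode$center + electrode$radius
    return(min(max(grid$rf) - electrode$radius,
               lo - min(grid$zf), max(grid$zf) - hi))
  }
  a <- electrode$shaft_diameter / 2
  z0 <- electrode$tip_position
  min(max(grid$rf) - a, z0 - min(grid$zf))
}
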