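#' Solve the electro-quasistatic potential around the electrode
#'
#' Solves the conduction-dominated electro-quasistatic equation
#' \eqn{\nabla\cdot\sigma\nabla\phi = 0} on an axisymmetric grid with the
#' active electrode tip as a Dirichlet equipotential at \code{voltage},
#' the insulated shaft as a zero-flux region, and a grounded return at
#' the outer boundary (unipolar configuration: the distant body ground is
#' mapped onto the domain boundary). At 100 kHz the displacement term of
#' the complex permittivity is negligible against conduction in brain
#' tissue, so only the real conductivity enters.
#'
#' A discrete maximum principle (\eqn{0 \le \phi \le} voltage) is asserted
#' on every solve. The volumetric Joule heat source
#' \eqn{q = \sigma|\nabla\phi|^2} is computed from face fluxes so that its
#' volume integral equals the delivered electrical power exactly.
#'
#' @param grid Axisymmetric \code{phantom_grid}.
#' @param electrode \code{electrode_spec}, or \code{NULL} with
#'   \code{ground = "plates"} for a uniform axial-field test configuration
#'   (top boundary at \code{voltage}, bottom grounded, side insulated).
#' @param voltage Applied electrode voltage, V (>= 0).
#' @param ground \code{"boundary"} (outer box grounded), \code{"sphere"}
#'   (cells beyond \code{ground_radius} from the origin grounded;
#'   concentric-spheres validation geometry) or \code{"plates"}.
#' @param ground_radius Radius of the grounded shell, mm
#'   (\code{ground = "sphere"} only).
#' @param min_clearance Required clearance (mm) between the active tip and
#'   the outer boundary; violation is a geometry error.
#' @return Object of class \code{field_solution}: \code{phi} (V, matrix;
#'   \code{NA} in blocked cells), \code{e_mag} (V/m), \code{q_src}
#'   (W/m^3), \code{power_total} (W), \code{impedance} (Ohm),
#'   \code{current} (A), \code{applied_voltage}, \code{residual} and the
#'   cell \code{type} matrix.
#' @examples
#' g <- axisymmetric_grid(r_extent = 30, z_extent = c(-30, 30), spacing = 1)
#' sol <- solve_potential(g, electrode_spec(tip_position = -1.5), 34)
#' sol$power_total
#' @export
solve_potential <- function(grid, electrode, voltage,
                            ground = c("boundary", "sphere", "plates"),
                            ground_radius = NULL, min_clearance = 10) {
  ground <- match.arg(ground)
  stopifnot(grid$mode == "axisymmetric-rz")
  if (voltage < 0) stop("voltage must be >= 0")
  sigma <- property_field(grid, "sigma")
  if (any(sigma <= 0)) stop("all conductivities must be > 0")

  type <- classify_cells(grid, electrode)
  fixed_value <- matrix(NA_real_, nrow(type), ncol(type))
  fixed_value[type == 1L] <- voltage
  active_cells <- type == 1L

  if (!is.null(electrode)) {
    if (!any(active_cells))
      stop("geometry error: electrode does not cover any grid cell")
    if (tip_clearance(grid, electrode) < min_clearance)
      stop("geometry error: active tip within ", min_clearance,
           " mm of the outer boundary")
  }

  boundary <- "insulated"
  if (ground == "boundary") boundary <- "dirichlet"
  if (ground == "sphere") {
    if (is.null(ground_radius))
      stop("ground_radius required for ground = 'sphere'")
    R <- matrix(grid$rc, length(grid$rc), length(grid$zc))
    Z <- matrix(grid$zc, length(grid$rc), length(grid$zc), byrow = TRUE)
    gm <- sqrt(R^2 + Z^2) >= ground_radius & type == 0L
    if (!any(gm))
      stop("geometry error: grounded shell outside the domain")
    type[gm] <- 1L
    fixed_value[gm] <- 0
  }
  bvalue <- 0
  if (ground == "plates") {
    if (!is.null(electrode))
      stop("ground = 'plates' is an electrode-free test configuration")
    boundary <- "plates"
    bvalue <- c(0, voltage)
  }

  asm <- assemble_faces(grid, sigma, type, fixed_value,
                        boundary = boundary, boundary_value = bvalue)
  sys <- fv_system(asm, type)
  if (!length(sys$unknown))
    stop("geometry error: no tissue cells to solve for")

  phi_u <- tryCatch({
    ch <- Matrix::Cholesky(sys$L, LDL = FALSE)
    as.numeric(Matrix::solve(ch, sys$b))
  }, error = function(e)
    stop("solver error: sparse factorization failed (",
         conditionMessage(e),
         "); the system may be singular (electrode touching ground?)"))
  res <- sqrt(sum((as.numeric(sys$L %*% phi_u) - sys$b)^2)) /
    max(sqrt(sum(sys$b^2)), 1e-300)
  if (voltage > 0 && res > 1e-8)
    stop("solver error: relative residual ", format(res))

  vmax <- max(voltage, 0)
  tol <- 1e-9 * max(vmax, 1)
  if (min(phi_u) < -tol || max(phi_u) > vmax + tol)
    stop("solver error: discrete maximum principle violated")

  phi <- matrix(NA_real_, nrow(type), ncol(type))
  phi[sys$unknown] <- phi_u
  phi[type == 1L] <- fixed_value[type == 1L]

  diss <- fv_dissipation(asm, phi, fixed_value, type)
  vol <- cell_volumes(grid) * MM^3          # m^3
  q <- matrix(0, nrow(type), ncol(type))
  tissue <- type == 0L
  q[tissue] <- diss$W[tissue] / vol[tissue]
  e_mag <- matrix(0, nrow(type), ncol(type))
  e_mag[tissue] <- sqrt(q[tissue] / sigma[tissue])

  # total dissipation equals the delivered power by the discrete Green
  # identity; the current follows from the energized-cell fluxes
  power <- sum(diss$W)
  current <- if (ground == "plates") {
    if (voltage > 0) power / voltage else 0
  } else {
    live <- !is.na(fixed_value) & fixed_value > 0
    sum(diss$flux_fixed[live])
  }
  structure(list(phi = phi, e_mag = e_mag, q_src = q,
                 power_total = power,
                 impedance = if (current > 0) voltage / current else NA_real_,
                 current = current, applied_voltage = voltage,
                 residual = res, type = type, ground = ground),
            class = "field_solution")
}

#' Volumetric Joule heat source of a field solution
#'
#' Returns the heat source \eqn{q = \sigma|\nabla\phi|^2} (W/m^3) of a
#' solved potential, checking consistency with the grid. The volume
#' integral of the returned field equals \code{power_total}.
#'
#' @param sol A \code{field_solution}.
#' @param grid The \code{phantom_grid} the solution was computed on.
#' @return Matrix of cell heat sources, W/m^3.
#' @export
heat_source <- function(sol, grid) {
  stopifnot(inherits(sol, "field_solution"))
  if (!identical(dim(sol$q_src), dim(grid$labels)))
    stop("consistency error: solution and grid shapes differ")
  sol$q_src
}

#' @export
print.field_solution <- function(x, ...) {
  cat("<field_solution>\n")
  cat(sprintf("  applied voltage: %.2f V\n", x$applied_voltage))
  cat(sprintf("  power: %.3f W   impedance: %s Ohm   current: %.4f A\n",
              x$power_total,
              if (is.na(x$impedance)) "NA" else sprintf("%.1f", x$impedance),
              x$current))
  cat(sprintf("  residual: %.2e\n", x$residual))
  invisible(x)
}

#' @export
plot.field_solution <- function(x, grid, what = c("phi", "q_src"), ...) {
  what <- match.arg(what)
  f <- x[[what]]
  f[is.na(f)] <- max(f, na.rm = TRUE)
  graphics::image(grid$rc, grid$zc, if (what == "q_src") log10(f + 1) else f,
                  xlab = "r (mm)", ylab = "z (mm)",
                  main = if (what == "phi") "potential (V)"
                         else "log10 heat source (W/m^3)", ...)
  invisible(x)
}
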