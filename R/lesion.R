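#' Radius of the lesion isotherm
#'
#' Maximum perpendicular distance from the electrode axis (r = 0) to the
#' \code{boundary_temp} contour of the end-of-ablation temperature
#' snapshot, with sub-grid linear interpolation along r. The 60 degree C
#' isotherm is taken as the margin of irreversible thermal damage.
#'
#' @param field A \code{temperature_field} (the final snapshot is used),
#'   or a plain nr x nz temperature matrix together with \code{grid}.
#' @param boundary_temp Isotherm temperature, degrees C (default 60).
#' @param grid Required when \code{field} is a matrix.
#' @param baseline_temp Baseline used for the sanity check that the
#'   isotherm lies above it.
#' @return Radius in mm; 0 if no cell reaches \code{boundary_temp}
#'   (attribute \code{reached} is \code{FALSE} in that case).
#' @examples
#' g <- axisymmetric_grid(r_extent = 20, z_extent = c(-20, 20),
#'                        spacing = 0.25)
#' Tmat <- matrix(37 + 43 * exp(-outer(g$rc^2, g$zc^2, "+") / (2 * 16)),
#'                length(g$rc), length(g$zc))
#' isotherm_radius(Tmat, 60, grid = g)   # ~ 4 * sqrt(2 * log(43/23))
#' @export
isotherm_radius <- function(field, boundary_temp = 60, grid = NULL,
                            baseline_temp = 37) {
  if (inherits(field, "temperature_field")) {
    grid <- field$grid
    baseline_temp <- field$protocol$baseline_temp
    Tmat <- field$snapshots[[length(field$snapshots)]]
  } else {
    Tmat <- field
    if (is.null(grid)) stop("grid required for a matrix input")
  }
  if (boundary_temp <= baseline_temp)
    stop("parameter error: boundary_temp must exceed the baseline ",
         "temperature (the whole domain would be lesion)")
  rc <- grid$rc
  nr <- length(rc)
  best <- 0
  reached <- FALSE
  for (j in seq_len(ncol(Tmat))) {
    Tj <- Tmat[, j]
    hot <- which(!is.na(Tj) & Tj >= boundary_temp)
    if (!length(hot)) next
    reached <- TRUE
    i <- max(hot)                       # outermost hot cell in this row
    if (i == nr) { best <- max(best, rc[nr]); next }
    Tin <- Tj[i]; Tout <- Tj[i + 1]
    r <- if (is.na(Tout) || Tout >= boundary_temp) rc[i]
         else rc[i] + (rc[i + 1] - rc[i]) * (Tin - boundary_temp) /
           (Tin - Tout)
    best <- max(best, r)
  }
  structure(best, reached = reached)
}

#' Planned lesion volume (planning formula)
#'
#' Volume of one trajectory's lesion under the hemisphere-plus-cylinder
#' planning model:
#' \deqn{V = \tfrac12 \pi r^3 + \pi r^2 \cdot 3 n}
#' where r (mm) is the lesion radius at the 60 degree C boundary, n is
#' the number of superimposed coagulations stacked by 3 mm pull-backs,
#' and pi is taken as 3.14. The formula is implemented exactly as used
#' for planning, including the 1/2 hemisphere coefficient; see
#' [lesion_geometric_volume()] for the self-consistent geometric solid
#' volume.
#'
#' @param r Lesion radius, mm (>= 0). Vectorized.
#' @param n Number of superimposed lesions (integer >= 0). Vectorized.
#' @param pi_value Value of pi used by the planning formula.
#' @param pullback_step Axial pull-back step, mm.
#' @return Volume in mm^3.
#' @examples
#' lesion_volume_eq1(5.4, 5)    # a typical single-trajectory plan
#' @export
lesion_volume_eq1 <- function(r, n, pi_value = 3.14, pullback_step = 3) {
  if (any(r < 0)) stop("parameter error: r must be >= 0")
  if (any(n < 0) || any(n != round(n)))
    stop("parameter error: n must be a non-negative integer")
  0.5 * pi_value * r^3 + pi_value * r^2 * pullback_step * n
}

#' Geometric volume of the lesion solid
#'
#' Exact volume of the hemisphere-capped cylinder actually rasterized:
#' \eqn{(2/3)\pi r^3 + \pi r^2 \cdot 3 n} with exact pi. Reported
#' alongside the planning volume, whose hemisphere coefficient is 1/2.
#'
#' @inheritParams lesion_volume_eq1
#' @return Volume in mm^3.
#' @export
lesion_geometric_volume <- function(r, n, pullback_step = 3) {
  if (any(r < 0)) stop("parameter error: r must be >= 0")
  (2 / 3) * pi * r^3 + pi * r^2 * pullback_step * n
}

#' Multi-trajectory ablation plan
#'
#' Electrode trajectories for a pull-back ablation: each trajectory runs
#' from an entry point to a (deepest) target point and stacks
#' \code{n_pullbacks} coagulations, the electrode being withdrawn
#' \code{pullback_step} mm axially between coagulations.
#'
#' @param entry,target Numeric matrices (one row per trajectory, columns
#'   x, y, z in mm) or length-3 vectors for a single trajectory.
#' @param n_pullbacks Integer vector, one per trajectory.
#' @param pullback_step Pull-back step, mm (default 3).
#' @return Object of class \code{trajectory_plan}.
#' @export
trajectory_plan <- function(entry, target, n_pullbacks,
                            pullback_step = 3) {
  if (is.null(dim(entry))) entry <- matrix(entry, nrow = 1)
  if (is.null(dim(target))) target <- matrix(target, nrow = 1)
  entry <- unname(as.matrix(entry))
  target <- unname(as.matrix(target))
  if (nrow(entry) != nrow(target) ||
      nrow(entry) != length(n_pullbacks))
    stop("consistency error: entry, target and n_pullbacks lengths differ")
  if (any(n_pullbacks < 0) || any(n_pullbacks != round(n_pullbacks)))
    stop("parameter error: n_pullbacks must be non-negative integers")
  if (!(pullback_step > 0))
    stop("parameter error: pullback_step must be > 0")
  structure(list(entry = entry, target = target,
                 n_pullbacks = as.integer(n_pullbacks),
                 pullback_step = pullback_step),
            class = "trajectory_plan")
}

#' @export
print.trajectory_plan <- function(x, ...) {
  cat(sprintf("<trajectory_plan> %d trajectories, %.0f mm pull-back step\n",
              nrow(x$entry), x$pullback_step))
  for (i in seq_len(nrow(x$entry)))
    cat(sprintf("  %d: (%s) -> (%s), n = %d\n", i,
                paste(format(x$entry[i, ], digits = 3), collapse = ", "),
                paste(format(x$target[i, ], digits = 3), collapse = ", "),
                x$n_pullbacks[i]))
  invisible(x)
}

#' Compose the planned lesion volume over all trajectories
#'
#' Applies the planning volume formula per trajectory with its isotherm
#' radius and pull-back count, sums the total, and constructs the
#' geometric solids (hemisphere-capped cylinders along each trajectory)
#' used for rasterization.
#'
#' @param plan A [trajectory_plan()].
#' @param r Isotherm radius per trajectory, mm (recycled if length 1).
#' @param pi_value Value of pi for the planning formula.
#' @param boundary_temp Isotherm temperature the radii refer to.
#' @return Object of class \code{lesion_estimate} with per-trajectory
#'   radii \code{r}, counts \code{n}, planning volumes \code{v_eq1},
#'   geometric volumes \code{v_geom}, totals \code{v_total} /
#'   \code{v_total_geom}, and the solids.
#' @export
compose_plan <- function(plan, r, pi_value = 3.14, boundary_temp = 60) {
  stopifnot(inherits(plan, "trajectory_plan"))
  ntraj <- nrow(plan$entry)
  if (length(r) == 1L) r <- rep(r, ntraj)
  if (length(r) != ntraj)
    stop("consistency error: one radius per trajectory required")
  n <- plan$n_pullbacks
  v_eq1 <- lesion_volume_eq1(r, n, pi_value, plan$pullback_step)
  v_geom <- lesion_geometric_volume(r, n, plan$pullback_step)
  solids <- lapply(seq_len(ntraj), function(i) {
    d <- plan$entry[i, ] - plan$target[i, ]
    len <- sqrt(sum(d^2))
    if (len == 0 && n[i] > 0)
      stop("geometry error: entry equals target with pull-backs planned")
    list(tip = plan$target[i, ],
         dir = if (len > 0) d / len else c(0, 0, 1),
         length = plan$pullback_step * n[i],
         radius = r[i])
  })
  structure(list(r = r, n = n, pi_value = pi_value,
                 v_eq1 = v_eq1, v_geom = v_geom,
                 v_total = sum(v_eq1), v_total_geom = sum(v_geom),
                 boundary_temp = boundary_temp, solids = solids),
            class = "lesion_estimate")
}

#' @export
print.lesion_estimate <- function(x, ...) {
  cat("<lesion_estimate>\n")
  for (i in seq_along(x$r))
    cat(sprintf(
      "  trajectory %d: r = %.2f mm, n = %d, V = %.2f mm^3 (geometric %.2f)\n",
      i, x$r[i], x$n[i], x$v_eq1[i], x$v_geom[i]))
  cat(sprintf("  total planned volume: %.2f mm^3 (geometric %.2f)\n",
              x$v_total, x$v_total_geom))
  invisible(x)
}

#' Rasterize the planned lesion solids
#'
#' Marks every voxel whose center falls inside the union of the
#' trajectory solids (hemisphere-capped cylinders). Overlapping
#' trajectories are counted once (set union).
#'
#' @param estimate A [compose_plan()] result.
#' @param plan The matching [trajectory_plan()] (kept for interface
#'   symmetry; the solids stored in \code{estimate} are used).
#' @param voxel_size Isotropic voxel size, mm.
#' @param margin Padding of the bounding box, mm.
#' @return Object of class \code{lesion_mask}: logical 3D array
#'   \code{mask}, \code{voxel_size} and \code{origin} (mm coordinates of
#'   the center of voxel [1,1,1]).
#' @export
rasterize_lesion <- function(estimate, plan = NULL, voxel_size,
                             margin = 2) {
  stopifnot(inherits(estimate, "lesion_estimate"))
  if (!(voxel_size > 0)) stop("parameter error: voxel_size must be > 0")
  solids <- Filter(function(s) s$radius > 0, estimate$solids)
  if (!length(solids)) {
    return(structure(list(mask = array(FALSE, c(1, 1, 1)),
                          voxel_size = voxel_size, origin = c(0, 0, 0)),
                     class = "lesion_mask"))
  }
  if (voxel_size > min(vapply(solids, `[[`, numeric(1), "radius")))
    warning("degenerate raster: voxel_size exceeds a lesion radius")
  pts <- do.call(rbind, lapply(solids, function(s)
    rbind(s$tip - s$radius, s$tip + s$dir * s$length + s$radius)))
  lo <- apply(pts, 2, min) - margin
  hi <- apply(pts, 2, max) + margin
  ax <- lapply(1:3, function(d)
    lo[d] + voxel_size * (seq_len(ceiling((hi[d] - lo[d]) / voxel_size))
                          - 0.5))
  nx <- lengths(ax)
  X <- array(ax[[1]], nx)
  Y <- aperm(array(ax[[2]], nx[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(ax[[3]], nx[c(3, 1, 2)]), c(2, 3, 1))
  mask <- array(FALSE, nx)
  for (s in solids) {
    vx <- X - s$tip[1]; vy <- Y - s$tip[2]; vz <- Z - s$tip[3]
    t <- vx * s$dir[1] + vy * s$dir[2] + vz * s$dir[3]
    d2 <- vx^2 + vy^2 + vz^2
    rad2 <- pmax(d2 - t^2, 0)
    inside <- (t >= 0 & t <= s$length & rad2 <= s$radius^2) |
      (t < 0 & d2 <= s$radius^2)
    mask <- mask | inside
  }
  structure(list(mask = mask, voxel_size = voxel_size,
                 origin = vapply(ax, `[`, numeric(1), 1)),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat(sprintf(
    "<lesion_mask> %s voxels at %.2f mm, %d set (%.2f mm^3)\n",
    paste(dim(x$mask), collapse = " x "), x$voxel_size,
    sum(x$mask), sum(x$mask) * x$voxel_size^3))
  invisible(x)
}
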