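#' Ablation protocol
#'
#' Parameters of one radiofrequency coagulation: applied voltage, the
#' temperature-control setpoint and band, the generator power clamp, ramp
#' window and total duration. The clinical generator raises the measured
#' tip temperature from 37 to 80 (+/- 2) degrees C within 10-15 s and
#' holds for 90 s with delivered power confined to 2-6 W; the published
#' simulation drives the electrode at a constant 34 V.
#'
#' Two modes are provided. \code{"constant_voltage"} applies the full
#' Joule source for the whole duration (the published simulation
#' setting). \code{"temperature_controlled"} emulates the generator: a
#' proportional controller modulates delivered power toward a setpoint
#' that ramps from baseline to \code{target_temp} over
#' \code{setpoint_ramp} seconds (generators ramp their setpoint at a
#' programmed rate; the measured temperature therefore crosses the
#' target near the end of the ramp), with power clamped to
#' \code{[power_min, power_max]}.
#'
#' The controlled temperature (\code{sensor}) is either
#' \code{"electrode"} -- the mean temperature of the metal tip,
#' emulating the thermocouple embedded in the cautery tip, which
#' requires the thermally conducting electrode model -- or
#' \code{"tissue_shell"} -- the maximum tissue temperature within 0.5 mm
#' of the tip surface.
#'
#' @param mode \code{"temperature_controlled"} or
#'   \code{"constant_voltage"}.
#' @param voltage Applied voltage, V (clinical range 30-33 V, simulation
#'   value 34 V).
#' @param power_min,power_max Generator power clamp, W.
#' @param target_temp Temperature setpoint, degrees C.
#' @param target_band Acceptable band around the setpoint, degrees C.
#' @param ramp_window Device specification of the first-crossing window
#'   of the setpoint, s (metadata used for reporting).
#' @param setpoint_ramp Duration of the programmed setpoint ramp from
#'   baseline to target, s; 0 applies the target as a step.
#' @param duration Total ablation time, s.
#' @param baseline_temp Body/tissue baseline temperature, degrees C.
#' @param frequency Generator frequency, Hz (conductivities are the
#'   100 kHz values; the solver is conduction-dominated so frequency is
#'   metadata).
#' @param sensor Which temperature the controller regulates; see
#'   Details.
#' @param control_gain Proportional gain of the power controller.
#' @param control_interval Time between controller updates, s.
#' @return Object of class \code{ablation_protocol}.
#' @export
ablation_protocol <- function(mode = c("temperature_controlled",
                                       "constant_voltage"),
                              voltage = 34, power_min = 2, power_max = 6,
                              target_temp = 80, target_band = 2,
                              ramp_window = c(10, 15),
                              setpoint_ramp = 10, duration = 90,
                              baseline_temp = 37, frequency = 1e5,
                              sensor = c("electrode", "tissue_shell"),
                              control_gain = 0.5,
                              control_interval = 0.5) {
  mode <- match.arg(mode)
  sensor <- match.arg(sensor)
  if (!(power_min > 0) || power_min > power_max)
    stop("parameter error: need 0 < power_min <= power_max")
  if (duration < 0) stop("parameter error: duration must be >= 0")
  if (!(target_temp > baseline_temp))
    stop("parameter error: target_temp must exceed baseline_temp")
  if (voltage < 0) stop("parameter error: voltage must be >= 0")
  if (setpoint_ramp < 0)
    stop("parameter error: setpoint_ramp must be >= 0")
  structure(list(mode = mode, voltage = voltage, power_min = power_min,
                 power_max = power_max, target_temp = target_temp,
                 target_band = target_band, ramp_window = ramp_window,
                 setpoint_ramp = setpoint_ramp, duration = duration,
                 baseline_temp = baseline_temp, frequency = frequency,
                 sensor = sensor, control_gain = control_gain,
                 control_interval = control_interval),
            class = "ablation_protocol")
}

#' @export
print.ablation_protocol <- function(x, ...) {
  cat(sprintf(
    "<ablation_protocol> %s: %.0f V, %.0f-%.0f W, target %.0f +/- %.0f C, %.0f s\n",
    x$mode, x$voltage, x$power_min, x$power_max, x$target_temp,
    x$target_band, x$duration))
  if (x$mode == "temperature_controlled")
    cat(sprintf("  sensor: %s, setpoint ramp %.0f s, gain %.2f every %.1f s\n",
                x$sensor, x$setpoint_ramp, x$control_gain,
                x$control_interval))
  invisible(x)
}

# time-dependent setpoint of the controller
protocol_setpoint <- function(protocol, time) {
  if (protocol$setpoint_ramp <= 0 || !is.finite(time))
    return(protocol$target_temp)
  protocol$baseline_temp +
    (protocol$target_temp - protocol$baseline_temp) *
    min(1, time / protocol$setpoint_ramp)
}

#' Temperature-controlled power update
#'
#' Proportional controller of the delivered power: the dimensionless
#' scale s multiplying the Joule heat source is updated by
#' \code{s <- s * (1 + gain * (setpoint - tip_temp) / setpoint)} and then
#' clamped so the instantaneous delivered power \code{s * base_power}
#' stays inside \code{[power_min, power_max]}. The setpoint equals
#' \code{target_temp} once the programmed ramp is over (and always when
#' \code{time} is omitted). In constant-voltage mode the scale is always
#' 1 (no regulation, no clamping).
#'
#' @param tip_temp Current sensed tip temperature, degrees C.
#' @param protocol An [ablation_protocol()].
#' @param current_scale Current scale s.
#' @param base_power Electrical power at scale 1 (the field solution's
#'   \code{power_total}), W.
#' @param time Time since the start of the ablation, s (drives the
#'   setpoint ramp; default: ramp finished).
#' @return New scale, with attributes \code{power} (delivered W) and
#'   \code{clamped} (logical).
#' @examples
#' pr <- ablation_protocol()
#' control_power(37, pr, current_scale = 0.5, base_power = 4)
#' @export
control_power <- function(tip_temp, protocol, current_scale = 1,
                          base_power, time = Inf) {
  if (protocol$mode == "constant_voltage") {
    s <- 1
    attr(s, "power") <- base_power
    attr(s, "clamped") <- FALSE
    return(s)
  }
  setp <- protocol_setpoint(protocol, time)
  s <- current_scale *
    (1 + protocol$control_gain * (setp - tip_temp) / setp)
  clamped <- FALSE
  if (base_power > 0) {
    lo <- protocol$power_min / base_power
    hi <- protocol$power_max / base_power
    if (s < lo) { s <- lo; clamped <- TRUE }
    if (s > hi) { s <- hi; clamped <- TRUE }
  }
  attr(s, "power") <- s * max(base_power, 0)
  attr(s, "clamped") <- clamped
  s
}

#' Transient Pennes bioheat simulation of one ablation
#'
#' Integrates the Pennes bioheat equation
#' \deqn{\rho c \,\partial T/\partial t = \nabla\cdot(k \nabla T) +
#'   \rho_b c_b \omega_b (T_b - T) + q_{met} + s(t)\, q_{src}}
#' from a uniform baseline over the protocol duration. The quasi-static
#' Joule source \eqn{q_{src}} is solved once at the protocol voltage
#' (conductivity is temperature-independent) and rescaled by the power
#' controller \eqn{s(t)}; the far boundary is held at the baseline
#' (body) temperature.
#'
#' Two electrode thermal models are available. \code{"insulated"}: no
#' heat flows into the electrode body (the configuration matching the
#' closed-form steady solutions). \code{"conducting"}: the electrode is
#' a solid metal domain (properties from the \code{electrode_spec}) that
#' spreads and drains heat along the shaft; required when the controller
#' senses the embedded thermocouple (\code{sensor = "electrode"}).
#' \code{"auto"} picks conducting for a temperature-controlled protocol
#' with electrode sensing and insulated otherwise.
#'
#' Time integration is implicit Euler by default (unconditionally
#' stable); an explicit scheme is retained for cross-checking and
#' enforces its CFL limit.
#'
#' @param grid Axisymmetric \code{phantom_grid}.
#' @param electrode \code{electrode_spec} (or \code{NULL} for
#'   source-free test configurations).
#' @param protocol An [ablation_protocol()].
#' @param dt Time step, s (adjusted slightly so the duration is an
#'   integer number of steps).
#' @param field Optional precomputed [solve_potential()] solution.
#' @param initial_temp Initial temperature (scalar or matrix), degrees
#'   C; defaults to the protocol baseline.
#' @param store_times Times (s) at which to store full snapshots; the
#'   final time is always stored. Default: every 5 s.
#' @param thermal_bc \code{"dirichlet"} (far boundary at baseline) or
#'   \code{"insulated"}.
#' @param ground,ground_radius Passed to the field solve; with
#'   \code{ground = "sphere"} the thermal Dirichlet condition is applied
#'   on the same shell.
#' @param electrode_thermal \code{"auto"}, \code{"insulated"} or
#'   \code{"conducting"}; see Details.
#' @param scheme \code{"implicit"} (default) or \code{"explicit"}.
#' @param tip_shell_mm Thickness of the tissue shell adjacent to the
#'   active tip over which the tissue maximum is tracked, mm.
#' @param energy_log Record a per-step energy balance?
#' @return Object of class \code{temperature_field}: \code{times},
#'   \code{snapshots} (list of tissue-temperature matrices, \code{NA}
#'   inside the electrode), \code{tip_trace} (data.frame: time,
#'   tip_temp = sensed temperature, tissue_max = maximum tissue
#'   temperature near the tip, scale, power), \code{dt}, the protocol,
#'   field solution, grid and a run \code{log}.
#' @export
run_transient <- function(grid, electrode, protocol, dt = 0.1,
                          field = NULL, initial_temp = NULL,
                          store_times = NULL,
                          thermal_bc = c("dirichlet", "insulated"),
                          ground = c("boundary", "sphere"),
                          ground_radius = NULL,
                          electrode_thermal = c("auto", "insulated",
                                                "conducting"),
                          scheme = c("implicit", "explicit"),
                          tip_shell_mm = 0.5,
                          energy_log = FALSE) {
  thermal_bc <- match.arg(thermal_bc)
  ground <- match.arg(ground)
  scheme <- match.arg(scheme)
  electrode_thermal <- match.arg(electrode_thermal)
  if (!(dt > 0)) stop("parameter error: dt must be > 0")
  stopifnot(inherits(protocol, "ablation_protocol"))
  if (!(protocol$duration > 0))
    stop("parameter error: transient run needs duration > 0")

  controlled <- protocol$mode == "temperature_controlled"
  if (electrode_thermal == "auto")
    electrode_thermal <- if (controlled && !is.null(electrode) &&
                             protocol$sensor == "electrode")
      "conducting" else "insulated"
  if (controlled && protocol$sensor == "electrode" &&
      electrode_thermal != "conducting")
    stop("parameter error: sensor = 'electrode' needs the conducting ",
         "electrode thermal model")

  T_inf <- protocol$baseline_temp
  log <- character(0)

  if (is.null(field) && !is.null(electrode) && protocol$voltage > 0) {
    field <- solve_potential(grid, electrode, protocol$voltage,
                             ground = ground,
                             ground_radius = ground_radius)
  }
  q_src <- if (is.null(field)) 0 * grid$labels else field$q_src
  base_power <- if (is.null(field)) 0 else field$power_total

  # thermal cell classification and per-cell properties
  el_type <- classify_cells(grid, electrode)
  el_mask <- el_type > 0L
  type <- matrix(0L, nrow(el_type), ncol(el_type))
  fixed_value <- matrix(NA_real_, nrow(type), ncol(type))
  k <- property_field(grid, "k")
  rho <- property_field(grid, "rho")
  cp <- property_field(grid, "c")
  omega <- property_field(grid, "omega_b")
  Tb <- property_field(grid, "T_b")
  qmet <- property_field(grid, "q_met")
  if (electrode_thermal == "conducting" && any(el_mask)) {
    k[el_mask] <- electrode$k_metal
    rho[el_mask] <- electrode$rho_metal
    cp[el_mask] <- electrode$c_metal
    omega[el_mask] <- 0
    qmet[el_mask] <- 0
  } else {
    type[el_mask] <- 2L                  # insulated: no heat flux
  }
  if (ground == "sphere") {
    R <- matrix(grid$rc, length(grid$rc), length(grid$zc))
    Z <- matrix(grid$zc, length(grid$rc), length(grid$zc), byrow = TRUE)
    gm <- sqrt(R^2 + Z^2) >= ground_radius & type == 0L
    type[gm] <- 1L
    fixed_value[gm] <- T_inf
  }

  asm <- assemble_faces(grid, k, type, fixed_value,
                        boundary = if (thermal_bc == "dirichlet" &&
                                       ground == "boundary")
                          "dirichlet" else "insulated",
                        boundary_value = T_inf)
  sys <- fv_system(asm, type)
  u <- sys$unknown
  nU <- length(u)
  if (!nU) stop("geometry error: no cells to solve for")

  vol <- cell_volumes(grid) * MM^3
  bl <- blood_properties()
  C_u <- (rho * cp * vol)[u]
  W_u <- (bl$rho_b * bl$c_b * omega * vol)[u]
  Tb_u <- Tb[u]
  S_u <- (q_src * vol)[u]                      # W at scale 1
  Smet_u <- (qmet * vol)[u]

  # time stepping setup
  nsteps <- max(1L, round(protocol$duration / dt))
  dt_eff <- protocol$duration / nsteps
  if (abs(dt_eff - dt) > 1e-9)
    log <- c(log, sprintf("dt adjusted to %.6g s (%d steps)", dt_eff,
                          nsteps))
  A_const <- sys$L + Matrix::Diagonal(nU, W_u)
  rhs_const <- sys$b + W_u * Tb_u + Smet_u
  if (scheme == "implicit") {
    A <- A_const + Matrix::Diagonal(nU, C_u / dt_eff)
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE)
  } else {
    dt_max <- min(C_u / (Matrix::diag(sys$L) + W_u))
    if (dt_eff > dt_max)
      stop(sprintf(
        "step-size error: explicit scheme needs dt <= %.4g s", dt_max))
  }

  # sensor and tissue-shell masks (on the unknown vector)
  shell_u <- if (!is.null(electrode)) {
    sd_u <- surface_distance(grid, electrode)[u]
    m <- sd_u > 0 & sd_u <= tip_shell_mm
    if (!any(m)) rep(TRUE, nU) else m
  } else rep(TRUE, nU)
  sensor_u <- if (controlled && protocol$sensor == "electrode") {
    m <- (el_type == 1L)[u]
    if (!any(m)) stop("geometry error: no active-tip cells to sense")
    m
  } else shell_u
  sense <- function(Tu) {
    if (controlled && protocol$sensor == "electrode")
      mean(Tu[sensor_u]) else max(Tu[sensor_u])
  }

  # snapshot schedule
  if (is.null(store_times))
    store_times <- seq(0, protocol$duration, by = 5)
  store_times <- sort(unique(c(store_times, protocol$duration)))
  store_steps <- unique(pmin(nsteps, pmax(0L,
                                          round(store_times / dt_eff))))

  Tn <- if (is.null(initial_temp)) rep(T_inf, nU)
        else if (length(initial_temp) == 1L) rep(initial_temp, nU)
        else initial_temp[u]

  full_snapshot <- function(Tu) {
    m <- matrix(NA_real_, nrow(type), ncol(type))
    m[u] <- Tu
    m[type == 1L] <- fixed_value[type == 1L]
    m[el_mask] <- NA_real_               # electrode body is not tissue
    m
  }

  s <- if (controlled && base_power > 0)
    protocol$power_min / base_power else 1
  ctrl_every <- max(1L, round(protocol$control_interval / dt_eff))
  n_clamped <- 0L

  snapshots <- list(); times <- numeric(0)
  if (0L %in% store_steps) {
    snapshots[["0"]] <- full_snapshot(Tn); times <- 0
  }
  trace_tip <- numeric(nsteps); trace_max <- numeric(nsteps)
  trace_s <- numeric(nsteps); trace_p <- numeric(nsteps)
  energy <- if (energy_log)
    matrix(NA_real_, nsteps, 4,
           dimnames = list(NULL, c("added", "perfusion", "boundary",
                                   "stored"))) else NULL
  if (energy_log) {
    bc_p <- integer(0); bc_G <- numeric(0); bc_v <- numeric(0)
    for (f in asm$faces) {
      if (is.null(f)) next
      fx <- f$fixedN
      bc_p <- c(bc_p, sys$comp[f$p[fx]])
      bc_G <- c(bc_G, f$G[fx]); bc_v <- c(bc_v, f$val[fx])
    }
    if (!is.null(asm$bfaces)) {
      bc_p <- c(bc_p, sys$comp[asm$bfaces$p])
      bc_G <- c(bc_G, asm$bfaces$G); bc_v <- c(bc_v, asm$bfaces$val)
    }
  }

  for (step in seq_len(nsteps)) {
    if (controlled && (step - 1L) %% ctrl_every == 0L) {
      s_new <- control_power(sense(Tn), protocol, s, base_power,
                             time = (step - 1L) * dt_eff)
      if (isTRUE(attr(s_new, "clamped"))) n_clamped <- n_clamped + 1L
      s <- as.numeric(s_new)
    }
    T1 <- if (scheme == "implicit") {
      as.numeric(Matrix::solve(ch, rhs_const + s * S_u +
                                 C_u / dt_eff * Tn))
    } else {
      Tn + dt_eff / C_u *
        (rhs_const + s * S_u - as.numeric(A_const %*% Tn))
    }
    if (energy_log) {
      energy[step, ] <- c(
        dt_eff * (s * sum(S_u) + sum(Smet_u)),
        dt_eff * sum(W_u * (T1 - Tb_u)),
        dt_eff * sum(bc_G * (T1[bc_p] - bc_v)),
        sum(C_u * (T1 - Tn)))
    }
    Tn <- T1
    trace_tip[step] <- sense(Tn)
    trace_max[step] <- max(Tn[shell_u])
    trace_s[step] <- s
    trace_p[step] <- s * base_power
    if (step %in% store_steps) {
      snapshots[[as.character(step)]] <- full_snapshot(Tn)
      times <- c(times, step * dt_eff)
    }
  }
  if (n_clamped > 0L)
    log <- c(log, sprintf(
      "controller power clamp active in %d of %d updates", n_clamped,
      ceiling(nsteps / ctrl_every)))

  T0 <- if (is.null(initial_temp)) T_inf else max(initial_temp)
  structure(list(times = times, snapshots = snapshots,
                 tip_trace = data.frame(
                   time = c(0, seq_len(nsteps) * dt_eff),
                   tip_temp = c(T0, trace_tip),
                   tissue_max = c(T0, trace_max),
                   scale = c(NA, trace_s),
                   power = c(NA, trace_p)),
                 dt = dt_eff, duration = protocol$duration,
                 protocol = protocol, field = field, grid = grid,
                 electrode = electrode,
                 electrode_thermal = electrode_thermal,
                 tip_shell_mm = tip_shell_mm,
                 energy = energy, log = log),
            class = "temperature_field")
}

#' Steady-state Pennes temperature field
#'
#' Solves the time-independent Pennes balance
#' \eqn{0 = \nabla\cdot(k\nabla T) + \rho_b c_b \omega_b (T_b - T) +
#' q_{met} + s\, q_{src}} with an insulated electrode body and the far
#' boundary at \code{T_inf}. Used for validation against closed-form
#' steady solutions and for quick lesion-size estimates.
#'
#' @inheritParams run_transient
#' @param scale Source scale s.
#' @param T_inf Far-boundary temperature, degrees C.
#' @return Temperature matrix (degrees C), \code{NA} inside the
#'   electrode.
#' @export
solve_steady_temperature <- function(grid, electrode, field = NULL,
                                     scale = 1, T_inf = 37,
                                     thermal_bc = c("dirichlet",
                                                    "insulated"),
                                     ground = c("boundary", "sphere"),
                                     ground_radius = NULL) {
  thermal_bc <- match.arg(thermal_bc)
  ground <- match.arg(ground)
  q_src <- if (is.null(field)) 0 * grid$labels else field$q_src
  el_type <- classify_cells(grid, electrode)
  type <- matrix(0L, nrow(el_type), ncol(el_type))
  type[el_type > 0L] <- 2L
  fixed_value <- matrix(NA_real_, nrow(type), ncol(type))
  if (ground == "sphere") {
    R <- matrix(grid$rc, length(grid$rc), length(grid$zc))
    Z <- matrix(grid$zc, length(grid$rc), length(grid$zc), byrow = TRUE)
    gm <- sqrt(R^2 + Z^2) >= ground_radius & type == 0L
    type[gm] <- 1L
    fixed_value[gm] <- T_inf
  }
  k <- property_field(grid, "k")
  asm <- assemble_faces(grid, k, type, fixed_value,
                        boundary = if (thermal_bc == "dirichlet" &&
                                       ground == "boundary")
                          "dirichlet" else "insulated",
                        boundary_value = T_inf)
  sys <- fv_system(asm, type)
  u <- sys$unknown
  vol <- cell_volumes(grid) * MM^3
  bl <- blood_properties()
  W_u <- (bl$rho_b * bl$c_b * property_field(grid, "omega_b") * vol)[u]
  rhs <- sys$b + W_u * property_field(grid, "T_b")[u] +
    scale * (q_src * vol)[u] +
    (property_field(grid, "q_met") * vol)[u]
  A <- sys$L + Matrix::Diagonal(length(u), W_u)
  Tu <- as.numeric(Matrix::solve(Matrix::Cholesky(
    Matrix::forceSymmetric(A), LDL = FALSE), rhs))
  out <- matrix(NA_real_, nrow(type), ncol(type))
  out[u] <- Tu
  out[type == 1L] <- fixed_value[type == 1L]
  out
}

#' First time the sensed tip temperature reaches a threshold
#'
#' Scans the tip temperature trace of a transient run and returns the
#' first crossing time of \code{threshold}, linearly interpolated
#' between time steps. If the trace starts at or above the threshold the
#' answer is 0; if it never reaches it, \code{NA} is returned
#' (not-reached).
#'
#' @param field A \code{temperature_field} from [run_transient()].
#' @param threshold Temperature, degrees C.
#' @param trace Which trace to scan: \code{"tip_temp"} (the sensed,
#'   controlled temperature) or \code{"tissue_max"}.
#' @return Time in seconds, or \code{NA_real_} if never reached.
#' @export
time_to_threshold <- function(field, threshold,
                              trace = c("tip_temp", "tissue_max")) {
  trace <- match.arg(trace)
  tr <- field$tip_trace
  if (!nrow(tr)) stop("empty temperature field")
  y <- tr[[trace]]
  above <- y >= threshold
  if (above[1]) return(0)
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  tr$time[i - 1] + (threshold - y[i - 1]) / (y[i] - y[i - 1]) *
    (tr$time[i] - tr$time[i - 1])
}

#' @export
print.temperature_field <- function(x, ...) {
  cat("<temperature_field>\n")
  cat(sprintf("  duration %.0f s, dt %.3g s, %d stored snapshots\n",
              x$duration, x$dt, length(x$snapshots)))
  cat(sprintf("  sensed tip: start %.1f C, end %.1f C, max %.1f C\n",
              x$tip_trace$tip_temp[1],
              utils::tail(x$tip_trace$tip_temp, 1),
              max(x$tip_trace$tip_temp)))
  if (length(x$log)) cat("  log:", paste(x$log, collapse = "; "), "\n")
  invisible(x)
}

#' @export
summary.temperature_field <- function(object, boundary_temp = 60, ...) {
  tr <- object$tip_trace
  hold <- tr$time >= min(30, object$duration / 3)
  out <- list(
    ramp_time = time_to_threshold(object, object$protocol$target_temp),
    plateau_temp = mean(tr$tip_temp[hold]),
    power_range = range(tr$power, na.rm = TRUE),
    isotherm_radius = as.numeric(isotherm_radius(object, boundary_temp)),
    boundary_temp = boundary_temp)
  class(out) <- "summary.temperature_field"
  out
}

#' @export
print.summary.temperature_field <- function(x, ...) {
  cat(sprintf("  time to target: %s s\n",
              if (is.na(x$ramp_time)) "not reached"
              else sprintf("%.1f", x$ramp_time)))
  cat(sprintf("  plateau sensed temperature: %.1f C\n", x$plateau_temp))
  cat(sprintf("  delivered power: %.2f - %.2f W\n",
              x$power_range[1], x$power_range[2]))
  cat(sprintf("  %.0f C isotherm radius: %.2f mm\n", x$boundary_temp,
              x$isotherm_radius))
  invisible(x)
}

#' @export
plot.temperature_field <- function(x, what = c("map", "trace"), ...) {
  what <- match.arg(what)
  if (what == "trace") {
    graphics::plot(x$tip_trace$time, x$tip_trace$tissue_max, type = "l",
                   xlab = "time (s)", ylab = "temperature (C)",
                   col = "grey40", ...)
    graphics::lines(x$tip_trace$time, x$tip_trace$tip_temp)
    graphics::abline(h = x$protocol$target_temp, lty = 2)
    graphics::legend("bottomright", c("tissue max", "sensed tip"),
                     col = c("grey40", "black"), lty = 1, bty = "n")
    return(invisible(x))
  }
  Tend <- x$snapshots[[length(x$snapshots)]]
  Tplot <- Tend
  Tplot[is.na(Tplot)] <- max(Tend, na.rm = TRUE)
  graphics::image(x$grid$rc, x$grid$zc, Tplot, xlab = "r (mm)",
                  ylab = "z (mm)", main = "temperature at end (C)", ...)
  graphics::contour(x$grid$rc, x$grid$zc, Tplot, levels = 60,
                    add = TRUE, lwd = 2)
  invisible(x)
}
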