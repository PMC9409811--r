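#' Percentage error between planned and measured volume
#'
#' \code{100 * |v_calc - v_meas| / v_calc}: the absolute volume
#' discrepancy relative to the calculated (planned) volume. The
#' calculated volume is the fixed denominator convention used throughout
#' the package.
#'
#' @param v_calc Calculated (simulation + planning formula) volume,
#'   mm^3 (> 0).
#' @param v_meas Measured (image-based) volume, mm^3.
#' @param digits Decimals to round to (default 1, matching the reporting
#'   precision); \code{NULL} for the unrounded value.
#' @return Percentage error (vectorized).
#' @examples
#' percentage_error(1867.87, 1841)   # 1.4
#' @export
percentage_error <- function(v_calc, v_meas, digits = 1) {
  if (any(v_calc <= 0))
    stop("undefined error: v_calc must be > 0")
  e <- 100 * abs(v_calc - v_meas) / v_calc
  if (!is.null(digits)) e <- round(e, digits)
  e
}

#' Mean and standard deviation of percentage errors
#'
#' Arithmetic mean and sample (n - 1) standard deviation of a set of
#' per-case percentage errors.
#'
#' @param errors Numeric vector of percentage errors (>= 1 value).
#' @param digits Decimals to round to (default 1); \code{NULL} for
#'   unrounded values.
#' @return Named numeric vector \code{c(mean =, sd =)}; the sd is 0 for
#'   a single value.
#' @examples
#' summarize_errors(c(1, 2, 3))   # mean 2.0, sd 1.0
#' @export
summarize_errors <- function(errors, digits = 1) {
  if (!length(errors)) stop("empty error list")
  m <- mean(errors)
  s <- if (length(errors) > 1) stats::sd(errors) else 0
  out <- c(mean = m, sd = s)
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Calculated-vs-measured volume report
#'
#' Assembles the per-case comparison of planned (simulation + planning
#' formula) against measured (image-based) ablation volumes, with
#' per-case percentage error and a mean +/- SD summary.
#'
#' @param case_id Case identifiers.
#' @param v_calc,v_meas Volumes per case, mm^3.
#' @param digits Rounding for the percentage columns.
#' @return Object of class \code{volume_report}: data.frame
#'   \code{cases} (case_id, v_calc, v_meas, pct_error) plus
#'   \code{mean_error} and \code{sd_error}.
#' @export
volume_report <- function(case_id, v_calc, v_meas, digits = 1) {
  stopifnot(length(case_id) == length(v_calc),
            length(v_calc) == length(v_meas))
  pe <- percentage_error(v_calc, v_meas, digits = NULL)
  s <- summarize_errors(pe, digits = digits)
  structure(list(cases = data.frame(case_id = case_id,
                                    v_calc = round(v_calc, 2),
                                    v_meas = round(v_meas, 2),
                                    pct_error = round(pe, digits)),
                 mean_error = s[["mean"]], sd_error = s[["sd"]]),
            class = "volume_report")
}

#' @export
print.volume_report <- function(x, ...) {
  cat("Ablation volume: calculated vs measured\n")
  df <- x$cases
  df$measured <- sprintf("%.10g (%.1f%%)", df$v_meas, df$pct_error)
  print(data.frame(case = df$case_id,
                   `calculated mm^3` = df$v_calc,
                   `measured mm^3 (error)` = df$measured,
                   check.names = FALSE), row.names = FALSE)
  cat(sprintf("mean error: %.1f +/- %.1f %%\n", x$mean_error,
              x$sd_error))
  invisible(x)
}

#' Published clinical volume series
#'
#' The three-case clinical series used as the package's worked example:
#' per-case calculated (simulation + planning formula) and measured
#' (post-operative image) ablation volumes, with the number of electrode
#' trajectories per case.
#'
#' @return data.frame with columns \code{case_id}, \code{trajectories},
#'   \code{v_calc} and \code{v_meas} (mm^3).
#' @export
reference_cases <- function() {
  data.frame(case_id = c("patient1", "patient2", "patient3"),
             trajectories = c(3L, 2L, 2L),
             v_calc = c(9949.69, 1867.87, 3941.89),
             v_meas = c(9727, 1841, 4073))
}
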