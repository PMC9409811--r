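# Serialization of run configurations to and from YAML, so a run can be
# described, archived and re-executed outside R.

config_to_list <- function(config) {
  plan <- config$plan
  list(
    case_id = config$case_id,
    seed = config$seed,
    pi_value = config$pi_value,
    phantom = config$phantom,
    electrode = unclass(config$electrode),
    protocol = unclass(config$protocol),
    plan = list(
      entry = lapply(seq_len(nrow(plan$entry)),
                     function(i) as.numeric(plan$entry[i, ])),
      target = lapply(seq_len(nrow(plan$target)),
                      function(i) as.numeric(plan$target[i, ])),
      n_pullbacks = as.integer(plan$n_pullbacks),
      pullback_step = plan$pullback_step),
    solver = config$solver,
    imaging = config$imaging)
}

list_to_config <- function(x) {
  ph <- x$phantom
  if (!is.null(ph$properties))
    ph$properties <- as.data.frame(ph$properties,
                                   stringsAsFactors = FALSE)
  run_config(
    phantom = ph,
    electrode = do.call(electrode_spec, x$electrode),
    protocol = do.call(ablation_protocol, x$protocol),
    plan = trajectory_plan(
      entry = do.call(rbind, x$plan$entry),
      target = do.call(rbind, x$plan$target),
      n_pullbacks = unlist(x$plan$n_pullbacks),
      pullback_step = x$plan$pullback_step),
    solver = x$solver,
    imaging = x$imaging,
    seed = x$seed,
    pi_value = x$pi_value,
    case_id = x$case_id)
}

#' Save or load a run configuration as YAML
#'
#' A saved configuration captures everything a run needs (phantom,
#' electrode, protocol, plan, solver and imaging settings, seed), so
#' re-running [run_pipeline()] on the loaded configuration reproduces
#' the original artifacts.
#'
#' @param config A [run_config()].
#' @param path File path of the YAML configuration.
#' @return \code{save_run_config} returns \code{path} invisibly;
#'   \code{read_run_config} returns a \code{run_config}.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' save_run_config(preset_reference(), f)
#' cfg <- read_run_config(f)
#' validate_config(cfg)
#' @export
save_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname save_run_config
#' @export
read_run_config <- function(path) {
  list_to_config(yaml::read_yaml(path))
}
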