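# Run configuration files: every tunable of a simulation (model
# hyperparameters, cue schedule, lesions, integration settings) can be
# expressed in a YAML or JSON file whose keys mirror the constructor
# arguments.

#' Load a run configuration from YAML or JSON
#'
#' Recognised top-level sections (all optional): `model` (arguments of
#' [reaching_config()]; `fast` and `slow` are argument lists of
#' [attractor_params()]), `schedule` (either `preset` for [make_schedule()]
#' or arguments of [cue_schedule()]), `world` (arguments of
#' [world_params()]), `sim` (arguments of [sim_config()] except `embed` and
#' `wp`), and `lesions` (a named map of site to log precision).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `model` (an `af_model`), `schedule`,
#'   `lesions` and `config` (an [sim_config()]), ready for
#'   [run_active_inference()].
#' @export
load_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  marg <- raw$model %||% list()
  for (nm in c("fast", "slow")) {
    if (!is.null(marg[[nm]])) marg[[nm]] <- do.call(attractor_params, marg[[nm]])
  }
  if (!is.null(marg$log_prec)) marg$log_prec <-
      utils::modifyList(formals(reaching_config)$log_prec |> eval(),
                        as.list(marg$log_prec))
  rc <- do.call(reaching_config, marg)
  model <- build_reaching_model(rc)
  sarg <- raw$schedule %||% list()
  schedule <- if (!is.null(sarg$preset)) {
    do.call(make_schedule, sarg)
  } else if (length(sarg)) {
    do.call(cue_schedule, sarg)
  } else {
    make_schedule("paper_default")
  }
  wp <- do.call(world_params, raw$world %||% list())
  simargs <- raw$sim %||% list()
  simargs$wp <- wp
  simargs$embed <- embedding(n_states = rc$n_states, n_causes = rc$n_causes,
                             smoothness = rc$smoothness)
  config <- do.call(sim_config, simargs)
  lesions <- raw$lesions
  if (!is.null(lesions)) lesions <- unlist(lesions)
  list(model = model, schedule = schedule, lesions = lesions,
       config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
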