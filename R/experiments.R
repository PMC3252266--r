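# Lesion-sweep experiments and figure-replication drivers.

#' Dopamine (precision) sweep at one lesion site
#'
#' Runs the full simulation at each depletion level of
#' [lesion_sweep()] with a shared seed and collects behavioural metrics in a
#' tidy table.
#'
#' @param site Lesion site name (see [apply_lesion()]).
#' @param n_levels Number of depletion levels (log precision spaced from
#'   nominal down to half nominal).
#' @param model Base model (nominal precisions).
#' @param schedule Cue schedule.
#' @param config An [sim_config()]; its seed is shared across levels.
#' @param nominal Nominal log precision.
#' @return A data frame with columns `site`, `level`, `log_prec`, `trial`,
#'   `target`, `rt_ms`, `accuracy`, `switch_latency`, `perseveration`,
#'   `perseveration_scorable`.
#' @export
dopamine_sweep <- function(site, n_levels = 6L,
                           model = build_reaching_model(),
                           schedule = make_schedule("paper_default"),
                           config = sim_config(), nominal = 4) {
  sweeps <- lesion_sweep(site, n_levels, nominal)
  out <- vector("list", length(sweeps))
  for (i in seq_along(sweeps)) {
    tr <- run_active_inference(model, schedule, lesions = sweeps[[i]],
                               config = config)
    tm <- trial_metrics(tr, schedule)
    pers <- attr(tm, "perseveration")
    out[[i]] <- data.frame(site = site, level = i,
                           log_prec = sweeps[[i]]$log_precision,
                           trial = tm$trial, target = tm$target,
                           rt_ms = tm$rt_ms, accuracy = tm$accuracy,
                           switch_latency = as.integer(attr(tm, "switch_latency")),
                           perseveration = pers$count,
                           perseveration_scorable = pers$scorable)
  }
  do.call(rbind, out)
}

write_trace_archive <- function(trace, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(time = trace$time, trace$world),
                   file.path(dir, "world.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time = trace$time, trace$action),
                   file.path(dir, "action.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time = trace$time, trace$mu),
                   file.path(dir, "mu.csv"), row.names = FALSE)
  utils::write.csv(data.frame(time = trace$time,
                              free_energy = trace$free_energy),
                   file.path(dir, "free_energy.csv"), row.names = FALSE)
  for (nm in names(trace$sensory))
    utils::write.csv(data.frame(time = trace$time, trace$sensory[[nm]]),
                     file.path(dir, paste0("sensory_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(trace$xi))
    utils::write.csv(data.frame(time = trace$time, trace$xi[[nm]]),
                     file.path(dir, paste0("xi_", nm, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

run_meta <- function(config, seed, extra = list()) {
  c(list(package = "affsim",
         version = as.character(utils::packageVersion("affsim")),
         seed = seed,
         config = unclass_deep(config)),
    extra)
}

unclass_deep <- function(x) {
  if (is.function(x)) return("<function>")
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  unclass(x)
}

#' Replicate one of the benchmark experiments
#'
#' Executes the corresponding experiment with default settings and writes a
#' plain-text archive: `fig5` the nominal 128-bin ten-cue run (full trace);
#' `fig7` traces at high, intermediate and low salience precision (sweep
#' levels 1, 4 and 6); `fig9` the six-level salience-precision sweep of
#' reaction time and accuracy; `fig10` reaction-time sweeps for the three
#' lesion sites (salience, arm-state, affordance-state).
#'
#' @param figure_id One of `"fig5"`, `"fig7"`, `"fig9"`, `"fig10"`.
#' @param out_dir Output directory (created if needed).
#' @param config An [sim_config()].
#' @param model,schedule Model and schedule (defaults as in the benchmark).
#' @return Invisibly, a list with the computed tables/traces.
#' @export
replicate_figure <- function(figure_id = c("fig5", "fig7", "fig9", "fig10"),
                             out_dir = tempfile("affsim_"),
                             config = sim_config(),
                             model = build_reaching_model(),
                             schedule = make_schedule("paper_default")) {
  figure_id <- match.arg(figure_id)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  res <- switch(figure_id,
    fig5 = {
      tr <- run_active_inference(model, schedule, config = config)
      write_trace_archive(tr, file.path(out_dir, "trace_nominal"))
      tm <- trial_metrics(tr)
      utils::write.csv(tm, file.path(out_dir, "trial_metrics.csv"),
                       row.names = FALSE)
      list(trace = tr, metrics = tm)
    },
    fig7 = {
      sweeps <- lesion_sweep("salience_sensory", 6)
      keep <- c(1, 4, 6)
      traces <- lapply(keep, function(i) {
        tr <- run_active_inference(model, schedule, lesions = sweeps[[i]],
                                   config = config)
        write_trace_archive(tr, file.path(out_dir, sprintf(
          "trace_salience_logprec_%g", sweeps[[i]]$log_precision)))
        tr
      })
      list(traces = traces)
    },
    fig9 = {
      tab <- dopamine_sweep("salience_sensory", 6, model, schedule, config)
      utils::write.csv(tab, file.path(out_dir, "salience_sweep.csv"),
                       row.names = FALSE)
      list(table = tab)
    },
    fig10 = {
      tabs <- lapply(c("salience_sensory", "arm_state", "affordance_state"),
                     function(s)
                       dopamine_sweep(s, 6, model, schedule, config))
      tab <- do.call(rbind, tabs)
      utils::write.csv(tab, file.path(out_dir, "site_sweeps.csv"),
                       row.names = FALSE)
      list(table = tab)
    })
  meta <- run_meta(config, config$seed,
                   list(figure = figure_id,
                        elapsed_s = proc.time()[["elapsed"]] - t0))
  jsonlite::write_json(meta, file.path(out_dir, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
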