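# Declarative description of hierarchical dynamic generative models:
# per-level flows f(x, v) on hidden states, observation maps g(x, v) whose
# output is the cause of the level below (sensory data at level 1), and log
# precisions for every prediction-error stream.  Precision lesions replace
# the log precision of a named stream, which is how tonic dopamine depletion
# is simulated.

#' Specify one level of a hierarchical dynamic model
#'
#' @param dim_x Hidden-state dimension (>= 0).
#' @param dim_v Hidden-cause dimension (>= 0).
#' @param flow Function `(x, v, params) -> dx/dt` (length `dim_x`).
#' @param obs Function `(x, v, params)` returning the predicted cause of the
#'   level below (at level 1, the predicted sensory data).
#' @param jac List of analytic Jacobians `fx`, `fv`, `gx`, `gv`, each a
#'   function `(x, v, params)` returning a matrix.
#' @param curv Optional curvature operators: list with functions `f` and `g`,
#'   each `(x, v, ux, uv, params)` returning `list(dx =, dv =)`, the
#'   derivative with respect to `(x, v)` of `Jx(x, v) ux + Jv(x, v) uv`.
#'   Omit (NULL) for linear levels, where the curvature vanishes.
#' @param state_partitions Named list of index vectors partitioning the
#'   hidden states; each partition carries its own state-motion log precision.
#' @param log_prec_state Named numeric vector of state-motion log precisions,
#'   one per partition.
#' @param log_prec_cause Log precision of the error on this level's predicted
#'   cause (ignored at level 1, where sensory streams carry precisions).
#' @param params Named list of constants passed to `flow`, `obs`, `jac`.
#' @return An object of class `af_level`.
#' @export
level_spec <- function(dim_x, dim_v, flow, obs, jac, curv = NULL,
                       state_partitions = NULL,
                       log_prec_state = NULL,
                       log_prec_cause = 4,
                       params = list()) {
  if (dim_x < 0 || dim_v < 0) stop("dimensions must be non-negative")
  if (is.null(state_partitions))
    state_partitions <- list(state = seq_len(dim_x))
  if (is.null(log_prec_state))
    log_prec_state <- stats::setNames(rep(4, length(state_partitions)),
                                      names(state_partitions))
  if (!all(is.finite(c(log_prec_state, log_prec_cause))))
    stop("log precisions must be finite")
  structure(list(dim_x = as.integer(dim_x), dim_v = as.integer(dim_v),
                 flow = flow, obs = obs, jac = jac, curv = curv,
                 state_partitions = state_partitions,
                 log_prec_state = log_prec_state,
                 log_prec_cause = log_prec_cause,
                 params = params),
            class = "af_level")
}

#' Assemble a hierarchical dynamic generative model
#'
#' @param levels List of [level_spec()] objects, level 1 (closest to the
#'   data) first.
#' @param streams Named list partitioning the level-1 observation output into
#'   sensory streams; each element is `list(idx =, log_prec =)`.
#' @param top_prior Prior on the top-level cause: `list(mean =, log_prec =)`
#'   where `mean` is a function of time (bins) returning the expected cause
#'   (recycled across derivative orders as a static prior).
#' @param lesion_sites Named list mapping lesion site names to the stream or
#'   partition they modulate (see [apply_lesion()]); built automatically by
#'   [build_reaching_model()].
#' @return An object of class `af_model`.
#' @export
hierarchical_model <- function(levels, streams, top_prior = NULL,
                               lesion_sites = NULL) {
  if (length(levels) < 1) stop("at least one level is required")
  top <- levels[[length(levels)]]
  if (is.null(top_prior))
    top_prior <- list(mean = function(t) rep(0, top$dim_v), log_prec = 4)
  structure(list(levels = levels, streams = streams, top_prior = top_prior,
                 lesion_sites = lesion_sites),
            class = "af_model")
}

#' @export
print.af_model <- function(x, ...) {
  cat("Hierarchical dynamic generative model (", length(x$levels),
      " level", if (length(x$levels) > 1) "s", ")\n", sep = "")
  for (i in seq_along(x$levels)) {
    l <- x$levels[[i]]
    cat(sprintf("  level %d: dim_x = %d, dim_v = %d, state log-prec: %s\n",
                i, l$dim_x, l$dim_v,
                paste(sprintf("%s = %g", names(l$log_prec_state),
                              l$log_prec_state), collapse = ", ")))
  }
  cat("  sensory streams:",
      paste(sprintf("%s (%d @ log-prec %g)", names(x$streams),
                    vapply(x$streams, function(s) length(s$idx), 1L),
                    vapply(x$streams, function(s) s$log_prec, 1)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Validate a hierarchical model
#'
#' Checks dimension chaining (the observation output of level i matches the
#' cause dimension of level i - 1; the level-1 output matches the sensory
#' stream partition), finiteness of flows and observations at the zero
#' state, and that the stream partition covers the sensory vector exactly
#' once. Returns diagnostics; never throws on model content.
#'
#' @param model An `af_model`.
#' @return `list(ok = logical, messages = character)`.
#' @export
validate_model <- function(model) {
  msg <- character()
  L <- length(model$levels)
  for (i in seq_len(L)) {
    lev <- model$levels[[i]]
    x0 <- rep(0, lev$dim_x)
    v0 <- rep(0, lev$dim_v)
    f0 <- tryCatch(lev$flow(x0, v0, lev$params), error = function(e) e)
    g0 <- tryCatch(lev$obs(x0, v0, lev$params), error = function(e) e)
    if (inherits(f0, "error") || any(!is.finite(f0)))
      msg <- c(msg, sprintf("level %d flow is not finite at the zero state", i))
    else if (length(f0) != lev$dim_x)
      msg <- c(msg, sprintf("level %d flow output length %d != dim_x %d",
                            i, length(f0), lev$dim_x))
    if (inherits(g0, "error") || any(!is.finite(g0))) {
      msg <- c(msg, sprintf("level %d observation is not finite at the zero state", i))
      g0 <- NULL
    }
    if (!is.null(g0)) {
      expected <- if (i == 1L) {
        sum(vapply(model$streams, function(s) length(s$idx), 1L))
      } else {
        model$levels[[i - 1L]]$dim_v
      }
      if (length(g0) != expected)
        msg <- c(msg, sprintf(
          "level %d observation dimension %d does not match %s (%d)",
          i, length(g0),
          if (i == 1L) "the sensory stream partition" else
            sprintf("dim_v of level %d", i - 1L),
          expected))
    }
    parts <- sort(unlist(lev$state_partitions, use.names = FALSE))
    if (lev$dim_x > 0 && !identical(as.integer(parts), seq_len(lev$dim_x)))
      msg <- c(msg, sprintf("level %d state partitions do not tile 1:%d",
                            i, lev$dim_x))
  }
  idx <- sort(unlist(lapply(model$streams, `[[`, "idx"), use.names = FALSE))
  g1 <- tryCatch(model$levels[[1]]$obs(rep(0, model$levels[[1]]$dim_x),
                                       rep(0, model$levels[[1]]$dim_v),
                                       model$levels[[1]]$params),
                 error = function(e) NULL)
  if (!is.null(g1) && !identical(as.integer(idx), seq_along(g1)))
    msg <- c(msg, "sensory streams do not partition the level-1 observation")
  list(ok = length(msg) == 0L, messages = msg)
}

#' Lesion configuration
#'
#' @param site One of the model's lesion sites (for the reaching model:
#'   `salience_sensory`, `proprio_sensory`, `visual_sensory`, `arm_state`,
#'   `affordance_state`, `context_level`).
#' @param log_precision Log precision replacing the nominal value at the site.
#' @return An object of class `af_lesion`.
#' @export
lesion <- function(site, log_precision) {
  structure(list(site = site, log_precision = log_precision),
            class = "af_lesion")
}

#' Apply precision lesions to a model
#'
#' Returns a copy of the model in which the log precision of each lesioned
#' error stream is replaced; dimensions, flows and observation functions are
#' untouched. Applying the same lesion twice is idempotent.
#'
#' @param model An `af_model` with a `lesion_sites` map.
#' @param lesions A single [lesion()], a list of them, or a named numeric
#'   vector / list `c(site = log_precision, ...)`. An empty list leaves the
#'   model unchanged.
#' @return The lesioned `af_model`.
#' @export
apply_lesion <- function(model, lesions) {
  if (is.null(lesions) || length(lesions) == 0L) return(model)
  if (inherits(lesions, "af_lesion")) lesions <- list(lesions)
  if ((is.numeric(lesions) || is.list(lesions)) && !is.null(names(lesions)) &&
      !inherits(lesions[[1]], "af_lesion") && all(nzchar(names(lesions)))) {
    lesions <- Map(lesion, names(lesions), as.numeric(lesions))
  }
  for (ls in lesions) {
    site <- ls$site
    map <- model$lesion_sites[[site]]
    if (is.null(map))
      stop(sprintf("unknown lesion site '%s' (known: %s)", site,
                   paste(names(model$lesion_sites), collapse = ", ")))
    for (tgt in map) {
      if (tgt$where == "stream") {
        model$streams[[tgt$name]]$log_prec <- ls$log_precision
      } else if (tgt$where == "state") {
        model$levels[[tgt$level]]$log_prec_state[tgt$name] <- ls$log_precision
      } else if (tgt$where == "cause") {
        model$levels[[tgt$level]]$log_prec_cause <- ls$log_precision
      }
    }
  }
  model
}

#' Lesion sweep from nominal to half-nominal precision
#'
#' Returns lesion configurations with log precision linearly spaced from the
#' nominal value down to 50% of nominal, emulating graded dopamine depletion.
#'
#' @param site Lesion site name.
#' @param n_levels Number of depletion levels (>= 2).
#' @param nominal Nominal log precision (default 4).
#' @return A list of [lesion()] objects, highest precision first.
#' @export
lesion_sweep <- function(site, n_levels, nominal = 4) {
  if (n_levels < 2) stop("`n_levels` must be >= 2")
  lp <- seq(nominal, nominal / 2, length.out = as.integer(n_levels))
  lapply(lp, function(l) lesion(site, l))
}
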