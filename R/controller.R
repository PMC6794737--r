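# Two-phase optimization controller: GSD screening (which also fixes
# categorical factors), then iterative CCF response-surface refinement with
# Q2-gated model prediction, design-space movement/shrinkage/clamping and
# explicit convergence rules, with restart from the next-best screening
# point when the best run never reaches acceptable response values.

#' Assemble an optimization problem
#'
#' @param factors A [factor_space()] (or list of [doe_factor()]s).
#' @param responses A [response_spec()] or list of them.  With more than one
#'   response every spec needs limits and a target (desirability mode).
#' @param reduction GSD reduction factor; default: number of factors
#'   (minimum 2).
#' @param levels Optional override of screening levels for all numeric
#'   factors.
#' @param shrinkage Multiplicative span contraction per iteration, in
#'   `(0, 1]`; default 0.9.
#' @param step_fraction Movement step as a fraction of the span; default
#'   0.25.
#' @param q2_threshold Minimum Q2 for using a model's predicted optimum;
#'   default 0.5.
#' @param model_selection `"auto"` (best subset up to 4 active factors,
#'   greedy above), `"best_subset"` or `"greedy"`.
#' @param complementary_index Which complementary GSD to screen with
#'   (default 0).
#' @param max_iterations Safety cap on optimization iterations; default 25.
#' @param restarts Maximum restarts from next-best screening points when
#'   the best run is still outside acceptable limits; default 3.
#' @param n_grid Grid resolution per factor for the model-optimum search;
#'   default 51.
#' @return An object of class `doe_problem`.
#' @export
doe_problem <- function(factors, responses, reduction = NULL, levels = NULL,
                        shrinkage = 0.9, step_fraction = 0.25,
                        q2_threshold = 0.5, model_selection = "auto",
                        complementary_index = 0L, max_iterations = 25L,
                        restarts = 3L, n_grid = 51L) {
  if (!inherits(factors, "factor_space")) factors <- factor_space(factors)
  responses <- response_set(responses)
  stopifnot(shrinkage > 0, shrinkage <= 1, step_fraction > 0,
            model_selection %in% c("auto", "best_subset", "greedy"))
  if (is.null(reduction)) reduction <- max(2L, length(factors))
  structure(
    list(factors = factors, responses = responses,
         options = list(reduction = as.integer(reduction), levels = levels,
                        shrinkage = shrinkage, step_fraction = step_fraction,
                        q2_threshold = q2_threshold,
                        model_selection = model_selection,
                        complementary_index = as.integer(complementary_index),
                        max_iterations = as.integer(max_iterations),
                        restarts = as.integer(restarts),
                        n_grid = as.integer(n_grid))),
    class = "doe_problem"
  )
}

numeric_factor_names <- function(space)
  names(space)[vapply(space, is_numeric_factor, logical(1L))]

categorical_factor_names <- function(space)
  names(space)[!vapply(space, is_numeric_factor, logical(1L))]

#' Run the GSD screening phase
#'
#' Builds screening levels for every factor (categories for categorical
#' factors), generates the GSD, decodes and executes it, ranks the runs by
#' desirability, and fixes categorical factors at the best run's categories.
#'
#' @param problem A [doe_problem()].
#' @param executor Executor function (see [mock_executor()] /
#'   [pipeline_executor()]).
#' @param run_offset Starting index for run ids.
#' @return List with `runs` (scored, best-first), `best` (top valid row),
#'   `fixed_categoricals`, `levels` and `n_runs`.
#' @export
run_screening <- function(problem, executor, run_offset = 0L) {
  stopifnot(inherits(problem, "doe_problem"))
  space <- problem$factors
  levels <- screening_grid(space, problem$options$levels)
  counts <- vapply(levels, length, integer(1L))
  reduction <- problem$options$reduction
  design <- if (reduction >= 2L && reduction <= prod(counts)) {
    generate_gsd(counts, reduction, problem$options$complementary_index)
  } else {
    generate_full_factorial(counts)
  }
  names(design) <- names(space)
  concrete <- decode_design(design, levels)
  configs <- cbind(
    run_id = sprintf("run%05d", run_offset + seq_len(nrow(concrete))),
    as.data.frame(concrete), stringsAsFactors = FALSE)
  executed <- executor(configs, "screening")
  scored <- rank_runs(executed, problem$responses)
  if (!any(scored$valid))
    stop("screening failure: no valid runs (", nrow(scored),
         " executed, all failed or invalid)", call. = FALSE)
  best <- scored[which(scored$valid)[1L], , drop = FALSE]
  fixed <- lapply(categorical_factor_names(space),
                  function(f) as.character(best[[f]]))
  names(fixed) <- categorical_factor_names(space)
  list(runs = scored, best = best, fixed_categoricals = fixed,
       levels = levels, n_runs = nrow(configs))
}

#' Anchor the first response-surface region on a screening result
#'
#' The best screening configuration becomes the center point; a best value
#' sitting on a factor's global min or max is shifted one screening level
#' inward so the region stays inside the global design space.  The working
#' low/high settings are the midpoints between the center and its
#' neighboring screening levels, and the span is `high - low`.
#'
#' @param best_config Named list/vector of the best screening settings
#'   (numeric factors; values must lie on screening levels).
#' @param levels Named list of per-factor screening level vectors.
#' @param space The [factor_space()] (used for bounds and ordinal handling).
#' @return List with named vectors `center`, `span`, `low`, `high`.
#' @export
initialize_rsm <- function(best_config, levels, space) {
  fnames <- numeric_factor_names(space)
  center <- span <- low <- high <- stats::setNames(numeric(length(fnames)),
                                                   fnames)
  for (nm in fnames) {
    lv <- levels[[nm]]
    if (length(lv) < 3L)
      stop("factor '", nm, "' has fewer than 3 screening levels; the ",
           "midpoint anchoring of the optimization region is undefined",
           call. = FALSE)
    v <- as.numeric(best_config[[nm]])
    idx <- which(abs(lv - v) <= 1e-9 * pmax(1, abs(lv)))
    if (length(idx) != 1L)
      stop("best value ", v, " for factor '", nm,
           "' does not lie on its screening levels", call. = FALSE)
    if (idx == 1L) idx <- 2L
    if (idx == length(lv)) idx <- length(lv) - 1L
    center[nm] <- lv[idx]
    low[nm] <- (lv[idx - 1L] + lv[idx]) / 2
    high[nm] <- (lv[idx] + lv[idx + 1L]) / 2
    span[nm] <- high[nm] - low[nm]
    # keep the symmetric working region [center +/- span/2] inside bounds
    f <- space[[nm]]
    ctr <- center[nm]
    if (ctr - span[nm] / 2 < f$min) ctr <- f$min + span[nm] / 2
    if (ctr + span[nm] / 2 > f$max) ctr <- f$max - span[nm] / 2
    center[nm] <- ctr
  }
  list(center = center, span = span, low = low, high = high)
}

new_state <- function(problem, anchor, fixed_categoricals, run_offset = 0L) {
  space <- problem$factors
  fnames <- numeric_factor_names(space)
  structure(
    list(problem = problem, iteration = 0L,
         center = anchor$center, span = anchor$span,
         frozen = stats::setNames(rep(FALSE, length(fnames)), fnames),
         fixed_categoricals = fixed_categoricals,
         history = list(), best = NULL, prev_best_score = -Inf,
         run_counter = as.integer(run_offset)),
    class = "doe_state"
  )
}

state_region <- function(state) {
  space <- state$problem$factors
  fnames <- names(state$center)
  region <- lapply(fnames, function(nm) {
    f <- space[[nm]]
    c(max(f$min, state$center[[nm]] - state$span[[nm]] / 2),
      min(f$max, state$center[[nm]] + state$span[[nm]] / 2))
  })
  names(region) <- fnames
  region
}

# Complete a data frame of active-factor settings with frozen numeric
# factors (held at center) and fixed categorical factors.
complete_configs <- function(df, state) {
  space <- state$problem$factors
  for (nm in names(state$center)) {
    if (!nm %in% names(df)) {
      v <- state$center[[nm]]
      if (space[[nm]]$kind == "ordinal") v <- round_half_up(v)
      df[[nm]] <- v
    }
  }
  for (nm in names(state$fixed_categoricals))
    df[[nm]] <- state$fixed_categoricals[[nm]]
  df
}

selection_method <- function(problem, n_active) {
  m <- problem$options$model_selection
  if (m == "auto") m <- if (n_active > 4L) "greedy" else "best_subset"
  if (m == "greedy") "greedy_forward" else m
}

#' Execute one optimization iteration
#'
#' Builds a CCF design over the active (non-frozen) numeric factors around
#' the current center/span, executes and scores it, selects an OLS surrogate
#' per response, and — when every model's Q2 exceeds the threshold — executes
#' the model's predicted optimum as one additional validation run.  The
#' iteration's best point is the top-ranked run among the iteration's
#' executed runs (validation included).
#'
#' @param state A `doe_state` (see [new_state] via [optimize_pipeline()]; for
#'   direct use build one with [run_screening()] + [initialize_rsm()]).
#' @param executor Executor function.
#' @return Updated state, with one new `history` entry carrying the scored
#'   runs, the models (or NULL), the iteration best and audit rows.
#' @export
run_iteration <- function(state, executor) {
  stopifnot(inherits(state, "doe_state"))
  problem <- state$problem
  space <- problem$factors
  specs <- problem$responses
  active <- names(state$center)[!state$frozen]
  if (length(active) == 0L)
    stop("no active numeric factors; optimization phase cannot run",
         call. = FALSE)
  it <- state$iteration + 1L
  ccf <- generate_ccf(length(active), factor_names = active)
  context <- lapply(active, function(nm)
    list(center = state$center[[nm]], span = state$span[[nm]],
         ordinal = space[[nm]]$kind == "ordinal"))
  names(context) <- active
  concrete <- as.data.frame(decode_design(ccf, context))
  for (nm in active)  # rounding may nudge past a global bound; clamp
    concrete[[nm]] <- pmin(pmax(concrete[[nm]], space[[nm]]$min),
                           space[[nm]]$max)
  concrete <- unique(complete_configs(concrete, state))
  configs <- cbind(
    run_id = sprintf("run%05d", state$run_counter + seq_len(nrow(concrete))),
    concrete, stringsAsFactors = FALSE)
  state$run_counter <- state$run_counter + nrow(concrete)
  executed <- executor(configs, paste0("iteration-", it))
  n_bad <- sum(executed$status != "ok")
  if (n_bad > nrow(executed) / 2)
    stop("iteration ", it, " error: ", n_bad, " of ", nrow(executed),
         " runs failed", call. = FALSE)
  scored <- rank_runs(executed, specs)
  scored$phase <- paste0("iteration-", it)

  ok <- scored[scored$valid, , drop = FALSE]
  models <- NULL
  gate <- FALSE
  method <- selection_method(problem, length(active))
  candidates <- candidate_terms(active)
  fit_design <- ok[, active, drop = FALSE]
  models <- tryCatch({
    ms <- lapply(specs, function(sp)
      select_model(fit_design, ok[[sp$name]], method = method,
                   candidates = candidates))
    names(ms) <- names(specs)
    ms
  }, error = function(e) NULL)
  if (!is.null(models)) {
    q2s <- vapply(models, `[[`, numeric(1L), "q2")
    gate <- all(q2s > problem$options$q2_threshold)
  }

  validation <- NULL
  if (gate) {
    region <- state_region(state)[active]
    ordinal <- stats::setNames(
      vapply(active, function(nm) space[[nm]]$kind == "ordinal",
             logical(1L)), active)
    opt <- if (length(specs) > 1L) {
      predict_optimum(models, region, ordinal = ordinal, specs = specs,
                      n_grid = problem$options$n_grid)
    } else {
      sp <- specs[[1L]]
      predict_optimum(models[[1L]], region, ordinal = ordinal,
                      goal = sp$criterion, target = sp$target,
                      n_grid = problem$options$n_grid)
    }
    vconf <- complete_configs(as.data.frame(opt$configuration), state)
    vconf <- cbind(run_id = sprintf("run%05d", state$run_counter + 1L),
                   vconf, stringsAsFactors = FALSE)
    state$run_counter <- state$run_counter + 1L
    vexec <- executor(vconf, "validation")
    vscored <- rank_runs(vexec, specs)
    vscored$phase <- paste0("validation-", it)
    validation <- vscored
    scored <- rank_runs(rbind(executed, vexec[, names(executed)]), specs)
    scored$phase <- ifelse(scored$run_id %in% vconf$run_id,
                           paste0("validation-", it),
                           paste0("iteration-", it))
  }

  it_best <- scored[which(scored$valid)[1L], , drop = FALSE]
  state$iteration <- it
  entry <- list(iteration = it, runs = scored, models = models,
                gate = gate, validation = validation,
                best = it_best, best_score = it_best$.score,
                moved = NA)
  state$history[[it]] <- entry
  if (is.null(state$best) || it_best$.score > state$best$.score)
    state$best <- it_best
  state
}

#' Move, shrink and clamp the design space
#'
#' For each active factor: when the iteration's best point lies more than
#' `step_fraction * span` from the center, the center moves toward it by one
#' step (`step_fraction * span`).  Every span then contracts by the
#' shrinkage factor.  A region pushed past a global bound is translated back
#' inside keeping its (post-shrinkage) span.  A span that falls below the
#' minimum resolution (1 for ordinals, `1e-9` of the global range otherwise)
#' freezes the factor at its center with a warning.
#'
#' @param state A `doe_state`.
#' @param best_point Named list/one-row data frame of the iteration's best
#'   configuration.
#' @return List `(state, moved)`, with `moved` TRUE when any factor's center
#'   moved.
#' @export
update_design_space <- function(state, best_point) {
  stopifnot(inherits(state, "doe_state"))
  problem <- state$problem
  space <- problem$factors
  shrink <- problem$options$shrinkage
  stepf <- problem$options$step_fraction
  moved <- FALSE
  for (nm in names(state$center)) {
    if (state$frozen[[nm]]) next
    f <- space[[nm]]
    ctr <- state$center[[nm]]
    spn <- state$span[[nm]]
    delta <- as.numeric(best_point[[nm]]) - ctr
    step <- stepf * spn
    if (abs(delta) > step) {
      ctr <- ctr + sign(delta) * step
      moved <- TRUE
    }
    spn <- spn * shrink
    # translate region inside the global bounds, keeping the span
    if (ctr - spn / 2 < f$min) ctr <- f$min + spn / 2
    if (ctr + spn / 2 > f$max) ctr <- f$max - spn / 2
    min_span <- if (f$kind == "ordinal") 1 else 1e-9 * (f$max - f$min)
    if (spn < min_span) {
      warning("factor '", nm, "' frozen: span ", signif(spn, 4),
              " fell below the minimum resolution", call. = FALSE)
      state$frozen[[nm]] <- TRUE
    }
    state$center[[nm]] <- ctr
    state$span[[nm]] <- spn
  }
  if (state$iteration >= 1L && length(state$history) >= state$iteration)
    state$history[[state$iteration]]$moved <- moved
  list(state = state, moved = moved)
}

#' Convergence check
#'
#' The optimization phase halts when (a) no factor moved in the last
#' iteration, (b) the last iteration's best did not improve on the previous
#' iteration's best (the screening best, for iteration 1), or (c) the
#' iteration cap is reached.
#'
#' @param state A `doe_state` with at least one completed iteration (whose
#'   `moved` flag has been set by [update_design_space()]).
#' @return List `(halt, reason)`; `reason` is `NA` while still running.
#' @export
check_convergence <- function(state) {
  stopifnot(inherits(state, "doe_state"), state$iteration >= 1L)
  entry <- state$history[[state$iteration]]
  prev <- if (state$iteration >= 2L)
    state$history[[state$iteration - 1L]]$best_score
  else state$prev_best_score
  if (isFALSE(entry$moved))
    return(list(halt = TRUE, reason = "design unmoved"))
  if (is.finite(prev) && entry$best_score <= prev)
    return(list(halt = TRUE, reason = "no improvement"))
  if (state$iteration >= state$problem$options$max_iterations)
    return(list(halt = TRUE, reason = "iteration cap reached"))
  if (all(state$frozen))
    return(list(halt = TRUE, reason = "all factors frozen"))
  list(halt = FALSE, reason = NA_character_)
}

audit_columns <- function(scored, phase) {
  df <- scored
  if (!"phase" %in% names(df)) df$phase <- phase
  df
}

best_is_acceptable <- function(best_row, specs) {
  ramps <- names(specs)[vapply(specs, `[[`, logical(1L), "has_ramp")]
  if (length(ramps) == 0L) return(TRUE)
  all(vapply(ramps, function(nm) {
    d <- best_row[[paste0("d_", nm)]]
    is.finite(d) && d > 0
  }, logical(1L)))
}

#' Run the full two-phase optimization
#'
#' Screens with a GSD, fixes categorical factors, then iterates CCF-based
#' response-surface optimization until convergence.  If at the halt the best
#' run still has a response outside its acceptable limits (desirability 0)
#' and restart attempts remain, the optimization phase restarts from the
#' next-best distinct screening configuration.  The reported optimum is the
#' best configuration over every executed run.
#'
#' @param problem A [doe_problem()].
#' @param executor Executor function mapping a configuration data frame to
#'   responses (see [mock_executor()], [pipeline_executor()]).
#' @param seed Integer seed (the controller itself is deterministic; the
#'   seed is applied for any stochastic executor/model components).
#' @return An object of class `doe_report`: list with `best_configuration`,
#'   `best_responses`, `best_overall`, `total_runs`, `iterations`,
#'   `halt_reason`, `restarts_used`, `screening` and `audit` (one row per
#'   executed run).
#' @export
optimize_pipeline <- function(problem, executor, seed = 1L) {
  stopifnot(inherits(problem, "doe_problem"))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  specs <- problem$responses
  space <- problem$factors
  scr <- run_screening(problem, executor)
  audit <- list(audit_columns(scr$runs, "screening"))
  n_runs <- scr$n_runs
  fnames <- numeric_factor_names(space)
  global_best <- scr$best
  halt_reason <- "no numeric factors"
  iterations <- 0L
  restarts_used <- 0L

  if (length(fnames) > 0L) {
    valid <- scr$runs[scr$runs$valid, , drop = FALSE]
    cfgs <- valid[, c("run_id", names(space)), drop = FALSE]
    distinct <- !duplicated(cfgs[, fnames, drop = FALSE])
    starts <- cfgs[distinct, , drop = FALSE]
    max_starts <- min(nrow(starts), 1L + problem$options$restarts)
    for (attempt in seq_len(max_starts)) {
      start_row <- starts[attempt, , drop = FALSE]
      fixed <- lapply(categorical_factor_names(space),
                      function(f) as.character(start_row[[f]]))
      names(fixed) <- categorical_factor_names(space)
      anchor <- initialize_rsm(as.list(start_row[, fnames, drop = FALSE]),
                               scr$levels, space)
      state <- new_state(problem, anchor, fixed, run_offset = n_runs)
      state$prev_best_score <- if (attempt == 1L) scr$best$.score
                               else start_row_score(scr$runs, start_row)
      repeat {
        state <- run_iteration(state, executor)
        entry <- state$history[[state$iteration]]
        audit[[length(audit) + 1L]] <- entry$runs
        n_runs <- state$run_counter
        upd <- update_design_space(state, entry$best)
        state <- upd$state
        conv <- check_convergence(state)
        if (conv$halt) { halt_reason <- conv$reason; break }
      }
      iterations <- iterations + state$iteration
      if (!is.null(state$best) &&
          state$best$.score > global_best$.score)
        global_best <- state$best
      if (best_is_acceptable(global_best, specs)) break
      if (attempt < max_starts) restarts_used <- restarts_used + 1L
    }
  }

  audit_df <- do.call(rbind, lapply(audit, function(a) {
    a$phase <- as.character(a$phase); a
  }))
  ord <- order(as.character(audit_df$run_id))
  audit_df <- audit_df[ord, , drop = FALSE]
  rownames(audit_df) <- NULL
  best_conf <- as.list(global_best[, names(space), drop = FALSE])
  best_resp <- as.list(global_best[, names(specs), drop = FALSE])
  structure(
    list(best_configuration = best_conf, best_responses = best_resp,
         best_overall = global_best$overall, best_run_id =
           as.character(global_best$run_id),
         best_score = global_best$.score,
         total_runs = n_runs, iterations = iterations,
         halt_reason = halt_reason, restarts_used = restarts_used,
         screening = scr, audit = audit_df, problem = problem),
    class = "doe_report"
  )
}

start_row_score <- function(scored, start_row) {
  i <- match(as.character(start_row$run_id), as.character(scored$run_id))
  scored$.score[i]
}

#' @export
print.doe_report <- function(x, ...) {
  cat("<doe_report>\n")
  cat("  best run:   ", x$best_run_id, "\n")
  cat("  best configuration:\n")
  for (nm in names(x$best_configuration))
    cat(sprintf("    %-14s %s\n", nm,
                format(x$best_configuration[[nm]])))
  cat("  responses at best:\n")
  for (nm in names(x$best_responses))
    cat(sprintf("    %-14s %s\n", nm, format(x$best_responses[[nm]])))
  if (length(x$problem$responses) > 1L && is.finite(x$best_overall))
    cat(sprintf("  overall desirability: %.4f\n", x$best_overall))
  cat(sprintf("  total runs: %d (%d optimization iterations, %d restarts)\n",
              x$total_runs, x$iterations, x$restarts_used))
  cat("  halt reason:", x$halt_reason, "\n")
  invisible(x)
}

#' Write a report's audit trail and best configuration to disk
#'
#' Writes `audit.csv` (run id, phase, factor/response/desirability columns,
#' overall, status) and `best.json`.
#'
#' @param report A `doe_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "doe_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  audit <- report$audit
  audit$.score <- NULL
  utils::write.csv(audit, file.path(dir, "audit.csv"), row.names = FALSE)
  best <- list(best_run_id = report$best_run_id,
               best_configuration = report$best_configuration,
               best_responses = report$best_responses,
               best_overall = report$best_overall,
               total_runs = report$total_runs,
               iterations = report$iterations,
               halt_reason = report$halt_reason,
               restarts_used = report$restarts_used)
  jsonlite::write_json(best, file.path(dir, "best.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
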