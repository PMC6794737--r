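# YAML-configured pipeline execution: parse the configuration document,
# render per-run batch scripts with factor values substituted into
# {{PLACEHOLDER}} slots, execute runs sequentially or in parallel, and
# collect responses from per-run results files.

# Only literal true/false become booleans; YAML 1.1 extras (y/n, yes/no,
# on/off) stay strings so that factors or responses named "y" survive
# parsing.
doeopt_yaml_handlers <- function() list(
  "bool#yes" = function(x) if (tolower(x) == "true") TRUE else x,
  "bool#no" = function(x) if (tolower(x) == "false") FALSE else x
)

read_yaml_strict <- function(path)
  yaml::read_yaml(path, handlers = doeopt_yaml_handlers())

load_yaml_strict <- function(text)
  yaml::yaml.load(text, handlers = doeopt_yaml_handlers())

placeholder_regex <- function(open = "{{", close = "}}") {
  paste0(gsub("([{}*.?+^$()\\[\\]|\\\\])", "\\\\\\1", open),
         "\\s*([A-Za-z0-9_.-]+)\\s*",
         gsub("([{}*.?+^$()\\[\\]|\\\\])", "\\\\\\1", close))
}

template_placeholders <- function(command, open = "{{", close = "}}") {
  m <- gregexpr(placeholder_regex(open, close), command, perl = TRUE)
  hits <- regmatches(command, m)[[1L]]
  if (!length(hits)) return(character(0))
  unique(gsub(placeholder_regex(open, close), "\\1", hits, perl = TRUE))
}

parse_factor_decl <- function(name, decl) {
  kind <- tolower(decl$type %||% "quantitative")
  if (kind == "categorical") {
    doe_factor(name, "categorical", categories = decl$categories)
  } else {
    doe_factor(name, kind, min = decl$min, max = decl$max,
               n_levels = decl$levels %||% decl$n_levels)
  }
}

parse_response_decl <- function(name, decl) {
  response_spec(name,
                criterion = tolower(decl$criterion %||% "maximize"),
                low_limit = decl$low_limit, high_limit = decl$high_limit,
                target = decl$target)
}

# Accept steps either as an ordered map (name: command) or as a list of
# {name:, command:} entries.
parse_steps <- function(steps) {
  if (is.null(steps) || length(steps) == 0L)
    stop("pipeline must declare at least one step", call. = FALSE)
  if (!is.null(names(steps)) && all(nzchar(names(steps))) &&
      all(vapply(steps, is.character, logical(1L)))) {
    return(mapply(function(nm, cmd) list(name = nm, command = cmd),
                  names(steps), steps, SIMPLIFY = FALSE, USE.NAMES = FALSE))
  }
  lapply(steps, function(s) {
    if (is.null(s$name) || is.null(s$command))
      stop("each pipeline step needs 'name' and 'command'", call. = FALSE)
    list(name = s$name, command = s$command)
  })
}

#' Load and validate a pipeline optimization configuration
#'
#' The YAML document has top-level sections `design` (factors, responses and
#' optimizer options), `pipeline` (ordered command templates) and optional
#' `execution` (mode, working directory, results-file name, scheduler
#' options).  Every `{{NAME}}` placeholder in a command must name a declared
#' factor; with more than one response each response needs limits and a
#' target.
#'
#' @param path Path to the YAML document (or a YAML string containing a
#'   newline).
#' @return An object of class `pipeline_config`: list with `problem`
#'   (a [doe_problem()]), `steps`, `execution`.
#' @export
load_config <- function(path) {
  doc <- tryCatch(
    if (grepl("\n", path, fixed = TRUE)) load_yaml_strict(path)
    else read_yaml_strict(path),
    error = function(e) stop("malformed configuration document: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(doc$design))
    stop("configuration needs a 'design' section", call. = FALSE)
  d <- doc$design
  if (is.null(d$factors) || length(d$factors) == 0L)
    stop("design must declare at least one factor", call. = FALSE)
  factors <- factor_space(mapply(parse_factor_decl, names(d$factors),
                                 d$factors, SIMPLIFY = FALSE,
                                 USE.NAMES = FALSE))
  if (is.null(d$responses) || length(d$responses) == 0L)
    stop("design must declare at least one response", call. = FALSE)
  responses <- mapply(parse_response_decl, names(d$responses), d$responses,
                      SIMPLIFY = FALSE, USE.NAMES = FALSE)
  model_selection <- d$model_selection %||% "auto"
  if (identical(model_selection, "greedy_forward")) model_selection <- "greedy"
  problem <- doe_problem(
    factors, responses,
    reduction = d$reduction_factor,
    levels = d$levels,
    shrinkage = d$shrinkage %||% 0.9,
    step_fraction = d$step_fraction %||% 0.25,
    q2_threshold = d$q2_threshold %||% 0.5,
    model_selection = model_selection)
  opt_design <- tolower(d$optimization_design %||% "ccf")
  if (opt_design != "ccf")
    stop("unsupported optimization design '", opt_design,
         "'; only 'ccf' is implemented", call. = FALSE)
  steps <- parse_steps(doc$pipeline$steps %||% doc$pipeline)
  for (s in steps) {
    ph <- template_placeholders(s$command)
    unknown <- setdiff(ph, names(factors))
    if (length(unknown))
      stop("step '", s$name, "' references undeclared factor(s): ",
           paste(sprintf("{{%s}}", unknown), collapse = ", "), call. = FALSE)
  }
  ex <- doc$execution %||% list()
  execution <- list(
    mode = match.arg(tolower(ex$mode %||% "sequential"),
                     c("sequential", "parallel")),
    workdir = ex$workdir %||% "doeopt_work",
    results_file = ex$results_file %||% "results.txt",
    scheduler = ex$scheduler)
  structure(list(problem = problem, steps = steps, execution = execution),
            class = "pipeline_config")
}

#' Serialize a pipeline configuration back to YAML
#'
#' Inverse of [load_config()] (up to default filling): round-trips all
#' factor, response, option, step and execution fields.
#'
#' @param config A `pipeline_config`.
#' @param path Optional output file; when NULL the YAML text is returned.
#' @return YAML text (invisibly when written to a file).
#' @export
serialize_config <- function(config, path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  pr <- config$problem
  factors <- lapply(pr$factors, function(f) {
    if (f$kind == "categorical")
      list(type = "categorical", categories = as.list(f$categories))
    else list(type = f$kind, min = f$min, max = f$max, levels = f$n_levels)
  })
  responses <- lapply(pr$responses, function(sp) {
    out <- list(criterion = sp$criterion)
    if (!is.null(sp$low_limit)) out$low_limit <- sp$low_limit
    if (!is.null(sp$high_limit)) out$high_limit <- sp$high_limit
    if (!is.null(sp$target)) out$target <- sp$target
    out
  })
  doc <- list(
    design = c(list(factors = factors, responses = responses),
               list(reduction_factor = pr$options$reduction,
                    optimization_design = "ccf",
                    shrinkage = pr$options$shrinkage,
                    step_fraction = pr$options$step_fraction,
                    model_selection = pr$options$model_selection,
                    q2_threshold = pr$options$q2_threshold)),
    pipeline = list(steps = lapply(config$steps, function(s)
      list(name = s$name, command = s$command))),
    execution = Filter(Negate(is.null), config$execution))
  txt <- yaml::as.yaml(doc)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

format_setting <- function(value, factor) {
  if (factor$kind == "categorical") return(as.character(value))
  if (factor$kind == "ordinal")
    return(format(as.integer(round_half_up(as.numeric(value))),
                  scientific = FALSE))
  format(as.numeric(value), digits = 15, scientific = FALSE)
}

#' Render one run's batch scripts (without executing them)
#'
#' Creates `<workdir>/<phase>/<run_id>/step_<i>_<name>.sh`, one script per
#' pipeline step, with every `{{FACTOR}}` placeholder substituted (ordinals
#' as integers, quantitative values at full precision, categories verbatim)
#' and any scheduler options emitted as `#SBATCH` header lines.
#'
#' @param config A `pipeline_config`.
#' @param run_id Run identifier.
#' @param configuration Named list of factor settings (must cover every
#'   declared factor).
#' @param phase Phase label used in the directory layout.
#' @return A run record: list with `run_id`, `phase`, `configuration`,
#'   `scripts` (paths), `workdir`, `status = "rendered"`.
#' @export
render_run <- function(config, run_id, configuration, phase = "screening") {
  stopifnot(inherits(config, "pipeline_config"))
  factors <- config$problem$factors
  missing <- setdiff(names(factors), names(configuration))
  if (length(missing))
    stop("configuration for run ", run_id, " missing factor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  run_dir <- file.path(config$execution$workdir, phase, run_id)
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  header <- c("#!/bin/bash")
  sched <- config$execution$scheduler
  if (!is.null(sched) && length(sched))
    header <- c(header,
                sprintf("#SBATCH --%s=%s", names(sched),
                        vapply(sched, as.character, character(1L))))
  scripts <- character(length(config$steps))
  for (i in seq_along(config$steps)) {
    s <- config$steps[[i]]
    cmd <- s$command
    for (nm in names(factors)) {
      nm_re <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", nm)
      cmd <- gsub(paste0("\\{\\{\\s*", nm_re, "\\s*\\}\\}"),
                  format_setting(configuration[[nm]], factors[[nm]]),
                  cmd, perl = TRUE)
    }
    left <- template_placeholders(cmd)
    if (length(left))
      stop("unsubstitutable placeholder(s) in step '", s$name, "': ",
           paste(left, collapse = ", "), call. = FALSE)
    path <- file.path(run_dir, sprintf("step_%02d_%s.sh", i, s$name))
    writeLines(c(header, "set -e", cmd), path)
    Sys.chmod(path, "0755")
    scripts[i] <- path
  }
  list(run_id = run_id, phase = phase, configuration = configuration,
       scripts = scripts, workdir = run_dir, status = "rendered")
}

parse_results_file <- function(path, response_names) {
  if (!file.exists(path)) return(NULL)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(NULL)
  out <- list()
  if (length(response_names) == 1L && !any(grepl(":", lines, fixed = TRUE))) {
    v <- suppressWarnings(as.numeric(lines[[1L]]))
    if (is.na(v)) return(NULL)
    out[[response_names[1L]]] <- v
    return(out)
  }
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1L]]
    if (length(kv) < 2L) next
    v <- suppressWarnings(as.numeric(trimws(paste(kv[-1L], collapse = ":"))))
    out[[trimws(kv[1L])]] <- v
  }
  missing <- setdiff(response_names, names(out))
  if (length(missing)) return(NULL)
  if (any(vapply(response_names, function(nm)
    is.na(out[[nm]]), logical(1L)))) return(NULL)
  out[response_names]
}

execute_one_run <- function(rec, config) {
  response_names <- names(config$problem$responses)
  # children run inside the run's working directory and inherit this
  # session's library paths so that steps invoking Rscript can load the
  # same packages
  libs <- paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))
  for (script in rec$scripts) {
    log <- paste0(script, ".log")
    cmd <- sprintf("cd %s && exec bash %s",
                   shQuote(rec$workdir), shQuote(basename(script)))
    status <- suppressWarnings(
      system2("bash", c("-c", shQuote(cmd)), stdout = log, stderr = log,
              env = libs))
    if (!identical(status, 0L) && !identical(status, 0)) {
      rec$status <- "failed"
      rec$responses <- NULL
      return(rec)
    }
  }
  res <- parse_results_file(file.path(rec$workdir,
                                      config$execution$results_file),
                            response_names)
  if (is.null(res)) {
    rec$status <- "invalid"
    rec$diagnostic <- paste0("missing or unparsable results file '",
                             config$execution$results_file, "'")
  } else {
    rec$status <- "ok"
    rec$responses <- res
  }
  rec
}

#' Render, execute and collect a batch of runs
#'
#' Each run's steps execute in order inside its working directory; a nonzero
#' exit marks the run `failed` and skips its remaining steps.  On success
#' the run's results file is parsed (`name: value` lines, or one bare number
#' in single-response mode).  Parallel mode executes whole runs concurrently
#' with `parallel::mclapply`; for deterministic pipelines both modes produce
#' identical records.
#'
#' @param config A `pipeline_config`.
#' @param configs Data frame with `run_id` and one column per factor.
#' @param phase Phase label.
#' @param mode `"sequential"` or `"parallel"` (default: the config's mode).
#' @return `configs` augmented with response columns and `status`.
#' @export
execute_and_collect <- function(config, configs, phase = "screening",
                                mode = NULL) {
  stopifnot(inherits(config, "pipeline_config"),
            is.data.frame(configs), "run_id" %in% names(configs))
  mode <- mode %||% config$execution$mode
  fnames <- names(config$problem$factors)
  recs <- lapply(seq_len(nrow(configs)), function(i)
    render_run(config, configs$run_id[i],
               as.list(configs[i, fnames, drop = FALSE]), phase))
  runner <- function(rec) execute_one_run(rec, config)
  done <- if (identical(mode, "parallel")) {
    parallel::mclapply(recs, runner,
                       mc.cores = max(1L, parallel::detectCores() - 1L))
  } else {
    lapply(recs, runner)
  }
  response_names <- names(config$problem$responses)
  for (rn in response_names) configs[[rn]] <- NA_real_
  configs$status <- vapply(done, `[[`, character(1L), "status")
  for (i in seq_along(done)) {
    if (identical(done[[i]]$status, "ok"))
      for (rn in response_names)
        configs[[rn]][i] <- done[[i]]$responses[[rn]]
  }
  configs
}

#' Executor backed by a real pipeline configuration
#'
#' Adapts [execute_and_collect()] to the executor interface used by
#' [optimize_pipeline()] and [grid_search()].
#'
#' @param config A `pipeline_config` from [load_config()].
#' @param mode Optional execution-mode override.
#' @return An executor function `(configs, phase) -> configs + responses`.
#' @export
pipeline_executor <- function(config, mode = NULL) {
  force(config); force(mode)
  function(configs, phase = "screening")
    execute_and_collect(config, configs, phase = phase, mode = mode)
}

#' Percent improvement of an optimized response over the default
#'
#' Maximize: `(optimized - default) / default * 100`; minimize:
#' `(default - optimized) / default * 100`.  Rounded half-up to one decimal,
#' matching the usual reporting style.
#'
#' @param default_value Response under default settings (nonzero).
#' @param optimized_value Response under optimized settings.
#' @param criterion `"maximize"` or `"minimize"`.
#' @return Percentage, one decimal.
#' @examples
#' percent_improvement(28149, 31847, "maximize")  # 13.1
#' percent_improvement(91, 89, "minimize")        # 2.2
#' @export
percent_improvement <- function(default_value, optimized_value,
                                criterion = c("maximize", "minimize")) {
  criterion <- match.arg(criterion)
  if (default_value == 0)
    stop("percent improvement undefined for a zero default value",
         call. = FALSE)
  pct <- switch(criterion,
    maximize = (optimized_value - default_value) / default_value * 100,
    minimize = (default_value - optimized_value) / default_value * 100)
  round_half_up(pct * 10) / 10
}
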