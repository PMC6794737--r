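# Seeded mock objectives and a mock pipeline entry point.  These stand in
# for real bioinformatics tools (assemblers, classifiers, variant callers)
# so the whole optimizer can be exercised end-to-end, with known optima,
# in milliseconds.

#' Seeded mock objective function
#'
#' A (by default concave quadratic) surface over the numeric factors with an
#' additive offset per category of any categorical factor and optional
#' deterministic Gaussian noise:
#'
#' `y = y0 - sum_f c_f (x_f - opt_f)^2 + sum_{f<g} w_fg (x_f - opt_f)(x_g - opt_g)
#'      + offset(category) + noise`
#'
#' Noise is seeded per configuration (hash of seed and settings), so
#' re-evaluating the same configuration — sequentially or in parallel —
#' always yields the same value.  Multi-response objectives emit additional
#' responses as affinely transformed copies of the surface with per-response
#' shifted optima, so that response goals genuinely conflict.
#'
#' @param optima Named numeric vector: location of the maximum per numeric
#'   factor.
#' @param curvatures Named numeric vector of positive quadratic penalties
#'   (recycled from a scalar; default 1).
#' @param interactions Named numeric vector of interaction weights, names
#'   `"f:g"`.  Keep `|w_fg| < 2*sqrt(c_f*c_g)` so the surface stays concave.
#' @param categorical_offsets Named list: for each categorical factor, a
#'   named numeric vector of per-category additive offsets.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed for the noise stream.
#' @param y0 Value at the optimum (default 0).
#' @param responses Named list describing emitted responses; each element is
#'   `list(shift = <named numeric or 0>, scale = 1, offset = 0)`.  Default:
#'   a single response `"y"` equal to the surface.
#' @return An object of class `mock_objective`.
#' @export
mock_objective <- function(optima, curvatures = 1, interactions = NULL,
                           categorical_offsets = NULL, noise_sd = 0,
                           seed = 1L, y0 = 0,
                           responses = list(y = list())) {
  stopifnot(is.numeric(optima))
  if (length(optima) && is.null(names(optima)))
    stop("optima must be a named vector", call. = FALSE)
  if (length(curvatures) == 1L)
    curvatures <- stats::setNames(rep(curvatures, length(optima)),
                                  names(optima))
  stopifnot(all(curvatures > 0), noise_sd >= 0)
  structure(
    list(optima = optima, curvatures = curvatures,
         interactions = interactions,
         categorical_offsets = categorical_offsets,
         noise_sd = noise_sd, seed = as.integer(seed), y0 = y0,
         responses = responses),
    class = "mock_objective"
  )
}

# Deterministic 31-bit hash of a configuration + seed for per-run noise.
config_hash <- function(seed, configuration) {
  key <- paste(names(configuration),
               vapply(configuration, function(v) format(v, digits = 15),
                      character(1L)),
               collapse = ";")
  h <- as.integer(seed) %% 2147483647L
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647L
  as.integer(h)
}

#' Evaluate a mock objective at one configuration
#'
#' @param objective A [mock_objective()].
#' @param configuration Named list of factor settings covering every factor
#'   the objective declares.
#' @return Named numeric vector, one element per declared response.
#' @export
evaluate <- function(objective, configuration) {
  stopifnot(inherits(objective, "mock_objective"))
  numeric_names <- names(objective$optima)
  missing <- setdiff(numeric_names, names(configuration))
  if (length(missing))
    stop("configuration missing factors: ",
         paste(missing, collapse = ", "), call. = FALSE)
  base_surface <- function(opt) {
    x <- vapply(numeric_names, function(nm)
      as.numeric(configuration[[nm]]), numeric(1L))
    d <- x - opt[numeric_names]
    y <- objective$y0 - sum(objective$curvatures[numeric_names] * d^2)
    if (!is.null(objective$interactions)) {
      for (nm in names(objective$interactions)) {
        fs <- strsplit(nm, ":", fixed = TRUE)[[1L]]
        y <- y + objective$interactions[[nm]] * d[[fs[1L]]] * d[[fs[2L]]]
      }
    }
    y
  }
  cat_offset <- 0
  if (!is.null(objective$categorical_offsets)) {
    for (f in names(objective$categorical_offsets)) {
      if (!f %in% names(configuration))
        stop("configuration missing factors: ", f, call. = FALSE)
      lvl <- as.character(configuration[[f]])
      offs <- objective$categorical_offsets[[f]]
      if (!lvl %in% names(offs))
        stop("unknown category '", lvl, "' for factor '", f, "'",
             call. = FALSE)
      cat_offset <- cat_offset + offs[[lvl]]
    }
  }
  noise <- 0
  if (objective$noise_sd > 0) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    set.seed(config_hash(objective$seed, configuration))
    noise <- stats::rnorm(1L, sd = objective$noise_sd)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  out <- vapply(names(objective$responses), function(rn) {
    rdef <- objective$responses[[rn]]
    opt <- objective$optima
    if (!is.null(rdef$shift)) {
      sh <- rdef$shift
      opt[names(sh)] <- opt[names(sh)] + sh
    }
    scale <- rdef$scale %||% 1
    offset <- rdef$offset %||% 0
    scale * (base_surface(opt) + cat_offset + noise) + offset
  }, numeric(1L))
  out
}

#' Executor backed by a mock objective
#'
#' Wraps a [mock_objective()] into the executor interface the optimizer
#' expects: a function taking a data frame of configurations (`run_id` plus
#' one column per factor) and returning it augmented with response columns
#' and a `status` column.
#'
#' @param objective A [mock_objective()].
#' @param fail_when Optional predicate `function(configuration)`; runs for
#'   which it returns TRUE get status `"failed"` (error-path testing).
#' @return An executor function.
#' @export
mock_executor <- function(objective, fail_when = NULL) {
  force(objective)
  function(configs, phase = "screening") {
    stopifnot(is.data.frame(configs), "run_id" %in% names(configs))
    fcols <- setdiff(names(configs), "run_id")
    rnames <- names(objective$responses)
    for (rn in rnames) configs[[rn]] <- NA_real_
    configs$status <- "ok"
    for (i in seq_len(nrow(configs))) {
      cfg <- as.list(configs[i, fcols, drop = FALSE])
      if (!is.null(fail_when) && isTRUE(fail_when(cfg))) {
        configs$status[i] <- "failed"
        next
      }
      vals <- evaluate(objective, cfg)
      for (rn in rnames) configs[[rn]][i] <- vals[[rn]]
    }
    configs
  }
}

#' F1 score (harmonic mean of precision and recall)
#'
#' @param precision,recall Numbers in `[0, 1]`.
#' @return `2 * precision * recall / (precision + recall)`; 0 (with a
#'   warning) when both inputs are 0.
#' @examples
#' f1_score(0.2, 0.8)  # 0.32
#' @export
f1_score <- function(precision, recall) {
  stopifnot(length(precision) == 1L, length(recall) == 1L,
            is.finite(precision), is.finite(recall),
            precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision == 0 && recall == 0) {
    warning("precision and recall both zero; F1 defined as 0", call. = FALSE)
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' Exhaustive grid-search baseline
#'
#' Executes the full factorial over the screening levels — the same
#' resolution the GSD screening phase subsamples — and ranks the runs with
#' the same desirability scoring as the optimizer.  This is the brute-force
#' comparator: it is guaranteed to find the best grid point but its run
#' count is the product of the level counts.
#'
#' @param problem A [doe_problem()].
#' @param executor Executor function (e.g. [mock_executor()] or
#'   [pipeline_executor()]).
#' @return List with `best` (top-ranked scored run, one-row data frame),
#'   `runs` (all scored runs) and `n_runs`.
#' @export
grid_search <- function(problem, executor) {
  stopifnot(inherits(problem, "doe_problem"))
  levels <- screening_grid(problem$factors, problem$options$levels)
  counts <- vapply(levels, length, integer(1L))
  design <- generate_full_factorial(counts)
  concrete <- decode_design(design, levels)
  configs <- cbind(run_id = sprintf("grid%05d", seq_len(nrow(concrete))),
                   as.data.frame(concrete), stringsAsFactors = FALSE)
  executed <- executor(configs, "gridsearch")
  scored <- rank_runs(executed, problem$responses)
  list(best = scored[1L, , drop = FALSE], runs = scored,
       n_runs = nrow(configs))
}

#' Mock pipeline command-line entry point
#'
#' Behaves like a user tool inside a pipeline step: reads a mock-objective
#' spec (YAML), evaluates it at the factor values given as `NAME=VALUE`
#' arguments, and writes `name: value` response lines to the output file.
#' `--fail-if EXPR` (an R expression over the factor values) forces a
#' nonzero exit without writing a results file, for error-path tests.
#'
#' Invoke through the installed script:
#' `Rscript $(Rscript -e 'cat(system.file("scripts/mock_pipeline.R", package="doeopt"))') --spec obj.yaml --out results.txt x=3`
#'
#' @param args Character vector of command-line arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return Exit status, invisibly (0 on success); also called for its side
#'   effect of writing the results file.
#' @export
mock_pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec_path <- NULL; out_path <- NULL; fail_if <- NULL
  config <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a == "--spec") { spec_path <- args[[i + 1L]]; i <- i + 2L }
    else if (a == "--out") { out_path <- args[[i + 1L]]; i <- i + 2L }
    else if (a == "--fail-if") { fail_if <- args[[i + 1L]]; i <- i + 2L }
    else if (grepl("=", a, fixed = TRUE)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1L]]
      v <- paste(kv[-1L], collapse = "=")
      num <- suppressWarnings(as.numeric(v))
      config[[kv[1L]]] <- if (is.na(num)) v else num
      i <- i + 1L
    } else {
      message("unknown argument: ", a)
      return(invisible(2L))
    }
  }
  if (is.null(spec_path) || is.null(out_path) || !file.exists(spec_path)) {
    message("usage: mock_pipeline --spec FILE --out FILE [--fail-if EXPR] ",
            "NAME=VALUE ...")
    return(invisible(2L))
  }
  if (!is.null(fail_if)) {
    hit <- tryCatch(
      isTRUE(eval(parse(text = fail_if), envir = list2env(config))),
      error = function(e) TRUE)
    if (hit) return(invisible(1L))
  }
  objective <- read_mock_objective(spec_path)
  vals <- tryCatch(evaluate(objective, config), error = function(e) {
    message(conditionMessage(e)); NULL
  })
  if (is.null(vals)) return(invisible(1L))
  writeLines(sprintf("%s: %.15g", names(vals), vals), out_path)
  invisible(0L)
}

#' Read a mock-objective spec file (YAML)
#'
#' @param path Path to a YAML document with keys `optima`, and optionally
#'   `curvatures`, `interactions`, `categorical_offsets`, `noise_sd`,
#'   `seed`, `y0`, `responses`.
#' @return A [mock_objective()].
#' @export
read_mock_objective <- function(path) {
  doc <- yaml::read_yaml(path, handlers = doeopt_yaml_handlers())
  if (is.null(doc$optima)) stop("mock objective spec needs 'optima'",
                                call. = FALSE)
  as_named_num <- function(x) if (is.null(x)) NULL else unlist(x)
  responses <- doc$responses
  if (is.null(responses)) responses <- list(y = list())
  responses <- lapply(responses, function(r) {
    if (is.null(r)) r <- list()
    if (!is.null(r$shift)) r$shift <- unlist(r$shift)
    r
  })
  mock_objective(
    optima = as_named_num(doc$optima),
    curvatures = as_named_num(doc$curvatures) %||% 1,
    interactions = as_named_num(doc$interactions),
    categorical_offsets = doc$categorical_offsets,
    noise_sd = doc$noise_sd %||% 0,
    seed = doc$seed %||% 1L,
    y0 = doc$y0 %||% 0,
    responses = responses
  )
}

#' Write a mock-objective spec file (YAML)
#'
#' @param objective A [mock_objective()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mock_objective <- function(objective, path) {
  stopifnot(inherits(objective, "mock_objective"))
  doc <- list(optima = as.list(objective$optima),
              curvatures = as.list(objective$curvatures),
              noise_sd = objective$noise_sd,
              seed = objective$seed, y0 = objective$y0,
              responses = lapply(objective$responses, function(r) {
                if (!is.null(r$shift)) r$shift <- as.list(r$shift)
                if (length(r) == 0L) list(scale = 1) else r
              }))
  if (!is.null(objective$interactions))
    doc$interactions <- as.list(objective$interactions)
  if (!is.null(objective$categorical_offsets))
    doc$categorical_offsets <- lapply(objective$categorical_offsets, as.list)
  yaml::write_yaml(doc, path)
  invisible(path)
}
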