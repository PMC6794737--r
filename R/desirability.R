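# Derringer-Suich desirability scoring: rescale each response into [0, 1]
# between an acceptability limit and a target, aggregate responses by the
# geometric mean, and rank runs.

#' Declare a response and its optimization goal
#'
#' A response is one measured pipeline outcome.  Its criterion is
#' `maximize`, `minimize` or `target`.  When several responses are optimized
#' jointly, each needs the limits/target that define its linear desirability
#' ramp: 0 at (or beyond) the failing limit, 1 at (or beyond) the target.
#' In single-response mode limits are optional and runs are compared on the
#' raw value.
#'
#' @param name Response name (unique within a configuration).
#' @param criterion `"maximize"`, `"minimize"` or `"target"`.
#' @param low_limit Worst acceptable value (maximize and target criteria).
#' @param high_limit Worst acceptable value (minimize and target criteria).
#' @param target Value at which desirability saturates at 1.
#' @return An object of class `response_spec`.
#' @examples
#' response_spec("N50", "maximize", low_limit = 28000, target = 35000)
#' @export
response_spec <- function(name,
                          criterion = c("maximize", "minimize", "target"),
                          low_limit = NULL, high_limit = NULL,
                          target = NULL) {
  criterion <- match.arg(criterion)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("response name must be a non-empty string", call. = FALSE)
  has_ramp <- !is.null(target)
  if (has_ramp) {
    if (criterion == "maximize") {
      if (is.null(low_limit) || low_limit >= target)
        stop("maximize response '", name, "' needs low_limit < target",
             call. = FALSE)
    } else if (criterion == "minimize") {
      if (is.null(high_limit) || target >= high_limit)
        stop("minimize response '", name, "' needs target < high_limit",
             call. = FALSE)
    } else {
      if (is.null(low_limit) || is.null(high_limit) ||
          !(low_limit < target && target < high_limit))
        stop("target response '", name,
             "' needs low_limit < target < high_limit", call. = FALSE)
    }
  } else if (criterion == "target") {
    stop("target response '", name, "' needs a target value", call. = FALSE)
  }
  structure(
    list(name = name, criterion = criterion, low_limit = low_limit,
         high_limit = high_limit, target = target, has_ramp = has_ramp),
    class = "response_spec"
  )
}

response_set <- function(specs) {
  if (inherits(specs, "response_spec")) specs <- list(specs)
  nms <- vapply(specs, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("duplicate response names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  if (length(specs) > 1L) {
    no_ramp <- nms[!vapply(specs, `[[`, logical(1L), "has_ramp")]
    if (length(no_ramp))
      stop("multi-response mode requires limits and target for every ",
           "response; missing for: ", paste(no_ramp, collapse = ", "),
           call. = FALSE)
  }
  names(specs) <- nms
  specs
}

#' Desirability of one response value
#'
#' Linear Derringer-Suich ramp: 0 when outside the accepted limit, 1 when at
#' or better than the target, linear in between.  A value exactly on the
#' failing limit scores 0 (conservative).  The target criterion is a
#' piecewise-linear tent with apex 1 at the target.
#'
#' @param value Observed response value.
#' @param spec A [response_spec()] with limits/target set.
#' @return A number in `[0, 1]`.
#' @examples
#' sp <- response_spec("tSeq", "maximize",
#'                     low_limit = 1830000, target = 1894157)
#' desirability_score(1835427, sp)  # 5427 / 64157
#' @export
desirability_score <- function(value, spec) {
  stopifnot(inherits(spec, "response_spec"))
  if (!spec$has_ramp)
    stop("response '", spec$name, "' has no limits/target; desirability is ",
         "undefined in single-response raw mode", call. = FALSE)
  if (length(value) != 1L || !is.finite(value))
    stop("non-finite response value for '", spec$name, "'", call. = FALSE)
  d <- switch(spec$criterion,
    maximize = {
      if (value <= spec$low_limit) 0
      else if (value >= spec$target) 1
      else (value - spec$low_limit) / (spec$target - spec$low_limit)
    },
    minimize = {
      if (value >= spec$high_limit) 0
      else if (value <= spec$target) 1
      else (spec$high_limit - value) / (spec$high_limit - spec$target)
    },
    target = {
      if (value <= spec$low_limit || value >= spec$high_limit) 0
      else if (value <= spec$target)
        (value - spec$low_limit) / (spec$target - spec$low_limit)
      else
        (spec$high_limit - value) / (spec$high_limit - spec$target)
    }
  )
  min(1, max(0, d))
}

#' Overall desirability (geometric mean)
#'
#' @param desirabilities Non-empty numeric vector with values in `[0, 1]`.
#' @return The geometric mean; exactly 0 when any element is 0.
#' @examples
#' overall_desirability(c(0.25, 1))  # 0.5
#' @export
overall_desirability <- function(desirabilities) {
  if (length(desirabilities) == 0L)
    stop("need at least one desirability", call. = FALSE)
  if (any(!is.finite(desirabilities)) ||
      any(desirabilities < 0) || any(desirabilities > 1))
    stop("desirabilities must be finite and within [0, 1]", call. = FALSE)
  if (any(desirabilities == 0)) return(0)
  exp(mean(log(desirabilities)))
}

# Internal comparable score for ranking: larger is better.  Multi-response
# mode ranks on overall desirability; single-response mode on the raw value
# under its criterion.
run_score <- function(raw, overall, specs) {
  if (length(specs) > 1L) return(overall)
  sp <- specs[[1L]]
  v <- raw[[sp$name]]
  switch(sp$criterion,
         maximize = v,
         minimize = -v,
         target = -abs(v - sp$target))
}

#' Score and rank executed runs
#'
#' Computes per-response desirabilities (multi-response mode), the overall
#' desirability, and orders runs best-first.  Single-response mode compares
#' raw values under the declared criterion and skips desirability unless
#' limits were provided.  Runs missing a declared response, or reporting a
#' non-finite value, are marked invalid and sorted last.  Ties break on the
#' lowest run id.
#'
#' @param runs Data frame with a `run_id` column and one column per declared
#'   response.  An optional `status` column ("ok"/"failed"/"invalid") marks
#'   runs that already failed upstream.
#' @param specs List of [response_spec()]s.
#' @return The input rows augmented with `d_<response>` columns (when
#'   desirability applies), `overall`, `.score` and `valid`, sorted
#'   best-first.
#' @export
rank_runs <- function(runs, specs) {
  specs <- response_set(specs)
  stopifnot(is.data.frame(runs), "run_id" %in% names(runs))
  nms <- names(specs)
  multi <- length(specs) > 1L
  with_ramp <- vapply(specs, `[[`, logical(1L), "has_ramp")
  n <- nrow(runs)
  out <- runs
  if (!("status" %in% names(out))) out$status <- "ok"
  for (nm in nms[with_ramp]) out[[paste0("d_", nm)]] <- NA_real_
  out$overall <- NA_real_
  out$.score <- NA_real_
  out$valid <- FALSE
  for (i in seq_len(n)) {
    if (!identical(out$status[i], "ok")) next
    raw <- lapply(nms, function(nm) {
      if (!nm %in% names(runs)) return(NULL)
      v <- runs[[nm]][i]
      if (is.null(v) || !is.finite(v)) NULL else v
    })
    names(raw) <- nms
    if (any(vapply(raw, is.null, logical(1L)))) {
      out$status[i] <- "invalid"
      warning("run ", runs$run_id[i],
              " is missing a declared response; marked invalid",
              call. = FALSE)
      next
    }
    ds <- numeric(0)
    for (nm in nms[with_ramp]) {
      d <- desirability_score(raw[[nm]], specs[[nm]])
      out[[paste0("d_", nm)]][i] <- d
      ds <- c(ds, d)
    }
    out$overall[i] <- if (multi) overall_desirability(ds)
                      else if (length(ds)) ds else raw[[1L]]
    out$.score[i] <- run_score(raw, out$overall[i], specs)
    out$valid[i] <- TRUE
  }
  ord <- order(!out$valid, -ifelse(out$valid, out$.score, Inf),
               as.character(out$run_id))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
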