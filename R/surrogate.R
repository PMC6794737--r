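# OLS response-surface surrogates: quadratic term sets over coded factors,
# leave-one-out Q2 validation, best-subset / greedy-forward term selection,
# and grid search for the model optimum inside the current design region.

# --- term sets ---------------------------------------------------------------

#' Candidate response-surface terms for a set of factors
#'
#' Default candidate set: all linear terms, all two-way interactions and all
#' pure quadratics of the active numeric factors (exactly what a CCF design
#' can estimate).  The intercept is implicit and always fitted.
#'
#' @param factor_names Character vector of active numeric factor names.
#' @param interactions,quadratics Include those term families?
#' @return Character vector of canonical term labels (`"x"`, `"x:y"`,
#'   `"I(x^2)"`).
#' @export
candidate_terms <- function(factor_names, interactions = TRUE,
                            quadratics = TRUE) {
  stopifnot(length(factor_names) >= 1L, !anyDuplicated(factor_names))
  terms <- factor_names
  if (interactions && length(factor_names) >= 2L) {
    pairs <- utils::combn(sort(factor_names), 2L)
    terms <- c(terms, apply(pairs, 2L, paste, collapse = ":"))
  }
  if (quadratics)
    terms <- c(terms, sprintf("I(%s^2)", factor_names))
  terms
}

# Canonicalize a term label: interactions sorted, intercept dropped.
canonical_terms <- function(terms) {
  terms <- terms[!(terms %in% c("intercept", "(Intercept)", "1"))]
  fix <- function(t) {
    if (grepl(":", t, fixed = TRUE))
      paste(sort(strsplit(t, ":", fixed = TRUE)[[1L]]), collapse = ":")
    else t
  }
  out <- vapply(terms, fix, character(1L), USE.NAMES = FALSE)
  if (anyDuplicated(out))
    stop("duplicate terms: ", paste(out[duplicated(out)], collapse = ", "),
         call. = FALSE)
  out
}

term_factors <- function(term) {
  if (startsWith(term, "I(")) sub("^I\\((.*)\\^2\\)$", "\\1", term)
  else strsplit(term, ":", fixed = TRUE)[[1L]]
}

# Model matrix (including intercept) for canonical terms over a coded
# data.frame.
term_matrix <- function(coded, terms) {
  n <- nrow(coded)
  cols <- lapply(terms, function(t) {
    if (startsWith(t, "I(")) {
      f <- term_factors(t)
      coded[[f]]^2
    } else {
      fs <- term_factors(t)
      Reduce(`*`, lapply(fs, function(f) coded[[f]]))
    }
  })
  X <- cbind(rep(1, n), if (length(cols)) do.call(cbind, cols))
  colnames(X) <- c("intercept", terms)
  X
}

# --- fitting -----------------------------------------------------------------

code_design <- function(design) {
  design <- as.data.frame(design)
  mid <- vapply(design, function(x) (max(x) + min(x)) / 2, numeric(1L))
  half <- vapply(design, function(x) (max(x) - min(x)) / 2, numeric(1L))
  half[half == 0] <- 1  # constant column: leave centered at 0
  coded <- as.data.frame(mapply(function(x, m, h) (x - m) / h,
                                design, mid, half, SIMPLIFY = FALSE))
  list(coded = coded, mid = mid, half = half)
}

apply_coding <- function(newdata, coding) {
  as.data.frame(mapply(function(nm) {
    (newdata[[nm]] - coding$mid[[nm]]) / coding$half[[nm]]
  }, names(coding$mid), SIMPLIFY = FALSE))
}

# Core least-squares + leave-one-out fit on a prebuilt model matrix.
# Returns NULL when the matrix is rank deficient or n <= p.  Solved through
# the Cholesky factor of X'X (the matrices here are tiny and coded to
# [-1, 1], so the normal equations are well conditioned), which keeps the
# exhaustive best-subset search fast.
ls_fit <- function(X, y) {
  n <- nrow(X); p <- ncol(X)
  if (n <= p) return(NULL)
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R) || min(diag(R))^2 < 1e-10 * max(diag(XtX))) return(NULL)
  beta <- backsolve(R, forwardsolve(t(R), crossprod(X, y)))
  beta <- stats::setNames(drop(beta), colnames(X))
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  U <- X %*% backsolve(R, diag(p))   # X R^{-1}; hat diagonal = row norms
  h <- rowSums(U^2)
  sst <- sum((y - mean(y))^2)
  sse <- sum(resid^2)
  press <- if (any(h > 1 - 1e-10)) Inf else sum((resid / (1 - h))^2)
  if (sst < .Machine$double.eps * max(1, mean(y)^2) * n) {
    # Degenerate constant response: fit is exact but carries no predictive
    # signal to cross-validate; report r2 = 1, q2 = 0 so the Q2 gate fails.
    r2 <- 1; q2 <- 0
  } else {
    r2 <- 1 - sse / sst
    q2 <- if (is.finite(press)) 1 - press / sst else -Inf
  }
  list(beta = beta, r2 = r2, q2 = q2, press = press, sse = sse, sst = sst)
}

# Expand coded-term coefficients into natural-unit polynomial coefficients.
natural_coefficients <- function(terms, beta, coding) {
  acc <- new.env(parent = emptyenv())
  add <- function(key, v) {
    assign(key, (if (exists(key, acc)) get(key, acc) else 0) + v, envir = acc)
  }
  # each coded factor is (x - m)/h -> polynomial a + b*x with a = -m/h, b = 1/h
  lin <- function(f) c(a = -coding$mid[[f]] / coding$half[[f]],
                       b = 1 / coding$half[[f]])
  add("intercept", beta[["intercept"]])
  for (t in terms) {
    co <- beta[[t]]
    if (startsWith(t, "I(")) {
      f <- term_factors(t); l <- lin(f)
      add("intercept", co * l[["a"]]^2)
      add(f, co * 2 * l[["a"]] * l[["b"]])
      add(sprintf("I(%s^2)", f), co * l[["b"]]^2)
    } else {
      fs <- term_factors(t)
      if (length(fs) == 1L) {
        l <- lin(fs)
        add("intercept", co * l[["a"]])
        add(fs, co * l[["b"]])
      } else {
        l1 <- lin(fs[1L]); l2 <- lin(fs[2L])
        add("intercept", co * l1[["a"]] * l2[["a"]])
        add(fs[1L], co * l1[["b"]] * l2[["a"]])
        add(fs[2L], co * l1[["a"]] * l2[["b"]])
        add(paste(fs, collapse = ":"), co * l1[["b"]] * l2[["b"]])
      }
    }
  }
  unlist(as.list(acc))
}

#' Fit an OLS surrogate model and cross-validate it
#'
#' Coordinates are normalized to coded `[-1, 1]` units internally (per-column
#' affine map over the design's range).  `r2 = 1 - SSE/SST` on the fitting
#' data; `q2 = 1 - PRESS/SST` where PRESS accumulates squared leave-one-out
#' prediction errors (computed exactly through the hat matrix).
#'
#' @param design Concrete design (data frame), numeric factors only.
#' @param responses Numeric response vector, one value per design row.
#' @param terms Character vector of term labels (see [candidate_terms()]);
#'   the intercept is always included.
#' @return An object of class `surrogate_model` with elements `terms`,
#'   `coefficients` (coded units), `coefficients_natural`, `r2`, `q2`,
#'   `n_runs` and the coding.
#' @export
fit_and_validate <- function(design, responses, terms = character(0)) {
  design <- as.data.frame(design)
  stopifnot(nrow(design) == length(responses))
  if (any(!is.finite(as.matrix(design))) || any(!is.finite(responses)))
    stop("design and responses must be finite", call. = FALSE)
  terms <- canonical_terms(terms)
  used <- unique(unlist(lapply(terms, term_factors)))
  unknown <- setdiff(used, names(design))
  if (length(unknown))
    stop("terms reference unknown factors: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  if (nrow(design) <= length(terms) + 1L)
    stop("need more runs (", nrow(design), ") than model terms (",
         length(terms) + 1L, " incl. intercept)", call. = FALSE)
  cd <- code_design(design)
  X <- term_matrix(cd$coded, terms)
  fit <- ls_fit(X, responses)
  if (is.null(fit)) {
    # name the collinear columns for the error message
    qrx <- qr(X)
    bad <- if (qrx$rank < ncol(X))
      colnames(X)[qrx$pivot[seq.int(qrx$rank + 1L, ncol(X))]]
    else colnames(X)
    stop("rank-deficient term matrix; collinear terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(
    list(terms = c("intercept", terms),
         coefficients = stats::setNames(as.numeric(fit$beta), colnames(X)),
         coefficients_natural = natural_coefficients(terms, fit$beta, cd),
         r2 = fit$r2, q2 = fit$q2, n_runs = nrow(design),
         coding = cd[c("mid", "half")], factor_names = names(design)),
    class = "surrogate_model"
  )
}

#' @export
print.surrogate_model <- function(x, ...) {
  cat(sprintf("<surrogate_model> %d terms, n = %d, R2 = %.4f, Q2 = %.4f\n",
              length(x$terms), x$n_runs, x$r2, x$q2))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' Predict from a surrogate model
#'
#' @param object A `surrogate_model`.
#' @param newdata Data frame of natural-unit factor settings.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.surrogate_model <- function(object, newdata, ...) {
  coded <- apply_coding(as.data.frame(newdata), object$coding)
  X <- term_matrix(coded, setdiff(object$terms, "intercept"))
  drop(X %*% object$coefficients)
}

# q2 of one candidate subset; -Inf when unfittable.
subset_q2 <- function(X, y, cols) {
  fit <- ls_fit(X[, c(1L, cols + 1L), drop = FALSE], y)
  if (is.null(fit)) -Inf else fit$q2
}

#' Select a surrogate model by cross-validated Q2
#'
#' `best_subset` exhaustively searches all subsets of the candidate terms
#' (intercept always forced) and keeps the subset with the highest Q2,
#' breaking ties toward fewer terms and then lexicographically smaller term
#' sets.  `greedy_forward` starts from the intercept-only model and
#' repeatedly adds the single term with the largest Q2 gain, stopping when no
#' addition improves Q2.  Greedy is preferred above four factors, where the
#' exhaustive search grows too fast.
#'
#' @param design Concrete numeric design (data frame).
#' @param responses Numeric vector of responses.
#' @param method `"best_subset"` or `"greedy_forward"`.
#' @param candidates Candidate term labels; defaults to
#'   [candidate_terms()] over the design's columns.
#' @return The selected `surrogate_model` (with a `method` attribute).
#' @export
select_model <- function(design, responses,
                         method = c("best_subset", "greedy_forward"),
                         candidates = NULL) {
  method <- match.arg(method)
  design <- as.data.frame(design)
  if (is.null(candidates)) candidates <- candidate_terms(names(design))
  candidates <- canonical_terms(candidates)
  cd <- code_design(design)
  X <- term_matrix(cd$coded, candidates)
  y <- responses
  p <- length(candidates)
  best_cols <- NULL
  best_q2 <- -Inf
  if (method == "best_subset") {
    if (p > 20L)
      stop("best_subset limited to 20 candidate terms; use greedy_forward",
           call. = FALSE)
    for (mask in 0:(2^p - 1L)) {
      cols <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(p) - 1L)) != 0L)
      q2 <- subset_q2(X, y, cols)
      if (is.infinite(q2) && q2 < 0) next
      better <- q2 > best_q2 + 1e-12 ||
        (abs(q2 - best_q2) <= 1e-12 && !is.null(best_cols) &&
           (length(cols) < length(best_cols) ||
              (length(cols) == length(best_cols) &&
                 paste(candidates[cols], collapse = ",") <
                   paste(candidates[best_cols], collapse = ","))))
      if (is.null(best_cols) && is.finite(q2)) better <- TRUE
      if (better) { best_cols <- cols; best_q2 <- q2 }
    }
  } else {
    current <- integer(0)
    best_q2 <- subset_q2(X, y, current)
    repeat {
      remaining <- setdiff(seq_len(p), current)
      if (!length(remaining)) break
      gains <- vapply(remaining, function(j)
        subset_q2(X, y, c(current, j)), numeric(1L))
      jbest <- remaining[which.max(gains)]
      if (max(gains) > best_q2 + 1e-12) {
        current <- sort(c(current, jbest))
        best_q2 <- max(gains)
      } else break
    }
    best_cols <- current
    if (!is.finite(best_q2)) best_cols <- NULL
  }
  if (is.null(best_cols) && best_q2 == -Inf)
    stop("no fittable model among the candidate subsets", call. = FALSE)
  model <- fit_and_validate(design, y,
                            terms = candidates[best_cols %||% integer(0)])
  attr(model, "method") <- method
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- optimum location --------------------------------------------------------

# Vectorized linear desirability ramp (same semantics as
# desirability_score) used on model predictions during the optimum search.
desirability_vec <- function(v, spec) {
  d <- switch(spec$criterion,
    maximize = (v - spec$low_limit) / (spec$target - spec$low_limit),
    minimize = (spec$high_limit - v) / (spec$high_limit - spec$target),
    target = pmin((v - spec$low_limit) / (spec$target - spec$low_limit),
                  (spec$high_limit - v) / (spec$high_limit - spec$target)))
  pmin(1, pmax(0, d))
}

# Per-factor search grid inside [low, high].
region_grid <- function(low, high, ordinal, n_grid) {
  if (ordinal) {
    lo <- ceiling(low - 1e-9); hi <- floor(high + 1e-9)
    if (hi - lo + 1 <= max(n_grid, 2L)) return(seq.int(lo, hi))
    unique(round_half_up(seq(low, high, length.out = n_grid)))
  } else {
    seq(low, high, length.out = n_grid)
  }
}

#' Locate a model's predicted optimum inside a region
#'
#' Dense-grid search (default 51 points per factor; ordinals are enumerated
#' exhaustively when their integer range fits).  Ties on the predicted value
#' break toward the configuration closest to the region center in coded
#' units, then lexicographically.  In multi-response mode pass a list of
#' models and the response specs: the search then maximizes the overall
#' desirability of the per-response predictions.
#'
#' @param model A `surrogate_model`, or (multi-response) a named list of
#'   `surrogate_model`s keyed by response name.
#' @param region Named list of `c(low, high)` per factor.
#' @param ordinal Named logical vector marking ordinal factors (default all
#'   FALSE).
#' @param goal `"maximize"`, `"minimize"` or `"target"` (single-response).
#' @param target Target value (required when `goal = "target"`).
#' @param specs Response specs (multi-response mode only).
#' @param n_grid Grid points per quantitative factor.
#' @return List with `configuration` (named list), `predicted`,
#'   `at_boundary` (named logical) and `objective` (internal score scale).
#' @export
predict_optimum <- function(model, region, ordinal = NULL,
                            goal = c("maximize", "minimize", "target"),
                            target = NULL, specs = NULL, n_grid = 51L) {
  goal <- match.arg(goal)
  fnames <- names(region)
  stopifnot(length(fnames) >= 1L)
  lows <- vapply(region, `[[`, numeric(1L), 1L)
  highs <- vapply(region, `[[`, numeric(1L), 2L)
  if (any(lows >= highs))
    stop("degenerate region: low must be < high for every factor",
         call. = FALSE)
  if (is.null(ordinal)) ordinal <- stats::setNames(rep(FALSE, length(fnames)),
                                                   fnames)
  multi <- !inherits(model, "surrogate_model")
  if (multi && is.null(specs))
    stop("multi-response prediction requires response specs", call. = FALSE)
  if (multi) specs <- response_set(specs)
  grids <- lapply(fnames, function(nm)
    region_grid(lows[[nm]], highs[[nm]], isTRUE(ordinal[[nm]]), n_grid))
  names(grids) <- fnames
  sizes <- vapply(grids, length, integer(1L))
  total <- prod(sizes)
  centers <- (lows + highs) / 2
  halfspan <- (highs - lows) / 2
  # precompile each model's terms into fast column operations
  model_list <- if (multi) model[names(specs)] else list(model)
  prep <- lapply(model_list, function(m) {
    ts <- setdiff(m$terms, "intercept")
    ops <- lapply(ts, function(t) {
      fs <- term_factors(t)
      kind <- if (startsWith(t, "I(")) "quad"
              else if (length(fs) == 2L) "int" else "lin"
      list(kind = kind, f = fs, beta = m$coefficients[[t]])
    })
    # per-factor coded grids under this model's coding
    cg <- lapply(fnames, function(nm)
      (grids[[nm]] - m$coding$mid[[nm]]) / m$coding$half[[nm]])
    names(cg) <- fnames
    list(b0 = m$coefficients[["intercept"]], ops = ops, cg = cg)
  })
  predict_with <- function(p, idx) {
    cols <- lapply(fnames, function(nm) p$cg[[nm]][idx[[nm]]])
    names(cols) <- fnames
    y <- rep(p$b0, length(idx[[1L]]))
    for (op in p$ops)
      y <- y + op$beta * switch(op$kind,
        lin = cols[[op$f]],
        quad = cols[[op$f]]^2,
        int = cols[[op$f[1L]]] * cols[[op$f[2L]]])
    y
  }
  objective_of <- function(idx) {
    if (!multi) {
      pred <- predict_with(prep[[1L]], idx)
      switch(goal, maximize = pred, minimize = -pred,
             target = -abs(pred - target))
    } else {
      logd <- 0
      for (j in seq_along(specs)) {
        d <- desirability_vec(predict_with(prep[[j]], idx), specs[[j]])
        logd <- logd + log(d)
      }
      exp(logd / length(specs))
    }
  }
  # chunked mixed-radix enumeration (last factor fastest = lexicographic)
  chunk <- 400000L
  best <- NULL  # list(obj, rows data.frame)
  idx0 <- 0
  while (idx0 < total) {
    take <- min(chunk, total - idx0)
    lin <- idx0 + seq_len(take) - 1
    idx <- vector("list", length(fnames))
    rem <- lin
    for (j in rev(seq_along(fnames))) {
      idx[[j]] <- (rem %% sizes[j]) + 1
      rem <- rem %/% sizes[j]
    }
    names(idx) <- fnames
    obj <- objective_of(idx)
    m <- max(obj)
    tol <- 1e-12 * max(1, abs(m))
    hit <- which(obj >= m - tol)
    rows <- as.data.frame(lapply(fnames, function(nm)
      grids[[nm]][idx[[nm]][hit]]))
    names(rows) <- fnames
    if (is.null(best) || m > best$obj + 1e-12 * max(1, abs(best$obj))) {
      best <- list(obj = m, rows = rows)
    } else if (abs(m - best$obj) <= 1e-12 * max(1, abs(best$obj))) {
      best$rows <- rbind(best$rows, rows)
    }
    idx0 <- idx0 + take
  }
  # tie-break: distance to region center in coded units, then lexicographic
  rows <- best$rows
  coded <- sweep(sweep(as.matrix(rows), 2L, centers[fnames]), 2L,
                 halfspan[fnames], FUN = "/")
  dist <- sqrt(rowSums(coded^2))
  ord <- do.call(order, c(list(round(dist, 12)), as.list(rows)))
  pick <- rows[ord[1L], , drop = FALSE]
  config <- as.list(pick)
  pred <- if (!multi) {
    predict(model, pick)
  } else {
    logd <- vapply(names(specs), function(nm)
      log(desirability_vec(predict(model[[nm]], pick), specs[[nm]])),
      numeric(1L))
    exp(mean(logd))
  }
  at_boundary <- stats::setNames(vapply(fnames, function(nm) {
    v <- config[[nm]]
    isTRUE(abs(v - lows[[nm]]) <= 1e-9 * max(1, abs(lows[[nm]]))) ||
      isTRUE(abs(v - highs[[nm]]) <= 1e-9 * max(1, abs(highs[[nm]])))
  }, logical(1L)), fnames)
  list(configuration = config, predicted = as.numeric(pred),
       at_boundary = at_boundary, objective = best$obj)
}
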