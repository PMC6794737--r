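# Shared fixtures: seeded random quadratic mock problems and independent
# oracles used to cross-check the design engine and model selection.

# A concave quadratic mock objective over [0, 10]^k with interior optimum,
# mild interactions (|w| <= 0.3 * sqrt(c_f c_g), keeping the surface
# near-separable and strictly concave) and a matching doe_problem.
random_quadratic_problem <- function(k, seed, noise_sd = 0,
                                     lo = 0, hi = 10) {
  set.seed(seed)
  nms <- paste0("x", seq_len(k))
  opt <- stats::setNames(stats::runif(k, lo + 0.2 * (hi - lo),
                                      hi - 0.2 * (hi - lo)), nms)
  curv <- stats::setNames(stats::runif(k, 0.5, 2), nms)
  inter <- NULL
  if (k >= 2) {
    pairs <- utils::combn(nms, 2L)
    w <- stats::runif(ncol(pairs), -0.3, 0.3) *
      sqrt(curv[pairs[1L, ]] * curv[pairs[2L, ]])
    inter <- stats::setNames(w, apply(pairs, 2L, paste, collapse = ":"))
  }
  obj <- mock_objective(opt, curv, interactions = inter,
                        noise_sd = noise_sd, seed = seed, y0 = 100)
  fs <- factor_space(lapply(nms, function(nm)
    doe_factor(nm, "quantitative", min = lo, max = hi)))
  prob <- doe_problem(fs, response_spec("y", "maximize"))
  list(problem = prob, objective = obj, optimum = opt, range = hi - lo)
}

# Independent GSD oracle: the "union of Cartesian products of class tuples"
# construction (level indices partitioned cyclically into residue classes;
# keep tuples whose class labels sum to `idx` mod `r`).
gsd_oracle <- function(counts, r, idx) {
  classes <- lapply(counts, function(n) {
    lv <- 0:(n - 1L)
    split(lv, lv %% r)
  })
  tuples <- as.matrix(expand.grid(rep(list(0:(r - 1L)), length(counts))))
  keep <- which(rowSums(tuples) %% r == idx)
  rows <- list()
  for (t in keep) {
    sets <- lapply(seq_along(counts), function(j)
      classes[[j]][[as.character(tuples[t, j])]])
    if (any(vapply(sets, is.null, logical(1L)))) next
    rows[[length(rows) + 1L]] <- expand.grid(sets)
  }
  if (!length(rows)) return(NULL)
  df <- unique(do.call(rbind, rows))
  names(df) <- paste0("f", seq_along(counts))
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

sort_design <- function(d) {
  df <- as.data.frame(d)
  attr(df, "form") <- NULL
  attr(df, "provenance") <- NULL
  class(df) <- "data.frame"
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Independent Q2 oracle: explicit leave-one-out refits with lm().
q2_oracle <- function(design, y, terms) {
  df <- as.data.frame(design)
  # fit in coded units exactly as the package does
  mid <- vapply(df, function(x) (max(x) + min(x)) / 2, numeric(1L))
  half <- vapply(df, function(x) (max(x) - min(x)) / 2, numeric(1L))
  half[half == 0] <- 1
  coded <- as.data.frame(mapply(function(x, m, h) (x - m) / h, df, mid, half,
                                SIMPLIFY = FALSE))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  form <- stats::as.formula(paste("y ~", rhs))
  dat <- cbind(coded, y = y)
  n <- nrow(dat)
  press <- 0
  for (i in seq_len(n)) {
    fit <- stats::lm(form, data = dat[-i, , drop = FALSE])
    pred <- unname(stats::predict(fit, newdata = dat[i, , drop = FALSE]))
    if (!is.finite(pred)) return(-Inf)
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Exhaustive best-subset oracle over all candidate subsets, same tie rules
# (max q2; fewer terms; lexicographically smaller term list).
best_subset_oracle <- function(design, y, candidates) {
  p <- length(candidates)
  best <- NULL
  for (mask in 0:(2^p - 1)) {
    sel <- candidates[bitwAnd(mask, bitwShiftL(1, seq_len(p) - 1)) != 0]
    if (nrow(as.data.frame(design)) <= length(sel) + 1L) next
    q2 <- tryCatch(q2_oracle(design, y, sel), error = function(e) -Inf)
    if (!is.finite(q2)) next
    cand <- list(terms = sel, q2 = q2)
    if (is.null(best) || q2 > best$q2 + 1e-12 ||
        (abs(q2 - best$q2) <= 1e-12 &&
         (length(sel) < length(best$terms) ||
          (length(sel) == length(best$terms) &&
           paste(sel, collapse = ",") < paste(best$terms, collapse = ",")))))
      best <- cand
  }
  best
}

# Audit-trail invariant checks applied to every simulated optimization.
check_report_invariants <- function(report) {
  audit <- report$audit
  testthat::expect_false(any(duplicated(audit$run_id)))
  testthat::expect_equal(nrow(audit), report$total_runs)
  valid <- audit[audit$valid, , drop = FALSE]
  testthat::expect_equal(max(valid$.score), report$best_score)
  scr_best <- max(valid$.score[valid$phase == "screening"])
  testthat::expect_gte(report$best_score, scr_best)
  invisible(report)
}
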