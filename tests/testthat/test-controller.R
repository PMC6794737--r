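# Two-phase controller: screening, region anchoring, iteration mechanics,
# design-space movement/shrinkage/clamping, convergence, restarts.

simple_problem <- function(...) {
  fs <- factor_space(doe_factor("a", "quantitative", min = 0, max = 10),
                     doe_factor("b", "quantitative", min = 0, max = 10))
  doe_problem(fs, response_spec("y", "maximize"), ...)
}

make_state <- function(problem, center, span) {
  st <- doeopt:::new_state(problem, list(center = center, span = span),
                           list())
  st$iteration <- 1L
  st$history[[1]] <- list(moved = NA)
  st
}

test_that("screening finds the best GSD grid point and fixes categoricals", {
  obj <- mock_objective(optima = c(a = 5, b = 7.5), curvatures = 1, y0 = 0)
  prob <- simple_problem(reduction = 2)
  scr <- run_screening(prob, mock_executor(obj))
  # oracle: enumerate exactly the executed subset
  lv <- screening_grid(prob$factors)
  idx <- as.data.frame(generate_gsd(c(5, 5), 2, 0))
  pts <- data.frame(a = lv$a[idx[[1]] + 1], b = lv$b[idx[[2]] + 1])
  vals <- apply(pts, 1, function(r)
    evaluate(obj, list(a = r[1], b = r[2]))[["y"]])
  expect_equal(scr$n_runs, nrow(pts))
  expect_equal(unname(c(scr$best$a, scr$best$b)),
               unname(unlist(pts[which.max(vals), ])))
  # categorical fixing: objective strongly favors category B (the offset
  # dominates any numeric effect visible on the screened subset)
  obj2 <- mock_objective(optima = c(a = 5), curvatures = 1, y0 = 0,
                         categorical_offsets = list(m = c(A = -200, B = 0)))
  fs2 <- factor_space(doe_factor("a", "quantitative", min = 0, max = 10),
                      doe_factor("m", "categorical",
                                 categories = c("A", "B")))
  prob2 <- doe_problem(fs2, response_spec("y", "maximize"))
  scr2 <- run_screening(prob2, mock_executor(obj2))
  expect_identical(scr2$fixed_categoricals$m, "B")
  # all runs failing is a screening failure
  expect_error(
    run_screening(prob, mock_executor(obj, fail_when = function(cfg) TRUE)),
    "screening failure")
})

test_that("the first RSM region anchors on midpoints with edge shift inward", {
  sp <- factor_space(doe_factor("MIKC", "quantitative", min = 2, max = 15))
  a <- initialize_rsm(list(MIKC = 8.5),
                      list(MIKC = c(2, 5.25, 8.5, 11.75, 15)), sp)
  expect_equal(unname(a$low["MIKC"]), 6.875)
  expect_equal(unname(a$high["MIKC"]), 10.125)
  expect_equal(unname(a$span["MIKC"]), 3.25)
  sp2 <- factor_space(doe_factor("A", "ordinal", min = 20, max = 60))
  a2 <- initialize_rsm(list(A = 60), list(A = c(20, 30, 40, 50, 60)), sp2)
  expect_equal(unname(a2$center["A"]), 50)  # edge -> shifted inward
  expect_equal(unname(c(a2$low["A"], a2$high["A"])), c(45, 55))
  sp3 <- factor_space(doe_factor("B", "quantitative", min = 5, max = 15))
  a3 <- initialize_rsm(list(B = 10), list(B = c(5, 8, 10, 13, 15)), sp3)
  expect_equal(unname(c(a3$low["B"], a3$high["B"])), c(9, 11.5))
  expect_error(initialize_rsm(list(B = 10), list(B = c(5, 10)), sp3),
               "fewer than 3")
})

test_that("design space moves by one step, shrinks every iteration, clamps at bounds", {
  prob <- doe_problem(
    factor_space(doe_factor("x", "quantitative", min = 0, max = 100)),
    response_spec("y", "maximize"))
  st <- make_state(prob, c(x = 50), c(x = 20))
  u <- update_design_space(st, list(x = 56))
  expect_true(u$moved)
  expect_equal(unname(u$state$center["x"]), 55)   # moved by 0.25 * 20
  expect_equal(unname(u$state$span["x"]), 18)     # then shrunk by 0.9
  # best at center: no move, span still shrinks
  st2 <- make_state(prob, c(x = 50), c(x = 20))
  u2 <- update_design_space(st2, list(x = 50))
  expect_false(u2$moved)
  expect_equal(unname(u2$state$span["x"]), 18)
  # clamping: moved+shrunk region crossing the global max is translated back
  prob3 <- doe_problem(
    factor_space(doe_factor("x", "quantitative", min = 0, max = 10)),
    response_spec("y", "maximize"))
  st3 <- make_state(prob3, c(x = 9), c(x = 4))
  u3 <- update_design_space(st3, list(x = 10.4))
  expect_equal(unname(u3$state$span["x"]), 3.6)
  expect_equal(unname(u3$state$center["x"] + u3$state$span["x"] / 2), 10)
  expect_equal(unname(u3$state$center["x"] - u3$state$span["x"] / 2), 6.4)
  # ordinal span below 1 freezes the factor
  prob4 <- doe_problem(
    factor_space(doe_factor("k", "ordinal", min = 0, max = 100)),
    response_spec("y", "maximize"))
  st4 <- make_state(prob4, c(k = 50), c(k = 1.05))
  expect_warning(u4 <- update_design_space(st4, list(k = 50)), "frozen")
  expect_true(u4$state$frozen[["k"]])
})

test_that("convergence halts on unmoved designs, non-improvement, or the cap", {
  prob <- simple_problem()
  st <- make_state(prob, c(a = 5, b = 5), c(a = 2, b = 2))
  st$history[[1]] <- list(moved = FALSE, best_score = 1)
  expect_equal(check_convergence(st)$reason, "design unmoved")
  st$history[[1]] <- list(moved = TRUE, best_score = 0.6)
  st$prev_best_score <- 0.6
  expect_equal(check_convergence(st)$reason, "no improvement")
  st$prev_best_score <- 0.5
  expect_false(check_convergence(st)$halt)
  st$problem$options$max_iterations <- 1L
  expect_equal(check_convergence(st)$reason, "iteration cap reached")
})

test_that("an iteration runs a CCF plus one validation run when the model is predictive", {
  obj <- mock_objective(optima = c(a = 5.2, b = 6.1), curvatures = 1,
                        y0 = 10)
  prob <- simple_problem(reduction = 2)
  scr <- run_screening(prob, mock_executor(obj))
  anchor <- initialize_rsm(as.list(scr$best[, c("a", "b")]), scr$levels,
                           prob$factors)
  st <- doeopt:::new_state(prob, anchor, scr$fixed_categoricals,
                           run_offset = scr$n_runs)
  st <- run_iteration(st, mock_executor(obj))
  entry <- st$history[[1]]
  expect_true(entry$gate)
  expect_equal(nrow(entry$runs), 9 + 1)  # CCF + validation
  vrun <- entry$runs[startsWith(entry$runs$phase, "validation"), ]
  expect_equal(nrow(vrun), 1L)
  # noiseless concave quadratic: the validated vertex is the iteration best
  expect_equal(as.character(entry$best$run_id), as.character(vrun$run_id))
  # and it sits at the true optimum clipped to the region (grid tolerance)
  region <- doeopt:::state_region(st)
  for (nm in c("a", "b")) {
    truth <- min(max(5.2 * (nm == "a") + 6.1 * (nm == "b"),
                     region[[nm]][1]), region[[nm]][2])
    expect_lt(abs(vrun[[nm]] - truth),
              (region[[nm]][2] - region[[nm]][1]) / 25)
  }
})

test_that("a pure-noise objective fails the q2 gate and skips validation", {
  obj <- mock_objective(optima = c(a = 5, b = 5), curvatures = 1e-9,
                        noise_sd = 1, seed = 99, y0 = 0)
  prob <- simple_problem(reduction = 2)
  scr <- run_screening(prob, mock_executor(obj))
  anchor <- initialize_rsm(as.list(scr$best[, c("a", "b")]), scr$levels,
                           prob$factors)
  st <- doeopt:::new_state(prob, anchor, scr$fixed_categoricals,
                           run_offset = scr$n_runs)
  st <- run_iteration(st, mock_executor(obj))
  entry <- st$history[[1]]
  expect_false(entry$gate)
  expect_equal(nrow(entry$runs), 9L)  # CCF only, no validation run
  expect_false(any(startsWith(entry$runs$phase, "validation")))
})

test_that("full optimization recovers a noiseless interior optimum", {
  pr <- random_quadratic_problem(2, seed = 42)
  report <- optimize_pipeline(pr$problem, mock_executor(pr$objective))
  check_report_invariants(report)
  for (nm in names(pr$optimum)) {
    expect_lt(abs(report$best_configuration[[nm]] - pr$optimum[[nm]]),
              0.1 * pr$range)
  }
  expect_lt(report$total_runs, 25)  # far below the 25-point grid
})

test_that("span shrinks monotonically and regions stay inside global bounds", {
  pr <- random_quadratic_problem(3, seed = 7)
  obj <- pr$objective
  prob <- pr$problem
  scr <- run_screening(prob, mock_executor(obj))
  anchor <- initialize_rsm(as.list(scr$best[, names(pr$optimum)]),
                           scr$levels, prob$factors)
  st <- doeopt:::new_state(prob, anchor, scr$fixed_categoricals,
                           run_offset = scr$n_runs)
  prev_span <- st$span
  for (i in 1:4) {
    st <- run_iteration(st, mock_executor(obj))
    u <- update_design_space(st, st$history[[st$iteration]]$best)
    st <- u$state
    active <- !st$frozen
    expect_true(all(st$span[active] <=
                      prev_span[active] * prob$options$shrinkage + 1e-12))
    for (nm in names(st$center)) {
      f <- prob$factors[[nm]]
      expect_gte(st$center[[nm]] - st$span[[nm]] / 2, f$min - 1e-9)
      expect_lte(st$center[[nm]] + st$span[[nm]] / 2, f$max + 1e-9)
    }
    prev_span <- st$span
  }
})

test_that("unreachable acceptability limits trigger a restart from the next-best screening basin", {
  # two-basin surface: broad basin A peaks at x = 25 (value 50, below the
  # acceptability limit 60); narrow basin B, entered via the second-best
  # screening point x = 75, peaks at x = 71 with value 75 (acceptable)
  two_basin <- function(x, y)
    pmax(50 - 0.02 * (x - 25)^2, 75 - 2 * (x - 71)^2) - 0.001 * (y - 50)^2
  executor <- function(configs, phase = "screening") {
    configs$F <- mapply(two_basin, configs$x, configs$y)
    configs$status <- "ok"
    configs
  }
  fs <- factor_space(doe_factor("x", "quantitative", min = 0, max = 100),
                     doe_factor("y", "quantitative", min = 0, max = 100))
  prob <- doe_problem(fs, response_spec("F", "maximize", low_limit = 60,
                                        target = 80), reduction = 2)
  report <- optimize_pipeline(prob, executor)
  check_report_invariants(report)
  expect_gte(report$restarts_used, 1L)
  expect_gt(report$best_responses$F, 60)  # desirability > 0 at the end
  expect_gt(report$best_overall, 0)
})

test_that("an all-categorical problem reduces to its screening best", {
  obj <- mock_objective(optima = numeric(0), curvatures = 1, y0 = 0,
                        categorical_offsets = list(
                          m = c(A = 0, B = 3), n = c(P = 1, Q = 0)))
  fs <- factor_space(doe_factor("m", "categorical",
                                categories = c("A", "B")),
                     doe_factor("n", "categorical",
                                categories = c("P", "Q")))
  prob <- doe_problem(fs, response_spec("y", "maximize"), reduction = 2)
  report <- optimize_pipeline(prob, mock_executor(obj))
  expect_equal(report$iterations, 0L)
  expect_equal(report$halt_reason, "no numeric factors")
  # GSD half-fraction of the 2x2 grid executes (A,P) and (B,Q); B+Q wins
  expect_identical(report$best_configuration$m, "B")
  expect_identical(report$best_configuration$n, "Q")
})

test_that("identical problem and seed give identical audits", {
  pr <- random_quadratic_problem(2, seed = 5, noise_sd = 0.3)
  r1 <- optimize_pipeline(pr$problem, mock_executor(pr$objective), seed = 3)
  r2 <- optimize_pipeline(pr$problem, mock_executor(pr$objective), seed = 3)
  expect_identical(r1$audit, r2$audit)
  expect_identical(r1$best_configuration, r2$best_configuration)
})
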