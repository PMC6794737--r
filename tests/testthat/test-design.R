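# Design engine: screening levels, GSD, full factorial, CCF, decoding.

test_that("screening levels are equally spaced with exact endpoints and half-up rounding", {
  expect_equal(screening_levels(doe_factor("MIKC", "quantitative",
                                           min = 2, max = 15)),
               c(2, 5.25, 8.5, 11.75, 15))
  expect_equal(screening_levels(doe_factor("MIAL", "ordinal",
                                           min = 20, max = 60)),
               c(20, 30, 40, 50, 60))
  # 37.5 and 72.5 round half-up to 38 and 73
  expect_equal(screening_levels(doe_factor("KMER", "ordinal",
                                           min = 20, max = 90)),
               c(20, 38, 55, 73, 90))
  set.seed(11)
  for (i in 1:25) {
    mn <- runif(1, -50, 0)
    mx <- mn + runif(1, 1, 100)
    n <- sample(2:9, 1)
    lv <- screening_levels(doe_factor("q", "quantitative",
                                      min = mn, max = mx, n_levels = n))
    expect_identical(lv[1], mn)
    expect_identical(lv[n], mx)
    if (n > 2) expect_lt(max(abs(diff(diff(lv)))), 1e-9)
    expect_true(all(diff(lv) > 0))
  }
  cats <- doe_factor("ALIGNER", "categorical",
                     categories = c("bwa-mem", "minimap2"))
  expect_identical(screening_levels(cats), c("bwa-mem", "minimap2"))
})

test_that("degenerate level requests error out", {
  expect_error(screening_levels(doe_factor("o", "ordinal",
                                           min = 1, max = 3, n_levels = 5)),
               "collapse")
  expect_error(doe_factor("q", "quantitative", min = 1, max = 2,
                          n_levels = 1), "n_levels")
  expect_error(doe_factor("q", "quantitative", min = 3, max = 2), "min")
  expect_error(factor_space(doe_factor("a", "quantitative", min = 0, max = 1),
                            doe_factor("a", "ordinal", min = 0, max = 9)),
               "duplicate")
})

test_that("GSD worked examples match the class-sum construction", {
  g <- generate_gsd(c(2, 2), reduction = 2, complementary_index = 0)
  expect_equal(sort_design(g), data.frame(f1 = c(0L, 1L), f2 = c(0L, 1L)))
  g0 <- generate_gsd(c(3, 3), 2, 0)
  g1 <- generate_gsd(c(3, 3), 2, 1)
  expect_equal(nrow(g0), 5L)
  expect_equal(nrow(g1), 4L)
  expect_equal(sort_design(rbind(as.data.frame(g0), as.data.frame(g1))),
               sort_design(generate_full_factorial(c(3, 3))))
  expect_equal(nrow(generate_gsd(c(5, 5, 5, 5), 8, 0)), 87L)
  expect_error(generate_gsd(c(2, 2), 5), "reduction")
  expect_error(generate_gsd(c(3, 3), 2, complementary_index = 2),
               "complementary_index")
})

test_that("GSD construction agrees with the subset-union oracle", {
  cases <- list(list(c(3, 3), 2), list(c(4, 3), 3), list(c(5, 5), 4),
                list(c(5, 4, 3), 3), list(c(2, 3, 4, 5), 4))
  for (cs in cases) {
    counts <- cs[[1]]; r <- cs[[2]]
    for (idx in 0:(r - 1)) {
      got <- sort_design(generate_gsd(counts, r, idx))
      names(got) <- paste0("f", seq_along(counts))
      expect_equal(got, gsd_oracle(counts, r, idx),
                   ignore_attr = TRUE)
    }
  }
})

test_that("complementary GSDs partition the full factorial (grids <= 2000 cells)", {
  cases <- list(list(c(2, 2), 2), list(c(3, 3), 2), list(c(3, 3), 3),
                list(c(5, 5, 5), 2), list(c(5, 5, 5), 5),
                list(c(5, 5, 5), 8), list(c(5, 5, 5, 5), 8),
                list(c(4, 3, 2), 3), list(c(7, 7), 4),
                list(c(2, 3, 4, 5), 4), list(c(6, 6, 6), 6))
  for (cs in cases) {
    counts <- cs[[1]]; r <- cs[[2]]
    expect_lte(prod(counts), 2000)
    parts <- lapply(0:(r - 1), function(i) generate_gsd(counts, r, i))
    sizes <- vapply(parts, nrow, integer(1L))
    expect_equal(sum(sizes), prod(counts))
    # each complementary design within a factor of 2 of the even share
    expect_true(all(sizes <= 2 * prod(counts) / r))
    expect_true(all(sizes >= prod(counts) / r / 2))
    all_rows <- do.call(rbind, lapply(parts, as.data.frame))
    expect_false(any(duplicated(all_rows)))
    expect_equal(sort_design(all_rows),
                 sort_design(generate_full_factorial(counts)))
    for (p in parts) expect_false(any(duplicated(as.data.frame(p))))
  }
})

test_that("full factorial is exhaustive, unique and lexicographic", {
  expect_equal(nrow(generate_full_factorial(c(5, 5, 5, 5))), 625L)
  expect_equal(nrow(generate_full_factorial(c(5, 5, 5))), 125L)
  expect_equal(nrow(generate_full_factorial(1)), 1L)
  ff <- as.data.frame(generate_full_factorial(c(2, 3)))
  expect_equal(ff, data.frame(f1 = rep(0:1, each = 3), f2 = rep(0:2, 2)),
               ignore_attr = TRUE)
  expect_error(generate_full_factorial(integer(0)), "at least one")
})

test_that("CCF has 2^k corners, 2k axial runs and one center run for k = 1..8", {
  for (k in 1:8) {
    d <- generate_ccf(k)
    m <- as.matrix(d)
    expect_equal(nrow(d), 2^k + 2 * k + 1)
    expect_true(all(m %in% c(-1L, 0L, 1L)))
    expect_equal(sum(rowSums(m != 0) == 0), 1L)                # one center
    if (k > 1) {
      expect_equal(sum(rowSums(m != 0) == k), 2^k)             # corners
      expect_equal(sum(rowSums(m != 0) == 1), 2 * k)           # axial
    }
  }
  expect_error(generate_ccf(9), "n_factors")
})

test_that("decoding is affine for coded designs and a lookup for index designs", {
  d1 <- new_design_matrix(data.frame(x = 1L), "coded", "ccf")
  expect_equal(decode_design(d1, list(x = list(center = 8.5, span = 6.5)))$x,
               11.75)
  d2 <- new_design_matrix(data.frame(KMER = 2L), "level-index", "gsd")
  expect_equal(decode_design(d2, list(KMER = c(20, 38, 55, 73, 90)))$KMER, 55)
  # ordinal: 46 - 5/2 = 43.5 rounds half-up to 44
  d3 <- new_design_matrix(data.frame(x = -1L), "coded", "ccf")
  expect_equal(
    decode_design(d3, list(x = list(center = 46, span = 5,
                                    ordinal = TRUE)))$x, 44)
  expect_error(decode_design(d3, list(y = list(center = 0, span = 1))),
               "missing factors")
})

test_that("decoding coded rows is injective for quantitative factors with span > 0", {
  set.seed(7)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    d <- generate_ccf(k)
    ctx <- lapply(seq_len(k), function(j)
      list(center = runif(1, -5, 5), span = runif(1, 0.1, 3)))
    names(ctx) <- names(d)
    dec <- as.data.frame(decode_design(d, ctx))
    if (k == 1) dec <- unique(dec)
    expect_equal(anyDuplicated(dec), anyDuplicated(as.data.frame(d)))
  }
})

test_that("designs export to CSV with run ids and provenance", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- design_to_csv(generate_ccf(2), path, phase = "iteration-1")
  got <- read.csv(path)
  expect_equal(nrow(got), 9L)
  expect_named(got, c("run_id", "f1", "f2", "phase", "provenance"))
  expect_equal(unique(got$provenance), "ccf")
})
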