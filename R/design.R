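# Design-matrix construction: generalized subset designs (GSD), full
# factorials, face-centered central composite (CCF) designs, and decoding of
# abstract designs into concrete factor settings.

#' Construct a design matrix object
#'
#' Wraps a data frame of runs (one column per factor) with its
#' representation `form` (`"level-index"`, `"coded"` or `"concrete"`) and
#' `provenance` (`"gsd"`, `"full_factorial"`, `"ccf"`, `"validation"`).
#'
#' @param df Data frame, one row per run, one column per factor.
#' @param form Representation of the values.
#' @param provenance Which construction produced the design.
#' @return A `doe_design` object.
#' @export
new_design_matrix <- function(df, form, provenance) {
  stopifnot(form %in% c("level-index", "coded", "concrete"),
            provenance %in% c("gsd", "full_factorial", "ccf", "validation"))
  rownames(df) <- NULL
  structure(df, form = form, provenance = provenance,
            class = c("doe_design", "data.frame"))
}

#' @export
print.doe_design <- function(x, ...) {
  cat(sprintf("<doe_design> %s (%s form), %d runs x %d factors\n",
              attr(x, "provenance"), attr(x, "form"), nrow(x), ncol(x)))
  print(as.data.frame(x), ...)
  invisible(x)
}

design_form <- function(x) attr(x, "form")
design_provenance <- function(x) attr(x, "provenance")

# Full factorial in level-index form (0-based indices), rows in
# lexicographic order of the index tuple (first factor varies slowest).
full_factorial_indices <- function(level_counts) {
  k <- length(level_counts)
  grids <- lapply(rev(level_counts), function(n) seq.int(0L, n - 1L))
  g <- do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE))
  g <- g[, rev(seq_len(k)), drop = FALSE]
  names(g) <- level_count_names(level_counts)
  g
}

level_count_names <- function(level_counts) {
  if (!is.null(names(level_counts)) && all(nzchar(names(level_counts))))
    names(level_counts)
  else paste0("f", seq_along(level_counts))
}

#' Full factorial design
#'
#' All combinations of the given level counts, in level-index form (0-based),
#' rows in lexicographic order.  This is the exhaustive grid that the
#' grid-search baseline executes.
#'
#' @param level_counts Integer vector (optionally named by factor) of levels
#'   per factor, all >= 1.
#' @return A `doe_design` in level-index form.
#' @examples
#' nrow(generate_full_factorial(c(5, 5, 5, 5)))  # 625
#' @export
generate_full_factorial <- function(level_counts) {
  if (length(level_counts) == 0L)
    stop("level_counts must name at least one factor", call. = FALSE)
  level_counts <- stats::setNames(as.integer(level_counts),
                                  names(level_counts))
  if (any(is.na(level_counts)) || any(level_counts < 1L))
    stop("all level counts must be >= 1", call. = FALSE)
  new_design_matrix(full_factorial_indices(level_counts),
                    "level-index", "full_factorial")
}

#' Generalized subset design (GSD)
#'
#' A balanced multi-level fractional design: level indices of each factor are
#' partitioned cyclically into `reduction` residue classes (index `i` falls in
#' class `i %% reduction`), and the design keeps exactly the full-factorial
#' rows whose class labels sum to `complementary_index` modulo `reduction`.
#' The `reduction` complementary designs (one per index) are pairwise disjoint
#' and their union is the full factorial, so each has roughly
#' `prod(level_counts) / reduction` runs.
#'
#' @param level_counts Integer vector of levels per factor (optionally named).
#' @param reduction Integer reduction factor, >= 2 and <= `prod(level_counts)`.
#'   A sensible default in practice is the number of factors.
#' @param complementary_index Which complementary design to return, in
#'   `[0, reduction - 1]`; default 0.
#' @return A `doe_design` in level-index form.
#' @examples
#' nrow(generate_gsd(c(5, 5, 5, 5), reduction = 4))
#' @export
generate_gsd <- function(level_counts, reduction, complementary_index = 0L) {
  if (length(level_counts) == 0L)
    stop("level_counts must name at least one factor", call. = FALSE)
  level_counts <- stats::setNames(as.integer(level_counts),
                                  names(level_counts))
  if (any(is.na(level_counts)) || any(level_counts < 1L))
    stop("all level counts must be >= 1", call. = FALSE)
  reduction <- as.integer(reduction)
  if (is.na(reduction) || reduction < 2L || reduction > prod(level_counts))
    stop("reduction must be an integer in [2, prod(level_counts)]",
         call. = FALSE)
  complementary_index <- as.integer(complementary_index)
  if (is.na(complementary_index) || complementary_index < 0L ||
      complementary_index >= reduction)
    stop("complementary_index must be in [0, reduction - 1]", call. = FALSE)
  full <- full_factorial_indices(level_counts)
  classes <- as.matrix(full) %% reduction
  keep <- (rowSums(classes) %% reduction) == complementary_index
  new_design_matrix(full[keep, , drop = FALSE], "level-index", "gsd")
}

#' Face-centered central composite (CCF) design
#'
#' Coded design for fitting full quadratic response-surface models:
#' `2^k` factorial corners (all coordinates +/-1), `2k` face-centered axial
#' runs (one coordinate +/-1, the rest 0) and a single all-zero center run,
#' for `2^k + 2k + 1` runs in total.
#'
#' @param n_factors Number of factors `k`, between 1 and `cap`.
#' @param factor_names Optional column names (default `f1..fk`).
#' @param cap Safety cap on `k` (default 8; 2^k corners grow fast).
#' @return A `doe_design` in coded form, values in `{-1, 0, 1}`.
#' @examples
#' nrow(generate_ccf(2))  # 9
#' @export
generate_ccf <- function(n_factors, factor_names = NULL, cap = 8L) {
  n_factors <- as.integer(n_factors)
  if (is.na(n_factors) || n_factors < 1L || n_factors > cap)
    stop("n_factors must be in [1, ", cap, "]", call. = FALSE)
  k <- n_factors
  corners <- as.matrix(full_factorial_indices(rep(2L, k))) * 2L - 1L
  axial <- matrix(0L, nrow = 2L * k, ncol = k)
  for (j in seq_len(k)) {
    axial[2L * j - 1L, j] <- -1L
    axial[2L * j, j] <- 1L
  }
  m <- rbind(corners, axial, rep(0L, k))
  df <- as.data.frame(m)
  names(df) <- if (is.null(factor_names)) paste0("f", seq_len(k))
               else factor_names
  new_design_matrix(df, "coded", "ccf")
}

#' Decode an abstract design into concrete factor settings
#'
#' Level-index designs are decoded through per-factor screening levels;
#' coded designs through a per-factor `(center, span)` region, where coded
#' -1/0/+1 map to `center - span/2`, `center`, `center + span/2` (a purely
#' affine map; any clamping to global bounds is the caller's job).  Ordinal
#' factors are rounded half-up to integers after the affine map.
#'
#' @param design A `doe_design` in level-index or coded form.
#' @param context Named list covering every design column: for level-index
#'   form, a vector of concrete levels per factor; for coded form, a list
#'   `list(center =, span =, ordinal = FALSE)` per factor.
#' @return A `doe_design` in concrete form (same provenance).
#' @export
decode_design <- function(design, context) {
  stopifnot(inherits(design, "doe_design"))
  form <- design_form(design)
  if (form == "concrete") return(design)
  missing <- setdiff(names(design), names(context))
  if (length(missing))
    stop("decode context missing factors: ",
         paste(missing, collapse = ", "), call. = FALSE)
  out <- as.data.frame(design)
  if (form == "level-index") {
    for (nm in names(out)) {
      levels <- context[[nm]]
      if (is.list(levels))
        stop("level-index design requires a levels vector for factor '",
             nm, "'", call. = FALSE)
      idx <- out[[nm]]
      if (any(idx < 0L) || any(idx > length(levels) - 1L))
        stop("level index out of range for factor '", nm, "'", call. = FALSE)
      out[[nm]] <- levels[idx + 1L]
    }
  } else {  # coded
    for (nm in names(out)) {
      ctx <- context[[nm]]
      if (!is.list(ctx) || is.null(ctx$center) || is.null(ctx$span))
        stop("coded design requires list(center, span) for factor '",
             nm, "'", call. = FALSE)
      v <- ctx$center + out[[nm]] * ctx$span / 2
      if (isTRUE(ctx$ordinal)) v <- round_half_up(v)
      out[[nm]] <- v
    }
  }
  new_design_matrix(out, "concrete", design_provenance(design))
}

#' Export a design as CSV
#'
#' Writes one row per run with a `run_id` column, one column per factor, and
#' `phase` / `provenance` metadata columns.
#'
#' @param design A `doe_design`.
#' @param path Output file path.
#' @param phase Phase label recorded in the `phase` column.
#' @return The augmented data frame, invisibly.
#' @export
design_to_csv <- function(design, path, phase = "screening") {
  stopifnot(inherits(design, "doe_design"))
  df <- cbind(run_id = sprintf("run%04d", seq_len(nrow(design))),
              as.data.frame(design),
              phase = phase,
              provenance = design_provenance(design),
              stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
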