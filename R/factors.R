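#' Declare a tunable pipeline parameter (factor)
#'
#' A factor is one parameter of the pipeline under optimization.  Numeric
#' factors (`quantitative` or `ordinal`) are described by a global
#' `[min, max]` design space; `categorical` factors by an ordered set of
#' category labels.  Ordinal factors are integer-valued: screening levels and
#' decoded design settings are rounded half-up to integers.
#'
#' @param name Factor name; must be unique within a factor space and usable
#'   as a command-template placeholder.
#' @param kind One of `"quantitative"`, `"ordinal"`, `"categorical"`.
#' @param min,max Global design-space bounds (numeric kinds only).  Ordinal
#'   bounds must be integers.
#' @param categories Character vector of labels (categorical kind only),
#'   at least two.
#' @param n_levels Number of screening levels.  Defaults to 5 for numeric
#'   factors (a resolution that spans large search spaces well) and to the
#'   number of categories for categorical factors.
#' @return An object of class `doe_factor`.
#' @examples
#' doe_factor("MIKC", "quantitative", min = 2, max = 15)
#' doe_factor("KMER", "ordinal", min = 20, max = 90)
#' doe_factor("ALIGNER", "categorical", categories = c("bwa-mem", "minimap2"))
#' @export
doe_factor <- function(name,
                       kind = c("quantitative", "ordinal", "categorical"),
                       min = NULL, max = NULL, categories = NULL,
                       n_levels = NULL) {
  kind <- match.arg(kind)
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("factor name must be a non-empty string", call. = FALSE)
  if (kind == "categorical") {
    if (is.null(categories) || length(categories) < 2L)
      stop("categorical factor '", name, "' needs >= 2 categories",
           call. = FALSE)
    categories <- as.character(categories)
    if (anyDuplicated(categories))
      stop("categories of '", name, "' must be unique", call. = FALSE)
    n_levels <- length(categories)
    min <- max <- NULL
  } else {
    if (is.null(min) || is.null(max) || !is.finite(min) || !is.finite(max))
      stop("numeric factor '", name, "' needs finite min and max",
           call. = FALSE)
    if (min >= max)
      stop("factor '", name, "': min must be < max", call. = FALSE)
    if (kind == "ordinal" && (min != round(min) || max != round(max)))
      stop("ordinal factor '", name, "': min and max must be integers",
           call. = FALSE)
    if (is.null(n_levels)) n_levels <- 5L
    categories <- NULL
  }
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop("factor '", name, "': n_levels must be >= 2", call. = FALSE)
  structure(
    list(name = name, kind = kind, min = min, max = max,
         categories = categories, n_levels = n_levels),
    class = "doe_factor"
  )
}

#' @export
print.doe_factor <- function(x, ...) {
  if (x$kind == "categorical") {
    cat(sprintf("<doe_factor> %s (categorical): {%s}\n",
                x$name, paste(x$categories, collapse = ", ")))
  } else {
    cat(sprintf("<doe_factor> %s (%s): [%g, %g], %d levels\n",
                x$name, x$kind, x$min, x$max, x$n_levels))
  }
  invisible(x)
}

#' Collect factors into a factor space
#'
#' @param ... `doe_factor` objects (or a single list of them).
#' @return A named list of factors with class `factor_space`.
#' @export
factor_space <- function(...) {
  fs <- list(...)
  if (length(fs) == 1L && !inherits(fs[[1L]], "doe_factor")) fs <- fs[[1L]]
  if (length(fs) == 0L) stop("factor space must contain >= 1 factor",
                             call. = FALSE)
  ok <- vapply(fs, inherits, logical(1L), what = "doe_factor")
  if (!all(ok)) stop("all elements must be doe_factor objects", call. = FALSE)
  nms <- vapply(fs, `[[`, character(1L), "name")
  if (anyDuplicated(nms))
    stop("duplicate factor names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  names(fs) <- nms
  structure(fs, class = "factor_space")
}

is_numeric_factor <- function(f) f$kind %in% c("quantitative", "ordinal")

# Round half away from zero is NOT what we want; convention here is
# "half-up" = round halves toward +Inf (43.5 -> 44, -43.5 -> -43).
round_half_up <- function(x) floor(x + 0.5)

#' Screening levels for one factor
#'
#' Numeric factors get `n_levels` equally spaced values from `min` to `max`
#' inclusive; ordinal values are rounded half-up to integers afterwards.
#' Categorical factors return their category labels unchanged.  Five levels
#' per numeric factor is the default screening resolution.
#'
#' @param factor A [doe_factor()].
#' @param n_levels Override of the factor's level count (numeric kinds).
#' @return Numeric vector (ascending) or character vector of categories.
#' @examples
#' screening_levels(doe_factor("MIKC", "quantitative", min = 2, max = 15))
#' screening_levels(doe_factor("KMER", "ordinal", min = 20, max = 90))
#' @export
screening_levels <- function(factor, n_levels = NULL) {
  stopifnot(inherits(factor, "doe_factor"))
  if (factor$kind == "categorical") return(factor$categories)
  if (is.null(n_levels)) n_levels <- factor$n_levels
  n_levels <- as.integer(n_levels)
  if (is.na(n_levels) || n_levels < 2L)
    stop("n_levels must be >= 2 for factor '", factor$name, "'",
         call. = FALSE)
  vals <- seq(factor$min, factor$max, length.out = n_levels)
  # endpoints exactly
  vals[1L] <- factor$min
  vals[n_levels] <- factor$max
  if (factor$kind == "ordinal") {
    vals <- round_half_up(vals)
    if (anyDuplicated(vals))
      stop("screening levels of ordinal factor '", factor$name,
           "' collapse after rounding to integers; reduce n_levels or widen ",
           "the [min, max] range", call. = FALSE)
  }
  vals
}

#' Screening levels for every factor in a space
#'
#' @param space A [factor_space()].
#' @param n_levels Optional single override applied to all numeric factors.
#' @return Named list of per-factor level vectors.
#' @export
screening_grid <- function(space, n_levels = NULL) {
  stopifnot(inherits(space, "factor_space"))
  lapply(space, screening_levels, n_levels = n_levels)
}
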