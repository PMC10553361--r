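## Size-class construction and the size-class x prey-item count grid that
## the DWM and CATS stages consume.

#' Bin predators into equal-count body-size classes
#'
#' Individuals are sorted by standard length (ties broken lexicographically
#' by `pred_id` for reproducibility) and filled into classes of `class_size`
#' in order; the last, largest-size class absorbs the remainder and is the
#' only one allowed to be short. Binning 619 individuals at 31 per class
#' therefore yields 20 classes with 30 in the largest.
#'
#' @param predators A `predator_table` (columns `pred_id`, `species`,
#'   `standard_length_mm`).
#' @param class_size Individuals per class; must not exceed the number of
#'   predators.
#' @return A `size_class_table`: list with `classes` (data frame
#'   `class_index`, `n`, `mean_length_mm`, `min_length_mm`, `max_length_mm`),
#'   `members` (data frame `pred_id`, `class_index`) and `class_size`.
#' @export
assign_size_classes <- function(predators, class_size = 31L) {
  req <- c("pred_id", "standard_length_mm")
  miss <- setdiff(req, names(predators))
  if (length(miss)) {
    stop("predator table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(predators)
  if (n < 1L) stop("predator table is empty", call. = FALSE)
  class_size <- assert_count(class_size, "class_size")
  if (class_size > n) {
    stop("`class_size` (", class_size, ") exceeds the number of predators (",
         n, ")", call. = FALSE)
  }
  if (any(!is.finite(predators$standard_length_mm) |
          predators$standard_length_mm <= 0)) {
    stop("standard_length_mm must be positive and finite", call. = FALSE)
  }
  ord <- order(predators$standard_length_mm, predators$pred_id)
  sorted <- predators[ord, , drop = FALSE]
  n_classes <- as.integer(ceiling(n / class_size))
  idx <- pmin(((seq_len(n) - 1L) %/% class_size) + 1L, n_classes)
  classes <- data.frame(
    class_index = seq_len(n_classes),
    n = as.integer(tabulate(idx, n_classes)),
    mean_length_mm = as.numeric(
      tapply(sorted$standard_length_mm, idx, mean)),
    min_length_mm = as.numeric(
      tapply(sorted$standard_length_mm, idx, min)),
    max_length_mm = as.numeric(
      tapply(sorted$standard_length_mm, idx, max))
  )
  out <- list(classes = classes,
              members = data.frame(pred_id = sorted$pred_id,
                                   class_index = idx,
                                   stringsAsFactors = FALSE),
              class_size = class_size)
  class(out) <- "size_class_table"
  out
}

#' @export
print.size_class_table <- function(x, ...) {
  cat(nrow(x$classes), "body size classes over",
      nrow(x$members), "predators (class size", x$class_size, ")\n")
  print(x$classes, ...)
  invisible(x)
}

#' Build the size-class x prey-item diet matrix
#'
#' Aggregates stomach-content records into a complete count grid with one
#' row per size class and one column per prey item; cells never observed are
#' zero. Items never observed anywhere are retained as zero columns but
#' flagged (they cannot enter the model offset).
#'
#' @param records Data frame `pred_id`, `item_id`, `count` (non-negative
#'   integers; duplicated (pred, item) rows are summed).
#' @param classes A `size_class_table` covering every `pred_id` in
#'   `records`.
#' @param pool A `prey_pool` covering every `item_id`.
#' @return A `diet_matrix`: list with integer matrix `counts` (classes x
#'   items), `classes`, `pool`, and `zero_items` (item ids never observed).
#' @export
build_diet_matrix <- function(records, classes, pool) {
  stopifnot(inherits(classes, "size_class_table"))
  pool <- validate_prey_pool(pool)
  req <- c("pred_id", "item_id", "count")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("records are missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_pred <- setdiff(unique(records$pred_id), classes$members$pred_id)
  if (length(bad_pred)) {
    stop("records contain unknown pred_id: ",
         paste(bad_pred, collapse = ", "), call. = FALSE)
  }
  bad_item <- setdiff(unique(records$item_id), pool$item_id)
  if (length(bad_item)) {
    stop("records contain unknown item_id: ",
         paste(bad_item, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(records$count) | records$count < 0 |
          records$count != round(records$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  C <- nrow(classes$classes)
  I <- nrow(pool)
  counts <- matrix(0L, C, I,
                   dimnames = list(as.character(seq_len(C)), pool$item_id))
  if (nrow(records)) {
    cls <- classes$members$class_index[
      match(records$pred_id, classes$members$pred_id)]
    itm <- match(records$item_id, pool$item_id)
    agg <- tapply(records$count, list(cls, itm), sum)
    ci <- as.integer(rownames(agg))
    ii <- as.integer(colnames(agg))
    agg[is.na(agg)] <- 0
    counts[ci, ii] <- as.integer(agg)
  }
  out <- list(counts = counts, classes = classes, pool = pool,
              zero_items = pool$item_id[colSums(counts) == 0L])
  class(out) <- "diet_matrix"
  out
}

#' @export
print.diet_matrix <- function(x, ...) {
  cat("diet matrix:", nrow(x$counts), "size classes x", ncol(x$counts),
      "prey items; total count", sum(x$counts), "\n")
  if (length(x$zero_items)) {
    cat("never-observed items:", paste(x$zero_items, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Pooled prey-frequency offset
#'
#' The CATS "prior abundance distribution": the relative frequency of each
#' prey item pooled over all predator size classes. Items never observed
#' have frequency zero and are excluded from model fitting (their log offset
#' is undefined); they are listed in `dropped`.
#'
#' @param matrix A `diet_matrix` with positive grand total.
#' @return An `offset_vector`: list with `pi` (named frequencies over all
#'   items, summing to 1), `log_offset` (log pi over retained items),
#'   `retained` and `dropped` item ids.
#' @export
compute_offset <- function(matrix) {
  stopifnot(inherits(matrix, "diet_matrix"))
  pooled <- colSums(matrix$counts)
  total <- sum(pooled)
  if (total <= 0) stop("all-zero diet matrix: no offset defined",
                       call. = FALSE)
  pi <- pooled / total
  retained <- names(pi)[pi > 0]
  out <- list(pi = pi, log_offset = log(pi[retained]),
              retained = retained, dropped = names(pi)[pi == 0])
  class(out) <- "offset_vector"
  out
}

#' Per-class relative prey abundances
#'
#' Divides each size-class row of the diet matrix by its total. Classes with
#' zero total consumption carry no diet information; they are dropped from
#' the result and listed in the `empty_classes` attribute (the DWM stage
#' skips them; the regression keeps their all-zero rows).
#'
#' @param matrix A `diet_matrix`.
#' @return Numeric matrix of row-normalized abundances, rows summing to 1,
#'   with attribute `empty_classes` (integer class indices excluded).
#' @export
relative_abundances <- function(matrix) {
  stopifnot(inherits(matrix, "diet_matrix"))
  totals <- rowSums(matrix$counts)
  keep <- totals > 0
  p <- matrix$counts[keep, , drop = FALSE] / totals[keep]
  attr(p, "empty_classes") <- unname(which(!keep))
  p
}

#' Correlation between class total consumption and class body size
#'
#' Pearson correlation of the per-class total prey count against the class
#' mean standard length, with the usual t test on C - 2 degrees of freedom.
#' A strong positive correlation is the count-based signature of the energy
#' demand mechanism.
#'
#' @param matrix A `diet_matrix` with at least 3 classes.
#' @param classes Optional `size_class_table` (defaults to the one in
#'   `matrix`).
#' @return A `correlation_result`: list `r`, `t`, `df`, `p`.
#' @export
prey_count_size_correlation <- function(matrix, classes = matrix$classes) {
  stopifnot(inherits(matrix, "diet_matrix"))
  totals <- rowSums(matrix$counts)
  s_c <- classes$classes$mean_length_mm
  C <- length(totals)
  if (C < 3L) stop("need at least 3 size classes", call. = FALSE)
  if (sd(totals) == 0 || sd(s_c) == 0) {
    stop("zero variance in class totals or class sizes: correlation ",
         "undefined", call. = FALSE)
  }
  r <- cor(totals, s_c)
  df <- C - 2L
  t <- r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * pt(-abs(t), df)
  out <- list(r = r, t = t, df = df, p = p)
  class(out) <- "correlation_result"
  out
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f; t(%d) = %.2f; p = %.3g\n",
              x$r, x$df, x$t, x$p))
  invisible(x)
}
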