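## Diet-weighted means: the diet analogue of the community-weighted mean.
## DWM = sum_i p_i * trait_i with p_i the relative abundance of prey item i
## in one predator size class.

#' Diet-weighted mean of a quantitative trait
#'
#' @param p Relative-abundance vector (sums to 1).
#' @param traits Trait value per item, same length as `p`.
#' @return `sum(p * traits)`.
#' @export
dwm_quantitative <- function(p, traits) {
  check_abundance(p)
  if (length(traits) != length(p)) {
    stop("`p` and `traits` must have the same length", call. = FALSE)
  }
  sum(p * traits)
}

#' Diet-weighted frequency of a categorical trait level
#'
#' For categorical traits the DWM of a level is simply the summed relative
#' abundance of the items carrying that level.
#'
#' @param p Relative-abundance vector (sums to 1).
#' @param groups Label per item.
#' @param level The level whose frequency is wanted; must occur among the
#'   allowed levels of `groups`.
#' @return Frequency in `[0, 1]`.
#' @export
dwm_categorical <- function(p, groups, level) {
  check_abundance(p)
  if (length(groups) != length(p)) {
    stop("`p` and `groups` must have the same length", call. = FALSE)
  }
  lv <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  if (!level %in% lv) {
    stop("unknown level '", level, "'; allowed: ",
         paste(lv, collapse = ", "), call. = FALSE)
  }
  sum(p[as.character(groups) == level])
}

check_abundance <- function(p) {
  if (length(p) < 1L || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("`p` must be a non-negative vector summing to 1", call. = FALSE)
  }
  invisible(p)
}

#' DWM series along the predator size gradient
#'
#' Computes, for every non-empty size class, the diet-weighted frequency of
#' each trophic group and the diet-weighted mean prey body size (combining
#' all trophic groups, in mm).
#'
#' @param matrix A `diet_matrix`.
#' @return A `dwm_series` data frame with columns `class_index`,
#'   `mean_length_mm`, `trait` (`"trophic_frequency"` or `"body_size"`),
#'   `level` (trophic level or `"all"`), `value`.
#' @export
compute_dwm <- function(matrix) {
  stopifnot(inherits(matrix, "diet_matrix"))
  p <- relative_abundances(matrix)
  keep <- setdiff(seq_len(nrow(matrix$counts)), attr(p, "empty_classes"))
  s_c <- matrix$classes$classes$mean_length_mm[keep]
  groups <- matrix$pool$trophic_group
  sizes <- matrix$pool$body_size_mm
  rows <- list()
  for (k in seq_along(keep)) {
    pk <- p[k, ]
    for (lv in trophic_levels()) {
      rows[[length(rows) + 1L]] <- data.frame(
        class_index = keep[k], mean_length_mm = s_c[k],
        trait = "trophic_frequency", level = lv,
        value = dwm_categorical(pk, groups, lv))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      class_index = keep[k], mean_length_mm = s_c[k],
      trait = "body_size", level = "all",
      value = dwm_quantitative(pk, sizes))
  }
  out <- do.call(rbind, rows)
  class(out) <- c("dwm_series", "data.frame")
  out
}

#' Linear trend of a DWM series along predator size
#'
#' Ordinary least squares of the DWM value on class mean length, reporting
#' slope, intercept, R-squared and the two-sided slope t-test p value. No
#' multiple-testing correction is applied across traits.
#'
#' @param series Data frame with columns `mean_length_mm` and `value`
#'   (e.g. one trait/level subset of [compute_dwm()]); needs >= 3 classes.
#' @return A `trend_fit` list: `slope`, `intercept`, `r_squared`, `p`, `df`.
#' @export
dwm_trend <- function(series) {
  if (nrow(series) < 3L) stop("need at least 3 classes for a trend",
                              call. = FALSE)
  x <- series$mean_length_mm
  y <- series$value
  if (sd(x) == 0) stop("zero variance in class mean length", call. = FALSE)
  fit <- lm(y ~ x)
  ## summary.lm warns on numerically perfect fits; the R^2/p below are
  ## still the quantities wanted
  sm <- suppressWarnings(summary(fit))
  sst <- sum((y - mean(y))^2)
  out <- list(
    slope = unname(coef(fit)[2L]),
    intercept = unname(coef(fit)[1L]),
    r_squared = if (sst == 0) 0 else sm$r.squared,
    p = if (sst == 0) 1 else unname(sm$coefficients[2L, 4L]),
    df = unname(fit$df.residual)
  )
  class(out) <- "trend_fit"
  out
}

#' All four standard DWM trends
#'
#' The trend of each trophic-group frequency and of the mean prey body size
#' along the predator size gradient.
#'
#' @param matrix A `diet_matrix`.
#' @return Data frame with one row per trait/level: slope, R-squared, p.
#' @export
dwm_trends <- function(matrix) {
  series <- compute_dwm(matrix)
  combos <- unique(series[, c("trait", "level")])
  res <- lapply(seq_len(nrow(combos)), function(i) {
    sub <- series[series$trait == combos$trait[i] &
                    series$level == combos$level[i], ]
    tr <- dwm_trend(sub)
    data.frame(trait = combos$trait[i], level = combos$level[i],
               slope = tr$slope, intercept = tr$intercept,
               r_squared = tr$r_squared, p = tr$p, df = tr$df)
  })
  do.call(rbind, res)
}
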