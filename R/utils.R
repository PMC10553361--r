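#' @useDynLib catselect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor lm optimize nlminb pchisq pnorm pt quantile rnorm
#'   rpois runif rmultinom sd setNames coef
#' @importFrom utils read.csv write.table
NULL

#' Trophic group levels
#'
#' The three prey trophic groups used throughout the package, in their
#' canonical order. Primary producers are the reference level of the CATS
#' regression, so animal-prey coefficients read as animal-vs-producer
#' selection.
#'
#' @return Character vector `c("producer", "herb_detr", "carnivore")`.
#' @export
trophic_levels <- function() c("producer", "herb_detr", "carnivore")

## Numerically stable log(1 + exp(u)); exact for large |u|.
softplus <- function(u) {
  pmax(u, 0) + log1p(exp(-abs(u)))
}

standardize <- function(x, center = mean(x), scale = sd(x)) {
  if (!is.finite(scale) || scale <= 0) {
    stop("cannot standardize a constant vector", call. = FALSE)
  }
  structure((x - center) / scale, center = center, scale = scale)
}

## Deterministic per-stream seed derived from a master seed; keeps every
## derived seed a valid 32-bit integer.
derive_seed <- function(master, stream) {
  as.integer((as.double(master) * 48271 + as.double(stream) * 16807) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be TRUE or FALSE", name), call. = FALSE)
  }
  x
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_infinite = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (!allow_infinite && !is.finite(x)) {
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("`%s` must be in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  as.double(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
      x < lower) {
    stop(sprintf("`%s` must be an integer >= %d", name, lower), call. = FALSE)
  }
  as.integer(x)
}
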