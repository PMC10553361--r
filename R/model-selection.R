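## AIC ladder, Akaike weights and Wilks' likelihood-ratio tests over nested
## CATS models.

#' Enumerate the nested model ladder
#'
#' Starting from a full model, systematically removes blocks of terms:
#' each random term (and both), the three-way interactions, all two-way
#' trait interactions, the quadratic predator-size block, prey body size,
#' the trophic group, down to the intercept+offset null. Every emitted spec
#' respects marginality; duplicates are removed and the order is
#' deterministic (full model first).
#'
#' @param full A `cats_model_spec`.
#' @return Named list of `cats_model_spec`s keyed by signature.
#' @export
enumerate_nested_models <- function(full) {
  stopifnot(inherits(full, "cats_model_spec"))
  drop_terms <- function(fixed, pattern) {
    fixed[!grepl(pattern, fixed)]
  }
  f0 <- full$fixed
  fixed_sets <- list(
    f0,
    drop_terms(f0, "PredBS2?:PreyBS:PreyTG"),          # no three-way
    intersect(f0, c("PredBS", "PredBS2", "PreyBS", "PreyTG")),  # mains only
    drop_terms(f0, "PredBS2"),                          # no quadratic block
    drop_terms(f0, "PreyBS"),                           # no prey size
    drop_terms(f0, "PreyTG"),                           # no trophic group
    character()                                         # intercept only
  )
  random_sets <- list(full$random)
  for (r in full$random) {
    random_sets[[length(random_sets) + 1L]] <- setdiff(full$random, r)
  }
  if (length(full$random) == 2L) {
    random_sets[[length(random_sets) + 1L]] <- character()
  }

  specs <- list()
  ## every random reduction of the full fixed set, then every fixed
  ## reduction with the full random set, then the bare null
  for (r in random_sets) {
    sp <- cats_model_spec(f0, r, full$use_offset)
    specs[[spec_signature(sp)]] <- sp
  }
  for (f in fixed_sets) {
    sp <- cats_model_spec(f, full$random, full$use_offset)
    specs[[spec_signature(sp)]] <- sp
  }
  null_sp <- cats_model_spec(character(), character(), full$use_offset)
  specs[[spec_signature(null_sp)]] <- null_sp
  specs
}

#' Akaike weights
#'
#' `w_m = exp(-Delta_m / 2) / sum_k exp(-Delta_k / 2)` with
#' `Delta_m = AIC_m - min(AIC)`; interpreted as the relative probability
#' that model m is the best of the candidate set.
#'
#' @param aic Vector of finite AIC values.
#' @return Weights summing to 1, same names as `aic`.
#' @export
akaike_weights <- function(aic) {
  if (!length(aic) || any(!is.finite(aic))) {
    stop("all AIC values must be finite", call. = FALSE)
  }
  rel <- exp(-(aic - min(aic)) / 2)
  rel / sum(rel)
}

#' Wilks' likelihood-ratio test of two nested fits
#'
#' `statistic = 2 * (logLik_full - logLik_reduced)` (clamped at zero),
#' referred to a chi-square with df equal to the parameter-count difference.
#' When the reduction removes a random term the test is on a variance
#' boundary and the plain chi-square p value is conservative; the 50:50
#' chi-square mixture correction is available via `boundary_mixture`.
#'
#' @param full_fit,reduced_fit `cats_fit` objects, reduced nested in full.
#' @param boundary_mixture Apply the 0.5*chisq(df-1) + 0.5*chisq(df) mixture
#'   for a single variance-component test (default FALSE: plain Wilks).
#' @return List `statistic`, `df`, `p`, `boundary` (TRUE when random terms
#'   were dropped).
#' @export
lrt <- function(full_fit, reduced_fit, boundary_mixture = FALSE) {
  check_nested(full_fit, reduced_fit)
  df <- full_fit$n_params - reduced_fit$n_params
  stat <- max(0, 2 * (full_fit$loglik - reduced_fit$loglik))
  boundary <- length(reduced_fit$sigma2) < length(full_fit$sigma2)
  p <- if (boundary_mixture && boundary && df == 1L) {
    0.5 * pchisq(stat, 1L, lower.tail = FALSE) + 0.5 * (stat == 0)
  } else {
    pchisq(stat, df, lower.tail = FALSE)
  }
  list(statistic = stat, df = df, p = p, boundary = boundary)
}

check_nested <- function(full_fit, reduced_fit) {
  fs <- full_fit$spec
  rs <- reduced_fit$spec
  if (!all(rs$fixed %in% fs$fixed) || !all(rs$random %in% fs$random)) {
    stop("models are not nested: reduced terms must be a subset of the ",
         "full model's", call. = FALSE)
  }
  if (full_fit$n_params <= reduced_fit$n_params) {
    stop("full model must have more parameters than the reduced model",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Fit and compare a ladder of CATS models
#'
#' Fits every spec to the same diet matrix, ranks by AIC, computes Akaike
#' weights and runs Wilks' tests of the first (full) model against every
#' nested reduction.
#'
#' @param matrix A `diet_matrix`.
#' @param specs Named list of `cats_model_spec`s; default the full ladder of
#'   [enumerate_nested_models()] on [full_cats_model()]. The first spec is
#'   treated as the full model.
#' @param log10_size Passed to [build_design()].
#' @return A `model_comparison`: list with `table` (signature, n_params,
#'   logLik, AIC, dAIC, weight), `lrt` (tests vs the full model), `fits`.
#' @export
compare_models <- function(matrix,
                           specs = enumerate_nested_models(full_cats_model()),
                           log10_size = TRUE) {
  stopifnot(length(specs) >= 1L)
  if (is.null(names(specs))) {
    names(specs) <- vapply(specs, spec_signature, character(1L))
  }
  fits <- lapply(specs, function(sp) fit_cats(matrix, sp,
                                              log10_size = log10_size))
  aic <- vapply(fits, function(f) f$aic, numeric(1L))
  ll <- vapply(fits, function(f) f$loglik, numeric(1L))
  np <- vapply(fits, function(f) f$n_params, numeric(1L))
  tab <- data.frame(model = names(specs), n_params = np, loglik = ll,
                    AIC = aic, dAIC = aic - min(aic),
                    weight = akaike_weights(aic),
                    row.names = NULL, stringsAsFactors = FALSE)
  full_fit <- fits[[1L]]
  lrt_rows <- list()
  for (k in seq_along(fits)[-1L]) {
    ok <- tryCatch({ check_nested(full_fit, fits[[k]]); TRUE },
                   error = function(e) FALSE)
    if (!ok) next
    tst <- lrt(full_fit, fits[[k]])
    lrt_rows[[length(lrt_rows) + 1L]] <- data.frame(
      full = names(specs)[1L], reduced = names(specs)[k],
      statistic = tst$statistic, df = tst$df, p = tst$p,
      boundary = tst$boundary, stringsAsFactors = FALSE)
  }
  out <- list(table = tab,
              lrt = if (length(lrt_rows)) do.call(rbind, lrt_rows) else NULL,
              fits = fits)
  class(out) <- "model_comparison"
  out
}

#' @export
print.model_comparison <- function(x, ...) {
  tab <- x$table[order(x$table$AIC), ]
  print(tab, digits = 5, row.names = FALSE)
  invisible(x)
}

#' AIC difference for dropping the class random effect
#'
#' Convenience extractor for the energy-demand evidence: AIC of the full
#' model without the size-class random intercept minus AIC of the full
#' model. Positive values mean the random effect is supported.
#'
#' @param comparison A `model_comparison` containing both models.
#' @return Scalar AIC difference.
#' @export
class_re_delta_aic <- function(comparison) {
  delta_aic_vs_full(comparison, function(full_spec)
    cats_model_spec(full_spec$fixed, setdiff(full_spec$random, "class_id"),
                    full_spec$use_offset),
    "without the class random effect")
}

#' AIC difference for dropping the quadratic predator-size block
#'
#' Evidence for curvature of prey selection along the size gradient: AIC of
#' the full model without `PredBS2` and all its interactions minus AIC of
#' the full model. A saturating (relaxing) selection constraint loads on
#' this block; a linear reward trade-off does not.
#'
#' @param comparison A `model_comparison` containing both models.
#' @return Scalar AIC difference (positive = curvature supported).
#' @export
quad_block_delta_aic <- function(comparison) {
  delta_aic_vs_full(comparison, function(full_spec)
    cats_model_spec(full_spec$fixed[!grepl("PredBS2", full_spec$fixed)],
                    full_spec$random, full_spec$use_offset),
    "without the quadratic predator-size block")
}

delta_aic_vs_full <- function(comparison, reduce, what) {
  tab <- comparison$table
  full_spec <- comparison$fits[[1L]]$spec
  sig <- spec_signature(reduce(full_spec))
  k <- match(sig, tab$model)
  if (is.na(k)) {
    stop("comparison does not contain the full model ", what, call. = FALSE)
  }
  tab$AIC[k] - tab$AIC[1L]
}
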