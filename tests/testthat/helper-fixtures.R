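## Small fixtures shared across test files; everything is built in code.

## A hand-sized prey pool with known sizes in every trophic group.
tiny_pool <- function() {
  pool <- data.frame(
    item_id = sprintf("it%02d", 1:6),
    taxon_label = letters[1:6],
    trophic_group = c("producer", "producer", "herb_detr", "herb_detr",
                      "carnivore", "carnivore"),
    body_size_mm = c(0.5, 1.2, 1.0, 3.0, 2.0, 8.0),
    stringsAsFactors = FALSE
  )
  validate_prey_pool(pool)
}

## Predators with deterministic lengths covering a wide range.
tiny_predators <- function(n = 24, lmin = 15, lmax = 60) {
  data.frame(pred_id = sprintf("p%03d", seq_len(n)),
             species = rep(c("sp_1", "sp_2"), length.out = n),
             standard_length_mm = seq(lmin, lmax, length.out = n),
             stringsAsFactors = FALSE)
}

## A small simulated dataset on a reduced design (fast to fit).
small_sim <- function(preset = "H1", seed = 1, n_individuals = 124,
                      n_items = 20, ...) {
  simulate_preset(preset, seed = seed, n_individuals = n_individuals,
                  n_items = n_items, ...)
}

small_dmat <- function(...) {
  sim <- small_sim(...)
  build_diet_matrix(sim$records, sim$classes, sim$pool)
}

## Random small Poisson design with intercept + one covariate, used by the
## fitter oracle tests. Returns a ready cats_design-like structure.
toy_design <- function(seed, n = 8) {
  set.seed(seed)
  x <- rnorm(n)
  offset <- rnorm(n, sd = 0.3)
  beta <- c(runif(1, -0.5, 1.5), runif(1, -0.8, 0.8))
  y <- rpois(n, exp(beta[1] + beta[2] * x + offset))
  X <- cbind("(Intercept)" = rep(1, n), x = x)
  structure(list(y = as.numeric(y), X = X, offset = offset,
                 class_idx = integer(0), item_idx = integer(0),
                 spec = cats_model_spec(random = character()),
                 meta = list()),
            class = "cats_design")
}

## Independent brute-force oracle: iteratively refined dense grid search of
## the 2-parameter Poisson log-likelihood. Never calls the IRLS path.
grid_oracle_loglik <- function(design, lo = c(-4, -3), hi = c(4, 3),
                               levels = 6, pts = 41) {
  ll <- function(b0, b1) {
    eta <- b0 + b1 * design$X[, 2] + design$offset
    sum(design$y * eta - exp(eta) - lgamma(design$y + 1))
  }
  best <- c(0, 0)
  for (lv in seq_len(levels)) {
    g0 <- seq(lo[1], hi[1], length.out = pts)
    g1 <- seq(lo[2], hi[2], length.out = pts)
    vals <- outer(g0, g1, Vectorize(ll))
    k <- arrayInd(which.max(vals), dim(vals))
    best <- c(g0[k[1]], g1[k[2]])
    span <- c(g0[2] - g0[1], g1[2] - g1[1])
    lo <- best - 2 * span
    hi <- best + 2 * span
  }
  ll(best[1], best[2])
}

## Fabricated model comparison with chosen AIC differences, for classifier
## unit tests that should not depend on a fitted model.
fake_comparison <- function(class_daic, quad_daic) {
  full <- full_cats_model()
  no_class <- cats_model_spec(full$fixed, "item_id", TRUE)
  no_quad <- cats_model_spec(full$fixed[!grepl("PredBS2", full$fixed)],
                             full$random, TRUE)
  specs <- list(full, no_class, no_quad)
  sigs <- vapply(specs, catselect:::spec_signature, character(1))
  aic <- c(100, 100 + class_daic, 100 + quad_daic)
  structure(list(
    table = data.frame(model = sigs, n_params = c(20, 19, 14),
                       loglik = -aic / 2, AIC = aic, dAIC = aic - min(aic),
                       weight = akaike_weights(aic),
                       stringsAsFactors = FALSE),
    fits = list(list(spec = full), list(spec = no_class),
                list(spec = no_quad))
  ), class = "model_comparison")
}

## Fabricated selection curves: linear gap profiles per group.
## gaps_small/gaps_large give the small-prey-minus-large-prey gap at the
## gradient ends per group; values are anchored so percentile 0.5 sits
## between the extremes.
fake_curves <- function(gap_small, gap_large, s = seq(16, 59, length.out = 41),
                        curvature = c(0, 0, 0)) {
  groups <- trophic_levels()
  rows <- list()
  t01 <- (s - min(s)) / diff(range(s))
  for (k in seq_along(groups)) {
    gap <- gap_small[k] + (gap_large[k] - gap_small[k]) * t01 +
      curvature[k] * t01 * (1 - t01) * 4
    for (q in c(0.05, 0.5, 0.95)) {
      val <- switch(as.character(q), "0.05" = gap / 2,
                    "0.5" = 0 * gap, "0.95" = -gap / 2)
      rows[[length(rows) + 1]] <- data.frame(
        group = groups[k], percentile = q, prey_size_mm = q * 10,
        s_mm = s, value = val, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("selection_curves", "data.frame")
  out
}

fake_corr <- function(r = 0.9, p = 1e-6) {
  structure(list(r = r, t = r * sqrt(18) / sqrt(1 - r^2), df = 18, p = p),
            class = "correlation_result")
}
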