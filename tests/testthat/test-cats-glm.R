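test_that("model specs enforce marginality and canonical ordering", {
  sp <- cats_model_spec(c("PreyBS", "PredBS"), "class_id")
  expect_equal(sp$fixed, c("PredBS", "PreyBS"))
  expect_error(cats_model_spec("PredBS:PreyBS"), "marginality")
  expect_error(cats_model_spec("PredBS2"), "marginality")
  expect_error(cats_model_spec("nonsense"), "unknown fixed")
  expect_error(cats_model_spec(random = "pond_id"), "unknown random")
  full <- full_cats_model()
  expect_length(full$fixed, 11)
  expect_equal(full$random, c("class_id", "item_id"))
})

test_that("design matrices have the documented layout and coding", {
  sim <- simulate_preset("H3", seed = 11, n_individuals = 620, n_items = 50,
                         base_log_abundance = log(2))
  dm <- build_diet_matrix(sim$records, sim$classes, sim$pool)
  expect_length(dm$zero_items, 0)   # deep counts: every item observed
  des <- build_design(dm)
  expect_equal(length(des$y), 20 * 50)
  expect_equal(mean(des$X[, "PredBS"]), 0, tolerance = 1e-9)
  ## standardized over the 20 class means (each value repeats per item)
  expect_equal(sd(unique(des$X[, "PredBS"])), 1, tolerance = 1e-9)
  ## producer rows carry zero treatment indicators
  prod_rows <- des$meta$items$trophic_group[des$item_idx] == "producer"
  expect_true(all(des$X[prod_rows, "PreyTGherb_detr"] == 0))
  expect_true(all(des$X[prod_rows, "PreyTGcarnivore"] == 0))
  ## offset equals the log pooled frequency of the row's item
  off <- compute_offset(dm)
  expect_equal(des$offset, unname(off$log_offset[des$item_idx]))
})

test_that("rank-deficient designs fail loudly naming aliased columns", {
  pool <- make_prey_pool(n_items = 10, group_proportions = c(1, 0, 0),
                         seed = 1)
  preds <- make_predators(62, 2, seed = 1)
  sim <- simulate_diet(pool, preds, mechanism_params(item_re_sd = 0),
                       class_size = 31)
  dm <- build_diet_matrix(sim$records, sim$classes, sim$pool)
  expect_error(build_design(dm), "aliased.*PreyTG")
})

test_that("Poisson IRLS reproduces closed-form special cases", {
  n <- 12
  design <- structure(list(
    y = rep(7, n), X = cbind("(Intercept)" = rep(1, n)),
    offset = rep(0, n), class_idx = integer(0), item_idx = integer(0),
    spec = cats_model_spec(random = character()), meta = list()),
    class = "cats_design")
  fit <- fit_poisson_glm(design)
  expect_true(fit$converged)
  expect_equal(unname(fit$coefficients), log(7), tolerance = 1e-8)

  ## with an offset, the fitted grand total matches the observed total
  set.seed(1)
  design$offset <- log(runif(n, 0.2, 2))
  design$y <- rpois(n, 5 * exp(design$offset))
  fit2 <- fit_poisson_glm(design)
  expect_equal(sum(fit2$fitted), sum(design$y), tolerance = 1e-6)
})

test_that("IRLS matches the dense grid-search oracle on random toys", {
  for (s in 1:8) {
    des <- toy_design(s)
    fit <- fit_poisson_glm(des)
    expect_true(fit$converged)
    expect_gte(fit$loglik, grid_oracle_loglik(des) - 1e-6)
  }
})

test_that("IRLS agrees with stats::glm estimates and standard errors", {
  des <- toy_design(99, n = 30)
  fit <- fit_poisson_glm(des)
  ref <- glm(des$y ~ des$X[, 2] + offset(des$offset), family = poisson())
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-7)
  expect_equal(unname(fit$se),
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$deviance, deviance(ref), tolerance = 1e-8)
})

test_that("rescaling the offset shifts only the intercept", {
  des <- toy_design(7, n = 20)
  fit1 <- fit_poisson_glm(des)
  des2 <- des
  des2$offset <- des$offset + log(3)
  fit2 <- fit_poisson_glm(des2)
  expect_equal(unname(fit2$coefficients[1]),
               unname(fit1$coefficients[1]) - log(3), tolerance = 1e-8)
  expect_equal(unname(fit2$coefficients[-1]),
               unname(fit1$coefficients[-1]), tolerance = 1e-8)

  ## logLik differences between nested fits are offset-scale invariant
  null1 <- des; null1$X <- des$X[, 1, drop = FALSE]
  null2 <- des2; null2$X <- des2$X[, 1, drop = FALSE]
  d1 <- fit1$loglik - fit_poisson_glm(null1)$loglik
  d2 <- fit2$loglik - fit_poisson_glm(null2)$loglik
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("pseudo R2 is zero for the null, monotone in added terms", {
  sim <- small_sim("H3", seed = 21)
  dm <- build_diet_matrix(sim$records, sim$classes, sim$pool)
  null_spec <- cats_model_spec(character(), character())
  null_fit <- fit_cats(dm, null_spec)
  expect_equal(pseudo_r2(null_fit, null_fit)$deviance_r2, 0)

  ladder <- list(
    cats_model_spec(c("PredBS"), character()),
    cats_model_spec(c("PredBS", "PreyBS"), character()),
    cats_model_spec(c("PredBS", "PreyBS", "PredBS:PreyBS"), character())
  )
  r2 <- vapply(ladder, function(sp)
    pseudo_r2(fit_cats(dm, sp), null_fit)$deviance_r2, numeric(1))
  expect_true(all(diff(c(0, r2)) >= -1e-10))
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("a saturated toy fit explains all deviance", {
  design <- structure(list(
    y = c(3, 9), X = cbind("(Intercept)" = c(1, 1), x = c(0, 1)),
    offset = c(0, 0), class_idx = integer(0), item_idx = integer(0),
    spec = cats_model_spec(random = character()), meta = list()),
    class = "cats_design")
  fit <- fit_poisson_glm(design)
  null_design <- design; null_design$X <- design$X[, 1, drop = FALSE]
  expect_gt(pseudo_r2(fit, fit_poisson_glm(null_design))$deviance_r2, 0.999)
})

test_that("predictions honour the offset and match training fitted values", {
  sim <- small_sim("H3", seed = 31)
  dm <- build_diet_matrix(sim$records, sim$classes, sim$pool)
  fit <- fit_cats(dm, cats_model_spec(c("PredBS", "PreyBS", "PredBS:PreyBS"),
                                      character()))
  it <- fit$design$meta$items$item_id[1]
  s0 <- fit$design$meta$s_raw[2]
  p1 <- predict_intensity(fit, s0, item_id = it)
  p2 <- predict_intensity(fit, s0, item_id = it,
                          pi = 2 * fit$design$meta$items$pi[1])
  expect_equal(p2 / p1, 2, tolerance = 1e-10)

  ## training rows reproduce the stored fitted values
  rows <- which(fit$design$item_idx == 1)
  for (c in c(1L, 3L)) {
    expect_equal(predict_intensity(fit, fit$design$meta$s_raw[c],
                                   item_id = it, class_index = c,
                                   include_random = TRUE),
                 fit$fitted[rows[fit$design$class_idx[rows] == c]],
                 tolerance = 1e-10)
  }
  expect_error(predict_intensity(fit, s0, group = "plankton",
                                 prey_size_mm = 2, pi = 0.1), "unknown")
  expect_warning(predict_intensity(fit, 200, item_id = it), "extrapolat")
})
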