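test_that("prey size percentiles use linear order-statistic interpolation", {
  pool <- data.frame(item_id = paste0("i", 1:7), taxon_label = "t",
                     trophic_group = c(rep("producer", 3),
                                       rep("herb_detr", 4)),
                     body_size_mm = c(1, 2, 3, 1, 2, 3, 4))
  expect_equal(prey_size_percentiles(pool, "producer", 0.5), 2)
  expect_equal(prey_size_percentiles(pool, "producer", 0), 1)
  expect_equal(prey_size_percentiles(pool, "herb_detr", 0.25), 1.75)
  expect_error(prey_size_percentiles(pool, "carnivore", 0.5), "no items")
  expect_error(prey_size_percentiles(pool, "plankton", 0.5), "unknown")
})

test_that("hypothesis labels enumerate the eight flag combinations", {
  combos <- expand.grid(m1 = c(FALSE, TRUE), m2 = c(FALSE, TRUE),
                        m3 = c(FALSE, TRUE))
  labels <- apply(combos, 1, function(f) hypothesis_label(as.logical(f)))
  expect_setequal(labels, c("none", paste0("H", 1:7)))
  expect_equal(anyDuplicated(labels), 0)
  expect_equal(hypothesis_label(c(FALSE, TRUE, TRUE)), "H6")
  expect_equal(hypothesis_label(c(TRUE, FALSE, TRUE)), "H5")
  expect_equal(hypothesis_label(c(TRUE, TRUE, FALSE)), "H4")
})

test_that("selection coefficients isolate the trait-dependent terms", {
  sim <- small_sim("H2", seed = 2)
  dm <- build_diet_matrix(sim$records, sim$classes, sim$pool)
  fit <- fit_cats(dm, cats_model_spec(
    c("PredBS", "PreyBS", "PreyTG", "PredBS:PreyBS", "PredBS:PreyTG"),
    character()))

  ## zeroing every trait coefficient flattens the curve exactly
  fit0 <- fit
  keep <- catselect:::trait_column_flags(names(fit0$coefficients))
  fit0$coefficients[keep] <- 0
  cv <- selection_coefficient(fit0, seq(20, 55, 5), "carnivore", 3)
  expect_equal(cv$value, rep(0, nrow(cv)))

  ## reference group at the standardization centre sits at exactly zero
  centre_size <- 10^fit$design$meta$prey_center
  cv0 <- selection_coefficient(fit, seq(20, 55, 5), "producer", centre_size)
  expect_equal(cv0$value, rep(0, nrow(cv0)), tolerance = 1e-12)

  ## curve contrasts equal linear-predictor contrasts (recombination
  ## identity: the choice of reference level cannot matter)
  s0 <- 40; size0 <- 2.5
  for (g in c("herb_detr", "carnivore")) {
    curve_diff <- selection_coefficient(fit, s0, g, size0)$value -
      selection_coefficient(fit, s0, "producer", size0)$value
    eta_diff <- log(predict_intensity(fit, s0, group = g,
                                      prey_size_mm = size0, pi = 1)) -
      log(predict_intensity(fit, s0, group = "producer",
                            prey_size_mm = size0, pi = 1))
    expect_equal(curve_diff, eta_diff, tolerance = 1e-8)
  }

  expect_warning(selection_coefficient(fit, 120, "producer", 1),
                 "extrapolat")
})

test_that("selection_curves covers groups x percentiles over the size range", {
  sim <- small_sim("H3", seed = 3)
  dm <- build_diet_matrix(sim$records, sim$classes, sim$pool)
  fit <- fit_cats(dm, cats_model_spec(c("PredBS", "PreyBS",
                                        "PredBS:PreyBS"), character()))
  curves <- selection_curves(fit, sim$pool)
  expect_equal(nrow(unique(curves[, c("group", "percentile")])), 9)
  rng <- fit$design$meta$s_raw_range
  expect_equal(range(curves$s_mm), rng)
  expect_true(all(is.finite(curves$value)))
})

test_that("fitted H6 curves cross: large producers gain preference with size", {
  ## the generating reward slope makes the large-producer curve overtake
  ## the small-producer curve towards large predator sizes
  excesses <- vapply(1:5, function(s) {
    rep <- run_pipeline(pipeline_config(preset = "H6", seed = s,
                                        ladder = "minimal"))
    rep$verdict$m3$inversion_excess
  }, numeric(1))
  expect_gt(mean(excesses > 0), 0.8)
  expect_gt(median(excesses), 0.4)
})

test_that("the classifier maps evidence patterns onto the Fig-1 hypotheses", {
  corr_pos <- fake_corr(r = 0.9, p = 1e-6)
  corr_null <- fake_corr(r = 0.1, p = 0.6)
  flat <- c(0.02, 0.01, -0.01)
  m2_gaps_s <- c(1.0, 1.5, 2.0)       # strong small-prey preference
  m2_gaps_l <- c(0.05, 0.1, 0.2)      # relaxed at large sizes

  cases <- list(
    list(lab = "none", cls = -2, quad = -12, gs = flat, gl = flat,
         corr = corr_null),
    list(lab = "H1", cls = 400, quad = -12, gs = flat, gl = flat,
         corr = corr_pos),
    list(lab = "H2", cls = -2, quad = 60, gs = m2_gaps_s, gl = m2_gaps_l,
         corr = corr_pos),
    list(lab = "H4", cls = 400, quad = 60, gs = m2_gaps_s, gl = m2_gaps_l,
         corr = corr_pos),
    ## reward trade-off: linear inversion, no curvature support
    list(lab = "H3", cls = -2, quad = -12, gs = c(0.8, 0.8, 0.8),
         gl = c(-0.8, -0.8, -0.8), corr = corr_null),
    list(lab = "H5", cls = 400, quad = -12, gs = c(0.8, 0.8, 0.8),
         gl = c(-0.8, -0.8, -0.8), corr = corr_pos),
    list(lab = "H6", cls = -2, quad = 60, gs = c(1.5, 2.0, 2.5),
         gl = c(-0.9, -0.3, 0.1), corr = corr_null),
    list(lab = "H7", cls = 400, quad = 60, gs = c(1.5, 2.0, 2.5),
         gl = c(-0.9, -0.3, 0.1), corr = corr_pos)
  )
  for (cs in cases) {
    v <- mechanism_support(fake_comparison(cs$cls, cs$quad),
                           fit = NULL,
                           fake_curves(cs$gs, cs$gl),
                           cs$corr)
    expect_equal(v$hypothesis, cs$lab,
                 label = paste("case", cs$lab, "->", v$hypothesis))
  }
})

test_that("growing avoidance of large carnivorous prey is flagged, not scored", {
  v <- mechanism_support(fake_comparison(-2, 60),
                         fit = NULL,
                         fake_curves(c(1.0, 1.5, 0.5), c(0.05, 0.1, 1.4)),
                         fake_corr(0.1, 0.6))
  expect_true(v$carnivore_large_avoidance)
  v2 <- mechanism_support(fake_comparison(-2, 60),
                          fit = NULL,
                          fake_curves(c(1.0, 1.5, 2.0),
                                      c(0.05, 0.1, 0.2)),
                          fake_corr(0.1, 0.6))
  expect_false(v2$carnivore_large_avoidance)

  expect_error(
    mechanism_support(fake_comparison(0, 0), NULL,
                      fake_curves(c(1, 1, 1), c(0, 0, 0))[1:41, ],
                      fake_corr()),
    "missing selection curve")
})
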