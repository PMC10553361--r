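test_that("prey pool respects proportions, determinism and degenerate simplex", {
  p1 <- make_prey_pool(n_items = 3, group_proportions = c(1, 0, 0), seed = 2)
  expect_equal(as.character(p1$trophic_group), rep("producer", 3))

  expect_identical(make_prey_pool(seed = 7), make_prey_pool(seed = 7))
  expect_false(identical(make_prey_pool(seed = 7), make_prey_pool(seed = 8)))

  ## multinomial 99% envelope oracle (binomial marginals) at n = 300
  pool <- make_prey_pool(n_items = 300,
                         group_proportions = c(0.2, 0.5, 0.3), seed = 1)
  counts <- table(pool$trophic_group)
  for (k in 1:3) {
    pr <- c(0.2, 0.5, 0.3)[k]
    expect_gte(counts[[k]], qbinom(0.005, 300, pr))
    expect_lte(counts[[k]], qbinom(0.995, 300, pr))
  }

  expect_error(make_prey_pool(group_proportions = c(0.5, 0.5, 0.5)),
               "summing to 1")
  expect_error(make_prey_pool(n_items = 2), ">= 3|smaller")
})

test_that("predator table covers the length range deterministically", {
  tab <- make_predators(619, 4, 15, 60, seed = 3)
  expect_equal(nrow(tab), 619)
  expect_true(all(tab$standard_length_mm >= 15 &
                    tab$standard_length_mm <= 60))
  expect_equal(sort(unique(tab$species)), paste0("sp_", 1:4))

  one <- make_predators(1, 2, 10, 20, seed = 1)
  expect_equal(nrow(one), 1)
  expect_true(one$standard_length_mm >= 10 && one$standard_length_mm <= 20)

  expect_identical(make_predators(seed = 4), make_predators(seed = 4))
  expect_error(make_predators(length_min = -5), "length_min")
  expect_error(make_predators(length_min = 50, length_max = 40), "smaller")
})

test_that("mechanism params force switched-off components to zero", {
  p <- mechanism_params(include_m1 = FALSE, demand_slope = 2,
                        include_m2 = FALSE, gape_penalty = 5,
                        include_m3 = FALSE, reward_slope = 1,
                        group_shift = c(producer = -1, herb_detr = 0,
                                        carnivore = 1))
  expect_equal(p$demand_slope, 0)
  expect_equal(p$gape_penalty, 0)
  expect_equal(p$reward_slope, 0)
  expect_equal(unname(p$group_shift), c(0, 0, 0))

  expect_error(mechanism_params(class_re_sd = -1), "class_re_sd")
  expect_error(
    mechanism_params(include_m3 = TRUE,
                     group_shift = c(producer = 1, herb_detr = 0,
                                     carnivore = -1)),
    "non-decreasing")
})

test_that("scenario presets map onto the Fig-1 style mechanism combinations", {
  expect_true(scenario_preset("H1")$params$include_m1)
  expect_false(scenario_preset("H1")$params$include_m2)
  h6 <- scenario_preset("H6")$params
  expect_false(h6$include_m1)
  expect_true(h6$include_m2 && h6$include_m3)
  h7 <- scenario_preset("H7")$params
  expect_true(h7$include_m1 && h7$include_m2 && h7$include_m3)
  expect_error(scenario_preset("H8"), "unknown preset")
})

test_that("intensity evaluates the stated log-linear form", {
  pool <- tiny_pool()
  off <- mechanism_params(base_log_abundance = 0)
  expect_equal(intensity(off, s = 0.7, pool), rep(1, 6))

  ## M2 exact value: kappa = 2, tau = 1, prey 3 mm above the gape line
  s_raw <- 30
  pars <- mechanism_params(include_m2 = TRUE, gape_intercept = 0,
                           gape_slope = 0.1, gape_sharpness = 1,
                           gape_penalty = 2, base_log_abundance = 0.4)
  item <- data.frame(item_id = "x", taxon_label = "x",
                     trophic_group = "carnivore",
                     body_size_mm = 0.1 * s_raw + 3)
  expect_equal(intensity(pars, 0, validate_prey_pool(item), s_raw = s_raw),
               exp(0.4 - 2 * log(1 + exp(3))), tolerance = 1e-12)

  ## softplus -> 0 limit: prey far below the gape carries no penalty
  small_item <- data.frame(item_id = "y", taxon_label = "y",
                           trophic_group = "producer",
                           body_size_mm = 0.01)
  pars2 <- mechanism_params(include_m2 = TRUE, gape_sharpness = 0.2,
                            gape_penalty = 50, base_log_abundance = 0.4)
  expect_equal(intensity(pars2, 0, validate_prey_pool(small_item),
                         s_raw = 60),
               exp(0.4), tolerance = 1e-6)

  expect_error(intensity(pars, 0, pool), "s_raw")
  pars3 <- mechanism_params(include_m3 = TRUE)
  expect_error(intensity(pars3, 0, pool), "prey_z")
})

test_that("simulate_diet is deterministic and honours degenerate settings", {
  pool <- make_prey_pool(n_items = 12, seed = 1)
  preds <- make_predators(62, 2, seed = 1)

  zero <- simulate_diet(pool, preds,
                        mechanism_params(base_log_abundance = -Inf,
                                         item_re_sd = 0),
                        class_size = 31)
  expect_equal(nrow(zero$records), 0)
  expect_true(all(zero$truth$class_counts == 0))

  pars <- mechanism_params(include_m1 = TRUE, seed = 9)
  s1 <- simulate_diet(pool, preds, pars, class_size = 31)
  s2 <- simulate_diet(pool, preds, pars, class_size = 31)
  expect_identical(s1$records, s2$records)
})

test_that("per-item random streams are stable when the pool grows", {
  preds <- make_predators(62, 2, seed = 1)
  pool <- make_prey_pool(n_items = 10, seed = 3)
  extra <- data.frame(item_id = "item_new", taxon_label = "extra",
                      trophic_group = "carnivore", body_size_mm = 4,
                      stringsAsFactors = FALSE)
  pool_plus <- validate_prey_pool(rbind(as.data.frame(pool), extra))
  pars <- mechanism_params(include_m1 = TRUE, seed = 5)
  a <- simulate_diet(pool, preds, pars, class_size = 31)
  b <- simulate_diet(pool_plus, preds, pars, class_size = 31)
  expect_equal(a$truth$class_counts[, pool$item_id],
               b$truth$class_counts[, pool$item_id])
})

test_that("with all mechanisms off counts are plain Poisson (dispersion test)", {
  ## ~10,000 cells, constant mean n_c * exp(base)
  pool <- make_prey_pool(n_items = 500, seed = 2)
  preds <- make_predators(620, 4, seed = 2)
  pars <- mechanism_params(base_log_abundance = log(0.8), item_re_sd = 0,
                           class_re_sd = 0, seed = 11)
  sim <- simulate_diet(pool, preds, pars, class_size = 31)
  y <- as.numeric(sim$truth$class_counts)
  mu <- as.numeric(sim$truth$expected_counts)
  expect_equal(length(y), 10000)
  stat <- sum((y - mu)^2 / mu)
  ## chi-square dispersion test at alpha = 0.01 (two-sided)
  expect_gt(stat, qchisq(0.005, length(y)))
  expect_lt(stat, qchisq(0.995, length(y)))
})

test_that("M1 makes expected class totals strictly increasing in size", {
  pool <- make_prey_pool(n_items = 30, seed = 4)
  preds <- make_predators(310, 4, seed = 4)
  pars <- mechanism_params(include_m1 = TRUE, class_re_sd = 0,
                           item_re_sd = 0, seed = 1)
  sim <- simulate_diet(pool, preds, pars, class_size = 31)
  totals <- rowSums(sim$truth$expected_counts)
  expect_true(all(diff(totals) > 0))
})

test_that("raising the gape penalty lowers the expected share above the gape line", {
  pool <- make_prey_pool(n_items = 40, seed = 6)
  preds <- make_predators(310, 4, seed = 6)
  shares <- sapply(c(0.5, 1.2, 2.5), function(kap) {
    pars <- mechanism_params(include_m2 = TRUE, gape_penalty = kap,
                             gape_sharpness = 1, class_re_sd = 0,
                             item_re_sd = 0, seed = 1)
    sim <- simulate_diet(pool, preds, pars, class_size = 31)
    gape <- 0.2 * sim$classes$classes$mean_length_mm
    above <- outer(gape, pool$body_size_mm, `<`)
    sum(sim$truth$expected_counts[above]) / sum(sim$truth$expected_counts)
  })
  expect_true(all(diff(shares) < 0))
})

test_that("energy demand induces a strong count-size correlation", {
  ## a = 0.5, 20 classes, expected counts >= 50 per cell at base
  rs <- vapply(1:10, function(s) {
    sim <- simulate_preset("H1", seed = s, base_log_abundance = log(2),
                           class_re_sd = 0.2)
    dmat <- build_diet_matrix(sim$records, sim$classes, sim$pool)
    prey_count_size_correlation(dmat)$r
  }, numeric(1))
  expect_true(all(rs > 0.8))
})
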