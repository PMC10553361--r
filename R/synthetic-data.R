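## Synthetic stomach-content generator.
##
## Counts arise from a log-linear Poisson intensity with three separately
## switchable components, one per candidate prey-selection mechanism:
##   M1 energy demand      -- a trait-independent log-rate increment a*s that
##                            raises total consumption with predator size,
##                            plus class-level consumption-rate scatter;
##   M2 gape limitation    -- a smooth softplus penalty on prey larger than
##                            the gape line g0 + g1 * predator length;
##   M3 optimal foraging   -- a reward interaction rho * s * z between
##                            standardized predator size and standardized
##                            log prey size, plus per-trophic-group slopes
##                            delta_k of log-preference on predator size.
## Each component maps onto an identifiable block of the CATS regression:
## M1 onto the size-class random effect and the count-size trend, M2 and M3
## onto the predator-size x prey-trait fixed effects.

#' Construct a synthetic prey pool
#'
#' Draws `n_items` prey items across the three trophic groups with
#' lognormally distributed body sizes, emulating a pond invertebrate/plant
#' prey spectrum spanning roughly 0.1--20 mm.
#'
#' @param n_items Number of prey items (>= number of groups with positive
#'   proportion).
#' @param group_proportions Length-3 probability vector (producer,
#'   herb_detr, carnivore); must sum to 1.
#' @param size_log_mean_by_group Mean of log body size (log mm) per group.
#' @param size_log_sd_by_group SD of log body size per group.
#' @param seed Integer seed; identical seeds give identical pools.
#'
#' @return A `prey_pool` data frame with columns `item_id`, `taxon_label`,
#'   `trophic_group` (factor with the canonical levels) and `body_size_mm`.
#' @export
make_prey_pool <- function(n_items = 60L,
                           group_proportions = c(0.25, 0.45, 0.30),
                           size_log_mean_by_group = log(c(0.8, 2.0, 3.0)),
                           size_log_sd_by_group = c(0.9, 0.7, 0.7),
                           seed = 1L) {
  n_items <- assert_count(n_items, "n_items", lower = 3L)
  if (length(group_proportions) != 3L || any(group_proportions < 0) ||
      abs(sum(group_proportions) - 1) > 1e-9) {
    stop("`group_proportions` must be a non-negative 3-vector summing to 1",
         call. = FALSE)
  }
  n_pos <- sum(group_proportions > 0)
  if (n_items < n_pos) {
    stop("`n_items` is smaller than the number of groups with positive ",
         "proportion", call. = FALSE)
  }
  stopifnot(length(size_log_mean_by_group) == 3L,
            length(size_log_sd_by_group) == 3L,
            all(size_log_sd_by_group >= 0))

  lv <- trophic_levels()
  set.seed(derive_seed(seed, 1L))
  counts <- as.integer(rmultinom(1L, n_items, group_proportions))
  ## A positive-proportion group must be represented: move items from the
  ## largest group if the multinomial draw left one empty.
  for (g in which(group_proportions > 0 & counts == 0L)) {
    donor <- which.max(counts)
    counts[donor] <- counts[donor] - 1L
    counts[g] <- counts[g] + 1L
  }
  group <- factor(rep(lv, counts), levels = lv)
  size <- exp(rnorm(n_items,
                    mean = rep(size_log_mean_by_group, counts),
                    sd = rep(size_log_sd_by_group, counts)))
  pool <- data.frame(
    item_id = sprintf("item_%03d", seq_len(n_items)),
    taxon_label = sprintf("%s_taxon_%03d", as.character(group),
                          seq_len(n_items)),
    trophic_group = group,
    body_size_mm = size,
    stringsAsFactors = FALSE
  )
  class(pool) <- c("prey_pool", "data.frame")
  validate_prey_pool(pool)
}

#' Validate a prey pool table
#'
#' Checks ids, trophic levels and positivity of body sizes; used by both the
#' generator and the file readers.
#'
#' @param pool Data frame with columns `item_id`, `trophic_group`,
#'   `body_size_mm`.
#' @return The validated pool, with `trophic_group` as a factor on the
#'   canonical levels, invisibly classed as `prey_pool`.
#' @export
validate_prey_pool <- function(pool) {
  req <- c("item_id", "trophic_group", "body_size_mm")
  miss <- setdiff(req, names(pool))
  if (length(miss)) {
    stop("prey pool is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(pool$item_id)) {
    stop("duplicate item_id in prey pool: ",
         paste(unique(pool$item_id[duplicated(pool$item_id)]),
               collapse = ", "), call. = FALSE)
  }
  bad <- !is.finite(pool$body_size_mm) | pool$body_size_mm <= 0
  if (any(bad)) {
    stop("non-positive or non-finite body_size_mm at row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  lv <- trophic_levels()
  grp <- as.character(pool$trophic_group)
  unknown <- setdiff(unique(grp), lv)
  if (length(unknown)) {
    stop("unknown trophic_group label(s): ",
         paste(unknown, collapse = ", "),
         "; allowed levels are: ", paste(lv, collapse = ", "), call. = FALSE)
  }
  pool$trophic_group <- factor(grp, levels = lv)
  if (!inherits(pool, "prey_pool")) class(pool) <- c("prey_pool", "data.frame")
  pool
}

#' Construct a synthetic predator table
#'
#' Standard lengths are drawn uniformly over the stated range (sufficient to
#' cover the size gradient) and species labels are assigned round-robin.
#'
#' @param n_individuals Number of predator individuals.
#' @param n_species Number of species labels.
#' @param length_min,length_max Standard-length range in mm (both > 0).
#' @param seed Integer seed.
#'
#' @return A `predator_table` data frame with `pred_id`, `species`,
#'   `standard_length_mm`.
#' @export
make_predators <- function(n_individuals = 619L, n_species = 4L,
                           length_min = 15, length_max = 60, seed = 1L) {
  n_individuals <- assert_count(n_individuals, "n_individuals")
  n_species <- assert_count(n_species, "n_species")
  length_min <- assert_number(length_min, "length_min", lower = 1e-12)
  length_max <- assert_number(length_max, "length_max", lower = 1e-12)
  if (length_min >= length_max) {
    stop("`length_min` must be smaller than `length_max`", call. = FALSE)
  }
  set.seed(derive_seed(seed, 2L))
  tab <- data.frame(
    pred_id = sprintf("pred_%04d", seq_len(n_individuals)),
    species = sprintf("sp_%d", ((seq_len(n_individuals) - 1L) %% n_species) + 1L),
    standard_length_mm = runif(n_individuals, length_min, length_max),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("predator_table", "data.frame")
  tab
}

#' Mechanism parameters for the synthetic generator
#'
#' Bundles the switchable components of the log-linear Poisson intensity.
#' When a mechanism flag is off its effect parameters are forced to zero, so
#' presets differ only in the components they activate.
#'
#' @param include_m1,include_m2,include_m3 Mechanism switches (energy demand,
#'   gape limitation, optimal foraging).
#' @param demand_slope M1: log-rate increment per unit standardized predator
#'   size.
#' @param gape_intercept,gape_slope M2 gape line `g0 + g1 * length` (mm of
#'   prey; `gape_slope` in mm prey per mm predator).
#' @param gape_sharpness M2 softplus scale tau in mm; `NA` means the
#'   convention `0.1 * gape_slope * median predator length`, resolved when
#'   simulating.
#' @param gape_penalty M2 penalty strength kappa (>= 0) multiplying the
#'   softplus excess.
#' @param gape_redistributes When TRUE (default) the gape penalty
#'   redistributes consumption instead of suppressing it: each size class's
#'   expected total intake is rescaled to what it would be without the
#'   penalty, so a gape-limited predator eats more accessible (small) prey
#'   rather than starving. Gape limitation then changes the diet
#'   composition of a class but not its consumption rate.
#' @param reward_slope M3 coefficient rho on standardized predator size times
#'   standardized log prey size.
#' @param group_shift M3 per-trophic-group slope delta_k of log-preference on
#'   standardized predator size, named vector over the three levels;
#'   must be non-decreasing producer <= herb_detr <= carnivore when M3 is on.
#' @param base_log_abundance Baseline log intensity per item (scalar or one
#'   value per item); `-Inf` is allowed and yields structural zeros.
#' @param class_re_sd,item_re_sd SDs of the class-level and item-level
#'   normal random effects (>= 0).
#' @param seed Master integer seed; per-(class, item) streams are derived
#'   from it so adding items does not perturb earlier draws.
#'
#' @return A `mechanism_params` list.
#' @export
mechanism_params <- function(include_m1 = FALSE, demand_slope = 0.5,
                             include_m2 = FALSE, gape_intercept = 0,
                             gape_slope = 0.2, gape_sharpness = NA_real_,
                             gape_penalty = 1.2, gape_redistributes = TRUE,
                             include_m3 = FALSE, reward_slope = 0.2,
                             group_shift = c(producer = -0.3, herb_detr = 0,
                                             carnivore = 0.3),
                             base_log_abundance = log(0.8),
                             class_re_sd = 0, item_re_sd = 0.3,
                             seed = 1L) {
  p <- list(
    include_m1 = assert_flag(include_m1, "include_m1"),
    demand_slope = assert_number(demand_slope, "demand_slope"),
    include_m2 = assert_flag(include_m2, "include_m2"),
    gape_intercept = assert_number(gape_intercept, "gape_intercept"),
    gape_slope = assert_number(gape_slope, "gape_slope"),
    gape_sharpness = if (is.na(gape_sharpness)) NA_real_ else
      assert_number(gape_sharpness, "gape_sharpness", lower = 1e-12),
    gape_penalty = assert_number(gape_penalty, "gape_penalty", lower = 0),
    gape_redistributes = assert_flag(gape_redistributes,
                                     "gape_redistributes"),
    include_m3 = assert_flag(include_m3, "include_m3"),
    reward_slope = assert_number(reward_slope, "reward_slope"),
    group_shift = group_shift,
    base_log_abundance = base_log_abundance,
    class_re_sd = assert_number(class_re_sd, "class_re_sd", lower = 0),
    item_re_sd = assert_number(item_re_sd, "item_re_sd", lower = 0),
    seed = assert_count(seed, "seed", lower = 0L)
  )
  if (!is.numeric(p$base_log_abundance) ||
      any(is.na(p$base_log_abundance)) ||
      any(p$base_log_abundance == Inf)) {
    stop("`base_log_abundance` must be numeric and < Inf", call. = FALSE)
  }
  lv <- trophic_levels()
  if (is.null(names(p$group_shift))) names(p$group_shift) <- lv
  if (!setequal(names(p$group_shift), lv)) {
    stop("`group_shift` must be named over: ", paste(lv, collapse = ", "),
         call. = FALSE)
  }
  p$group_shift <- p$group_shift[lv]
  ## switched-off mechanisms contribute exactly nothing
  if (!p$include_m1) p$demand_slope <- 0
  if (!p$include_m2) p$gape_penalty <- 0
  if (!p$include_m3) {
    p$reward_slope <- 0
    p$group_shift[] <- 0
  }
  if (p$include_m3 && is.unsorted(p$group_shift)) {
    stop("`group_shift` must be non-decreasing over ",
         "producer <= herb_detr <= carnivore when M3 is on", call. = FALSE)
  }
  class(p) <- "mechanism_params"
  p
}

#' Scenario presets H1--H7
#'
#' Maps each hypothesis label to its mechanism combination:
#' H1 = \{M1\}, H2 = \{M2\}, H3 = \{M3\}, H4 = \{M1,M2\}, H5 = \{M1,M3\},
#' H6 = \{M2,M3\}, H7 = \{M1,M2,M3\}. Effect sizes are the package defaults;
#' class-level random scatter is part of the energy-demand component and is
#' therefore only present when M1 is on.
#'
#' @param name One of `"H1"` .. `"H7"`.
#' @param seed Master seed stored in the parameters.
#' @param ... Overrides passed on to [mechanism_params()].
#' @return A `scenario_preset` list with elements `name` and `params`.
#' @export
scenario_preset <- function(name, seed = 1L, ...) {
  flags <- preset_flags(name)
  dots <- list(...)
  defaults <- list(include_m1 = flags[1L], include_m2 = flags[2L],
                   include_m3 = flags[3L],
                   gape_sharpness = 1.0,
                   class_re_sd = if (flags[1L]) 0.2 else 0,
                   seed = seed)
  args <- utils::modifyList(defaults, dots)
  out <- list(name = name, params = do.call(mechanism_params, args))
  class(out) <- "scenario_preset"
  out
}

preset_flags <- function(name) {
  map <- list(H1 = c(TRUE, FALSE, FALSE), H2 = c(FALSE, TRUE, FALSE),
              H3 = c(FALSE, FALSE, TRUE), H4 = c(TRUE, TRUE, FALSE),
              H5 = c(TRUE, FALSE, TRUE), H6 = c(FALSE, TRUE, TRUE),
              H7 = c(TRUE, TRUE, TRUE))
  if (!name %in% names(map)) {
    stop("unknown preset; use one of ", paste(names(map), collapse = ", "),
         call. = FALSE)
  }
  map[[name]]
}

#' Log-linear Poisson intensity of the generator
#'
#' Evaluates, for one predator size and one or more prey items,
#' \deqn{\lambda = \exp(b_i + a s + c + v_i - \kappa\,
#'   \mathrm{softplus}((x_i - g_0 - g_1 s_{raw})/\tau) + \rho s z_i +
#'   \delta_{k(i)} s)}
#' where `s` is the standardized predator size, `s_raw` the raw length in mm,
#' `x_i` the prey body size in mm and `z_i` the standardized log prey size.
#'
#' @param params A [mechanism_params()] object.
#' @param s Standardized predator size (finite scalar).
#' @param items One or more rows of a `prey_pool`.
#' @param class_effect,item_effect Realized random effects (scalar /
#'   per-item).
#' @param s_raw Raw predator length in mm; required when M2 is active.
#' @param prey_z Standardized log prey size per item; required when M3 is
#'   active.
#' @return Positive intensity vector, one value per item.
#' @export
intensity <- function(params, s, items, class_effect = 0, item_effect = 0,
                      s_raw = NULL, prey_z = NULL) {
  stopifnot(inherits(params, "mechanism_params"))
  s <- assert_number(s, "s")
  n <- nrow(items)
  base <- rep_len(params$base_log_abundance, n)
  eta <- base + class_effect + rep_len(item_effect, n)
  if (params$include_m1) eta <- eta + params$demand_slope * s
  if (params$include_m2 && params$gape_penalty > 0) {
    if (is.null(s_raw)) stop("`s_raw` is required when M2 is active",
                             call. = FALSE)
    tau <- params$gape_sharpness
    if (is.na(tau)) stop("unresolved `gape_sharpness`; set it or simulate ",
                         "through simulate_diet()", call. = FALSE)
    gape <- params$gape_intercept + params$gape_slope * s_raw
    eta <- eta - params$gape_penalty *
      softplus((items$body_size_mm - gape) / tau)
  }
  if (params$include_m3) {
    if (is.null(prey_z)) stop("`prey_z` is required when M3 is active",
                              call. = FALSE)
    delta <- params$group_shift[as.character(items$trophic_group)]
    eta <- eta + params$reward_slope * s * prey_z + unname(delta) * s
  }
  exp(eta)
}

#' Simulate stomach-content records
#'
#' Bins predators into equal-count size classes, draws class- and item-level
#' random effects, computes the intensity surface at class mean sizes, and
#' draws each (class, item) count as Poisson with exposure equal to the
#' class's member count. Class counts are then spread multinomially over the
#' class members to give per-individual records. Per-(class, item) random
#' streams are derived from the master seed so enlarging the prey pool never
#' perturbs earlier draws.
#'
#' @param prey_pool A `prey_pool`.
#' @param predators A `predator_table`.
#' @param params A [mechanism_params()] object.
#' @param class_size Individuals per size class (default 31).
#'
#' @return A `diet_simulation` list: `records` (pred_id, item_id, count;
#'   zero rows omitted), `pool`, `predators`, `classes`, and `truth` holding
#'   the resolved generating parameters, realized random effects, the
#'   expected-count matrix, and the standardization constants.
#' @export
simulate_diet <- function(prey_pool, predators, params, class_size = 31L) {
  prey_pool <- validate_prey_pool(prey_pool)
  stopifnot(inherits(params, "mechanism_params"))
  classes <- assign_size_classes(predators, class_size)
  C <- nrow(classes$classes)
  I <- nrow(prey_pool)

  params <- resolve_gape_sharpness(params, predators$standard_length_mm)
  s_raw <- classes$classes$mean_length_mm
  s <- standardize(s_raw)
  z <- standardize(log(prey_pool$body_size_mm))

  set.seed(derive_seed(params$seed, 3L))
  class_effects <- rnorm(C, 0, params$class_re_sd)

  ## Per-item streams: the item effect is the first draw of the stream and
  ## the item's counts follow in the same stream, so the draws for item i
  ## are untouched by the presence of any other item.
  item_effects <- vapply(seq_len(I), function(i) {
    set.seed(derive_seed(params$seed, 1000L + i))
    rnorm(1L, 0, params$item_re_sd)
  }, numeric(1L))

  lambda <- matrix(0, C, I, dimnames = list(NULL, prey_pool$item_id))
  for (c in seq_len(C)) {
    lambda[c, ] <- intensity(params, s[c], prey_pool,
                             class_effect = class_effects[c],
                             item_effect = item_effects,
                             s_raw = s_raw[c], prey_z = z)
  }
  if (params$include_m2 && params$gape_penalty > 0 &&
      params$gape_redistributes) {
    ## class-wise rescaling to the no-penalty total intake: gape limitation
    ## redirects consumption to accessible prey, it does not reduce it
    params0 <- params
    params0$gape_penalty <- 0
    for (c in seq_len(C)) {
      lam0 <- intensity(params0, s[c], prey_pool,
                        class_effect = class_effects[c],
                        item_effect = item_effects,
                        s_raw = s_raw[c], prey_z = z)
      tot <- sum(lambda[c, ])
      if (tot > 0) lambda[c, ] <- lambda[c, ] * (sum(lam0) / tot)
    }
  }

  counts <- matrix(0L, C, I, dimnames = list(NULL, prey_pool$item_id))
  n_c <- classes$classes$n
  member_by_class <- split(classes$members$pred_id,
                           classes$members$class_index)
  rec_pred <- rec_item <- rec_count <- vector("list", I)
  for (i in seq_len(I)) {
    set.seed(derive_seed(params$seed, 1000L + i))
    rnorm(1L)                       # skip the item-effect draw of the stream
    y <- rpois(C, n_c * lambda[, i])
    counts[, i] <- y
    pid <- character(0); cnt <- integer(0)
    for (c in which(y > 0L)) {
      alloc <- as.integer(rmultinom(1L, y[c], rep(1, n_c[c])))
      keep <- alloc > 0L
      pid <- c(pid, member_by_class[[c]][keep])
      cnt <- c(cnt, alloc[keep])
    }
    if (length(pid)) {
      rec_pred[[i]] <- pid
      rec_item[[i]] <- rep(prey_pool$item_id[i], length(pid))
      rec_count[[i]] <- cnt
    }
  }
  records <- data.frame(pred_id = unlist(rec_pred) %||% character(),
                        item_id = unlist(rec_item) %||% character(),
                        count = unlist(rec_count) %||% integer(),
                        stringsAsFactors = FALSE)
  rownames(records) <- NULL

  out <- list(
    records = records,
    pool = prey_pool,
    predators = predators,
    classes = classes,
    truth = list(params = params, class_effects = class_effects,
                 item_effects = item_effects,
                 expected_counts = sweep(lambda, 1L, n_c, `*`),
                 class_counts = counts,
                 pred_size = list(center = attr(s, "center"),
                                  scale = attr(s, "scale")),
                 prey_logsize = list(center = attr(z, "center"),
                                     scale = attr(z, "scale")))
  )
  class(out) <- "diet_simulation"
  out
}

resolve_gape_sharpness <- function(params, lengths) {
  if (params$include_m2 && is.na(params$gape_sharpness)) {
    params$gape_sharpness <- 0.1 * params$gape_slope *
      stats::median(lengths)
  }
  params
}

#' Simulate a preset scenario end to end
#'
#' Convenience wrapper generating a prey pool, a predator table and the
#' stomach-content records for one hypothesis preset under the study design
#' defaults (619 predators of 4 species, classes of 31, 60 prey items).
#'
#' @param preset A `scenario_preset` or a name `"H1"`..`"H7"`.
#' @param seed Master seed for pool, predators and counts.
#' @param n_individuals,n_items,class_size Design sizes.
#' @param ... Overrides forwarded to [scenario_preset()].
#' @return A `diet_simulation` (see [simulate_diet()]).
#' @export
simulate_preset <- function(preset, seed = 1L, n_individuals = 619L,
                            n_items = 60L, class_size = 31L, ...) {
  if (is.character(preset)) preset <- scenario_preset(preset, seed = seed, ...)
  pool <- make_prey_pool(n_items = n_items, seed = seed)
  preds <- make_predators(n_individuals = n_individuals, seed = seed)
  sim <- simulate_diet(pool, preds, preset$params, class_size = class_size)
  sim$preset <- preset$name
  sim
}
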