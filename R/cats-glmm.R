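## The CATS regression: a Poisson log-link (mixed) regression of the
## size-class x prey-item counts on predator size, prey traits and their
## interactions, with the pooled prey frequency as a log offset so that
## coefficients measure selection relative to availability.

cats_term_universe <- function() {
  c("PredBS", "PredBS2", "PreyBS", "PreyTG",
    "PredBS:PreyBS", "PredBS:PreyTG", "PreyBS:PreyTG",
    "PredBS2:PreyBS", "PredBS2:PreyTG",
    "PredBS:PreyBS:PreyTG", "PredBS2:PreyBS:PreyTG")
}

cats_term_parents <- function() {
  list(
    "PredBS" = character(),
    "PredBS2" = "PredBS",
    "PreyBS" = character(),
    "PreyTG" = character(),
    "PredBS:PreyBS" = c("PredBS", "PreyBS"),
    "PredBS:PreyTG" = c("PredBS", "PreyTG"),
    "PreyBS:PreyTG" = c("PreyBS", "PreyTG"),
    "PredBS2:PreyBS" = c("PredBS2", "PredBS:PreyBS"),
    "PredBS2:PreyTG" = c("PredBS2", "PredBS:PreyTG"),
    "PredBS:PreyBS:PreyTG" = c("PredBS:PreyBS", "PredBS:PreyTG",
                               "PreyBS:PreyTG"),
    "PredBS2:PreyBS:PreyTG" = c("PredBS2:PreyBS", "PredBS2:PreyTG",
                                "PredBS:PreyBS:PreyTG")
  )
}

#' Specify a CATS model
#'
#' A model is a subset of the fixed-term universe (`PredBS`, `PredBS2`,
#' `PreyBS`, `PreyTG` and their two- and three-way interactions), a subset
#' of the random intercepts (`class_id`, `item_id`) and an offset switch.
#' The intercept is always present, and marginality is enforced: every
#' interaction requires its lower-order terms.
#'
#' @param fixed Character vector of fixed terms (possibly empty).
#' @param random Character subset of `c("class_id", "item_id")`.
#' @param use_offset Include the log pooled-frequency offset (default TRUE).
#' @return A `cats_model_spec`.
#' @export
cats_model_spec <- function(fixed = character(), random = character(),
                            use_offset = TRUE) {
  universe <- cats_term_universe()
  unknown <- setdiff(fixed, universe)
  if (length(unknown)) {
    stop("unknown fixed term(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  fixed <- universe[universe %in% fixed]
  parents <- cats_term_parents()
  for (tm in fixed) {
    missing_par <- setdiff(parents[[tm]], fixed)
    if (length(missing_par)) {
      stop("marginality violated: term '", tm, "' requires ",
           paste(missing_par, collapse = ", "), call. = FALSE)
    }
  }
  unknown_r <- setdiff(random, c("class_id", "item_id"))
  if (length(unknown_r)) {
    stop("unknown random term(s): ", paste(unknown_r, collapse = ", "),
         call. = FALSE)
  }
  random <- c("class_id", "item_id")[c("class_id", "item_id") %in% random]
  out <- list(fixed = fixed, random = random,
              use_offset = assert_flag(use_offset, "use_offset"))
  class(out) <- "cats_model_spec"
  out
}

#' The full CATS model
#'
#' `(PredBS + PredBS2)` crossed with `(PreyBS + PreyTG + PreyBS:PreyTG)`,
#' both random intercepts, and the prior-abundance offset.
#'
#' @return A `cats_model_spec`.
#' @export
full_cats_model <- function() {
  cats_model_spec(fixed = cats_term_universe(),
                  random = c("class_id", "item_id"), use_offset = TRUE)
}

#' @export
print.cats_model_spec <- function(x, ...) {
  cat("CATS model:",
      if (length(x$fixed)) paste(x$fixed, collapse = " + ") else
        "intercept only",
      "\n  random:",
      if (length(x$random)) paste(x$random, collapse = " + ") else "none",
      " offset:", x$use_offset, "\n")
  invisible(x)
}

spec_signature <- function(spec) {
  paste0("f(", paste(spec$fixed, collapse = "+"), ")|r(",
         paste(spec$random, collapse = "+"), ")|o(",
         as.integer(spec$use_offset), ")")
}

## Fixed-effect design columns for given standardized covariates. tgh / tgc
## are the treatment-coded indicators with producer as reference.
cats_design_columns <- function(terms, s, z, tgh, tgc) {
  n <- length(s)
  cols <- list("(Intercept)" = rep(1, n))
  add <- function(name, v) cols[[name]] <<- v
  for (tm in terms) {
    switch(tm,
      "PredBS" = add("PredBS", s),
      "PredBS2" = add("PredBS2", s^2),
      "PreyBS" = add("PreyBS", z),
      "PreyTG" = {
        add("PreyTGherb_detr", tgh)
        add("PreyTGcarnivore", tgc)
      },
      "PredBS:PreyBS" = add("PredBS:PreyBS", s * z),
      "PredBS:PreyTG" = {
        add("PredBS:PreyTGherb_detr", s * tgh)
        add("PredBS:PreyTGcarnivore", s * tgc)
      },
      "PreyBS:PreyTG" = {
        add("PreyBS:PreyTGherb_detr", z * tgh)
        add("PreyBS:PreyTGcarnivore", z * tgc)
      },
      "PredBS2:PreyBS" = add("PredBS2:PreyBS", s^2 * z),
      "PredBS2:PreyTG" = {
        add("PredBS2:PreyTGherb_detr", s^2 * tgh)
        add("PredBS2:PreyTGcarnivore", s^2 * tgc)
      },
      "PredBS:PreyBS:PreyTG" = {
        add("PredBS:PreyBS:PreyTGherb_detr", s * z * tgh)
        add("PredBS:PreyBS:PreyTGcarnivore", s * z * tgc)
      },
      "PredBS2:PreyBS:PreyTG" = {
        add("PredBS2:PreyBS:PreyTGherb_detr", s^2 * z * tgh)
        add("PredBS2:PreyBS:PreyTGcarnivore", s^2 * z * tgc)
      },
      stop("unknown term: ", tm)
    )
  }
  do.call(cbind, cols)
}

## Which design columns carry prey-trait information (PreyBS or PreyTG,
## including all their interactions)? Used by the selection-coefficient
## extraction.
trait_column_flags <- function(colnames) {
  grepl("PreyBS|PreyTG", colnames)
}

#' Build design matrices for the CATS regression
#'
#' Lays out one row per (size class, retained prey item) cell; items never
#' observed anywhere are excluded (their offset is undefined). Predator size
#' is the standardized class mean standard length, with the quadratic term
#' computed after standardization; prey size is standardized log10 body size
#' by default; the trophic group is treatment-coded with producers as
#' reference.
#'
#' @param matrix A `diet_matrix`.
#' @param spec A `cats_model_spec` (default: the full model).
#' @param log10_size Log10-transform prey size before standardizing
#'   (default TRUE; FALSE standardizes the raw mm scale).
#' @return A `cats_design`: list `y`, `X`, `class_idx`, `item_idx`,
#'   `offset` (log pooled frequency per row, or zeros), `spec`, `meta`
#'   (standardization constants, item table, class sizes, retained pi).
#' @export
build_design <- function(matrix, spec = full_cats_model(),
                         log10_size = TRUE) {
  stopifnot(inherits(matrix, "diet_matrix"),
            inherits(spec, "cats_model_spec"))
  off <- compute_offset(matrix)
  keep_items <- match(off$retained, matrix$pool$item_id)
  pool <- matrix$pool[keep_items, , drop = FALSE]
  counts <- matrix$counts[, keep_items, drop = FALSE]
  C <- nrow(counts)
  I <- ncol(counts)

  s_raw <- matrix$classes$classes$mean_length_mm
  s_std <- standardize(s_raw)
  size_cov <- if (log10_size) log10(pool$body_size_mm) else pool$body_size_mm
  z_std <- standardize(size_cov)

  class_idx <- rep(seq_len(C), times = I)
  item_idx <- rep(seq_len(I), each = C)
  y <- as.numeric(counts[cbind(class_idx, item_idx)])

  s <- as.numeric(s_std)[class_idx]
  z <- as.numeric(z_std)[item_idx]
  grp <- pool$trophic_group[item_idx]
  tgh <- as.numeric(grp == "herb_detr")
  tgc <- as.numeric(grp == "carnivore")

  X <- cats_design_columns(spec$fixed, s, z, tgh, tgc)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  offset <- if (spec$use_offset) as.numeric(off$log_offset[item_idx]) else
    rep(0, length(y))

  out <- list(
    y = y, X = X, class_idx = class_idx, item_idx = item_idx,
    offset = offset, spec = spec,
    meta = list(
      pred_center = attr(s_std, "center"), pred_scale = attr(s_std, "scale"),
      prey_center = attr(z_std, "center"), prey_scale = attr(z_std, "scale"),
      log10_size = log10_size,
      s_raw_range = range(s_raw), s_raw = s_raw,
      class_n = matrix$classes$classes$n,
      items = data.frame(item_id = pool$item_id,
                         trophic_group = pool$trophic_group,
                         body_size_mm = pool$body_size_mm,
                         z = as.numeric(z_std),
                         pi = as.numeric(off$pi[off$retained]),
                         stringsAsFactors = FALSE),
      dropped_items = off$dropped
    )
  )
  class(out) <- "cats_design"
  out
}

poisson_loglik <- function(y, mu) {
  sum(y * log(ifelse(mu > 0, mu, 1)) - mu - lgamma(y + 1))
}

poisson_deviance <- function(y, mu) {
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

## Closed-form intercept-plus-offset null: exp(b0) = sum(y) / sum(exp(off)).
null_deviance_offset <- function(y, offset) {
  mu0 <- exp(offset) * sum(y) / sum(exp(offset))
  poisson_deviance(y, mu0)
}

#' Fit the fixed-effects CATS Poisson regression
#'
#' Plain iteratively reweighted least squares for the Poisson log-link model
#' with offset; no random effects. This transparent fitter doubles as the
#' reference for the mixed fitter's zero-variance limit.
#'
#' @param design A `cats_design`.
#' @param tol Relative deviance convergence tolerance.
#' @param maxit Maximum IRLS iterations.
#' @return A `cats_fit` with coefficients, standard errors (inverse Fisher
#'   information), log-likelihood, AIC, deviances and convergence flags.
#' @export
fit_poisson_glm <- function(design, tol = 1e-10, maxit = 100L) {
  stopifnot(inherits(design, "cats_design"))
  y <- design$y
  X <- design$X
  offset <- design$offset
  p <- ncol(X)
  beta <- numeric(p)
  beta[1L] <- log(max(mean(y), 1e-8)) - mean(offset)
  dev_old <- Inf
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  for (iter in seq_len(maxit)) {
    eta <- drop(X %*% beta) + offset
    if (max(eta) > 300) { diverged <- TRUE; break }
    mu <- exp(eta)
    info <- crossprod(X, X * mu)
    score <- crossprod(X, y - mu)
    step <- tryCatch(solve(info, score), error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    ## step halving: Poisson deviance must not increase
    fac <- 1
    repeat {
      beta_new <- beta + fac * drop(step)
      eta_new <- drop(X %*% beta_new) + offset
      if (max(eta_new) <= 300) {
        dev_new <- poisson_deviance(y, exp(eta_new))
        if (is.finite(dev_new) && dev_new <= dev_old + 1e-12) break
      }
      fac <- fac / 2
      if (fac < 1e-10) { dev_new <- dev_old; beta_new <- beta; break }
    }
    beta <- beta_new
    if (is.finite(dev_old) &&
        abs(dev_old - dev_new) < tol * (abs(dev_new) + 0.1)) {
      dev_old <- dev_new
      converged <- TRUE
      break
    }
    dev_old <- dev_new
  }
  if (max(abs(beta)) > 1e4) diverged <- TRUE
  eta <- drop(X %*% beta) + offset
  mu <- exp(pmin(eta, 300))
  info <- crossprod(X, X * mu)
  vcov <- tryCatch(solve(info), error = function(e) matrix(NA, p, p))
  ll <- poisson_loglik(y, mu)
  new_cats_fit(
    coefficients = setNames(drop(beta), colnames(X)),
    se = setNames(sqrt(pmax(diag(vcov), 0)), colnames(X)),
    vcov = vcov,
    sigma2 = setNames(numeric(0), character(0)),
    u = list(),
    loglik = ll,
    n_params = p,
    deviance = poisson_deviance(y, mu),
    null_deviance = null_deviance_offset(y, design$offset),
    fitted = mu,
    converged = converged && !diverged,
    boundary = logical(0),
    n_iter = iter,
    design = design
  )
}

new_cats_fit <- function(coefficients, se, vcov, sigma2, u, loglik, n_params,
                         deviance, null_deviance, fitted, converged,
                         boundary, n_iter, design, outer_evals = NA_integer_) {
  out <- list(coefficients = coefficients, se = se, vcov = vcov,
              sigma2 = sigma2, u = u, loglik = loglik,
              aic = -2 * loglik + 2 * n_params, n_params = n_params,
              deviance = deviance, null_deviance = null_deviance,
              fitted = fitted, converged = converged, boundary = boundary,
              n_iter = n_iter, outer_evals = outer_evals, design = design,
              spec = design$spec)
  class(out) <- "cats_fit"
  out
}

#' @export
print.cats_fit <- function(x, ...) {
  cat("CATS Poisson", if (length(x$sigma2)) "mixed" else "fixed-effects",
      "fit\n")
  cat(sprintf("  logLik %.3f  AIC %.3f  deviance %.3f  (params %d)\n",
              x$loglik, x$aic, x$deviance, x$n_params))
  if (length(x$sigma2)) {
    cat("  random-intercept variances:",
        paste(sprintf("%s = %.4g%s", names(x$sigma2), x$sigma2,
                      ifelse(x$boundary, " (boundary)", "")),
              collapse = ", "), "\n")
  }
  if (!x$converged) cat("  WARNING: fit flagged as non-converged\n")
  print(coef_table(x), digits = 4)
  invisible(x)
}

#' Coefficient table of a CATS fit
#'
#' @param fit A `cats_fit`.
#' @return Data frame with term, estimate, SE, z and two-sided p.
#' @export
coef_table <- function(fit) {
  z <- fit$coefficients / fit$se
  data.frame(term = names(fit$coefficients),
             estimate = unname(fit$coefficients),
             se = unname(fit$se), z = unname(z),
             p = unname(2 * pnorm(-abs(z))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the CATS Poisson mixed model by Laplace approximation
#'
#' Inner loop: penalized IRLS jointly in the fixed effects and the random
#' intercepts given the variance components. Outer loop: deterministic
#' quasi-Newton search over the log random-effect SDs maximizing the Laplace
#' marginal log-likelihood, started at sigma = 1 with the GLM coefficients
#' as inner warm start. The parameter count is the number of fixed effects
#' plus the number of variance components.
#'
#' @param design A `cats_design` whose spec has at least one random term.
#' @param inner_tol,outer_tol Convergence tolerances for the penalized IRLS
#'   objective and the marginal log-likelihood.
#' @param max_outer Maximum marginal-likelihood evaluations before the fit
#'   is flagged.
#' @param sigma_lower Lower box bound for each SD; an estimate at this bound
#'   is reported as variance 0 with a boundary flag.
#' @return A `cats_fit` with random-effect variances and predicted random
#'   effects.
#' @export
fit_poisson_glmm <- function(design, inner_tol = 1e-10, outer_tol = 1e-8,
                             max_outer = 500L, sigma_lower = 1e-4) {
  stopifnot(inherits(design, "cats_design"))
  rterms <- design$spec$random
  if (!length(rterms)) {
    stop("no random terms in the model spec; use fit_poisson_glm()",
         call. = FALSE)
  }
  has_class <- "class_id" %in% rterms
  has_item <- "item_id" %in% rterms
  qc <- if (has_class) max(design$class_idx) else 0L
  qi <- if (has_item) max(design$item_idx) else 0L
  p <- ncol(design$X)
  m <- p + qc + qi

  glm_fit <- fit_poisson_glm(design)
  warm <- new.env(parent = emptyenv())
  warm$theta <- c(glm_fit$coefficients, numeric(qc + qi))
  n_evals <- 0L

  inner <- function(log_sigma, want_hessian = FALSE) {
    sc <- if (has_class) exp(log_sigma[["class_id"]]) else 0
    si <- if (has_item) exp(log_sigma[["item_id"]]) else 0
    cpp_pirls(design$X, design$y, design$offset,
              if (has_class) design$class_idx else integer(0),
              if (has_item) design$item_idx else integer(0),
              sc, si, warm$theta, inner_tol, 200L, want_hessian)
  }
  objective <- function(ls) {
    n_evals <<- n_evals + 1L
    names(ls) <- rterms
    res <- inner(ls)
    if (res$diverged) return(1e10)
    warm$theta <- res$coef
    -res$loglik
  }

  start <- setNames(rep(0, length(rterms)), rterms)
  opt <- nlminb(start, objective,
                lower = log(sigma_lower), upper = log(30),
                control = list(rel.tol = outer_tol,
                               eval.max = max_outer, iter.max = max_outer))
  log_sigma <- setNames(opt$par, rterms)
  fin <- inner(log_sigma, want_hessian = TRUE)

  vcov_all <- tryCatch(solve(fin$hessian), error = function(e)
    matrix(NA, m, m))
  se <- sqrt(pmax(diag(vcov_all)[seq_len(p)], 0))
  boundary <- setNames(opt$par <= log(sigma_lower) + 1e-6, rterms)
  sigma2 <- exp(2 * opt$par)
  sigma2[boundary] <- 0
  u <- list()
  if (has_class) u$class_id <- fin$coef[p + seq_len(qc)]
  if (has_item) u$item_id <- fin$coef[p + qc + seq_len(qi)]

  new_cats_fit(
    coefficients = setNames(fin$coef[seq_len(p)], colnames(design$X)),
    se = setNames(se, colnames(design$X)),
    vcov = vcov_all[seq_len(p), seq_len(p), drop = FALSE],
    sigma2 = setNames(sigma2, rterms),
    u = u,
    loglik = fin$loglik,
    n_params = p + length(rterms),
    deviance = poisson_deviance(design$y, fin$fitted),
    null_deviance = null_deviance_offset(design$y, design$offset),
    fitted = fin$fitted,
    converged = (opt$convergence == 0 || opt$convergence == 1) &&
      fin$converged && n_evals <= max_outer,
    boundary = boundary,
    n_iter = fin$iter,
    design = design,
    outer_evals = n_evals
  )
}

#' Fit a CATS model spec to a diet matrix
#'
#' Dispatches to the mixed fitter when the spec has random terms and to the
#' fixed-effects fitter otherwise.
#'
#' @param matrix A `diet_matrix`.
#' @param spec A `cats_model_spec`.
#' @param log10_size Passed to [build_design()].
#' @param ... Passed to the fitter.
#' @return A `cats_fit`.
#' @export
fit_cats <- function(matrix, spec = full_cats_model(), log10_size = TRUE,
                     ...) {
  design <- build_design(matrix, spec, log10_size = log10_size)
  if (length(spec$random)) fit_poisson_glmm(design, ...) else
    fit_poisson_glm(design, ...)
}

#' Pseudo R-squared of a CATS fit
#'
#' Two variants side by side: deviance explained,
#' `1 - deviance(fit) / deviance(null)`, and the squared Pearson correlation
#' between observed and fitted counts. `null_fit` must be the
#' intercept(+offset, +same random terms) model nested in `fit`.
#'
#' @param fit,null_fit `cats_fit` objects on the same response.
#' @return List with `deviance_r2` and `corr_r2`.
#' @export
pseudo_r2 <- function(fit, null_fit) {
  if (length(null_fit$coefficients) > length(fit$coefficients)) {
    stop("`null_fit` must be nested in `fit`", call. = FALSE)
  }
  if (null_fit$deviance <= 0) {
    stop("null deviance is zero; pseudo R2 undefined", call. = FALSE)
  }
  list(deviance_r2 = 1 - fit$deviance / null_fit$deviance,
       corr_r2 = if (sd(fit$fitted) == 0 || sd(fit$design$y) == 0) 0 else
         cor(fit$design$y, fit$fitted)^2)
}

#' Predict the expected count for a predator size and prey item
#'
#' Evaluates `exp(log(pi) + x' beta [+ u])` passing the raw covariates
#' through the fit's standardization metadata. Warns when the predator size
#' lies more than 10% outside the training class-size range.
#'
#' @param fit A `cats_fit`.
#' @param s Predator size in mm (class mean standard length scale).
#' @param item_id Training item id (supplies group, size and pi); or give
#'   `group`, `prey_size_mm` and `pi` directly.
#' @param group,prey_size_mm,pi Explicit prey attributes; `pi` is the
#'   prior-abundance frequency entering the offset.
#' @param class_index Training class index; with `include_random = TRUE`
#'   adds the predicted random intercepts.
#' @param include_random Add predicted random effects (needs `class_index`
#'   and a training `item_id` for the respective term).
#' @return Expected count (scalar).
#' @export
predict_intensity <- function(fit, s, item_id = NULL, group = NULL,
                              prey_size_mm = NULL, pi = NULL,
                              class_index = NULL, include_random = FALSE) {
  meta <- fit$design$meta
  if (!is.null(item_id)) {
    row <- meta$items[meta$items$item_id == item_id, , drop = FALSE]
    if (!nrow(row)) stop("unknown item_id: ", item_id, call. = FALSE)
    group <- as.character(row$trophic_group)
    prey_size_mm <- row$body_size_mm
    if (is.null(pi)) pi <- row$pi
  }
  if (!group %in% trophic_levels()) {
    stop("unknown trophic level '", group, "'; allowed: ",
         paste(trophic_levels(), collapse = ", "), call. = FALSE)
  }
  rng <- meta$s_raw_range
  pad <- 0.1 * diff(rng)
  if (s < rng[1] - pad || s > rng[2] + pad) {
    warning("predator size ", s, " mm extrapolates beyond the training ",
            "range [", round(rng[1], 1), ", ", round(rng[2], 1), "] mm")
  }
  s_std <- (s - meta$pred_center) / meta$pred_scale
  size_cov <- if (meta$log10_size) log10(prey_size_mm) else prey_size_mm
  z_std <- (size_cov - meta$prey_center) / meta$prey_scale
  x <- cats_design_columns(fit$spec$fixed, s_std, z_std,
                           as.numeric(group == "herb_detr"),
                           as.numeric(group == "carnivore"))
  eta <- drop(x %*% fit$coefficients)
  if (fit$spec$use_offset) {
    if (is.null(pi)) stop("`pi` required for offset models", call. = FALSE)
    eta <- eta + log(pi)
  }
  if (include_random) {
    if (!is.null(class_index) && "class_id" %in% names(fit$u)) {
      eta <- eta + fit$u$class_id[class_index]
    }
    if (!is.null(item_id) && "item_id" %in% names(fit$u)) {
      eta <- eta + fit$u$item_id[match(item_id, meta$items$item_id)]
    }
  }
  unname(exp(eta))
}
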