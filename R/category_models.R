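#' Assign distribution categories from a presence table
#'
#' Classifies each species into one of four distribution categories from a
#' user-supplied presence table describing its range between the two study
#' regions. Precedence: a migratory flag wins outright; then a distribution
#' gap above 500 km makes the species `disjunct`; then presence in all
#' intermediate countries (Germany, Czech Republic, Poland, at least two of
#' the three Baltic states, NW Russia) together with occupancy of at least
#' half the provinces of Germany and Poland makes it `continuous`; everything
#' else is `fragmented`.
#'
#' @param presence A tibble with one row per species and columns `species`,
#'   logical `present_germany`, `present_czech`, `present_poland`,
#'   `present_lithuania`, `present_latvia`, `present_estonia`,
#'   `present_nw_russia`, numeric `province_fraction_germany`,
#'   `province_fraction_poland` (in `[0, 1]`), `max_gap_km` (>= 0) and logical
#'   `migratory_flag`.
#' @return A tibble `species`, `distribution_category`.
#' @export
assign_distribution_category <- function(presence) {
  needed <- c("species", "present_germany", "present_czech", "present_poland",
              "present_lithuania", "present_latvia", "present_estonia",
              "present_nw_russia", "province_fraction_germany",
              "province_fraction_poland", "max_gap_km", "migratory_flag")
  for (col in needed) {
    if (!col %in% names(presence)) abort(paste0("Missing field: ", col))
    if (anyNA(presence[[col]])) abort(paste0("Missing values in field: ", col))
  }
  stopifnot(all(presence$max_gap_km >= 0),
            all(presence$province_fraction_germany >= 0 & presence$province_fraction_germany <= 1),
            all(presence$province_fraction_poland >= 0 & presence$province_fraction_poland <= 1))
  n_baltic <- presence$present_lithuania + presence$present_latvia +
    presence$present_estonia
  all_between <- presence$present_germany & presence$present_czech &
    presence$present_poland & n_baltic >= 2 & presence$present_nw_russia
  dense <- presence$province_fraction_germany >= 0.5 &
    presence$province_fraction_poland >= 0.5
  category <- dplyr::case_when(
    presence$migratory_flag ~ "migratory",
    presence$max_gap_km > 500 ~ "disjunct",
    all_between & dense ~ "continuous",
    TRUE ~ "fragmented")
  tibble::tibble(species = presence$species, distribution_category = category)
}

#' Fit a category-effect model with a family random intercept
#'
#' Gaussian linear mixed model for a per-species response (e.g. maximum
#' intraspecific distance or the log ratio of intraspecific to NN distance):
#' fixed category effects, an optional covariate (typically sample size), a
#' family-level random intercept absorbing phylogenetic correlation, and —
#' when `heteroscedastic = TRUE` — a separate residual standard deviation per
#' category. The marginal likelihood is maximized numerically (full ML, no
#' REML) with the fixed effects profiled out by generalized least squares;
#' three fixed starting points guard against local optima, and the best
#' log-likelihood wins, so the fit is deterministic given the data.
#'
#' @param data A tibble with one row per species.
#' @param response,category,family,covariate Column names (strings) in
#'   `data`; `covariate` may be `NULL`.
#' @param heteroscedastic Estimate a residual SD per category (default
#'   `TRUE`)? Otherwise a single residual SD is shared.
#' @param include_category Include the category fixed effect (default `TRUE`)?
#'   Setting `FALSE` (together with `heteroscedastic = FALSE`) produces the
#'   null model for a likelihood-ratio test of the category variable.
#' @return An object of class `category_fit` with components `coefficients`
#'   (fixed effects), `vcov`, `sigma` (per-category or single residual SD),
#'   `sigma_b` (random-intercept SD), `logLik`, `df` (number of free
#'   parameters), `n`, `category_means` (model-implied mean per category at
#'   the covariate mean), plus bookkeeping fields. Supports [tidy()] and
#'   [glance()].
#' @export
fit_category_model <- function(data, response, category, family,
                               covariate = NULL, heteroscedastic = TRUE,
                               include_category = TRUE) {
  y <- data[[response]]
  cat_f <- factor(data[[category]])
  fam_f <- factor(data[[family]])
  if (anyNA(y) || anyNA(cat_f) || anyNA(fam_f)) abort("NA in model variables")
  if (include_category && (nlevels(cat_f) < 2 || any(table(cat_f) < 3))) {
    abort("Need >= 2 categories with >= 3 species each")
  }
  n <- length(y)
  X <- if (include_category) stats::model.matrix(~cat_f) else matrix(1, n, 1)
  colnames(X)[1] <- "(Intercept)"
  if (include_category) {
    colnames(X)[-1] <- paste0("category_", levels(cat_f)[-1])
  }
  if (!is.null(covariate)) {
    X <- cbind(X, covariate = data[[covariate]])
  }
  var_group <- if (heteroscedastic) as.integer(cat_f) else rep(1L, n)
  n_var <- length(unique(var_group))
  fam_i <- as.integer(fam_f)

  # profiled marginal log-likelihood; theta = c(log sigma_b, log sigma[1..n_var])
  nll <- function(theta) {
    fit <- gls_profile(exp(2 * theta[1]), exp(2 * theta[-1]), y, X, var_group, fam_i)
    -fit$logLik
  }
  s0 <- stats::sd(stats::residuals(lm(y ~ X - 1)))
  if (!is.finite(s0) || s0 <= 0) s0 <- max(sd(y), 1e-3)
  starts <- list(c(log(s0 / 2), rep(log(s0), n_var)),
                 c(log(s0), rep(log(s0 / 2), n_var)),
                 c(log(s0 / 10), rep(log(2 * s0), n_var)))
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(optim(st, nll, method = "Nelder-Mead",
                          control = list(maxit = 1000, reltol = 1e-10)),
                    error = function(e) NULL)
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) abort("fit_category_model: optimization failed")
  theta <- best$par
  sigma_b <- exp(theta[1])
  sigmas <- exp(theta[-1])
  fit <- gls_profile(sigma_b^2, sigmas^2, y, X, var_group, fam_i, want_vcov = TRUE)
  beta <- fit$beta
  names(beta) <- colnames(X)
  vc <- fit$vcov
  dimnames(vc) <- list(colnames(X), colnames(X))

  cat_means <- NULL
  if (include_category) {
    cov_mean <- if (is.null(covariate)) 0 else mean(data[[covariate]])
    cat_means <- vapply(levels(cat_f), function(lv) {
      x <- numeric(ncol(X))
      names(x) <- colnames(X)
      x["(Intercept)"] <- 1
      nm <- paste0("category_", lv)
      if (nm %in% names(x)) x[nm] <- 1
      if ("covariate" %in% names(x)) x["covariate"] <- cov_mean
      sum(x * beta)
    }, numeric(1))
  }
  sigma_named <- if (heteroscedastic) setNames(sigmas, levels(cat_f)) else
    setNames(sigmas, "residual")

  structure(list(
    coefficients = beta, vcov = vc, sigma = sigma_named, sigma_b = sigma_b,
    logLik = fit$logLik, df = ncol(X) + 1 + n_var, n = n,
    category_means = cat_means, response = response,
    heteroscedastic = heteroscedastic, include_category = include_category,
    covariate = covariate, category_levels = levels(cat_f),
    converged = best$convergence == 0), class = "category_fit")
}

# GLS with block covariance sigma_b^2 * J + diag(sigma^2) per family, via
# Woodbury; returns profiled ML log-likelihood and beta (vcov only on request)
gls_profile <- function(sb2, s2, y, X, var_group, fam_i, want_vcov = FALSE) {
  w <- 1 / s2[var_group]
  S_f <- rowsum(w, fam_i)[, 1]
  c_f <- sb2 / (1 + sb2 * S_f)
  wX <- X * w
  u <- rowsum(wX, fam_i)                       # families x p
  vy <- rowsum(w * y, fam_i)[, 1]
  A <- crossprod(X, wX) - crossprod(u * sqrt(c_f))
  b <- crossprod(wX, y) - crossprod(u, c_f * vy)
  beta <- solve(A, b)[, 1]
  r <- y - X %*% beta
  wr_f <- rowsum(w * r, fam_i)[, 1]
  q <- sum(w * r^2) - sum(c_f * wr_f^2)
  logdet <- sum(log(s2[var_group])) + sum(log1p(sb2 * S_f))
  list(logLik = -0.5 * (length(y) * log(2 * pi) + logdet + q),
       beta = beta, vcov = if (want_vcov) solve(A) else NULL)
}

#' @export
print.category_fit <- function(x, ...) {
  cat(sprintf("Category-effect model for '%s' (%s, %s): logLik %.3f, %d species, %d parameters\n",
              x$response,
              if (x$heteroscedastic) "heteroscedastic" else "homoscedastic",
              if (x$include_category) "with category effects" else "null",
              x$logLik, x$n, x$df))
  if (!is.null(x$category_means)) {
    cat("Category means:\n")
    print(round(x$category_means, 4))
  }
  invisible(x)
}

#' @describeIn fit_category_model Fixed effects and variance components as a
#'   tibble (`term`, `estimate`, `std_error`, `statistic`, `p_value` for fixed
#'   effects; variance components carry `NA` inferential columns).
#' @param x A `category_fit` object.
#' @param ... Unused.
#' @export
tidy.category_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  fixed <- tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
                          std_error = unname(se), statistic = unname(z),
                          p_value = 2 * stats::pnorm(-abs(z)))
  vpars <- tibble::tibble(
    term = c("sd_family_intercept", paste0("sd_residual_", names(x$sigma))),
    estimate = c(x$sigma_b, unname(x$sigma)),
    std_error = NA_real_, statistic = NA_real_, p_value = NA_real_)
  dplyr::bind_rows(fixed, vpars)
}

#' @describeIn fit_category_model One-row model summary (`logLik`, `df`,
#'   `nobs`, `AIC`).
#' @export
glance.category_fit <- function(x, ...) {
  tibble::tibble(logLik = x$logLik, df = x$df, nobs = x$n,
                 AIC = -2 * x$logLik + 2 * x$df)
}

#' Likelihood-ratio test between nested category models
#'
#' `chi_sq = 2 (logLik_full - logLik_null)`, clamped at zero, referred to a
#' chi-square distribution with `df = df_full - df_null`. For a four-level
#' category tested heteroscedastically this difference is 6 (three mean
#' contrasts plus three variance ratios). Identical models (`df = 0`) give
#' `chi_sq = 0`, `p = 1`.
#'
#' @param full,null `category_fit` objects fitted to the same data, with
#'   `null` nested in `full`.
#' @return A one-row tibble `chi_sq`, `df`, `p_value`.
#' @export
lrt <- function(full, null) {
  if (full$n != null$n) abort("Models were fitted to different data")
  df <- full$df - null$df
  if (df < 0) abort("'null' must be nested in 'full' (not more parameters)")
  chi <- max(0, 2 * (full$logLik - null$logLik))
  # df = 0 (identical models): chi-square degenerates to a point mass at 0
  p <- if (df == 0) as.numeric(chi <= 1e-8) else pchisq(chi, df, lower.tail = FALSE)
  tibble::tibble(chi_sq = chi, df = df, p_value = p)
}

#' Pairwise Wald contrasts between category means
#'
#' Differences between all pairs of model-implied category means with Wald
#' z-tests from the fitted covariance; p-values are reported raw, without
#' multiplicity correction.
#'
#' @param fit A `category_fit` with category effects.
#' @return A tibble `contrast`, `estimate`, `std_error`, `statistic`,
#'   `p_value`.
#' @export
category_contrasts <- function(fit) {
  if (!fit$include_category) abort("Fit has no category effects")
  lv <- fit$category_levels
  p <- length(fit$coefficients)
  rows <- combn(lv, 2, simplify = FALSE) |> purrr::map(function(pr) {
    cvec <- numeric(p)
    names(cvec) <- names(fit$coefficients)
    for (sgn in c(1, -1)) {
      nm <- paste0("category_", if (sgn == 1) pr[1] else pr[2])
      if (nm %in% names(cvec)) cvec[nm] <- cvec[nm] + sgn
    }
    est <- sum(cvec * fit$coefficients)
    se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
    tibble::tibble(contrast = paste(pr[1], "-", pr[2]), estimate = est,
                   std_error = se, statistic = est / se,
                   p_value = 2 * stats::pnorm(-abs(est / se)))
  })
  dplyr::bind_rows(rows)
}

#' Log ratio of maximum intraspecific to NN distance
#'
#' Per-species response `log10(max_intra / nn_dist)` used for the
#' distribution-category models. Species with `nn_dist = 0` are always
#' excluded (the ratio is undefined); species with `max_intra = 0` are
#' excluded by default because the log is undefined, unless `zero_floor =
#' TRUE`, which substitutes half the smallest nonzero `max_intra`; species
#' whose maximum intraspecific distance exceeds their NN distance can be
#' excluded with `exclude_overlap = TRUE`.
#'
#' @param stats Output of [species_gap_stats()].
#' @param exclude_overlap Drop species with `max_intra > nn_dist` (default
#'   `FALSE`).
#' @param zero_floor Replace zero `max_intra` by half the smallest nonzero
#'   value instead of excluding (default `FALSE`).
#' @return A tibble `species`, `log_ratio`; exclusion counts are reported via
#'   a message.
#' @export
ratio_response <- function(stats, exclude_overlap = FALSE, zero_floor = FALSE) {
  dat <- stats[!is.na(stats$nn_dist), ]
  n_zero_nn <- sum(dat$nn_dist == 0)
  dat <- dat[dat$nn_dist > 0, ]
  n_overlap <- 0L
  if (exclude_overlap) {
    n_overlap <- sum(dat$max_intra > dat$nn_dist)
    dat <- dat[dat$max_intra <= dat$nn_dist, ]
  }
  n_zero_intra <- sum(dat$max_intra == 0)
  if (zero_floor && n_zero_intra > 0) {
    floor_val <- min(dat$max_intra[dat$max_intra > 0]) / 2
    dat$max_intra[dat$max_intra == 0] <- floor_val
    n_zero_intra <- 0L
  } else {
    dat <- dat[dat$max_intra > 0, ]
  }
  inform(sprintf(
    "ratio_response: excluded %d species with nn_dist = 0, %d with max_intra > nn_dist, %d with max_intra = 0",
    n_zero_nn, n_overlap, n_zero_intra))
  tibble::tibble(species = dat$species,
                 log_ratio = log10(dat$max_intra / dat$nn_dist))
}
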