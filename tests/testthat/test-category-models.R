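test_that("distribution categories follow rule precedence", {
  base <- tibble::tibble(
    species = "x", present_germany = TRUE, present_czech = TRUE,
    present_poland = TRUE, present_lithuania = TRUE, present_latvia = TRUE,
    present_estonia = FALSE, present_nw_russia = TRUE,
    province_fraction_germany = 0.7, province_fraction_poland = 0.6,
    max_gap_km = 0, migratory_flag = FALSE)
  expect_equal(assign_distribution_category(base)$distribution_category,
               "continuous")
  # >500 km gap wins over an otherwise continuous range
  gap <- dplyr::mutate(base, max_gap_km = 600)
  expect_equal(assign_distribution_category(gap)$distribution_category, "disjunct")
  expect_equal(assign_distribution_category(
    dplyr::mutate(base, max_gap_km = 500))$distribution_category, "continuous")
  # migratory flag beats everything
  mig <- dplyr::mutate(base, migratory_flag = TRUE, max_gap_km = 900)
  expect_equal(assign_distribution_category(mig)$distribution_category, "migratory")
  # sparse provinces or a missing corridor country demote to fragmented
  sparse <- dplyr::mutate(base, province_fraction_poland = 0.3)
  expect_equal(assign_distribution_category(sparse)$distribution_category,
               "fragmented")
  nocz <- dplyr::mutate(base, present_czech = FALSE)
  expect_equal(assign_distribution_category(nocz)$distribution_category,
               "fragmented")
  onebaltic <- dplyr::mutate(base, present_lithuania = FALSE, present_latvia = FALSE)
  expect_equal(assign_distribution_category(onebaltic)$distribution_category,
               "fragmented")
  # missing fields are named
  expect_error(assign_distribution_category(dplyr::select(base, -"max_gap_km")),
               "max_gap_km")
  expect_error(assign_distribution_category(
    dplyr::mutate(base, migratory_flag = NA)), "migratory_flag")
})

sim_category_data <- function(n_per_cat = 30, nfam = 6, means = rep(1, 4),
                              sds = rep(0.4, 4), sd_fam = 0.3, seed = 1) {
  set.seed(seed)
  cats <- c("continuous", "fragmented", "disjunct", "migratory")
  n <- n_per_cat * 4
  fam <- sample(rep(sprintf("F%02d", seq_len(nfam)), length.out = n))
  cat_v <- rep(cats, each = n_per_cat)
  b <- stats::rnorm(nfam, 0, sd_fam)
  tibble::tibble(
    family = fam, category = cat_v,
    y = means[match(cat_v, cats)] + b[as.integer(factor(fam))] +
      stats::rnorm(n, 0, sds[match(cat_v, cats)]))
}

test_that("single-family homoscedastic fit degenerates to per-category means", {
  set.seed(61)
  d <- tibble::tibble(
    family = "onefam",
    category = rep(c("a", "b", "c"), each = 6),
    y = stats::rnorm(18, rep(c(1, 3, 5), each = 6), 0.5))
  fit <- fit_category_model(d, "y", "category", "family", heteroscedastic = FALSE)
  obs <- tapply(d$y, d$category, mean)
  expect_equal(unname(fit$category_means),
               as.numeric(obs[fit$category_levels]), tolerance = 1e-8)
})

test_that("category means and variance structure are recovered on simulated data", {
  d <- sim_category_data(n_per_cat = 60, means = c(0.9, 0.9, 0.9, 0.1),
                         sds = c(0.4, 0.4, 0.4, 0.05), seed = 62)
  fit <- fit_category_model(d, "y", "category", "family", heteroscedastic = TRUE)
  m <- fit$category_means
  expect_lt(abs(m[["migratory"]] - 0.1), 0.15)
  expect_true(all(abs(m[c("continuous", "fragmented", "disjunct")] - 0.9) < 0.25))
  # migratory contrast significant, others not
  ct <- category_contrasts(fit)
  mig <- grepl("migratory", ct$contrast)
  expect_true(all(ct$p_value[mig] < 0.01))
  # per-category SD ratio recovered within a factor consistent with n = 60
  expect_lt(fit$sigma[["migratory"]] / fit$sigma[["continuous"]], 0.35)
})

test_that("equal-mean data produce a small LRT and near-zero effects", {
  d <- sim_category_data(n_per_cat = 40, seed = 63)
  full <- fit_category_model(d, "y", "category", "family", heteroscedastic = TRUE)
  null <- fit_category_model(d, "y", "category", "family",
                             heteroscedastic = FALSE, include_category = FALSE)
  out <- lrt(full, null)
  expect_equal(out$df, 6)
  expect_gt(out$p_value, 0.05)
  expect_true(all(abs(full$category_means - mean(d$y)) < 0.3))
})

test_that("likelihood-ratio test mechanics", {
  d <- sim_category_data(seed = 64)
  fit <- fit_category_model(d, "y", "category", "family", heteroscedastic = TRUE)
  ident <- lrt(fit, fit)
  expect_equal(ident$chi_sq, 0)
  expect_equal(ident$p_value, 1)
  # a 52.02 / 6 df statistic sits far beyond the 0.001 tail
  expect_lt(stats::pchisq(52.02, df = 6, lower.tail = FALSE), 0.001)
  null <- fit_category_model(d, "y", "category", "family",
                             heteroscedastic = FALSE, include_category = FALSE)
  out <- lrt(fit, null)
  expect_gte(out$chi_sq, 0)
  expect_equal(out$p_value,
               stats::pchisq(out$chi_sq, out$df, lower.tail = FALSE))
})

test_that("heteroscedastic likelihood matches nlme::lme with varIdent", {
  skip_if_not_installed("nlme")
  d <- sim_category_data(n_per_cat = 25, sds = c(0.2, 0.4, 0.6, 0.1), seed = 65)
  fit <- fit_category_model(d, "y", "category", "family", heteroscedastic = TRUE)
  ref <- nlme::lme(y ~ category, random = ~ 1 | family,
                   weights = nlme::varIdent(form = ~ 1 | category),
                   data = d, method = "ML",
                   control = nlme::lmeControl(opt = "optim"))
  expect_equal(fit$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-4)
  # model-implied category means agree
  pred <- unique(data.frame(category = d$category))
  ref_means <- stats::predict(ref, pred, level = 0)
  expect_equal(unname(fit$category_means[pred$category]),
               as.numeric(ref_means), tolerance = 1e-3)
})

test_that("tidy and glance expose coefficients and fit summary", {
  d <- sim_category_data(seed = 66)
  fit <- fit_category_model(d, "y", "category", "family", heteroscedastic = TRUE)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "p_value") %in% names(td)))
  expect_true("sd_family_intercept" %in% td$term)
  expect_equal(sum(grepl("^sd_residual_", td$term)), 4)
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(d))
  expect_equal(gl$df, 4 + 1 + 4)
})

test_that("log ratio response applies the exclusion rules", {
  st <- tibble::tibble(
    species = c("a", "b", "c", "d", "e"),
    max_intra = c(1, 0, 3, 2, 5),
    nn_dist = c(10, 8, 3, 0, 4))
  out <- suppressMessages(ratio_response(st))
  expect_equal(out$log_ratio[out$species == "a"], -1)       # log10(0.1)
  expect_equal(out$log_ratio[out$species == "c"], 0)        # max == nn
  expect_false("d" %in% out$species)                        # nn = 0 excluded
  expect_false("b" %in% out$species)                        # max = 0 excluded
  expect_true("e" %in% out$species)                         # overlap kept by default
  out2 <- suppressMessages(ratio_response(st, exclude_overlap = TRUE))
  expect_false("e" %in% out2$species)
  out3 <- suppressMessages(ratio_response(st, zero_floor = TRUE))
  expect_equal(out3$log_ratio[out3$species == "b"], log10(0.5 / 8))
})
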