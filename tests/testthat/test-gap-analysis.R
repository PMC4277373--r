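test_that("per-species statistics match hand enumeration on a constructed matrix", {
  # sp1: three specimens with pairwise {1.0, 2.0, 1.5}%; sp2 two specimens,
  # nearest heterospecific pair at 5.0%
  d <- matrix(c(0.0, 1.0, 2.0, 5.0, 6.0,
                1.0, 0.0, 1.5, 5.5, 6.5,
                2.0, 1.5, 0.0, 6.0, 7.0,
                5.0, 5.5, 6.0, 0.0, 0.4,
                6.0, 6.5, 7.0, 0.4, 0.0), 5, 5, byrow = TRUE)
  ds <- make_ds(rep(strrep("A", 658), 5), c(rep("Aus bus", 3), rep("Aus cus", 2)))
  st <- species_gap_stats(make_dm(d), ds)
  sp1 <- st[st$species == "Aus bus", ]
  expect_equal(sp1$max_intra, 2.0)
  expect_equal(sp1$mean_intra, 1.5)
  expect_equal(sp1$nn_species, "Aus cus")
  expect_equal(sp1$nn_dist, 5.0)
  expect_true(sp1$gap_present)
  expect_equal(sp1$harmonic_n, harmonic_mean(3, 2))
})

test_that("singletons and shared barcodes are handled per convention", {
  d <- matrix(c(0, 0, 4,
                0, 0, 4,
                4, 4, 0), 3, 3)
  ds <- make_ds(rep(strrep("A", 658), 3), c("Aus bus", "Aus cus", "Aus dus"))
  st <- species_gap_stats(make_dm(d), ds)
  expect_true(all(st$singleton))
  expect_equal(st$max_intra, rep(0, 3))
  # two species sharing an identical barcode: nn 0, no gap, not diagnosable
  shared <- st[st$species %in% c("Aus bus", "Aus cus"), ]
  expect_equal(shared$nn_dist, c(0, 0))
  expect_false(any(shared$gap_present))
  expect_false(any(shared$diagnosable))
  expect_true(st$diagnosable[st$species == "Aus dus"])
})

test_that("deep-split species stay diagnosable while intermingled ones fail", {
  # sp1 has a 4% internal split but nn at 7%: the intra chain (max MST edge 4)
  # still sits below the interspecific minimum
  d <- matrix(c(0.0, 0.3, 4.0, 7.0,
                0.3, 0.0, 4.1, 7.2,
                4.0, 4.1, 0.0, 7.5,
                7.0, 7.2, 7.5, 0.0), 4, 4, byrow = TRUE)
  ds <- make_ds(rep(strrep("A", 658), 4), c(rep("Aus bus", 3), "Aus cus"))
  expect_true(diagnosable("Aus bus", make_dm(d), ds))

  # intermingled: one sp1 specimen is closer to sp2 than the sp1 chain is tight
  d2 <- matrix(c(0.0, 6.0, 1.0,
                 6.0, 0.0, 1.2,
                 1.0, 1.2, 0.0), 3, 3, byrow = TRUE)
  ds2 <- make_ds(rep(strrep("A", 658), 3), c("Aus bus", "Aus bus", "Aus cus"))
  expect_false(diagnosable("Aus bus", make_dm(d2), ds2))
})

test_that("species statistics equal exhaustive recomputation on random libraries", {
  for (seed in c(21, 22)) {
    lib <- generate_library(simulation_config(
      n_families = 1, genera_per_family = 2, species_per_genus = 3,
      seq_length = 400, seed = seed))
    ds <- lib$dataset
    dm <- k2p_matrix(ds)
    st <- species_gap_stats(dm, ds)
    brute <- gap_stats_brute(dm, ds)
    expect_equal(st$species, brute$species)
    expect_equal(st$max_intra, brute$max_intra)
    expect_equal(st$mean_intra, brute$mean_intra)
    expect_equal(st$nn_dist, brute$nn_dist)
    expect_equal(st$nn_species, brute$nn_species)
  }
})

test_that("threshold census uses strict inequalities and nested bins", {
  st <- tibble::tibble(max_intra = c(0, 0.5, 1.5, 3.0))
  cen <- threshold_census(st, c(1, 2))
  expect_equal(cen$count[cen$bin == "=0"], 1)
  expect_equal(cen$count[cen$bin == "<1"], 2)
  expect_equal(cen$count[cen$bin == "<2"], 3)
  expect_equal(cen$count[cen$bin == ">=2"], 1)
  # species exactly at a threshold fall outside the strict "<" bin
  at <- threshold_census(tibble::tibble(max_intra = c(1, 1)), c(1, 2))
  expect_equal(at$count[at$bin == "<1"], 0)
  expect_equal(at$count[at$bin == "<2"], 2)
  empty <- threshold_census(tibble::tibble(max_intra = numeric()), c(1, 2))
  expect_true(all(empty$count == 0))
  expect_error(threshold_census(st, c(2, 1)), "increasing")
})

test_that("harmonic mean follows the closed form", {
  expect_equal(harmonic_mean(4, 4), 4)
  expect_equal(harmonic_mean(1, 3), 1.5)
  expect_equal(harmonic_mean(1, 1), 1)
  expect_error(harmonic_mean(0, 3), ">= 1")
  # H never exceeds twice the smaller sample
  for (pair in list(c(1, 9), c(2, 5), c(3, 50))) {
    expect_lte(harmonic_mean(pair[1], pair[2]), 2 * min(pair))
  }
})

test_that("NN regression matches the normal-equation oracle", {
  st <- tibble::tibble(species = letters[1:5],
                       nn_dist = c(9.1, 8.4, 7.9, 6.2, 5.5),
                       harmonic_n = c(1, 1.5, 2, 4, 6))
  fit <- nn_vs_samplesize_regression(st)
  expect_equal(fit$slope, -4.78250376925, tolerance = 1e-9)
  expect_equal(fit$intercept, 9.19653993299, tolerance = 1e-9)

  exact <- tibble::tibble(species = letters[1:4],
                          harmonic_n = c(1, 10, 100, 1000),
                          nn_dist = 8 - 2 * log10(c(1, 10, 100, 1000)))
  f2 <- suppressWarnings(nn_vs_samplesize_regression(exact))  # exact fit
  expect_equal(f2$slope, -2, tolerance = 1e-10)
  expect_lt(f2$p_value, 1e-10)

  flat <- tibble::tibble(species = letters[1:4], harmonic_n = c(1, 2, 4, 8),
                         nn_dist = rep(5, 4))
  expect_equal(suppressWarnings(nn_vs_samplesize_regression(flat))$slope, 0,
               tolerance = 1e-12)
  same_x <- tibble::tibble(species = letters[1:3], harmonic_n = rep(2, 3),
                           nn_dist = 1:3)
  expect_error(nn_vs_samplesize_regression(same_x), "variance")
})

test_that("sample-size residuals match hand OLS and degrade to centering", {
  st <- tibble::tibble(species = letters[1:4], n_specimens = c(2, 3, 5, 6),
                       max_intra = c(0.2, 0.9, 0.5, 1.4))
  res <- intra_vs_samplesize_residuals(st)
  expect_equal(res$residual, c(-0.15, 0.35, -0.45, 0.25), tolerance = 1e-10)

  perfect <- tibble::tibble(species = letters[1:4], n_specimens = 1:4,
                            max_intra = 2 + 0.5 * (1:4))
  expect_equal(intra_vs_samplesize_residuals(perfect)$residual, rep(0, 4),
               tolerance = 1e-12)

  equal_n <- tibble::tibble(species = letters[1:4], n_specimens = rep(4, 4),
                            max_intra = c(1, 2, 3, 4))
  expect_equal(intra_vs_samplesize_residuals(equal_n)$residual,
               c(1, 2, 3, 4) - 2.5)
})

test_that("pooling can only raise the intraspecific max and lower the NN minimum", {
  lib <- generate_library(simulation_config(
    n_families = 2, genera_per_family = 2, species_per_genus = 3,
    seq_length = 400, seed = 31))
  ds <- lib$dataset
  dm <- k2p_matrix(ds)
  pc <- suppressMessages(partition_compare(dm, ds))
  expect_true(all(pc$max_intra_pooled >= pc$max_intra_ref - 1e-12))
  expect_true(all(pc$nn_dist_pooled <= pc$nn_dist_ref + 1e-12))
})

test_that("a divergent query specimen raises the pooled maximum", {
  # reference pair at 0.2%, query specimen at ~3% from both
  d <- matrix(c(0.0, 0.2, 3.0, 8.0,
                0.2, 0.0, 3.1, 8.1,
                3.0, 3.1, 0.0, 8.2,
                8.0, 8.1, 8.2, 0.0), 4, 4, byrow = TRUE)
  ds <- make_ds(rep(strrep("A", 658), 4),
                c("Aus bus", "Aus bus", "Aus bus", "Aus cus"),
                region = c("reference", "reference", "query", "reference"))
  pc <- partition_compare(make_dm(d), ds)
  sp1 <- pc[pc$species == "Aus bus", ]
  expect_equal(sp1$max_intra_ref, 0.2)
  expect_equal(sp1$max_intra_pooled, 3.1)
  expect_equal(sp1$nn_reduction_pct, 0)
  expect_false(sp1$nn_changed)
})
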