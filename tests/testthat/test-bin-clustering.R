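test_that("single-linkage pre-clustering chains below the threshold", {
  # chain A-B 2.0, B-C 2.0, A-C 4.0 -> one component at 2.2
  d <- matrix(c(0, 2, 4,
                2, 0, 2,
                4, 2, 0), 3, 3)
  dm <- make_dm(d)
  pre <- single_linkage_preclusters(dm, 2.2)
  expect_equal(length(unique(pre$cluster_id)), 1)

  # all pairs at/above threshold: all singletons (strict "<")
  d2 <- matrix(3, 3, 3); diag(d2) <- 0
  pre2 <- single_linkage_preclusters(make_dm(d2), 2.2)
  expect_equal(length(unique(pre2$cluster_id)), 3)
  expect_equal(pre2$cluster_id, c("C0001", "C0002", "C0003"))

  # two tight groups separated by >= 3%
  d3 <- matrix(c(0, .1, 3, 3,
                 .1, 0, 3, 3,
                 3, 3, 0, .1,
                 3, 3, .1, 0), 4, 4)
  expect_equal(length(unique(single_linkage_preclusters(make_dm(d3), 2.2)$cluster_id)), 2)
})

test_that("MCL splits bimodal pre-clusters and leaves uniform ones whole", {
  # two tight clumps (intra 0.3%) at 2.0% mutual distance chain into one
  # precluster but carry clear two-part structure
  clump <- function(off) matrix(off, 3, 3) - diag(off, 3)
  d <- rbind(cbind(clump(0.3), matrix(2.0, 3, 3)),
             cbind(matrix(2.0, 3, 3), clump(0.3)))
  diag(d) <- 0
  dm <- make_dm(d)
  parts <- mcl_refine(dm, dm$ids)
  expect_equal(length(unique(parts)), 2)
  expect_equal(parts[1:3], rep(parts[1], 3))
  expect_equal(parts[4:6], rep(parts[4], 3))
  # the 2-partition is also the silhouette optimum over all 2-part splits
  best <- silhouette_mean(parts, d)
  combn(6, 3, function(g) {
    memb <- rep(1L, 6); memb[g] <- 2L
    expect_lte(silhouette_mean(memb, d), best + 1e-12)
  })

  uniform <- matrix(0.2, 5, 5); diag(uniform) <- 0
  dmu <- make_dm(uniform)
  expect_equal(length(unique(mcl_refine(dmu, dmu$ids))), 1)

  two <- matrix(c(0, .5, .5, 0), 2, 2)
  dm2 <- make_dm(two)
  expect_true(length(unique(mcl_refine(dm2, dm2$ids))) %in% 1:2)
})

test_that("silhouette follows its closed form and conventions", {
  # construct: x1 alone in cluster 1 at distance 1 from x2 (own cluster?) ->
  # use 4 points: {x1,x2} with d=1, {x3,x4} with d=1, cross distances 3
  d <- matrix(c(0, 1, 3, 3,
                1, 0, 3, 3,
                3, 3, 0, 1,
                3, 3, 1, 0), 4, 4)
  m <- c(1L, 1L, 2L, 2L)
  expect_equal(silhouette_mean(m, d), (3 - 1) / 3)   # every point has a=1, b=3
  # a == b -> 0
  dd <- matrix(1, 4, 4); diag(dd) <- 0
  expect_equal(silhouette_mean(m, dd), 0)
  # single cluster and singleton conventions
  expect_equal(silhouette_mean(rep(1L, 4), d), 0)
  expect_equal(silhouette_mean(c(1L, 2L, 3L, 4L), d), 0)
  # well-separated tight clusters approach 1
  far <- d; far[far == 3] <- 50; far[far == 1] <- 0.1
  expect_gt(silhouette_mean(m, far), 0.95)
})

test_that("refinement is accepted only on silhouette gain and never crosses preclusters", {
  set.seed(51)
  lib <- generate_library(scenario_config("no_structure", seed = 51,
                                          n_families = 2, genera_per_family = 2,
                                          species_per_genus = 3, seq_length = 500))
  dm <- k2p_matrix(lib$dataset)
  pre <- single_linkage_preclusters(dm, 2.2)
  bins <- assign_bins(dm, lib$dataset)
  # refinement property: bins never merge specimens across preclusters
  tab <- table(pre$cluster_id, bins$cluster_id)
  expect_true(all(colSums(tab > 0) == 1))
})

test_that("cluster labels are order-stable and permutation gives the same partition", {
  set.seed(52)
  lib <- generate_library(simulation_config(
    n_families = 1, genera_per_family = 2, species_per_genus = 3,
    seq_length = 400, seed = 52))
  ds <- lib$dataset
  dm <- k2p_matrix(ds)
  bins <- assign_bins(dm, ds)
  perm <- sample(nrow(ds))
  ds_p <- ds[perm, ]
  bins_p <- assign_bins(k2p_matrix(ds_p), ds_p)
  # same partition up to relabeling
  key <- split(bins$specimen_id, bins$cluster_id)
  key_p <- split(bins_p$specimen_id, bins_p$cluster_id)
  expect_setequal(lapply(unname(key), sort), lapply(unname(key_p), sort))
})

test_that("all four concordance classes are produced and labelled on a toy set", {
  assignment <- tibble::tibble(
    specimen_id = sprintf("s%02d", 1:10),
    cluster_id = c("C1", "C2",        # spA split across C1, C2
                   "C3", "C3",        # spB, spC merged in C3
                   "C4",              # spD match
                   "C5", "C6", "C6",  # spE mixture (C6 shared with spF)
                   "C6",              # spF merge
                   "C7"))             # spG match
  ds <- tibble::tibble(
    specimen_id = sprintf("s%02d", 1:10),
    species = c("spA", "spA", "spB", "spC", "spD", "spE", "spE", "spE",
                "spF", "spG"),
    region = c("reference", "query", "reference", "reference", "reference",
               "reference", "reference", "query", "reference", "reference"))
  con <- bin_concordance(assignment, ds)
  cls <- setNames(con$class, con$species)
  expect_equal(cls[["spA"]], "split")
  expect_equal(cls[["spB"]], "merge")
  expect_equal(cls[["spC"]], "merge")
  expect_equal(cls[["spD"]], "match")
  expect_equal(cls[["spE"]], "mixture")
  expect_equal(cls[["spF"]], "merge")
  expect_equal(cls[["spG"]], "match")
  # spA's two clusters occupy disjoint regions; spE's clusters share 'reference'
  pat <- setNames(con$split_regional_pattern, con$species)
  expect_equal(pat[["spA"]], "between_regions")
  expect_equal(pat[["spE"]], "within_region")
  expect_true(is.na(pat[["spD"]]))

  agg <- concordance_summary(con)
  expect_equal(sum(agg$by_class$n_species), 7)
})

test_that("well-separated tight species come out as exactly one cluster each", {
  lib <- generate_library(scenario_config("no_structure", seed = 53,
                                          n_families = 2, genera_per_family = 2,
                                          species_per_genus = 3, seq_length = 658))
  dm <- k2p_matrix(lib$dataset)
  bins <- assign_bins(dm, lib$dataset)
  con <- bin_concordance(bins, lib$dataset)
  expect_true(all(con$class == "match"))
  expect_equal(length(unique(bins$cluster_id)), dplyr::n_distinct(lib$dataset$species))
})
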