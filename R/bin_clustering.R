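#' Configuration for refined-single-linkage (RESL-lite) clustering
#'
#' The clustering proceeds in three steps: single-linkage pre-clustering at a
#' minimum divergence threshold (2.2% by default, the standard BIN threshold),
#' Markov clustering (MCL) of each pre-cluster on a similarity graph, and a
#' mean-silhouette criterion deciding whether the MCL refinement is accepted.
#'
#' @param precluster_threshold Single-linkage threshold in percent (default
#'   2.2): edges exist where distance < threshold.
#' @param mcl_inflation MCL inflation exponent (> 1, default 2).
#' @param mcl_expansion MCL expansion power (default 2).
#' @param mcl_tol Convergence tolerance on the max elementwise change
#'   (default 1e-8).
#' @param mcl_max_iter Iteration cap (default 200); non-convergence leaves the
#'   pre-cluster unrefined with a warning.
#' @param silhouette_min_gain Minimum improvement of the refined partition's
#'   mean silhouette over the unsplit pre-cluster (whose value is 0 by
#'   convention) required to accept a split (default 0, i.e. any strictly
#'   positive silhouette).
#' @param similarity_threshold Distance (in percent) at which graph edge
#'   weight reaches 0; weights are `max(0, 1 - d/similarity_threshold)`.
#'   Defaults to the pre-cluster threshold: pairs further apart than the
#'   linkage threshold contribute no flow, which is what lets MCL cut a
#'   chained pre-cluster at its internal gaps. (A laxer transform, e.g. twice
#'   the threshold, keeps weak flow across 2%-deep gaps and the MCL iteration
#'   then collapses to the uniform fixed point instead of splitting.)
#' @return A list of class `resl_config`.
#' @export
resl_config <- function(precluster_threshold = 2.2, mcl_inflation = 2,
                        mcl_expansion = 2, mcl_tol = 1e-8, mcl_max_iter = 200,
                        silhouette_min_gain = 0,
                        similarity_threshold = precluster_threshold) {
  stopifnot(precluster_threshold > 0, mcl_inflation > 1)
  structure(list(precluster_threshold = precluster_threshold,
                 mcl_inflation = mcl_inflation, mcl_expansion = mcl_expansion,
                 mcl_tol = mcl_tol, mcl_max_iter = mcl_max_iter,
                 silhouette_min_gain = silhouette_min_gain,
                 similarity_threshold = similarity_threshold),
            class = "resl_config")
}

#' Single-linkage pre-clusters at a divergence threshold
#'
#' Connected components of the graph whose edges join specimen pairs with
#' distance strictly below `threshold`; undefined distances contribute no
#' edge. Because linkage chains, two specimens further apart than the
#' threshold can still share a cluster through intermediates.
#'
#' @param dm A `k2p_dist` object.
#' @param threshold Percent threshold (default 2.2).
#' @return A tibble `specimen_id`, `cluster_id`; cluster ids (`C0001`, ...)
#'   are assigned in order of each cluster's first member in the input order.
#' @export
single_linkage_preclusters <- function(dm, threshold = 2.2) {
  adj <- !is.na(dm$d) & dm$d * 100 < threshold
  comp <- graph_components(adj)
  tibble::tibble(specimen_id = dm$ids, cluster_id = label_clusters(comp))
}

# BFS connected components of a logical adjacency matrix
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# membership integers -> "C####" in order of first appearance
label_clusters <- function(comp) {
  first <- match(unique(comp), comp)
  ord <- rank(first)
  relabel <- setNames(ord[match(comp, unique(comp))], NULL)
  sprintf("C%04d", relabel)
}

#' Markov-clustering refinement of one pre-cluster
#'
#' Runs MCL on the similarity graph of the pre-cluster's members (edge weight
#' `max(0, 1 - d/similarity_threshold)`, self-loops of weight 1, column
#' stochastic; expansion then elementwise inflation per iteration) and returns
#' the resulting partition as an integer membership vector. If MCL fails to
#' converge within the iteration cap the pre-cluster is returned unsplit with
#' a warning.
#'
#' @param dm A `k2p_dist` object.
#' @param ids Specimen ids of one pre-cluster (length >= 2).
#' @param config A [resl_config()].
#' @return Integer membership vector along `ids`.
#' @export
mcl_refine <- function(dm, ids, config = resl_config()) {
  n <- length(ids)
  stopifnot(n >= 2)
  d <- dm$d[ids, ids, drop = FALSE] * 100
  w <- 1 - d / config$similarity_threshold
  w[is.na(d) | w < 0] <- 0
  diag(w) <- 1
  M <- sweep(w, 2, colSums(w), "/")
  converged <- FALSE
  for (iter in seq_len(config$mcl_max_iter)) {
    M2 <- M
    for (e in seq_len(config$mcl_expansion - 1)) M2 <- M2 %*% M
    M2 <- M2^config$mcl_inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < config$mcl_tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warn("mcl_refine: no convergence; pre-cluster left unsplit")
    return(rep(1L, n))
  }
  graph_components(M > 1e-6 | t(M) > 1e-6)
}

#' Mean silhouette of a partition under a distance matrix
#'
#' For each specimen, `s = (b - a) / max(a, b)` with `a` the mean distance to
#' its own cluster's other members and `b` the smallest mean distance to any
#' other cluster. Members of singleton clusters contribute `s = 0`, and a
#' single-cluster partition has mean silhouette 0 by convention (there is no
#' between-cluster structure to reward).
#'
#' @param membership Integer membership vector.
#' @param d Distance matrix (any consistent units) aligned with `membership`;
#'   undefined entries (`NA`) are skipped in the means.
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(membership, d) {
  ks <- unique(membership)
  if (length(ks) < 2) return(0)
  n <- length(membership)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- membership == membership[i]
    own[i] <- FALSE
    if (!any(own)) { s[i] <- 0; next }
    a <- mean(d[i, own], na.rm = TRUE)
    b <- min(vapply(setdiff(ks, membership[i]), function(k) {
      mean(d[i, membership == k], na.rm = TRUE)
    }, numeric(1)))
    if (is.nan(a) || is.nan(b)) { s[i] <- 0; next }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Assign BIN-style clusters by refined single linkage
#'
#' Full RESL-lite procedure: single-linkage pre-clustering at
#' `precluster_threshold`, MCL refinement of each pre-cluster, and acceptance
#' of the refinement only if it improves the pre-cluster's mean silhouette by
#' more than `silhouette_min_gain` over the unsplit value of 0. The silhouette
#' criterion is applied per pre-cluster. Cluster ids are deterministic given
#' the input order.
#'
#' @param dm A `k2p_dist` object.
#' @param ds The barcode dataset tibble (used only for order/validation).
#' @param config A [resl_config()].
#' @return A tibble `specimen_id`, `cluster_id`.
#' @export
assign_bins <- function(dm, ds, config = resl_config()) {
  stopifnot(identical(dm$ids, ds$specimen_id))
  pre <- single_linkage_preclusters(dm, config$precluster_threshold)
  d_pct <- dm$d * 100
  membership <- integer(nrow(pre))
  next_id <- 0L
  for (cl in unique(pre$cluster_id)) {
    idx <- which(pre$cluster_id == cl)
    if (length(idx) == 1) {
      parts <- 1L
    } else {
      refined <- mcl_refine(dm, dm$ids[idx], config)
      if (length(unique(refined)) > 1 &&
          silhouette_mean(refined, d_pct[idx, idx, drop = FALSE]) >
          config$silhouette_min_gain) {
        parts <- refined
      } else {
        parts <- rep(1L, length(idx))
      }
    }
    membership[idx] <- next_id + as.integer(factor(parts, levels = unique(parts)))
    next_id <- next_id + length(unique(parts))
  }
  tibble::tibble(specimen_id = dm$ids, cluster_id = label_clusters(membership))
}

#' Species-cluster concordance classification
#'
#' Classifies each species by how its specimens map onto clusters:
#' `match` (one cluster, not shared with any other species), `merge` (one
#' cluster, shared), `split` (several clusters, none shared) and `mixture`
#' (several clusters, at least one shared). For split/mixture species the
#' regional pattern distinguishes splits that separate the two regions
#' (`between_regions`: its clusters occupy disjoint region sets), splits whose
#' clusters co-occur within a region (`within_region`), or `both`.
#'
#' @param assignment A tibble `specimen_id`, `cluster_id` from [assign_bins()].
#' @param ds The barcode dataset tibble (species and region per specimen).
#' @return A tibble per species: `species`, `n_specimens`, `n_clusters`,
#'   `cluster_ids` (list column), `sharing`, `class`,
#'   `split_regional_pattern`.
#' @export
bin_concordance <- function(assignment, ds) {
  dat <- dplyr::left_join(assignment,
                          dplyr::select(ds, "specimen_id", "species", "region",
                                        dplyr::any_of("distribution_category")),
                          by = "specimen_id")
  if (anyNA(dat$species) || anyNA(dat$region)) {
    abort("Every specimen needs a species and a region")
  }
  species_per_cluster <- dat |>
    dplyr::distinct(.data$cluster_id, .data$species) |>
    dplyr::count(.data$cluster_id, name = "n_species")
  shared_clusters <- species_per_cluster$cluster_id[species_per_cluster$n_species > 1]

  dat |>
    dplyr::group_by(.data$species) |>
    dplyr::group_modify(function(g, key) {
      cls <- unique(g$cluster_id)
      k <- length(cls)
      sharing <- any(cls %in% shared_clusters)
      class <- if (k == 1 && !sharing) "match" else if (k == 1) "merge"
        else if (!sharing) "split" else "mixture"
      pattern <- if (k == 1) NA_character_ else {
        regions_by_cluster <- lapply(cls, function(cl)
          unique(g$region[g$cluster_id == cl]))
        pairs <- combn(k, 2)
        disjoint <- apply(pairs, 2, function(p)
          length(intersect(regions_by_cluster[[p[1]]], regions_by_cluster[[p[2]]])) == 0)
        if (all(disjoint)) "between_regions"
        else if (!any(disjoint)) "within_region"
        else "both"
      }
      tibble::tibble(n_specimens = nrow(g), n_clusters = k,
                     cluster_ids = list(sort(cls)), sharing = sharing,
                     class = class, split_regional_pattern = pattern)
    }) |>
    dplyr::ungroup()
}

#' Aggregate concordance counts
#'
#' Cross-tabulates species by number of clusters, sharing and regional
#' pattern, overall and (when the dataset carries distribution categories) per
#' category.
#'
#' @param concordance Output of [bin_concordance()].
#' @param ds Optional dataset tibble providing `distribution_category` per
#'   species.
#' @return A list with `by_class` (species counts per concordance class) and
#'   `by_pattern` (counts per `n_clusters` x `sharing` x pattern cell), the
#'   latter stratified by category if available.
#' @export
concordance_summary <- function(concordance, ds = NULL) {
  by_class <- dplyr::count(concordance, .data$class, name = "n_species")
  tab <- concordance
  if (!is.null(ds) && "distribution_category" %in% names(ds)) {
    cat_by_sp <- dplyr::distinct(ds, .data$species, .data$distribution_category)
    tab <- dplyr::left_join(tab, cat_by_sp, by = "species")
    by_pattern <- dplyr::count(tab, .data$distribution_category, .data$n_clusters,
                               .data$sharing, .data$split_regional_pattern,
                               name = "n_species")
  } else {
    by_pattern <- dplyr::count(tab, .data$n_clusters, .data$sharing,
                               .data$split_regional_pattern, name = "n_species")
  }
  list(by_class = by_class, by_pattern = by_pattern)
}
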