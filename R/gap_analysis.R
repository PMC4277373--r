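#' Per-species barcode-gap statistics
#'
#' For every species in the dataset, computes the maximum and mean pairwise
#' intraspecific K2P distance, the nearest-neighbour (NN) species — the
#' heterospecific species attaining the minimum interspecific distance — and
#' that minimum, the presence of a barcode gap (`nn_dist > max_intra`), a
#' diagnosability call (see [diagnosable()]), and the harmonic mean of the
#' focal and NN sample sizes. All distances are reported in percent.
#'
#' Undefined pairs (insufficient overlap or saturation) are skipped in every
#' minimum and maximum. Singletons get `max_intra = mean_intra = 0` and a
#' `singleton` flag. NN ties are broken by lexicographic species name and the
#' tie is signalled with a message.
#'
#' @param dm A `k2p_dist` object over the specimens of `ds`.
#' @param ds The barcode dataset tibble (every specimen must carry a species).
#' @return A tibble with one row per species: `species`, `n_specimens`,
#'   `singleton`, `max_intra`, `mean_intra`, `nn_species`, `nn_dist`,
#'   `gap_present`, `diagnosable`, `harmonic_n` (distances in %).
#' @export
species_gap_stats <- function(dm, ds) {
  validate_barcode_dataset(ds)
  if (anyNA(ds$species)) abort("Every specimen must have a species label")
  stopifnot(identical(dm$ids, ds$specimen_id))
  sp <- ds$species
  species <- sort(unique(sp))
  n_by_sp <- table(sp)
  d <- dm$d * 100

  rows <- lapply(species, function(s) {
    idx <- which(sp == s)
    n <- length(idx)
    if (n == 1) {
      max_intra <- 0; mean_intra <- 0
    } else {
      intra <- d[idx, idx][upper.tri(diag(n))]
      intra <- intra[!is.na(intra)]
      max_intra <- if (length(intra)) max(intra) else 0
      mean_intra <- if (length(intra)) mean(intra) else 0
    }
    inter <- d[idx, -idx, drop = FALSE]
    other_sp <- sp[-idx]
    fin <- !is.na(inter)
    if (!any(fin)) {
      nn_species <- NA_character_; nn_dist <- NA_real_
    } else {
      nn_dist <- min(inter[fin])
      cand <- sort(unique(other_sp[colSums(fin & inter <= nn_dist + 1e-12, na.rm = TRUE) > 0]))
      # per-species minima, to identify exact attainment
      mins <- vapply(cand, function(o) {
        sub <- inter[, other_sp == o, drop = FALSE]
        min(sub, na.rm = TRUE)
      }, numeric(1))
      att <- cand[abs(mins - nn_dist) < 1e-12]
      if (length(att) > 1) {
        inform(sprintf("NN tie for %s between: %s (lexicographic winner kept)",
                       s, paste(att, collapse = ", ")))
      }
      nn_species <- sort(att)[1]
    }
    harmonic_n <- if (is.na(nn_species)) NA_real_ else
      harmonic_mean(n, as.integer(n_by_sp[[nn_species]]))
    tibble::tibble(
      species = s, n_specimens = n, singleton = n == 1,
      max_intra = max_intra, mean_intra = mean_intra,
      nn_species = nn_species, nn_dist = nn_dist,
      gap_present = !is.na(nn_dist) & nn_dist > max_intra,
      diagnosable = diagnosable_idx(idx, d, sp),
      harmonic_n = harmonic_n)
  })
  dplyr::bind_rows(rows)
}

#' Is a species diagnosable by its barcodes?
#'
#' A species is called diagnosable when (a) no conspecific-heterospecific pair
#' has distance zero (no barcode sharing) and (b) the maximum edge of the
#' minimum spanning tree connecting its specimens under conspecific distances
#' is strictly less than its minimum interspecific distance — i.e. there is a
#' threshold at which single-linkage clustering isolates the species exactly.
#' Species with deep internal splits remain diagnosable as long as their
#' internal chain stays tighter than the distance to the nearest neighbour;
#' intermingled or barcode-sharing species fail.
#'
#' @param species Species name.
#' @param dm A `k2p_dist` object.
#' @param ds The barcode dataset tibble.
#' @return Logical scalar.
#' @export
diagnosable <- function(species, dm, ds) {
  if (!species %in% ds$species) abort(sprintf("Species '%s' not in dataset", species))
  diagnosable_idx(which(ds$species == species), dm$d * 100, ds$species)
}

diagnosable_idx <- function(idx, d_pct, sp) {
  inter <- d_pct[idx, -idx, drop = FALSE]
  if (any(inter == 0, na.rm = TRUE)) return(FALSE)
  min_inter <- if (all(is.na(inter))) Inf else min(inter, na.rm = TRUE)
  if (length(idx) == 1) return(min_inter > 0)
  sub <- d_pct[idx, idx, drop = FALSE]
  sub[is.na(sub)] <- Inf
  mst_max_edge(sub) < min_inter
}

# Prim's algorithm; returns the largest edge of the MST (Inf if disconnected,
# which only happens via undefined distances)
mst_max_edge <- function(d) {
  n <- nrow(d)
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best <- d[1, ]
  max_edge <- 0
  for (step in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    max_edge <- max(max_edge, best[j])
    in_tree[j] <- TRUE
    best <- pmin(best, d[j, ])
  }
  max_edge
}

#' Census of species against maximum-intraspecific thresholds
#'
#' Counts, for each threshold `t`, the species whose maximum intraspecific
#' distance is strictly below `t` (the strict inequality matches the
#' convention of reporting "<1%", "<2%" bins), plus the species with zero
#' divergence and those at or above the top threshold.
#'
#' @param stats Output of [species_gap_stats()].
#' @param thresholds Strictly increasing percent thresholds (default `c(1, 2)`).
#' @return A tibble with columns `bin`, `count`, `fraction`.
#' @export
threshold_census <- function(stats, thresholds = c(1, 2)) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("thresholds must be strictly increasing")
  }
  n <- nrow(stats)
  frac <- function(k) if (n == 0) 0 else k / n
  rows <- list(tibble::tibble(bin = "=0", count = sum(stats$max_intra == 0),
                              fraction = frac(sum(stats$max_intra == 0))))
  for (t in thresholds) {
    k <- sum(stats$max_intra < t)
    rows[[length(rows) + 1]] <- tibble::tibble(
      bin = paste0("<", t), count = k, fraction = frac(k))
  }
  top <- thresholds[length(thresholds)]
  k <- sum(stats$max_intra >= top)
  rows[[length(rows) + 1]] <- tibble::tibble(
    bin = paste0(">=", top), count = k, fraction = frac(k))
  dplyr::bind_rows(rows)
}

#' Harmonic mean of two sample sizes
#'
#' `H = 2 n1 n2 / (n1 + n2)`, used to weight nearest-neighbour distances by
#' the sampling depth of both members of the pair.
#'
#' @param n1,n2 Positive sample sizes.
#' @return The harmonic mean.
#' @export
harmonic_mean <- function(n1, n2) {
  if (any(c(n1, n2) < 1)) abort("Sample sizes must be >= 1")
  2 * n1 * n2 / (n1 + n2)
}

#' Regression of NN distance on log10 harmonic-mean sample size
#'
#' Ordinary least squares of the nearest-neighbour distance (%) on the base-10
#' logarithm of the harmonic mean of the focal and NN sample sizes; sparser
#' sampling inflates the apparent distance to the nearest neighbour, and the
#' slope quantifies that bias.
#'
#' @param stats Output of [species_gap_stats()].
#' @return A one-row tibble: `slope`, `intercept`, `p_value` (two-sided t-test
#'   on the slope), `n`.
#' @export
nn_vs_samplesize_regression <- function(stats) {
  dat <- stats[!is.na(stats$nn_dist) & !is.na(stats$harmonic_n), ]
  if (nrow(dat) < 3) abort("Need >= 3 species with a defined NN distance")
  x <- log10(dat$harmonic_n)
  if (var(x) == 0) abort("Zero variance in log10 harmonic-mean sample size")
  fit <- lm(nn_dist ~ x, data = tibble::tibble(nn_dist = dat$nn_dist, x = x))
  s <- summary(fit)$coefficients
  tibble::tibble(slope = s["x", "Estimate"], intercept = s["(Intercept)", "Estimate"],
                 p_value = s["x", "Pr(>|t|)"], n = nrow(dat))
}

#' Residuals of maximum intraspecific distance against sample size
#'
#' Residuals from an OLS regression of `max_intra` (%) on the number of
#' specimens, used to compare families or categories while accounting for
#' unequal sampling. When every species has the same sample size the slope is
#' unidentifiable and the function falls back to mean-centering.
#'
#' @param stats Output of [species_gap_stats()].
#' @return A tibble `species`, `residual`.
#' @export
intra_vs_samplesize_residuals <- function(stats) {
  if (nrow(stats) < 3) abort("Need >= 3 species")
  if (var(stats$n_specimens) == 0) {
    res <- stats$max_intra - mean(stats$max_intra)
  } else {
    res <- stats::residuals(lm(max_intra ~ n_specimens, data = stats))
  }
  tibble::tibble(species = stats$species, residual = unname(res))
}

#' Compare reference-only with pooled barcode-gap statistics
#'
#' Recomputes per-species statistics on the reference-region subset alone and
#' on the pooled dataset, quantifying how extending geographic sampling raises
#' maximum intraspecific distances and erodes nearest-neighbour distances.
#' Only species with at least one reference-region specimen appear; others are
#' dropped with a message.
#'
#' @param dm A `k2p_dist` over all specimens of `ds`.
#' @param ds A barcode dataset containing both regions.
#' @return A tibble per species: `max_intra_ref`, `max_intra_pooled`,
#'   `nn_dist_ref`, `nn_dist_pooled`, `nn_species_ref`, `nn_species_pooled`,
#'   `nn_changed`, `nn_reduction_pct` (= 100 (nn_ref - nn_pooled) / nn_ref).
#' @export
partition_compare <- function(dm, ds) {
  if (!all(c("reference", "query") %in% ds$region)) {
    abort("Dataset must contain both a reference and a query region")
  }
  ref <- ds[ds$region == "reference", , drop = FALSE]
  dropped <- setdiff(unique(ds$species), unique(ref$species))
  if (length(dropped)) {
    inform(sprintf("partition_compare: %d species without reference specimens excluded",
                   length(dropped)))
  }
  stats_ref <- species_gap_stats(subset_k2p(dm, ref$specimen_id), ref)
  stats_pool <- species_gap_stats(dm, ds)
  dplyr::inner_join(
    dplyr::select(stats_ref, "species", max_intra_ref = "max_intra",
                  nn_dist_ref = "nn_dist", nn_species_ref = "nn_species"),
    dplyr::select(stats_pool, "species", max_intra_pooled = "max_intra",
                  nn_dist_pooled = "nn_dist", nn_species_pooled = "nn_species"),
    by = "species") |>
    dplyr::mutate(
      nn_changed = .data$nn_species_ref != .data$nn_species_pooled,
      nn_reduction_pct = ifelse(.data$nn_dist_ref > 0,
                                100 * (.data$nn_dist_ref - .data$nn_dist_pooled) /
                                  .data$nn_dist_ref, 0))
}
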