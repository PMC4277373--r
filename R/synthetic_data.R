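#' Configuration for the synthetic barcode-library generator
#'
#' The generator emulates a two-region barcode-library study: a densely
#' sampled reference region (3-4 specimens per species) and a sparsely
#' sampled query region (1-2 specimens), species nested in genera nested in
#' families, mostly sub-1% intraspecific divergence, nearest-neighbour
#' distances averaging several percent, a minority of species carrying deep
#' (>2%) splits, and migratory species with near-zero divergence.
#'
#' Sequences evolve under a K80 substitution process, the same model family as
#' the K2P analysis metric, so configured branch lengths are recovered (in
#' expectation) by the distance computation.
#'
#' @param n_families,genera_per_family,species_per_genus Taxonomic layout
#'   (defaults 10 x 4 x 5 = 200 species).
#' @param seq_length Alignment length in bp (default 658).
#' @param kappa Transition/transversion rate ratio of the K80 process
#'   (default 4).
#' @param inter_mean,inter_floor Mean and floor of the expected pairwise
#'   interspecific divergence within a genus, in percent (defaults 8 and 3).
#'   Species branch depths are `inter_floor/2` plus an exponential with mean
#'   `(inter_mean - inter_floor)/2`, so pairwise sums have the stated mean and
#'   floor.
#' @param intra_expected Named numeric: expected maximum intraspecific
#'   divergence (%) per distribution category (defaults continuous 0.8,
#'   fragmented 1.1, disjunct 0.9, migratory 0.1).
#' @param category_props Named numeric summing to 1: share of species per
#'   category (defaults 0.45, 0.30, 0.235, 0.015). Counts are allocated
#'   deterministically by largest remainder so every category with positive
#'   share is represented.
#' @param deep_split_fraction Fraction of non-migratory species carrying an
#'   extra deep split (default 0.12). The count is allocated exactly
#'   (rounded); which species carry a split, and the split depths, are drawn
#'   from the seeded generator.
#' @param deep_split_range Depth range of injected splits in percent (default
#'   `c(2, 10)`, uniform).
#' @param n_ref,n_query Ranges (integer vectors) of specimens per species in
#'   the reference and query regions (defaults `3:4` and `1:2`).
#' @param n_noise_rate Per-site probability of masking a base as `N` in the
#'   emitted sequences (default 0), for exercising pairwise deletion.
#' @param seed Mandatory integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_families = 10, genera_per_family = 4,
                              species_per_genus = 5, seq_length = 658,
                              kappa = 4, inter_mean = 8, inter_floor = 3,
                              intra_expected = c(continuous = 0.8, fragmented = 1.1,
                                                 disjunct = 0.9, migratory = 0.1),
                              category_props = c(continuous = 0.45, fragmented = 0.30,
                                                 disjunct = 0.235, migratory = 0.015),
                              deep_split_fraction = 0.12,
                              deep_split_range = c(2, 10),
                              n_ref = 3:4, n_query = 1:2,
                              n_noise_rate = 0, seed) {
  if (missing(seed)) abort("A seed is mandatory")
  if (inter_floor > inter_mean) abort("inter_floor must not exceed inter_mean")
  stopifnot(kappa > 0, deep_split_fraction >= 0, deep_split_fraction <= 1,
            abs(sum(category_props) - 1) < 1e-8,
            all(deep_split_range > 0), diff(deep_split_range) >= 0)
  structure(list(n_families = n_families, genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus, seq_length = seq_length,
                 kappa = kappa, inter_mean = inter_mean, inter_floor = inter_floor,
                 intra_expected = intra_expected, category_props = category_props,
                 deep_split_fraction = deep_split_fraction,
                 deep_split_range = deep_split_range,
                 n_ref = n_ref, n_query = n_query,
                 n_noise_rate = n_noise_rate, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Evolve a sequence along a branch under K80
#'
#' Applies the K80 transition probabilities for a branch of `d` expected
#' substitutions per site (transition/transversion ratio `kappa`) to each site
#' independently: per site the base stays, undergoes the transition, or one of
#' the two transversions, with the exact finite-time probabilities. Because
#' the process is a proper Markov chain, branch lengths are additive and the
#' K2P distance estimator recovers the total path length in expectation.
#'
#' @param seq_int Integer-encoded sequence (A=1, C=2, G=3, T=4).
#' @param d Branch length as expected substitutions per site (proportion, not
#'   percent).
#' @param kappa Transition/transversion rate ratio.
#' @return The evolved integer-encoded sequence.
#' @export
evolve_k80 <- function(seq_int, d, kappa = 4) {
  if (d <= 0) return(seq_int)
  bt <- d / (kappa + 2)               # beta * t with rate alpha + 2 beta = 1
  at <- kappa * bt
  p_tv_each <- 0.25 - 0.25 * exp(-4 * bt)
  p_ti <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  L <- length(seq_int)
  u <- runif(L)
  ti_partner <- c(3L, 4L, 1L, 2L)     # A<->G, C<->T
  tv1 <- c(2L, 1L, 2L, 1L)            # A->C, C->A, G->C, T->A
  tv2 <- c(4L, 3L, 4L, 3L)            # A->T, C->G, G->T, T->G
  out <- seq_int
  sel_ti <- u < p_ti
  sel_tv1 <- !sel_ti & u < p_ti + p_tv_each
  sel_tv2 <- !sel_ti & !sel_tv1 & u < p_ti + 2 * p_tv_each
  out[sel_ti] <- ti_partner[seq_int[sel_ti]]
  out[sel_tv1] <- tv1[seq_int[sel_tv1]]
  out[sel_tv2] <- tv2[seq_int[sel_tv2]]
  out
}

decode_dna <- function(seq_int) {
  paste(c("A", "C", "G", "T", "N")[ifelse(seq_int == 0L, 5L, seq_int)], collapse = "")
}

#' Generate a synthetic two-region barcode library with ground truth
#'
#' Draws an ancestral sequence per genus, evolves each species' ancestor down
#' a branch giving the configured interspecific divergence, then places
#' reference- and query-region specimens on regionally diverged lineages. The
#' category's `intra_expected` value is the expected *realized maximum*
#' intraspecific distance: because the maximum over several noisy pairwise
#' estimates exceeds the largest single-pair expectation, the cross-region
#' pair expectation is set to 0.7 of it and the within-region pairwise
#' expectation to 0.35 of it (mirroring the roughly 0.6 ratio between
#' reference-only and pooled maxima). A fraction `deep_split_fraction` of the
#' non-migratory species (exact count, seeded placement) receives an extra
#' split of uniform depth from `deep_split_range`, placed between the regions
#' with probability 1/2 and inside the reference region otherwise. Migratory
#' species keep near-zero divergence and never receive deep splits. All draws
#' come from the seeded generator, so equal seeds give identical output.
#'
#' @param config A [simulation_config()].
#' @return A list with `dataset` (a barcode dataset tibble as produced by
#'   [read_barcode_dataset()]) and `truth`, itself a list of `species` (per
#'   species: category, deep-split flag/depth/placement, regional divergence)
#'   and `specimens` (per specimen: lineage label).
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_species <- config$n_families * config$genera_per_family * config$species_per_genus
  categories <- allocate_categories(config$category_props, n_species)
  # deep-split prevalence is a composition of the library, not a per-species
  # coin flip: allocate the configured fraction of non-migratory species
  # exactly, with seeded placement
  eligible <- which(categories != "migratory")
  n_split <- round(config$deep_split_fraction * length(eligible))
  split_flags <- logical(n_species)
  if (n_split > 0) split_flags[sample(eligible, n_split)] <- TRUE

  species_rows <- list()
  specimen_rows <- list()
  sp_i <- 0
  for (f in seq_len(config$n_families)) {
    fam <- sprintf("Family%02d", f)
    for (g in seq_len(config$genera_per_family)) {
      genus <- sprintf("Genus%02d%02d", f, g)
      anc <- sample.int(4L, config$seq_length, replace = TRUE)
      for (s in seq_len(config$species_per_genus)) {
        sp_i <- sp_i + 1
        species <- sprintf("%s sp%02d", genus, s)
        category <- categories[sp_i]
        # branch depth from genus ancestor, percent
        depth <- config$inter_floor / 2 +
          rexp(1, rate = 2 / max(config$inter_mean - config$inter_floor, 1e-9))
        sp_anc <- evolve_k80(anc, depth / 100, config$kappa)

        # delta is the expected realized MAX intraspecific distance; the max
        # over ~6-10 noisy pairwise estimates sits ~1.3x above the largest
        # pairwise expectation at barcode length, so the cross-region pair
        # expectation is set to 0.7 delta (within-region 0.35 delta)
        delta <- config$intra_expected[[category]]
        b_ref <- 0.175 * delta
        b_query <- 0.05 * delta
        r_div <- max(0.7 * delta - b_ref - b_query, 0)

        deep <- split_flags[sp_i]
        split_depth <- 0
        split_where <- "none"
        if (deep) {
          split_depth <- runif(1, config$deep_split_range[1], config$deep_split_range[2])
          split_where <- if (runif(1) < 0.5) "between_regions" else "within_reference"
        }
        if (split_where == "between_regions") r_div <- split_depth

        ref_anc <- sp_anc
        query_anc <- evolve_k80(sp_anc, r_div / 100, config$kappa)
        n_ref <- sample_int_from(config$n_ref)
        n_query <- sample_int_from(config$n_query)
        split_anc <- if (split_where == "within_reference")
          evolve_k80(ref_anc, split_depth / 100, config$kappa) else NULL
        n_split <- if (is.null(split_anc)) 0 else max(1, floor(n_ref / 2))

        for (k in seq_len(n_ref)) {
          on_split <- k <= n_split
          start <- if (on_split) split_anc else ref_anc
          seq_k <- evolve_k80(start, b_ref / 100, config$kappa)
          specimen_rows[[length(specimen_rows) + 1]] <- tibble::tibble(
            specimen_id = sprintf("SP%04d-R%02d", sp_i, k),
            species = species, genus = genus, family = fam,
            region = "reference", distribution_category = category,
            sequence_int = list(seq_k),
            lineage = if (on_split) "reference_split" else "reference_main")
        }
        for (k in seq_len(n_query)) {
          seq_k <- evolve_k80(query_anc, b_query / 100, config$kappa)
          specimen_rows[[length(specimen_rows) + 1]] <- tibble::tibble(
            specimen_id = sprintf("SP%04d-Q%02d", sp_i, k),
            species = species, genus = genus, family = fam,
            region = "query", distribution_category = category,
            sequence_int = list(seq_k), lineage = "query")
        }
        species_rows[[sp_i]] <- tibble::tibble(
          species = species, genus = genus, family = fam,
          distribution_category = category, deep_split = deep,
          split_depth = split_depth, split_location = split_where,
          regional_divergence = r_div, n_reference = n_ref, n_query = n_query)
      }
    }
  }
  spec <- dplyr::bind_rows(specimen_rows)
  seqs <- vapply(spec$sequence_int, function(x) {
    if (config$n_noise_rate > 0) {
      x[runif(length(x)) < config$n_noise_rate] <- 0L
    }
    decode_dna(x)
  }, character(1))
  dataset <- spec |>
    dplyr::select(-"sequence_int", -"lineage") |>
    dplyr::mutate(dispersal_class = NA_character_, sequence = seqs,
                  effective_length = effective_length(seqs), .after = "distribution_category")
  attr(dataset, "alignment_length") <- config$seq_length
  list(dataset = dataset,
       truth = list(species = dplyr::bind_rows(species_rows),
                    specimens = dplyr::select(spec, "specimen_id", "species", "lineage")))
}

sample_int_from <- function(rng) if (length(rng) == 1) rng else sample(rng, 1)

# largest-remainder allocation, then a seeded shuffle across species
allocate_categories <- function(props, n) {
  base <- floor(props * n)
  rem <- props * n - base
  short <- n - sum(base)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    base[add] <- base[add] + 1
  }
  sample(rep(names(props), times = base))
}

#' Named simulation scenario presets
#'
#' * `study_like`: the default configuration — 200 species, ~12% deep splits,
#'   category-specific intraspecific divergences, interspecific mean 8% with
#'   floor 3%.
#' * `no_structure`: no deep splits, uniformly tight intraspecific divergence
#'   (0.3%) and well-separated species (floor 7%), so clusters should
#'   reproduce species exactly.
#' * `heavy_splits`: 40% of species carry deep splits of 4-10%.
#'
#' @param name Preset name; omit to list available presets.
#' @param seed Seed passed to [simulation_config()].
#' @param ... Overrides forwarded to [simulation_config()] (e.g. a smaller
#'   taxonomic layout).
#' @return A `simulation_config`.
#' @export
scenario_config <- function(name, seed, ...) {
  presets <- list(
    study_like = list(),
    no_structure = list(
      deep_split_fraction = 0,
      intra_expected = c(continuous = 0.3, fragmented = 0.3,
                         disjunct = 0.3, migratory = 0.1),
      inter_mean = 9, inter_floor = 7),
    heavy_splits = list(deep_split_fraction = 0.4, deep_split_range = c(4, 10)))
  if (!name %in% names(presets)) {
    abort(paste0("Unknown preset '", name, "'; available: ",
                 paste(names(presets), collapse = ", ")))
  }
  args <- utils::modifyList(presets[[name]], list(seed = seed, ...))
  do.call(simulation_config, args)
}
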