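# Shared fixtures and independent oracles for the test suite.

DNA <- c("A", "C", "G", "T")

# build a dataset tibble directly from sequences
make_ds <- function(sequences, species, region = "reference",
                    genus = sub(" .*", "", species), family = "Fam",
                    category = NA_character_) {
  n <- length(sequences)
  tibble::tibble(
    specimen_id = sprintf("s%02d", seq_len(n)),
    species = rep_len(species, n), genus = rep_len(genus, n),
    family = rep_len(family, n), region = rep_len(region, n),
    distribution_category = rep_len(category, n),
    dispersal_class = NA_character_,
    sequence = sequences,
    effective_length = effective_length(sequences))
}

# a k2p_dist object built from an explicit percent-distance matrix
make_dm <- function(d_percent, ids = NULL) {
  n <- nrow(d_percent)
  if (is.null(ids)) ids <- sprintf("s%02d", seq_len(n))
  d <- d_percent / 100
  dimnames(d) <- list(ids, ids)
  ns <- matrix(658, n, n, dimnames = list(ids, ids))
  structure(list(ids = ids, d = d, n_sites = ns,
                 undefined_pairs = tibble::tibble(id1 = character(),
                                                  id2 = character(),
                                                  reason = character()),
                 min_overlap = 100),
            class = "k2p_dist")
}

# random related sequences: one ancestor, descendants at random K80 branch
# lengths (avoids saturation so every pair is defined)
random_related_seqs <- function(n, L = 658, max_branch = 0.06) {
  anc <- sample.int(4L, L, replace = TRUE)
  vapply(seq_len(n), function(i) {
    s <- evolve_k80(anc, runif(1, 0.001, max_branch), 4)
    paste(DNA[s], collapse = "")
  }, character(1))
}

# literal site-by-site K2P oracle, independent of the matrix implementation
k2p_brute <- function(a, b, min_overlap = 100) {
  sa <- strsplit(a, "")[[1]]
  sb <- strsplit(b, "")[[1]]
  n <- 0L; ti <- 0L; tv <- 0L
  for (i in seq_along(sa)) {
    x <- sa[i]; y <- sb[i]
    if (!(x %in% DNA) || !(y %in% DNA)) next
    n <- n + 1L
    if (x == y) next
    if ((x %in% c("A", "G") && y %in% c("A", "G")) ||
        (x %in% c("C", "T") && y %in% c("C", "T"))) ti <- ti + 1L else tv <- tv + 1L
  }
  if (n < min_overlap) return(NA_real_)
  P <- ti / n; Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -1 / 2 * log(1 - 2 * P - Q) - 1 / 4 * log(1 - 2 * Q)
}

# exhaustive double-loop recomputation of per-species gap statistics
gap_stats_brute <- function(dm, ds) {
  d <- dm$d * 100
  sp <- ds$species
  out <- list()
  for (s in sort(unique(sp))) {
    idx <- which(sp == s)
    intra <- c()
    if (length(idx) > 1) {
      for (i in idx) for (j in idx) if (i < j && !is.na(d[i, j])) {
        intra <- c(intra, d[i, j])
      }
    }
    best <- Inf; best_sp <- NA_character_
    for (i in idx) for (j in seq_along(sp)) {
      if (sp[j] == s || is.na(d[i, j])) next
      if (d[i, j] < best - 1e-12 ||
          (abs(d[i, j] - best) <= 1e-12 && !is.na(best_sp) && sp[j] < best_sp)) {
        best <- d[i, j]; best_sp <- sp[j]
      }
    }
    out[[s]] <- tibble::tibble(
      species = s,
      max_intra = if (length(intra)) max(intra) else 0,
      mean_intra = if (length(intra)) mean(intra) else 0,
      nn_species = best_sp,
      nn_dist = if (is.finite(best)) best else NA_real_)
  }
  dplyr::bind_rows(out)
}
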