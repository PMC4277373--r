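#' Count transition/transversion site pairs between two aligned sequences
#'
#' Compares two equal-length aligned sequences site by site under pairwise
#' deletion: positions where either base is not an unambiguous A/C/G/T
#' (ambiguity codes, N, gaps) are excluded from the comparison. Among the
#' remaining sites, transitions are A<->G and C<->T; every other mismatch is a
#' transversion.
#'
#' @param a,b Character scalars: aligned DNA sequences of equal length.
#' @return A list with `P` (transition proportion), `Q` (transversion
#'   proportion) and `n_sites` (number of compared sites). `P` and `Q` are 0
#'   when no sites are comparable.
#' @export
#' @examples
#' count_site_pairs("ACGT", "GCGT") # one A<->G transition over 4 sites
count_site_pairs <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort(sprintf("Sequence lengths differ (%d vs %d)", nchar(a), nchar(b)))
  }
  ai <- encode_dna(a)
  bi <- encode_dna(b)
  valid <- ai > 0L & bi > 0L
  n <- sum(valid)
  if (n == 0) return(list(P = 0, Q = 0, n_sites = 0L))
  av <- ai[valid]; bv <- bi[valid]
  diff <- av != bv
  # purines are A(1), G(3); a mismatch within purines or within pyrimidines is
  # a transition
  ti <- diff & ((av %% 2L) == (bv %% 2L))
  list(P = sum(ti) / n, Q = sum(diff & !ti) / n, n_sites = as.integer(n))
}

# A=1, C=2, G=3, T=4, anything else 0; odd codes are purines
encode_dna <- function(x) {
  map <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  s <- strsplit(toupper(x), "")[[1]]
  out <- unname(map[s])
  out[is.na(out)] <- 0L
  out
}

#' Kimura 2-parameter distance from site-pair counts
#'
#' Evaluates `d = -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)` where `P` and
#' `Q` are the transition and transversion proportions among compared sites.
#' The distance is undefined (returned as `NA`) when the site overlap is below
#' `min_overlap` or when either logarithm argument is non-positive
#' (saturation); saturated pairs are reported as undefined rather than clamped,
#' since clamping would silently distort nearest-neighbour minima.
#'
#' @param counts A list as returned by [count_site_pairs()].
#' @param min_overlap Minimum number of compared sites for a defined distance
#'   (default 100).
#' @return A non-negative distance (proportion units, e.g. 0.0717 = 7.17%), or
#'   `NA_real_` when undefined.
#' @export
#' @examples
#' k2p(list(P = 0.03, Q = 0.01, n_sites = 600))
k2p <- function(counts, min_overlap = 100) {
  if (counts$n_sites < min_overlap) return(NA_real_)
  a1 <- 1 - 2 * counts$P - counts$Q
  a2 <- 1 - 2 * counts$Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

#' Pairwise K2P distance matrix for a barcode dataset
#'
#' Computes the full symmetric matrix of Kimura 2-parameter distances between
#' all specimens, with pairwise deletion of sites where either sequence is
#' ambiguous or gapped. The transition/transversion site counts are obtained
#' for all pairs at once via indicator-matrix cross-products, so the cost is a
#' handful of dense matrix multiplications.
#'
#' Pairs whose compared-site count falls below `min_overlap`, or for which the
#' K2P logarithms are undefined (saturation), carry `NA` in the distance
#' matrix and are listed in `undefined_pairs`; downstream minima/maxima skip
#' them.
#'
#' @param ds A barcode dataset tibble with `specimen_id` and `sequence`
#'   columns (at least 2 rows).
#' @param min_overlap Minimum compared sites for a defined distance.
#' @return An object of class `k2p_dist`: a list with `ids`, `d` (symmetric
#'   matrix of distances in proportion units, zero diagonal), `n_sites`
#'   (matrix of compared-site counts), `undefined_pairs` (tibble `id1`, `id2`,
#'   `reason`) and `min_overlap`.
#' @export
k2p_matrix <- function(ds, min_overlap = 100) {
  validate_barcode_dataset(ds)
  n <- nrow(ds)
  if (n < 2) abort("At least 2 records are required for a distance matrix")
  L <- nchar(ds$sequence[1])
  S <- matrix(0L, n, L)
  for (i in seq_len(n)) S[i, ] <- encode_dna(ds$sequence[i])

  M <- lapply(1:4, function(b) (S == b) * 1)
  n_sites <- tcrossprod(M[[1]] + M[[2]] + M[[3]] + M[[4]])
  matches <- tcrossprod(M[[1]]) + tcrossprod(M[[2]]) +
    tcrossprod(M[[3]]) + tcrossprod(M[[4]])
  pur <- M[[1]] + M[[3]]
  pyr <- M[[2]] + M[[4]]
  # mismatches within purines plus within pyrimidines = transitions
  ti <- (tcrossprod(pur) - tcrossprod(M[[1]]) - tcrossprod(M[[3]])) +
    (tcrossprod(pyr) - tcrossprod(M[[2]]) - tcrossprod(M[[4]]))
  tv <- (n_sites - matches) - ti

  safe_n <- pmax(n_sites, 1)
  P <- ti / safe_n
  Q <- tv / safe_n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  d <- matrix(NA_real_, n, n)
  ok <- n_sites >= min_overlap & a1 > 0 & a2 > 0
  d[ok] <- -0.5 * log(a1[ok]) - 0.25 * log(a2[ok])
  diag(d) <- 0
  ids <- ds$specimen_id
  dimnames(d) <- dimnames(n_sites) <- list(ids, ids)

  und <- which(!ok & upper.tri(ok), arr.ind = TRUE)
  undefined_pairs <- tibble::tibble(
    id1 = ids[und[, 1]], id2 = ids[und[, 2]],
    reason = ifelse(n_sites[und] < min_overlap, "insufficient overlap", "saturation"))

  structure(list(ids = ids, d = d, n_sites = round(n_sites),
                 undefined_pairs = undefined_pairs, min_overlap = min_overlap),
            class = "k2p_dist")
}

#' @export
print.k2p_dist <- function(x, ...) {
  cat(sprintf("K2P distance matrix: %d specimens, %d undefined pair(s), min_overlap = %d\n",
              length(x$ids), nrow(x$undefined_pairs), x$min_overlap))
  fin <- x$d[upper.tri(x$d)]
  fin <- fin[is.finite(fin)]
  if (length(fin)) {
    cat(sprintf("  distances (%%): mean %.2f, range %.2f-%.2f\n",
                mean(fin) * 100, min(fin) * 100, max(fin) * 100))
  }
  invisible(x)
}

#' Tidy a K2P distance matrix into long form
#'
#' @param x A `k2p_dist` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered specimen pair: `id1`, `id2`,
#'   `d_percent` (`NA` for undefined pairs) and `n_sites`.
#' @export
tidy.k2p_dist <- function(x, ...) {
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble::tibble(
    id1 = x$ids[idx[, 1]],
    id2 = x$ids[idx[, 2]],
    d_percent = x$d[idx] * 100,
    n_sites = as.integer(x$n_sites[idx]))
}

#' Subset a K2P distance matrix to a set of specimens
#'
#' @param dm A `k2p_dist` object.
#' @param ids Specimen ids to keep (order preserved as given).
#' @return A `k2p_dist` over the subset.
#' @export
subset_k2p <- function(dm, ids) {
  stopifnot(all(ids %in% dm$ids))
  und <- dm$undefined_pairs
  structure(list(ids = ids, d = dm$d[ids, ids, drop = FALSE],
                 n_sites = dm$n_sites[ids, ids, drop = FALSE],
                 undefined_pairs = und[und$id1 %in% ids & und$id2 %in% ids, ],
                 min_overlap = dm$min_overlap),
            class = "k2p_dist")
}

#' Export a distance matrix
#'
#' Writes either a long-form TSV (`id1`, `id2`, `d_percent`, `n_sites`) or a
#' square lower-triangle PHYLIP matrix (distances in proportion units,
#' undefined pairs as -1).
#'
#' @param dm A `k2p_dist` object.
#' @param path Output path.
#' @param format `"tsv"` or `"phylip"`.
#' @return `path`, invisibly.
#' @export
export_distances <- function(dm, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write_barcode_table(tidy.k2p_dist(dm), path)
  } else {
    d <- dm$d
    d[is.na(d)] <- -1
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%5d", length(dm$ids)), con)
    for (i in seq_along(dm$ids)) {
      writeLines(paste(c(format(dm$ids[i], width = 10),
                         sprintf("%.6f", d[i, ])), collapse = " "), con)
    }
  }
  invisible(path)
}
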