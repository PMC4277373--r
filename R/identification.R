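#' Nearest-neighbour identification of one query specimen
#'
#' Assigns the query the species of its nearest library specimen (pure NN, no
#' distance threshold). An exact distance tie between specimens of different
#' species yields the verdict `ambiguous`; if every distance to the library is
#' undefined the verdict is `no_id`.
#'
#' @param dm A `k2p_dist` covering the query and the library specimens.
#' @param ds The barcode dataset tibble.
#' @param query_id Specimen id of the query (must not be in `library_ids`).
#' @param library_ids Specimen ids forming the reference library; defaults to
#'   all reference-region specimens.
#' @return A one-row tibble: `specimen_id`, `true_species`,
#'   `assigned_species`, `verdict` (`correct`/`incorrect`/`no_id`/`ambiguous`),
#'   `nn_distance` (%).
#' @export
identify_nn <- function(dm, ds, query_id, library_ids = NULL) {
  library_ids <- library_ids %||% ds$specimen_id[ds$region == "reference"]
  if (query_id %in% library_ids) abort("Query must not be part of the library")
  dvec <- dm$d[query_id, library_ids] * 100
  lib_sp <- ds$species[match(library_ids, ds$specimen_id)]
  true_sp <- ds$species[ds$specimen_id == query_id]
  fin <- !is.na(dvec)
  if (!any(fin)) {
    return(id_row(query_id, true_sp, NA_character_, "no_id", NA_real_))
  }
  nn <- min(dvec[fin])
  hit_sp <- unique(lib_sp[fin & abs(dvec - nn) < 1e-12])
  if (length(hit_sp) > 1) {
    inform(sprintf("identify_nn: tie at %.4f%% for %s between %s", nn, query_id,
                   paste(sort(hit_sp), collapse = ", ")))
    return(id_row(query_id, true_sp, NA_character_, "ambiguous", nn))
  }
  verdict <- if (hit_sp == true_sp) "correct" else "incorrect"
  id_row(query_id, true_sp, hit_sp, verdict, nn)
}

#' Best-close-match identification of one query specimen
#'
#' Collects all library specimens within `threshold` of the query and assigns
#' the majority species among them: `no_id` when no specimen is that close,
#' `ambiguous` when two species tie for the majority.
#'
#' @inheritParams identify_nn
#' @param threshold Distance threshold in percent (default 2).
#' @return A one-row tibble as in [identify_nn()].
#' @export
best_close_match <- function(dm, ds, query_id, library_ids = NULL, threshold = 2) {
  stopifnot(threshold > 0)
  library_ids <- library_ids %||% ds$specimen_id[ds$region == "reference"]
  if (query_id %in% library_ids) abort("Query must not be part of the library")
  dvec <- dm$d[query_id, library_ids] * 100
  lib_sp <- ds$species[match(library_ids, ds$specimen_id)]
  true_sp <- ds$species[ds$specimen_id == query_id]
  fin <- !is.na(dvec)
  nn <- if (any(fin)) min(dvec[fin]) else NA_real_
  close <- fin & dvec <= threshold
  if (!any(close)) {
    return(id_row(query_id, true_sp, NA_character_, "no_id", nn))
  }
  tab <- sort(table(lib_sp[close]), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) {
    return(id_row(query_id, true_sp, NA_character_, "ambiguous", nn))
  }
  assigned <- names(tab)[1]
  id_row(query_id, true_sp, assigned,
         if (assigned == true_sp) "correct" else "incorrect", nn)
}

id_row <- function(id, true_sp, assigned, verdict, nn) {
  tibble::tibble(specimen_id = id, true_species = true_sp,
                 assigned_species = assigned, verdict = verdict,
                 nn_distance = nn)
}

#' Identify every query-region specimen against the reference library
#'
#' Runs [identify_nn()] or [best_close_match()] for each query-region specimen
#' against the reference-region subset, the central test of whether a
#' regionally sampled library identifies material from a distant region.
#' Query specimens whose species has no reference-region representative are
#' reported under verdict `not_in_library` and excluded from the success
#' rates (absence from the library is a coverage problem, not a
#' misidentification).
#'
#' @param dm A `k2p_dist` over all specimens.
#' @param ds A barcode dataset containing both regions.
#' @param mode `"nn"` (default) or `"bcm"` (best close match).
#' @param threshold Percent threshold for `"bcm"` mode.
#' @return A list with `results` (one row per query specimen), `summary`
#'   (verdict counts and rates over queries whose species is represented) and
#'   `by_family` (verdict counts per family).
#' @export
library_test <- function(dm, ds, mode = c("nn", "bcm"), threshold = 2) {
  mode <- match.arg(mode)
  if (!all(c("reference", "query") %in% ds$region)) {
    abort("Dataset must contain both a reference and a query region")
  }
  lib_ids <- ds$specimen_id[ds$region == "reference"]
  lib_species <- unique(ds$species[ds$region == "reference"])
  queries <- ds$specimen_id[ds$region == "query"]

  results <- purrr::map(queries, function(q) {
    true_sp <- ds$species[ds$specimen_id == q]
    if (!true_sp %in% lib_species) {
      return(id_row(q, true_sp, NA_character_, "not_in_library", NA_real_))
    }
    if (mode == "nn") identify_nn(dm, ds, q, lib_ids)
    else best_close_match(dm, ds, q, lib_ids, threshold)
  }) |> dplyr::bind_rows()

  covered <- results[results$verdict != "not_in_library", ]
  lev <- c("correct", "incorrect", "no_id", "ambiguous")
  counts <- table(factor(covered$verdict, levels = lev))
  summary <- tibble::tibble(
    verdict = lev, count = as.integer(counts),
    rate = if (nrow(covered)) as.numeric(counts) / nrow(covered) else 0)
  by_family <- results |>
    dplyr::left_join(dplyr::select(ds, "specimen_id", "family"), by = "specimen_id") |>
    dplyr::count(.data$family, .data$verdict, name = "count")
  list(results = results, summary = summary, by_family = by_family,
       mode = mode, threshold = if (mode == "bcm") threshold else NA_real_)
}
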