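#' Run the full barcode-library evaluation pipeline
#'
#' Orchestrates every stage on one dataset: length filtering, K2P distances,
#' per-species barcode-gap statistics, threshold census, the NN
#' vs. sample-size regression, reference-vs-pooled partition comparison,
#' library-based identification of the query region, RESL-lite clustering with
#' species-cluster concordance, and — when distribution categories are
#' available with enough species — the heteroscedastic category-effect model
#' with its likelihood-ratio test. All tabular artifacts plus a summary JSON
#' are written when `out_dir` is given. The pipeline is a pure function of its
#' inputs and configuration: re-running with the same inputs reproduces the
#' same outputs.
#'
#' @param ds A barcode dataset tibble ([read_barcode_dataset()] or
#'   [generate_library()]`$dataset`).
#' @param min_bp Minimum effective sequence length (default 500).
#' @param min_overlap Minimum compared sites per pair (default 100).
#' @param resl A [resl_config()].
#' @param id_mode Identification mode, `"nn"` or `"bcm"`.
#' @param id_threshold Percent threshold for `"bcm"` identification.
#' @param thresholds Census thresholds in percent.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @return Invisibly, a list of class `barcode_pipeline` with components
#'   `dataset`, `distances`, `gap_stats`, `census`, `nn_regression`,
#'   `partition`, `identification`, `clusters`, `concordance`,
#'   `category_fit` (or `NULL`), `lrt` (or `NULL`) and `summary` (a plain
#'   list mirroring the summary JSON).
#' @export
run_barcode_pipeline <- function(ds, min_bp = 500, min_overlap = 100,
                                 resl = resl_config(), id_mode = "nn",
                                 id_threshold = 2, thresholds = c(1, 2),
                                 out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  validate_barcode_dataset(ds)
  ds <- stage("filter", filter_by_length(ds, min_bp))
  dm <- stage("distances", k2p_matrix(ds, min_overlap))
  stats <- stage("gapstats", species_gap_stats(dm, ds))
  census <- stage("census", threshold_census(stats, thresholds))
  nn_reg <- if (sum(!is.na(stats$nn_dist)) >= 3 &&
                var(log10(stats$harmonic_n[!is.na(stats$harmonic_n)])) > 0) {
    stage("nn_regression", nn_vs_samplesize_regression(stats))
  } else NULL

  both_regions <- all(c("reference", "query") %in% ds$region)
  partition <- if (both_regions) stage("partition", partition_compare(dm, ds)) else NULL
  ident <- if (both_regions) {
    stage("identify", library_test(dm, ds, id_mode, id_threshold))
  } else NULL

  clusters <- stage("cluster", assign_bins(dm, ds, resl))
  concord <- stage("concord", bin_concordance(clusters, ds))

  cat_fit <- NULL; lrt_tab <- NULL
  has_cats <- "distribution_category" %in% names(ds) &&
    !all(is.na(ds$distribution_category))
  if (has_cats) {
    cat_by_sp <- ds |>
      dplyr::distinct(.data$species, .data$family, .data$distribution_category)
    model_dat <- dplyr::inner_join(stats, cat_by_sp, by = "species")
    tab <- table(model_dat$distribution_category)
    if (length(tab) >= 2 && all(tab >= 3)) {
      cat_fit <- stage("catfit", fit_category_model(
        model_dat, "max_intra", "distribution_category", "family",
        covariate = "n_specimens", heteroscedastic = TRUE))
      null_fit <- stage("catfit", fit_category_model(
        model_dat, "max_intra", "distribution_category", "family",
        covariate = "n_specimens", heteroscedastic = FALSE,
        include_category = FALSE))
      lrt_tab <- lrt(cat_fit, null_fit)
    } else {
      inform("Category model skipped: need >= 2 categories with >= 3 species each")
    }
  }

  id_correct <- if (!is.null(ident))
    ident$summary$rate[ident$summary$verdict == "correct"] else NA_real_
  summary <- list(
    n_specimens = nrow(ds),
    n_species = nrow(stats),
    diagnosable_fraction = mean(stats$diagnosable),
    mean_max_intra = mean(stats$max_intra),
    max_max_intra = max(stats$max_intra),
    mean_nn_dist = mean(stats$nn_dist, na.rm = TRUE),
    max_nn_dist = max(stats$nn_dist, na.rm = TRUE),
    census = setNames(as.list(census$count), census$bin),
    nn_regression_slope = if (!is.null(nn_reg)) nn_reg$slope else NA_real_,
    partition_mean_max_intra_ref = if (!is.null(partition))
      mean(partition$max_intra_ref) else NA_real_,
    partition_mean_max_intra_pooled = if (!is.null(partition))
      mean(partition$max_intra_pooled) else NA_real_,
    partition_nn_changed = if (!is.null(partition))
      sum(partition$nn_changed, na.rm = TRUE) else NA_integer_,
    identification_correct_rate = id_correct,
    n_clusters = length(unique(clusters$cluster_id)),
    concordance = setNames(as.list(
      table(factor(concord$class, levels = c("match", "merge", "split", "mixture")))),
      c("match", "merge", "split", "mixture")),
    lrt = if (!is.null(lrt_tab)) as.list(lrt_tab) else NULL)

  out <- structure(list(dataset = ds, distances = dm, gap_stats = stats,
                        census = census, nn_regression = nn_reg,
                        partition = partition, identification = ident,
                        clusters = clusters, concordance = concord,
                        category_fit = cat_fit, lrt = lrt_tab,
                        summary = summary),
                   class = "barcode_pipeline")
  if (!is.null(out_dir)) write_pipeline_artifacts(out, out_dir)
  invisible(out)
}

write_pipeline_artifacts <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_barcode_table(x$gap_stats, file.path(out_dir, "gapstats.tsv"))
  write_barcode_table(x$census, file.path(out_dir, "census.tsv"))
  if (!is.null(x$partition)) {
    write_barcode_table(x$partition, file.path(out_dir, "partition.tsv"))
  }
  if (!is.null(x$identification)) {
    write_barcode_table(x$identification$results, file.path(out_dir, "identify.tsv"))
  }
  write_barcode_table(x$clusters, file.path(out_dir, "clusters.tsv"))
  write_barcode_table(x$concordance, file.path(out_dir, "concordance.tsv"))
  jsonlite::write_json(x$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.barcode_pipeline <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Barcode-library evaluation: %d specimens, %d species\n",
              s$n_specimens, s$n_species))
  cat(sprintf("  diagnosable: %.1f%%; mean max intra %.2f%%; mean NN %.2f%%\n",
              100 * s$diagnosable_fraction, s$mean_max_intra, s$mean_nn_dist))
  cat(sprintf("  clusters: %d; concordance match/merge/split/mixture: %d/%d/%d/%d\n",
              s$n_clusters, s$concordance$match, s$concordance$merge,
              s$concordance$split, s$concordance$mixture))
  if (!is.na(s$identification_correct_rate)) {
    cat(sprintf("  identification correct rate: %.1f%%\n",
                100 * s$identification_correct_rate))
  }
  invisible(x)
}
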