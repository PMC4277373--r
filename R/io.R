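#' Read a barcode dataset from FASTA plus a specimen metadata table
#'
#' Reads an aligned FASTA file of COI barcodes and a tab-separated specimen
#' metadata table, matches the two on `specimen_id`, and returns a tibble of
#' specimen records. FASTA headers must carry only the specimen id (BOLD-style
#' process id); taxonomy, region and category information come from the
#' metadata table, which is the single source for them.
#'
#' Region labels in the metadata are free strings mapped to the two roles the
#' analyses use, `"reference"` (the densely sampled library region) and
#' `"query"` (the region identified against it), via `region_map`. The default
#' maps `FI` to reference and `AT` to query; labels already equal to
#' `"reference"`/`"query"` pass through.
#'
#' @param fasta_path Path to an aligned FASTA file. All sequences must have the
#'   same length; IUPAC ambiguity codes and gaps are retained (they are
#'   excluded pair-by-pair at distance time, not stripped here).
#' @param metadata_path Path to a TSV with columns `specimen_id`, `species`,
#'   `genus`, `family`, `region` and optionally `distribution_category` and
#'   `dispersal_class`.
#' @param region_map Named character vector mapping metadata region labels to
#'   `"reference"`/`"query"`.
#' @return A tibble with one row per specimen, in FASTA file order, with
#'   columns `specimen_id`, `species`, `genus`, `family`, `region`,
#'   `distribution_category`, `dispersal_class`, `sequence` (uppercase) and
#'   `effective_length` (number of unambiguous A/C/G/T positions). The
#'   alignment length is stored in the `alignment_length` attribute.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c(">s1", "ACGTACGT", ">s2", "ACGTACGA"), fa)
#' writeLines(c("specimen_id\tspecies\tgenus\tfamily\tregion",
#'              "s1\tAus bus\tAus\tAidae\tFI",
#'              "s2\tAus bus\tAus\tAidae\tAT"), tsv)
#' read_barcode_dataset(fa, tsv)
read_barcode_dataset <- function(fasta_path, metadata_path,
                                 region_map = c(FI = "reference", AT = "query")) {
  seqs <- ape::read.FASTA(fasta_path)
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate ids in FASTA: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seq_chr <- vapply(as.character(seqs), function(x) toupper(paste(x, collapse = "")),
                    character(1))
  lens <- nchar(seq_chr)
  aln_len <- lens[1]
  if (any(lens != aln_len)) {
    bad <- ids[lens != aln_len][1]
    abort(sprintf(
      "All sequences must share one alignment length; '%s' has %d bp where %d bp was expected",
      bad, lens[ids == bad][1], aln_len))
  }

  meta <- readr::read_tsv(metadata_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  required <- c("specimen_id", "species", "genus", "family", "region")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(paste0("Metadata is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$specimen_id)) {
    abort(paste0("Duplicate specimen_id in metadata: ",
                 paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
                       collapse = ", ")))
  }
  orphans <- setdiff(ids, meta$specimen_id)
  if (length(orphans)) {
    abort(paste0("FASTA id(s) absent from metadata: ",
                 paste(orphans, collapse = ", ")))
  }
  extra <- setdiff(meta$specimen_id, ids)
  if (length(extra)) {
    inform(paste0(length(extra), " metadata row(s) without a sequence dropped: ",
                  paste(head(extra, 5), collapse = ", ")))
  }
  for (opt in c("distribution_category", "dispersal_class")) {
    if (!opt %in% names(meta)) meta[[opt]] <- NA_character_
  }

  ds <- tibble::tibble(specimen_id = ids) |>
    dplyr::left_join(
      dplyr::select(meta, dplyr::all_of(c(required, "distribution_category",
                                          "dispersal_class"))),
      by = "specimen_id") |>
    dplyr::mutate(
      region = map_regions(.data$region, region_map),
      sequence = unname(seq_chr),
      effective_length = effective_length(.data$sequence))
  attr(ds, "alignment_length") <- unname(aln_len)
  ds
}

map_regions <- function(region, region_map) {
  out <- ifelse(region %in% c("reference", "query"), region,
                unname(region_map[region]))
  if (anyNA(out)) {
    abort(paste0("Region label(s) not covered by region_map: ",
                 paste(unique(region[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Number of unambiguous A/C/G/T positions per sequence
#'
#' @param sequence Character vector of (aligned) DNA sequences.
#' @return Integer vector of counts of unambiguous bases.
#' @export
effective_length <- function(sequence) {
  vapply(strsplit(toupper(sequence), ""),
         function(s) sum(s %in% c("A", "C", "G", "T")), integer(1))
}

#' Filter specimens by effective sequence length
#'
#' Retains specimens whose `effective_length` (unambiguous A/C/G/T positions)
#' is at least `min_bp`, preserving record order. Barcode libraries typically
#' keep sequences above 500 bp.
#'
#' @param ds A barcode dataset tibble (see [read_barcode_dataset()]).
#' @param min_bp Minimum effective length in base pairs (default 500).
#' @return The filtered dataset; a warning (not an error) is raised if nothing
#'   survives.
#' @export
filter_by_length <- function(ds, min_bp = 500) {
  stopifnot(min_bp >= 0)
  keep <- ds$effective_length >= min_bp
  out <- ds[keep, , drop = FALSE]
  inform(sprintf("filter_by_length: retained %d of %d specimens (removed %d below %d bp)",
                 sum(keep), length(keep), sum(!keep), min_bp))
  if (nrow(out) == 0) warn("filter_by_length: no specimens retained")
  attr(out, "alignment_length") <- attr(ds, "alignment_length")
  out
}

#' Write a tabular result as TSV
#'
#' Writes any pipeline result tibble as a UTF-8 TSV with a header and stable
#' column order. Floating-point columns are rendered with 6 decimals so files
#' round-trip exactly at that precision; list columns (e.g. the cluster-id sets
#' of a concordance report) are flattened to comma-separated strings.
#'
#' @param rows A data frame; may be empty (header-only file).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_barcode_table <- function(rows, path) {
  rows <- tibble::as_tibble(rows)
  flat <- dplyr::mutate(rows, dplyr::across(
    dplyr::where(is.list),
    function(col) vapply(col, function(x) paste(unlist(x), collapse = ","), character(1))))
  flat <- dplyr::mutate(flat, dplyr::across(
    dplyr::where(function(x) is.double(x) && !is.integer(x)),
    function(x) ifelse(is.na(x), NA_character_, sprintf("%.6f", x))))
  readr::write_tsv(flat, path, na = "NA")
  invisible(path)
}

#' Write a barcode dataset back to FASTA + metadata TSV
#'
#' Inverse of [read_barcode_dataset()]: emits the sequences as single-line
#' FASTA (headers carry only the specimen id) and the metadata columns as TSV.
#'
#' @param ds A barcode dataset tibble.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_barcode_dataset <- function(ds, fasta_path, metadata_path) {
  lines <- as.vector(rbind(paste0(">", ds$specimen_id), ds$sequence))
  writeLines(lines, fasta_path)
  meta <- dplyr::select(ds, "specimen_id", "species", "genus", "family",
                        "region", "distribution_category", "dispersal_class")
  readr::write_tsv(meta, metadata_path, na = "")
  invisible(list(fasta = fasta_path, metadata = metadata_path))
}

validate_barcode_dataset <- function(ds) {
  required <- c("specimen_id", "species", "region", "sequence")
  missing_cols <- setdiff(required, names(ds))
  if (length(missing_cols)) {
    abort(paste0("Dataset is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(ds$specimen_id)) abort("specimen_id values must be unique")
  if (nrow(ds) > 0 && length(unique(nchar(ds$sequence))) != 1) {
    abort("All sequences must have the same aligned length")
  }
  invisible(ds)
}
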