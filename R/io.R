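#' Read / write the allele-count table
#'
#' Plain TSV with columns `chrom`, `pos`, (`is_causal`,) `ref_base`,
#' `alt_base` and the eight count columns `mut_A` ... `wt_T`. Coordinates are
#' 1-based inclusive throughout the package.
#'
#' @param counts Allele-count tibble (see [sample_bulk_counts()]).
#' @param path File path.
#' @return `read_counts_tsv()` returns the tibble; `write_counts_tsv()`
#'   returns `path` invisibly.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write candidate intervals as BED
#'
#' Internally coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start` is decremented by 1 and `end` kept.
#'
#' @param intervals Interval tibble from [call_intervals()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  bed <- tibble(chrom = intervals$chrom,
                start = as.integer(intervals$start) - 1L,
                end = as.integer(intervals$end),
                name = sprintf("interval_%d", seq_len(nrow(intervals))))
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Write a WT/mutant allele pair as FASTA
#'
#' @param wt_seq,mut_seq DNA strings.
#' @param path File path.
#' @param names Record names (default `c("WT", "mutant")`).
#' @return `path`, invisibly.
#' @export
write_allele_fasta <- function(wt_seq, mut_seq, path,
                               names = c("WT", "mutant")) {
  set <- Biostrings::DNAStringSet(c(wt_seq, mut_seq))
  names(set) <- names
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write a lipid dataset as CSV triplet
#'
#' The on-disk layout mirrors vendor exports: a species table
#' (`species`, `subclass`, `carbons`, `double_bonds`), a wide intensity
#' matrix (`species` x sample columns) and a design table (`sample`,
#' `group`, `replicate`). [read_lipid_csv()] reassembles the long tidy
#' format used by the analysis functions.
#'
#' @param ds Long-format lipid dataset.
#' @param dir Directory for the three CSVs.
#' @return `write_lipid_csv()` returns `dir` invisibly; `read_lipid_csv()`
#'   the long tibble.
#' @export
write_lipid_csv <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  species <- dplyr::distinct(
    ds, .data$species, .data$subclass, .data$carbons, .data$double_bonds)
  readr::write_csv(species, file.path(dir, "species.csv"))
  wide <- tidyr::pivot_wider(
    dplyr::distinct(ds, .data$species, .data$sample, .data$intensity),
    names_from = "sample", values_from = "intensity")
  readr::write_csv(wide, file.path(dir, "intensities.csv"))
  design <- dplyr::distinct(ds, .data$sample, .data$group, .data$replicate)
  readr::write_csv(design, file.path(dir, "design.csv"))
  invisible(dir)
}

#' @rdname write_lipid_csv
#' @export
read_lipid_csv <- function(dir) {
  species <- readr::read_csv(file.path(dir, "species.csv"),
                             show_col_types = FALSE)
  wide <- readr::read_csv(file.path(dir, "intensities.csv"),
                          show_col_types = FALSE)
  design <- readr::read_csv(file.path(dir, "design.csv"),
                            show_col_types = FALSE)
  long <- tidyr::pivot_longer(wide, -"species", names_to = "sample",
                              values_to = "intensity")
  out <- dplyr::left_join(long, species, by = "species")
  out <- dplyr::left_join(out, design, by = "sample")
  dplyr::select(out, "species", "subclass", "carbons", "double_bonds",
                "sample", "group", "replicate", "intensity")
}

#' Read fine-mapping inputs
#'
#' @param path TSV path. The marker map has columns `marker`, `chrom`,
#'   `pos`; the genotype table has `plant`, `phenotype` and one column per
#'   marker.
#' @return Tibble.
#' @export
read_marker_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_marker_map
#' @export
read_genotype_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}
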