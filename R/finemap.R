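#' Refine a candidate interval with recombinant plants
#'
#' Under a recessive single-locus model every sterile plant is homozygous for
#' the mutant-parent haplotype (`M`) at the causal locus, so the locus must
#' lie where each sterile plant's marker genotypes are compatible with `M`.
#' The chromosome is partitioned into bins: each marker position, and each
#' gap between adjacent markers. For a given sterile plant a marker bin is
#' feasible iff its genotype there is `M` (or missing `?`), and a gap bin is
#' feasible iff at least one flanking marker genotype is `M`/`?` (at most one
#' crossover per inter-marker gap). The candidate region is the intersection
#' of feasible bins over all sterile plants; the reported interval is bounded
#' by the innermost markers flanking that region (exclusive bounds).
#'
#' Fertile plants never shrink the interval (a phenotypically fertile plant
#' can be `M/H` or `H/H` across it); fertile plants that are `M` at every
#' marker inside the final interval are reported as potential double
#' recombinants (or phenotyping errors). An empty intersection yields an
#' inconsistency report naming the conflicting plants instead of an interval.
#'
#' @param markers Tibble with columns `marker`, `chrom`, `pos` (one
#'   chromosome, positions strictly increasing).
#' @param genotypes Tibble with columns `plant`, `phenotype`
#'   (`"sterile"`/`"fertile"`) and one column per marker holding codes
#'   `M` (homozygous mutant parent), `H` (heterozygous), `B` (homozygous
#'   B73), `?` (missing).
#' @return List of class `finemap_result`:
#'   `consistent` (logical); when consistent: `left_marker`, `right_marker`
#'   (one-row tibbles, exclusive flanks), `interval_bp`
#'   (`right pos - left pos`), `inner_markers` (markers feasible for all
#'   sterile plants), `bins` (tibble of all bins with feasibility),
#'   `double_recombinants` (fertile plant ids); when inconsistent:
#'   `conflicts` (tibble of sterile plant pairs with no common feasible bin).
#' @examples
#' mk <- tibble::tibble(marker = paste0("m", 1:5), chrom = "chr5",
#'                      pos = c(1.0e6, 1.5e6, 1.612e6, 1.724e6, 2.0e6))
#' gt <- tibble::tibble(plant = c("A", "B"),
#'                      phenotype = "sterile",
#'                      m1 = c("H", "M"), m2 = c("M", "M"), m3 = c("M", "M"),
#'                      m4 = c("M", "M"), m5 = c("M", "H"))
#' refine_interval(mk, gt)
#' @export
refine_interval <- function(markers, genotypes) {
  markers <- as_tibble(markers)
  genotypes <- as_tibble(genotypes)
  if (!all(c("marker", "chrom", "pos") %in% names(markers))) {
    abort("`markers` needs columns marker, chrom, pos")
  }
  if (is.unsorted(markers$pos, strictly = TRUE)) {
    abort("marker positions must be strictly increasing")
  }
  if (!all(c("plant", "phenotype") %in% names(genotypes))) {
    abort("`genotypes` needs columns plant, phenotype plus marker columns")
  }
  missing_m <- setdiff(markers$marker, names(genotypes))
  if (length(missing_m)) {
    abort(sprintf("genotype columns missing for marker(s): %s",
                  toString(missing_m)))
  }
  geno <- as.matrix(genotypes[markers$marker])
  bad <- setdiff(unique(as.vector(geno)), c("M", "H", "B", "?"))
  if (length(bad)) {
    abort(sprintf("invalid genotype code(s): %s", toString(bad)))
  }
  sterile <- genotypes$phenotype == "sterile"
  if (!any(sterile)) abort("need at least one sterile plant")

  k <- nrow(markers)
  feas <- do.call(rbind, lapply(seq_len(nrow(geno)), function(i) {
    feasible_bins(geno[i, ])
  }))  # plants x (2k - 1) bins
  joint <- apply(feas[sterile, , drop = FALSE], 2L, all)

  bins <- bin_table(markers)
  bins$feasible <- joint

  if (!any(joint)) {
    pairs <- conflicting_pairs(feas[sterile, , drop = FALSE],
                               genotypes$plant[sterile])
    return(structure(
      list(consistent = FALSE, conflicts = pairs, bins = bins,
           markers = markers),
      class = "finemap_result"))
  }

  hull <- range(which(joint))
  ## exclusive flanking markers: nearest marker strictly outside the hull;
  ## the outermost markers bound the mapped region when the hull reaches an end
  marker_bin <- 2L * seq_len(k) - 1L
  left_candidates <- marker_bin[marker_bin < hull[1]]
  right_candidates <- marker_bin[marker_bin > hull[2]]
  left_i <- if (length(left_candidates)) (max(left_candidates) + 1L) %/% 2L else 1L
  right_i <- if (length(right_candidates)) (min(right_candidates) + 1L) %/% 2L else k
  inner <- markers[joint[marker_bin], ]

  ## fertile plants M (or ?) at every marker inside the exclusive flanks
  inside <- which(markers$pos > markers$pos[left_i] &
                    markers$pos < markers$pos[right_i])
  if (left_i == 1L && joint[1L]) inside <- union(1L, inside)
  if (right_i == k && joint[2L * k - 1L]) inside <- union(inside, k)
  dbl <- character(0)
  if (any(!sterile) && length(inside)) {
    gm <- geno[!sterile, , drop = FALSE]
    all_m <- apply(gm[, inside, drop = FALSE], 1L,
                   function(g) all(g %in% c("M", "?")))
    dbl <- genotypes$plant[!sterile][all_m]
  }

  structure(
    list(consistent = TRUE,
         left_marker = markers[left_i, ],
         right_marker = markers[right_i, ],
         interval_bp = markers$pos[right_i] - markers$pos[left_i],
         inner_markers = inner,
         bins = bins,
         double_recombinants = dbl,
         markers = markers),
    class = "finemap_result")
}

## feasibility over the 2k-1 alternating bins (marker, gap, marker, ...)
## for one plant's genotype vector
feasible_bins <- function(g) {
  k <- length(g)
  ok <- g %in% c("M", "?")
  out <- logical(2L * k - 1L)
  out[2L * seq_len(k) - 1L] <- ok
  if (k > 1L) out[2L * seq_len(k - 1L)] <- ok[-k] | ok[-1L]
  out
}

bin_table <- function(markers) {
  k <- nrow(markers)
  n_bins <- 2L * k - 1L
  type <- rep(c("marker", "gap"), length.out = n_bins)
  mi <- (seq_len(n_bins) + 1L) %/% 2L
  tibble(
    bin = seq_len(n_bins),
    type = type,
    start = ifelse(type == "marker", markers$pos[mi], markers$pos[mi]),
    end = ifelse(type == "marker", markers$pos[mi], markers$pos[mi + (type == "gap")]),
    label = ifelse(type == "marker", markers$marker[mi],
                   paste0("(", markers$marker[mi], ",",
                          markers$marker[pmin(mi + 1L, k)], ")"))
  )
}

conflicting_pairs <- function(feas, plants) {
  n <- nrow(feas)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (!any(feas[i, ] & feas[j, ])) {
        out[[length(out) + 1L]] <- tibble(plant_a = plants[i],
                                          plant_b = plants[j])
      }
    }
  }
  if (length(out)) {
    dplyr::bind_rows(out)
  } else {
    ## joint intersection empty but every pair compatible: implicate all
    tibble(plant_a = plants, plant_b = NA_character_)
  }
}

#' @export
print.finemap_result <- function(x, ...) {
  if (!x$consistent) {
    cat("<finemap_result> INCONSISTENT with a recessive single locus\n")
    cat("conflicting plants:\n")
    print(x$conflicts)
    return(invisible(x))
  }
  cat(sprintf(
    "<finemap_result> causal interval (%s, %s): %s:%s-%s, %.0f bp\n",
    x$left_marker$marker, x$right_marker$marker,
    x$left_marker$chrom, format(x$left_marker$pos, big.mark = ","),
    format(x$right_marker$pos, big.mark = ","), x$interval_bp))
  invisible(x)
}

#' @export
tidy.finemap_result <- function(x, ...) {
  x$bins
}

#' @export
glance.finemap_result <- function(x, ...) {
  if (!x$consistent) {
    return(tibble(consistent = FALSE, interval_bp = NA_real_,
                  left_marker = NA_character_, right_marker = NA_character_,
                  n_double_recombinants = NA_integer_))
  }
  tibble(consistent = TRUE, interval_bp = x$interval_bp,
         left_marker = x$left_marker$marker,
         right_marker = x$right_marker$marker,
         n_double_recombinants = length(x$double_recombinants))
}
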