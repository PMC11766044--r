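#' Per-bulk base frequencies from allele counts
#'
#' Converts the 4-base read counts of the two bulks into base-frequency
#' vectors. A locus is informative when both bulks reach `min_depth` reads;
#' loci failing the filter (including zero-depth loci) are flagged and their
#' frequencies set to `NA`, with a message reporting how many were excluded.
#'
#' @param counts Tibble with columns `chrom`, `pos` and the eight count
#'   columns `mut_A` ... `mut_T`, `wt_A` ... `wt_T`
#'   (see [sample_bulk_counts()]).
#' @param min_depth Minimum reads per bulk for a locus to be informative
#'   (default 4).
#' @return `counts` with added columns `depth_mut`, `depth_wt`,
#'   `informative`, and frequency columns `fmut_A` ... `fwt_T`.
#' @export
allele_frequencies <- function(counts, min_depth = 4) {
  counts <- as_tibble(counts)
  mut_cols <- paste0("mut_", DNA_BASES)
  wt_cols <- paste0("wt_", DNA_BASES)
  if (!all(c("chrom", "pos", mut_cols, wt_cols) %in% names(counts))) {
    abort("`counts` must have chrom, pos and mut_A..mut_T, wt_A..wt_T columns.")
  }
  assert_scalar_number(min_depth, "min_depth", lower = 1)
  cm <- as.matrix(counts[mut_cols])
  cw <- as.matrix(counts[wt_cols])
  if (any(cm < 0) || any(cw < 0)) abort("negative read counts")
  depth_mut <- rowSums(cm)
  depth_wt <- rowSums(cw)
  informative <- depth_mut >= min_depth & depth_wt >= min_depth
  fm <- cm / ifelse(depth_mut > 0, depth_mut, NA_real_)
  fw <- cw / ifelse(depth_wt > 0, depth_wt, NA_real_)
  fm[!informative, ] <- NA_real_
  fw[!informative, ] <- NA_real_
  colnames(fm) <- paste0("fmut_", DNA_BASES)
  colnames(fw) <- paste0("fwt_", DNA_BASES)
  n_excl <- sum(!informative)
  if (n_excl > 0) {
    inform(sprintf("%d of %d loci excluded (depth < %s in a bulk)",
                   n_excl, nrow(counts), format(min_depth)))
  }
  dplyr::bind_cols(
    counts,
    tibble(depth_mut = depth_mut, depth_wt = depth_wt,
           informative = informative),
    as_tibble(fm), as_tibble(fw)
  )
}

#' Euclidean-distance association statistic
#'
#' The per-locus ED statistic is the Euclidean distance between the two
#' bulks' base-frequency 4-vectors,
#' `ed = sqrt(sum((f_mut - f_wt)^2))`, which lies in `[0, sqrt(2)]`; raising
#' it to the `k`-th power (default 5) suppresses background noise relative to
#' loci linked to the causal locus.
#'
#' @param freq_mut,freq_wt Numeric 4-vectors (or matrices with 4 columns, one
#'   row per locus) of base frequencies, each (row) summing to 1 within 1e-9.
#' @param k Power applied to ED (default 5).
#' @return Tibble with columns `ed` and `ed_k`.
#' @examples
#' ed_statistic(c(1, 0, 0, 0), c(0.5, 0.5, 0, 0))
#' @export
ed_statistic <- function(freq_mut, freq_wt, k = 5) {
  fm <- if (is.matrix(freq_mut)) freq_mut else matrix(freq_mut, nrow = 1)
  fw <- if (is.matrix(freq_wt)) freq_wt else matrix(freq_wt, nrow = 1)
  if (ncol(fm) != 4L || ncol(fw) != 4L || nrow(fm) != nrow(fw)) {
    abort("frequency inputs must be 4-vectors or 4-column matrices of equal rows")
  }
  assert_scalar_number(k, "k", lower = 0)
  bad <- abs(rowSums(fm) - 1) > 1e-9 | abs(rowSums(fw) - 1) > 1e-9 |
    fm < 0 | fw < 0
  if (any(bad, na.rm = TRUE)) abort("malformed frequency vector (must be >= 0 and sum to 1)")
  ed <- sqrt(rowSums((fm - fw)^2))
  tibble(ed = ed, ed_k = ed^k)
}

#' LOESS fit of association values along a chromosome
#'
#' Local linear regression with tricube weights. For each locus the window is
#' its `q = max(3, ceiling(span * n))` nearest neighbours by position;
#' weights are `w = (1 - (d / d_max)^3)^3` with `d_max` the largest distance
#' in the window. With fewer than 3 loci the fit falls back to the
#' chromosome mean (with a message). Duplicate or degenerate windows fall
#' back to the weighted mean.
#'
#' @param positions Numeric vector of bp positions (one chromosome).
#' @param values Numeric vector of association values (same length).
#' @param span Fraction of loci in each local window, `0 < span <= 1`
#'   (default 0.1).
#' @return Numeric vector of fitted values, one per input locus.
#' @export
loess_fit <- function(positions, values, span = 0.1) {
  if (length(positions) != length(values)) {
    abort("`positions` and `values` must have equal length")
  }
  assert_scalar_number(span, "span", lower = 1e-12, upper = 1)
  n <- length(positions)
  if (n == 0L) return(numeric(0))
  if (n < 3L) {
    inform("fewer than 3 loci: falling back to the chromosome mean")
    return(rep(mean(values), n))
  }
  ord <- order(positions)
  x <- as.numeric(positions[ord])
  y <- as.numeric(values[ord])
  q <- max(3L, min(n, as.integer(ceiling(span * n))))
  lo_all <- window_starts(x, q)
  fitted_sorted <- vapply(seq_len(n), function(i) {
    win <- lo_all[i]:(lo_all[i] + q - 1L)
    d <- abs(x[win] - x[i])
    dmax <- max(d)
    if (dmax == 0) return(mean(y[win]))
    w <- (1 - (d / dmax)^3)^3
    xw <- x[win]
    yw <- y[win]
    sw <- sum(w)
    xbar <- sum(w * xw) / sw
    ybar <- sum(w * yw) / sw
    sxx <- sum(w * (xw - xbar)^2)
    if (sxx <= 0) return(ybar)
    beta <- sum(w * (xw - xbar) * (yw - ybar)) / sxx
    ybar + beta * (x[i] - xbar)
  }, numeric(1))
  out <- numeric(n)
  out[ord] <- fitted_sorted
  out
}

## start index of the q-nearest-neighbour window for every point of sorted x;
## lo is non-decreasing in i, so one amortized left-to-right pass suffices
window_starts <- function(x, q) {
  n <- length(x)
  lo_all <- integer(n)
  lo <- 1L
  for (i in seq_len(n)) {
    if (lo > i) lo <- i
    while (lo + q - 1L < n && lo < i &&
           x[i] - x[lo] > x[lo + q] - x[i]) {
      lo <- lo + 1L
    }
    lo_all[i] <- lo
  }
  lo_all
}

#' Genome-wide association threshold
#'
#' `median(fitted) + 3 * sd(fitted)` over the fitted values of all informative
#' loci genome-wide; `sd` uses the sample (n - 1) denominator.
#'
#' @param fitted Numeric vector of LOESS-fitted association values.
#' @return Single numeric threshold.
#' @export
association_threshold <- function(fitted) {
  fitted <- fitted[!is.na(fitted)]
  if (length(fitted) < 2) abort("need at least 2 fitted values")
  median(fitted) + 3 * sd(fitted)
}

#' BSR-seq association profile
#'
#' The full association stage: base frequencies per bulk, per-locus ED and
#' ED^k, per-chromosome LOESS smoothing of ED^k, the genome-wide
#' median + 3 SD threshold, and candidate intervals where the fitted values
#' stay above it.
#'
#' @inheritParams allele_frequencies
#' @param span LOESS span (fraction of each chromosome's loci), default 0.1.
#' @param power Power applied to ED, default 5.
#' @param min_gap_loci Runs separated by fewer than this many
#'   below-threshold loci are merged when calling intervals (default 0,
#'   no merging).
#' @return Tibble of class `bsa_profile` with one row per locus: `chrom`,
#'   `pos`, `depth_mut`, `depth_wt`, `informative`, `ed`, `ed_k`, `fitted`
#'   (NA for non-informative loci). Attributes: `threshold`, `intervals`
#'   (tibble from [call_intervals()]), `params`.
#' @examples
#' g <- genome_spec(data.frame(name = "chr1", length = 1e6), 200,
#'                  causal = list(chrom = "chr1", pos = 5e5))
#' d <- bulk_design(n_f2 = 200, bulk_size = 30, mean_depth = 40, seed = 7)
#' prof <- bsa_profile(sample_bulk_counts(simulate_f2(g, d), d))
#' glance(prof)
#' @export
bsa_profile <- function(counts, span = 0.1, power = 5, min_depth = 4,
                        min_gap_loci = 0) {
  freqs <- allele_frequencies(counts, min_depth = min_depth)
  fm <- as.matrix(freqs[paste0("fmut_", DNA_BASES)])
  fw <- as.matrix(freqs[paste0("fwt_", DNA_BASES)])
  ok <- freqs$informative
  ed <- rep(NA_real_, nrow(freqs))
  if (any(ok)) {
    ed[ok] <- ed_statistic(fm[ok, , drop = FALSE], fw[ok, , drop = FALSE],
                           k = power)$ed
  }
  prof <- tibble(
    chrom = freqs$chrom, pos = freqs$pos,
    depth_mut = freqs$depth_mut, depth_wt = freqs$depth_wt,
    informative = ok, ed = ed, ed_k = ed^power, fitted = NA_real_
  )
  prof <- dplyr::arrange(prof, factor(.data$chrom, levels = unique(prof$chrom)),
                         .data$pos)
  for (ch in unique(prof$chrom)) {
    sel <- which(prof$chrom == ch & prof$informative)
    if (length(sel) > 0) {
      prof$fitted[sel] <- loess_fit(prof$pos[sel], prof$ed_k[sel], span = span)
    }
  }
  threshold <- association_threshold(prof$fitted)
  out <- structure(
    prof,
    threshold = threshold,
    params = list(span = span, power = power, min_depth = min_depth,
                  min_gap_loci = min_gap_loci),
    class = c("bsa_profile", class(prof))
  )
  attr(out, "intervals") <- call_intervals(out, min_gap_loci = min_gap_loci)
  out
}

#' Candidate intervals above the association threshold
#'
#' Maximal runs of consecutive informative loci whose fitted values are at or
#' above the threshold; runs on the same chromosome separated by fewer than
#' `min_gap_loci` below-threshold loci are merged. Interval endpoints are the
#' positions of the first and last locus of the run (1-based, inclusive).
#'
#' @param profile A [bsa_profile()] tibble (or any tibble with `chrom`,
#'   `pos`, `fitted`).
#' @param threshold Threshold value; defaults to the profile's
#'   `threshold` attribute (or [association_threshold()] of `fitted`).
#' @param min_gap_loci Merge runs separated by fewer than this many
#'   below-threshold loci (default 0).
#' @return Tibble: `chrom`, `start`, `end`, `n_loci`, `width`
#'   (`end - start`). Zero rows when nothing exceeds the threshold.
#' @export
call_intervals <- function(profile, threshold = NULL, min_gap_loci = 0) {
  threshold <- threshold %||% attr(profile, "threshold") %||%
    association_threshold(profile$fitted)
  assert_count(min_gap_loci, "min_gap_loci")
  prof <- dplyr::filter(as_tibble(profile), !is.na(.data$fitted))
  prof <- dplyr::arrange(prof, factor(.data$chrom, levels = unique(prof$chrom)),
                         .data$pos)
  out <- list()
  for (ch in unique(prof$chrom)) {
    sub <- prof[prof$chrom == ch, ]
    above <- sub$fitted >= threshold
    if (!any(above)) next
    idx <- which(above)
    ## split into runs, merging gaps shorter than min_gap_loci
    breaks <- which(diff(idx) - 1 >= max(1, min_gap_loci) &
                      diff(idx) > 1)
    run_id <- cumsum(c(1, seq_along(idx)[-1] %in% (breaks + 1)))
    for (r in unique(run_id)) {
      ii <- idx[run_id == r]
      out[[length(out) + 1L]] <- tibble(
        chrom = ch, start = sub$pos[min(ii)], end = sub$pos[max(ii)],
        n_loci = length(ii), width = sub$pos[max(ii)] - sub$pos[min(ii)]
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  n_loci = integer(), width = numeric()))
  }
  dplyr::bind_rows(out)
}

#' Genes overlapping a candidate interval
#'
#' Extracts gene features from a GFF3 annotation and returns those whose span
#' overlaps the interval. Coordinates are 1-based inclusive on both sides
#' (GFF3 convention), and overlap is inclusive: a gene ending exactly at
#' `start` or starting exactly at `end` is included.
#'
#' @param annotation Path to a GFF3 file, or a `GRanges` of features with a
#'   `type` column.
#' @param interval List or one-row data frame with `chrom`, `start`, `end`.
#' @param feature_type Feature type to extract (default `"gene"`).
#' @return Tibble of overlapping genes sorted by ID: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`.
#' @export
genes_in_interval <- function(annotation, interval, feature_type = "gene") {
  gr <- if (is.character(annotation)) {
    rtracklayer::import(annotation, format = "gff3")
  } else {
    annotation
  }
  interval <- as.list(interval)
  if (interval$end < interval$start) abort("interval end before start")
  genes <- gr[!is.na(gr$type) & as.character(gr$type) == feature_type]
  if (length(genes) > 0 &&
      !interval$chrom %in% as.character(GenomicRanges::seqnames(genes))) {
    abort(sprintf(
      "chromosome '%s' not present in the annotation (has: %s)",
      interval$chrom,
      toString(unique(as.character(GenomicRanges::seqnames(genes))))))
  }
  query <- GenomicRanges::GRanges(
    interval$chrom,
    IRanges::IRanges(interval$start, interval$end))
  hits <- IRanges::subsetByOverlaps(genes, query)
  ids <- if (length(hits) == 0) {
    character(0)
  } else if (!is.null(hits$ID)) {
    as.character(hits$ID)
  } else if (!is.null(hits$Name)) {
    as.character(hits$Name)
  } else {
    paste0(as.character(GenomicRanges::seqnames(hits)), ":",
           GenomicRanges::start(hits))
  }
  out <- tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(hits)),
    start = GenomicRanges::start(hits),
    end = GenomicRanges::end(hits),
    strand = as.character(GenomicRanges::strand(hits))
  )
  dplyr::arrange(out, .data$gene_id)
}

#' @export
glance.bsa_profile <- function(x, ...) {
  iv <- attr(x, "intervals")
  tibble(
    n_loci = nrow(x),
    n_informative = sum(x$informative),
    threshold = attr(x, "threshold"),
    n_intervals = nrow(iv),
    top_chrom = if (all(is.na(x$fitted))) NA_character_ else
      x$chrom[which.max(x$fitted)]
  )
}

#' @export
tidy.bsa_profile <- function(x, ...) {
  attr(x, "intervals")
}
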