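#' Detect a clean insertion between a WT and a mutant allele
#'
#' Compares the two sequences by their longest common prefix `P` and longest
#' common suffix `S`. A clean insertion requires `P + S >= nchar(wt)`; the
#' insertion is placed at the end of the common prefix (`pos = P`, the
#' convention under which the inserted block is `mut[(P+1)..(P+L)]` with
#' `L = nchar(mut) - nchar(wt)`). When flanking repeats make several
#' placements equivalent (`P + S > nchar(wt)`), the full range of valid
#' placements is recorded in `placement_range`.
#'
#' @param wt_seq,mut_seq Uppercase DNA strings; `mut_seq` must be longer.
#' @return List of class `insertion_report`: `insertion_pos` (1-based WT
#'   position after which the insert sits), `insert_len`, `insert_seq`,
#'   `placement_range` (length-2 integer vector of equivalent positions),
#'   `wt_len`, and `tsd`/`tir` slots (`NULL` until annotated).
#' @examples
#' detect_insertion("ACGTACGT", "ACGTTTTACGT")
#' @export
detect_insertion <- function(wt_seq, mut_seq) {
  assert_dna(wt_seq, "wt_seq")
  assert_dna(mut_seq, "mut_seq")
  nw <- nchar(wt_seq)
  nm <- nchar(mut_seq)
  if (nm <= nw) abort("not an insertion: mutant sequence is not longer than WT")
  L <- nm - nw
  wt <- strsplit(wt_seq, "")[[1]]
  mut <- strsplit(mut_seq, "")[[1]]
  pmax_len <- nw
  diffs <- which(wt != mut[seq_len(nw)])
  P <- if (length(diffs)) diffs[1] - 1L else pmax_len
  diffs_s <- which(rev(wt) != rev(mut)[seq_len(nw)])
  S <- if (length(diffs_s)) diffs_s[1] - 1L else pmax_len
  if (P + S < nw) {
    abort(paste0(
      "not a clean insertion: sequences differ outside a single inserted ",
      sprintf("block (common prefix %d + common suffix %d < WT length %d)",
              P, S, nw)))
  }
  pos <- P
  insert_seq <- substring(mut_seq, pos + 1L, pos + L)
  structure(
    list(insertion_pos = as.integer(pos), insert_len = as.integer(L),
         insert_seq = insert_seq,
         placement_range = c(as.integer(nw - S), as.integer(P)),
         wt_len = as.integer(nw), mut_seq = mut_seq, wt_seq = wt_seq,
         tsd = NULL, tir = NULL),
    class = "insertion_report"
  )
}

#' Annotate the target-site duplication of an insertion
#'
#' Finds the largest `k <= max_tsd` such that the `k` WT bases immediately 5'
#' of the insertion point are duplicated as the last `k` bases of the
#' inserted block (the hallmark of a cut-and-paste transposon: the element is
#' flanked by two copies of the target site, of which WT carries a single
#' copy). A duplication inside a homopolymer (single-base) run is flagged
#' ambiguous, since its length is not uniquely defined there. `k = 0` yields
#' a `NULL`-length (absent) TSD.
#'
#' @param wt_seq WT DNA string (used for the single-copy flank).
#' @param report An [detect_insertion()] report.
#' @param max_tsd Largest TSD length considered (default 12; hAT-family
#'   elements typically duplicate 8 bp).
#' @return The report with `tsd = list(length, seq, ambiguous)` (`length` 0
#'   and `seq` `""` when no duplication is present).
#' @export
find_tsd <- function(wt_seq, report, max_tsd = 12) {
  stopifnot(inherits(report, "insertion_report"))
  assert_count(max_tsd, "max_tsd", lower = 0)
  P <- report$insertion_pos
  L <- report$insert_len
  ins <- report$insert_seq
  kmax <- min(max_tsd, P, L)
  k <- 0L
  for (j in seq_len(kmax)) {
    if (substring(wt_seq, P - j + 1L, P) ==
        substring(ins, L - j + 1L, L)) {
      k <- j
    }
  }
  tsd_seq <- if (k > 0) substring(ins, L - k + 1L, L) else ""
  ambiguous <- FALSE
  if (k > 0) {
    bases <- unique(strsplit(tsd_seq, "")[[1]])
    if (length(bases) == 1L && P > k &&
        str_at(wt_seq, P - k) == bases) {
      ambiguous <- TRUE
    }
  }
  report$tsd <- list(length = k, seq = tsd_seq, ambiguous = ambiguous)
  report
}

#' Find terminal inverted repeats of an inserted element
#'
#' Returns the longest arm length `L >= min_len` (capped at half the element
#' length) such that the element's first `L` bases and the reverse complement
#' of its last `L` bases disagree at no more than
#' `floor(max_mismatch_frac * L)` positions; `NULL` if no length qualifies.
#'
#' @param insert_seq Element sequence (DNA string).
#' @param min_len Minimum arm length considered (default 5).
#' @param max_mismatch_frac Tolerated mismatch fraction per arm (default 0.1;
#'   use 0 to require exact inverted repeats).
#' @return `NULL`, or a list `length`, `arm5`, `arm3`, `mismatches`.
#' @export
find_tir <- function(insert_seq, min_len = 5, max_mismatch_frac = 0.1) {
  assert_dna(insert_seq, "insert_seq")
  assert_count(min_len, "min_len", lower = 1)
  assert_scalar_number(max_mismatch_frac, "max_mismatch_frac",
                       lower = 0, upper = 1)
  n <- nchar(insert_seq)
  cap <- n %/% 2L
  if (cap < min_len) return(NULL)
  rc <- revcomp(insert_seq)   # rc[1..L] is revcomp of the last L bases
  s <- strsplit(insert_seq, "")[[1]]
  r <- strsplit(rc, "")[[1]]
  mism_cum <- cumsum(s[seq_len(cap)] != r[seq_len(cap)])
  for (L in cap:min_len) {
    if (mism_cum[L] <= floor(max_mismatch_frac * L)) {
      return(list(
        length = as.integer(L),
        arm5 = substring(insert_seq, 1L, L),
        arm3 = substring(insert_seq, n - L + 1L, n),
        mismatches = as.integer(mism_cum[L])
      ))
    }
  }
  NULL
}

#' Characterize a transposon insertion from a WT/mutant allele pair
#'
#' Runs the full characterization: [detect_insertion()], then [find_tsd()]
#' to split the inserted block into the element and the duplicated target
#' site, then [find_tir()] on the element proper.
#'
#' @inheritParams detect_insertion
#' @inheritParams find_tsd
#' @inheritParams find_tir
#' @return An `insertion_report` with `tsd`, `te_seq`, `te_length` and `tir`
#'   filled in.
#' @examples
#' wt <- paste(rep("ACGGTCA", 100), collapse = "")
#' sim <- simulate_te_insertion(wt, te_length = 60, tir_length = 6,
#'                              tsd_length = 4, pos = 350, seed = 2)
#' rep <- characterize_insertion(wt, sim$mut_seq, max_mismatch_frac = 0)
#' glance(rep)
#' @export
characterize_insertion <- function(wt_seq, mut_seq, max_tsd = 12,
                                   min_len = 5, max_mismatch_frac = 0.1) {
  report <- detect_insertion(wt_seq, mut_seq)
  report <- find_tsd(wt_seq, report, max_tsd = max_tsd)
  k <- report$tsd$length
  report$te_seq <- substring(report$insert_seq, 1L, report$insert_len - k)
  report$te_length <- report$insert_len - k
  report$tir <- find_tir(report$te_seq, min_len = min_len,
                         max_mismatch_frac = max_mismatch_frac)
  report
}

#' Characterize an insertion from a two-record FASTA file
#'
#' @param path FASTA with two records, WT first and mutant second (order is
#'   detected by length: the shorter record is taken as WT).
#' @inheritParams characterize_insertion
#' @return An `insertion_report`; see [characterize_insertion()].
#' @export
characterize_insertion_fasta <- function(path, max_tsd = 12, min_len = 5,
                                         max_mismatch_frac = 0.1) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 2L) abort("FASTA must contain exactly two records")
  lens <- Biostrings::width(seqs)
  wt <- as.character(seqs[[which.min(lens)]])
  mut <- as.character(seqs[[which.max(lens)]])
  characterize_insertion(wt, mut, max_tsd = max_tsd, min_len = min_len,
                         max_mismatch_frac = max_mismatch_frac)
}

#' Reconstruct the mutant allele from an insertion report
#'
#' `wt[1..pos] + insert + wt[(pos+1)..]`; equality with the observed mutant
#' sequence is the report's defining invariant.
#'
#' @param report An `insertion_report`.
#' @return DNA string.
#' @export
reconstruct_mutant <- function(report) {
  stopifnot(inherits(report, "insertion_report"))
  paste0(substring(report$wt_seq, 1L, report$insertion_pos),
         report$insert_seq,
         substring(report$wt_seq, report$insertion_pos + 1L, report$wt_len))
}

#' @export
print.insertion_report <- function(x, ...) {
  cat(sprintf("<insertion_report> %d bp inserted after WT position %d\n",
              x$insert_len, x$insertion_pos))
  if (!is.null(x$tsd)) {
    cat(sprintf("  TSD: %d bp%s%s\n", x$tsd$length,
                if (x$tsd$length > 0) paste0(" (", x$tsd$seq, ")") else "",
                if (isTRUE(x$tsd$ambiguous)) " [homopolymer, ambiguous]" else ""))
  }
  if (!is.null(x$te_length)) {
    cat(sprintf("  element: %d bp\n", x$te_length))
  }
  if (!is.null(x$tir)) {
    cat(sprintf("  TIR: %d bp, %d mismatch(es)\n",
                x$tir$length, x$tir$mismatches))
  }
  invisible(x)
}

#' @export
glance.insertion_report <- function(x, ...) {
  tibble(
    insertion_pos = x$insertion_pos,
    insert_len = x$insert_len,
    te_length = x$te_length %||% NA_integer_,
    tsd_length = if (is.null(x$tsd)) NA_integer_ else x$tsd$length,
    tsd_seq = if (is.null(x$tsd)) NA_character_ else x$tsd$seq,
    tir_length = if (is.null(x$tir)) NA_integer_ else x$tir$length,
    tir_mismatches = if (is.null(x$tir)) NA_integer_ else x$tir$mismatches
  )
}
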