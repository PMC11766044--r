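#' Chi-square test of a Mendelian segregation ratio
#'
#' Goodness-of-fit test of observed fertile/sterile progeny counts against an
#' expected Mendelian ratio (e.g. 3:1 for a recessive single-locus F2, 1:1
#' for a testcross or allelism cross). The statistic is
#' `sum((O - E)^2 / E)` with no continuity correction; with two classes it has
#' one degree of freedom, so the 5% critical value is 3.841 and counts are
#' declared consistent with the ratio when the statistic falls below it.
#'
#' @param n_fertile,n_sterile Observed counts.
#' @param ratio Length-2 vector of positive integers, expected
#'   `fertile:sterile` parts (default `c(3, 1)`).
#' @return One-row tibble: `n_fertile`, `n_sterile`, `ratio`, `statistic`,
#'   `df`, `p_value`, `critical_value`, `consistent`.
#' @examples
#' chi_square_segregation(546, 166)            # 3:1 F2 segregation
#' chi_square_segregation(252, 248, c(1, 1))   # 1:1 allelism cross
#' @export
chi_square_segregation <- function(n_fertile, n_sterile, ratio = c(3, 1)) {
  assert_count(n_fertile, "n_fertile")
  assert_count(n_sterile, "n_sterile")
  if (length(ratio) != 2 || any(ratio <= 0) || any(ratio != as.integer(ratio))) {
    abort("`ratio` must be two positive integers (fertile, sterile parts).")
  }
  total <- n_fertile + n_sterile
  if (total == 0) abort("total count must be positive")
  expected <- total * ratio / sum(ratio)
  if (any(expected == 0)) abort("degenerate ratio gives a zero expected count")
  obs <- c(n_fertile, n_sterile)
  statistic <- sum((obs - expected)^2 / expected)
  critical <- qchisq(0.95, df = 1)
  tibble(
    n_fertile = as.integer(n_fertile), n_sterile = as.integer(n_sterile),
    ratio = paste(ratio, collapse = ":"),
    statistic = statistic, df = 1L,
    p_value = pchisq(statistic, df = 1, lower.tail = FALSE),
    critical_value = critical,
    consistent = statistic < critical
  )
}

#' Allelism chi-square test (fixed 1:1 ratio)
#'
#' Crossing a homozygous recessive sterile mutant with a heterozygous carrier
#' of a second recessive sterility mutation yields 1:1 fertile:sterile
#' progeny iff the two mutations are allelic. This is
#' [chi_square_segregation()] with the expected ratio fixed at 1:1;
#' consistency supports allelism under that cross design.
#'
#' @inheritParams chi_square_segregation
#' @return One-row tibble, as [chi_square_segregation()].
#' @export
allelism_test <- function(n_fertile, n_sterile) {
  chi_square_segregation(n_fertile, n_sterile, ratio = c(1, 1))
}

#' Find IUPAC motif matches on the forward strand
#'
#' Reports every (possibly overlapping) start position at which `seq` matches
#' the degenerate `motif` under IUPAC nucleotide codes (e.g. Y = C/T,
#' R = A/G). An `N` in the sequence never matches. Only the forward strand is
#' searched; note that the Ban I site GGYRCC is its own reverse complement
#' under IUPAC, so forward-strand search is lossless for it.
#'
#' @param seq Uppercase DNA string (ACGTN).
#' @param motif IUPAC motif, e.g. `"GGYRCC"` (Ban I).
#' @return Integer vector of 1-based match start positions.
#' @examples
#' find_iupac_sites("GGCACCGGTGCC", "GGYRCC")
#' @export
find_iupac_sites <- function(seq, motif) {
  assert_dna(seq, "seq", allow_n = TRUE)
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L) {
    abort("`motif` must be a single non-empty string.")
  }
  letters_m <- strsplit(motif, "")[[1]]
  bad <- setdiff(letters_m, names(IUPAC_SETS))
  if (length(bad)) {
    abort(sprintf("invalid IUPAC letter(s) in motif: %s", toString(unique(bad))))
  }
  classes <- vapply(letters_m, function(l) {
    paste0("[", paste(IUPAC_SETS[[l]], collapse = ""), "]")
  }, character(1))
  ## lookahead so overlapping matches are all reported
  pattern <- paste0("(?=", paste(classes, collapse = ""), ")")
  hits <- gregexpr(pattern, seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

#' Restriction-digestion fragment lengths
#'
#' Cuts `seq` at every forward-strand match of `motif`, `cut_offset` bases
#' into the site (Ban I G^GYRCC cuts after the first base, offset 1), and
#' returns the resulting fragment lengths. Fragments always partition the
#' sequence: their lengths sum to `nchar(seq)`.
#'
#' @inheritParams find_iupac_sites
#' @param cut_offset Bases into the site after which the cut falls;
#'   `0 <= cut_offset <= nchar(motif)`.
#' @return Integer vector of fragment lengths, 5' to 3'.
#' @examples
#' digestion_fragments(paste0(strrep("A", 99), "GGCACC", strrep("A", 94),
#'                            "GGTACC", strrep("A", 95)), "GGYRCC")
#' @export
digestion_fragments <- function(seq, motif, cut_offset = 1) {
  assert_count(cut_offset, "cut_offset")
  if (cut_offset > nchar(motif)) abort("`cut_offset` exceeds the motif length.")
  sites <- find_iupac_sites(seq, motif)
  n <- nchar(seq)
  cuts <- sites + cut_offset - 1L
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < n]))
  as.integer(diff(c(0L, cuts, n)))
}
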