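#' Simulate a DNA transposon insertion allele
#'
#' Builds a mutant allele carrying a class-II (cut-and-paste) transposon at a
#' chosen position of the wild-type sequence. On insertion the `tsd_length`
#' host bases immediately 5' of the insertion point are duplicated so the
#' element ends up flanked by two copies of the target site (TSD):
#'
#' `mutant = wt[1..pos] + TE + TSD + wt[(pos+1)..]`, `TSD = wt[(pos-tsd+1)..pos]`
#'
#' so `nchar(mutant) = nchar(wt) + te_length + tsd_length`. The element
#' carries exact reverse-complement terminal inverted repeats (TIR) of
#' `tir_length` bp. So that position, TSD and TIR lengths are well-defined
#' truth parameters, the element's terminal bases are drawn to differ from
#' the adjacent host bases and the base pair just inside the TIR is drawn
#' non-complementary (otherwise the insertion admits equivalent placements
#' and longer apparent TSDs/TIRs).
#'
#' @param wt_seq Wild-type DNA string (uppercase ACGT).
#' @param te_length Element length in bp (default 548, an hAT-family size).
#' @param tir_length TIR arm length (default 11); `2 * tir_length <= te_length`.
#' @param tsd_length Target-site duplication length (default 8, typical for
#'   hAT elements); must satisfy `tsd_length <= pos`.
#' @param pos 1-based host position after which the element is inserted;
#'   `0 < pos < nchar(wt_seq)`.
#' @param seed Optional integer seed.
#' @return List with `mut_seq` (the mutant allele) and `truth`, a record of
#'   `pos`, `te_length`, `tsd_length`, `tsd_seq`, `tir_length`, `te_seq` and
#'   `insert_seq` (the contiguous novel block `TE + TSD`).
#' @examples
#' wt <- paste(rep("ACGT", 300), collapse = "")
#' sim <- simulate_te_insertion(wt, te_length = 60, tir_length = 5,
#'                              tsd_length = 4, pos = 600, seed = 1)
#' nchar(sim$mut_seq) - nchar(wt)
#' @export
simulate_te_insertion <- function(wt_seq, te_length = 548, tir_length = 11,
                                  tsd_length = 8, pos, seed = NULL) {
  assert_dna(wt_seq, "wt_seq", allow_n = FALSE)
  assert_count(te_length, "te_length", lower = 1)
  assert_count(tir_length, "tir_length", lower = 0)
  assert_count(tsd_length, "tsd_length", lower = 0)
  assert_count(pos, "pos", lower = 1)
  n <- nchar(wt_seq)
  if (pos >= n) abort("`pos` must be strictly inside the wild-type sequence.")
  if (2 * tir_length > te_length) abort("`2 * tir_length` must be <= `te_length`.")
  if (tsd_length > pos) abort("`tsd_length` exceeds the 5' flank (tsd_length > pos).")
  with_seed_if(seed, {
    te <- strsplit(random_dna(te_length), "")[[1]]
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    if (tir_length > 0) {
      ## impose exact reverse-complement TIR arms
      te[te_length - seq_len(tir_length) + 1L] <-
        comp[te[seq_len(tir_length)]]
    }
    ## identifiability conditions (see Details)
    flank3 <- str_at(wt_seq, pos + 1L)          # host base just 3' of insertion
    flank5 <- str_at(wt_seq, pos - tsd_length)  # host base just 5' of the TSD
    forbid_first <- flank3
    if (nzchar(flank5)) {
      if (tir_length > 0) {
        ## last TE base is comp(first): forbid first = comp(flank5)
        forbid_first <- c(forbid_first, comp[[flank5]])
      }
    }
    choices <- setdiff(DNA_BASES, forbid_first)
    te[1L] <- sample(choices, 1L)
    if (tir_length > 0) {
      te[te_length] <- comp[[te[1L]]]
    } else if (nzchar(flank5)) {
      te[te_length] <- sample(setdiff(DNA_BASES, flank5), 1L)
    }
    if (tir_length > 0 && te_length >= 2 * (tir_length + 1L)) {
      ## force a non-complementary pair just inside the TIR so tir_length is
      ## the maximal exact TIR
      inner5 <- tir_length + 1L
      inner3 <- te_length - tir_length
      if (te[inner3] == comp[[te[inner5]]]) {
        te[inner3] <- sample(setdiff(DNA_BASES, comp[[te[inner5]]]), 1L)
      }
    }
    te_seq <- paste(te, collapse = "")
    tsd_seq <- if (tsd_length > 0) {
      substring(wt_seq, pos - tsd_length + 1L, pos)
    } else {
      ""
    }
    mut_seq <- paste0(substring(wt_seq, 1L, pos), te_seq, tsd_seq,
                      substring(wt_seq, pos + 1L, n))
    list(
      mut_seq = mut_seq,
      truth = list(pos = as.integer(pos), te_length = as.integer(te_length),
                   tsd_length = as.integer(tsd_length), tsd_seq = tsd_seq,
                   tir_length = as.integer(tir_length), te_seq = te_seq,
                   insert_seq = paste0(te_seq, tsd_seq))
    )
  })
}
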