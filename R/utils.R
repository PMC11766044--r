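## internal helpers shared across modules

DNA_BASES <- c("A", "C", "G", "T")

## IUPAC degenerate nucleotide codes -> the set of plain bases each matches
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 0) {
  assert_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) abort(sprintf("`%s` must be a whole number.", name))
  invisible(as.integer(x))
}

assert_dna <- function(seq, name, allow_n = TRUE) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L) {
    abort(sprintf("`%s` must be a single non-empty string.", name))
  }
  ok <- if (allow_n) grepl("^[ACGTN]+$", seq) else grepl("^[ACGT]+$", seq)
  if (!ok) {
    abort(sprintf("`%s` must be an uppercase DNA string (ACGT%s).",
                  name, if (allow_n) "N" else ""))
  }
  invisible(seq)
}

## set the RNG deterministically when a seed is supplied, leaving the caller's
## RNG state untouched otherwise
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  assert_count(seed, "seed")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

str_at <- function(seq, i) substring(seq, i, i)
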