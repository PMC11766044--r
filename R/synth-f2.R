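#' Genome specification for the F2 simulator
#'
#' Describes the simulated genome: chromosome names and lengths, the number of
#' observable loci per chromosome (SNPs segregating between the two parents,
#' e.g. mutant line x B73), a uniform crossover rate, and the position of the
#' causal male-sterility locus. Defaults emulate a maize-sized genome of ten
#' chromosomes with the causal locus on chromosome 5 at 30 Mb.
#'
#' @param chromosomes Data frame with columns `name` and `length` (bp).
#' @param loci_per_chrom Number of segregating loci simulated per chromosome.
#' @param recomb_rate Expected crossovers per bp per meiosis (uniform along
#'   the genome). The maize genome averages roughly 1.6 cM/Mb, i.e. `1.6e-8`.
#' @param causal List with elements `chrom` and `pos` (1-based bp) giving the
#'   causal locus. The position is always included among the simulated loci.
#' @return A list of class `genome_spec`.
#' @examples
#' genome_spec(chromosomes = data.frame(name = "chr1", length = 1e6),
#'             loci_per_chrom = 50, causal = list(chrom = "chr1", pos = 5e5))
#' @export
genome_spec <- function(chromosomes = maize_chromosomes(),
                        loci_per_chrom = 2000,
                        recomb_rate = 1.6e-8,
                        causal = list(chrom = "chr5", pos = 30e6)) {
  chromosomes <- as_tibble(chromosomes)
  if (!all(c("name", "length") %in% names(chromosomes))) {
    abort("`chromosomes` needs columns `name` and `length`.")
  }
  if (any(chromosomes$length <= 0)) abort("zero-length chromosome")
  if (anyDuplicated(chromosomes$name)) abort("duplicated chromosome names")
  assert_count(loci_per_chrom, "loci_per_chrom", lower = 1)
  assert_scalar_number(recomb_rate, "recomb_rate", lower = 0)
  if (!causal$chrom %in% chromosomes$name) {
    abort(sprintf("causal chromosome '%s' is not in the genome", causal$chrom))
  }
  clen <- chromosomes$length[chromosomes$name == causal$chrom]
  assert_scalar_number(causal$pos, "causal$pos", lower = 1, upper = clen)
  structure(
    list(chromosomes = chromosomes,
         loci_per_chrom = as.integer(loci_per_chrom),
         recomb_rate = recomb_rate,
         causal = list(chrom = causal$chrom, pos = as.numeric(causal$pos))),
    class = "genome_spec"
  )
}

#' Approximate B73 chromosome lengths (bp)
#'
#' @return Tibble with columns `name`, `length`.
#' @export
maize_chromosomes <- function() {
  tibble(
    name = paste0("chr", 1:10),
    length = c(307e6, 244e6, 235e6, 247e6, 223e6,
               174e6, 182e6, 181e6, 159e6, 151e6)
  )
}

#' Bulk-sequencing design
#'
#' Parameters of the bulked-segregant experiment: F2 population size, plants
#' per phenotype bulk, expected sequencing depth per locus per bulk, and the
#' per-base miscall rate. Defaults follow the study design of 50 sterile plus
#' 50 fertile plants drawn from a segregating population.
#'
#' @param n_f2 F2 population size.
#' @param bulk_size Plants per bulk (one sterile, one fertile bulk).
#' @param mean_depth Expected reads per locus per bulk (Poisson).
#' @param error_rate Per-base miscall probability, spread uniformly over the
#'   three other bases. Must be below 0.25.
#' @param seed Optional integer seed; when given, simulation output is fully
#'   deterministic.
#' @return A list of class `bulk_design`.
#' @export
bulk_design <- function(n_f2 = 700, bulk_size = 50, mean_depth = 30,
                        error_rate = 0.01, seed = NULL) {
  assert_count(n_f2, "n_f2", lower = 4)
  assert_count(bulk_size, "bulk_size", lower = 1)
  assert_scalar_number(mean_depth, "mean_depth", lower = 0)
  assert_scalar_number(error_rate, "error_rate", lower = 0)
  if (error_rate >= 0.25) abort("`error_rate` must be < 0.25.")
  if (!is.null(seed)) assert_count(seed, "seed")
  structure(
    list(n_f2 = as.integer(n_f2), bulk_size = as.integer(bulk_size),
         mean_depth = mean_depth, error_rate = error_rate, seed = seed),
    class = "bulk_design"
  )
}

#' Simulate an F2 population segregating a single recessive locus
#'
#' Each plant is formed from two independent gametes. Crossovers along a
#' chromosome follow a Poisson process with no interference (Haldane), so the
#' recombination fraction between adjacent loci at distance `d` bp is
#' `(1 - exp(-2 * recomb_rate * d)) / 2`. Genotypes are coded as the dosage of
#' the mutant-parent allele: 2 (`M`, homozygous mutant parent), 1 (`H`), and
#' 0 (`B`, homozygous B73). A plant is sterile iff it is `M` at the causal
#' locus (recessive single-locus model).
#'
#' @param genome A [genome_spec()].
#' @param design A [bulk_design()]; `n_f2` and `seed` are used.
#' @return An object of class `f2_pop`: a list with `loci` (tibble of
#'   `chrom`, `pos`, `is_causal`), `geno` (integer matrix, loci x plants,
#'   mutant-allele dosage), `phenotype` (character, "sterile"/"fertile"),
#'   and the `genome`/`design` used.
#' @examples
#' g <- genome_spec(data.frame(name = "chr1", length = 1e6), 20,
#'                  causal = list(chrom = "chr1", pos = 5e5))
#' pop <- simulate_f2(g, bulk_design(n_f2 = 40, seed = 1))
#' table(pop$phenotype)
#' @export
simulate_f2 <- function(genome, design) {
  stopifnot(inherits(genome, "genome_spec"), inherits(design, "bulk_design"))
  with_seed_if(design$seed, {
    loci <- simulate_locus_positions(genome)
    n <- design$n_f2
    geno_list <- lapply(seq_len(nrow(genome$chromosomes)), function(ci) {
      chrom <- genome$chromosomes$name[ci]
      pos <- loci$pos[loci$chrom == chrom]
      simulate_chrom_genotypes(pos, genome$recomb_rate, n)
    })
    geno <- do.call(rbind, geno_list)
    rownames(geno) <- NULL
    causal_row <- which(loci$is_causal)
    phenotype <- ifelse(geno[causal_row, ] == 2L, "sterile", "fertile")
    structure(
      list(loci = loci, geno = geno, phenotype = phenotype,
           genome = genome, design = design),
      class = "f2_pop"
    )
  })
}

## sorted unique locus positions per chromosome; the causal position is
## forced in (it is an observable segregating site in the RNA-seq data)
simulate_locus_positions <- function(genome) {
  chroms <- genome$chromosomes
  out <- lapply(seq_len(nrow(chroms)), function(ci) {
    nm <- chroms$name[ci]
    len <- chroms$length[ci]
    k <- genome$loci_per_chrom
    causal_here <- identical(nm, genome$causal$chrom)
    n_draw <- if (causal_here) k - 1L else k
    pos <- sort(sample.int(len, n_draw))
    if (causal_here) {
      pos <- sort(unique(c(pos, genome$causal$pos)))
      while (length(pos) < k) {
        pos <- sort(unique(c(pos, sample.int(len, k - length(pos)))))
      }
    }
    tibble(chrom = nm, pos = as.numeric(pos),
           is_causal = causal_here & pos == genome$causal$pos)
  })
  dplyr::bind_rows(out)
}

## gametes for one chromosome: loci x (2n) matrix of 0/1 mutant-allele
## indicators built from a start allele plus cumulative crossover switches
simulate_chrom_genotypes <- function(pos, recomb_rate, n) {
  m <- length(pos)
  ng <- 2L * n
  start <- rbinom(ng, 1L, 0.5)
  i1 <- seq_len(n)
  i2 <- n + i1
  if (m == 1L) {
    return(matrix(start[i1] + start[i2], nrow = 1L))
  }
  d <- diff(pos)
  rf <- (1 - exp(-2 * recomb_rate * d)) / 2
  switches <- runif((m - 1L) * ng) < rf  # rf recycled per gamete
  ## per-gamete cumulative switch count via one flat cumsum with a
  ## per-column offset; the gamete's start allele is folded into the offset
  cs <- cumsum(switches)
  ends <- (m - 1L) * seq_len(ng)
  offset <- start - c(0L, cs[ends[-ng]])
  gam <- (cs + rep(offset, each = m - 1L)) %% 2L
  dim(gam) <- c(m - 1L, ng)
  rbind(start[i1] + start[i2],
        gam[, i1, drop = FALSE] + gam[, i2, drop = FALSE])
}

#' Letter codes for simulated genotypes
#'
#' @param pop An [simulate_f2()] population.
#' @return Character matrix with entries `"M"`, `"H"`, `"B"`.
#' @export
genotype_codes <- function(pop) {
  stopifnot(inherits(pop, "f2_pop"))
  matrix(c("B", "H", "M")[pop$geno + 1L], nrow = nrow(pop$geno))
}

#' @export
print.f2_pop <- function(x, ...) {
  cat(sprintf("<f2_pop> %d plants, %d loci on %d chromosome(s); %d sterile\n",
              ncol(x$geno), nrow(x$geno), nrow(x$genome$chromosomes),
              sum(x$phenotype == "sterile")))
  invisible(x)
}

#' Sample bulk allele counts from an F2 population
#'
#' Draws `bulk_size` sterile and `bulk_size` fertile plants (fertile plants
#' are selected by phenotype only, so the fertile bulk mixes heterozygotes and
#' homozygous B73 plants 2:1 in expectation), then simulates pooled
#' short-read allele counts at every locus: read depth is Poisson per locus
#' per bulk, each read draws a parental base by the bulk allele frequency, and
#' miscalls land uniformly on the three other bases.
#'
#' @param pop An [simulate_f2()] population.
#' @param design A [bulk_design()]; `bulk_size`, `mean_depth`, `error_rate`
#'   and `seed` are used. Counts are drawn with seed `seed + 1` so the
#'   population and the reads come from distinct deterministic streams.
#' @return Tibble with one row per locus: `chrom`, `pos`, `is_causal`,
#'   `ref_base` (B73 parent), `alt_base` (mutant parent), and count columns
#'   `mut_A` ... `mut_T` (sterile bulk), `wt_A` ... `wt_T` (fertile bulk).
#' @export
sample_bulk_counts <- function(pop, design) {
  stopifnot(inherits(pop, "f2_pop"), inherits(design, "bulk_design"))
  sterile <- which(pop$phenotype == "sterile")
  fertile <- which(pop$phenotype == "fertile")
  if (length(sterile) < design$bulk_size) {
    abort(sprintf(
      "population has %d sterile plants but the design needs a bulk of %d",
      length(sterile), design$bulk_size))
  }
  if (length(fertile) < design$bulk_size) {
    abort(sprintf(
      "population has %d fertile plants but the design needs a bulk of %d",
      length(fertile), design$bulk_size))
  }
  seed <- if (is.null(design$seed)) NULL else design$seed + 1L
  with_seed_if(seed, {
    mut_bulk <- sample(sterile, design$bulk_size)
    wt_bulk <- sample(fertile, design$bulk_size)
    ## bulk mutant-allele frequency = mean allele dosage of the sampled plants
    f_mut <- rowMeans(pop$geno[, mut_bulk, drop = FALSE]) / 2
    f_wt <- rowMeans(pop$geno[, wt_bulk, drop = FALSE]) / 2
    m <- nrow(pop$loci)
    ## distinct parental bases per locus
    ref_i <- sample.int(4L, m, replace = TRUE)
    alt_i <- 1L + (ref_i - 1L + sample.int(3L, m, replace = TRUE)) %% 4L
    cm <- draw_base_counts(f_mut, ref_i, alt_i, design)
    cw <- draw_base_counts(f_wt, ref_i, alt_i, design)
    out <- tibble(
      chrom = pop$loci$chrom, pos = pop$loci$pos, is_causal = pop$loci$is_causal,
      ref_base = DNA_BASES[ref_i], alt_base = DNA_BASES[alt_i]
    )
    colnames(cm) <- paste0("mut_", DNA_BASES)
    colnames(cw) <- paste0("wt_", DNA_BASES)
    dplyr::bind_cols(out, as_tibble(cm), as_tibble(cw))
  })
}

## vectorized multinomial draw over the four bases at every locus:
## P(alt) = f(1-e) + (1-f)e/3, P(ref) = (1-f)(1-e) + f e/3, others e/3
draw_base_counts <- function(f, ref_i, alt_i, design) {
  m <- length(f)
  depth <- rpois(m, design$mean_depth)
  e <- design$error_rate
  p <- matrix(e / 3, nrow = m, ncol = 4L)
  p[cbind(seq_len(m), alt_i)] <- f * (1 - e) + (1 - f) * e / 3
  p[cbind(seq_len(m), ref_i)] <- (1 - f) * (1 - e) + f * e / 3
  counts <- matrix(0L, nrow = m, ncol = 4L)
  remaining <- depth
  prem <- rep(1, m)
  for (b in 1:3) {
    pb <- ifelse(prem > 0, pmin(1, pmax(0, p[, b] / prem)), 0)
    counts[, b] <- rbinom(m, remaining, pb)
    remaining <- remaining - counts[, b]
    prem <- prem - p[, b]
  }
  counts[, 4L] <- remaining
  counts
}
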