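test_that("zero recombination gives genotypes constant along each chromosome", {
  g <- tiny_genome(n_loci = 40, recomb_rate = 0)
  pop <- simulate_f2(g, bulk_design(n_f2 = 60, seed = 11))
  expect_true(all(apply(pop$geno, 2, function(col) length(unique(col)) == 1)))
  codes <- genotype_codes(pop)
  expect_setequal(unique(as.vector(codes)), c("M", "H", "B"))
})

test_that("sterile fraction matches the 1/4 binomial expectation at n = 10,000", {
  g <- tiny_genome(n_loci = 10)
  pop <- simulate_f2(g, bulk_design(n_f2 = 10000, seed = 21))
  frac <- mean(pop$phenotype == "sterile")
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(frac - 0.25), 3 * se)
})

test_that("every sterile plant is homozygous mutant at the causal locus", {
  g <- tiny_genome(n_loci = 30)
  pop <- simulate_f2(g, bulk_design(n_f2 = 400, seed = 5))
  causal <- which(pop$loci$is_causal)
  expect_length(causal, 1L)
  expect_true(all(pop$geno[causal, pop$phenotype == "sterile"] == 2L))
  expect_true(all(pop$geno[causal, pop$phenotype == "fertile"] != 2L))
})

test_that("identical seed reproduces the population and counts exactly", {
  g <- tiny_genome(n_loci = 25)
  d <- bulk_design(n_f2 = 100, bulk_size = 10, seed = 33)
  p1 <- simulate_f2(g, d)
  p2 <- simulate_f2(g, d)
  expect_identical(p1$geno, p2$geno)
  expect_identical(p1$loci, p2$loci)
  expect_identical(sample_bulk_counts(p1, d), sample_bulk_counts(p2, d))
  d2 <- bulk_design(n_f2 = 100, bulk_size = 10, seed = 34)
  expect_false(identical(simulate_f2(g, d2)$geno, p1$geno))
})

test_that("degenerate genome specifications are rejected", {
  expect_error(genome_spec(data.frame(name = "c1", length = 0), 10,
                           causal = list(chrom = "c1", pos = 1)),
               "zero-length")
  expect_error(genome_spec(data.frame(name = "c1", length = 100), 10,
                           causal = list(chrom = "c2", pos = 1)),
               "causal")
  expect_error(genome_spec(data.frame(name = "c1", length = 100), 10,
                           recomb_rate = -1,
                           causal = list(chrom = "c1", pos = 1)))
})

test_that("error-free causal-locus reads are all mutant-parent base in the sterile bulk", {
  g <- tiny_genome(n_loci = 30)
  d <- bulk_design(n_f2 = 300, bulk_size = 40, mean_depth = 50,
                   error_rate = 0, seed = 8)
  pop <- simulate_f2(g, d)
  cnt <- sample_bulk_counts(pop, d)
  causal <- cnt[cnt$is_causal, ]
  alt_count <- as.numeric(causal[paste0("mut_", causal$alt_base)])
  depth <- sum(causal[paste0("mut_", c("A", "C", "G", "T"))])
  expect_equal(alt_count, depth)
  expect_gt(depth, 0)
})

test_that("unlinked loci have mutant-base frequency near 0.5 in both bulks", {
  g <- two_chrom_genome(n_loci = 20)
  d <- bulk_design(n_f2 = 500, bulk_size = 50, mean_depth = 10000,
                   error_rate = 0, seed = 13)
  pop <- simulate_f2(g, d)
  cnt <- sample_bulk_counts(pop, d)
  unlinked <- cnt[cnt$chrom == "c2", ][1, ]
  ## plant-sampling variance of the bulk frequency dominates at this depth:
  ## var(dosage/2) = 0.125, over 50 plants -> SE ~ 0.05
  se <- sqrt(0.125 / 50 + 0.25 / 10000)
  for (bulk in c("mut", "wt")) {
    alt <- as.numeric(unlinked[paste0(bulk, "_", unlinked$alt_base)])
    depth <- sum(unlinked[paste0(bulk, "_", c("A", "C", "G", "T"))])
    expect_lt(abs(alt / depth - 0.5), 3 * se)
  }
})

test_that("expected ED at the causal locus reflects the 1 vs 1/3 bulk frequencies", {
  ## sterile bulk fixes the mutant allele; the fertile bulk mixes Mm:BB 2:1,
  ## so its mutant-allele frequency is 1/3 and ED -> sqrt(2) * 2/3 = 0.9428
  g <- tiny_genome(n_loci = 10)
  eds <- vapply(1:5, function(s) {
    d <- bulk_design(n_f2 = 600, bulk_size = 50, mean_depth = 10000,
                     error_rate = 0, seed = 300 + s)
    pop <- simulate_f2(g, d)
    cnt <- sample_bulk_counts(pop, d)
    prof <- suppressMessages(bsa_profile(cnt, min_depth = 4))
    prof$ed[cnt$is_causal]
  }, numeric(1))
  expect_lt(abs(mean(eds) - sqrt(2) * 2 / 3), 0.06)
})

test_that("zero mean depth yields all-zero counts flagged uninformative", {
  g <- tiny_genome(n_loci = 15)
  d <- bulk_design(n_f2 = 60, bulk_size = 5, mean_depth = 0, seed = 4)
  pop <- simulate_f2(g, d)
  cnt <- sample_bulk_counts(pop, d)
  count_cols <- grep("^(mut|wt)_", names(cnt), value = TRUE)
  expect_true(all(as.matrix(cnt[count_cols]) == 0))
  freqs <- suppressMessages(allele_frequencies(cnt))
  expect_true(all(!freqs$informative))
})

test_that("a bulk larger than the available phenotype class is rejected", {
  g <- tiny_genome(n_loci = 10)
  d <- bulk_design(n_f2 = 20, bulk_size = 19, seed = 6)
  pop <- simulate_f2(g, d)
  expect_error(sample_bulk_counts(pop, d), "sterile plants")
})

test_that("noise-free lipidome with zero fold-changes has ratio exactly 100%", {
  sc <- tibble::tibble(subclass = c("PC", "TG"), n_species = c(5L, 5L),
                       log2fc = 0, base_scale = c(1e6, 2e6))
  ds <- simulate_lipidome(lipidome_spec(sc, noise_sigma = 0, seed = 1))
  expect_identical(total_content(ds)$ratio, 100)
})

test_that("a single subclass at log2FC -1 halves exactly without noise", {
  sc <- tibble::tibble(subclass = c("PE", "TG"), n_species = c(6L, 4L),
                       log2fc = c(-1, 0), base_scale = 1e6)
  ds <- simulate_lipidome(lipidome_spec(sc, noise_sigma = 0, seed = 2))
  st <- subclass_tests(ds)
  expect_equal(st$mean_mutant[st$subclass == "PE"] /
                 st$mean_wt[st$subclass == "PE"], 0.5)
  expect_equal(st$mean_mutant[st$subclass == "TG"] /
                 st$mean_wt[st$subclass == "TG"], 1)
})

test_that("simulated lipid names parse round-trip and are unique", {
  ds <- simulate_lipidome(lipidome_spec(seed = 3))
  species <- unique(ds$species)
  expect_identical(length(species), 1088L)
  parsed <- parse_lipid_name(species)
  expect_true(all(parsed$parse_ok))
  truth <- dplyr::distinct(ds, species, subclass, carbons, double_bonds)
  expect_identical(parsed$subclass, truth$subclass)
  expect_identical(parsed$carbons, as.integer(truth$carbons))
  expect_identical(parsed$double_bonds, as.integer(truth$double_bonds))
})

test_that("the default lipidome spec mirrors the study scale", {
  sc <- default_lipid_subclasses()
  expect_identical(nrow(sc), 49L)
  expect_identical(sum(sc$n_species), 1088L)
  expect_identical(sum(sc$log2fc <= -1), 15L)
  expect_identical(sum(sc$log2fc >= 1), 4L)
})

test_that("TE insertion length arithmetic and TIR construction hold", {
  wt <- withr::with_seed(77, paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                            collapse = ""))
  sim <- simulate_te_insertion(wt, te_length = 548, tsd_length = 8,
                               tir_length = 11, pos = 1000, seed = 1)
  expect_identical(nchar(sim$mut_seq), nchar(wt) + 548L + 8L)
  te <- sim$truth$te_seq
  arm5 <- substring(te, 1, 11)
  arm3 <- substring(te, 548 - 10, 548)
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_identical(arm5, rc(arm3))
  ## TSD is the 5' flank copy
  expect_identical(sim$truth$tsd_seq, substring(wt, 993, 1000))
  ## deterministic under the seed
  sim2 <- simulate_te_insertion(wt, 548, 11, 8, pos = 1000, seed = 1)
  expect_identical(sim2$mut_seq, sim$mut_seq)
})

test_that("TE insertion rejects invalid geometry", {
  wt <- strrep("ACGT", 50)
  expect_error(simulate_te_insertion(wt, 50, 5, tsd_length = 30, pos = 20),
               "tsd_length")
  expect_error(simulate_te_insertion(wt, 50, 30, 4, pos = 20), "tir_length")
  expect_error(simulate_te_insertion(wt, 50, 5, 4, pos = 200), "pos")
})

test_that("zero TIR length imposes no terminal inverted repeat", {
  wt <- withr::with_seed(5, paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                           collapse = ""))
  sim <- simulate_te_insertion(wt, te_length = 40, tir_length = 0,
                               tsd_length = 4, pos = 250, seed = 9)
  expect_identical(sim$truth$tir_length, 0L)
  expect_identical(nchar(sim$truth$te_seq), 40L)
})
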