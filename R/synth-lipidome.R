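#' Lipidome simulation specification
#'
#' Describes a two-group (mutant vs WT) lipidome with subclass-level effects:
#' each subclass has a species count, a log2 fold-change (mutant relative to
#' WT) shared by all of its species, and a base intensity scale. Species
#' log2 intensities are normal around a species-specific baseline with SD
#' `noise_sigma` (log2 units).
#'
#' @param subclasses Data frame with columns `subclass`, `n_species`,
#'   `log2fc`, `base_scale`. Defaults to [default_lipid_subclasses()].
#' @param n_replicates Biological replicates per group (default 4).
#' @param noise_sigma SD of log2-intensity noise (default 0.3).
#' @param seed Optional integer seed.
#' @return A list of class `lipidome_spec`.
#' @export
lipidome_spec <- function(subclasses = default_lipid_subclasses(),
                          n_replicates = 4, noise_sigma = 0.3, seed = NULL) {
  subclasses <- as_tibble(subclasses)
  need <- c("subclass", "n_species", "log2fc", "base_scale")
  if (!all(need %in% names(subclasses))) {
    abort(sprintf("`subclasses` needs columns %s.", toString(need)))
  }
  if (any(subclasses$n_species < 1)) abort("every subclass needs >= 1 species")
  if (anyDuplicated(subclasses$subclass)) abort("duplicated subclass names")
  assert_count(n_replicates, "n_replicates", lower = 2)
  assert_scalar_number(noise_sigma, "noise_sigma", lower = 0)
  if (!is.null(seed)) assert_count(seed, "seed")
  structure(
    list(subclasses = subclasses, n_replicates = as.integer(n_replicates),
         noise_sigma = noise_sigma, seed = seed),
    class = "lipidome_spec"
  )
}

#' Default subclass table for the simulated tassel lipidome
#'
#' 49 subclasses totalling 1088 species, mirroring the scale of a maize
#' tassel lipidome. Fifteen subclasses are down-regulated in the mutant
#' (the four dominant membrane/storage classes PE, PC, DG and MGDG at
#' log2FC -1.5, the others at -1), four are up-regulated at +1, and the
#' remaining thirty are unchanged. Base intensity scales put most of the
#' total signal in storage (TG) and membrane (PC/PE/DG/MGDG) classes.
#'
#' @return Tibble with columns `subclass`, `n_species`, `log2fc`,
#'   `base_scale`.
#' @export
default_lipid_subclasses <- function() {
  down_major <- c("PE", "PC", "DG", "MGDG")
  down_minor <- c("BisMeLPA", "CmE", "Co", "D5TG", "LPC", "LPEt", "MG",
                  "MePC", "OAHFA", "SiE", "WE")
  up <- c("AcHexChE", "AcHexSiE", "AEA", "PG")
  null_major <- c("TG", "DGDG", "PA", "PI", "PS", "SQDG", "Cer", "HexCer",
                  "SM", "CL", "LPE", "LPA", "LPG", "LPI", "LPS", "FA",
                  "CoQ", "ChE", "ST", "AcCa", "GM3", "PEt", "PMe", "dMePE",
                  "Hex2Cer", "CerP", "SPH", "GD1a", "MGMG", "DGMG")
  tb <- dplyr::bind_rows(
    tibble(subclass = down_major, n_species = c(90L, 110L, 70L, 40L),
           log2fc = -1.5, base_scale = c(3e6, 4e6, 2.5e6, 2e6)),
    tibble(subclass = down_minor, n_species = 12L, log2fc = -1,
           base_scale = 2e5),
    tibble(subclass = up, n_species = 10L, log2fc = 1, base_scale = 1e5),
    tibble(subclass = null_major,
           n_species = c(120L, 30L, 25L, 30L, 20L, 25L, 30L, 30L, 30L, 20L,
                         15L, 12L, 12L, 12L, 12L, 25L, 8L, 15L, 12L, 15L,
                         8L, 10L, 10L, 12L, 15L, 8L, 8L, 8L, 15L, 14L),
           log2fc = 0,
           base_scale = c(6e6, 8e5, 3e5, 5e5, 3e5, 6e5, 4e5, 3e5, 3e5, 2e5,
                          1e5, 1e5, 1e5, 1e5, 1e5, 5e5, 1e5, 2e5, 2e5, 1e5,
                          5e4, 1e5, 1e5, 1e5, 1e5, 5e4, 5e4, 5e4, 2e5, 2e5))
  )
  stopifnot(nrow(tb) == 49L, sum(tb$n_species) == 1088L)
  tb
}

#' Simulate a two-group lipidome
#'
#' Species names follow the shorthand `SUBCLASS(C:D)` with total acyl carbons
#' `C` and double bonds `D` drawn per species; duplicate names within a
#' subclass get a deterministic `_k` suffix. WT log2 intensity is normal
#' around the species baseline with SD `noise_sigma`; the mutant group adds
#' the subclass log2 fold-change. Output is a tidy long table that
#' round-trips through [parse_lipid_name()].
#'
#' @param spec A [lipidome_spec()].
#' @return Tibble of class `lipidome` in long format: `species`, `subclass`,
#'   `carbons`, `double_bonds`, `true_log2fc`, `sample`, `group`
#'   (`"WT"`/`"mutant"`), `replicate`, `intensity`.
#' @examples
#' ds <- simulate_lipidome(lipidome_spec(seed = 1))
#' total_content(ds)
#' @export
simulate_lipidome <- function(spec) {
  stopifnot(inherits(spec, "lipidome_spec"))
  with_seed_if(spec$seed, {
    sc <- spec$subclasses
    species <- purrr::pmap_dfr(
      sc,
      function(subclass, n_species, log2fc, base_scale) {
        carbons <- 2L * sample(14:30, n_species, replace = TRUE)
        dbs <- sample(0:8, n_species, replace = TRUE)
        name <- sprintf("%s(%d:%d)", subclass, carbons, dbs)
        if (anyDuplicated(name)) {
          name <- make.unique(name, sep = "_")
        }
        tibble(species = name, subclass = subclass, carbons = carbons,
               double_bonds = dbs, true_log2fc = log2fc,
               log2_base = log2(base_scale) + rnorm(n_species, 0, 1))
      }
    )
    n_rep <- spec$n_replicates
    design <- tibble(
      group = rep(c("WT", "mutant"), each = n_rep),
      replicate = rep(seq_len(n_rep), 2)
    )
    design$sample <- paste0(ifelse(design$group == "WT", "WT_", "mut_"),
                            design$replicate)
    out <- tidyr::expand_grid(species, design)
    shift <- ifelse(out$group == "mutant", out$true_log2fc, 0)
    out$intensity <- 2^(out$log2_base + shift +
                          rnorm(nrow(out), 0, spec$noise_sigma))
    out <- dplyr::select(out, "species", "subclass", "carbons",
                         "double_bonds", "true_log2fc", "sample", "group",
                         "replicate", "intensity")
    class(out) <- c("lipidome", class(out))
    out
  })
}
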