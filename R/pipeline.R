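#' Pipeline configuration
#'
#' Bundles every stage parameter with its default. Defaults are the
#' method-faithful values: ED power 5, LOESS span 0.1, depth filter 4,
#' median + 3 SD threshold rule, VIP > 1 and p < 0.05 screening.
#' Configurations serialize losslessly to YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed Integer seed used by every stochastic stage.
#' @param stages Character vector of stages to run, any of
#'   `"simulate"`, `"map"`, `"lipid"` (dependency order is enforced).
#' @param out_dir Output directory.
#' @param n_f2,bulk_size,mean_depth,error_rate Bulk design (see
#'   [bulk_design()]).
#' @param loci_per_chrom,recomb_rate Genome (see [genome_spec()]).
#' @param causal_chrom,causal_pos Causal locus.
#' @param span,power,min_depth,min_gap_loci Association stage (see
#'   [bsa_profile()]).
#' @param vip_threshold,p_threshold,n_components Lipid screening (see
#'   [differential_species()]).
#' @param n_replicates,noise_sigma Lipidome generator (see
#'   [lipidome_spec()]).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, stages = c("simulate", "map", "lipid"),
                            out_dir = tempfile("msmapr_run_"),
                            n_f2 = 700, bulk_size = 50, mean_depth = 30,
                            error_rate = 0.01, loci_per_chrom = 2000,
                            recomb_rate = 1.6e-8, causal_chrom = "chr5",
                            causal_pos = 30e6, span = 0.1, power = 5,
                            min_depth = 4, min_gap_loci = 0,
                            vip_threshold = 1, p_threshold = 0.05,
                            n_components = 2, n_replicates = 4,
                            noise_sigma = 0.3) {
  cfg <- list(
    seed = as.integer(seed), stages = stages, out_dir = out_dir,
    n_f2 = as.integer(n_f2), bulk_size = as.integer(bulk_size),
    mean_depth = mean_depth, error_rate = error_rate,
    loci_per_chrom = as.integer(loci_per_chrom), recomb_rate = recomb_rate,
    causal_chrom = causal_chrom, causal_pos = causal_pos,
    span = span, power = power, min_depth = min_depth,
    min_gap_loci = as.integer(min_gap_loci),
    vip_threshold = vip_threshold, p_threshold = p_threshold,
    n_components = as.integer(n_components),
    n_replicates = as.integer(n_replicates), noise_sigma = noise_sigma)
  bad <- setdiff(cfg$stages, c("simulate", "map", "lipid"))
  if (length(bad)) abort(sprintf("unknown stage(s): %s", toString(bad)))
  ## validate stage parameters eagerly, before any computation
  bulk_design(n_f2 = cfg$n_f2, bulk_size = cfg$bulk_size,
              mean_depth = cfg$mean_depth, error_rate = cfg$error_rate,
              seed = cfg$seed)
  assert_scalar_number(cfg$span, "span", lower = 1e-12, upper = 1)
  assert_scalar_number(cfg$noise_sigma, "noise_sigma", lower = 0)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the mapping / lipidomics pipeline
#'
#' Runs the selected stages in dependency order: `simulate` (F2 population
#' and bulk allele counts), `map` (ED^k association profile, threshold,
#' intervals), `lipid` (simulated lipidome, totals, subclass tests,
#' VIP screening). Every run writes a machine-readable `run_report.json`
#' carrying the seed and a hash of the configuration; reruns with the same
#' configuration are bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`counts`,
#'   `profile`, `intervals`, `lipidome`, `totals`, `subclass`, `diff`) and
#'   the `report` list. An empty stage selection is a valid no-op.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  report <- list(config_hash = rlang::hash(unclass(config)),
                 seed = config$seed, outputs = character(0))
  results <- list()

  if (any(c("simulate", "map") %in% config$stages)) {
    genome <- genome_spec(
      loci_per_chrom = config$loci_per_chrom,
      recomb_rate = config$recomb_rate,
      causal = list(chrom = config$causal_chrom, pos = config$causal_pos))
    design <- bulk_design(n_f2 = config$n_f2, bulk_size = config$bulk_size,
                          mean_depth = config$mean_depth,
                          error_rate = config$error_rate, seed = config$seed)
    pop <- simulate_f2(genome, design)
    results$counts <- sample_bulk_counts(pop, design)
    if ("simulate" %in% config$stages) {
      p <- file.path(config$out_dir, "allele_counts.tsv")
      write_counts_tsv(results$counts, p)
      truth <- list(causal_chrom = config$causal_chrom,
                    causal_pos = config$causal_pos,
                    n_sterile = sum(pop$phenotype == "sterile"),
                    n_f2 = config$n_f2, seed = config$seed)
      tp <- file.path(config$out_dir, "simulation_truth.json")
      jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA)
      report$outputs <- c(report$outputs, p, tp)
    }
  }

  if ("map" %in% config$stages) {
    prof <- bsa_profile(results$counts, span = config$span,
                        power = config$power, min_depth = config$min_depth,
                        min_gap_loci = config$min_gap_loci)
    results$profile <- prof
    results$intervals <- attr(prof, "intervals")
    pp <- file.path(config$out_dir, "association_profile.tsv")
    readr::write_tsv(as_tibble(prof), pp)
    bp <- file.path(config$out_dir, "intervals.bed")
    write_intervals_bed(results$intervals, bp)
    sp <- file.path(config$out_dir, "map_summary.json")
    jsonlite::write_json(
      list(threshold = attr(prof, "threshold"),
           intervals = results$intervals),
      sp, auto_unbox = TRUE, digits = NA)
    report$outputs <- c(report$outputs, pp, bp, sp)
  }

  if ("lipid" %in% config$stages) {
    spec <- lipidome_spec(n_replicates = config$n_replicates,
                          noise_sigma = config$noise_sigma,
                          seed = config$seed)
    ds <- simulate_lipidome(spec)
    results$lipidome <- ds
    results$totals <- total_content(ds)
    results$subclass <- subclass_tests(ds)
    results$diff <- differential_species(
      ds, vip_threshold = config$vip_threshold,
      p_threshold = config$p_threshold, n_components = config$n_components)
    lp <- file.path(config$out_dir, "lipid_species_diff.tsv")
    readr::write_tsv(as_tibble(results$diff), lp)
    sp2 <- file.path(config$out_dir, "lipid_subclass_tests.tsv")
    readr::write_tsv(results$subclass, sp2)
    report$outputs <- c(report$outputs, lp, sp2)
  }

  rp <- file.path(config$out_dir, "run_report.json")
  jsonlite::write_json(report, rp, auto_unbox = TRUE, digits = NA)
  results$report <- report
  invisible(results)
}
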