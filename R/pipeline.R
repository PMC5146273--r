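#' Run the spike-in validation experiment
#'
#' Executes the full simulate-then-call loop used to measure the caller's
#' error rates: generate (or reuse) a synthetic reference, spike the
#' configured homozygous and heterozygous mutations, simulate a focal
#' genome matrix plus a mutation-free background cohort at the configured
#' coverage and error rate, call the focal genome against the cohort, and
#' score the calls against the truth set.
#'
#' @param config A [sim_config()].
#' @param seed Integer master seed; every stage derives its own stream, so
#'   the whole report is reproducible from this one value.
#' @param n_background Number of background genomes (default 9).
#' @param ref Optional pre-built `synthetic_reference` (so a fixed genome
#'   can be reused across replicate runs); must match `config`.
#' @return List: `truth`, `calls` (accepted records), `evaluation` (from
#'   [evaluate_caller()]), `n_accessible`, `summary` and `seed`.
#' @examples
#' \donttest{
#' cfg <- sim_config(genome_size = 5e4, n_hom = 3, n_het = 6)
#' rep <- run_validation_experiment(cfg, seed = 1)
#' rep$evaluation$fn
#' }
#' @export
run_validation_experiment <- function(config, seed = 1, n_background = 9,
                                      ref = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(ref)) ref <- generate_reference(config, derive_seed(seed, 1))
  stopifnot(inherits(ref, "synthetic_reference"))
  truth <- spike_mutations(ref, config$n_hom, config$n_het,
                           seed = derive_seed(seed, 2))
  focal <- simulate_matrix(ref, truth, seed = derive_seed(seed, 3))
  backgrounds <- lapply(seq_len(n_background), function(j) {
    simulate_matrix(ref, NULL, seed = derive_seed(seed, 3 + j))
  })
  res <- call_genome(focal, ref, backgrounds, mask = ref$mask,
                     genome_id = "sim_focal")
  ev <- evaluate_caller(truth, res$mutations, res$accessibility,
                        calls = res$calls)
  list(truth = truth, calls = res$mutations, evaluation = ev,
       n_accessible = res$n_accessible, summary = res$summary, seed = seed)
}

#' Run a full simulated mutation-accumulation analysis
#'
#' Simulates a sibling cohort of genomes of one genotype, each carrying
#' private mutations from a configurable mix of spontaneous and UV-B-like
#' processes, calls every genome against the remaining cohort members as
#' background, and produces the downstream summary tables: per-genome
#' rates, substitution spectrum, context motif matrix, genomic-fraction
#' distribution, methylation overlap, and the germline timing summary.
#'
#' @param config A [sim_config()]; `n_hom`/`n_het` are the per-genome
#'   private mutation counts.
#' @param seed Integer master seed.
#' @param n_genomes Cohort size (default 10, i.e. nine backgrounds each).
#' @param uvb Logical: draw mutations from the UV-B-like process
#'   ([simulate_uvb_process()], het/hom mix preserved) instead of the
#'   uniform spontaneous process.
#' @param outdir Optional directory; when given, mutation records (TSV and
#'   VCF), rate, spectrum, fraction, methylation and timing tables are
#'   written there alongside a run manifest.
#' @return List of tables: `mutations` (annotated, all genomes), `rates`,
#'   `spectrum`, `motif`, `fractions`, `methylation`, `timing`, plus
#'   `reference` and `manifest`.
#' @export
run_full_analysis <- function(config, seed = 1, n_genomes = 10, uvb = TRUE,
                              outdir = NULL) {
  stopifnot(inherits(config, "sim_config"), n_genomes >= 7)
  ref <- generate_reference(config, derive_seed(seed, 1))
  n_per <- config$n_hom + config$n_het

  truths <- list()
  mats <- list()
  for (g in seq_len(n_genomes)) {
    s <- derive_seed(seed, 10 + g)
    tr <- if (uvb && n_per > 0) {
      t0 <- simulate_uvb_process(ref, n_per, seed = s)
      t0$zygosity <- with_seed(derive_seed(seed, 200 + g),
                               sample(rep(c("hom", "het"),
                                          c(config$n_hom, config$n_het))))
      t0
    } else {
      spike_mutations(ref, config$n_hom, config$n_het, seed = s)
    }
    truths[[g]] <- tr
    mats[[g]] <- simulate_matrix(ref, tr, seed = derive_seed(seed, 100 + g))
  }

  all_mut <- list()
  rates <- list()
  for (g in seq_len(n_genomes)) {
    res <- call_genome(mats[[g]], ref, mats[-g], mask = ref$mask,
                       genome_id = paste0("genome", g))
    mut <- annotate_mutations(res$mutations, ref)
    all_mut[[g]] <- mut
    rates[[g]] <- rate_summary(paste0("genome", g), nrow(mut),
                               res$n_accessible, config$genome_size,
                               config$generations)
  }
  mutations <- do.call(rbind, all_mut)
  rates <- do.call(rbind, rates)

  spectrum <- spectrum_table(mutations)
  contexts <- mutations$context[!is.na(mutations$context) &
                                  mutations$class == "G:C>A:T"]
  motif <- if (length(contexts) > 0) motif_scores(contexts) else NULL
  fractions <- as.data.frame(table(fraction = mutations$fraction),
                             stringsAsFactors = FALSE)

  profiles <- simulate_methylation_profiles(ref, seed = derive_seed(seed, 5))
  status <- call_methylation(profiles)
  methylation <- methylation_overlap(mutations, status)

  mutations$group <- "cohort"
  timing <- timing_summary(
    rbind(mutations[, c("zygosity", "group")],
          data.frame(zygosity = character(0), group = character(0))),
    group = "group")

  manifest <- list(seed = seed, n_genomes = n_genomes, uvb = uvb,
                   config = unclass(config),
                   package_version = as.character(utils::packageVersion("mutacc")))

  out <- list(mutations = mutations, rates = rates, spectrum = spectrum,
              motif = motif, fractions = fractions,
              methylation = methylation, timing = timing,
              reference = ref, manifest = manifest)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    fwrite(mutations, file.path(outdir, "mutations.tsv"), sep = "\t")
    write_vcf(mutations, ref, file.path(outdir, "mutations.vcf"))
    fwrite(rates, file.path(outdir, "rates.tsv"), sep = "\t")
    fwrite(spectrum, file.path(outdir, "spectrum.tsv"), sep = "\t")
    fwrite(fractions, file.path(outdir, "fractions.tsv"), sep = "\t")
    fwrite(methylation, file.path(outdir, "methylation_overlap.tsv"), sep = "\t")
    fwrite(timing$summary, file.path(outdir, "timing.tsv"), sep = "\t")
    writeLines(paste(names(unlist(manifest)), unlist(manifest), sep = "\t"),
               file.path(outdir, "manifest.tsv"))
  }
  out
}
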