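#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator: genome geometry,
#' annotation proportions, sequencing model, spike-in counts and the
#' parameters of the UV-B-like mutational process.  The defaults describe the
#' desk-scale validation condition used throughout the package: a 1 Mb
#' single-chromosome genome read at 41x mean Poisson coverage with a 2%
#' per-read-base error rate, carrying 31 homozygous and 59 heterozygous
#' spiked mutations (a one-tenth scaling of a 900-spike genome-wide design
#' at the same hom:het ratio).
#'
#' @param genome_size Total genome length in bp (>= 10 kb).
#' @param n_chrom Number of chromosomes; the genome is split evenly.
#' @param p_gene,p_te Target proportion of the genome covered by gene models
#'   and by transposable elements; the remainder is intergenic.
#' @param coverage Mean sequencing depth \eqn{\lambda} (reads per position,
#'   Poisson).
#' @param error_rate Per-read-base probability \eqn{\epsilon} that the
#'   emitted base is replaced by one of the three other bases (uniformly).
#' @param error_del_rate,error_n_rate Optional extra per-read-base rates of
#'   corruption to the deletion symbol and to N (default 0).
#' @param n_hom,n_het Number of homozygous / heterozygous mutations to spike.
#' @param gc_at_fraction Fraction of UV-B-process mutations that are
#'   G:C->A:T transitions (0.88 reproduces a saturating UV-B exposure).
#' @param tc_weight Multiplicative placement weight for cytosines in a
#'   TC(C/T) pyrimidine-strand context (the UV-B-mutation-prone motif).
#' @param meth_multiplier Multiplicative placement weight for methylated
#'   cytosines; the default 2.1 is the odds ratio turning a 15% methylated
#'   genome background into a 27% methylated share among mutations.
#' @param meth_rates Named per-context probabilities that a cytosine is
#'   methylated (contexts CG, CHG, CHH).
#' @param mask_fraction Fraction of the genome covered by the low-complexity
#'   stand-in mask.
#' @param generations Number of treated generations (rate denominator).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(genome_size = 5e4)
#' cfg$coverage
#' @export
sim_config <- function(genome_size = 1e6, n_chrom = 1,
                       p_gene = 0.45, p_te = 0.2,
                       coverage = 41, error_rate = 0.02,
                       error_del_rate = 0, error_n_rate = 0,
                       n_hom = 31, n_het = 59,
                       gc_at_fraction = 0.88, tc_weight = 20,
                       meth_multiplier = 2.1,
                       meth_rates = c(CG = 0.45, CHG = 0.25, CHH = 0.05),
                       mask_fraction = 0.025, generations = 1) {
  cfg <- list(genome_size = as.numeric(genome_size), n_chrom = as.integer(n_chrom),
              p_gene = p_gene, p_te = p_te,
              coverage = coverage, error_rate = error_rate,
              error_del_rate = error_del_rate, error_n_rate = error_n_rate,
              n_hom = as.integer(n_hom), n_het = as.integer(n_het),
              gc_at_fraction = gc_at_fraction, tc_weight = tc_weight,
              meth_multiplier = meth_multiplier, meth_rates = meth_rates,
              mask_fraction = mask_fraction, generations = as.integer(generations))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$genome_size > 0, cfg$n_chrom >= 1)
  if (cfg$p_gene < 0 || cfg$p_te < 0 || cfg$p_gene + cfg$p_te > 1)
    stop("gene/TE/intergenic proportions must be non-negative and sum to <= 1")
  if (cfg$coverage <= 0) stop("coverage (lambda) must be > 0")
  total_err <- cfg$error_rate + cfg$error_del_rate + cfg$error_n_rate
  if (cfg$error_rate < 0 || total_err >= 0.5)
    stop("error rates must satisfy 0 <= epsilon < 0.5")
  if (cfg$n_hom < 0 || cfg$n_het < 0) stop("spike counts must be >= 0")
  if (cfg$gc_at_fraction < 0 || cfg$gc_at_fraction > 1)
    stop("gc_at_fraction must be in [0, 1]")
  if (cfg$tc_weight < 0 || cfg$meth_multiplier < 0)
    stop("context/methylation multipliers must be >= 0")
  if (!all(c("CG", "CHG", "CHH") %in% names(cfg$meth_rates)))
    stop("meth_rates must name CG, CHG and CHH")
  if (any(cfg$meth_rates < 0 | cfg$meth_rates > 1))
    stop("meth_rates must be probabilities")
  if (cfg$mask_fraction < 0 || cfg$mask_fraction >= 1)
    stop("mask_fraction must be in [0, 1)")
  if (cfg$generations < 1) stop("generations must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", format(x$genome_size, big.mark = ","), "bp,",
      x$n_chrom, "chromosome(s)\n")
  cat("  fractions: gene", x$p_gene, "/ TE", x$p_te,
      "/ intergenic", round(1 - x$p_gene - x$p_te, 3), "\n")
  cat("  sequencing: lambda =", x$coverage, ", epsilon =", x$error_rate, "\n")
  cat("  spikes:", x$n_hom, "hom +", x$n_het, "het\n")
  cat("  UV-B process: G:C->A:T fraction", x$gc_at_fraction,
      ", TC(C/T) weight", x$tc_weight,
      ", methylation multiplier", x$meth_multiplier, "\n")
  invisible(x)
}
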