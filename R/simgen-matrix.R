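# Pileup-count simulation.  Coverage is Poisson(lambda) per position; each
# read-base emits the genotype allele (heterozygous sites emit the mutant
# with probability 0.5) and is then corrupted with probability epsilon to a
# uniformly chosen one of the three other bases (plus optional sub-rates for
# the deletion symbol and N).  Deletion truth alleles put their reads in the
# deletion column; their error mass spreads uniformly over the four bases.

# Per-read emission probabilities over (A, C, G, T, del, N) for one genotype.
emission_probs <- function(ref_allele, alt_allele, zygosity, eps, ed, en) {
  hap <- function(allele) {
    p <- setNames(numeric(6), ALLELE_COLS)
    if (allele == "-") {
      p["del"] <- 1 - eps - en
      p[DNA_BASES4] <- eps / 4
      p["N"] <- en
    } else {
      p[allele] <- 1 - eps - ed - en
      others <- setdiff(DNA_BASES4, allele)
      p[others] <- eps / 3
      p["del"] <- ed
      p["N"] <- en
    }
    p
  }
  if (zygosity == "hom") hap(alt_allele)
  else (hap(ref_allele) + hap(alt_allele)) / 2
}

#' Simulate a genome matrix from a truth set
#'
#' @param ref A `synthetic_reference`.
#' @param truth Optional TruthSet data.frame (from [spike_mutations()] or
#'   [simulate_uvb_process()]); `NULL` simulates a mutation-free genome.
#' @param coverage Mean Poisson depth; default from `ref$config`.
#' @param error_rate Per-read-base substitution error rate; default from
#'   `ref$config`.
#' @param seed Integer seed.
#' @return A [genome_matrix()] covering every reference position.
#' @examples
#' ref <- generate_reference(sim_config(genome_size = 2e4), seed = 1)
#' truth <- spike_mutations(ref, 3, 5, seed = 2)
#' mat <- simulate_matrix(ref, truth, seed = 3)
#' head(mat)
#' @export
simulate_matrix <- function(ref, truth = NULL,
                            coverage = ref$config$coverage,
                            error_rate = ref$config$error_rate,
                            seed = 1) {
  stopifnot(inherits(ref, "synthetic_reference"))
  ed <- ref$config$error_del_rate
  en <- ref$config$error_n_rate
  if (!is.null(truth) && nrow(truth) > 0) {
    bad <- !truth$chrom %in% names(ref$chars) |
      truth$pos < 1 |
      truth$pos > lengths(ref$chars)[truth$chrom]
    if (any(bad)) stop("truth positions outside the reference")
  }
  with_seed(seed, {
    pieces <- lapply(names(ref$chars), function(cm) {
      b <- ref$chars[[cm]]
      L <- length(b)
      cov <- rpois(L, coverage)
      counts <- matrix(0L, nrow = L, ncol = 6,
                       dimnames = list(NULL, ALLELE_COLS))

      # variant rows (deletions expanded to one row per deleted base)
      var_pos <- integer(0); var_ref <- character(0)
      var_alt <- character(0); var_zyg <- character(0)
      if (!is.null(truth) && nrow(truth) > 0) {
        tr <- truth[truth$chrom == cm, , drop = FALSE]
        for (k in seq_len(nrow(tr))) {
          len <- if (!is.na(tr$del_len[k]) && tr$alt[k] == "-") tr$del_len[k] else 1L
          ps <- tr$pos[k]:(tr$pos[k] + len - 1L)
          var_pos <- c(var_pos, ps)
          var_ref <- c(var_ref, b[ps])
          var_alt <- c(var_alt, rep(tr$alt[k], len))
          var_zyg <- c(var_zyg, rep(tr$zygosity[k], len))
        }
      }
      is_var <- rep(FALSE, L)
      is_var[var_pos] <- TRUE

      # bulk: genotype = reference, grouped by reference base
      for (base in DNA_BASES4) {
        idx <- which(b == base & !is_var)
        if (length(idx) == 0) next
        p <- emission_probs(base, base, "hom", error_rate, ed, en)
        # put the dominant (reference) category last for the stick-breaking
        ord <- c(setdiff(ALLELE_COLS, base), base)
        counts[idx, ord] <- rmultinom_rows(cov[idx], p[ord])
      }

      for (k in seq_along(var_pos)) {
        p <- emission_probs(var_ref[k], var_alt[k], var_zyg[k],
                            error_rate, ed, en)
        counts[var_pos[k], ] <- rmultinom(1L, cov[var_pos[k]], p)[, 1L]
      }

      data.frame(chrom = cm, pos = seq_len(L), cov = cov,
                 A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
                 T = counts[, "T"], del = counts[, "del"], N = counts[, "N"],
                 stringsAsFactors = FALSE)
    })
    genome_matrix(do.call(rbind, pieces))
  })
}

#' Simulate selfing of a mutation-carrying parent
#'
#' Models single-seed-descent transmission: a heterozygous mutation that
#' arose before the split of male and female cell lineages segregates
#' 1:2:1 (absent : het : hom) in each progeny; a post-split mutation is
#' transmitted heterozygous to the sequenced progeny (which descends from
#' the affected gamete lineage); a homozygous parental mutation is fixed.
#'
#' @param truth Parental TruthSet with `origin` labels
#'   (`"somatic-pre-split"` or post-split labels).
#' @param n_progeny Number of selfed progeny to draw.
#' @param seed Integer seed.
#' @return Data.frame with one row per progeny x parental record:
#'   progeny_id, chrom, pos, ref, alt, origin, parental_zygosity and the
#'   progeny `zygosity` in `absent` / `het` / `hom`.
#' @examples
#' tr <- data.frame(chrom = "chr1", pos = 1:100, ref = "C", alt = "T",
#'                  del_len = NA, zygosity = "het",
#'                  origin = "somatic-pre-split")
#' prog <- simulate_selfing(tr, n_progeny = 1, seed = 1)
#' table(prog$zygosity)
#' @export
simulate_selfing <- function(truth, n_progeny = 1, seed = 1) {
  stopifnot(is.data.frame(truth), "origin" %in% names(truth))
  with_seed(seed, {
    out <- lapply(seq_len(n_progeny), function(j) {
      zyg <- character(nrow(truth))
      pre_het <- truth$zygosity == "het" & truth$origin == "somatic-pre-split"
      post <- truth$origin != "somatic-pre-split"
      zyg[truth$zygosity == "hom"] <- "hom"
      zyg[post & truth$zygosity == "het"] <- "het"
      n_seg <- sum(pre_het)
      if (n_seg > 0) {
        u <- runif(n_seg)
        zyg[pre_het] <- ifelse(u < 0.25, "absent",
                               ifelse(u < 0.75, "het", "hom"))
      }
      data.frame(progeny_id = paste0("progeny", j),
                 chrom = truth$chrom, pos = truth$pos,
                 ref = truth$ref, alt = truth$alt,
                 origin = truth$origin,
                 parental_zygosity = truth$zygosity,
                 zygosity = zyg, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate a reciprocal cross
#'
#' Transmits parental mutations to F1 offspring of a cross: homozygous
#' parental mutations are always transmitted, heterozygous ones with
#' probability 0.5, and every transmitted mutation is heterozygous in the
#' F1.  Records are tagged with their parent of origin.
#'
#' @param mother_truth,father_truth Parental TruthSet data.frames.
#' @param n_progeny Number of F1 individuals.
#' @param seed Integer seed.
#' @return Data.frame of transmitted F1 records: progeny_id, chrom, pos,
#'   ref, alt, parent_of_origin (`"mother"`/`"father"`), origin and
#'   zygosity (always `"het"`).
#' @export
simulate_reciprocal_cross <- function(mother_truth, father_truth,
                                      n_progeny = 1, seed = 1) {
  one_parent <- function(truth, label, j) {
    if (is.null(truth) || nrow(truth) == 0) return(NULL)
    transmit <- truth$zygosity == "hom" | runif(nrow(truth)) < 0.5
    tr <- truth[transmit, , drop = FALSE]
    if (nrow(tr) == 0) return(NULL)
    data.frame(progeny_id = paste0("F1_", j),
               chrom = tr$chrom, pos = tr$pos, ref = tr$ref, alt = tr$alt,
               parent_of_origin = label,
               origin = if ("origin" %in% names(tr)) tr$origin else NA_character_,
               zygosity = "het", stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    out <- lapply(seq_len(n_progeny), function(j) {
      rbind(one_parent(mother_truth, "mother", j),
            one_parent(father_truth, "father", j))
    })
    res <- do.call(rbind, out)
    if (is.null(res)) {
      res <- data.frame(progeny_id = character(0), chrom = character(0),
                        pos = integer(0), ref = character(0),
                        alt = character(0), parent_of_origin = character(0),
                        origin = character(0), zygosity = character(0),
                        stringsAsFactors = FALSE)
    }
    res
  })
}
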