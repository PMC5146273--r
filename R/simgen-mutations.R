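# Mutational-process simulators emitting TruthSet tables.

# Assemble a TruthSet data.frame with fraction / methylation / context
# annotation pulled from the reference.
make_truth <- function(ref, chrom, pos, ref_allele, alt, zygosity, origin,
                       del_len = NA_integer_) {
  n <- length(pos)
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      del_len = integer(0), zygosity = character(0),
                      origin = character(0), fraction = character(0),
                      methylated = logical(0), context = character(0),
                      stringsAsFactors = FALSE))
  }
  frac <- assign_fraction(chrom, pos, ref$annotation)
  # methylation flag: the cytosine of a mutated G:C pair (strand of the
  # pyrimidine); NA for A:T reference pairs.
  strand_c <- ifelse(ref_allele == "C", "+", ifelse(ref_allele == "G", "-", NA))
  methylated <- rep(NA, n)
  idx <- which(!is.na(strand_c))
  if (length(idx) > 0) {
    key <- paste(chrom[idx], pos[idx], strand_c[idx])
    mk <- paste(ref$methylome$chrom, ref$methylome$pos, ref$methylome$strand)
    m <- match(key, mk)
    methylated[idx] <- ifelse(is.na(m), FALSE, ref$methylome$methylated[m])
  }
  context <- context_7mer(ref, chrom, pos, ref_allele)
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref_allele,
                   alt = alt, del_len = as.integer(del_len),
                   zygosity = zygosity, origin = origin,
                   fraction = frac, methylated = methylated,
                   context = context, stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# 7-mer on the pyrimidine strand (NA near contig ends).
context_7mer <- function(ref, chrom, pos, ref_allele, flank = 3L) {
  n <- length(pos)
  out <- rep(NA_character_, n)
  for (cm in unique(chrom)) {
    i <- which(chrom == cm)
    b <- ref$chars[[cm]]
    L <- length(b)
    ok <- pos[i] > flank & pos[i] <= L - flank
    for (j in i[ok]) {
      s <- paste(b[(pos[j] - flank):(pos[j] + flank)], collapse = "")
      if (ref_allele[j] %in% c("A", "G")) s <- revcomp_chr(s)
      out[j] <- s
    }
  }
  out
}

eligible_positions <- function(ref, flank = 3L) {
  out <- list()
  for (cm in names(ref$chars)) {
    L <- length(ref$chars[[cm]])
    pos <- (flank + 1L):(L - flank)
    if (length(ref$mask) > 0) {
      msk <- ref$mask[GenomeInfoDb::seqnames(ref$mask) == cm]
      if (length(msk) > 0) {
        hit <- IRanges::overlapsAny(IRanges(pos, width = 1L), ranges(msk))
        pos <- pos[!hit]
      }
    }
    out[[cm]] <- pos
  }
  out
}

#' Spike in silico mutations into a synthetic reference
#'
#' Places `n_hom + n_het` single-base substitutions at unique unmasked
#' positions, with alternate alleles drawn uniformly from the three
#' non-reference bases.  Each record is annotated with its genomic fraction,
#' methylation flag and pyrimidine-strand 7-mer context.
#'
#' @param ref A `synthetic_reference`.
#' @param n_hom,n_het Numbers of homozygous and heterozygous mutations.
#' @param seed Integer seed.
#' @param origin Origin label stored in the truth set (default
#'   `"somatic-pre-split"`).
#' @return A TruthSet data.frame (chrom, pos, ref, alt, del_len, zygosity,
#'   origin, fraction, methylated, context).
#' @examples
#' ref <- generate_reference(sim_config(genome_size = 2e4), seed = 1)
#' truth <- spike_mutations(ref, n_hom = 5, n_het = 10, seed = 2)
#' table(truth$zygosity)
#' @export
spike_mutations <- function(ref, n_hom = ref$config$n_hom,
                            n_het = ref$config$n_het, seed = 1,
                            origin = "somatic-pre-split") {
  stopifnot(inherits(ref, "synthetic_reference"))
  n <- n_hom + n_het
  elig <- eligible_positions(ref)
  total <- sum(lengths(elig))
  if (n > total)
    stop("cannot place ", n, " unique mutations on ", total,
         " eligible (unmasked) positions")
  with_seed(seed, {
    all_chrom <- rep(names(elig), lengths(elig))
    all_pos <- unlist(elig, use.names = FALSE)
    pick <- sample.int(length(all_pos), n)
    chrom <- all_chrom[pick]
    pos <- all_pos[pick]
    refb <- ref_base(ref, chrom, pos)
    alt <- vapply(refb, function(rb) sample(setdiff(DNA_BASES4, rb), 1L),
                  character(1))
    zyg <- sample(rep(c("hom", "het"), c(n_hom, n_het)))
    make_truth(ref, chrom, pos, refb, unname(alt), zyg, origin)
  })
}

#' Simulate a UV-B-like mutational process
#'
#' Samples `n` mutations of which a binomial share `gc_at_fraction` are
#' G:C->A:T transitions placed at cytosines (on either strand) with
#' probability proportional to a TC(C/T)-context weight times a
#' methylated-cytosine multiplier; the remaining mutations are substitutions
#' of the other five classes at uniform unmasked positions.
#'
#' @param ref A `synthetic_reference`.
#' @param n Number of mutations.
#' @param gc_at_fraction,tc_weight,meth_multiplier Process parameters;
#'   default from `ref$config`.  An infinite `tc_weight` restricts placement
#'   to TC(C/T)-context cytosines.
#' @param seed Integer seed.
#' @param zygosity Zygosity assigned to every record (default `"het"`).
#' @param origin Origin label (default `"somatic-pre-split"`).
#' @return A TruthSet data.frame (see [spike_mutations()]).
#' @export
simulate_uvb_process <- function(ref, n,
                                 gc_at_fraction = ref$config$gc_at_fraction,
                                 tc_weight = ref$config$tc_weight,
                                 meth_multiplier = ref$config$meth_multiplier,
                                 seed = 1, zygosity = "het",
                                 origin = "somatic-pre-split") {
  stopifnot(inherits(ref, "synthetic_reference"), n >= 0)
  with_seed(seed, {
    n_gc <- rbinom(1L, n, gc_at_fraction)

    me <- ref$methylome
    # drop cytosines too close to ends (no context) and masked ones
    keep <- rep(TRUE, nrow(me))
    for (cm in unique(me$chrom)) {
      L <- length(ref$chars[[cm]])
      i <- me$chrom == cm
      keep[i] <- me$pos[i] > 3L & me$pos[i] <= L - 3L
      msk <- ref$mask[GenomeInfoDb::seqnames(ref$mask) == cm]
      if (length(msk) > 0) {
        hit <- IRanges::overlapsAny(IRanges(me$pos[i], width = 1L), ranges(msk))
        keep[i] <- keep[i] & !hit
      }
    }
    me <- me[keep, , drop = FALSE]
    if (n_gc > 0 && nrow(me) == 0)
      stop("no eligible cytosines for the G:C->A:T process")

    # pyrimidine-strand -1 / +1 bases for the TC(C/T) motif
    in_tc <- logical(nrow(me))
    for (cm in unique(me$chrom)) {
      b <- ref$chars[[cm]]
      i <- which(me$chrom == cm)
      p <- me$pos[i]
      plus <- me$strand[i] == "+"
      prev <- ifelse(plus, b[p - 1L], comp_base(b[p + 1L]))
      nxt <- ifelse(plus, b[p + 1L], comp_base(b[p - 1L]))
      in_tc[i] <- prev == "T" & nxt %in% c("C", "T")
    }
    if (is.infinite(tc_weight)) {
      me <- me[in_tc, , drop = FALSE]
      in_tc <- rep(TRUE, nrow(me))
      w <- ifelse(me$methylated, meth_multiplier, 1)
    } else {
      w <- ifelse(in_tc, tc_weight, 1) * ifelse(me$methylated, meth_multiplier, 1)
    }
    if (n_gc > 0 && (nrow(me) == 0 || sum(w > 0) < n_gc))
      stop("no eligible cytosines under the context constraint")
    gc_idx <- if (n_gc > 0) sample.int(nrow(me), n_gc, prob = w) else integer(0)
    gc_chrom <- me$chrom[gc_idx]
    gc_pos <- me$pos[gc_idx]
    gc_ref <- ifelse(me$strand[gc_idx] == "+", "C", "G")
    gc_alt <- ifelse(gc_ref == "C", "T", "A")

    # other five classes, uniform over eligible positions not already used
    n_other <- n - n_gc
    oth_chrom <- character(0); oth_pos <- integer(0)
    oth_ref <- character(0); oth_alt <- character(0)
    if (n_other > 0) {
      elig <- eligible_positions(ref)
      all_chrom <- rep(names(elig), lengths(elig))
      all_pos <- unlist(elig, use.names = FALSE)
      used <- paste(gc_chrom, gc_pos)
      free <- !(paste(all_chrom, all_pos) %in% used)
      pick <- sample(which(free), n_other)
      oth_chrom <- all_chrom[pick]
      oth_pos <- all_pos[pick]
      oth_ref <- ref_base(ref, oth_chrom, oth_pos)
      non_gcat <- list(A = c("C", "G", "T"), T = c("A", "C", "G"),
                       C = c("A", "G"), G = c("C", "T"))
      oth_alt <- vapply(oth_ref, function(rb) sample(non_gcat[[rb]], 1L),
                        character(1))
    }
    make_truth(ref,
               c(gc_chrom, oth_chrom), c(gc_pos, oth_pos),
               c(gc_ref, oth_ref), c(gc_alt, unname(oth_alt)),
               zygosity, origin)
  })
}
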