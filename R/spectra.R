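#' The six strand-symmetric substitution classes
#'
#' @format Character vector of the class labels, G:C>A:T first.
#' @export
SUBSTITUTION_CLASSES <- c("G:C>A:T", "A:T>G:C", "A:T>T:A",
                          "G:C>T:A", "A:T>C:G", "G:C>C:G")

#' Collapse a substitution into its strand-symmetric class
#'
#' A substitution and its reverse complement are the same event read from
#' opposite strands, so the twelve directed base changes collapse into six
#' classes; purine-reference changes are mapped through the complement
#' (e.g. G>A and C>T are both G:C>A:T).
#'
#' @param ref,alt Reference and mutant bases (vectors over A, C, G, T;
#'   pairwise unequal).
#' @return Character vector of class labels (see [SUBSTITUTION_CLASSES]).
#' @examples
#' collapse_class("C", "T")
#' collapse_class("G", "A")
#' @export
collapse_class <- function(ref, alt) {
  stopifnot(all(ref %in% DNA_BASES4), all(alt %in% DNA_BASES4))
  if (any(ref == alt)) stop("reference and mutant allele must differ")
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp_base(ref), ref)
  a <- ifelse(pur, comp_base(alt), alt)
  key <- paste0(r, ">", a)
  map <- c("C>T" = "G:C>A:T", "T>C" = "A:T>G:C", "T>A" = "A:T>T:A",
           "C>A" = "G:C>T:A", "T>G" = "A:T>C:G", "C>G" = "G:C>C:G")
  unname(map[key])
}

#' Substitution spectrum of a set of mutation records
#'
#' Counts and proportions over the six strand-symmetric classes.  Deletion
#' records are excluded (the spectrum concerns single-nucleotide changes).
#'
#' @param records Mutation records (or TruthSet) with `ref` and `alt`
#'   columns.
#' @param by Optional column name to stratify by (e.g. `"fraction"`).
#' @return Data.frame with class, count and proportion (per stratum).
#' @export
spectrum_table <- function(records, by = NULL) {
  subs <- records[records$alt %in% DNA_BASES4 & records$ref %in% DNA_BASES4, ,
                  drop = FALSE]
  cls <- factor(collapse_class(subs$ref, subs$alt),
                levels = SUBSTITUTION_CLASSES)
  if (is.null(by)) {
    tab <- table(cls)
    return(data.frame(class = names(tab), count = as.integer(tab),
                      proportion = as.numeric(tab) / max(1, sum(tab)),
                      stringsAsFactors = FALSE))
  }
  strata <- split(cls, subs[[by]])
  out <- lapply(names(strata), function(s) {
    tab <- table(strata[[s]])
    df <- data.frame(class = names(tab), count = as.integer(tab),
                     proportion = as.numeric(tab) / max(1, sum(tab)),
                     stringsAsFactors = FALSE)
    df[[by]] <- s
    df
  })
  do.call(rbind, out)
}

#' Assign positions to gene / TE / intergenic genome fractions
#'
#' Transposable elements take precedence over overlapping gene models
#' (TE-gene features count as TE); positions inside a gene model but no TE
#' are genic; everything else is intergenic.
#'
#' @param chrom,pos Parallel position vectors (1-based).
#' @param annotation GRanges with a `type` column containing `gene`,
#'   `transposable_element` (and/or `transposable_element_gene`); `CDS`
#'   features are ignored here.
#' @return Character vector over `"TE"`, `"gene"`, `"intergenic"`.
#' @export
assign_fraction <- function(chrom, pos, annotation) {
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  te <- annotation[annotation$type %in%
                     c("transposable_element", "transposable_element_gene")]
  gene <- annotation[annotation$type == "gene"]
  out <- rep("intergenic", length(gr))
  out[IRanges::overlapsAny(gr, gene, ignore.strand = TRUE)] <- "gene"
  out[IRanges::overlapsAny(gr, te, ignore.strand = TRUE)] <- "TE"
  out
}

#' Coding effect of a substitution
#'
#' Looks up the codon containing the position in its (strand-aware) CDS
#' model, substitutes the mutant base, and translates with the standard
#' genetic code.  Stop gain or loss counts as non-synonymous.  Positions in
#' no CDS are noncoding; deletion records are classed `noncoding` with a
#' frameshift flag and are excluded from synonymous/non-synonymous tallies.
#'
#' @param chrom,pos,ref,alt Parallel vectors describing substitutions.
#' @param reference A `synthetic_reference` or DNAStringSet.
#' @param cds GRanges of CDS intervals with strand and a `Parent` (gene id)
#'   column; per-gene CDS length must be a multiple of 3.
#' @return Character vector over `"synonymous"`, `"non-synonymous"`,
#'   `"noncoding"`.
#' @export
coding_effect <- function(chrom, pos, ref, alt, reference, cds) {
  seqs <- if (inherits(reference, "synthetic_reference")) reference$seq else reference
  if (!is.null(cds$type)) cds <- cds[cds$type == "CDS"]
  if (is.null(cds$Parent)) cds$Parent <- sprintf("cds%d", seq_along(cds))
  bad_len <- tapply(width(cds), cds$Parent, sum) %% 3 != 0
  if (any(bad_len))
    stop("CDS length not a multiple of 3 for: ",
         paste(names(bad_len)[bad_len], collapse = ", "))
  n <- length(pos)
  out <- rep("noncoding", n)
  if (n == 0) return(out)
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  hits <- findOverlaps(gr, cds, ignore.strand = TRUE)
  for (h in seq_along(queryHits(hits))) {
    i <- queryHits(hits)[h]
    if (ref[i] == "-" || alt[i] == "-") next
    j <- subjectHits(hits)[h]
    gene_cds <- cds[cds$Parent == cds$Parent[j]]
    gene_cds <- sort(gene_cds, ignore.strand = TRUE)
    minus <- as.character(strand(gene_cds)[1]) == "-"
    # coding coordinate of the position (1-based within the spliced CDS)
    offs <- 0L
    cpos <- NA_integer_
    for (k in seq_along(gene_cds)) {
      if (pos[i] >= start(gene_cds)[k] && pos[i] <= end(gene_cds)[k]) {
        cpos <- offs + (pos[i] - start(gene_cds)[k] + 1L)
      }
      offs <- offs + width(gene_cds)[k]
    }
    total <- offs
    cds_seq <- paste(vapply(seq_along(gene_cds), function(k) {
      as.character(Biostrings::subseq(seqs[[chrom[i]]],
                                      start(gene_cds)[k], end(gene_cds)[k]))
    }, character(1)), collapse = "")
    mut_seq <- cds_seq
    substr(mut_seq, cpos, cpos) <- alt[i]
    if (minus) {
      cds_seq <- revcomp_chr(cds_seq)
      mut_seq <- revcomp_chr(mut_seq)
      cpos <- total - cpos + 1L
    }
    codon_i <- (cpos - 1L) %/% 3L
    cod_ref <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    cod_alt <- substr(mut_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
    out[i] <- if (GENETIC_CODE[[cod_ref]] == GENETIC_CODE[[cod_alt]])
      "synonymous" else "non-synonymous"
  }
  out
}

#' Extract the +/-3 bp context of a mutation on the pyrimidine strand
#'
#' Returns the 7-mer centred on the mutated base, oriented so that the
#' mutated base is a pyrimidine: purine-reference records (e.g. G>A, which
#' is C>T on the reverse strand) are reverse-complemented, aligning all
#' members of a class in a common frame.
#'
#' @param reference A `synthetic_reference` or DNAStringSet.
#' @param chrom,pos,ref Parallel vectors for the mutated positions.
#' @param flank Bases on either side (default 3).
#' @return Character vector of 7-mers; positions within `flank` of a contig
#'   end return `NA` with a warning.
#' @export
extract_context <- function(reference, chrom, pos, ref, flank = 3L) {
  seqs <- if (inherits(reference, "synthetic_reference")) reference$seq else reference
  chrom <- rep_len(chrom, length(pos))
  ref <- rep_len(ref, length(pos))
  out <- rep(NA_character_, length(pos))
  for (i in seq_along(pos)) {
    L <- Biostrings::width(seqs[chrom[i]])
    if (pos[i] <= flank || pos[i] > L - flank) next
    s <- as.character(Biostrings::subseq(seqs[[chrom[i]]],
                                         pos[i] - flank, pos[i] + flank))
    if (ref[i] %in% c("A", "G")) s <- revcomp_chr(s)
    out[i] <- s
  }
  if (anyNA(out))
    warning(sum(is.na(out)), " record(s) within ", flank,
            " bp of a contig end were skipped")
  out
}

#' Position-wise motif scores for a set of aligned contexts
#'
#' Builds the base-frequency matrix over positions -flank..+flank and
#' scores each column by its relative entropy (in bits) against a
#' non-uniform background,
#' \deqn{D_j = \sum_b f_{b,j} \log_2(f_{b,j} / p_b),}
#' so a column matching the background scores 0 and over-represented bases
#' get taller letters (height \eqn{h_{b,j} = f_{b,j} D_j}).  Following the
#' usual logo display convention, the mutated column's *display* height is
#' capped at 1 bit; stored scores are not altered.
#'
#' @param contexts Character vector of equal-length context k-mers
#'   ([extract_context()] output; `NA`s are dropped).
#' @param background Named base probabilities (default C = G = 0.2,
#'   A = T = 0.3).
#' @return Object of class `motif_matrix`: list with `freq` (4 x k),
#'   `score` (bits per column), `heights`, `display_heights`, `offsets`
#'   and `background`.
#' @examples
#' ms <- motif_scores(c("ATCCGAT", "TTCCGTT", "ATCCGAA"))
#' round(ms$score, 3)
#' @export
motif_scores <- function(contexts,
                         background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)) {
  contexts <- contexts[!is.na(contexts)]
  if (length(contexts) == 0) stop("at least one context is required")
  k <- unique(nchar(contexts))
  if (length(k) != 1) stop("contexts must have equal width")
  stopifnot(all(sort(names(background)) == DNA_BASES4),
            abs(sum(background) - 1) < 1e-8)
  m <- do.call(rbind, strsplit(contexts, "", fixed = TRUE))
  freq <- vapply(seq_len(k), function(j) {
    tab <- table(factor(m[, j], levels = DNA_BASES4))
    as.numeric(tab) / length(contexts)
  }, numeric(4))
  rownames(freq) <- DNA_BASES4
  if (any(abs(colSums(freq) - 1) > 1e-8))
    stop("internal error: column frequencies do not sum to 1 (non-ACGT symbol?)")
  p <- background[DNA_BASES4]
  score <- vapply(seq_len(k), function(j) {
    f <- freq[, j]
    sum(ifelse(f > 0, f * log2(f / p), 0))
  }, numeric(1))
  heights <- sweep(freq, 2, score, `*`)
  display <- heights
  centre <- (k + 1L) / 2L
  if (k %% 2L == 1L && score[centre] > 1) {
    display[, centre] <- heights[, centre] / score[centre]
  }
  offsets <- seq_len(k) - ceiling(k / 2)
  structure(list(freq = freq, score = score, heights = heights,
                 display_heights = display, offsets = offsets,
                 background = p, n = length(contexts)),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("motif_matrix over", length(x$score), "positions (offsets",
      min(x$offsets), "..", max(x$offsets), "), n =", x$n, "contexts\n")
  cat("column scores (bits):", paste(round(x$score, 3), collapse = " "), "\n")
  invisible(x)
}

#' Annotate mutation records with fraction, context, class and methylation
#'
#' Convenience wrapper adding the downstream characterization columns to
#' accepted mutation records: genomic fraction (TE precedence), the
#' strand-collapsed substitution class, the pyrimidine-strand 7-mer
#' context, coding effect, and (when a methylome is available) the
#' methylation status of mutated G:C pairs.
#'
#' @param mutations Accepted records from [call_genome()].
#' @param ref A `synthetic_reference`.
#' @param meth_status Optional methylation-status table from
#'   [call_methylation()]; defaults to the reference's simulated methylome
#'   truth.
#' @return The records with columns `fraction`, `class`, `context`,
#'   `effect`, `methylated` added.
#' @export
annotate_mutations <- function(mutations, ref, meth_status = NULL) {
  stopifnot(inherits(ref, "synthetic_reference"))
  if (nrow(mutations) == 0) {
    mutations$fraction <- character(0)
    mutations$class <- character(0)
    mutations$context <- character(0)
    mutations$effect <- character(0)
    mutations$methylated <- logical(0)
    return(mutations)
  }
  mutations$fraction <- assign_fraction(mutations$chrom, mutations$pos,
                                        ref$annotation)
  is_sub <- mutations$alt %in% DNA_BASES4
  mutations$class <- NA_character_
  mutations$class[is_sub] <- collapse_class(mutations$ref[is_sub],
                                            mutations$alt[is_sub])
  mutations$context <- NA_character_
  if (any(is_sub)) {
    mutations$context[is_sub] <- suppressWarnings(
      extract_context(ref, mutations$chrom[is_sub], mutations$pos[is_sub],
                      mutations$ref[is_sub]))
  }
  cds <- ref$annotation[ref$annotation$type == "CDS"]
  mutations$effect <- "noncoding"
  if (any(is_sub) && length(cds) > 0) {
    mutations$effect[is_sub] <- coding_effect(
      mutations$chrom[is_sub], mutations$pos[is_sub],
      mutations$ref[is_sub], mutations$alt[is_sub], ref, cds)
  }
  strand_c <- ifelse(mutations$ref == "C", "+",
                     ifelse(mutations$ref == "G", "-", NA))
  mutations$methylated <- NA
  idx <- which(!is.na(strand_c) & is_sub)
  if (length(idx) > 0) {
    if (is.null(meth_status)) {
      mk <- paste(ref$methylome$chrom, ref$methylome$pos, ref$methylome$strand)
      mval <- ref$methylome$methylated
    } else {
      mk <- paste(meth_status$chrom, meth_status$pos, meth_status$strand)
      mval <- meth_status$status == "methylated"
      mval[meth_status$status == "not_analysed"] <- NA
    }
    m <- match(paste(mutations$chrom[idx], mutations$pos[idx], strand_c[idx]), mk)
    mutations$methylated[idx] <- mval[m]
  }
  mutations
}
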