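test_that("substitution classes are strand-symmetric and complete", {
  expect_equal(collapse_class("C", "T"), "G:C>A:T")
  expect_equal(collapse_class("G", "A"), "G:C>A:T")
  expect_equal(collapse_class("A", "C"), "A:T>C:G")
  expect_equal(collapse_class("T", "G"), "A:T>C:G")

  # involution: a change and its reverse complement share a class
  bases <- c("A", "C", "G", "T")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (r in bases) for (a in setdiff(bases, r)) {
    expect_equal(collapse_class(r, a),
                 collapse_class(unname(comp[r]), unname(comp[a])))
  }
  # exactly six classes over the twelve directed changes
  all_cls <- unlist(lapply(bases, function(r)
    lapply(setdiff(bases, r), function(a) collapse_class(r, a))))
  expect_setequal(unique(all_cls), SUBSTITUTION_CLASSES)
  expect_error(collapse_class("C", "C"), "must differ")
})

test_that("fraction assignment gives TEs precedence over genes", {
  ann <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(100, 250, 400), c(200, 300, 450)),
    type = c("gene", "transposable_element", "transposable_element_gene"))
  expect_equal(assign_fraction("chr1", 150, ann), "gene")
  expect_equal(assign_fraction("chr1", 275, ann), "TE")
  expect_equal(assign_fraction("chr1", 420, ann), "TE")   # TE gene is TE
  expect_equal(assign_fraction("chr1", 350, ann), "intergenic")

  # overlap: add a TE across the gene tail
  ann2 <- c(ann, GenomicRanges::GRanges("chr1", IRanges::IRanges(180, 220),
                                        type = "transposable_element"))
  expect_equal(assign_fraction("chr1", 190, ann2), "TE")
  expect_equal(assign_fraction("chr1", 150, ann2), "gene")
})

test_that("coding effects use strand-aware codons and the genetic code", {
  # plus strand: CDS 4..12 = GCT GAT AAA
  seqs <- Biostrings::DNAStringSet(c(chr1 = "AAAGCTGATAAACCCGGG"))
  cds <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4, 12), strand = "+",
                                type = "CDS", Parent = "g1")
  # GCT -> GCC at codon position 3: Ala -> Ala
  expect_equal(coding_effect("chr1", 6, "T", "C", seqs, cds), "synonymous")
  # GCT -> ACT at codon position 1: Ala -> Thr
  expect_equal(coding_effect("chr1", 4, "G", "A", seqs, cds), "non-synonymous")
  # stop gain counts as non-synonymous: AAA -> TAA
  expect_equal(coding_effect("chr1", 10, "A", "T", seqs, cds), "non-synonymous")
  # outside any CDS
  expect_equal(coding_effect("chr1", 15, "C", "T", seqs, cds), "noncoding")

  # minus strand: reverse complement of 4..12 read 3'->5'
  cds_m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4, 12), strand = "-",
                                  type = "CDS", Parent = "g2")
  # CDS (minus) = TTT ATC AGC; genomic pos 12 (A) is codon 1 base 1 (T on -)
  # A->G at pos 12 => minus-strand T->C: TTT(Phe) -> CTT(Leu)
  expect_equal(coding_effect("chr1", 12, "A", "G", seqs, cds_m),
               "non-synonymous")
  # genomic pos 10 (A) is codon 1 base 3: TTT(Phe) -> TTC(Phe) via A->G
  expect_equal(coding_effect("chr1", 10, "A", "G", seqs, cds_m), "synonymous")

  bad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(4, 11), strand = "+",
                                type = "CDS", Parent = "g3")
  expect_error(coding_effect("chr1", 5, "C", "T", seqs, bad), "multiple of 3")
})

test_that("contexts are extracted on the pyrimidine strand", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = "TTATCCGTTA"))
  # C>T at position 5: forward 7-mer, T at -1 and C at +1
  ctx <- extract_context(seqs, "chr1", 5, "C")
  expect_equal(ctx, "TATCCGT")
  expect_equal(substr(ctx, 3, 3), "T")
  expect_equal(substr(ctx, 5, 5), "C")

  # G>A: reverse complement so the record aligns in the C>T frame
  ctx_g <- extract_context(seqs, "chr1", 7, "G")
  fwd7 <- substring(as.character(seqs[[1]]), 4, 10)
  expect_equal(ctx_g, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(fwd7))))
  expect_equal(substr(ctx_g, 4, 4), "C")   # mutated base, pyrimidine frame

  # near-edge records are skipped with a warning
  expect_warning(ctx_e <- extract_context(seqs, "chr1", c(2, 5), c("T", "C")),
                 "skipped")
  expect_true(is.na(ctx_e[1]) && !is.na(ctx_e[2]))
})

test_that("motif scores equal their closed forms", {
  bg <- c(A = 0.3, C = 0.2, G = 0.2, T = 0.3)

  # background-matching column scores exactly zero: 3A 2C 2G 3T
  ctx <- paste0(c(rep("A", 3), rep("C", 2), rep("G", 2), rep("T", 3)),
                "TT", "C", "TTT")
  ms <- motif_scores(ctx, bg)
  expect_equal(ms$score[1], 0, tolerance = 1e-12)

  # pure-T column: log2(1/0.3)
  expect_equal(ms$score[2], log2(1 / 0.3), tolerance = 1e-12)

  # uniform column vs the default background
  ctx_u <- paste0(c("A", "C", "G", "T"), "AACAAA")
  ms_u <- motif_scores(ctx_u, bg)
  expect_equal(ms_u$score[1],
               2 * 0.25 * log2(0.25 / 0.2) + 2 * 0.25 * log2(0.25 / 0.3),
               tolerance = 1e-12)

  # heights h = f * D; mutated-column display capped at 1 bit
  expect_equal(colSums(ms$heights), ms$score, tolerance = 1e-12)
  expect_equal(ms$score[4], log2(1 / 0.2), tolerance = 1e-12)  # all-C centre
  expect_equal(sum(ms$display_heights[, 4]), 1, tolerance = 1e-12)
  expect_gt(ms$score[4], 1)   # stored score not altered by the display cap
  expect_equal(ms$offsets, -3:3)

  expect_error(motif_scores(character(0)), "at least one")
  expect_error(motif_scores(c("AAA", "AAAA")), "equal width")
})

test_that("simulated UV-B contexts show the TC(C/T) enrichment", {
  ref <- generate_reference(sim_config(genome_size = 1e5), seed = 21)
  tr <- simulate_uvb_process(ref, 2000, gc_at_fraction = 1, tc_weight = 20,
                             meth_multiplier = 1, seed = 22)
  ms <- motif_scores(tr$context)
  f <- ms$freq
  # T enriched at -1 and pyrimidines at +1 relative to background
  expect_gt(f["T", 3], 0.6)
  expect_gt(f["C", 5] + f["T", 5], 0.8)
  # and the spectrum is pure G:C>A:T
  st <- spectrum_table(tr)
  expect_equal(st$proportion[st$class == "G:C>A:T"], 1)
})
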