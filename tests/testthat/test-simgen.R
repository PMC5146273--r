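test_that("reference generation is deterministic and honours proportions", {
  cfg <- sim_config(genome_size = 1e5, p_gene = 0.3, p_te = 0.2)
  r1 <- generate_reference(cfg, seed = 7)
  r2 <- generate_reference(cfg, seed = 7)
  expect_identical(as.character(r1$seq), as.character(r2$seq))
  expect_identical(r1$methylome, r2$methylome)
  expect_identical(as.data.frame(r1$annotation), as.data.frame(r2$annotation))

  frac <- assign_fraction(rep("chr1", 1e5), 1:1e5, r1$annotation)
  p <- table(frac) / 1e5
  expect_gte(p[["gene"]], 0.28); expect_lte(p[["gene"]], 0.32)
  expect_gte(p[["TE"]], 0.18); expect_lte(p[["TE"]], 0.22)

  # at least one gene/TE overlap exists, and overlapping bases resolve to TE
  genes <- r1$annotation[r1$annotation$type == "gene"]
  tes <- r1$annotation[r1$annotation$type == "transposable_element"]
  ov <- GenomicRanges::intersect(GenomicRanges::reduce(genes, ignore.strand = TRUE),
                                 GenomicRanges::reduce(tes, ignore.strand = TRUE),
                                 ignore.strand = TRUE)
  expect_gt(sum(GenomicRanges::width(ov)), 0)
  opos <- GenomicRanges::start(ov)[1]
  expect_equal(assign_fraction("chr1", opos, r1$annotation), "TE")

  # structural invariants
  cds <- r1$annotation[r1$annotation$type == "CDS"]
  expect_true(all(GenomicRanges::width(cds) %% 3 == 0))
  b <- r1$chars$chr1
  expect_true(all(b[r1$methylome$pos[r1$methylome$strand == "+"]] == "C"))
  expect_true(all(b[r1$methylome$pos[r1$methylome$strand == "-"]] == "G"))
})

test_that("zero TE proportion emits no TE intervals and tiny genomes error", {
  r <- generate_reference(sim_config(genome_size = 2e4, p_te = 0), seed = 1)
  expect_false(any(r$annotation$type == "transposable_element"))
  expect_error(generate_reference(sim_config(genome_size = 5e3), seed = 1),
               "too small")
})

test_that("spike_mutations places the requested unique mutations", {
  ref <- generate_reference(sim_config(genome_size = 2e5), seed = 3)
  tr <- spike_mutations(ref, n_hom = 308, n_het = 592, seed = 11)
  expect_equal(nrow(tr), 900)
  expect_equal(sum(tr$zygosity == "hom"), 308)
  expect_equal(sum(tr$zygosity == "het"), 592)
  expect_false(any(duplicated(paste(tr$chrom, tr$pos))))
  expect_true(all(tr$alt != tr$ref))
  expect_true(all(tr$alt %in% c("A", "C", "G", "T")))
  expect_true(all(tr$fraction %in% c("gene", "TE", "intergenic")))
  # spiked positions never fall in the mask
  msk <- IRanges::overlapsAny(IRanges::IRanges(tr$pos, width = 1),
                              GenomicRanges::ranges(ref$mask))
  expect_false(any(msk))

  expect_equal(nrow(spike_mutations(ref, 0, 0, seed = 1)), 0)
  expect_identical(spike_mutations(ref, 5, 5, seed = 9),
                   spike_mutations(ref, 5, 5, seed = 9))
  expect_error(spike_mutations(ref, n_hom = 3e5, n_het = 0, seed = 1),
               "eligible")
})

test_that("UV-B process obeys its limit cases and the methylation null", {
  ref <- generate_reference(sim_config(genome_size = 1e5), seed = 5)

  # fraction 1 with infinite TC(C/T) weight: all G:C>A:T in the motif frame
  tr <- simulate_uvb_process(ref, 300, gc_at_fraction = 1,
                             tc_weight = Inf, seed = 2)
  expect_true(all(collapse_class(tr$ref, tr$alt) == "G:C>A:T"))
  expect_true(all(substr(tr$context, 3, 3) == "T"))        # -1 base
  expect_true(all(substr(tr$context, 4, 4) == "C"))        # mutated base
  expect_true(all(substr(tr$context, 5, 5) %in% c("C", "T")))  # +1 base

  # methylation multiplier 1: methylated share among mutated cytosines
  # matches the methylated share of eligible cytosines
  tr0 <- simulate_uvb_process(ref, 3000, gc_at_fraction = 1, tc_weight = 1,
                              meth_multiplier = 1, seed = 4)
  expect_equal(mean(tr0$methylated), mean(ref$methylome$methylated),
               tolerance = 0.2)

  expect_identical(simulate_uvb_process(ref, 100, seed = 8),
                   simulate_uvb_process(ref, 100, seed = 8))
})

test_that("matrix simulation reproduces the coverage and error model", {
  cfg <- sim_config(genome_size = 2e4, coverage = 40, error_rate = 0)
  ref <- generate_reference(cfg, seed = 2)

  # noiseless genotypes: hom sites at frequency exactly 1, het mean ~0.5
  hom <- spike_mutations(ref, n_hom = 20, n_het = 0, seed = 3)
  m <- simulate_matrix(ref, hom, error_rate = 0, seed = 4)
  cls <- classify_matrix(m, ref)
  expect_true(all(cls$frequency[hom$pos] == 1))

  het <- spike_mutations(ref, n_hom = 0, n_het = 500, seed = 5)
  mh <- simulate_matrix(ref, het, error_rate = 0, seed = 6)
  clh <- classify_matrix(mh, ref)
  expect_gt(mean(clh$frequency[het$pos]), 0.49)
  expect_lt(mean(clh$frequency[het$pos]), 0.51)

  # 2% error: genome-wide non-reference read share ~0.02 at non-mutated sites
  me <- simulate_matrix(ref, NULL, error_rate = 0.02, seed = 7)
  refb <- ref_base(ref, me$chrom, me$pos)
  refcnt <- as.matrix(as.data.frame(me)[, c("A", "C", "G", "T")])[
    cbind(seq_len(nrow(me)), match(refb, c("A", "C", "G", "T")))]
  err_share <- sum(me$cov - refcnt) / sum(me$cov)
  expect_equal(err_share, 0.02, tolerance = 0.02)

  # coverage is Poisson(lambda)
  expect_equal(mean(me$cov), 40, tolerance = 0.01)
  expect_equal(var(me$cov), 40, tolerance = 0.05)

  # deletion truth alleles land in the deletion column
  del <- hom[1, ]; del$alt <- "-"; del$del_len <- 2L
  md <- simulate_matrix(ref, del, error_rate = 0, seed = 8)
  expect_equal(md$del[del$pos], md$cov[del$pos])
  expect_equal(md$del[del$pos + 1], md$cov[del$pos + 1])
})

test_that("selfing transmits by origin and crosses tag parent of origin", {
  pre <- data.frame(chrom = "chr1", pos = 1:3000, ref = "C", alt = "T",
                    del_len = NA_integer_, zygosity = "het",
                    origin = "somatic-pre-split", stringsAsFactors = FALSE)
  post <- transform(pre, origin = "post-split-maternal")

  s_post <- simulate_selfing(post, n_progeny = 1, seed = 1)
  expect_true(all(s_post$zygosity == "het"))

  s_pre <- simulate_selfing(pre, n_progeny = 1, seed = 2)
  expect_setequal(unique(s_pre$zygosity), c("absent", "het", "hom"))
  expect_identical(simulate_selfing(pre, 2, seed = 3),
                   simulate_selfing(pre, 2, seed = 3))

  mother <- data.frame(chrom = "chr1", pos = 1:10, ref = "G", alt = "A",
                       del_len = NA_integer_, zygosity = "hom",
                       origin = "somatic-pre-split", stringsAsFactors = FALSE)
  f1 <- simulate_reciprocal_cross(mother, mother[0, ], n_progeny = 3, seed = 4)
  expect_equal(nrow(f1), 30)
  expect_true(all(f1$zygosity == "het"))
  expect_true(all(f1$parent_of_origin == "mother"))

  expect_equal(nrow(simulate_reciprocal_cross(mother[0, ], mother[0, ],
                                              n_progeny = 2, seed = 5)), 0)

  het100 <- transform(mother[rep(1, 100), ], zygosity = "het", pos = 1:100)
  f1h <- simulate_reciprocal_cross(het100, het100[0, ], n_progeny = 200,
                                   seed = 6)
  expect_equal(nrow(f1h) / 200, 50, tolerance = 0.06)
})
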