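test_that("mutant allele frequency picks the top non-reference allele", {
  r <- mutant_allele_frequency(c(A = 0, C = 1, G = 0, T = 29, del = 0, N = 0),
                               "C")
  expect_equal(r$allele, "T")
  expect_equal(r$frequency, 29 / 30)

  # tie: lexicographically smallest allele wins the report
  r <- mutant_allele_frequency(c(A = 10, C = 20, G = 0, T = 10, del = 0, N = 0),
                               "C")
  expect_equal(r$allele, "A")
  expect_equal(r$frequency, 0.25)

  r <- mutant_allele_frequency(c(A = 0, C = 30, G = 0, T = 0, del = 0, N = 0),
                               "C")
  expect_true(is.na(r$allele))
  expect_equal(r$frequency, 0)

  r <- mutant_allele_frequency(c(A = 0, C = 0, G = 0, T = 0, del = 0, N = 0),
                               "C")
  expect_true(is.na(r$allele) && is.na(r$frequency))

  # N is never the mutant allele
  r <- mutant_allele_frequency(c(A = 0, C = 20, G = 0, T = 0, del = 0, N = 20),
                               "C")
  expect_true(is.na(r$allele))
})

test_that("classification thresholds and their boundaries are exact", {
  cases <- data.frame(
    freq = c(0.95, 0.5, 0.2, 0.05, 0.1, 0.3, 0.8, 0.9, 0.9001, 0.2999),
    want = c("hom_mut", "het", "seq_error", "hom_ref", "seq_error", "het",
             "undefined", "undefined", "hom_mut", "seq_error"))
  expect_equal(classify_position(cases$freq, coverage = 40), cases$want)
  expect_equal(classify_position(0.5, coverage = 15), "low_coverage")
  expect_equal(classify_position(0.5, coverage = 19), "low_coverage")
  expect_equal(classify_position(0.5, coverage = 20), "het")
  expect_equal(classify_position(0.95, coverage = 40, masked = TRUE), "masked")
})

test_that("multi-allelic sites are undefined, not fabricated calls", {
  refb <- c("C", "C")
  m <- flat_matrix(refb, cov = 40)
  m <- add_variant(m, refb, 1, "T", 10)
  m <- add_variant(m, refb, 1, "A", 10)   # two alleles at 0.25
  m <- add_variant(m, refb, 2, "T", 20)   # clean het
  cls <- classify_matrix(m, refb)
  expect_equal(cls$classification, c("undefined", "het"))
  expect_equal(cls$allele[2], "T")
})

test_that("cohort filtering applies the shared-variant check then rules (i)-(iv)", {
  hom_ref9 <- rep("hom_ref", 9)
  na9 <- rep(NA_character_, 9)
  expect_true(accept_novel_mutation("het", "T", hom_ref9, na9)$accept)

  # shared variant
  v <- accept_novel_mutation("het", "T", c("het", hom_ref9[-1]),
                             c("T", na9[-1]))
  expect_false(v$accept); expect_equal(v$reason, "shared_variant")

  # (i) more than one undefined
  v <- accept_novel_mutation("het", "T", c("undefined", "undefined",
                                           hom_ref9[-(1:2)]), na9)
  expect_false(v$accept); expect_equal(v$reason, "too_many_undefined")
  expect_true(accept_novel_mutation("het", "T",
                                    c("undefined", hom_ref9[-1]), na9)$accept)

  # (ii) a different mutation in a background genome
  v <- accept_novel_mutation("het", "T", c("hom_mut", hom_ref9[-1]),
                             c("A", na9[-1]))
  expect_false(v$accept); expect_equal(v$reason, "other_mutation")

  # (iii) more than three insufficiently covered backgrounds
  v <- accept_novel_mutation("het", "T", c(rep("low_coverage", 4),
                                           hom_ref9[-(1:4)]), na9)
  expect_false(v$accept); expect_equal(v$reason, "low_coverage_background")
  expect_true(accept_novel_mutation("het", "T", c(rep("low_coverage", 3),
                                                  hom_ref9[-(1:3)]),
                                    na9)$accept)

  # (iv) fewer than six homozygous wild-type backgrounds; seq_error is not
  # wild-type evidence
  v <- accept_novel_mutation("het", "T", c(rep("hom_ref", 5),
                                           rep("seq_error", 4)), na9)
  expect_false(v$accept); expect_equal(v$reason, "few_hom_ref")

  # reason precedence: shared variant outranks the undefined count
  v <- accept_novel_mutation("het", "T",
                             c("het", "undefined", "undefined", hom_ref9[-(1:3)]),
                             c("T", na9[-1]))
  expect_equal(v$reason, "shared_variant")

  expect_error(accept_novel_mutation("het", "T", rep("hom_ref", 5), na9[1:5]),
               "cohort too small")
  expect_error(accept_novel_mutation("hom_ref", "T", hom_ref9, na9),
               "het or hom_mut")
})

test_that("call_genome recovers clean spikes and rejects shared variants", {
  set.seed(42)
  refb <- random_bases(2000)
  clean <- flat_matrix(refb, cov = 40)
  focal <- clean
  spike_pos <- seq(100, 2000, by = 100)
  for (p in spike_pos) {
    alt <- setdiff(c("A", "C", "G", "T"), refb[p])[1]
    k <- if (p %% 200 == 0) 40 else 20          # hom and het spikes
    focal <- add_variant(focal, refb, p, alt, k)
  }
  bgs <- replicate(9, clean, simplify = FALSE)
  res <- call_genome(focal, refb, bgs)
  expect_equal(nrow(res$mutations), length(spike_pos))
  expect_setequal(res$mutations$pos, spike_pos)
  expect_equal(sum(res$mutations$zygosity == "hom"), sum(spike_pos %% 200 == 0))

  # the focal genome among its own backgrounds: everything is shared
  res2 <- call_genome(focal, refb, c(list(focal), bgs[1:8]))
  expect_equal(nrow(res2$mutations), 0)
  expect_true(all(res2$rejections$reason == "shared_variant"))
})

test_that("adjacent accepted deletions merge into one multi-base record", {
  refb <- random_bases(200)
  clean <- flat_matrix(refb, cov = 40)
  focal <- clean
  for (p in 50:52) {
    focal$del[p] <- 40L; focal[[refb[p]]][p] <- 0L
  }
  focal$del[100] <- 20L; focal[[refb[100]]][100] <- 20L
  focal <- genome_matrix(as.data.frame(focal))
  res <- call_genome(focal, refb, replicate(9, clean, simplify = FALSE))
  expect_equal(nrow(res$mutations), 2)
  run <- res$mutations[res$mutations$pos == 50, ]
  expect_equal(run$del_len, 3L)
  expect_equal(run$ref, paste(refb[50:52], collapse = ""))
  expect_equal(run$zygosity, "hom")
  expect_equal(res$mutations$del_len[res$mutations$pos == 100], 1L)

  # VCF uses the left-anchored deletion convention
  path <- withr::local_tempfile(fileext = ".vcf")
  seqs <- Biostrings::DNAStringSet(c(chr1 = paste(refb, collapse = "")))
  write_vcf(res$mutations, seqs, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(f[2], "49")
  expect_equal(f[4], paste(refb[49:52], collapse = ""))
  expect_equal(f[5], refb[49])
  expect_equal(f[10], "1/1")
})

test_that("caller evaluation computes FN over accessible truth only", {
  # the published worked example: 685 accessible truth, 684 found
  truth <- data.frame(chrom = "chr1", pos = 1:900, ref = "C", alt = "T",
                      del_len = NA_integer_, zygosity = "het",
                      stringsAsFactors = FALSE)
  track <- data.frame(chrom = "chr1", pos = 1:900,
                      accessible = c(rep(TRUE, 685), rep(FALSE, 215)),
                      reason = NA, stringsAsFactors = FALSE)
  called <- data.frame(chrom = "chr1", pos = 1:684, ref = "C", alt = "T",
                       del_len = NA_integer_, zygosity = "het",
                       stringsAsFactors = FALSE)
  ev <- evaluate_caller(truth, called, track)
  expect_equal(ev$n_truth_accessible, 685)
  expect_equal(ev$fn, 1)
  expect_equal(round(ev$fn_percent, 2), 0.15)
  expect_equal(ev$fp, 0)
  expect_equal(ev$missed$pos, 685)

  # perfect recovery with nothing extra
  ev2 <- evaluate_caller(truth, truth, transform(track, accessible = TRUE))
  expect_equal(ev2$fn, 0); expect_equal(ev2$fp, 0)

  # a call outside the truth is a false positive
  fp <- rbind(called, data.frame(chrom = "chr1", pos = 899, ref = "C",
                                 alt = "A", del_len = NA_integer_,
                                 zygosity = "het"))
  expect_equal(evaluate_caller(truth, fp, track)$fp, 1)
})
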