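# In-code fixtures shared across test files.

# Small reference reused by several files (generated once per test run).
tiny_cfg <- function(...) sim_config(genome_size = 2e4, n_hom = 3, n_het = 6, ...)

# A noise-free genome matrix over an explicit base vector: every position
# covered by `cov` reads of the reference base.
flat_matrix <- function(refbases, cov = 40, chrom = "chr1") {
  n <- length(refbases)
  df <- data.frame(chrom = chrom, pos = seq_len(n), cov = cov,
                   A = 0L, C = 0L, G = 0L, T = 0L, del = 0L, N = 0L,
                   stringsAsFactors = FALSE)
  for (b in c("A", "C", "G", "T")) df[[b]][refbases == b] <- cov
  genome_matrix(df)
}

# Move `n` reads from the reference base to `allele` at `pos`.
add_variant <- function(mat, refbases, pos, allele, n) {
  refb <- refbases[pos]
  mat[[refb]][pos] <- mat[[refb]][pos] - n
  mat[[allele]][pos] <- mat[[allele]][pos] + n
  genome_matrix(as.data.frame(mat))
}

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# Expand (possibly run-merged) mutation records to per-position keys for
# set comparisons.
record_keys <- function(records) {
  if (nrow(records) == 0) return(character(0))
  unlist(Map(function(cm, p, a, l) {
    l <- if (is.na(l)) 1L else l
    paste(cm, p:(p + l - 1L), a)
  }, records$chrom, records$pos, records$alt, records$del_len),
  use.names = FALSE)
}
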