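# Shared internal helpers.

DNA_BASES4 <- c("A", "C", "G", "T")
ALLELE_COLS <- c("A", "C", "G", "T", "del", "N")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

comp_base <- function(x) unname(COMP[x])

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators never perturb user code.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  code
}

# Derive a stream-specific child seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 999983 * as.double(offset)) %% 2147483587)
}

# Character vector of bases for one chromosome of a synthetic reference (or
# any DNAStringSet).
seq_chars <- function(seqs, chrom) {
  strsplit(as.character(seqs[[chrom]]), "", fixed = TRUE)[[1]]
}

# Draw one multinomial count vector per row, vectorised over rows via
# sequential (stick-breaking) binomials.  `size` is an integer vector,
# `prob` a single probability vector over categories (constant across rows).
rmultinom_rows <- function(size, prob) {
  n <- length(size)
  k <- length(prob)
  out <- matrix(0L, nrow = n, ncol = k)
  rem_n <- as.integer(size)
  rem_p <- 1
  for (j in seq_len(k - 1L)) {
    if (prob[j] <= 0 || rem_p <= 0) {
      rem_p <- rem_p - prob[j]
      next
    }
    p <- min(1, prob[j] / rem_p)
    draw <- rbinom(n, rem_n, p)
    out[, j] <- draw
    rem_n <- rem_n - draw
    rem_p <- rem_p - prob[j]
  }
  out[, k] <- rem_n
  out
}
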