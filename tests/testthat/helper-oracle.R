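# Independent brute-force oracles, written as literal transcriptions of the
# classification table and cohort rules; they share no code with the
# package implementation.

oracle_classify <- function(counts, cov, refb, masked, min_cov = 20) {
  if (masked) return(list(class = "masked", allele = NA_character_))
  if (cov < min_cov) return(list(class = "low_coverage", allele = NA_character_))
  alleles <- c("A", "C", "G", "T", "del")
  nonref <- setdiff(alleles, refb)
  vals <- vapply(nonref, function(a) counts[[a]], numeric(1))
  top <- nonref[which.max(vals)]           # lexicographic tie-break
  f1 <- max(vals) / cov
  f2 <- sort(vals, decreasing = TRUE)[2] / cov
  allele <- if (max(vals) > 0) (if (top == "del") "-" else top) else NA_character_
  if (f1 >= 0.1 && f2 >= 0.1)
    return(list(class = "undefined", allele = allele))
  cls <- if (f1 > 0.9) "hom_mut"
  else if (f1 >= 0.8) "undefined"
  else if (f1 >= 0.3) "het"
  else if (f1 >= 0.1) "seq_error"
  else "hom_ref"
  list(class = cls, allele = allele)
}

# Literal per-position caller: classification table + shared-variant check +
# background rules (i)-(iv), looped over every position.
oracle_call <- function(focal, refbases, masked, backgrounds, min_cov = 20) {
  accepted <- list()
  for (i in seq_len(nrow(focal))) {
    fc <- oracle_classify(focal[i, ], focal$cov[i], refbases[i], masked[i],
                          min_cov)
    if (!fc$class %in% c("het", "hom_mut")) next
    bg <- lapply(backgrounds, function(b)
      oracle_classify(b[i, ], b$cov[i], refbases[i], FALSE, min_cov))
    bcls <- vapply(bg, `[[`, character(1), "class")
    ball <- vapply(bg, `[[`, character(1), "allele")
    same <- bcls %in% c("het", "hom_mut") & !is.na(ball) & ball == fc$allele
    other <- bcls %in% c("het", "hom_mut") & !is.na(ball) & ball != fc$allele
    if (any(same)) next                                   # shared variant
    if (sum(bcls == "undefined") > 1) next                # (i)
    if (any(other)) next                                  # (ii)
    if (sum(bcls == "low_coverage") > 3) next             # (iii)
    if (sum(bcls == "hom_ref") < 6) next                  # (iv)
    accepted[[length(accepted) + 1L]] <-
      data.frame(chrom = focal$chrom[i], pos = focal$pos[i],
                 alt = fc$allele,
                 zygosity = if (fc$class == "hom_mut") "hom" else "het",
                 stringsAsFactors = FALSE)
  }
  if (length(accepted) == 0)
    return(data.frame(chrom = character(0), pos = integer(0),
                      alt = character(0), zygosity = character(0)))
  do.call(rbind, accepted)
}

# Random noisy cohort generator for the oracle-equivalence property: counts
# are drawn to hit every classification band, including multi-allelic and
# deletion sites.
random_cohort_matrix <- function(refbases, chrom = "chr1") {
  n <- length(refbases)
  cov <- rpois(n, 30)
  low <- runif(n) < 0.05
  cov[low] <- sample(0:19, sum(low), replace = TRUE)
  df <- data.frame(chrom = chrom, pos = seq_len(n), cov = cov,
                   A = 0L, C = 0L, G = 0L, T = 0L, del = 0L, N = 0L,
                   stringsAsFactors = FALSE)
  for (b in c("A", "C", "G", "T")) df[[b]][refbases == b] <- cov[refbases == b]
  alleles <- c("A", "C", "G", "T", "del")
  variant <- which(runif(n) < 0.15 & cov > 0)
  for (i in variant) {
    a <- sample(setdiff(alleles, refbases[i]), 1)
    k <- rbinom(1, cov[i], runif(1))
    df[[refbases[i]]][i] <- df[[refbases[i]]][i] - k
    df[[a]][i] <- df[[a]][i] + k
    if (runif(1) < 0.2) {   # second allele -> multi-allelic candidates
      a2 <- sample(setdiff(alleles, c(refbases[i], a)), 1)
      k2 <- rbinom(1, df[[refbases[i]]][i], 0.3)
      df[[refbases[i]]][i] <- df[[refbases[i]]][i] - k2
      df[[a2]][i] <- df[[a2]][i] + k2
    }
  }
  genome_matrix(df)
}

# Two-sided Fisher p by full hypergeometric enumeration.
fisher_p_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Direct evaluation of the Yates-corrected chi-square statistic.
yates_stat <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum(pmax(0, abs(tab - E) - 0.5)^2 / E)
}
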