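#' Call per-cytosine methylation status from replicate profiles
#'
#' Applies the replicate-based calling rules: only replicates with at least
#' `min_depth` (10) sequencing reads at the cytosine are considered; the
#' cytosine is methylated if its methylation fraction reaches `min_frac`
#' (10%, inclusive) in at least `min_reps` (2) qualifying replicates;
#' cytosines with fewer than `min_reps` qualifying replicates are not
#' analysed.
#'
#' @param profile Data.frame with columns `chrom`, `pos`, `strand`,
#'   `context` plus replicate columns `depth_1..k` and `frac_1..k`.
#' @param min_depth,min_frac,min_reps Inclusive thresholds (defaults 10,
#'   0.10, 2).
#' @return The profile's key columns plus a `status` column over
#'   `"methylated"`, `"unmethylated"`, `"not_analysed"`.
#' @examples
#' p <- data.frame(chrom = "chr1", pos = 5, strand = "+", context = "CG",
#'                 depth_1 = 12, depth_2 = 15, depth_3 = 9,
#'                 frac_1 = 0.12, frac_2 = 0.11, frac_3 = 0.50)
#' call_methylation(p)$status
#' @export
call_methylation <- function(profile, min_depth = 10, min_frac = 0.10,
                             min_reps = 2) {
  depth_cols <- grep("^depth_", names(profile), value = TRUE)
  frac_cols <- grep("^frac_", names(profile), value = TRUE)
  if (length(depth_cols) < min_reps || length(depth_cols) != length(frac_cols))
    stop("profile needs matching depth_k / frac_k columns for >= ",
         min_reps, " replicates")
  depth <- as.matrix(profile[, sort(depth_cols), drop = FALSE])
  frac <- as.matrix(profile[, sort(frac_cols), drop = FALSE])
  stopifnot(all(frac >= 0 & frac <= 1, na.rm = TRUE))
  qual <- !is.na(depth) & depth >= min_depth
  n_qual <- rowSums(qual)
  n_meth <- rowSums(qual & !is.na(frac) & frac >= min_frac)
  status <- ifelse(n_qual < min_reps, "not_analysed",
                   ifelse(n_meth >= min_reps, "methylated", "unmethylated"))
  out <- profile[, c("chrom", "pos", "strand", "context"), drop = FALSE]
  out$status <- status
  out
}

#' Cytosine context at a position
#'
#' Determined from the two bases immediately downstream on the cytosine's
#' own strand: CG if the next base is G, CHG if the base after next is G,
#' otherwise CHH (H is A, T or C).
#'
#' @param reference A `synthetic_reference` or DNAStringSet.
#' @param chrom,pos,strand Parallel vectors; the base at (pos, strand) must
#'   be a cytosine.
#' @return Character vector over `"CG"`, `"CHG"`, `"CHH"`.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "AACGAT"))
#' context_of(ref, "chr1", 3, "+")
#' @export
context_of <- function(reference, chrom, pos, strand) {
  seqs <- if (inherits(reference, "synthetic_reference")) reference$seq else reference
  n <- length(pos)
  out <- character(n)
  for (i in seq_len(n)) {
    chars <- strsplit(as.character(seqs[[chrom[i]]]), "")[[1]]
    L <- length(chars)
    if (strand[i] == "+") {
      if (chars[pos[i]] != "C") stop("no cytosine at ", chrom[i], ":", pos[i], " (+)")
      if (pos[i] > L - 2L) stop("context unresolvable at contig end")
      n1 <- chars[pos[i] + 1L]; n2 <- chars[pos[i] + 2L]
    } else {
      if (chars[pos[i]] != "G") stop("no cytosine at ", chrom[i], ":", pos[i], " (-)")
      if (pos[i] < 3L) stop("context unresolvable at contig end")
      n1 <- comp_base(chars[pos[i] - 1L]); n2 <- comp_base(chars[pos[i] - 2L])
    }
    out[i] <- if (n1 == "G") "CG" else if (n2 == "G") "CHG" else "CHH"
  }
  out
}

#' Simulate replicate methylation profiles from a reference methylome
#'
#' Emits per-cytosine replicate read depths (Poisson) and methylation
#' fractions (binomial around a high rate for methylated and a low rate for
#' unmethylated cytosines), the input format of [call_methylation()].
#'
#' @param ref A `synthetic_reference`.
#' @param n_rep Number of biological replicates (default 3).
#' @param depth Mean per-replicate read depth (default 30).
#' @param p_meth,p_unmeth Per-read methylation probabilities for methylated
#'   and unmethylated cytosines (defaults 0.8 and 0.01).
#' @param seed Integer seed.
#' @return A profile data.frame (chrom, pos, strand, context,
#'   depth_k, frac_k).
#' @export
simulate_methylation_profiles <- function(ref, n_rep = 3, depth = 30,
                                          p_meth = 0.8, p_unmeth = 0.01,
                                          seed = 1) {
  stopifnot(inherits(ref, "synthetic_reference"))
  me <- ref$methylome
  with_seed(seed, {
    out <- me[, c("chrom", "pos", "strand", "context")]
    p <- ifelse(me$methylated, p_meth, p_unmeth)
    for (r in seq_len(n_rep)) {
      d <- rpois(nrow(me), depth)
      k <- rbinom(nrow(me), d, p)
      out[[paste0("depth_", r)]] <- d
      out[[paste0("frac_", r)]] <- ifelse(d > 0, k / d, 0)
    }
    out
  })
}

#' Mutation-methylation overlap, per cytosine context
#'
#' Restricts to G:C>A:T mutations (the UV-B-relevant class) at analysable
#' cytosines -- a G>A record is looked up at its own position on the
#' reverse strand, where the mutated cytosine sits -- and contrasts the
#' methylated share among mutated cytosines with the genome-wide methylated
#' share of analysable cytosines, per context (CG, CHG, CHH) and pooled
#' (CNN), with a Yates-corrected chi-square test on the 2x2
#' methylated/unmethylated x mutations/genome table.
#'
#' @param mutations Mutation records with `chrom`, `pos`, `ref`, `alt`.
#' @param meth_status Status table from [call_methylation()].
#' @return Data.frame per context: `n_mut` (testable mutated positions),
#'   `overlap_pct`, `n_genome`, `genome_pct`, `statistic`, `p_value`
#'   (`NA` when a context has no testable mutation).
#' @export
methylation_overlap <- function(mutations, meth_status) {
  subs <- mutations[mutations$alt %in% DNA_BASES4 &
                      mutations$ref %in% c("C", "G"), , drop = FALSE]
  if (nrow(subs) > 0) {
    cls <- collapse_class(subs$ref, subs$alt)
    subs <- subs[cls == "G:C>A:T", , drop = FALSE]
  }
  strand_c <- ifelse(subs$ref == "C", "+", "-")
  analysable <- meth_status[meth_status$status != "not_analysed", , drop = FALSE]
  key <- paste(analysable$chrom, analysable$pos, analysable$strand)
  m <- match(paste(subs$chrom, subs$pos, strand_c), key)
  mut_status <- analysable$status[m]
  mut_context <- analysable$context[m]
  testable <- !is.na(m)

  contexts <- c("CNN", "CG", "CHG", "CHH")
  out <- lapply(contexts, function(ctx) {
    g <- if (ctx == "CNN") rep(TRUE, nrow(analysable)) else
      analysable$context == ctx
    mu <- if (ctx == "CNN") testable else testable & mut_context == ctx
    mu[is.na(mu)] <- FALSE
    n_mut <- sum(mu)
    meth_mut <- sum(mut_status[mu] == "methylated")
    n_gen <- sum(g)
    meth_gen <- sum(analysable$status[g] == "methylated")
    res <- data.frame(context = ctx, n_mut = n_mut,
                      overlap_pct = if (n_mut > 0) 100 * meth_mut / n_mut else NA,
                      n_genome = n_gen,
                      genome_pct = if (n_gen > 0) 100 * meth_gen / n_gen else NA,
                      statistic = NA_real_, p_value = NA_real_,
                      stringsAsFactors = FALSE)
    if (n_mut > 0 && n_gen > 0) {
      tab <- rbind(c(meth_mut, n_mut - meth_mut),
                   c(meth_gen, n_gen - meth_gen))
      if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        ch <- chi_square_yates(tab)
        res$statistic <- ch$statistic
        res$p_value <- ch$p_value
      }
    }
    res
  })
  do.call(rbind, out)
}
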