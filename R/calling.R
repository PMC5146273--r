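CLASSIFICATIONS <- c("hom_ref", "hom_mut", "het", "undefined", "seq_error",
                     "low_coverage", "masked")

#' Mutant allele and its frequency for one pileup row
#'
#' Returns the highest-count non-reference allele among A, C, G, T and the
#' deletion symbol, and its frequency (count / total coverage).  N is never
#' a mutant allele (it only contributes to the coverage denominator).  Ties
#' are broken towards the lexicographically smallest allele (deletion
#' last); a genuine multi-allelic tie at frequency >= 0.1 leads to an
#' `undefined` classification downstream.
#'
#' @param counts Named counts for `A`, `C`, `G`, `T`, `del` (and optionally
#'   `N`).
#' @param ref_allele Reference base at the position.
#' @param coverage Total coverage; defaults to `sum(counts)`.
#' @return List with `allele` (`NA` if no non-reference reads, or no data)
#'   and `frequency` (`NA` at zero coverage).
#' @examples
#' mutant_allele_frequency(c(A = 0, C = 1, G = 0, T = 29, del = 0, N = 0), "C")
#' @export
mutant_allele_frequency <- function(counts, ref_allele, coverage = sum(counts)) {
  if (coverage < 1) return(list(allele = NA_character_, frequency = NA_real_))
  alleles <- c("A", "C", "G", "T", "del")
  cnt <- counts[alleles]
  cnt[is.na(cnt)] <- 0
  cnt[ref_allele] <- -1
  top <- which.max(cnt)  # first maximum = lexicographic tie-break
  if (cnt[top] <= 0) return(list(allele = NA_character_, frequency = 0))
  list(allele = ifelse(alleles[top] == "del", "-", alleles[top]),
       frequency = unname(cnt[top]) / coverage)
}

#' Classify a position by mutant-allele frequency
#'
#' Applies the frequency thresholds used for genotype classification:
#' frequency in \[0, 0.1) is homozygous reference, \[0.1, 0.3) putative
#' sequencing error (not accepted), \[0.3, 0.8) heterozygous mutation,
#' \[0.8, 0.9\] undefined, and above 0.9 homozygous mutation.  Positions
#' covered by fewer than `min_coverage` reads are `low_coverage`
#' regardless of frequency, and masked positions override everything.
#'
#' @param frequency Mutant-allele frequency in \[0, 1\] (vectorised).
#' @param coverage Read coverage (vectorised).
#' @param masked Logical masked flag (vectorised, default `FALSE`).
#' @param min_coverage Low-coverage cutoff (default 20).
#' @return Character vector of classifications.
#' @examples
#' classify_position(c(0.95, 0.5, 0.2, 0.05), coverage = 40)
#' classify_position(0.5, coverage = 15)
#' @export
classify_position <- function(frequency, coverage, masked = FALSE,
                              min_coverage = 20) {
  n <- max(length(frequency), length(coverage), length(masked))
  frequency <- rep_len(frequency, n)
  coverage <- rep_len(coverage, n)
  masked <- rep_len(masked, n)
  stopifnot(all(is.na(frequency) | (frequency >= 0 & frequency <= 1)))
  cls <- rep("hom_ref", n)
  cls[frequency >= 0.1 & frequency < 0.3] <- "seq_error"
  cls[frequency >= 0.3 & frequency < 0.8] <- "het"
  cls[frequency >= 0.8 & frequency <= 0.9] <- "undefined"
  cls[frequency > 0.9] <- "hom_mut"
  cls[coverage < min_coverage] <- "low_coverage"
  cls[masked] <- "masked"
  cls
}

ref_bases_for <- function(mat, ref) {
  if (inherits(ref, "synthetic_reference")) return(ref_base(ref, mat$chrom, mat$pos))
  if (is(ref, "DNAStringSet")) {
    out <- character(nrow(mat))
    for (cm in unique(mat$chrom)) {
      i <- mat$chrom == cm
      out[i] <- strsplit(as.character(ref[[cm]]), "")[[1]][mat$pos[i]]
    }
    return(out)
  }
  if (is.character(ref) && length(ref) == nrow(mat)) return(ref)
  stop("ref must be a synthetic_reference, DNAStringSet, or per-row base vector")
}

#' Classify every position of a genome matrix
#'
#' Vectorised application of [mutant_allele_frequency()] and
#' [classify_position()], with the additional multi-allelic rule: when two
#' distinct non-reference alleles each reach frequency 0.1 the position is
#' `undefined` (no call is fabricated at such sites).
#'
#' @param mat A [genome_matrix()].
#' @param ref Reference: a `synthetic_reference`, a
#'   [Biostrings::DNAStringSet], or a character vector of per-row bases.
#' @param min_coverage Low-coverage cutoff (default 20).
#' @return Data.frame with chrom, pos, cov, ref, classification, allele,
#'   frequency.
#' @export
classify_matrix <- function(mat, ref, min_coverage = 20) {
  stopifnot(inherits(mat, "genome_matrix"))
  refb <- ref_bases_for(mat, ref)
  n <- nrow(mat)
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = integer(0), cov = integer(0),
                      ref = character(0), classification = character(0),
                      allele = character(0), frequency = numeric(0)))
  }
  alleles <- c("A", "C", "G", "T", "del")
  cnt <- as.matrix(as.data.frame(mat)[, alleles])
  storage.mode(cnt) <- "double"
  refi <- match(refb, alleles)
  cnt[cbind(seq_len(n), refi)] <- -1
  top1 <- max.col(cnt, ties.method = "first")
  v1 <- cnt[cbind(seq_len(n), top1)]
  cnt[cbind(seq_len(n), top1)] <- -1
  top2 <- max.col(cnt, ties.method = "first")
  v2 <- cnt[cbind(seq_len(n), top2)]

  cov <- mat$cov
  freq <- ifelse(cov > 0, pmax(v1, 0) / cov, 0)
  freq2 <- ifelse(cov > 0, pmax(v2, 0) / cov, 0)
  masked <- if (is.null(mat$masked)) rep(FALSE, n) else mat$masked

  cls <- classify_position(freq, cov, masked, min_coverage)
  multi <- freq >= 0.1 & freq2 >= 0.1 & !masked & cov >= min_coverage
  cls[multi] <- "undefined"

  allele <- ifelse(v1 > 0, c(alleles[1:4], "-")[top1], NA_character_)
  data.frame(chrom = mat$chrom, pos = mat$pos, cov = cov, ref = refb,
             classification = cls, allele = allele, frequency = freq,
             stringsAsFactors = FALSE)
}

#' Accept or reject a candidate novel mutation against a background cohort
#'
#' A focal variant call (heterozygous or homozygous-mutant) is accepted as a
#' novel mutation only if no background genome shows the same variant and at
#' least six background genomes show evidence for a homozygous wild-type
#' allele.  Rejection reasons are evaluated in a fixed order after the
#' shared-variant check: (i) more than one background genome `undefined`;
#' (ii) any background genome carrying a different mutation at the
#' position; (iii) more than three background genomes insufficiently
#' covered; (iv) fewer than six background genomes homozygous wild-type.
#' Sequencing-error-class background calls count as neither wild-type
#' evidence nor as mutations.
#'
#' @param focal_class Focal classification (`"het"` or `"hom_mut"`).
#' @param focal_allele Focal mutant allele.
#' @param bg_class Character vector of background classifications at the
#'   position.
#' @param bg_allele Background mutant alleles (parallel to `bg_class`).
#' @param max_undefined,max_low_coverage,min_hom_ref Cohort thresholds
#'   (defaults 1, 3, 6).
#' @return List with `accept` (logical) and `reason` (`NA` when accepted,
#'   otherwise the first failing rule: `shared_variant`,
#'   `too_many_undefined`, `other_mutation`, `low_coverage_background`,
#'   `few_hom_ref`).
#' @examples
#' accept_novel_mutation("het", "T", rep("hom_ref", 9), rep(NA, 9))
#' accept_novel_mutation("het", "T", c("het", rep("hom_ref", 8)),
#'                       c("T", rep(NA, 8)))
#' @export
accept_novel_mutation <- function(focal_class, focal_allele, bg_class,
                                  bg_allele, max_undefined = 1,
                                  max_low_coverage = 3, min_hom_ref = 6) {
  if (!focal_class %in% c("het", "hom_mut"))
    stop("focal classification must be het or hom_mut")
  if (length(bg_class) < min_hom_ref)
    stop("background cohort too small (", length(bg_class),
         " genomes after parent exclusion; need >= ", min_hom_ref, ")")
  is_mut <- bg_class %in% c("het", "hom_mut")
  if (any(is_mut & bg_allele == focal_allele, na.rm = TRUE))
    return(list(accept = FALSE, reason = "shared_variant"))
  if (sum(bg_class == "undefined") > max_undefined)
    return(list(accept = FALSE, reason = "too_many_undefined"))
  if (any(is_mut & bg_allele != focal_allele, na.rm = TRUE))
    return(list(accept = FALSE, reason = "other_mutation"))
  if (sum(bg_class == "low_coverage") > max_low_coverage)
    return(list(accept = FALSE, reason = "low_coverage_background"))
  if (sum(bg_class == "hom_ref") < min_hom_ref)
    return(list(accept = FALSE, reason = "few_hom_ref"))
  list(accept = TRUE, reason = NA_character_)
}

#' Call novel mutations in a focal genome against a background cohort
#'
#' End-to-end per-genome calling: mask application, per-position
#' classification, focal-only accessibility, and cohort filtering of every
#' candidate (heterozygous or homozygous-mutant) position.  Runs of
#' adjacent accepted deletion calls with equal zygosity are merged into a
#' single multi-base deletion record.
#'
#' @param focal A [genome_matrix()] for the focal genome.
#' @param ref Reference (`synthetic_reference`, DNAStringSet, or per-row
#'   base vector).
#' @param backgrounds List of background [genome_matrix()] objects (or
#'   zero-argument functions returning one), all aligned to the same
#'   reference rows as `focal`.  Typically the nine sibling genomes of the
#'   same genotype; an excluded parent is simply left out of the list.
#' @param mask Optional mask (GRanges or BED path) applied to the focal
#'   genome.
#' @param genome_id Label stamped into the mutation records.
#' @param min_coverage,max_undefined,max_low_coverage,min_hom_ref
#'   Thresholds; defaults are the standard values (20x, 1, 3, 6).
#' @return List with `mutations` (accepted records: chrom, pos, ref, alt,
#'   del_len, zygosity, frequency, coverage, genome_id), `rejections`
#'   (audit table with reasons), `calls` (the full focal
#'   [classify_matrix()] table), `accessibility` track, `n_accessible` and
#'   a `summary` of per-class position counts.
#' @export
call_genome <- function(focal, ref, backgrounds, mask = NULL,
                        genome_id = "focal", min_coverage = 20,
                        max_undefined = 1, max_low_coverage = 3,
                        min_hom_ref = 6) {
  stopifnot(inherits(focal, "genome_matrix"))
  if (length(backgrounds) < min_hom_ref)
    stop("background cohort too small (", length(backgrounds), " genomes)")
  if (!is.null(mask)) focal <- apply_mask(focal, mask)
  if (inherits(ref, "synthetic_reference")) {
    if (sum(lengths(ref$chars)) != nrow(focal))
      stop("reference and focal matrix lengths differ")
  }
  cls <- classify_matrix(focal, ref, min_coverage)
  acc <- accessibility(focal, cls, min_coverage)
  cand <- which(cls$classification %in% c("het", "hom_mut"))

  bg_class <- matrix(character(0), nrow = length(cand), ncol = 0)
  bg_allele <- matrix(character(0), nrow = length(cand), ncol = 0)
  if (length(cand) > 0) {
    bg_class <- matrix(NA_character_, length(cand), length(backgrounds))
    bg_allele <- matrix(NA_character_, length(cand), length(backgrounds))
    for (j in seq_along(backgrounds)) {
      b <- backgrounds[[j]]
      if (is.function(b)) b <- b()
      stopifnot(inherits(b, "genome_matrix"))
      if (nrow(b) != nrow(focal))
        stop("background genome ", j, " is not aligned to the focal matrix")
      sub <- b[cand, , drop = FALSE]
      if (any(sub$chrom != cls$chrom[cand]) || any(sub$pos != cls$pos[cand]))
        stop("background genome ", j, " rows do not match focal coordinates")
      sub$masked <- NULL
      bcls <- classify_matrix(genome_matrix(sub), cls$ref[cand], min_coverage)
      bg_class[, j] <- bcls$classification
      bg_allele[, j] <- bcls$allele
    }
  }

  records <- list()
  rejections <- list()
  for (k in seq_along(cand)) {
    i <- cand[k]
    verdict <- accept_novel_mutation(cls$classification[i], cls$allele[i],
                                     bg_class[k, ], bg_allele[k, ],
                                     max_undefined, max_low_coverage,
                                     min_hom_ref)
    rec <- data.frame(chrom = cls$chrom[i], pos = cls$pos[i],
                      ref = cls$ref[i], alt = cls$allele[i],
                      del_len = ifelse(cls$allele[i] == "-", 1L, NA_integer_),
                      zygosity = ifelse(cls$classification[i] == "hom_mut",
                                        "hom", "het"),
                      frequency = cls$frequency[i], coverage = cls$cov[i],
                      genome_id = genome_id, stringsAsFactors = FALSE)
    if (verdict$accept) {
      records[[length(records) + 1L]] <- rec
    } else {
      rec$reason <- verdict$reason
      rejections[[length(rejections) + 1L]] <- rec
    }
  }
  mutations <- if (length(records) > 0) do.call(rbind, records) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), del_len = integer(0),
               zygosity = character(0), frequency = numeric(0),
               coverage = numeric(0), genome_id = character(0),
               stringsAsFactors = FALSE)
  rejections <- if (length(rejections) > 0) do.call(rbind, rejections) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), del_len = integer(0),
               zygosity = character(0), frequency = numeric(0),
               coverage = numeric(0), genome_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  mutations <- merge_deletion_runs(mutations)
  mutations <- mutations[order(mutations$chrom, mutations$pos), , drop = FALSE]
  rownames(mutations) <- NULL

  summary <- list(
    n_positions = nrow(focal),
    class_counts = table(factor(cls$classification, levels = CLASSIFICATIONS)),
    n_candidates = length(cand),
    n_accepted = nrow(mutations),
    rejections_by_reason = table(rejections$reason),
    n_accessible = acc$n_accessible)
  list(mutations = mutations, rejections = rejections, calls = cls,
       accessibility = acc$track, n_accessible = acc$n_accessible,
       summary = summary)
}

# Adjacent accepted single-base deletion calls of equal zygosity on the same
# chromosome are reported as one multi-base deletion record (the matrix has
# no native multi-base representation, so run-merging is the convention).
merge_deletion_runs <- function(mutations) {
  if (nrow(mutations) == 0 || !any(mutations$alt == "-")) return(mutations)
  mutations <- mutations[order(mutations$chrom, mutations$pos), , drop = FALSE]
  is_del <- mutations$alt == "-"
  run_id <- cumsum(!(is_del &
                       c(FALSE, is_del[-length(is_del)]) &
                       c(FALSE, mutations$chrom[-1] == mutations$chrom[-nrow(mutations)] &
                           mutations$pos[-1] == mutations$pos[-nrow(mutations)] + 1L &
                           mutations$zygosity[-1] == mutations$zygosity[-nrow(mutations)])))
  merged <- lapply(split(seq_len(nrow(mutations)), run_id), function(idx) {
    if (length(idx) == 1L) return(mutations[idx, , drop = FALSE])
    first <- mutations[idx[1], , drop = FALSE]
    first$ref <- paste(mutations$ref[idx], collapse = "")
    first$del_len <- length(idx)
    first$frequency <- mean(mutations$frequency[idx])
    first$coverage <- mean(mutations$coverage[idx])
    first
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Measure caller error rates against a simulated truth set
#'
#' Computes the false-negative rate over *accessible* truth mutations
#' (truth records at inaccessible sites are excluded from the denominator,
#' since they cannot affect rate estimates normalized by accessible sites),
#' the false-positive count, and the mutant-allele-frequency histograms
#' that motivate the 0.3 heterozygous cutoff.
#'
#' @param truth TruthSet data.frame.
#' @param mutations Accepted mutation records from [call_genome()].
#' @param accessibility Accessibility track from [call_genome()].
#' @param calls Optional full [classify_matrix()] table; when given, the
#'   returned histogram data include per-site frequencies at truth sites
#'   and at error (non-truth, non-reference) sites.
#' @return List: `n_truth`, `n_truth_accessible`, `n_called`, `fn`,
#'   `fn_rate` (fraction), `fn_percent`, `fp` (count), `missed` and
#'   `false_positives` record tables, and `frequencies` (list of numeric
#'   vectors `truth` and `error`).
#' @export
evaluate_caller <- function(truth, mutations, accessibility, calls = NULL) {
  expand_keys <- function(chrom, pos, alt, del_len) {
    del_len[is.na(del_len)] <- 1L
    unlist(Map(function(cm, p, a, l) paste(cm, p:(p + l - 1L), a),
               chrom, pos, alt, del_len), use.names = FALSE)
  }
  truth_keys <- if (nrow(truth) > 0)
    expand_keys(truth$chrom, truth$pos, truth$alt, truth$del_len) else character(0)
  call_keys <- if (nrow(mutations) > 0)
    expand_keys(mutations$chrom, mutations$pos, mutations$alt,
                mutations$del_len) else character(0)

  acc_key <- paste(accessibility$chrom, accessibility$pos)
  truth_acc <- if (nrow(truth) > 0) {
    m <- match(paste(truth$chrom, truth$pos), acc_key)
    !is.na(m) & accessibility$accessible[m]
  } else logical(0)

  found <- if (nrow(truth) > 0) {
    vapply(seq_len(nrow(truth)), function(i) {
      l <- if (is.na(truth$del_len[i])) 1L else truth$del_len[i]
      any(paste(truth$chrom[i], truth$pos[i]:(truth$pos[i] + l - 1L),
                truth$alt[i]) %in% call_keys)
    }, logical(1))
  } else logical(0)

  fp_flag <- if (nrow(mutations) > 0) {
    vapply(seq_len(nrow(mutations)), function(i) {
      l <- if (is.na(mutations$del_len[i])) 1L else mutations$del_len[i]
      !any(paste(mutations$chrom[i],
                 mutations$pos[i]:(mutations$pos[i] + l - 1L),
                 mutations$alt[i]) %in% truth_keys)
    }, logical(1))
  } else logical(0)

  n_truth_acc <- sum(truth_acc)
  fn <- sum(truth_acc & !found)
  freqs <- list(truth = numeric(0), error = numeric(0))
  if (!is.null(calls)) {
    tk <- paste(truth$chrom, truth$pos)
    ck <- paste(calls$chrom, calls$pos)
    at_truth <- ck %in% tk
    freqs$truth <- calls$frequency[at_truth]
    freqs$error <- calls$frequency[!at_truth & calls$frequency > 0]
  }
  list(n_truth = nrow(truth), n_truth_accessible = n_truth_acc,
       n_called = nrow(mutations),
       fn = fn,
       fn_rate = if (n_truth_acc > 0) fn / n_truth_acc else 0,
       fn_percent = if (n_truth_acc > 0) 100 * fn / n_truth_acc else 0,
       fp = sum(fp_flag),
       missed = truth[truth_acc & !found, , drop = FALSE],
       false_positives = mutations[fp_flag, , drop = FALSE],
       frequencies = freqs)
}

#' Write accepted mutations as a minimal VCF v4.2
#'
#' Substitutions are written as-is; deletion records use the conventional
#' left-anchored representation (POS is the base before the deleted run,
#' REF is anchor + deleted bases, ALT the anchor).
#'
#' @param mutations Accepted mutation records.
#' @param ref A `synthetic_reference` or DNAStringSet (for contig lengths
#'   and deletion anchors).
#' @param path Output path.
#' @param sample Sample column name.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(mutations, ref, path, sample = "focal") {
  seqs <- if (inherits(ref, "synthetic_reference")) ref$seq else ref
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
           "##INFO=<ID=ZYG,Number=1,Type=String,Description=\"Zygosity of the accepted mutation\">",
           "##INFO=<ID=GENOME,Number=1,Type=String,Description=\"Focal genome id\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", sample, sep = "\t"))
  rows <- character(0)
  if (nrow(mutations) > 0) {
    rows <- vapply(seq_len(nrow(mutations)), function(i) {
      m <- mutations[i, ]
      if (m$alt == "-") {
        anchor_pos <- m$pos - 1L
        chars <- strsplit(as.character(seqs[[m$chrom]]), "")[[1]]
        anchor <- chars[max(anchor_pos, 1L)]
        pos <- max(anchor_pos, 1L)
        reffield <- paste0(anchor, m$ref)
        altfield <- anchor
      } else {
        pos <- m$pos
        reffield <- m$ref
        altfield <- m$alt
      }
      gt <- if (m$zygosity == "hom") "1/1" else "0/1"
      paste(m$chrom, pos, ".", reffield, altfield, ".", "PASS",
            sprintf("ZYG=%s;GENOME=%s", m$zygosity, m$genome_id),
            "GT", gt, sep = "\t")
    }, character(1))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}
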