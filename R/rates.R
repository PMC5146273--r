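#' Normalize an accepted-mutation count to mutations per genome per generation
#'
#' Implements the accessibility-corrected normalization
#' \deqn{n = \frac{(G_{total} / G_{accessible}) \times m}{g}}
#' where \eqn{m} is the number of accepted mutations and \eqn{g} the number
#' of treated generations: mutations observed over the accessible fraction
#' of the genome are scaled up to the full genome, then divided by the
#' generations over which they accumulated.
#'
#' @param total_genome Total genome size in bp.
#' @param accessible Accessible-site count in bp (> 0, <= `total_genome`).
#' @param accepted Number of accepted mutations.
#' @param generations Number of treated generations (>= 1).
#' @return The normalized mutation count `n` (per haploid genome and
#'   generation), unrounded.
#' @examples
#' normalize_count(120e6, 90e6, 3, 1)   # 4
#' @export
normalize_count <- function(total_genome, accessible, accepted, generations) {
  stopifnot(accessible > 0, generations >= 1, accepted >= 0)
  if (any(accessible > total_genome))
    stop("accessible sites cannot exceed the total genome size")
  ((total_genome / accessible) * accepted) / generations
}

#' Per-site mutation rate
#'
#' @param n Normalized mutations per haploid genome per generation
#'   ([normalize_count()]).
#' @param genome_size Total genome size in bp.
#' @return Mutations per site per generation.
#' @examples
#' per_site_rate(2.6, 119e6)   # ~2.2e-8
#' @export
per_site_rate <- function(n, genome_size) {
  stopifnot(genome_size > 0)
  n / genome_size
}

#' Fold change between two normalized mutation counts
#'
#' @param a,b Normalized counts (numerator, denominator); `b` must be > 0.
#' @return The unrounded ratio `a / b`.  Use [format_fold()] for the
#'   reporting convention.
#' @examples
#' fold_change(20.3, 2.6)
#' @export
fold_change <- function(a, b) {
  if (any(b == 0)) stop("fold change undefined for a zero denominator")
  a / b
}

#' Display-round a fold change (or ratio)
#'
#' Reporting convention: round half-even to one decimal; values whose
#' rounded form is integral are shown as integers (so 33.0 prints as 33).
#' The unrounded value should always be carried alongside.
#'
#' @param x Numeric ratio(s).
#' @param digits Decimals to keep (default 1).
#' @return Numeric vector rounded at the display precision.
#' @examples
#' format_fold(fold_change(66, 2))     # 33
#' format_fold(fold_change(20.3, 2.6)) # 7.8
#' @export
format_fold <- function(x, digits = 1) {
  round(x, digits)
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided p-value by summation of hypergeometric probabilities no larger
#' than that of the observed table (the classic conditional exact test).
#' For mutation-rate contrasts the conventional table is
#' `rbind(c(mut_A, accessible_A - mut_A), c(mut_B, accessible_B - mut_B))`;
#' see [compare_groups()].
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` (conditional MLE) and `p_value`.  A table
#'   with an empty margin returns `p_value = 1` with a warning.
#' @examples
#' fisher_exact(rbind(c(0, 10), c(10, 0)))
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    warning("contingency table has an empty margin; p = 1")
    return(list(odds_ratio = NA_real_, p_value = 1))
  }
  ft <- stats::fisher.test(table)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Chi-square test with Yates continuity correction on a 2x2 table
#'
#' Statistic \eqn{\sum (\max(0, |O - E| - 0.5))^2 / E} with p-value from
#' the chi-square distribution with 1 degree of freedom (the form used for
#' methylated-versus-unmethylated cytosine contrasts).
#'
#' @param table 2x2 matrix of non-negative counts; both margins must be
#'   positive.
#' @return List with `statistic` and `p_value`.
#' @examples
#' chi_square_yates(rbind(c(10, 90), c(30, 70)))  # statistic 11.28
#' @export
chi_square_yates <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("chi-square undefined for a table with an empty margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Per-genome (or per-group) rate summary
#'
#' @param genome_id Identifier(s).
#' @param accepted Accepted mutation count(s).
#' @param accessible Accessible-site count(s) in bp.
#' @param total_genome Total genome size in bp.
#' @param generations Treated generations.
#' @return Data.frame with the normalized count `n` and the per-site rate.
#' @export
rate_summary <- function(genome_id, accepted, accessible, total_genome,
                         generations = 1) {
  n <- mapply(normalize_count, total_genome, accessible, accepted, generations)
  data.frame(genome_id = genome_id, accepted = accepted,
             accessible = accessible, total_genome = total_genome,
             generations = generations, n = n,
             per_site_rate = n / total_genome, stringsAsFactors = FALSE)
}

#' Compare two groups' mutation loads
#'
#' Pools each group's accepted mutations and accessible sites, reports the
#' fold change of the normalized counts, and tests the contrast
#' mutated-versus-non-mutated accessible sites with [fisher_exact()].
#' The contingency layout is a convention (the natural sites-by-mutations
#' contrast); p-values from it are indicative.
#'
#' @param summary_a,summary_b [rate_summary()] tables for the two groups.
#' @return List with `n_a`, `n_b`, `fold` (raw), `fold_display`,
#'   `fisher` (list from [fisher_exact()]) and the pooled `table`.
#' @export
compare_groups <- function(summary_a, summary_b) {
  pool <- function(s) {
    list(mut = sum(s$accepted), acc = sum(s$accessible),
         n = sum(s$n * s$generations) / sum(s$generations))
  }
  a <- pool(summary_a); b <- pool(summary_b)
  tab <- rbind(c(a$mut, a$acc - a$mut), c(b$mut, b$acc - b$mut))
  n_a <- mean(summary_a$n); n_b <- mean(summary_b$n)
  fold <- fold_change(n_a, n_b)
  list(n_a = n_a, n_b = n_b, fold = fold, fold_display = format_fold(fold),
       fisher = fisher_exact(tab), table = tab)
}
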