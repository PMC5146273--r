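#' Heterozygous:homozygous mutation ratio
#'
#' Computed on normalized per-haploid-genome counts (or raw counts if that
#' is what is supplied).  A zero homozygous count gives an infinite,
#' flagged ratio.
#'
#' @param het,hom Heterozygous and homozygous mutation counts (normalized
#'   or raw).
#' @return List with `ratio` and `infinite` flag.
#' @examples
#' het_hom_ratio(44.22, 5.44)
#' @export
het_hom_ratio <- function(het, hom) {
  stopifnot(het >= 0, hom >= 0)
  if (hom == 0) return(list(ratio = Inf, infinite = TRUE))
  list(ratio = het / hom, infinite = FALSE)
}

#' Expected het:hom ratio under pure pre-split mutagenesis
#'
#' A heterozygous mutation arising before the separation of male and
#' female cell lineages segregates 1:2:1 in a selfed progeny; among
#' mutation carriers 2/3 are heterozygous and 1/3 homozygous, so the
#' expected ratio is exactly 2.
#'
#' @return 2.
#' @export
expected_selfing_ratio <- function() 2

#' Estimate the post-split fraction from a het:hom ratio
#'
#' Among transmitted mutations, a fraction `q` arising after the split of
#' male and female cell lineages are all heterozygous, while pre-split
#' mutations are 2/3 het and 1/3 hom among carriers; the mixture gives
#' \eqn{R = (2 + q) / (1 - q)} and hence
#' \eqn{\hat q = (R - 2) / (R + 1)}, clipped to \[0, 1\].  Ratios below 2
#' are reported as 0 with a flag (no post-split signal).
#'
#' @param R A het:hom ratio (>= 0); `Inf` allowed.
#' @return List with `q_hat` and `below_expected` flag (`TRUE` when
#'   `R < 2`).
#' @examples
#' post_split_fraction(8.1)$q_hat   # ~0.67
#' @export
post_split_fraction <- function(R) {
  stopifnot(R >= 0)
  if (is.infinite(R)) return(list(q_hat = 1, below_expected = FALSE))
  q <- (R - 2) / (R + 1)
  list(q_hat = min(1, max(0, q)), below_expected = R < 2)
}

#' Timing summary for groups of genomes
#'
#' Tabulates het and hom counts per group, the het:hom ratio, the
#' estimated post-split fraction, and pairwise Fisher tests of the het/hom
#' contrast between groups.
#'
#' @param records Data.frame with a `zygosity` column (`het`/`hom`) and a
#'   grouping column.
#' @param group Name of the grouping column (default `"group"`).
#' @return List with `summary` (per-group table) and `pairwise`
#'   (group pairs with Fisher p-values).
#' @export
timing_summary <- function(records, group = "group") {
  stopifnot(group %in% names(records), "zygosity" %in% names(records))
  groups <- split(records, records[[group]])
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    het <- sum(groups[[g]]$zygosity == "het")
    hom <- sum(groups[[g]]$zygosity == "hom")
    r <- het_hom_ratio(het, hom)
    q <- post_split_fraction(r$ratio)
    data.frame(group = g, het = het, hom = hom, ratio = r$ratio,
               q_hat = q$q_hat, below_expected = q$below_expected,
               stringsAsFactors = FALSE)
  }))
  if (length(groups) < 2) {
    return(list(summary = summary,
                pairwise = data.frame(group_a = character(0),
                                      group_b = character(0),
                                      p_value = numeric(0))))
  }
  pairs <- t(utils::combn(names(groups), 2))
  pairwise <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    a <- summary[summary$group == pairs[i, 1], ]
    b <- summary[summary$group == pairs[i, 2], ]
    tab <- rbind(c(a$het, a$hom), c(b$het, b$hom))
    p <- if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      fisher_exact(tab)$p_value else NA_real_
    data.frame(group_a = pairs[i, 1], group_b = pairs[i, 2], p_value = p,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, pairwise = pairwise)
}

#' Reciprocal-cross parent-of-origin analysis
#'
#' For F1 genomes from reciprocal crosses of an irradiated and a control
#' parent: asserts that every recovered mutation is heterozygous (a
#' homozygous mutation flags the genome as a selfing contaminant),
#' attributes each genome's mutations from the irradiated parent to that
#' parent, and compares the two cross directions' per-genome counts with a
#' two-sample t-test.
#'
#' @param f1 Data.frame of F1 mutation records with columns `progeny_id`,
#'   `zygosity`, `parent_of_origin` (`mother`/`father`) and
#'   `irradiated_parent` (`mother`/`father`, the cross-direction label,
#'   constant per progeny).
#' @return List with `per_genome` (counts of irradiated-parent mutations
#'   per F1 genome plus selfing flags), `group_stats` (mean, sd and n per
#'   direction), `selfing_flagged` genome ids, and `t_test` (statistic and
#'   p-value; `NA` when either direction has < 2 genomes).
#' @export
cross_analysis <- function(f1) {
  req <- c("progeny_id", "zygosity", "parent_of_origin", "irradiated_parent")
  miss <- setdiff(req, names(f1))
  if (length(miss) > 0)
    stop("cross design columns missing: ", paste(miss, collapse = ", "))
  per <- lapply(split(f1, f1$progeny_id), function(g) {
    data.frame(progeny_id = g$progeny_id[1],
               irradiated_parent = g$irradiated_parent[1],
               n_mutations = sum(g$parent_of_origin == g$irradiated_parent[1]),
               n_total = nrow(g),
               selfing_flag = any(g$zygosity == "hom"),
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  clean <- per[!per$selfing_flag, , drop = FALSE]
  stats <- do.call(rbind, lapply(split(clean, clean$irradiated_parent),
                                 function(g) {
    data.frame(irradiated_parent = g$irradiated_parent[1],
               n_genomes = nrow(g), mean = mean(g$n_mutations),
               sd = stats::sd(g$n_mutations), stringsAsFactors = FALSE)
  }))
  rownames(stats) <- NULL
  tt <- list(statistic = NA_real_, p_value = NA_real_)
  a <- clean$n_mutations[clean$irradiated_parent == "mother"]
  b <- clean$n_mutations[clean$irradiated_parent == "father"]
  if (length(a) >= 2 && length(b) >= 2 && (sd(a) > 0 || sd(b) > 0)) {
    t <- stats::t.test(a, b)
    tt <- list(statistic = unname(t$statistic), p_value = t$p.value)
  }
  list(per_genome = per, group_stats = stats,
       selfing_flagged = per$progeny_id[per$selfing_flag], t_test = tt)
}
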