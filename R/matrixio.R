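#' Genome matrix construction and validation
#'
#' A genome matrix is the per-position pileup summary one genome is reduced
#' to: total read coverage plus counts of the six observable alleles A, C,
#' G, T, deletion and N.  Allele counts must sum to the total coverage at
#' every position.
#'
#' @param df Data.frame with columns `chrom`, `pos` (1-based), `cov`, `A`,
#'   `C`, `G`, `T`, `del`, `N` (and optionally a logical `masked`).
#' @return The validated data.frame with class `genome_matrix`.
#' @examples
#' gm <- genome_matrix(data.frame(chrom = "chr1", pos = 1, cov = 30,
#'                                A = 0, C = 29, G = 0, T = 1,
#'                                del = 0, N = 0))
#' @export
genome_matrix <- function(df) {
  req <- c("chrom", "pos", "cov", ALLELE_COLS)
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("genome matrix lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(df) > 0) {
    cnt <- as.matrix(df[, ALLELE_COLS])
    if (any(cnt < 0) || any(df$cov < 0))
      stop("genome matrix counts must be non-negative")
    bad <- which(rowSums(cnt) != df$cov)
    if (length(bad) > 0)
      stop(sprintf("allele counts do not sum to coverage at %s:%d (row %d)",
                   df$chrom[bad[1]], df$pos[bad[1]], bad[1]))
  }
  class(df) <- unique(c("genome_matrix", class(df)))
  df
}

#' Read / write a genome matrix TSV
#'
#' The on-disk dialect is a headered tab-separated table with columns
#' `chrom`, `pos`, `cov`, `A`, `C`, `G`, `T`, `del`, `N`, one row per
#' position, 1-based inclusive coordinates.  Reading validates the
#' count-sum invariant and reports the offending file line.
#'
#' @param path File path.
#' @return `read_matrix()` returns a [genome_matrix()]; an empty file gives
#'   an empty matrix with a warning.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) {
    warning("empty genome matrix file: ", path)
    df <- data.frame(chrom = character(0), pos = integer(0), cov = integer(0),
                     A = integer(0), C = integer(0), G = integer(0),
                     T = integer(0), del = integer(0), N = integer(0))
    return(genome_matrix(df))
  }
  df <- setDF(fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = "chrom")))
  req <- c("chrom", "pos", "cov", ALLELE_COLS)
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("malformed genome matrix (missing columns ",
         paste(miss, collapse = ", "), "): ", path)
  cnt <- as.matrix(df[, ALLELE_COLS])
  bad <- which(rowSums(cnt) != df$cov)
  if (length(bad) > 0)
    stop(sprintf(
      "count-sum mismatch at %s:%d (file line %d): counts sum %d, coverage %d",
      df$chrom[bad[1]], df$pos[bad[1]], bad[1] + 1L,
      sum(cnt[bad[1], ]), df$cov[bad[1]]))
  genome_matrix(df)
}

#' @rdname read_matrix
#' @param mat A [genome_matrix()].
#' @export
write_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "genome_matrix"))
  cols <- c("chrom", "pos", "cov", ALLELE_COLS)
  fwrite(as.data.frame(mat)[, cols], path, sep = "\t")
  invisible(path)
}

as_mask_granges <- function(mask) {
  if (is.character(mask)) mask <- rtracklayer::import(mask, format = "bed")
  if (!is(mask, "GRanges")) stop("mask must be a GRanges or a BED file path")
  reduce(mask)
}

#' Flag masked positions of a genome matrix
#'
#' Positions falling in any mask interval (low-complexity / tandem-repeat
#' stand-in) are flagged; they are excluded from mutation calling and from
#' accessible-site counts.  Masking is idempotent: re-applying a mask (or an
#' empty mask) never unflags a position.
#'
#' @param mat A [genome_matrix()].
#' @param mask A GRanges of masked intervals, or a path to a BED file
#'   (0-based half-open on disk; imported as 1-based inclusive).
#' @param seqlengths Optional named chromosome lengths used to reject
#'   intervals running past a chromosome end.
#' @return The matrix with a logical `masked` column.
#' @export
apply_mask <- function(mat, mask, seqlengths = NULL) {
  stopifnot(inherits(mat, "genome_matrix"))
  gr <- as_mask_granges(mask)
  if (is.null(mat$masked)) mat$masked <- FALSE
  if (length(gr) == 0) return(mat)
  if (!is.null(seqlengths)) {
    cm <- as.character(GenomeInfoDb::seqnames(gr))
    over <- !is.na(seqlengths[cm]) & end(gr) > seqlengths[cm]
    if (any(over))
      stop("mask interval beyond chromosome end: ",
           cm[which(over)[1]], ":", end(gr)[which(over)[1]])
  }
  for (cm in unique(as.character(GenomeInfoDb::seqnames(gr)))) {
    rows <- which(mat$chrom == cm)
    if (length(rows) == 0) next
    if (is.null(seqlengths) && max(end(gr[GenomeInfoDb::seqnames(gr) == cm])) >
        max(mat$pos[rows]))
      stop("mask interval beyond chromosome end on ", cm)
    hit <- IRanges::overlapsAny(IRanges(mat$pos[rows], width = 1L),
                                ranges(gr[GenomeInfoDb::seqnames(gr) == cm]))
    mat$masked[rows] <- mat$masked[rows] | hit
  }
  mat
}

#' Positional accessibility of a focal genome
#'
#' A position is accessible -- i.e. enters the denominator of mutation-rate
#' normalization -- when it is unmasked, covered by at least `min_coverage`
#' reads, and not classified `undefined` in the focal genome.  Accessibility
#' is a property of the focal genome only; background-cohort criteria affect
#' mutation acceptance, not the denominator.
#'
#' @param mat A [genome_matrix()] (after [apply_mask()] if a mask exists).
#' @param calls Optional classification table from [classify_matrix()] for
#'   the same rows (needed to flag `undefined` positions).
#' @param min_coverage Minimum read depth (default 20; positions covered by
#'   fewer than 20 reads are low-coverage).
#' @return A list with `track` (chrom, pos, accessible, reason) and
#'   `n_accessible`.
#' @examples
#' gm <- genome_matrix(data.frame(chrom = "chr1", pos = 1:2, cov = c(19, 20),
#'                                A = c(19, 20), C = 0, G = 0, T = 0,
#'                                del = 0, N = 0))
#' accessibility(gm)$track
#' @export
accessibility <- function(mat, calls = NULL, min_coverage = 20) {
  stopifnot(inherits(mat, "genome_matrix"))
  masked <- if (is.null(mat$masked)) rep(FALSE, nrow(mat)) else mat$masked
  low <- mat$cov < min_coverage
  undef <- if (is.null(calls)) rep(FALSE, nrow(mat)) else
    calls$classification == "undefined"
  accessible <- !masked & !low & !undef
  reason <- rep(NA_character_, nrow(mat))
  reason[undef] <- "undefined"
  reason[low] <- "low-coverage"
  reason[masked] <- "masked"
  list(track = data.frame(chrom = mat$chrom, pos = mat$pos,
                          accessible = accessible, reason = reason,
                          stringsAsFactors = FALSE),
       n_accessible = sum(accessible))
}
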