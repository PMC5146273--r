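#' Generate a synthetic annotated reference genome
#'
#' Builds a small diploid reference emulating the structure the caller
#' assumes: a base composition matching the motif background (A = T = 0.3,
#' C = G = 0.2), a gene / transposable-element / intergenic partition hitting
#' the configured proportions, CDS models (multiple-of-3 length, random
#' strand) inside genes, one deliberate gene-TE overlap so the TE-precedence
#' fraction rule is exercised, a low-complexity stand-in mask, and a
#' context-stratified cytosine methylome on both strands.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical config + seed gives a byte-identical
#'   reference.
#' @return An object of class `synthetic_reference`: a list with elements
#'   `seq` ([Biostrings::DNAStringSet]), `chars` (per-chromosome character
#'   vectors), `annotation` (GRanges with `type` in gene / CDS /
#'   transposable_element), `mask` (GRanges), `methylome` (data.frame with
#'   chrom, pos, strand, context, methylated), `config` and `seed`.
#' @examples
#' ref <- generate_reference(sim_config(genome_size = 2e4), seed = 1)
#' ref
#' @export
generate_reference <- function(config, seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  if (config$genome_size < 1e4)
    stop("genome too small to place the requested annotation (need >= 10 kb)")
  with_seed(seed, {
    lens <- rep(floor(config$genome_size / config$n_chrom), config$n_chrom)
    lens[config$n_chrom] <- config$genome_size - sum(lens[-config$n_chrom])
    chroms <- paste0("chr", seq_len(config$n_chrom))
    names(lens) <- chroms

    chars <- list()
    ann <- list()
    mask <- list()
    meth <- list()
    for (i in seq_along(chroms)) {
      cm <- chroms[i]
      L <- lens[i]
      b <- sample(DNA_BASES4, L, replace = TRUE, prob = c(0.3, 0.2, 0.2, 0.3))
      chars[[cm]] <- b
      ann[[cm]] <- place_annotation(cm, L, config)
      mask[[cm]] <- place_mask(cm, L, config)
      meth[[cm]] <- build_methylome(cm, b, config)
    }
    seqs <- DNAStringSet(vapply(chars, paste, character(1), collapse = ""))
    names(seqs) <- chroms
    annotation <- do.call(c, unname(ann))
    mask_gr <- do.call(c, unname(mask))
    GenomeInfoDb::seqlevels(annotation) <- chroms
    GenomeInfoDb::seqlengths(annotation) <- lens
    GenomeInfoDb::seqlevels(mask_gr) <- chroms
    GenomeInfoDb::seqlengths(mask_gr) <- lens
    methylome <- do.call(rbind, unname(meth))
    rownames(methylome) <- NULL
    structure(list(seq = seqs, chars = chars, annotation = annotation,
                   mask = mask_gr, methylome = methylome,
                   config = config, seed = seed),
              class = "synthetic_reference")
  })
}

# Slot-based placement: the chromosome is divided into 500 bp slots whose
# labels are a random permutation with exact per-label counts, so measured
# proportions land within rounding error of the targets.  Adjacent
# equal-label slots merge into larger elements (gene/TE length variation).
place_annotation <- function(chrom, L, config) {
  slot <- 500L
  n_slots <- L %/% slot
  n_gene <- round(config$p_gene * n_slots)
  n_te <- round(config$p_te * n_slots)
  labels <- sample(rep(c("gene", "TE", "IG"),
                       times = c(n_gene, n_te, n_slots - n_gene - n_te)))
  r <- rle(labels)
  ends_slot <- cumsum(r$lengths)
  starts_slot <- ends_slot - r$lengths + 1L
  keep <- r$values != "IG"
  if (!any(keep)) {
    return(GRanges(seqnames = character(0), ranges = IRanges(),
                   type = character(0), ID = character(0),
                   Parent = character(0), phase = integer(0)))
  }
  starts <- (starts_slot[keep] - 1L) * slot + 1L
  ends <- ends_slot[keep] * slot
  types <- ifelse(r$values[keep] == "gene", "gene", "transposable_element")

  gr <- GRanges(chrom, IRanges(starts, ends), type = types)
  genes <- gr[gr$type == "gene"]
  tes <- gr[gr$type == "transposable_element"]
  if (length(tes) > 0) strand(tes) <- sample(c("+", "-"), length(tes), TRUE)

  # Guarantee one gene-TE overlap so fraction precedence is testable.
  if (config$p_te > 0 && length(genes) > 0) {
    g1 <- genes[1]
    ov_start <- max(1L, end(g1) - 199L)
    ov_end <- min(L, end(g1) + 200L)
    ov <- GRanges(chrom, IRanges(ov_start, ov_end), type = "transposable_element")
    strand(ov) <- "+"
    tes <- c(tes, ov)
  }

  cds <- GRanges(seqnames = character(0), ranges = IRanges())
  if (length(genes) > 0) {
    strand(genes) <- sample(c("+", "-"), length(genes), TRUE)
    genes$ID <- sprintf("%s_gene%03d", chrom, seq_along(genes))
    w <- width(genes)
    cds_len <- 3L * ((w - 100L) %/% 3L)
    ok <- cds_len >= 90L
    if (any(ok)) {
      cds <- GRanges(chrom,
                     IRanges(start(genes)[ok] + 50L,
                             width = cds_len[ok]),
                     strand = strand(genes)[ok],
                     type = "CDS",
                     ID = sprintf("%s.cds", genes$ID[ok]),
                     Parent = genes$ID[ok],
                     phase = 0L)
    }
  }
  fill <- function(g) {
    if (is.null(g$ID)) g$ID <- sprintf("%s_feat%03d", chrom, seq_along(g))
    if (is.null(g$Parent)) g$Parent <- rep(NA_character_, length(g))
    if (is.null(g$phase)) g$phase <- rep(NA_integer_, length(g))
    g
  }
  out <- c(fill(genes), fill(tes), fill(cds))
  sort(out, ignore.strand = TRUE)
}

place_mask <- function(chrom, L, config) {
  n_int <- round(config$mask_fraction * L / 500)
  if (n_int < 1) {
    return(GRanges(seqnames = character(0), ranges = IRanges()))
  }
  starts <- sample.int(L - 499L, n_int, replace = TRUE)
  reduce(GRanges(chrom, IRanges(starts, width = 500L)))
}

# Cytosines on both strands with their CG/CHG/CHH context (determined from
# the two downstream bases on the cytosine's own strand) and a Bernoulli
# methylation state at the configured per-context rate.  Cytosines within
# 2 bp of a chromosome end have no resolvable context and are omitted.
build_methylome <- function(chrom, b, config) {
  L <- length(b)
  fwd <- which(b == "C" & seq_along(b) <= L - 2L)
  rev <- which(b == "G" & seq_along(b) >= 3L)
  ctx_from <- function(n1, n2) {
    ifelse(n1 == "G", "CG", ifelse(n2 == "G", "CHG", "CHH"))
  }
  ctx_f <- ctx_from(b[fwd + 1L], b[fwd + 2L])
  ctx_r <- ctx_from(comp_base(b[rev - 1L]), comp_base(b[rev - 2L]))
  df <- data.frame(chrom = chrom,
                   pos = c(fwd, rev),
                   strand = rep(c("+", "-"), c(length(fwd), length(rev))),
                   context = c(ctx_f, ctx_r),
                   stringsAsFactors = FALSE)
  df <- df[order(df$pos, df$strand), , drop = FALSE]
  df$methylated <- runif(nrow(df)) < unname(config$meth_rates[df$context])
  df
}

#' @export
print.synthetic_reference <- function(x, ...) {
  lens <- Biostrings::width(x$seq)
  cat("synthetic_reference:", length(x$seq), "chromosome(s),",
      format(sum(lens), big.mark = ","), "bp\n")
  tab <- table(x$annotation$type)
  cat("  features:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat("  masked bp:", sum(width(x$mask)), "\n")
  cat("  methylome:", nrow(x$methylome), "cytosines,",
      round(100 * mean(x$methylome$methylated), 1), "% methylated\n")
  invisible(x)
}

#' Reference base(s) at given positions
#'
#' @param ref A `synthetic_reference`.
#' @param chrom,pos Parallel vectors of chromosome names and 1-based
#'   positions.
#' @return Character vector of bases.
#' @export
ref_base <- function(ref, chrom, pos) {
  stopifnot(inherits(ref, "synthetic_reference"))
  out <- character(length(pos))
  for (cm in unique(chrom)) {
    i <- chrom == cm
    out[i] <- ref$chars[[cm]][pos[i]]
  }
  out
}

#' Write a synthetic reference to standard formats
#'
#' Writes the sequence as FASTA, the annotation as GFF3, the mask as 0-based
#' half-open BED, and the methylome as a headered TSV.
#'
#' @param ref A `synthetic_reference`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "synthetic_reference"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(fasta = file.path(dir, "reference.fa"),
             gff = file.path(dir, "annotation.gff3"),
             bed = file.path(dir, "mask.bed"),
             methylome = file.path(dir, "methylome.tsv"))
  writeXStringSet(ref$seq, paths[["fasta"]])
  rtracklayer::export(ref$annotation, paths[["gff"]], format = "gff3")
  rtracklayer::export(ref$mask, paths[["bed"]], format = "bed")
  fwrite(ref$methylome, paths[["methylome"]], sep = "\t")
  invisible(paths)
}
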