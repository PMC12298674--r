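# Transcript and gene models.
#
# Exon coordinates are held internally as 0-based half-open intervals
# [start, end); GTF's 1-based inclusive convention is converted at I/O.
# This keeps all interval arithmetic (junctions, intron gaps, reflections)
# free of off-by-one corrections.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id Identifiers.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column numeric matrix of exon `(start, end)` in 0-based
#'   half-open coordinates, sorted ascending, pairwise disjoint.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, chrom, strand, exons) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  tx <- structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         chrom = chrom, strand = strand, exons = exons),
    class = "transcript_model")
  validate_transcript(tx)
  tx
}

validate_transcript <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 1) {
    stop("transcript ", tx$transcript_id, " has no exons", call. = FALSE)
  }
  if (any(ex[, 1] >= ex[, 2])) {
    stop("transcript ", tx$transcript_id, " has an empty or inverted exon",
         call. = FALSE)
  }
  if (nrow(ex) > 1) {
    if (is.unsorted(ex[, 1], strictly = TRUE) ||
        any(ex[-1, 1] < ex[-nrow(ex), 2])) {
      stop("transcript ", tx$transcript_id,
           " has unsorted or overlapping exons", call. = FALSE)
    }
  }
  if (!tx$strand %in% c("+", "-")) {
    stop("transcript ", tx$transcript_id, " has invalid strand", call. = FALSE)
  }
  invisible(tx)
}

#' Construct a gene model
#'
#' A gene groups one or more transcript models sharing chromosome and
#' strand. The subgenome label (`"A"`/`"B"`) is derived from the trailing
#' letter of the chromosome name (e.g. `chr01A`).
#'
#' @param gene_id Identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param transcripts List of [transcript_model()] objects.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, transcripts) {
  for (tx in transcripts) {
    if (tx$gene_id != gene_id || tx$chrom != chrom || tx$strand != strand) {
      stop("transcript ", tx$transcript_id,
           " does not match gene ", gene_id, call. = FALSE)
    }
  }
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         subgenome = subgenome_of(chrom), transcripts = transcripts),
    class = "gene_model")
}

#' Subgenome label of a chromosome
#'
#' @param chrom Chromosome name(s) ending in `A` or `B`.
#' @param strict Error on names without an `A`/`B` suffix (default); with
#'   `strict = FALSE` such names yield `NA`.
#' @return Character vector of `"A"`/`"B"` labels.
#' @export
subgenome_of <- function(chrom, strict = TRUE) {
  sg <- sub("^.*([AB])$", "\\1", chrom)
  bad <- !sg %in% c("A", "B") | nchar(chrom) < 2
  if (any(bad)) {
    if (strict) {
      stop("chromosome name(s) without A/B subgenome suffix: ",
           paste(unique(chrom[bad]), collapse = ", "), call. = FALSE)
    }
    sg[bad] <- NA_character_
  }
  sg
}

#' Read gene models from a GTF file
#'
#' Parses exon features (1-based inclusive, `gene_id`/`transcript_id`
#' attributes) and assembles transcript and gene models in the package's
#' internal 0-based half-open convention.
#'
#' @param path GTF file path.
#' @return Named list of [gene_model()] objects.
#' @export
read_gtf_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    gene_id = S4Vectors::mcols(gr)$gene_id,
    transcript_id = S4Vectors::mcols(gr)$transcript_id,
    stringsAsFactors = FALSE)
  genes <- list()
  for (gid in unique(df$gene_id)) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    txs <- lapply(unique(gdf$transcript_id), function(tid) {
      tdf <- gdf[gdf$transcript_id == tid, , drop = FALSE]
      tdf <- tdf[order(tdf$start), , drop = FALSE]
      transcript_model(tid, gid, tdf$chrom[1], tdf$strand[1],
                       cbind(tdf$start, tdf$end))
    })
    genes[[gid]] <- gene_model(gid, gdf$chrom[1], gdf$strand[1], txs)
  }
  genes
}

#' Write gene models to a GTF file
#'
#' Emits one `exon` feature per exon with `gene_id` and `transcript_id`
#' attributes, converting back to GTF's 1-based inclusive coordinates.
#' Output is deterministic for a fixed input.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf_models <- function(genes, path) {
  rows <- list()
  for (g in genes) {
    for (tx in g$transcripts) {
      ex <- tx$exons
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = g$chrom, start = ex[, 1] + 1, end = ex[, 2],
        strand = g$strand, gene_id = g$gene_id,
        transcript_id = tx$transcript_id, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$transcript_id <- df$transcript_id
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# Flat data.frame of transcript -> gene mapping for a gene-model list.
transcript_index <- function(genes) {
  do.call(rbind, lapply(genes, function(g) {
    data.frame(transcript_id = vapply(g$transcripts, `[[`, "",
                                      "transcript_id"),
               gene_id = g$gene_id, stringsAsFactors = FALSE)
  }))
}
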