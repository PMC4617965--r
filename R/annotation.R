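# Gene/transcript models built from GTF + FASTA.
#
# All internal coordinates are 0-based half-open; GTF input (1-based
# inclusive) is converted on read and back on write. Exons of a transcript
# are kept sorted and non-overlapping; the CDS is stored as its genomic span.

#' Construct a transcript model
#'
#' @param transcript_id,gene_id identifiers.
#' @param exons two-column matrix of 0-based half-open genomic intervals.
#' @param cds optional length-2 vector, genomic span of the coding sequence
#'   (0-based half-open), contained in the exon union projection.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, exons, cds = NULL,
                             strand = "+") {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  .assert(all(exons[, 2L] > exons[, 1L]), "empty exon in transcript %s",
          transcript_id)
  if (nrow(exons) > 1L)
    .assert(all(exons[-1L, 1L] >= exons[-nrow(exons), 2L]),
            "overlapping exons in transcript %s", transcript_id)
  .assert(strand %in% c("+", "-"), "bad strand for %s", transcript_id)
  if (!is.null(cds)) {
    cds <- as.integer(cds)
    .assert(cds[1L] >= exons[1L, 1L] && cds[2L] <= exons[nrow(exons), 2L],
            "CDS span outside exon projection in %s", transcript_id)
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 exons = exons, cds = cds, strand = strand),
            class = "transcript_model")
}

#' Construct a gene model from transcript models
#'
#' @param gene_id identifier.
#' @param chrom contig name.
#' @param transcripts list of [transcript_model()] objects, all on one strand.
#' @return an object of class `gene_model` with fields `locus` (genomic span),
#'   `is_spliced` (any transcript with >= 2 exons) and `is_coding`.
#' @export
gene_model <- function(gene_id, chrom, transcripts) {
  .assert(length(transcripts) >= 1L, "gene %s has no transcripts", gene_id)
  strands <- vapply(transcripts, `[[`, "", "strand")
  .assert(length(unique(strands)) == 1L, "mixed-strand gene %s", gene_id)
  ex <- do.call(rbind, lapply(transcripts, `[[`, "exons"))
  names(transcripts) <- vapply(transcripts, `[[`, "", "transcript_id")
  structure(list(
    gene_id = gene_id, chrom = chrom, strand = strands[[1L]],
    transcripts = transcripts,
    locus = c(min(ex[, 1L]), max(ex[, 2L])),
    is_spliced = any(vapply(transcripts, function(t) nrow(t$exons), 0L) >= 2L),
    is_coding = any(!vapply(transcripts, function(t) is.null(t$cds), TRUE))
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s) %d transcript(s)%s%s\n",
              x$gene_id, x$chrom, x$locus[1L], x$locus[2L], x$strand,
              length(x$transcripts),
              if (x$is_spliced) " spliced" else "",
              if (x$is_coding) " coding" else ""))
  invisible(x)
}

#' Load gene annotation and genome sequence
#'
#' Reads a GTF (exon and optionally CDS features, attributes `gene_id` and
#' `transcript_id`) plus a FASTA of the contigs and assembles one
#' [gene_model()] per gene. Genes whose transcripts disagree on strand are
#' rejected with a warning; a feature referencing a missing contig is a hard
#' error, as is a transcript carrying CDS but no exons.
#'
#' @param gtf_path path to GTF file (1-based inclusive coordinates).
#' @param fasta_path path to FASTA covering all annotated contigs.
#' @return list with `genes` (named list of `gene_model`) and `seqs`
#'   (a [Biostrings::DNAStringSet] genome accessor).
#' @export
load_annotation <- function(gtf_path, fasta_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end   = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = gr$transcript_id,
    stringsAsFactors = FALSE)
  df <- df[df$type %in% c("exon", "CDS"), , drop = FALSE]
  missing <- setdiff(unique(df$chrom), names(seqs))
  .assert(length(missing) == 0L,
          "GTF references contigs absent from FASTA: %s",
          paste(missing, collapse = ", "))
  genes <- list()
  for (gid in unique(df$gene_id)) {
    gdf <- df[df$gene_id == gid, , drop = FALSE]
    if (length(unique(gdf$strand)) != 1L) {
      warning(sprintf("gene %s has mixed strands; rejected", gid))
      next
    }
    txs <- lapply(split(gdf, gdf$transcript_id), function(t) {
      ex <- t[t$type == "exon", , drop = FALSE]
      cd <- t[t$type == "CDS", , drop = FALSE]
      .assert(nrow(ex) > 0L || nrow(cd) == 0L,
              "transcript %s has CDS but no exons", t$transcript_id[1L])
      transcript_model(t$transcript_id[1L], gid,
                       cbind(ex$start, ex$end),
                       cds = if (nrow(cd)) c(min(cd$start), max(cd$end)),
                       strand = t$strand[1L])
    })
    genes[[gid]] <- gene_model(gid, gdf$chrom[1L], txs)
  }
  list(genes = genes, seqs = seqs)
}

#' Write gene models to GTF
#'
#' Inverse of [load_annotation()]; 0-based half-open internal coordinates are
#' converted back to 1-based inclusive GTF lines.
#' @param genes named list of `gene_model`.
#' @param path output path.
#' @export
write_gtf <- function(genes, path) {
  lines <- character(0)
  for (g in genes) for (tx in g$transcripts) {
    attr_s <- sprintf('gene_id "%s"; transcript_id "%s";',
                      g$gene_id, tx$transcript_id)
    ex <- tx$exons
    lines <- c(lines, sprintf("%s\tripnet\texon\t%d\t%d\t.\t%s\t.\t%s",
                              g$chrom, ex[, 1L] + 1L, ex[, 2L], g$strand,
                              attr_s))
    if (!is.null(tx$cds)) {
      # CDS emitted per overlapping exon chunk
      for (i in seq_len(nrow(ex))) {
        s <- max(ex[i, 1L], tx$cds[1L]); e <- min(ex[i, 2L], tx$cds[2L])
        if (s < e)
          lines <- c(lines, sprintf("%s\tripnet\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                                    g$chrom, s + 1L, e, g$strand, attr_s))
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Mature (spliced) transcript sequence and its genomic coordinate map
#'
#' @return list with `seq` (character, 5'->3' sense sequence) and `gpos`
#'   (integer vector, genomic 0-based position of each transcript base; on
#'   the minus strand positions descend).
#' @keywords internal
.mature_seq <- function(tx, chrom, seqs) {
  ex <- tx$exons
  pieces <- character(nrow(ex))
  gpos <- integer(0)
  for (i in seq_len(nrow(ex))) {
    pieces[i] <- as.character(Biostrings::subseq(seqs[[chrom]],
                                                 ex[i, 1L] + 1L, ex[i, 2L]))
    gpos <- c(gpos, seq.int(ex[i, 1L], ex[i, 2L] - 1L))
  }
  s <- paste0(pieces, collapse = "")
  if (tx$strand == "-") {
    s <- .revcomp(s)
    gpos <- rev(gpos)
  }
  list(seq = toupper(s), gpos = gpos)
}

#' Locus RPKM and expressed-gene universe from control samples
#'
#' RPKM is reads per kilobase of locus span per million mapped reads in the
#' sample, averaged over control samples. A gene is called expressed when its
#' mean control RPKM reaches `threshold` (default 1).
#'
#' @param counts a [count_table()] containing control samples.
#' @param genes named list of `gene_model` (locus lengths).
#' @param threshold RPKM cutoff, default 1.
#' @return data.frame with `gene_id`, `rpkm_control`, `expressed`.
#' @export
expression_summary <- function(counts, genes, threshold = 1.0) {
  ctrl <- counts$sample_sheet$sample_id[counts$sample_sheet$is_control]
  .assert(length(ctrl) >= 1L, "no control samples in count table")
  m <- counts$counts[, ctrl, drop = FALSE]
  lib <- colSums(counts$counts[, ctrl, drop = FALSE])
  .assert(all(lib > 0), "control sample with zero total mapped reads")
  ids <- intersect(rownames(m), names(genes))
  len_kb <- vapply(genes[ids], function(g) diff(g$locus) / 1e3, 0)
  .assert(all(len_kb > 0), "gene with non-positive locus length")
  rpkm <- rowMeans(sweep(m[ids, , drop = FALSE], 2L, lib / 1e6, "/")) / len_kb
  data.frame(gene_id = ids, rpkm_control = unname(rpkm),
             expressed = unname(rpkm) >= threshold,
             stringsAsFactors = FALSE)
}
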