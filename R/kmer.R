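# Isoform-aware k-mer location index.
#
# For each gene, the union over its transcripts of transcript-internal k-mer
# windows, mapped back to genomic coordinates and deduplicated: a window
# lying fully within one exon is keyed by the genomic position of its first
# base; a junction-spanning window is keyed by its first base plus the full
# signature of the genomic positions it covers, so isoforms sharing a splice
# junction contribute a single location while distinct junction contexts at
# the same start are kept apart. Windows containing non-ACGT characters are
# dropped.

#' Build an isoform-aware k-mer location index
#'
#' @param genes named list of [gene_model()].
#' @param seqs genome [Biostrings::DNAStringSet].
#' @param k word size, default 7.
#' @return object of class `kmer_index`: per gene a data.frame of unique
#'   k-mer locations (`pos` = genomic 0-based start of the window's first
#'   base in transcript orientation, `kmer` = sense-strand sequence,
#'   `junction` = TRUE for junction-spanning windows), plus `k`.
#' @export
build_kmer_index <- function(genes, seqs, k = 7L) {
  .assert(k >= 1L, "k must be >= 1")
  k <- as.integer(k)
  per_gene <- lapply(genes, function(g) {
    keys <- character(0); pos <- integer(0); kmer <- character(0)
    junc <- logical(0)
    for (tx in g$transcripts) {
      m <- .mature_seq(tx, g$chrom, seqs)
      L <- nchar(m$seq)
      if (L < k) next
      starts <- seq_len(L - k + 1L)
      km <- substring(m$seq, starts, starts + k - 1L)
      valid <- !grepl("[^ACGT]", km)
      if (!any(valid)) next
      g0 <- m$gpos[starts]
      dir <- if (tx$strand == "+") 1L else -1L
      # contiguous iff the window's genomic span is an unbroken run
      gend <- m$gpos[starts + k - 1L]
      contiguous <- gend == g0 + dir * (k - 1L)
      key <- as.character(g0)
      if (any(!contiguous)) {
        jidx <- which(!contiguous)
        key[jidx] <- vapply(jidx, function(i)
          paste(m$gpos[i:(i + k - 1L)], collapse = ","), "")
      }
      keys <- c(keys, key[valid]); pos <- c(pos, g0[valid])
      kmer <- c(kmer, km[valid]); junc <- c(junc, !contiguous[valid])
    }
    if (length(keys) == 0L) {
      if (length(g$transcripts) > 0L)
        warning(sprintf("gene %s: no transcript long enough for k=%d",
                        g$gene_id, k))
      return(data.frame(pos = integer(0), kmer = character(0),
                        junction = logical(0), stringsAsFactors = FALSE))
    }
    keep <- !duplicated(keys)
    data.frame(pos = pos[keep], kmer = kmer[keep], junction = junc[keep],
               stringsAsFactors = FALSE)
  })
  structure(list(k = k, genes = per_gene), class = "kmer_index")
}

#' Distinct k-mer sequences present per gene
#' @param index a `kmer_index`.
#' @return named list of character vectors.
#' @export
kmer_sets <- function(index) {
  lapply(index$genes, function(df) unique(df$kmer))
}
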