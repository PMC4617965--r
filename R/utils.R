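# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
.assert <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

# floor for p-values before -log transforms
.P_FLOOR <- 1e-300

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Overlap of a draw of size `n_draw` with `n_white` successes in a universe
#' of size `n_total`.
#' @keywords internal
.hyper_upper <- function(k, n_white, n_total, n_draw) {
  stats::phyper(k - 1, n_white, n_total - n_white, n_draw, lower.tail = FALSE)
}

# reverse complement for plain character DNA (delegates to Biostrings)
.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract sense-strand sequence for a genomic interval
#'
#' Coordinates are 0-based half-open; minus-strand intervals are
#' reverse-complemented so the returned string reads 5' to 3' on the
#' transcribed strand.
#' @keywords internal
.get_seq <- function(seqs, chrom, start0, end0, strand = "+") {
  .assert(chrom %in% names(seqs), "contig '%s' absent from FASTA", chrom)
  s <- as.character(Biostrings::subseq(seqs[[chrom]], start0 + 1L, end0))
  if (strand == "-") s <- .revcomp(s) else s
}
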