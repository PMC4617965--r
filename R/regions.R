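# Collapse multi-isoform gene structure into unambiguous regions.
#
# A base of the locus is given a structure label (five_utr / cds / three_utr /
# intron) only when EVERY transcript covering that base assigns it the same
# label; any disagreement, coverage by a non-coding transcript's exon, or
# absence of coverage yields "ambiguous". This mirrors the usual
# "constitutive region" collapse used for region-level motif statistics.

REGION_LABELS <- c("five_utr", "cds", "three_utr", "intron", "ambiguous")

# per-base labels over the transcript's own genomic span (local coordinates,
# offset = span start); bases outside the span are NA (not covered)
.tx_labels <- function(tx, span) {
  n <- span[2L] - span[1L]
  lab <- rep(NA_integer_, n)            # index into REGION_LABELS
  ts <- tx$exons[1L, 1L]; te <- tx$exons[nrow(tx$exons), 2L]
  idx <- function(a, b) if (b > a) (a - span[1L] + 1L):(b - span[1L]) else integer(0)
  lab[idx(ts, te)] <- 4L                # intron by default within tx span
  coding <- !is.null(tx$cds)
  for (i in seq_len(nrow(tx$exons))) {
    a <- tx$exons[i, 1L]; b <- tx$exons[i, 2L]
    ii <- idx(a, b)
    if (!coding) { lab[ii] <- 5L; next }     # non-coding exon -> ambiguous
    gpos <- seq.int(a, b - 1L)
    l <- integer(length(gpos))
    before <- gpos < tx$cds[1L]; after <- gpos >= tx$cds[2L]
    inside <- !(before | after)
    if (tx$strand == "+") {
      l[before] <- 1L; l[after] <- 3L
    } else {
      l[before] <- 3L; l[after] <- 1L
    }
    l[inside] <- 2L
    lab[ii] <- l
  }
  lab
}

#' Collapse a gene's isoforms into an unambiguous region partition
#'
#' @param gene a [gene_model()].
#' @return object of class `region_partition`: data.frame `regions` with
#'   0-based half-open genomic `start`, `end` and `label`, plus named vector
#'   `lengths` of per-label base totals; regions tile the locus span exactly.
#' @export
collapse_regions <- function(gene) {
  span <- gene$locus
  n <- span[2L] - span[1L]
  cover <- integer(n)
  agree <- rep(NA_integer_, n)   # candidate consensus label
  ok <- rep(TRUE, n)             # still unanimous
  for (tx in gene$transcripts) {
    lab <- .tx_labels(tx, span)
    cov <- !is.na(lab)
    newly <- cov & cover == 0L
    agree[newly] <- lab[newly]
    disagree <- cov & cover > 0L & (agree != lab)
    ok[disagree] <- FALSE
    cover <- cover + cov
  }
  final <- rep(5L, n)  # ambiguous
  keep <- cover > 0L & ok & !is.na(agree)
  final[keep] <- agree[keep]
  r <- rle(final)
  ends <- cumsum(r$lengths)
  regions <- data.frame(
    start = span[1L] + c(0L, ends[-length(ends)]),
    end = span[1L] + ends,
    label = REGION_LABELS[r$values],
    stringsAsFactors = FALSE)
  lens <- vapply(REGION_LABELS, function(l)
    sum(regions$end[regions$label == l] - regions$start[regions$label == l]),
    0L)
  structure(list(gene_id = gene$gene_id, chrom = gene$chrom,
                 strand = gene$strand, regions = regions, lengths = lens),
            class = "region_partition")
}

#' Look up the region label at genomic positions
#' @param part a `region_partition`.
#' @param pos integer vector of 0-based genomic positions.
#' @return character vector of labels (`NA` outside the locus).
#' @export
region_label_at <- function(part, pos) {
  i <- findInterval(pos, part$regions$start)
  lab <- rep(NA_character_, length(pos))
  valid <- i >= 1L & pos < part$regions$end[pmax(i, 1L)]
  lab[valid] <- part$regions$label[i[valid]]
  lab
}

#' Write region partitions as BED6
#'
#' name = region label, score = region length, strand from the gene.
#' @param partitions list of `region_partition`.
#' @param path output path.
#' @export
write_regions_bed <- function(partitions, path) {
  rows <- lapply(partitions, function(p)
    sprintf("%s\t%d\t%d\t%s\t%d\t%s", p$chrom, p$regions$start, p$regions$end,
            p$regions$label, p$regions$end - p$regions$start, p$strand))
  writeLines(unlist(rows), path)
  invisible(path)
}
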