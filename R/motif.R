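# Isoform-aware k-mer motif discovery and gene-region enrichment.
#
# Per-bait 7-mer enrichment is a gene-presence hypergeometric: how many
# target genes contain the k-mer (at any unique location) versus nontarget
# expressed genes. The most enriched k-mers are summarized into one position
# weight matrix by weighted seed alignment, the transcriptome is scanned
# with the top-quantile k-mers under that PWM, and per-locus region
# preferences are scored with binomial z-scores against region length
# fractions.

#' Hypergeometric k-mer enrichment in target genes
#'
#' A gene counts once per k-mer however many locations it carries. The
#' universe is targets plus background (nontarget expressed genes).
#'
#' @param index a [build_kmer_index()] result.
#' @param targets,background disjoint character vectors of gene ids present
#'   in the index.
#' @return data.frame sorted by p-value: `kmer`, `n_target`, `n_background`,
#'   `p_value`, `weight` (-log10 p).
#' @export
kmer_enrichment <- function(index, targets, background) {
  .assert(length(targets) > 0L, "empty target set")
  .assert(length(intersect(targets, background)) == 0L,
          "targets and background overlap")
  sets <- kmer_sets(index)
  .assert(all(c(targets, background) %in% names(sets)),
          "gene ids missing from k-mer index")
  tgt_tab <- table(unlist(sets[targets], use.names = FALSE))
  bg_tab <- table(unlist(sets[background], use.names = FALSE))
  kmers <- union(names(tgt_tab), names(bg_tab))
  nt <- as.integer(tgt_tab[kmers]); nt[is.na(nt)] <- 0L
  nb <- as.integer(bg_tab[kmers]); nb[is.na(nb)] <- 0L
  NT <- length(targets); NB <- length(background)
  p <- stats::phyper(nt - 1, NT, NB, nt + nb, lower.tail = FALSE)
  out <- data.frame(kmer = kmers, n_target = nt, n_background = nb,
                    p_value = p,
                    weight = -log10(pmax(p, .P_FLOOR)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.BASES <- c("A", "C", "G", "U")

# candidate shifts tried in deterministic preference order
.SHIFT_ORDER <- c(0L, -1L, 1L, -2L, 2L)

#' Build a weighted position weight matrix from enriched k-mers
#'
#' The most enriched k-mer seeds the alignment; every other k-mer is placed
#' at the shift (within +/-2, no reverse complement) maximizing the number
#' of matching bases (ties resolved toward smaller shifts). Aligned k-mers
#' contribute their enrichment weights (-log10 p) to a position frequency
#' matrix over the seed's columns; a pseudocount of 0.25 per cell is added
#' before column normalization.
#'
#' @param kstats data.frame from [kmer_enrichment()] (sorted by p-value) or
#'   any data.frame with `kmer` and `weight`.
#' @param n_top number of k-mers used, default 50 (only rows with positive
#'   weight are kept).
#' @param pseudocount per-cell pseudocount, default 0.25.
#' @return object of class `pwm`: 4 x L column-stochastic matrix (rows
#'   A,C,G,U), the source k-mers/weights/shifts, and the pseudocount.
#' @export
build_pwm <- function(kstats, n_top = 50L, pseudocount = 0.25) {
  .assert(n_top >= 1L, "n_top must be >= 1")
  ks <- kstats[kstats$weight > 0, , drop = FALSE]
  if (nrow(ks) == 0L) {
    warning("all k-mer weights zero; returning uniform PWM")
    L <- nchar(kstats$kmer[1L])
    m <- matrix(0.25, 4L, L, dimnames = list(.BASES, NULL))
    return(structure(list(matrix = m, kmers = character(0),
                          weights = numeric(0), shifts = integer(0),
                          pseudocount = pseudocount), class = "pwm"))
  }
  ks <- ks[seq_len(min(n_top, nrow(ks))), , drop = FALSE]
  kmers <- chartr("T", "U", toupper(ks$kmer))
  L <- nchar(kmers[1L])
  .assert(all(nchar(kmers) == L), "k-mers of unequal length")
  seed <- strsplit(kmers[1L], "")[[1L]]
  counts <- matrix(0, 4L, L, dimnames = list(.BASES, NULL))
  shifts <- integer(length(kmers))
  for (i in seq_along(kmers)) {
    km <- strsplit(kmers[i], "")[[1L]]
    best <- 0L; best_match <- -1L
    for (s in .SHIFT_ORDER) {
      # km position j aligns to seed column j + s
      cols <- seq_len(L) + s
      ok <- cols >= 1L & cols <= L
      nm <- sum(km[ok] == seed[cols[ok]])
      if (nm > best_match) { best_match <- nm; best <- s }
    }
    shifts[i] <- best
    cols <- seq_len(L) + best
    ok <- cols >= 1L & cols <= L
    idx <- cbind(match(km[ok], .BASES), cols[ok])
    counts[idx] <- counts[idx] + ks$weight[i]
  }
  counts <- counts + pseudocount
  m <- sweep(counts, 2L, colSums(counts), "/")
  structure(list(matrix = m, kmers = kmers, weights = ks$weight,
                 shifts = shifts, pseudocount = pseudocount),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(.BASES[apply(x$matrix, 2L, which.max)], collapse = "")
  cat(sprintf("<pwm> width %d, consensus %s, %d source k-mers\n",
              ncol(x$matrix), cons, length(x$kmers)))
  invisible(x)
}

#' Select the top-quantile k-mers under a PWM
#'
#' Every k-mer of the PWM's width is scored by log-likelihood; the top
#' `ceiling(q * 4^L)` are returned, ties broken lexicographically.
#'
#' @param pwm a `pwm`.
#' @param q quantile in (0,1); default 0.01 (a stricter 0.001 variant is a
#'   plain argument change).
#' @return character vector of k-mers (ACGU alphabet), best first.
#' @export
score_and_select <- function(pwm, q = 0.01) {
  .assert(q > 0 && q < 1, "quantile outside (0,1)")
  L <- ncol(pwm$matrix)
  grid <- expand.grid(rep(list(1:4), L))[, L:1, drop = FALSE]  # lexicographic
  score <- numeric(nrow(grid))
  lp <- log(pwm$matrix)
  for (j in seq_len(L)) score <- score + lp[cbind(grid[[j]], j)]
  kmers <- do.call(paste0, lapply(seq_len(L), function(j) .BASES[grid[[j]]]))
  n_sel <- ceiling(q * 4^L)
  o <- order(-score, kmers)
  kmers[o[seq_len(n_sel)]]
}

#' Scan the transcriptome with a top-quantile k-mer set
#'
#' Every unique indexed k-mer location whose sequence belongs to the top set
#' becomes a motif hit, labeled with the collapsed region of its first
#' (5'-most) base. Hits in ambiguous regions are retained but excluded from
#' region statistics.
#'
#' @param index a `kmer_index`.
#' @param top_kmers character vector from [score_and_select()] (ACGU or
#'   ACGT).
#' @param partitions named list of `region_partition` covering the genes.
#' @return data.frame of hits: `gene_id`, `pos`, `kmer`, `region`.
#' @export
scan_transcriptome <- function(index, top_kmers, partitions) {
  top_dna <- chartr("U", "T", toupper(top_kmers))
  rows <- lapply(names(index$genes), function(gid) {
    df <- index$genes[[gid]]
    hit <- df[df$kmer %in% top_dna, , drop = FALSE]
    if (nrow(hit) == 0L) return(NULL)
    part <- partitions[[gid]]
    region <- if (is.null(part)) rep(NA_character_, nrow(hit))
    else region_label_at(part, hit$pos)
    data.frame(gene_id = gid, pos = hit$pos, kmer = hit$kmer,
               region = region, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L)
    return(data.frame(gene_id = character(0), pos = integer(0),
                      kmer = character(0), region = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-locus gene-region motif enrichment z-scores
#'
#' For each gene with at least `min_hits` non-ambiguous motif hits, each
#' structure region is scored by the binomial test of the fraction of hits
#' falling in the region against the region's share of the locus's
#' non-ambiguous sequence: `z = (x - n p0) / sqrt(n p0 (1 - p0))` with an
#' exact binomial upper-tail p-value.
#'
#' @param hits data.frame from [scan_transcriptome()].
#' @param partitions named list of `region_partition`.
#' @param min_hits locus inclusion threshold, default 20.
#' @return data.frame: `gene_id`, `region`, `hits_in_region`, `total_hits`,
#'   `length_fraction`, `z`, `p_value`.
#' @export
region_zscore <- function(hits, partitions, min_hits = 20L) {
  core <- c("five_utr", "cds", "three_utr", "intron")
  h <- hits[!is.na(hits$region) & hits$region %in% core, , drop = FALSE]
  out <- lapply(split(h, h$gene_id), function(gh) {
    n <- nrow(gh)
    if (n < min_hits) return(NULL)
    lens <- partitions[[gh$gene_id[1L]]]$lengths[core]
    tot_len <- sum(lens)
    res <- lapply(core, function(rg) {
      p0 <- lens[[rg]] / tot_len
      if (p0 <= 0 || p0 >= 1) return(NULL)   # degenerate region skipped
      x <- sum(gh$region == rg)
      data.frame(gene_id = gh$gene_id[1L], region = rg, hits_in_region = x,
                 total_hits = n, length_fraction = p0,
                 z = (x - n * p0) / sqrt(n * p0 * (1 - p0)),
                 p_value = stats::pbinom(x - 1, n, p0, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, res)
  })
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(gene_id = character(0), region = character(0),
                      hits_in_region = integer(0), total_hits = integer(0),
                      length_fraction = numeric(0), z = numeric(0),
                      p_value = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full per-bait motif discovery
#'
#' k-mer enrichment, PWM construction, top-quantile selection, transcriptome
#' scan and region z-scores in one call.
#'
#' @inheritParams kmer_enrichment
#' @inheritParams build_pwm
#' @inheritParams score_and_select
#' @inheritParams region_zscore
#' @param partitions named list of `region_partition`.
#' @return list: `kmer_stats`, `pwm`, `top_kmers`, `hits`,
#'   `region_enrichment`.
#' @export
discover_motif <- function(index, targets, background, partitions,
                           n_top = 50L, q = 0.01, min_hits = 20L) {
  ks <- kmer_enrichment(index, targets, background)
  pwm <- build_pwm(ks, n_top = n_top)
  top <- score_and_select(pwm, q = q)
  hits <- scan_transcriptome(index, top, partitions)
  list(kmer_stats = ks, pwm = pwm, top_kmers = top, hits = hits,
       region_enrichment = region_zscore(hits, partitions,
                                         min_hits = min_hits))
}

#' Write a PWM in MEME minimal text format
#' @param pwm a `pwm`.
#' @param path output path.
#' @param name motif name, default "motif1".
#' @export
write_meme <- function(pwm, path, name = "motif1") {
  m <- t(pwm$matrix)   # MEME rows = positions, columns = A C G U
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 U 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(m))), con)
  writeLines(apply(m, 1L, function(r) paste(sprintf("%.6f", r),
                                            collapse = " ")), con)
  invisible(path)
}
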