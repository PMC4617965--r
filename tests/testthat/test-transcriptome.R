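test_that("load_annotation assembles gene models and honors strand", {
  d <- withr::local_tempdir()
  fx <- fixture_annotation_files(d)
  ann <- load_annotation(fx$gtf, fx$fasta)
  expect_length(ann$genes, 3L)
  expect_true(ann$genes$gA$is_spliced)
  expect_false(ann$genes$gB$is_spliced)
  expect_true(ann$genes$gB$is_coding)
  expect_false(ann$genes$gC$is_coding)
  expect_equal(sum(vapply(ann$genes, function(g) length(g$transcripts), 0L)),
               3L)
  # minus-strand mature sequence is the reverse complement of the interval
  m <- ripnet:::.mature_seq(ann$genes$gB$transcripts[[1]], "chr2", ann$seqs)
  fwd <- as.character(Biostrings::subseq(fx$seqs[["chr2"]], 11, 210))
  expect_identical(m$seq,
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(fwd))))
  expect_equal(m$gpos[1], 209L)  # 5'-most base sits at the genomic right end
})

test_that("load_annotation rejects bad inputs", {
  d <- withr::local_tempdir()
  fx <- fixture_annotation_files(d)
  # contig missing from FASTA
  bad <- file.path(d, "bad.gtf")
  writeLines(paste0("chrX\tsrc\texon\t1\t50\t.\t+\t.\t",
                    'gene_id "gX"; transcript_id "gX.1";'), bad)
  expect_error(load_annotation(bad, fx$fasta), "absent from FASTA")
  # mixed-strand gene is rejected with a warning, others survive
  mixed <- file.path(d, "mixed.gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t1\t50\t.\t+\t.\t",
           'gene_id "gM"; transcript_id "gM.1";'),
    paste0("chr1\tsrc\texon\t60\t90\t.\t-\t.\t",
           'gene_id "gM"; transcript_id "gM.2";'),
    paste0("chr1\tsrc\texon\t100\t150\t.\t+\t.\t",
           'gene_id "gK"; transcript_id "gK.1";')), mixed)
  expect_warning(ann <- load_annotation(mixed, fx$fasta), "mixed strand")
  expect_named(ann$genes, "gK")
})

test_that("collapse_regions recovers the hand-laid single-transcript case", {
  part <- collapse_regions(fixture_gene_simple())
  expect_equal(unname(part$lengths[c("five_utr", "cds", "three_utr",
                                     "intron")]),
               c(50L, 150L, 50L, 50L))
  expect_equal(unname(part$lengths[["ambiguous"]]), 0L)
  # partition tiles the locus exactly
  expect_equal(sum(part$lengths), 300L)
  expect_equal(part$regions$start[1], 0L)
  expect_equal(part$regions$end[nrow(part$regions)], 300L)
})

test_that("collapse_regions marks disagreement ambiguous, respects order", {
  # tx1: CDS up to 250; tx2: CDS ends at 200, so [200,250) is tx2's 3'UTR
  tx1 <- transcript_model("t1", "g", rbind(c(0L, 300L)), cds = c(50L, 250L))
  tx2 <- transcript_model("t2", "g", rbind(c(0L, 300L)), cds = c(50L, 200L))
  p12 <- collapse_regions(gene_model("g", "chr1", list(tx1, tx2)))
  p21 <- collapse_regions(gene_model("g", "chr1", list(tx2, tx1)))
  expect_equal(unname(p12$lengths[["ambiguous"]]), 50L)
  expect_equal(unname(p12$lengths[["cds"]]), 150L)
  expect_equal(p12$lengths, p21$lengths)   # invariant to transcript order
  lab <- region_label_at(p12, c(60L, 220L, 260L))
  expect_equal(lab, c("cds", "ambiguous", "three_utr"))
})

test_that("non-coding exons collapse to ambiguous", {
  tx <- transcript_model("t", "g", rbind(c(0L, 80L), c(120L, 200L)))
  p <- collapse_regions(gene_model("g", "chr1", list(tx)))
  expect_equal(unname(p$lengths[["ambiguous"]]), 160L)
  expect_equal(unname(p$lengths[["intron"]]), 40L)
})

test_that("region partition lengths always tile the locus", {
  cfg <- simulation_config(seed = 11, n_genes = 25)
  tr <- simulate_transcriptome(cfg)
  for (g in tr$genes) {
    p <- tr$partitions[[g$gene_id]]
    expect_equal(sum(p$lengths), diff(g$locus))
    expect_true(all(diff(c(p$regions$start, p$regions$end[
      nrow(p$regions)])) > 0))
  }
})

test_that("k-mer index counts windows and deduplicates isoforms", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGTTA"))
  tx <- transcript_model("t1", "g", rbind(c(0L, 7L)))
  g1 <- gene_model("g", "chr1", list(tx))
  idx <- build_kmer_index(list(g = g1), seqs, k = 7)
  expect_equal(nrow(idx$genes$g), 1L)
  expect_equal(idx$genes$g$kmer, "ACGTACG")
  # transcript of length 10 -> L - k + 1 = 4 windows
  tx10 <- transcript_model("t1", "g", rbind(c(0L, 10L)))
  idx10 <- build_kmer_index(list(g = gene_model("g", "chr1", list(tx10))),
                            seqs, k = 7)
  expect_equal(nrow(idx10$genes$g), 4L)
  # identical transcripts collapse to a single location set
  two <- gene_model("g", "chr1",
                    list(transcript_model("t1", "g", rbind(c(0L, 10L))),
                         transcript_model("t2", "g", rbind(c(0L, 10L)))))
  expect_equal(build_kmer_index(list(g = two), seqs, k = 7)$genes$g,
               idx10$genes$g)
  # k longer than every transcript -> empty with warning
  expect_warning(e <- build_kmer_index(list(g = g1), seqs, k = 9),
                 "no transcript long enough")
  expect_equal(nrow(e$genes$g), 0L)
})

test_that("k-mers with N are dropped; junctions indexed once per context", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = "ACGTNCGTACGTACGTACGT"))
  tx <- transcript_model("t1", "g", rbind(c(0L, 20L)))
  idx <- build_kmer_index(list(g = gene_model("g", "chr1", list(tx))),
                          seqs, k = 7)
  expect_false(any(grepl("N", idx$genes$g$kmer)))
  # two isoforms sharing a splice junction contribute one junction window
  seqs2 <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 20),
                                                   collapse = "")))
  ex <- rbind(c(0L, 10L), c(30L, 40L))
  iso1 <- transcript_model("i1", "g", ex)
  iso2 <- transcript_model("i2", "g", rbind(ex, c(60L, 70L)))
  idx2 <- build_kmer_index(list(g = gene_model("g", "chr1",
                                               list(iso1, iso2))),
                           seqs2, k = 7)
  junc_at_10 <- idx2$genes$g[idx2$genes$g$junction &
                               idx2$genes$g$pos < 10, ]
  expect_equal(nrow(junc_at_10), 6L)  # positions 4..9 span the junction once
})

test_that("minus-strand index equals index of the sense sequence", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
  seqs <- Biostrings::DNAStringSet(c(chr1 = s))
  tx <- transcript_model("t1", "g", rbind(c(5L, 25L), c(35L, 55L)),
                         strand = "-")
  g <- gene_model("g", "chr1", list(tx))
  idx <- build_kmer_index(list(g = g), seqs, k = 7)
  sense <- ripnet:::.mature_seq(tx, "chr1", seqs)$seq
  expected <- substring(sense, 1:(nchar(sense) - 6), 7:nchar(sense))
  expect_equal(idx$genes$g$kmer, unname(expected))
})

test_that("expression_summary implements the RPKM unit definition", {
  # one gene of interest plus a filler that fixes the library size
  mk <- function(count, locus_len, lib) {
    tx <- transcript_model("t", "g", rbind(c(0L, as.integer(locus_len))))
    genes <- list(g = gene_model("g", "chr1", list(tx)))
    m <- matrix(c(count, lib - count, count, lib - count), nrow = 2,
                dimnames = list(c("g", "filler"), c("c1", "c2")))
    sheet <- data.frame(sample_id = c("c1", "c2"), bait = NA,
                        replicate = NA, is_control = TRUE)
    expression_summary(count_table(m, sheet), genes)
  }
  expect_equal(mk(1000, 1000, 1e6)$rpkm_control, 1000)
  expect_equal(mk(500, 2000, 1e7)$rpkm_control, 25)
  z <- mk(0, 1000, 1e6)
  expect_equal(z$rpkm_control, 0)
  expect_false(z$expressed)
  expect_true(mk(1000, 1000, 1e6)$expressed)
})
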