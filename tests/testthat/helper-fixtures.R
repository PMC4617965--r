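# Shared fixtures and independent oracles, built in code.

# -- tiny gene models ---------------------------------------------------------

# single-transcript coding gene: exons [0,100) [150,300), CDS span [50,250)
# => 5'UTR 50 / CDS 150 / 3'UTR 50 / intron 50 on the plus strand
fixture_gene_simple <- function(gene_id = "gA", strand = "+") {
  tx <- transcript_model(paste0(gene_id, ".1"), gene_id,
                         rbind(c(0L, 100L), c(150L, 300L)),
                         cds = c(50L, 250L), strand = strand)
  gene_model(gene_id, "chr1", list(tx))
}

# write a 3-gene GTF + FASTA pair; returns list(gtf=, fasta=, seqs=)
fixture_annotation_files <- function(dir) {
  set.seed(42)
  seqs <- Biostrings::DNAStringSet(c(
    chr1 = paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = ""),
    chr2 = paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")))
  g1 <- fixture_gene_simple("gA")
  tx2 <- transcript_model("gB.1", "gB", rbind(c(10L, 210L)),
                          cds = c(40L, 160L), strand = "-")
  g2 <- gene_model("gB", "chr2", list(tx2))
  tx3 <- transcript_model("gC.1", "gC", rbind(c(220L, 380L)), strand = "+")
  g3 <- gene_model("gC", "chr2", list(tx3))
  gtf <- file.path(dir, "ann.gtf"); fa <- file.path(dir, "ann.fa")
  write_gtf(list(gA = g1, gB = g2, gC = g3), gtf)
  Biostrings::writeXStringSet(seqs, fa)
  list(gtf = gtf, fasta = fa, seqs = seqs,
       genes = list(gA = g1, gB = g2, gC = g3))
}

# -- independent oracles ------------------------------------------------------

# NB pmf from first principles (lgamma), no dnbinom
oracle_nb_pmf <- function(k, mu, size) {
  exp(lgamma(k + size) - lgamma(size) - lgamma(k + 1) +
        size * (log(size) - log(size + mu)) +
        k * (log(mu) - log(size + mu)))
}

# conditional two-sided exact NB test by explicit enumeration
oracle_nb_test <- function(k_ip, k_ctrl, s_ip, s_ctrl, alpha) {
  ks <- k_ip + sum(k_ctrl)
  sA <- s_ip; sB <- sum(s_ctrl)
  q <- ks / (sA + sB)
  muA <- sA * q; muB <- sB * q
  sizeA <- 1 / alpha
  sizeB <- sum(s_ctrl)^2 / (alpha * sum(s_ctrl^2))
  probs <- numeric(ks + 1)
  for (a in 0:ks)
    probs[a + 1] <- oracle_nb_pmf(a, muA, sizeA) *
      oracle_nb_pmf(ks - a, muB, sizeB)
  pobs <- probs[k_ip + 1]
  sum(probs[probs <= pobs * (1 + 1e-7)]) / sum(probs)
}

# Poisson-binomial by exhaustive enumeration over all 2^n outcomes:
# per-outcome probabilities and success counts, computed once per p
oracle_poisbin_dist <- function(p) {
  n <- length(p)
  bits <- vapply(0:(2^n - 1), function(m)
    as.integer(intToBits(m))[seq_len(n)], integer(n))
  probs <- apply(bits, 2, function(b) prod(ifelse(b == 1, p, 1 - p)))
  list(counts = colSums(bits), probs = probs)
}

oracle_poisbin_tail <- function(p, t, dist = oracle_poisbin_dist(p)) {
  sum(dist$probs[dist$counts >= t])
}

# hypergeometric upper tail by enumerating all draws (small universes)
oracle_hyper_upper <- function(k, ref, universe, query_size) {
  draws <- utils::combn(universe, query_size)
  hits <- apply(draws, 2, function(d) length(intersect(d, ref)))
  mean(hits >= k)
}

# simulate the IDR latent copula mixture directly
sim_idr_mixture <- function(seed, n = 3000, pi1 = 0.65, mu = 2.5,
                            sigma = 1, rho = 0.84) {
  set.seed(seed)
  z <- stats::rbinom(n, 1, pi1)
  x <- ifelse(z == 1, mu + sigma * stats::rnorm(n), stats::rnorm(n))
  eps <- stats::rnorm(n)
  y <- ifelse(z == 1,
              mu + sigma * (rho * (x - mu) / sigma +
                              sqrt(1 - rho^2) * eps), eps)
  list(p1 = exp(-x), p2 = exp(-y), latent = z)
}

# hand-built k-mer index (bypasses sequence machinery)
fixture_kmer_index <- function(gene_kmers, k = 7L) {
  genes <- lapply(gene_kmers, function(kms)
    data.frame(pos = seq_along(kms) - 1L, kmer = kms,
               junction = FALSE, stringsAsFactors = FALSE))
  structure(list(k = k, genes = genes), class = "kmer_index")
}

# binding-call data.frame in the shape call_targets() emits
fixture_calls <- function(baits, target_sets, idr = 0.01) {
  do.call(rbind, lapply(baits, function(b) {
    g <- target_sets[[b]]
    if (length(g) == 0L) return(NULL)
    data.frame(feature_id = g, bait = b, local_idr = idr, global_idr = idr,
               min_fold_change = 2, pass = TRUE,
               strength = -log10(idr), stringsAsFactors = FALSE)
  }))
}
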