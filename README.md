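# ripnet

Integrative analysis of native RIP-seq and co-IP data across a panel of
RNA-binding protein (RBP) baits.

In a native (non-crosslinked) RNA immunoprecipitation experiment, each
epitope-tagged bait protein pulls down whole ribonucleoprotein complexes;
sequencing the RNA fraction and running mass spectrometry on the protein
fraction of the *same* IP yields matched RNA-target and protein-partner
profiles per bait. `ripnet` provides the downstream statistics for such a
panel (the motivating design: 20 baits in biological duplicate against a
shared pool of 10 controls):

- **Differential binding.** Per-replicate enrichment of IP over pooled
  controls with a DESeq-style model: median-of-ratios size factors
  `s_j = median_i (k_ij / (prod_j k_ij)^{1/m})`, NB variance
  `Var(K) = mu + alpha mu^2` with a trended empirical-Bayes dispersion
  prior, and an exact-style conditional test on the total count of the two
  groups. The reported p-value integrates the conditional test over the
  per-feature dispersion posterior, which keeps null p-values uniform with
  only a handful of controls.
- **Reproducibility (IDR).** Replicate p-values are combined with a
  two-component Gaussian copula mixture (noise: independent standard
  bivariate normal; signal: mean `(mu, mu)`, sd `sigma`, correlation
  `rho`), fitted by pseudo-likelihood EM on rank-transformed scores. A
  target passes at local IDR <= 0.10 *and* fold change >= 1.5 in every
  replicate.
- **HOT RNAs.** Genes bound by at least half the baits are high-occupancy
  targets. The null is Poisson-binomial — `X = sum_j Bern(p_j)` with
  `p_j = n_j / |bound universe|` — computed exactly by dynamic-programming
  convolution and conservatively conditioned on `X >= 1`.
- **Motifs.** Isoform-aware 7-mer location indexes (unique locations across
  all transcripts of a gene), gene-presence hypergeometric enrichment of
  targets vs expressed non-targets, a weighted-alignment PWM from the top
  k-mers, transcriptome scans with the top-1% k-mers under the PWM, and
  per-locus gene-region z-scores
  `z = (x - n p0) / sqrt(n p0 (1 - p0))` against the unambiguous
  5'UTR/CDS/3'UTR/intron region collapse.
- **Networks.** Bait-to-gene edges typed `rna` / `protein` / `both`,
  per-bait hypergeometric overlap of protein partners and RNA targets,
  Fisher-combined across baits (`chi^2 = -2 sum log p`, `2m` df), and
  gene-vs-intron target concordance (per-bait Jaccard, cross-bait Spearman).
- **Synthetic data.** A seeded generator that plants target sets, fold
  changes, HOT genes, sequence motifs in chosen gene regions, protein
  complexes with cross-regulated preys, and biased gene-set labels — so
  every stage is testable against known truth.

## Worked example

```r
library(ripnet)

cfg <- simulation_config(seed = 7, n_genes = 120, fc_range = c(2, 8),
                         mean_log = log(500))
sim <- simulate_rip_experiment(cfg)

calls <- differential_binding(sim$gene_counts)$calls
bm    <- build_binding_matrix(calls)
hot   <- hot_test(bm)
hot
#> <hot_set> threshold >=10 baits: observed 6, expected 0.125 (fold 48.1), P = 4.11e-09

mean(sim$truth$hot_genes %in% hot$hot_genes)   # planted HOT recall
#> [1] 1
```

`hot` says: 6 RNAs were bound by >= 10 of the 20 baits, while the
conditioned Poisson-binomial null expects 0.125 such RNAs — a 48-fold
enrichment with binomial tail probability 4.1e-09 — and every planted HOT
RNA was recovered. Motif discovery on the same fixture:

```r
idx <- build_kmer_index(sim$genes, sim$seqs, k = 7)
tg  <- calls$feature_id[calls$bait == "RBP01" & calls$pass]
mot <- discover_motif(idx, tg, setdiff(names(sim$genes), tg),
                      sim$partitions)
head(mot$kmer_stats, 3)   # per-7-mer gene-presence hypergeometric
mot$pwm                   # weighted PWM over the top k-mers
```

## Command line

```sh
Rscript -e 'quit(status = ripnet::ripnet_cli())' --args \
    all --seed 1 --outdir results/
```

Subcommands `simulate`, `calls`, `occupancy`, `motif`, `network`, `all`;
configuration via a JSON file (`--config`) with flag overrides
(`--idr`, `--fc`, `--top-quantile`). Exit status 2 flags missing inputs or
invalid thresholds.

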