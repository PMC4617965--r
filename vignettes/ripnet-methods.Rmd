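---
title: "ripnet: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ripnet: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`ripnet` analyzes panels of native RIP-seq experiments: each of a set of
epitope-tagged RNA-binding proteins (baits) is immunoprecipitated in
biological duplicate, the RNA fraction is sequenced, and the protein
fraction is profiled by mass spectrometry, against a shared pool of
control IPs. This vignette records the models behind each stage, the
parameters that matter, what the synthetic-data generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the package's tests do not
themselves compute.

## Differential binding

### Normalization and dispersion

Counts are modeled as negative binomial, `Var(K) = mu + alpha * mu^2`.
Size factors are classic median-of-ratios: for each sample, the median over
features (nonzero in every sample) of the count divided by the feature's
geometric mean. Dispersions are estimated from the control pool only:

1. a method-of-moments estimate per feature from normalized counts,
   `alpha_raw = (v - xi * mu) / mu^2` with `xi = mean(1 / s_j)`;
2. a gamma-family trend `alpha ~ a0 + a1 / mu` fitted across features;
3. a parametric bootstrap under `NB(s_j * mu_i, alpha_trend_i)` that
   measures, in bins of `alpha * mu` (the quantity governing how
   informative count data are about dispersion), the bias and the sampling
   variance of the raw log-dispersion estimate. The raw MoM estimator is
   severely downward-biased in log space at low `alpha * mu`; analytic
   chi-square corrections underestimate this for NB data, which is why the
   calibration is simulated rather than derived;
4. empirical-Bayes shrinkage: per-feature weight
   `w = v_samp / (v_samp + tau2)`, where `tau2` is the prior spread of true
   log dispersions around the trend, estimated by trimmed-variance
   deconvolution (a MAD-based scale is systematically too small for skewed
   log-dispersion residuals and was rejected for that reason).

Dispersion defaults are floored at `1e-8`; `shrink` can be forced to a
fixed weight for diagnostic work.

### The conditional test and dispersion uncertainty

`nb_test()` is an exact-style conditional test: the IP replicate and the
pooled controls share an abundance `q = total / (s_A + s_B)`; conditioned
on the observed total, the p-value sums the probabilities of all splits as
likely or less likely than the observed one, with the pooled control group
moment-matched to a single NB (its effective size absorbs
`sum(s_j^2)`). The fold change is the ratio of normalized IP count to
normalized control mean with a pseudocount of 0.5 on both sides — the
source methodology is silent on zero handling, and 0.5 keeps all-zero
features finite and flagged rather than dropped.

Plugging a *point* dispersion estimate into this test leaves p-values
detectably non-uniform under the null even when the estimator is unbiased:
with ten controls the estimate carries roughly +/- 50% multiplicative
noise, and the induced distortion does not cancel across features. The
pipeline therefore reports a posterior-predictive p-value: a per-feature
posterior over log dispersion (control-sample NB likelihood times the
log-normal empirical-Bayes prior, whose center is mean-matched at
`log(trend) - tau2/2`) is evaluated on a 9-point grid spanning +/- 2.5
prior standard deviations, weights below 0.02 are pruned, and the reported
p-value is the posterior-weighted mean of the conditional p-values. The
acceptance suite verifies per-seed Kolmogorov-Smirnov uniformity on null
data; with point estimates that check fails, with the posterior average it
sits at the same level as supplying the true dispersions. `nb_test()`
itself remains the pure point-dispersion conditional test so that the
brute-force enumeration oracle remains an exact identity.

Interpretation of the KS criterion: the stated rule is one KS test per
seed at alpha = 0.01 over 20 seeds, with at least 18 non-rejections
(perfect uniformity would average 0.2 rejections). This reading was fixed
before any calibration run.

### Reproducibility: the IDR copula mixture

Replicate scores `-log p` are rank-transformed (`u = rank / (n + 1)`,
average ties) and mapped to pseudo-normal values through the inverse of the
current mixture marginal — so the fit depends on the data only through
ranks, and any strictly monotone transform of the scores leaves the result
unchanged. The mixture has a noise component (independent standard
bivariate normal) and a reproducible component (means `(mu, mu)`, sd
`sigma`, correlation `rho`) with weight `pi1`. EM starts from
`pi1 = 0.5, mu = 1, sigma = 1, rho = 0.5`; pseudo-data are refreshed each
step; convergence is declared when the largest parameter change falls
below `1e-6`, with a 500-iteration cap. The pseudo-likelihood fixed point
converges linearly, so the cap is often reached while the parameters are
already stable to three or four decimals; the fit then carries
`converged = FALSE` as a flag (with a message, not a warning), and the
acceptance suite checks what actually matters — parameter recovery of a
planted mixture to within +/- 0.05.

A binding call requires local IDR <= 0.10 *and* fold change >= 1.5 in
every replicate; thresholding is by reproducibility, not by
Benjamini-Hochberg on p-values. `strength = -log10(local IDR)` is capped
at 12 (IDR floored at `1e-12`) to keep downstream shading finite. Global
IDR at rank r is the running mean of the r smallest local IDRs, hence
never exceeds the local threshold on the selected set.

## Occupancy statistics

With `n_j` targets per bait and a bound universe `U` (genes bound by at
least one bait), the occupancy null is Poisson-binomial with
`p_j = n_j / |U|`, computed exactly by DP convolution. HOT RNAs are genes
bound by at least `ceil(n_baits / 2)` baits. Following the conservative
conditioning of the source design, the per-gene tail `q = P(X >= t)` is
renormalized by `1 - P(X = 0)`; expected HOT count is `|U| * q`, and the
observed count's significance is the upper binomial tail — genes are
treated as i.i.d. under the null, a documented choice since the original
aggregation is unstated. The unconditioned variant is a flag. The maximum
occupancy statistic uses the unconditioned tail:
`P(max >= m) = 1 - (1 - q_m)^|U|`.

Pairwise bait overlaps, generic set enrichment (hypergeometric or
binomial upper tails), rank-sum class comparisons (exact Wilcoxon null for
tie-free groups of at most 10, normal approximation with tie correction
otherwise), and down-the-rank-list enrichment curves (consecutive bins of
100 targets ranked by local IDR, each scored by `-log10` hypergeometric
p against the expressed universe) complete the module. The enrichment
universe defaults to expressed genes (mean control RPKM >= 1 — the only
expression cutoff the source states); p-values are floored at `1e-300`
before log transforms.

## Gene structure and motifs

Coordinates are 0-based half-open internally, converted from and to
1-based GTF on IO. A base of a locus receives a structure label (5'UTR,
CDS, 3'UTR, intron) only when *every* transcript covering it agrees;
disagreement, non-coding exons (no CDS to anchor a UTR call), and
uncovered gaps are `ambiguous` and excluded from region statistics.

The 7-mer index records, per gene, the union of k-mer windows across all
transcripts: windows inside one exon are keyed by their genomic start;
junction-spanning windows by the full signature of covered positions, so
isoforms sharing a junction contribute one location while distinct
junction contexts at the same start stay apart. This junction rule is a
package choice (the source leaves it unstated) and is deliberately
conservative about double counting. Windows containing non-ACGT characters
are dropped; minus-strand genes are indexed on their mature sense
sequence.

Per bait, each 7-mer is scored by the gene-presence hypergeometric of
target genes vs expressed non-target genes (a gene counts once however
many locations it has). The top 50 k-mers with positive weight
(`-log10 p`; the "transform" is unnamed in the source and -log10 is the
natural choice) are summarized into one PWM: the most enriched k-mer seeds
the alignment, the rest join at the shift in +/- 2 maximizing base matches
(ties resolved toward 0, then negative shifts), contributing their weights
to a position-frequency matrix with pseudocount 0.25 per cell, column
normalized. Full motif-EM refinement was judged out of proportion for
summarizing weighted 7-mers into one matrix. The alphabet is displayed as
ACGU; computation is on the DNA sense strand; no reverse-complement
scanning (RIP enriches sense transcripts).

Transcriptome scanning takes the top quantile of all `4^7` k-mers by PWM
log-likelihood (ties lexicographic). The default quantile is 0.01; the
source alternates between "top 1%" and "top 0.1%" in different places,
so both are reachable through the `q` argument. Hits are assigned the
region label of their 5'-most base; ambiguous-region hits are kept in the
hit set but excluded from region tests. Per locus with at least 20
non-ambiguous hits, each region is scored by
`z = (x - n p0) / sqrt(n p0 (1 - p0))` with `p0` the region's share of
the locus's non-ambiguous length, plus an exact binomial upper tail.

## Networks

Protein preys are mapped to encoding genes by a required input table (no
identifier lookups over the network). Edges are typed `rna`, `protein` or
`both`; a bait's own overexpressed gene is excluded from its RNA edges. An
optional exclusion list drops bait-bait PPI rows (cross-contamination
mirror). Per bait, cross-regulation is the hypergeometric overlap of prey
genes and RNA targets in the expressed universe; baits lacking either
layer are excluded (undefined is not null evidence). Evidence combines by
Fisher's method, `chi^2 = -2 sum log p` on `2m` df. Fisher's method
assumes continuous inputs; with small discrete overlap supports the plain
combination is conservative (its null combined p piles up near 1), so
`midp = TRUE` applies Lancaster's mid-p (`p - P(X = k)/2`) inside the
combination only — reported per-bait p-values are always plain upper
tails, and the default stays plain so that degenerate identities (all
p = 1 combining to exactly 1) hold. Gene-vs-intron concordance is the
per-bait Jaccard index of gene targets and intron-target parent loci, plus
the cross-bait Spearman correlation of target counts. Intron features are
collapsed intron regions that overlap no exon of any transcript of any
gene on the contig.

## The synthetic world

The generator states the experimental design it emulates: 20 baits in
biological duplicate; a shared control pool of 10 samples (five control
constructs in duplicate); gene abundances log-normal
(`meanlog = log 150`, `sdlog = 1`); per-gene NB dispersions gamma with
mean 0.05 (the value the build contract itself uses in its generator
checks); sample size factors log-uniform in [0.5, 2]; per-bait target
fraction 0.15; planted fold changes log-uniform in [1.5, 8] shared between
replicates; 5% of genes planted as HOT (forced into the target sets of at
least half the baits). Planted-recovery fixtures follow the stated
conditions of the corresponding check: fold changes at least 2 and deeper
coverage (`meanlog = log 500`) for target recovery. Planted motifs are
drawn from a consensus-concentrated PWM (0.85 on the consensus base) and
inserted into the designated collapsed region; the default insertion rate
of about 10 copies per bound transcript reflects the repeat-motif binding
typical of sequence-specific RBPs. Gene models are one gene per contig,
one to four isoforms varying UTR lengths or skipping an internal coding
exon — enough to exercise the ambiguity rules, not a model of real exon
statistics.

What a green test does not establish: the generator has no sequencing-error
or mappability structure, no correlated dispersion between baits, no GC or
length bias, uniform background sequence, and independent intron features;
real-data behavior on those axes is untested by construction.

## Numerical and interface choices

- All randomness flows through explicit seeds; generator stages restore
  the caller's RNG state.
- The pipeline configuration file is JSON (not YAML): the deployment
  environment guarantees a JSON parser but not a YAML one, and the config
  surface is flat enough that the formats are interchangeable.
- Degenerate inputs: all-zero features test at p = 1 with the fold change
  flagged undefined; all-tied IDR scores are a hard error; empty intron
  sets after filtering warn and return empty results; a region with
  `p0` of 0 or 1 is skipped in z-scoring.
- Known limitations: replicate counts other than 2 fall back to requiring
  the fold-change threshold in every replicate while IDR uses the first
  two; the NB test supports IP-vs-pooled-control contrasts only; GO-style
  sets are flat (no DAG propagation); multiple-testing control across gene
  sets is Bonferroni-or-BH by the caller, matching the thresholding-by-IDR
  design.
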