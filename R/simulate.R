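# Seeded synthetic-data generator with known ground truth.
#
# The generator states the world the tests run in: 20 epitope-tagged baits
# in biological duplicate against a shared control pool, negative-binomial
# gene counts with planted enriched target sets (log-uniform fold changes
# above 1.5), a multi-isoform transcriptome with motifs planted into chosen
# collapsed regions of true-target genes, planted protein complexes whose
# preys' mRNAs may be co-targets, intron-level features with their own
# truth, and gene-set labels enriched among planted HOT RNAs.

# uniform integer in [lo, hi]; immune to the scalar-sample trap
.runif_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

# evaluate expr under a given seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults describe the emulated experiment: 20 baits in biological
#' duplicate, a shared pool of 6 controls, log-normal gene abundances with
#' gamma-distributed NB dispersions, per-bait target fraction 0.15,
#' 5 percent of genes planted as HOT (bound by at least half of the baits),
#' planted fold changes log-uniform in `fc_range`, and one planted sequence
#' motif per entry of `motifs`.
#'
#' @param seed integer; fully determines every generated artifact.
#' @param n_genes number of genes, default 300.
#' @param n_rbps number of bait RBPs, default 20.
#' @param n_replicates IP replicates per bait, default 2.
#' @param n_controls control samples in the shared pool, default 10 (five
#'   control constructs in biological duplicate).
#' @param mean_log,mean_sdlog log-normal parameters of gene mean counts.
#' @param disp_shape,disp_rate gamma parameters of per-gene NB dispersion.
#' @param fc_range planted fold-change range (log-uniform), default
#'   `c(1.5, 8)`.
#' @param target_fraction per-bait probability that a non-HOT gene is a
#'   target, default 0.15.
#' @param hot_fraction_genes fraction of genes planted as HOT, default 0.05.
#' @param intron_co_rate probability that an intron of a gene-level target
#'   is itself an intron-level target of the same bait, default 0.5.
#' @param intron_base_rate intron-target rate for non-target parents,
#'   default 0.02.
#' @param motifs named list (names = baits) of
#'   `list(consensus =, region =, rate =)`: a 7-letter ACGU consensus, the
#'   collapsed region to enrich (`"cds"`, `"three_utr"`, ...) and the mean
#'   number of inserted copies per target gene (Poisson, minimum 1).
#' @param motif_conc probability mass on the consensus base at each planted
#'   motif position, default 0.85.
#' @param n_complexes,complex_size_range planted protein complexes.
#' @param cross_regulation fraction of preys whose mRNA is added to the
#'   bait's true RNA-target set, default 0.5.
#' @param n_go_sets,go_size,go_hot_odds gene-set labels: number of sets,
#'   set size, and sampling odds favoring HOT genes, defaults 8 / 40 / 4.
#' @return object of class `sim_config`.
#' @export
simulation_config <- function(seed = 1L, n_genes = 300L, n_rbps = 20L,
                              n_replicates = 2L, n_controls = 10L,
                              mean_log = log(150), mean_sdlog = 1,
                              disp_shape = 2, disp_rate = 40,
                              fc_range = c(1.5, 8),
                              target_fraction = 0.15,
                              hot_fraction_genes = 0.05,
                              intron_co_rate = 0.5,
                              intron_base_rate = 0.02,
                              motifs = list(),
                              motif_conc = 0.85,
                              n_complexes = 6L,
                              complex_size_range = c(4L, 8L),
                              cross_regulation = 0.5,
                              n_go_sets = 8L, go_size = 40L,
                              go_hot_odds = 4) {
  cfg <- as.list(environment())
  .assert(all(fc_range >= 1), "fold changes must be >= 1")
  .assert(target_fraction >= 0 && target_fraction <= 1 &&
            hot_fraction_genes >= 0 && hot_fraction_genes <= 1 &&
            cross_regulation >= 0 && cross_regulation <= 1,
          "fractions must lie in [0,1]")
  .assert(is.null(names(motifs)) || all(names(motifs) != "") ||
            length(motifs) == 0L, "motifs must be a named list")
  structure(cfg, class = "sim_config")
}

.bait_names <- function(n) sprintf("RBP%02d", seq_len(n))
.gene_names <- function(n) sprintf("G%04d", seq_len(n))

# draw one motif instance from a consensus-concentrated PWM (DNA alphabet)
.draw_motif <- function(consensus_dna, conc) {
  paste(vapply(strsplit(consensus_dna, "")[[1L]], function(b) {
    probs <- stats::setNames(rep((1 - conc) / 3, 4), c("A", "C", "G", "T"))
    probs[b] <- conc
    sample(names(probs), 1L, prob = probs)
  }, ""), collapse = "")
}

# consensus-concentrated PWM matrix (4 x L, rows ACGU) for truth records
planted_pwm_matrix <- function(consensus, conc) {
  bases <- strsplit(chartr("T", "U", consensus), "")[[1L]]
  m <- matrix((1 - conc) / 3, 4L, length(bases),
              dimnames = list(c("A", "C", "G", "U"), NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- conc
  m
}

#' Simulate an annotated multi-isoform transcriptome with planted motifs
#'
#' Each gene lives on its own contig with a 1-4 isoform model
#' (5'UTR / multi-exon CDS / 3'UTR); extra isoforms vary UTR lengths or skip
#' an internal coding exon, creating genuinely ambiguous collapsed bases.
#' Target-set truth (including HOT genes and per-pair fold changes) is drawn
#' first so that motif instances can be planted into the designated
#' collapsed region of each motif-bait's true targets.
#'
#' @param cfg a [simulation_config()].
#' @return list: `genes` (gene models), `seqs` (DNAStringSet),
#'   `partitions` (collapsed regions), `truth` (partial ground truth).
#' @export
simulate_transcriptome <- function(cfg) with_seed(cfg$seed, {
  gids <- .gene_names(cfg$n_genes)
  baits <- .bait_names(cfg$n_rbps)
  hot_t <- ceiling(cfg$n_rbps / 2)

  # --- target truth -------------------------------------------------------
  n_hot <- round(cfg$hot_fraction_genes * cfg$n_genes)
  hot_genes <- sample(gids, n_hot)
  targets <- stats::setNames(vector("list", cfg$n_rbps), baits)
  occ <- matrix(stats::runif(cfg$n_genes * cfg$n_rbps) <
                  cfg$target_fraction,
                cfg$n_genes, cfg$n_rbps, dimnames = list(gids, baits))
  for (g in hot_genes) {
    k <- .runif_int(hot_t, cfg$n_rbps)
    occ[g, ] <- FALSE
    occ[g, sample(baits, k)] <- TRUE
  }
  for (b in baits) targets[[b]] <- gids[occ[, b]]
  fc <- matrix(1, cfg$n_genes, cfg$n_rbps, dimnames = list(gids, baits))
  fc[occ] <- exp(stats::runif(sum(occ), log(cfg$fc_range[1L]),
                              log(cfg$fc_range[2L])))

  # --- gene models and genome --------------------------------------------
  genes <- list(); seq_chr <- character(0)
  for (gid in gids) {
    strand <- sample(c("+", "-"), 1L, prob = c(0.7, 0.3))
    n_tx <- sample(1:4, 1L, prob = c(0.4, 0.3, 0.2, 0.1))
    u5 <- sample(80:250, 1L); u3 <- sample(150:400, 1L)
    n_cds_ex <- sample(2:4, 1L)
    cds_len <- sample(120:300, n_cds_ex, replace = TRUE)
    intr <- sample(60:150, n_cds_ex - 1L, replace = TRUE)
    flank <- 50L
    # primary isoform layout on the genome (plus orientation; for minus
    # strand the labels are interpreted through the strand by the models)
    segs <- integer(0)
    for (i in seq_len(n_cds_ex)) {
      segs <- c(segs, cds_len[i])
      if (i < n_cds_ex) segs <- c(segs, intr[i])
    }
    if (strand == "+") lens <- c(u5 = u5, segs, u3 = u3)
    else lens <- c(u3 = u3, segs, u5 = u5)
    bnd <- flank + c(0L, cumsum(lens))
    total <- bnd[length(bnd)] + flank
    # exon/cds genomic intervals of the primary isoform
    is_intron <- rep(FALSE, length(lens))
    is_intron[seq(3L, by = 2L, length.out = n_cds_ex - 1L)] <- n_cds_ex > 1L
    seg_start <- bnd[-length(bnd)]; seg_end <- bnd[-1L]
    exon_iv <- cbind(seg_start[!is_intron], seg_end[!is_intron])
    # merge adjacent exonic segments (UTR abuts terminal CDS exon)
    merged <- exon_iv[1L, , drop = FALSE]
    for (i in seq_len(nrow(exon_iv))[-1L]) {
      if (exon_iv[i, 1L] == merged[nrow(merged), 2L])
        merged[nrow(merged), 2L] <- exon_iv[i, 2L]
      else merged <- rbind(merged, exon_iv[i, ])
    }
    cds_span <- if (strand == "+") c(flank + u5, total - flank - u3)
    else c(flank + u3, total - flank - u5)
    txs <- list(transcript_model(paste0(gid, ".1"), gid, merged,
                                 cds = cds_span, strand = strand))
    for (v in seq_len(n_tx - 1L)) {
      kind <- sample(c("short3", "short5", "skip"), 1L)
      ex <- merged; cds_v <- cds_span
      if (kind == "short3") {
        trim <- sample(50:min(120, u3 - 10L), 1L)
        if (strand == "+") ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] - trim
        else ex[1L, 1L] <- ex[1L, 1L] + trim
      } else if (kind == "short5") {
        trim <- sample(30:min(60, u5 - 10L), 1L)
        if (strand == "+") ex[1L, 1L] <- ex[1L, 1L] + trim
        else ex[nrow(ex), 2L] <- ex[nrow(ex), 2L] - trim
      } else if (nrow(ex) >= 3L) {
        # sample.int avoids the scalar-sample trap when only one internal exon
        ex <- ex[-(1L + sample.int(nrow(ex) - 2L, 1L)), , drop = FALSE]
      }
      txs <- c(txs, list(transcript_model(sprintf("%s.%d", gid, v + 1L),
                                          gid, ex, cds = cds_v,
                                          strand = strand)))
    }
    genes[[gid]] <- gene_model(gid, paste0("chr_", gid), txs)
    seq_chr[paste0("chr_", gid)] <- paste(
      sample(c("A", "C", "G", "T"), total, replace = TRUE), collapse = "")
  }
  seqs <- Biostrings::DNAStringSet(seq_chr)
  partitions <- lapply(genes, collapse_regions)

  # --- motif planting -----------------------------------------------------
  planted <- list()
  for (b in names(cfg$motifs)) {
    spec <- cfg$motifs[[b]]
    cons_dna <- chartr("U", "T", toupper(spec$consensus))
    L <- nchar(cons_dna)
    for (gid in targets[[b]]) {
      part <- partitions[[gid]]
      runs <- part$regions[part$regions$label == spec$region, , drop = FALSE]
      runs <- runs[runs$end - runs$start >= L, , drop = FALSE]
      if (nrow(runs) == 0L) {
        message(sprintf("gene %s: region %s too short for motif; skipped",
                        gid, spec$region))
        next
      }
      n_copies <- stats::rpois(1L, spec$rate)
      for (cp in seq_len(n_copies)) {
        r <- runs[sample(nrow(runs), 1L), , drop = FALSE]
        gstart <- r$start + sample.int(r$end - r$start - L + 1L, 1L) - 1L
        inst <- .draw_motif(cons_dna, cfg$motif_conc)
        # plant on the sense strand of the gene
        if (genes[[gid]]$strand == "-") {
          inst_g <- .revcomp(inst)
        } else inst_g <- inst
        chrom <- genes[[gid]]$chrom
        s <- as.character(seqs[[chrom]])
        substr(s, gstart + 1L, gstart + L) <- inst_g
        seqs[[chrom]] <- Biostrings::DNAString(s)
      }
    }
    planted[[b]] <- list(consensus = chartr("T", "U", cons_dna),
                         region = spec$region, rate = spec$rate,
                         pwm = planted_pwm_matrix(spec$consensus,
                                                  cfg$motif_conc))
  }

  truth <- list(targets = targets, hot_genes = sort(hot_genes),
                fold_change = fc, motifs = planted,
                hot_threshold = hot_t,
                bait_gene = stats::setNames(gids[seq_len(cfg$n_rbps)],
                                            baits))
  list(genes = genes, seqs = seqs, partitions = partitions, truth = truth)
})

#' Simulate gene-level and intron-level RIP count tables
#'
#' Controls follow NB(mu_g, alpha_g); each IP replicate of a bait follows
#' NB(s_j * mu_g * FC, alpha_g) with FC = 1 for non-targets, and both
#' replicates of a bait share targets and fold changes. Sample size factors
#' are log-uniform in [0.5, 2]. Intron features are independent NB features
#' attached to parent genes with their own target truth.
#'
#' @param cfg a [simulation_config()].
#' @param truth truth list from [simulate_transcriptome()].
#' @param intron_feats optional data.frame from [intron_features()]; when
#'   supplied an intron-level table and its truth are generated too.
#' @return list: `gene_counts` (a [count_table()]), `intron_counts` (or
#'   `NULL`), updated `truth` gaining `intron_targets`, `mu`, `alpha`,
#'   `size_factors`.
#' @export
simulate_rip_counts <- function(cfg, truth,
                                intron_feats = NULL) with_seed(cfg$seed + 1L, {
  gids <- rownames(truth$fold_change)
  baits <- colnames(truth$fold_change)
  samples <- c(as.vector(t(outer(baits, seq_len(cfg$n_replicates),
                                 function(b, r) sprintf("%s_rep%d", b, r)))),
               sprintf("control_%d", seq_len(cfg$n_controls)))
  sheet <- data.frame(
    sample_id = samples,
    bait = c(rep(baits, each = cfg$n_replicates),
             rep(NA_character_, cfg$n_controls)),
    replicate = c(rep(seq_len(cfg$n_replicates), cfg$n_rbps),
                  rep(NA_integer_, cfg$n_controls)),
    is_control = c(rep(FALSE, cfg$n_rbps * cfg$n_replicates),
                   rep(TRUE, cfg$n_controls)),
    stringsAsFactors = FALSE)
  sf <- exp(stats::runif(length(samples), log(0.5), log(2)))
  names(sf) <- samples

  draw_table <- function(ids, mu, alpha, fcm) {
    m <- matrix(0L, length(ids), length(samples),
                dimnames = list(ids, samples))
    for (j in seq_along(samples)) {
      b <- sheet$bait[j]
      f <- if (is.na(b)) rep(1, length(ids)) else fcm[, b]
      m[, j] <- stats::rnbinom(length(ids), mu = sf[j] * mu * f,
                               size = 1 / alpha)
    }
    m
  }

  mu_g <- stats::rlnorm(length(gids), cfg$mean_log, cfg$mean_sdlog)
  alpha_g <- stats::rgamma(length(gids), cfg$disp_shape, cfg$disp_rate)
  names(mu_g) <- names(alpha_g) <- gids
  gene_tab <- count_table(draw_table(gids, mu_g, alpha_g,
                                     truth$fold_change), sheet)

  intron_tab <- NULL
  if (!is.null(intron_feats) && nrow(intron_feats) > 0L) {
    iids <- intron_feats$feature_id
    parent <- stats::setNames(intron_feats$gene_id, iids)
    ifc <- matrix(1, length(iids), length(baits),
                  dimnames = list(iids, baits))
    itargets <- stats::setNames(vector("list", length(baits)), baits)
    for (b in baits) {
      parent_is_target <- parent %in% truth$targets[[b]]
      pr <- ifelse(parent_is_target, cfg$intron_co_rate,
                   cfg$intron_base_rate)
      hit <- stats::runif(length(iids)) < pr
      itargets[[b]] <- iids[hit]
      ifc[hit, b] <- exp(stats::runif(sum(hit), log(cfg$fc_range[1L]),
                                      log(cfg$fc_range[2L])))
    }
    mu_i <- stats::rlnorm(length(iids), cfg$mean_log - 1.5, cfg$mean_sdlog)
    alpha_i <- stats::rgamma(length(iids), cfg$disp_shape, cfg$disp_rate)
    intron_tab <- count_table(draw_table(iids, mu_i, alpha_i, ifc), sheet)
    truth$intron_targets <- itargets
    truth$intron_fold_change <- ifc
    truth$intron_parent <- parent
  }
  truth$mu <- mu_g; truth$alpha <- alpha_g; truth$size_factors <- sf
  list(gene_counts = gene_tab, intron_counts = intron_tab, truth = truth)
})

#' Simulate protein-interaction complexes and gene-set labels
#'
#' Each planted complex contributes bait-prey edges among its members; for a
#' configured fraction of preys the prey's encoding mRNA is added to the
#' bait's true RNA-target set (the cross-regulation signal). Gene sets are
#' sampled with odds `go_hot_odds` of including planted HOT genes.
#'
#' @param cfg a [simulation_config()].
#' @param truth truth list (target sets are updated and returned).
#' @return list: `ppi` data.frame (`bait`, `prey_protein`, `prey_gene`),
#'   `go` data.frame (`set_id`, `gene_id`), `complexes`, updated `truth`.
#' @export
simulate_networks <- function(cfg, truth) with_seed(cfg$seed + 2L, {
  baits <- names(truth$targets)
  gids <- rownames(truth$fold_change)
  complexes <- list(); ppi <- NULL
  for (ci in seq_len(cfg$n_complexes)) {
    b <- baits[(ci - 1L) %% length(baits) + 1L]
    size <- .runif_int(cfg$complex_size_range[1L],
                       cfg$complex_size_range[2L])
    preys <- sample(setdiff(gids, truth$bait_gene[[b]]), size - 1L)
    complexes[[ci]] <- list(bait = b, preys = preys)
    ppi <- rbind(ppi, data.frame(bait = b,
                                 prey_protein = paste0("P_", preys),
                                 prey_gene = preys,
                                 stringsAsFactors = FALSE))
    co <- preys[stats::runif(length(preys)) < cfg$cross_regulation]
    truth$targets[[b]] <- union(truth$targets[[b]], co)
    add <- setdiff(co, rownames(truth$fold_change)[
      truth$fold_change[, b] > 1])
    if (length(add))
      truth$fold_change[add, b] <- exp(stats::runif(
        length(add), log(cfg$fc_range[1L]), log(cfg$fc_range[2L])))
  }
  go <- do.call(rbind, lapply(seq_len(cfg$n_go_sets), function(si) {
    w <- ifelse(gids %in% truth$hot_genes, cfg$go_hot_odds, 1)
    data.frame(set_id = sprintf("SET%03d", si),
               gene_id = sample(gids, min(cfg$go_size, length(gids)),
                                prob = w),
               stringsAsFactors = FALSE)
  }))
  list(ppi = ppi, go = go, complexes = complexes, truth = truth)
})

#' Generate a complete seeded fixture dataset
#'
#' Runs [simulate_transcriptome()], [intron_features()],
#' [simulate_networks()] and [simulate_rip_counts()] in the order that lets
#' cross-regulation preys receive planted count fold changes.
#'
#' @param cfg a [simulation_config()].
#' @return list: `genes`, `seqs`, `partitions`, `gene_counts`,
#'   `intron_counts`, `intron_feats`, `ppi`, `go`, `complexes`, `truth`.
#' @export
simulate_rip_experiment <- function(cfg) {
  tr <- simulate_transcriptome(cfg)
  feats <- intron_features(tr$partitions, tr$genes)
  net <- simulate_networks(cfg, tr$truth)
  cnt <- simulate_rip_counts(cfg, net$truth, feats)
  list(genes = tr$genes, seqs = tr$seqs, partitions = tr$partitions,
       gene_counts = cnt$gene_counts, intron_counts = cnt$intron_counts,
       intron_feats = feats, ppi = net$ppi, go = net$go,
       complexes = net$complexes, truth = cnt$truth)
}

#' Write a simulated experiment to disk
#'
#' GTF + FASTA annotation, TSV count tables and sample sheet, TSV PPI and
#' gene-set maps, and a JSON ground-truth file.
#'
#' @param sim result of [simulate_rip_experiment()].
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(sim$genes, file.path(dir, "annotation.gtf"))
  Biostrings::writeXStringSet(sim$seqs, file.path(dir, "genome.fa"))
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(data.frame(feature_id = rownames(sim$gene_counts$counts),
                sim$gene_counts$counts, check.names = FALSE),
     "gene_counts.tsv")
  if (!is.null(sim$intron_counts))
    wt(data.frame(feature_id = rownames(sim$intron_counts$counts),
                  sim$intron_counts$counts, check.names = FALSE),
       "intron_counts.tsv")
  wt(sim$gene_counts$sample_sheet, "sample_sheet.tsv")
  wt(sim$ppi, "ppi.tsv")
  wt(sim$go, "go_sets.tsv")
  if (!is.null(sim$intron_feats)) wt(sim$intron_feats, "introns.tsv")
  truth <- sim$truth
  truth$fold_change <- NULL; truth$intron_fold_change <- NULL
  truth$motifs <- lapply(truth$motifs, function(m) m[c("consensus",
                                                       "region", "rate")])
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
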