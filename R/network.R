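# RNA-protein network integration and cross-regulation statistics.

#' Integrate RNA-binding calls with protein co-IP interactions
#'
#' Builds typed bait -> gene edges: `rna` when the gene's transcript is a
#' binding target, `protein` when a prey protein encoded by the gene
#' co-purifies with the bait, `both` when both layers agree. A bait's own
#' (overexpressed) gene is excluded from its rna edges.
#'
#' @param calls output of [call_targets()] (passing rows become rna edges).
#' @param ppi data.frame with columns `bait`, `prey_protein`, `prey_gene`.
#' @param bait_gene named character vector mapping each bait to the gene
#'   encoding it (used for the self-edge exclusion; optional).
#' @param exclude_baits optional character vector of bait-encoding genes
#'   whose bait-bait PPI rows are dropped (cross-contamination filter).
#' @return object of class `integrated_network`: `edges` data.frame
#'   (`bait`, `gene`, `type`, `strength`), `partners` (per-bait prey gene
#'   sets), `rna_targets` (per-bait RNA target sets).
#' @export
integrate_network <- function(calls, ppi, bait_gene = NULL,
                              exclude_baits = NULL) {
  .assert(all(c("bait", "prey_protein", "prey_gene") %in% names(ppi)),
          "ppi needs bait, prey_protein, prey_gene columns")
  unmapped <- is.na(ppi$prey_gene) | ppi$prey_gene == ""
  if (any(unmapped)) {
    warning(sprintf("%d PPI rows with unmappable preys dropped",
                    sum(unmapped)))
    ppi <- ppi[!unmapped, , drop = FALSE]
  }
  if (!is.null(exclude_baits))
    ppi <- ppi[!(ppi$prey_gene %in% exclude_baits), , drop = FALSE]
  cc <- calls[calls$pass, , drop = FALSE]
  baits <- union(unique(cc$bait), unique(ppi$bait))
  no_rna <- setdiff(unique(ppi$bait), unique(cc$bait))
  if (length(no_rna))
    warning(sprintf("baits with protein edges but no RNA calls: %s",
                    paste(no_rna, collapse = ", ")))
  rna_targets <- lapply(stats::setNames(baits, baits), function(b) {
    tg <- cc$feature_id[cc$bait == b]
    own <- bait_gene[[b]] %||% b
    setdiff(tg, own)
  })
  partners <- lapply(stats::setNames(baits, baits), function(b)
    unique(ppi$prey_gene[ppi$bait == b]))
  strength <- stats::setNames(cc$strength, paste(cc$bait, cc$feature_id))
  edges <- do.call(rbind, lapply(baits, function(b) {
    genes <- union(rna_targets[[b]], partners[[b]])
    if (length(genes) == 0L) return(NULL)
    in_rna <- genes %in% rna_targets[[b]]
    in_ppi <- genes %in% partners[[b]]
    data.frame(bait = b, gene = genes,
               type = ifelse(in_rna & in_ppi, "both",
                             ifelse(in_rna, "rna", "protein")),
               strength = ifelse(in_rna,
                                 unname(strength[paste(b, genes)]), 0),
               stringsAsFactors = FALSE)
  }))
  rownames(edges) <- NULL
  structure(list(edges = edges, partners = partners,
                 rna_targets = rna_targets),
            class = "integrated_network")
}

#' @export
print.integrated_network <- function(x, ...) {
  tab <- table(factor(x$edges$type, levels = c("rna", "protein", "both")))
  cat(sprintf("<integrated_network> %d baits, edges: %d rna / %d protein / %d both\n",
              length(x$partners), tab[["rna"]], tab[["protein"]],
              tab[["both"]]))
  invisible(x)
}

#' Cross-regulation: do baits bind the mRNAs of their protein partners?
#'
#' Per bait, the upper-tail hypergeometric overlap between the bait's prey
#' gene set and its RNA target set within the expressed universe; evidence
#' is combined across baits with Fisher's method
#' (chi-square = -2 sum log p, 2m degrees of freedom). Baits with an empty
#' prey or target set are excluded (undefined, not null, evidence).
#'
#' @param network an `integrated_network`.
#' @param universe expressed-gene universe.
#' @param midp combine Lancaster mid-p values (`p - P(X = k)/2`) instead of
#'   the plain upper-tail p-values (default `FALSE`). Fisher's method
#'   assumes continuous uniform inputs; with small discrete overlap counts
#'   the plain combination is conservative, and the mid-p variant restores
#'   null calibration. Reported per-bait p-values are always the plain
#'   upper tail.
#' @return list: data.frame `per_bait` (`bait`, `n_partners`, `n_targets`,
#'   `overlap`, `p_value`), `chi_sq`, `df`, `combined_p`.
#' @export
cross_regulation_test <- function(network, universe, midp = FALSE) {
  per <- lapply(names(network$partners), function(b) {
    pg <- intersect(network$partners[[b]], universe)
    tg <- intersect(network$rna_targets[[b]], universe)
    if (length(pg) == 0L || length(tg) == 0L) return(NULL)
    k <- length(intersect(pg, tg))
    p <- .hyper_upper(k, length(tg), length(universe), length(pg))
    atom <- stats::dhyper(k, length(tg), length(universe) - length(tg),
                          length(pg))
    data.frame(bait = b, n_partners = length(pg), n_targets = length(tg),
               overlap = k, p_value = p, p_combine = p - midp * atom / 2,
               stringsAsFactors = FALSE)
  })
  per <- per[!vapply(per, is.null, TRUE)]
  .assert(length(per) > 0L, "no bait with both protein partners and RNA targets")
  df <- do.call(rbind, per)
  chi <- -2 * sum(log(pmax(df$p_combine, .P_FLOOR)))
  m <- nrow(df)
  df$p_combine <- NULL
  list(per_bait = df, chi_sq = chi, df = 2L * m,
       combined_p = stats::pchisq(chi, df = 2 * m, lower.tail = FALSE))
}

#' Concordance of gene-level and intron-level targets
#'
#' Per bait, the Jaccard index of gene-level target loci and the parent loci
#' of intron-level targets; across baits, the Spearman correlation of
#' gene-target and intron-target counts.
#'
#' @param gene_calls,intron_calls outputs of [call_targets()] on genes and
#'   introns.
#' @param intron_parent named character vector mapping intron feature ids to
#'   parent gene ids.
#' @return list: data.frame `per_bait` (`bait`, `n_gene_targets`,
#'   `n_intron_loci`, `jaccard`), `spearman_rho`.
#' @export
gene_intron_concordance <- function(gene_calls, intron_calls,
                                    intron_parent) {
  baits <- union(unique(gene_calls$bait), unique(intron_calls$bait))
  per <- do.call(rbind, lapply(baits, function(b) {
    g <- unique(gene_calls$feature_id[gene_calls$bait == b &
                                        gene_calls$pass])
    ii <- unique(intron_calls$feature_id[intron_calls$bait == b &
                                           intron_calls$pass])
    iloci <- unique(unname(intron_parent[ii]))
    un <- union(g, iloci)
    data.frame(bait = b, n_gene_targets = length(g),
               n_intron_loci = length(iloci),
               jaccard = if (length(un) == 0L) NA_real_
               else length(intersect(g, iloci)) / length(un),
               stringsAsFactors = FALSE)
  }))
  rho <- if (nrow(per) >= 3L)
    stats::cor(per$n_gene_targets, per$n_intron_loci, method = "spearman")
  else NA_real_
  list(per_bait = per, spearman_rho = rho)
}

#' Write an integrated network as edge-list TSV and GraphML
#' @param network an `integrated_network`.
#' @param tsv_path,graphml_path output paths (either may be `NULL`).
#' @export
write_network <- function(network, tsv_path = NULL, graphml_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(network$edges, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path)) {
    e <- network$edges
    nodes <- unique(c(e$bait, e$gene))
    lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
               '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
               '<key id="type" for="edge" attr.name="type" attr.type="string"/>',
               '<graph edgedefault="directed">',
               sprintf('<node id="%s"/>', nodes),
               sprintf('<edge source="%s" target="%s"><data key="type">%s</data></edge>',
                       e$bait, e$gene, e$type),
               "</graph>", "</graphml>")
    writeLines(lines, graphml_path)
  }
  invisible(network)
}
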