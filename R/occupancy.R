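# Gene x RBP occupancy statistics.
#
# The occupancy null is a Poisson-binomial: each bait binds a given RNA
# independently with its own probability p_j, estimated as the bait's target
# count over the size of the bound universe (RNAs bound by at least one
# bait). The high-occupancy tail is conditioned on membership in that
# universe by renormalizing with 1 - P(X = 0).

#' Build the gene x bait occupancy matrix from binding calls
#'
#' @param calls output of [call_targets()]; only passing rows are used.
#' @return object of class `binding_matrix`: logical `occupancy`
#'   (genes x baits), numeric `strength` (-log10 local IDR, 0 where
#'   unbound), per-bait target counts `n_targets`, and the bound universe.
#' @export
build_binding_matrix <- function(calls) {
  cc <- calls[calls$pass, , drop = FALSE]
  baits <- sort(unique(calls$bait))
  if (nrow(cc) == 0L) {
    occ <- matrix(FALSE, 0L, length(baits), dimnames = list(NULL, baits))
    return(structure(list(occupancy = occ, strength = occ * 0,
                          n_targets = colSums(occ),
                          universe = character(0)),
                     class = "binding_matrix"))
  }
  dup <- duplicated(cc[, c("feature_id", "bait")])
  if (any(dup)) {
    warning("duplicate (gene, bait) calls; keeping minimum local IDR")
    cc <- cc[order(cc$local_idr), , drop = FALSE]
    cc <- cc[!duplicated(cc[, c("feature_id", "bait")]), , drop = FALSE]
  }
  genes <- sort(unique(cc$feature_id))
  occ <- matrix(FALSE, length(genes), length(baits),
                dimnames = list(genes, baits))
  str <- matrix(0, length(genes), length(baits),
                dimnames = list(genes, baits))
  occ[cbind(cc$feature_id, cc$bait)] <- TRUE
  str[cbind(cc$feature_id, cc$bait)] <- cc$strength
  structure(list(occupancy = occ, strength = str, n_targets = colSums(occ),
                 universe = genes),
            class = "binding_matrix")
}

#' Exact Poisson-binomial PMF by dynamic-programming convolution
#'
#' @param p vector of success probabilities in `[0, 1]`.
#' @return numeric vector of length `length(p) + 1`, P(X = 0..n).
#' @export
poisson_binomial_pmf <- function(p) {
  .assert(all(p >= 0 & p <= 1), "probabilities outside [0,1]")
  pmf <- 1
  for (pj in p) pmf <- c(pmf * (1 - pj), 0) + c(0, pmf * pj)
  pmf
}

#' Poisson-binomial upper tail P(X >= t)
#' @param p vector of success probabilities.
#' @param t integer threshold, `0 <= t <= length(p)`.
#' @export
poisson_binomial_tail <- function(p, t) {
  .assert(t >= 0 && t <= length(p), "t outside 0..n")
  if (t == 0L) return(1)
  pmf <- poisson_binomial_pmf(p)
  sum(pmf[(t + 1L):length(pmf)])
}

#' High-occupancy target (HOT) RNA statistics
#'
#' RNAs bound by at least `hot_fraction` of the baits are HOT. The expected
#' HOT count under independence uses the Poisson-binomial tail at the
#' threshold, conditioned (by default) on binding by at least one bait; the
#' observed count's p-value is the upper binomial tail over the bound
#' universe at the conditioned per-gene tail probability.
#'
#' @param matrix a `binding_matrix`.
#' @param hot_fraction fraction of baits defining "high occupancy",
#'   default 0.5 (threshold `ceiling(n_baits * hot_fraction)`).
#' @param conditioned condition the null on X >= 1 (default TRUE).
#' @return object of class `hot_set`: `threshold`, `hot_genes`, `observed`,
#'   `expected`, `fold`, `p_value`, `tail_prob`.
#' @export
hot_test <- function(matrix, hot_fraction = 0.5, conditioned = TRUE) {
  U <- length(matrix$universe)
  .assert(U > 0L, "bound universe is empty")
  nb <- ncol(matrix$occupancy)
  pj <- matrix$n_targets / U
  .assert(any(pj > 0), "all per-bait probabilities are zero")
  t <- ceiling(nb * hot_fraction)
  pmf <- poisson_binomial_pmf(pj)
  q <- sum(pmf[(t + 1L):length(pmf)])
  if (conditioned) q <- q / (1 - pmf[1L])
  occ_counts <- rowSums(matrix$occupancy)
  hot <- names(occ_counts)[occ_counts >= t]
  observed <- length(hot)
  expected <- U * q
  pval <- stats::pbinom(observed - 1, U, q, lower.tail = FALSE)
  structure(list(threshold = t, hot_genes = hot, observed = observed,
                 expected = expected,
                 fold = observed / max(expected, .Machine$double.xmin),
                 p_value = pval, tail_prob = q, conditioned = conditioned),
            class = "hot_set")
}

#' @export
print.hot_set <- function(x, ...) {
  cat(sprintf(paste0("<hot_set> threshold >=%d baits: observed %d, ",
                     "expected %.3g (fold %.3g), P = %.3g\n"),
              x$threshold, x$observed, x$expected, x$fold, x$p_value))
  invisible(x)
}

#' Tail probability that the maximum occupancy reaches m
#'
#' Under independence across genes, the chance that any RNA in the bound
#' universe is bound by at least `m` baits:
#' `1 - (1 - P(X >= m))^N` with the unconditioned Poisson-binomial tail.
#'
#' @param matrix a `binding_matrix`.
#' @param m occupancy level of interest.
#' @export
max_occupancy_test <- function(matrix, m) {
  nb <- ncol(matrix$occupancy)
  .assert(m <= nb, "m exceeds the number of baits")
  U <- length(matrix$universe)
  pj <- matrix$n_targets / U
  q <- poisson_binomial_tail(pj, m)
  1 - (1 - q)^U
}

#' Hypergeometric overlap tests for every pair of baits
#'
#' @param matrix a `binding_matrix`.
#' @param universe_size size of the gene universe for the hypergeometric
#'   (default: expressed-gene universe must be supplied; falls back to the
#'   bound universe with a warning when `NULL`).
#' @param alpha significance level for the summary count, default 0.01.
#' @return list: data.frame `pairs` (bait_a, bait_b, overlap, p_value),
#'   `n_pairs`, `n_significant`.
#' @export
pairwise_overlap <- function(matrix, universe_size = NULL, alpha = 0.01) {
  baits <- colnames(matrix$occupancy)
  .assert(length(baits) >= 2L, "need >= 2 baits")
  if (is.null(universe_size)) {
    warning("no expressed universe given; using bound universe")
    universe_size <- length(matrix$universe)
  }
  cmb <- utils::combn(baits, 2L)
  res <- apply(cmb, 2L, function(pr) {
    a <- matrix$occupancy[, pr[1L]]; b <- matrix$occupancy[, pr[2L]]
    na <- sum(a); nb_ <- sum(b); k <- sum(a & b)
    p <- if (na == 0L || nb_ == 0L) 1
    else .hyper_upper(k, na, universe_size, nb_)
    c(overlap = k, p_value = p)
  })
  pairs <- data.frame(bait_a = cmb[1L, ], bait_b = cmb[2L, ],
                      overlap = res["overlap", ],
                      p_value = res["p_value", ], stringsAsFactors = FALSE)
  list(pairs = pairs, n_pairs = nrow(pairs),
       n_significant = sum(pairs$p_value < alpha))
}

#' Generic gene-set enrichment test
#'
#' Upper-tail hypergeometric (overlap of query and reference within the
#' universe) or binomial (query draws at rate |reference| / |universe|).
#'
#' @param query,reference,universe character vectors of gene ids; both sets
#'   must be subsets of the universe.
#' @param test `"hypergeometric"` (default) or `"binomial"`.
#' @return list: `overlap`, `fold`, `p_value`, `test`.
#' @export
set_enrichment <- function(query, reference, universe,
                           test = c("hypergeometric", "binomial")) {
  test <- match.arg(test)
  .assert(length(universe) > 0L, "empty universe")
  query <- unique(query); reference <- unique(reference)
  .assert(all(query %in% universe) && all(reference %in% universe),
          "query/reference not contained in universe")
  k <- length(intersect(query, reference))
  rate <- length(reference) / length(universe)
  p <- if (test == "hypergeometric")
    .hyper_upper(k, length(reference), length(universe), length(query))
  else stats::pbinom(k - 1, length(query), rate, lower.tail = FALSE)
  fold <- if (length(query) == 0L || rate == 0) NA_real_
  else (k / length(query)) / rate
  list(overlap = k, fold = fold, p_value = p, test = test)
}

#' Two-sided rank-sum test of one bait class against the rest
#'
#' Exact null (Wilcoxon distribution) when both groups have at most
#' `exact_max` members and the data are tie-free; otherwise a normal
#' approximation with tie correction. Classes with fewer than 2 members are
#' flagged with `NA`.
#'
#' @param statistic named numeric vector, one value per bait.
#' @param class_labels character vector parallel to `statistic`.
#' @param exact_max exact-enumeration group-size limit, default 10.
#' @return data.frame: `class`, `n`, `p_value`.
#' @export
class_rank_sum <- function(statistic, class_labels, exact_max = 10L) {
  .assert(length(statistic) == length(class_labels), "length mismatch")
  .assert(length(unique(class_labels)) >= 2L, "need >= 2 classes")
  out <- lapply(unique(class_labels), function(cl) {
    x <- statistic[class_labels == cl]
    y <- statistic[class_labels != cl]
    if (length(x) < 2L)
      return(data.frame(class = cl, n = length(x), p_value = NA_real_))
    data.frame(class = cl, n = length(x),
               p_value = rank_sum_test(x, y, exact_max))
  })
  do.call(rbind, out)
}

#' Two-sided Wilcoxon rank-sum p-value
#' @inheritParams class_rank_sum
#' @param x,y the two groups.
#' @export
rank_sum_test <- function(x, y, exact_max = 10L) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2   # Mann-Whitney U for x
  ties <- any(duplicated(c(x, y)))
  if (!ties && m <= exact_max && n <= exact_max) {
    p <- if (W > m * n / 2)
      2 * stats::pwilcox(W - 1, m, n, lower.tail = FALSE)
    else 2 * stats::pwilcox(W, m, n)
    return(min(p, 1))
  }
  muW <- m * n / 2
  tie_tab <- table(r)
  sig2 <- m * n / 12 * ((m + n + 1) -
                          sum(tie_tab^3 - tie_tab) / ((m + n) * (m + n - 1)))
  if (sig2 <= 0) return(1)
  z <- (W - muW) / sqrt(sig2)
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' Down-the-rank-list enrichment curve
#'
#' Targets of a bait are ranked by local IDR (ascending, strongest first)
#' and split into consecutive non-overlapping bins; each bin's overlap with
#' a gene set is scored by the -log10 upper-tail hypergeometric p-value
#' against the expressed universe.
#'
#' @param ranked_genes character vector of target genes, strongest first.
#' @param gene_set character vector (subset of universe).
#' @param universe expressed-gene universe.
#' @param bin bin size, default 100.
#' @return data.frame: `bin`, `from`, `to`, `overlap`, `neg_log10_p`.
#' @export
rank_list_enrichment <- function(ranked_genes, gene_set, universe,
                                 bin = 100L) {
  n <- length(ranked_genes)
  .assert(n > 0L, "no ranked targets")
  if (n < bin) warning("fewer targets than one full bin")
  starts <- seq(1L, n, by = bin)
  out <- lapply(seq_along(starts), function(i) {
    idx <- starts[i]:min(starts[i] + bin - 1L, n)
    g <- ranked_genes[idx]
    k <- length(intersect(g, gene_set))
    p <- .hyper_upper(k, length(intersect(gene_set, universe)),
                      length(universe), length(g))
    data.frame(bin = i, from = idx[1L], to = idx[length(idx)], overlap = k,
               neg_log10_p = -log10(max(p, .P_FLOOR)))
  })
  do.call(rbind, out)
}

#' Median rank-list enrichment curve across baits
#'
#' @param curves list of data.frames from [rank_list_enrichment()], one per
#'   bait.
#' @return data.frame with `bin` and `median_neg_log10_p` over the bins
#'   present in every curve.
#' @export
median_rank_curve <- function(curves) {
  nb <- min(vapply(curves, nrow, 0L))
  .assert(nb >= 1L, "empty curves")
  data.frame(bin = seq_len(nb),
             median_neg_log10_p = vapply(seq_len(nb), function(i)
               stats::median(vapply(curves, function(cv)
                 cv$neg_log10_p[i], 0)), 0))
}
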