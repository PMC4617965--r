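# Per-replicate negative-binomial enrichment testing.
#
# The machinery mirrors the classic count-based differential pipeline:
# median-of-ratios size factors, per-feature method-of-moments dispersion
# shrunk toward a gamma-family mean-dispersion trend, and an exact-style
# conditional NB test of one IP replicate against the pooled controls.

#' Assemble a count table with its sample sheet
#'
#' @param counts integer matrix, features x samples.
#' @param sample_sheet data.frame with columns `sample_id`, `bait`
#'   (NA/"" for controls), `replicate`, `is_control`.
#' @return object of class `count_table`.
#' @export
count_table <- function(counts, sample_sheet) {
  counts <- as.matrix(counts)
  .assert(all(counts >= 0) && all(counts == round(counts)),
          "counts must be non-negative integers")
  .assert(all(c("sample_id", "bait", "replicate", "is_control") %in%
                names(sample_sheet)), "incomplete sample sheet")
  .assert(setequal(colnames(counts), sample_sheet$sample_id),
          "sample sheet does not match count columns")
  counts <- counts[, sample_sheet$sample_id, drop = FALSE]
  structure(list(counts = counts, sample_sheet = sample_sheet),
            class = "count_table")
}

#' Read a count table and sample sheet from TSV files
#' @param counts_path TSV, first column feature ids, remaining columns samples.
#' @param sheet_path TSV sample sheet.
#' @export
read_count_table <- function(counts_path, sheet_path) {
  df <- utils::read.delim(counts_path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  sheet$is_control <- as.logical(sheet$is_control)
  count_table(m, sheet)
}

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median, over features with nonzero counts in
#' every sample, of that sample's count divided by the feature's geometric
#' mean across samples.
#'
#' @param counts matrix or `count_table`.
#' @return positive numeric vector, one per sample.
#' @export
estimate_size_factors <- function(counts) {
  m <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  use <- rowSums(m == 0) == 0L
  .assert(any(use), paste("no feature with nonzero counts in all samples;",
                          "cannot normalize (check library quality)"))
  lg <- rowMeans(log(m[use, , drop = FALSE]))
  sf <- apply(m[use, , drop = FALSE], 2L, function(col)
    exp(stats::median(log(col) - lg)))
  .assert(all(sf > 0), "non-positive size factor")
  sf
}

#' Trend-shrunk NB dispersion estimates from control samples
#'
#' Method-of-moments dispersion per feature from the normalized control
#' counts (NB variance model mu + alpha * mu^2), then empirical-Bayes
#' shrinkage toward a gamma-family regression of dispersion on base mean
#' (alpha_trend = a0 + a1 / mu). By default the shrinkage weight is set per
#' feature from the variance ratio in log space: the delta-method sampling
#' variance of the raw log dispersion against the prior spread of true log
#' dispersions around the trend (estimated robustly from the residuals).
#' A numeric `shrink` in [0,1] forces that fixed weight instead.
#'
#' @param counts `count_table` (controls are taken from the sample sheet) or
#'   a plain matrix of control counts.
#' @param size_factors per-sample factors for the control samples.
#' @param shrink `"adaptive"` (default) or a fixed trend weight in [0,1].
#' @return list: `alpha` (per-feature dispersion used), `alpha_raw`,
#'   `alpha_trend`, `base_mean`, `shrink_weight`, trend coefficients.
#' @export
estimate_dispersions <- function(counts, size_factors = NULL,
                                 shrink = "adaptive") {
  if (inherits(counts, "count_table")) {
    ctrl <- counts$sample_sheet$sample_id[counts$sample_sheet$is_control]
    m <- counts$counts[, ctrl, drop = FALSE]
    if (is.null(size_factors)) size_factors <- estimate_size_factors(m)
    if (!is.null(names(size_factors))) size_factors <- size_factors[ctrl]
  } else {
    m <- as.matrix(counts)
    if (is.null(size_factors)) size_factors <- estimate_size_factors(m)
  }
  .assert(ncol(m) >= 2L, "need >= 2 control samples to estimate dispersion")
  norm <- sweep(m, 2L, size_factors, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  xi <- mean(1 / size_factors)
  alpha_raw <- ifelse(mu > 0, (v - xi * mu) / mu^2, 0)
  alpha_raw <- pmax(alpha_raw, 1e-8)
  # gamma-family trend alpha ~ a0 + a1/mu on features with real signal
  ok <- mu > 1 & alpha_raw > 1e-8
  if (sum(ok) >= 10L) {
    fit <- tryCatch(
      stats::glm(alpha_raw[ok] ~ I(1 / mu[ok]),
                 family = stats::Gamma(link = "identity"),
                 start = c(stats::median(alpha_raw[ok]), 1)),
      error = function(e) NULL)
    if (!is.null(fit) && all(stats::coef(fit) >= 0)) {
      a <- stats::coef(fit)
    } else a <- c(stats::median(alpha_raw[ok]), 0)
  } else a <- c(stats::median(alpha_raw), 0)
  alpha_trend <- pmax(a[1L] + a[2L] / pmax(mu, 1e-8), 1e-8)
  if (identical(shrink, "adaptive")) {
    # parametric bootstrap under NB(sf_j * mu_i, alpha_trend_i): bias and
    # sampling variance of the raw log dispersion, smoothed over bins of
    # alpha * mu (the quantity that governs how informative the data are
    # about the dispersion), then variance-ratio shrinkage toward the trend
    bt <- .bootstrap_log_disp_noise(mu, alpha_trend, size_factors, xi)
    log_raw <- log(alpha_raw) - bt$bias
    v_samp <- bt$v_samp
    sane <- mu > 5 & alpha_raw > 1e-6
    tau2 <- if (sum(sane) >= 10L) {
      resid <- log_raw[sane] - log(alpha_trend[sane])
      # lightly trimmed variance: robust to floor artifacts without the
      # systematic shrinkage a MAD implies for skewed log dispersions
      lo <- stats::quantile(resid, 0.01); hi <- stats::quantile(resid, 0.99)
      max(stats::var(resid[resid >= lo & resid <= hi]) -
            stats::median(v_samp[sane]), 0.04)
    } else 0.04
    w <- v_samp / (v_samp + tau2)
  } else {
    .assert(is.numeric(shrink) && shrink >= 0 && shrink <= 1,
            "shrink must be 'adaptive' or a weight in [0,1]")
    log_raw <- log(alpha_raw)
    w <- rep(shrink, length(mu))
  }
  alpha <- exp(w * log(alpha_trend) + (1 - w) * log_raw)
  list(alpha = pmax(alpha, 1e-8), alpha_raw = alpha_raw,
       alpha_trend = alpha_trend, base_mean = mu, shrink_weight = w,
       tau2 = if (identical(shrink, "adaptive")) tau2 else NA_real_,
       trend_coef = a)
}

# Monte-Carlo calibration of the raw MoM log-dispersion estimator: per
# feature, draw B replicate control vectors from NB(sf_j * mu_i, trend_i),
# recompute the raw estimate, and record the mean (bias) and variance
# (sampling noise) of log(alpha_hat / alpha_true) within quantile bins of
# log(alpha * mu). Uses its own RNG stream and restores the caller's.
.bootstrap_log_disp_noise <- function(mu, alpha_trend, sf, xi, B = 60L,
                                      n_bins = 15L) {
  n <- length(mu)
  with_seed(777L, {
    ok <- mu > 0
    idx <- rep(which(ok), each = B)
    nm <- length(idx)
    ncol_m <- length(sf)
    draws <- vapply(seq_len(ncol_m), function(j)
      stats::rnbinom(nm, mu = sf[j] * mu[idx],
                     size = 1 / alpha_trend[idx]) / sf[j],
      numeric(nm))
    mb <- rowMeans(draws)
    vb <- (rowSums(draws^2) - ncol_m * mb^2) / (ncol_m - 1)
    ab <- pmax((vb - xi * mb) / pmax(mb, 1e-8)^2, 1e-8)
    r <- log(ab) - log(alpha_trend[idx])
    # bin by information content alpha * mu
    info <- log(pmax(alpha_trend * pmax(mu, 1e-8), 1e-12))
    br <- unique(stats::quantile(info[ok], probs = seq(0, 1,
                                                       length.out = n_bins)))
    bin_of <- findInterval(info, br, all.inside = TRUE)
    bias <- v_samp <- numeric(n)
    for (b in unique(bin_of[ok])) {
      sel <- bin_of[idx] == b
      bias[bin_of == b] <- mean(r[sel])
      v_samp[bin_of == b] <- stats::var(r[sel])
    }
    v_samp[v_samp <= 0 | !ok] <- 4
    list(bias = bias, v_samp = v_samp)
  })
}

#' Exact-style conditional NB test of one IP sample against controls
#'
#' Conditions on the total count across the two groups: with a shared
#' per-unit abundance estimated from the pooled normalized counts, the
#' p-value is the summed probability of all splits of the total that are as
#' likely or less likely than the observed one. The control group is pooled
#' into a single NB with matched mean and variance. Fold change is the ratio
#' of normalized IP count to the normalized control mean, with a pseudocount
#' of 0.5 on both sides.
#'
#' @param k_ip IP count (one replicate).
#' @param k_ctrl integer vector of control counts.
#' @param s_ip,s_ctrl size factors for the IP sample and the controls.
#' @param alpha NB dispersion for the feature.
#' @return list: `p_value`, `fold_change`, `base_mean`, `undefined` flag for
#'   all-zero features.
#' @export
nb_test <- function(k_ip, k_ctrl, s_ip, s_ctrl, alpha) {
  ks <- k_ip + sum(k_ctrl)
  sA <- s_ip; sB <- sum(s_ctrl)
  q <- ks / (sA + sB)
  fc <- (k_ip / s_ip + 0.5) / (mean(k_ctrl / s_ctrl) + 0.5)
  if (ks == 0L)
    return(list(p_value = 1, fold_change = fc, base_mean = 0,
                undefined = TRUE))
  muA <- sA * q; muB <- sB * q
  sizeA <- 1 / alpha
  # pooled controls: variance sum  sB*q + alpha*q^2*sum(s^2)
  sizeB <- sum(s_ctrl)^2 / (alpha * sum(s_ctrl^2))
  a <- 0:ks
  logp <- stats::dnbinom(a, mu = muA, size = sizeA, log = TRUE) +
    stats::dnbinom(ks - a, mu = muB, size = sizeB, log = TRUE)
  lobs <- logp[k_ip + 1L]
  keep <- logp <= lobs + 1e-7
  # normalized within the conditional slice
  mx <- max(logp)
  p <- sum(exp(logp[keep] - mx)) / sum(exp(logp - mx))
  list(p_value = min(p, 1), fold_change = fc, base_mean = q,
       undefined = FALSE)
}

#' Per-replicate enrichment results for every bait
#'
#' Runs the conditional NB test for every feature of every IP replicate
#' against the pooled controls. By default the p-value integrates over the
#' dispersion uncertainty: a per-feature posterior over log dispersion
#' (control-sample NB likelihood times the empirical-Bayes log-normal prior
#' centered on the trend) is evaluated on a small grid, and the reported
#' p-value is the posterior-weighted average of the conditional [nb_test()]
#' p-values. With a handful of controls this posterior-predictive form is
#' markedly better calibrated than plugging in a point estimate.
#'
#' @param counts a [count_table()].
#' @param size_factors optional; estimated from all samples if missing.
#' @param dispersions optional; estimated from controls if missing.
#' @param dispersion_uncertainty integrate over the dispersion posterior
#'   (default TRUE; requires adaptive dispersion estimates).
#' @param posterior_k grid size for the log-dispersion posterior, default 9.
#' @return data.frame (one row per feature x bait x replicate) with columns
#'   `feature_id`, `bait`, `replicate`, `base_mean`, `fold_change`,
#'   `p_value`, `undefined`.
#' @export
enrichment_results <- function(counts, size_factors = NULL,
                               dispersions = NULL,
                               dispersion_uncertainty = TRUE,
                               posterior_k = 9L) {
  sheet <- counts$sample_sheet
  m <- counts$counts
  if (is.null(size_factors)) size_factors <- estimate_size_factors(m)
  names(size_factors) <- colnames(m)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(counts,
                                                                size_factors)
  alpha <- dispersions$alpha
  ctrl_ids <- sheet$sample_id[sheet$is_control]
  .assert(length(ctrl_ids) >= 2L, "need >= 2 control samples")
  n <- nrow(m)
  use_post <- isTRUE(dispersion_uncertainty) &&
    is.finite(dispersions$tau2 %||% NA_real_)
  if (use_post) {
    # posterior over log alpha from the controls, shared grid offsets
    tau <- sqrt(dispersions$tau2)
    offs <- seq(-2.5, 2.5, length.out = posterior_k) * tau
    sfc <- size_factors[ctrl_ids]
    qc <- rowMeans(sweep(m[, ctrl_ids, drop = FALSE], 2L, sfc, "/"))
    lw_prior <- stats::dnorm(offs, 0, tau, log = TRUE)
    post_w <- matrix(0, n, posterior_k)
    # the trend tracks the MEAN dispersion; the log-normal prior center is
    # mean-matched at log(trend) - tau2/2
    ag <- exp(outer(log(dispersions$alpha_trend) - dispersions$tau2 / 2,
                    offs, "+"))
    for (k in seq_len(posterior_k)) {
      ll <- rowSums(vapply(ctrl_ids, function(s)
        stats::dnbinom(m[, s], mu = size_factors[s] * qc,
                       size = 1 / ag[, k], log = TRUE),
        numeric(n)))
      post_w[, k] <- ll + lw_prior[k]
    }
    post_w <- exp(post_w - apply(post_w, 1L, max))
    post_w <- post_w / rowSums(post_w)
    post_w[post_w < 0.02] <- 0         # prune negligible grid points
    post_w <- post_w / rowSums(post_w)
  }
  ip <- sheet[!sheet$is_control, , drop = FALSE]
  out <- vector("list", nrow(ip))
  for (j in seq_len(nrow(ip))) {
    sid <- ip$sample_id[j]
    res <- lapply(seq_len(n), function(i) {
      if (!use_post)
        return(nb_test(m[i, sid], m[i, ctrl_ids], size_factors[sid],
                       size_factors[ctrl_ids], alpha[i]))
      ks <- which(post_w[i, ] > 0)
      parts <- lapply(ks, function(k)
        nb_test(m[i, sid], m[i, ctrl_ids], size_factors[sid],
                size_factors[ctrl_ids], ag[i, k]))
      r <- parts[[1L]]
      r$p_value <- sum(post_w[i, ks] *
                         vapply(parts, `[[`, 0, "p_value"))
      r
    })
    out[[j]] <- data.frame(
      feature_id = rownames(m), bait = ip$bait[j],
      replicate = ip$replicate[j],
      base_mean = vapply(res, `[[`, 0, "base_mean"),
      fold_change = vapply(res, `[[`, 0, "fold_change"),
      p_value = vapply(res, `[[`, 0, "p_value"),
      undefined = vapply(res, `[[`, TRUE, "undefined"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Call reproducible binding targets for every bait
#'
#' Fits the two-replicate IDR copula mixture to the per-replicate NB
#' p-values of each bait and applies the joint threshold: local IDR at or
#' below `idr_threshold` AND fold change at or above `fc_threshold` in every
#' replicate.
#'
#' @param enr output of [enrichment_results()].
#' @param idr_threshold local IDR cutoff, default 0.10.
#' @param fc_threshold per-replicate fold-change cutoff, default 1.5.
#' @return data.frame of binding calls sorted by local IDR: `feature_id`,
#'   `bait`, `local_idr`, `global_idr`, `min_fold_change`, `pass`,
#'   `strength` (-log10 local IDR, capped at 12).
#' @export
call_targets <- function(enr, idr_threshold = 0.10, fc_threshold = 1.5) {
  out <- lapply(split(enr, enr$bait), function(be) {
    be <- be[order(be$replicate, be$feature_id), , drop = FALSE]
    reps <- sort(unique(be$replicate))
    if (length(reps) != 2L)
      warning(sprintf("bait %s has %d replicates; FC required in all",
                      be$bait[1L], length(reps)))
    wide_p <- stats::reshape(
      be[, c("feature_id", "replicate", "p_value")],
      idvar = "feature_id", timevar = "replicate", direction = "wide")
    wide_fc <- stats::reshape(
      be[, c("feature_id", "replicate", "fold_change")],
      idvar = "feature_id", timevar = "replicate", direction = "wide")
    pm <- as.matrix(wide_p[, -1L, drop = FALSE])
    fcm <- as.matrix(wide_fc[, -1L, drop = FALSE])
    if (ncol(pm) >= 2L) {
      idr <- fit_idr(pm[, 1L], pm[, 2L])
      local_idr <- idr$local_idr; global_idr <- idr$global_idr
    } else {
      local_idr <- pm[, 1L]; global_idr <- pm[, 1L]
    }
    minfc <- apply(fcm, 1L, min)
    df <- data.frame(
      feature_id = wide_p$feature_id, bait = be$bait[1L],
      local_idr = local_idr, global_idr = global_idr,
      min_fold_change = minfc,
      pass = local_idr <= idr_threshold & minfc >= fc_threshold,
      stringsAsFactors = FALSE)
    df$strength <- -log10(pmax(df$local_idr, 1e-12))
    df$strength <- pmin(df$strength, 12)
    df[order(df$local_idr), , drop = FALSE]
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-level and intron-level differential binding in one call
#'
#' Convenience wrapper: size factors, dispersions, per-replicate tests and
#' IDR-filtered calls.
#' @inheritParams call_targets
#' @param counts a [count_table()].
#' @return list with `enrichment` and `calls`.
#' @export
differential_binding <- function(counts, idr_threshold = 0.10,
                                 fc_threshold = 1.5) {
  enr <- enrichment_results(counts)
  list(enrichment = enr,
       calls = call_targets(enr, idr_threshold, fc_threshold))
}

#' Keep intron features whose span overlaps no exon of any gene
#'
#' The intron universe for intron-mode testing: collapsed intron regions
#' whose genomic interval intersects no exon of any transcript of any gene
#' on the same contig.
#'
#' @param partitions named list of `region_partition`.
#' @param genes named list of `gene_model`.
#' @return data.frame of qualifying introns: `feature_id`
#'   (`<gene>.intron<i>`), `gene_id`, `chrom`, `start`, `end`.
#' @export
intron_features <- function(partitions, genes) {
  exons_by_chrom <- list()
  for (g in genes) {
    ex <- do.call(rbind, lapply(g$transcripts, `[[`, "exons"))
    exons_by_chrom[[g$chrom]] <- rbind(exons_by_chrom[[g$chrom]], ex)
  }
  rows <- list()
  for (p in partitions) {
    ir <- p$regions[p$regions$label == "intron", , drop = FALSE]
    if (nrow(ir) == 0L) next
    ex <- exons_by_chrom[[p$chrom]]
    keep <- vapply(seq_len(nrow(ir)), function(i)
      !any(ex[, 1L] < ir$end[i] & ex[, 2L] > ir$start[i]), TRUE)
    ir <- ir[keep, , drop = FALSE]
    if (nrow(ir) == 0L) next
    rows[[p$gene_id]] <- data.frame(
      feature_id = sprintf("%s.intron%d", p$gene_id, seq_len(nrow(ir))),
      gene_id = p$gene_id, chrom = p$chrom,
      start = ir$start, end = ir$end, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    warning("no qualifying intron features after exon-overlap filter")
    return(data.frame(feature_id = character(0), gene_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Binding calls as BED6
#'
#' One line per passing call; score = round(1000 * min(1, strength / 12)).
#' @param calls output of [call_targets()] (passing rows are written).
#' @param genes named list of `gene_model` for spans.
#' @param path output path.
#' @export
write_calls_bed <- function(calls, genes, path) {
  cc <- calls[calls$pass & calls$feature_id %in% names(genes), , drop = FALSE]
  lines <- vapply(seq_len(nrow(cc)), function(i) {
    g <- genes[[cc$feature_id[i]]]
    sprintf("%s\t%d\t%d\t%s|%s\t%d\t%s", g$chrom, g$locus[1L], g$locus[2L],
            cc$bait[i], cc$feature_id[i],
            as.integer(round(1000 * min(1, cc$strength[i] / 12))), g$strand)
  }, "")
  writeLines(lines, path)
  invisible(path)
}
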