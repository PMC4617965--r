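test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 5, 10, 20, 5), ncol = 2,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m)), c(1, 1))
  m2 <- cbind(s1 = c(10, 20, 5), s2 = 2 * c(10, 20, 5))
  rownames(m2) <- paste0("g", 1:3)
  expect_equal(unname(estimate_size_factors(m2)),
               c(1 / sqrt(2), sqrt(2)))
  m3 <- matrix(c(10, 40), nrow = 1,
               dimnames = list("g1", c("s1", "s2")))
  expect_equal(unname(estimate_size_factors(m3)), c(0.5, 2))
  # no feature with all-nonzero counts is a hard error
  m4 <- matrix(c(0, 5, 5, 0), 2)
  expect_error(estimate_size_factors(m4), "cannot normalize")
})

test_that("normalization fixed point: equal medians of ratios", {
  set.seed(1)
  m <- matrix(rnbinom(2000, mu = 100, size = 5), ncol = 4)
  m <- sweep(m, 2, c(0.5, 1, 1.5, 2), "*")
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  sf <- estimate_size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  lg <- rowMeans(log(norm[rowSums(norm == 0) == 0, ]))
  med <- apply(norm[rowSums(norm == 0) == 0, ], 2,
               function(col) median(log(col) - lg))
  expect_equal(max(med) - min(med), 0, tolerance = 1e-8)
})

test_that("dispersion estimation recovers known regimes", {
  set.seed(2)
  n <- 2000
  # constant counts -> raw dispersion pinned at the floor
  mc <- matrix(50, 5, 4, dimnames = list(paste0("g", 1:5), NULL))
  d <- estimate_dispersions(mc, rep(1, 4))
  expect_true(all(d$alpha_raw <= 1e-8 + 1e-12))
  # Poisson counts -> fitted dispersion near zero
  mp <- matrix(rpois(n * 10, lambda = 200), n, 10)
  rownames(mp) <- paste0("g", 1:n)
  dp <- estimate_dispersions(mp, rep(1, 10))
  expect_lt(median(dp$alpha), 0.01)
  # NB alpha = 0.2 -> recovered within +/- 0.05
  mn <- matrix(rnbinom(n * 10, mu = 300, size = 1 / 0.2), n, 10)
  rownames(mn) <- paste0("g", 1:n)
  dn <- estimate_dispersions(mn, rep(1, 10))
  expect_lt(abs(median(dn$alpha) - 0.2), 0.05)
  expect_error(estimate_dispersions(mn[, 1, drop = FALSE], 1),
               ">= 2 control")
})

test_that("nb_test centers at the null and flags all-zero features", {
  r <- nb_test(100L, rep(100L, 4), 1, rep(1, 4), 0.05)
  expect_gt(r$p_value, 0.5)
  expect_equal(r$fold_change, 1, tolerance = 0.01)
  z <- nb_test(0L, rep(0L, 4), 1, rep(1, 4), 0.05)
  expect_equal(z$p_value, 1)
  expect_true(z$undefined)
})

test_that("nb_test matches the enumeration oracle on small totals", {
  cases <- expand.grid(k_ip = c(0L, 3L, 10L, 25L),
                       k_c = c(1L, 5L, 12L),
                       alpha = c(0.01, 0.1, 0.5),
                       s_ip = c(0.8, 1.3))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    k_ctrl <- rep(cs$k_c, 3)
    if (cs$k_ip + sum(k_ctrl) > 50) next
    got <- nb_test(cs$k_ip, k_ctrl, cs$s_ip, c(1, 1.1, 0.9), cs$alpha)
    want <- oracle_nb_test(cs$k_ip, k_ctrl, cs$s_ip, c(1, 1.1, 0.9),
                           cs$alpha)
    expect_equal(got$p_value, want, tolerance = 1e-10,
                 info = paste(unlist(cs), collapse = "/"))
  }
})

test_that("type-I control on null fixtures (scaled down)", {
  # null world, modest size so the default suite stays fast
  rates <- vapply(1:3, function(s) {
    cfg <- simulation_config(seed = 100 + s, n_genes = 250, n_rbps = 4,
                             target_fraction = 0, hot_fraction_genes = 0)
    sim <- simulate_rip_experiment(cfg)
    calls <- suppressMessages(
      differential_binding(sim$gene_counts)$calls)
    mean(calls$pass)
  }, 0)
  expect_lt(mean(rates), 0.02)
})

test_that("fit_idr separates a reproducible component and ranks by it", {
  m <- sim_idr_mixture(21, n = 1000)
  f <- suppressMessages(fit_idr(m$p1, m$p2))
  # strong features (both replicates small p) get local IDR near zero
  strong <- m$p1 < exp(-4) & m$p2 < exp(-4)
  expect_lt(median(f$local_idr[strong]), 0.05)
  # latent reproducible features score lower than noise features
  expect_lt(median(f$local_idr[m$latent == 1]),
            median(f$local_idr[m$latent == 0]))
  # global IDR is the running mean of sorted local IDRs: non-decreasing
  o <- order(f$local_idr)
  expect_true(all(diff(f$global_idr[o]) >= -1e-12))
  expect_true(all(f$global_idr[o] <= f$local_idr[o][length(o)] + 1e-12))
})

test_that("fit_idr is invariant to strictly monotone score transforms", {
  m <- sim_idr_mixture(22, n = 500)
  f1 <- suppressMessages(fit_idr(m$p1, m$p2))
  f2 <- suppressMessages(fit_idr(m$p1^3, sqrt(m$p2)))  # rank-preserving
  expect_equal(f1$local_idr, f2$local_idr, tolerance = 1e-10)
  expect_equal(f1$rho, f2$rho, tolerance = 1e-10)
})

test_that("fit_idr rejects degenerate input and survives perfect copies", {
  expect_error(suppressMessages(fit_idr(rep(0.5, 100), runif(100))),
               "degenerate")
  set.seed(23)
  p <- c(10^-runif(300, 3, 12), runif(700))
  f <- suppressMessages(fit_idr(p, p))
  expect_lt(median(f$local_idr[p < 1e-3]), 0.05)
  expect_gt(f$pi1, 0.2)
})

test_that("independent replicates yield almost no confident discoveries", {
  set.seed(24)
  f <- suppressMessages(fit_idr(runif(2000), runif(2000)))
  expect_lt(mean(f$local_idr <= 0.1), 0.02)
})

test_that("call_targets enforces both thresholds and orders by IDR", {
  cfg <- simulation_config(seed = 31, n_genes = 100, n_rbps = 3,
                           fc_range = c(2, 8), mean_log = log(500))
  sim <- simulate_rip_experiment(cfg)
  enr <- suppressMessages(enrichment_results(sim$gene_counts))
  calls <- suppressMessages(call_targets(enr))
  expect_equal(calls$pass,
               calls$local_idr <= 0.10 & calls$min_fold_change >= 1.5)
  for (b in unique(calls$bait))
    expect_true(!is.unsorted(calls$local_idr[calls$bait == b]))
  expect_true(all(calls$strength <= 12 + 1e-12))
  # global IDR at the local-IDR cutoff stays below the cutoff
  sel <- calls[calls$local_idr <= 0.10, ]
  expect_true(all(sel$global_idr <= 0.10 + 1e-12))
})

test_that("intron_features drops introns overlapping any exon", {
  gA <- fixture_gene_simple("gA")                       # intron [100,150)
  # gB's exon sits inside gA's intron on the same contig
  gB <- gene_model("gB", "chr1",
                   list(transcript_model("gB.1", "gB",
                                         rbind(c(110L, 140L)))))
  parts <- list(gA = collapse_regions(gA), gB = collapse_regions(gB))
  expect_warning(both <- intron_features(parts, list(gA = gA, gB = gB)),
                 "no qualifying intron")
  expect_false("gA.intron1" %in% both$feature_id)
  alone <- intron_features(parts["gA"], list(gA = gA))
  expect_equal(alone$feature_id, "gA.intron1")
  expect_equal(alone$start, 100L)
  expect_equal(alone$end, 150L)
  # gene with zero qualifying introns is absent entirely
  expect_false("gB" %in% both$gene_id)
})

test_that("duplicate replicate counts warn and still produce calls", {
  cfg <- simulation_config(seed = 32, n_genes = 60, n_rbps = 2,
                           n_replicates = 3L)
  sim <- simulate_rip_experiment(cfg)
  enr <- suppressMessages(enrichment_results(sim$gene_counts))
  w <- testthat::capture_warnings(
    calls <- suppressMessages(call_targets(enr)))
  expect_match(w, "3 replicates", all = TRUE)
  expect_length(w, 2L)   # one per bait
  expect_true(nrow(calls) > 0)
})
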