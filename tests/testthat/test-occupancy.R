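test_that("binding matrix assembles occupancy and strengths", {
  calls <- fixture_calls(c("b1", "b2"),
                         list(b1 = c("g1", "g2"), b2 = c("g2", "g3")))
  bm <- build_binding_matrix(calls)
  expect_equal(dim(bm$occupancy), c(3L, 2L))
  expect_equal(unname(bm$n_targets), c(2L, 2L))
  expect_equal(bm$universe, c("g1", "g2", "g3"))
  expect_equal(bm$strength > 0, bm$occupancy)
  # empty calls -> empty matrix
  e <- build_binding_matrix(fixture_calls("b1", list(b1 = "g1"))[0, ])
  expect_equal(nrow(e$occupancy), 0L)
  # duplicate (gene,bait) keeps the smaller local IDR
  dup <- rbind(fixture_calls("b1", list(b1 = "g1"), idr = 0.05),
               fixture_calls("b1", list(b1 = "g1"), idr = 0.001))
  expect_warning(bmd <- build_binding_matrix(dup), "duplicate")
  expect_equal(unname(bmd$strength["g1", "b1"]), 3)
})

test_that("Poisson-binomial DP matches closed forms and enumeration", {
  expect_equal(poisson_binomial_tail(rep(0, 5), 1), 0)
  expect_equal(poisson_binomial_tail(runif(5), 0), 1)
  # equal p reduces to the binomial survival function
  p <- rep(0.5, 20)
  for (t in c(1, 5, 10, 15, 20))
    expect_equal(poisson_binomial_tail(p, t),
                 pbinom(t - 1, 20, 0.5, lower.tail = FALSE),
                 tolerance = 1e-12)
  # exhaustive enumeration for n <= 12
  set.seed(3)
  for (n in c(3, 7, 12)) {
    pr <- runif(n)
    pmf <- poisson_binomial_pmf(pr)
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    for (t in c(0, 1, n %/% 2, n))
      expect_equal(poisson_binomial_tail(pr, t),
                   oracle_poisbin_tail(pr, t), tolerance = 1e-12)
  }
})

test_that("Poisson-binomial tail agrees with a Monte-Carlo oracle (n=20)", {
  set.seed(4)
  pr <- runif(20)
  t <- 8
  q <- poisson_binomial_tail(pr, t)
  draws <- 2e5
  x <- colSums(matrix(runif(20 * draws), 20) < pr)
  mc <- mean(x >= t)
  se <- sqrt(mc * (1 - mc) / draws)
  expect_lt(abs(q - mc), 3 * se + 1e-12)
})

test_that("hot_test thresholds, conditioning and planted recovery", {
  calls <- fixture_calls(sprintf("b%02d", 1:20),
                         setNames(rep(list(c("g1", "g2")), 20),
                                  sprintf("b%02d", 1:20)))
  bm <- build_binding_matrix(calls)
  hot <- hot_test(bm)
  expect_equal(hot$threshold, 10L)       # ceil(20/2)
  expect_equal(hot$observed, 2L)
  expect_true(all(c("g1", "g2") %in% hot$hot_genes))
  # conditioned tail exceeds the unconditioned one
  hot_u <- hot_test(bm, conditioned = FALSE)
  expect_gte(hot$tail_prob, hot_u$tail_prob)
  cfg <- simulation_config(seed = 41, n_genes = 150)
  tr <- simulate_transcriptome(cfg)
  occ <- sapply(tr$truth$targets, function(tg)
    rownames(tr$truth$fold_change) %in% tg)
  rownames(occ) <- rownames(tr$truth$fold_change)
  bound <- occ[rowSums(occ) > 0, ]
  bmt <- structure(list(occupancy = bound, strength = bound * 1,
                        n_targets = colSums(bound),
                        universe = rownames(bound)),
                   class = "binding_matrix")
  ht <- hot_test(bmt)
  expect_true(all(tr$truth$hot_genes %in% ht$hot_genes))
  expect_gt(ht$fold, 3)
  expect_lt(ht$p_value, 1e-6)
})

test_that("max occupancy tail matches independence closed form", {
  calls <- fixture_calls(c("b1", "b2", "b3"),
                         list(b1 = c("g1", "g2", "g3"), b2 = "g1",
                              b3 = c("g1", "g2")))
  bm <- build_binding_matrix(calls)
  q <- poisson_binomial_tail(bm$n_targets / 3, 2)
  expect_equal(max_occupancy_test(bm, 2), 1 - (1 - q)^3)
  expect_equal(max_occupancy_test(bm, 0), 1)  # q = 1 at t = 0
  # single-gene universe: p equals the per-gene tail
  one <- build_binding_matrix(fixture_calls("b1", list(b1 = "g1")))
  expect_equal(max_occupancy_test(one, 1),
               poisson_binomial_tail(one$n_targets / 1, 1))
})

test_that("pairwise overlap evaluates every unordered pair", {
  set.seed(5)
  sets <- setNames(lapply(1:20, function(i)
    sprintf("g%02d", sample(40, 10))), sprintf("b%02d", 1:20))
  bm <- build_binding_matrix(fixture_calls(names(sets), sets))
  pw <- pairwise_overlap(bm, universe_size = 100)
  expect_equal(pw$n_pairs, 190L)
  # symmetry in pair order
  i <- 17
  a <- pw$pairs$bait_a[i]; b <- pw$pairs$bait_b[i]
  ka <- sum(bm$occupancy[, a]); kb <- sum(bm$occupancy[, b])
  k <- sum(bm$occupancy[, a] & bm$occupancy[, b])
  expect_equal(pw$pairs$p_value[i],
               phyper(k - 1, kb, 100 - kb, ka, lower.tail = FALSE))
  # identical 5-element columns in a 10-gene universe: p = 1 / C(10,5)
  two <- build_binding_matrix(fixture_calls(
    c("x", "y"), list(x = paste0("g", 1:5), y = paste0("g", 1:5))))
  pw2 <- pairwise_overlap(two, universe_size = 10)
  expect_equal(pw2$pairs$p_value, 1 / choose(10, 5))
  # disjoint target sets: upper-tail p = 1
  dj <- build_binding_matrix(fixture_calls(
    c("x", "y"), list(x = paste0("g", 1:5), y = paste0("g", 6:10))))
  expect_equal(pairwise_overlap(dj, universe_size = 10)$pairs$p_value, 1)
})

test_that("set_enrichment matches the enumeration oracle", {
  U <- paste0("g", 1:12)
  A <- U[1:4]; B <- U[3:8]
  r <- set_enrichment(A, B, U)
  expect_equal(r$p_value, oracle_hyper_upper(r$overlap, B, U, length(A)),
               tolerance = 1e-12)
  # query = reference = universe: fold 1, p 1
  full <- set_enrichment(U, U, U)
  expect_equal(full$fold, 1)
  expect_equal(full$p_value, 1)
  # overlap below expectation: upper-tail p > 0.5
  lo <- set_enrichment(U[1:6], U[5:12], U)
  expect_gt(lo$p_value, 0.5)
  # binomial variant agrees in direction and uses the reference rate
  bi <- set_enrichment(A, B, U, test = "binomial")
  expect_equal(bi$p_value,
               pbinom(r$overlap - 1, 4, 0.5, lower.tail = FALSE))
  expect_error(set_enrichment(c(A, "zz"), B, U), "not contained")
})

test_that("rank-sum test: exact small-sample null and tie handling", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3)), 0.1)
  expect_equal(rank_sum_test(rep(2, 4), rep(2, 5)), 1)
  # large tie-free samples agree with the normal-approx wilcox.test
  set.seed(6)
  x <- rnorm(25); y <- rnorm(30) + 0.5
  expect_equal(rank_sum_test(x, y),
               wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-10)
  cls <- class_rank_sum(c(1, 2, 3, 10, 11, 12, 5),
                        c("a", "a", "a", "b", "b", "b", "c"))
  expect_true(is.na(cls$p_value[cls$class == "c"]))
  expect_lt(cls$p_value[cls$class == "a"], 0.2)
})

test_that("rank-sum null calibration (scaled down)", {
  set.seed(7)
  ps <- replicate(400, {
    v <- rnorm(16)
    rank_sum_test(v[1:8], v[9:16])
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 1e-3)
})

test_that("rank_list_enrichment bins and scores against the universe", {
  universe <- sprintf("g%03d", 1:500)
  gs <- universe[1:60]
  ranked <- c(universe[1:50], universe[101:300])  # head enriched in gs
  expect_warning(short <- rank_list_enrichment(universe[1:40], gs,
                                               universe), "one full bin")
  expect_equal(nrow(short), 1L)
  cur <- rank_list_enrichment(ranked, gs, universe)
  expect_equal(cur$to - cur$from + 1, c(100, 100, 50))
  expect_gt(cur$neg_log10_p[1], cur$neg_log10_p[3])
  # disjoint gene set: flat curve at p = 1
  flat <- rank_list_enrichment(universe[101:300], universe[1:50], universe)
  expect_equal(flat$neg_log10_p, rep(0, 2))
  med <- median_rank_curve(list(cur, cur))
  expect_equal(med$median_neg_log10_p, cur$neg_log10_p)
})
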