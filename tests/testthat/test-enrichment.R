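test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_upper_tail(10, 5, 4, 4), 5 / 210)
  expect_equal(hypergeom_upper_tail(6, 3, 3, 2), 0.5)
  expect_equal(hypergeom_upper_tail(100, 10, 20, 0), 1)
  # spot grid against the subset-enumeration oracle
  for (N in c(6, 9, 12)) for (K in c(2, N %/% 2)) for (m in c(3, N - 2)) {
    for (k in 0:min(K, m)) {
      expect_equal(hypergeom_upper_tail(N, K, m, k),
                   hyper_tail_oracle(N, K, m, k), tolerance = 1e-12)
    }
  }
  expect_error(hypergeom_upper_tail(10, 5, 4, 5), "min")
  # pmf mode sums to one over the support
  for (N in c(20, 60)) {
    K <- N %/% 3; m <- N %/% 2
    pmf <- vapply(0:min(K, m), function(k) {
      hypergeom_upper_tail(N, K, m, k, mode = "pmf")
    }, numeric(1))
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
  }
})

test_that("BH adjustment matches the literal step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(41)
  p <- stats::runif(37)
  expect_equal(bh_fdr(p), bh_oracle(p))
  expect_true(all(bh_fdr(p) >= p))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("module enrichment composes counts with the hypergeometric tail", {
  genes <- sprintf("G%02d", 1:10)
  part <- devcoexpr:::new_module_partition(
    genes, rep(1:2, c(4, 6)), "planted", "planted")
  query <- gene_set(genes[c(1:4, 5)], "q")  # overlaps module1 in 4, module2 in 1
  tab <- enrich_modules(part, query, alpha = 0.05)
  expect_equal(tab$N, c(10, 10))
  expect_equal(tab$K, c(5, 5))
  expect_equal(tab$k, c(4, 1))
  expect_equal(tab$p_hyper[1], hypergeom_upper_tail(10, 5, 4, 4))
  expect_equal(tab$p_hyper[2], hypergeom_upper_tail(10, 5, 6, 1))
  expect_equal(tab$p_hyper[1], hyper_tail_oracle(10, 5, 4, 4))
  expect_true(all(tab$p_fdr >= tab$p_hyper))
  expect_identical(tab$significant, tab$p_fdr < 0.05)
  # a module identical to the query is the most enriched
  part2 <- devcoexpr:::new_module_partition(
    genes, rep(1:2, c(5, 5)), "planted", "planted")
  query2 <- gene_set(genes[1:5], "exact")
  tab2 <- enrich_modules(part2, query2, alpha = 0.05)
  expect_equal(tab2$k[1], 5)
  expect_lt(tab2$p_hyper[1], min(tab2$p_hyper[-1]))
  # empty intersection: K = 0 rows with p = 1 and a warning
  expect_warning(tab3 <- enrich_modules(part, gene_set("ZZZ", "none")),
                 "no gene")
  expect_true(all(tab3$p_hyper == 1))
})

test_that("random queries are flagged at close to the nominal rate", {
  sim <- sim_default()
  genes <- sort(sim$pre$genes)
  part <- devcoexpr:::new_module_partition(
    genes, rep(1:8, each = 50), "fixed", "fixed")
  set.seed(123)
  n_reps <- 200
  flags <- vapply(seq_len(n_reps), function(i) {
    q <- gene_set(sample(genes, 80), "rand", case_normalize = FALSE)
    tab <- enrich_modules(part, q, alpha = 0.05)
    sum(tab$p_hyper < 0.05)
  }, numeric(1))
  rate <- sum(flags) / (n_reps * 8)
  half <- stats::qnorm(0.995) * sqrt(0.05 * 0.95 / (n_reps * 8))
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("permutation p is reproducible, bounded away from 0, and honest at
           the boundary", {
  sim <- sim_default()
  g <- sim$truth$genes
  query <- gene_set(g$gene[g$pair_module %in% 1], "planted")
  p1 <- permutation_pair_survival(sim$pre, query, R = 30, seed = 7)
  p2 <- permutation_pair_survival(sim$pre, query, R = 30, seed = 7)
  expect_identical(p1$null_counts, p2$null_counts)
  expect_equal(p1$p_empirical, (1 + sum(p1$null_counts >=
                                          p1$observed_pairs)) / 31)
  expect_gt(p1$p_empirical, 0)
  # unreachable threshold: observed 0 pairs and every null >= 0 -> p = 1
  q0 <- gene_set(g$gene[is.na(g$pair_module) & is.na(g$expr_module)][1:10],
                 "bg")
  p0 <- permutation_pair_survival(sim$pre, q0, R = 20, min_abs_rho = 0.999,
                                  seed = 8)
  expect_equal(p0$observed_pairs, 0)
  expect_equal(p0$p_empirical, 1)
  expect_error(permutation_pair_survival(sim$pre, query, R = 1e9, seed = 1),
               "cap")
  expect_error(permutation_pair_survival(sim$pre, query, R = 10), "seed")
})

test_that("the permutation p falls as planted co-expression strengthens", {
  res <- vapply(c(0.3, 0.6, 0.9), function(rho_t) {
    cfg <- sim_config(
      n_genes = 120,
      planted_pair_modules = list(
        list(size = 30, trajectory_shape = "prenatal_high",
             rho_target = rho_t)),
      planted_expr_modules = list(), seed = 17)
    sim <- simulate_atlas(cfg)
    pre <- suppressMessages(preprocess_atlas(sim$atlas))
    g <- sim$truth$genes$gene[sim$truth$genes$pair_module %in% 1]
    query <- gene_set(g, "planted")
    perm <- permutation_pair_survival(pre, query, R = 60,
                                      min_abs_rho = 0.6, seed = 18)
    c(rho1 = mean(stage_pair_trajectories(pre, g)$rho[, 1]),
      p = perm$p_empirical)
  }, numeric(2))
  # observed stage-1 correlation rises with the target ...
  expect_true(all(diff(res["rho1", ]) > 0))
  # ... and the permutation p falls (weakest planting is indistinguishable
  # from random sets, strongest is maximally significant)
  expect_true(all(diff(res["p", ]) <= 0))
  expect_lt(res["p", 3], res["p", 1])
  expect_equal(res["p", 3], 1 / 61, ignore_attr = TRUE)
})
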