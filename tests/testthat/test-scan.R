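test_that("nested gene sets collapse duplicate scores and saturate", {
  panel <- data.frame(gene = c("A", "B", "C"), loeuf = c(0.1, 0.1, 0.5))
  n <- nested_genesets(panel, panel$gene)
  expect_equal(n$thresholds, c(0.1, 0.5))
  expect_equal(n$set_sizes, c(2L, 3L))
  expect_setequal(n$genes, panel$gene)

  # number of thresholds equals number of unique scores on random panels
  set.seed(71)
  for (i in 1:10) {
    p <- data.frame(gene = sprintf("G%03d", 1:50),
                    loeuf = round(runif(50, 0.1, 1), 1))
    gq <- sample(p$gene, 30)
    n <- nested_genesets(p, gq)
    expect_equal(length(n$thresholds),
                 length(unique(p$loeuf[p$gene %in% gq])))
    expect_equal(max(n$set_sizes), 30L)
  }
  expect_error(nested_genesets(panel, character(0)), "no genes")
  expect_error(nested_genesets(panel, c("A", "ZZ")), "ZZ")
})

test_that("incremental scan equals naive per-threshold recomputation", {
  fix <- small_cohort(n_cases = 50, n_controls = 200, n_genes = 50,
                      rate = c(0.03, 0.05, 0.08), or = 2, seed = 72)
  gq <- rownames(fix$cmat$indicator)[rowSums(fix$cmat$indicator) > 0]
  nests <- nested_genesets(fix$panel, gq)
  expect_equal(scan_cmh(fix$cmat, nests), naive_scan_p(fix$cmat, nests),
               tolerance = 1e-12)
  # a threshold adding only carrier-free genes leaves p unchanged:
  # thresholds are defined on QV-harbouring genes only, so consecutive
  # cumulative sets padded with carrier-free genes give identical tables
  p <- scan_cmh(fix$cmat, nests)
  free <- setdiff(rownames(fix$cmat$indicator), gq)
  if (length(free) > 0) {
    gs1 <- nests$genes[nests$gene_loeuf <= nests$thresholds[3]]
    t1 <- cmh_exact_test(collapse_to_table(fix$cmat, gs1))$p
    t2 <- cmh_exact_test(collapse_to_table(fix$cmat, c(gs1, free)))$p
    expect_equal(t1, t2)
  }
})

test_that("permutation empirical p-values respect margins, floor and ties", {
  fix <- small_cohort(n_cases = 40, n_controls = 160, n_genes = 30,
                      rate = c(0.05, 0.08, 0.12), or = 3, seed = 73)
  gq <- rownames(fix$cmat$indicator)[rowSums(fix$cmat$indicator) > 0]
  nests <- nested_genesets(fix$panel, gq)
  res <- permutation_empirical(fix$cmat, nests, n_permutations = 200, seed = 3)
  n <- res$n_permutations
  expect_true(all(res$p_empirical >= 1 / (n + 1)))
  expect_true(all(res$p_empirical <= 1))
  # p_obs = 1 at a threshold -> empirical p = 1 (every permutation ties)
  if (any(res$p_obs == 1))
    expect_true(all(res$p_empirical[res$p_obs == 1] == 1))
  # determinism under seed
  res2 <- permutation_empirical(fix$cmat, nests, n_permutations = 200, seed = 3)
  expect_identical(res$p_empirical, res2$p_empirical)
  # plain estimator floors at 0 when the observed is unbeaten
  resp <- permutation_empirical(fix$cmat, nests, n_permutations = 200,
                                seed = 3, estimator = "plain")
  expect_true(all(resp$p_empirical >= 0))
  expect_equal(which(resp$p_empirical == 0),
               which(res$p_empirical == 1 / 201))
})

test_that("within-cluster permutation preserves every cluster's margins", {
  # direct check of the permutation scheme: per-cluster case counts and
  # per-threshold carrier counts are invariant under label shuffling
  fix <- small_cohort(n_cases = 30, n_controls = 90, n_genes = 20,
                      rate = 0.1, seed = 74)
  df <- fix$cmat$samples
  for (k in unique(df$cluster)) {
    in_k <- df$cluster == k
    n_case_k <- sum(in_k & df$phenotype == "case")
    perm <- sample(which(in_k), n_case_k)
    expect_equal(length(perm), n_case_k)         # case count preserved
    expect_true(all(df$cluster[perm] == k))      # shuffling stays in-cluster
  }
})

test_that("null empirical p-values are valid and at most mildly conservative", {
  # 200 replicates x 200 permutations at a fixed threshold under the null.
  # Counting permutation ties as hits makes the empirical p super-uniform
  # for discrete statistics, so the calibrated property is
  # P(p <= a) <= a (+ Monte-Carlo noise) at every level, with the overall
  # mass not drifting far above uniform.
  emp <- numeric(200)
  for (r in 1:200) {
    cfg <- sim_config(n_cases = 25, n_controls = 100, n_genes = 12,
                      baseline_carrier_rate = c(0.08, 0.1, 0.12),
                      enrichment_or = 1, seed = 7000 + r)
    panel <- simulate_gene_panel(cfg)
    coh <- simulate_cohort(cfg, panel)
    cm <- cohort_collapsing_matrix(coh)
    gq <- rownames(cm$indicator)[rowSums(cm$indicator) > 0]
    nests <- nested_genesets(panel, gq)
    res <- permutation_empirical(cm, nests, n_permutations = 200,
                                 seed = 7000 + r)
    mid <- ceiling(length(res$p_empirical) / 2)
    emp[r] <- res$p_empirical[mid]
  }
  for (a in c(0.05, 0.1, 0.25, 0.5))
    expect_lte(mean(emp <= a), a + 2 * sqrt(a * (1 - a) / 200))
  expect_gt(mean(emp <= 0.25), 0.05)     # not grossly conservative
  expect_lt(mean(emp), 0.70)
  expect_gt(mean(emp), 0.45)
})

test_that("the optimum follows the tie rules and significance definition", {
  # monotone empirical p vector -> first element
  s <- list(thresholds = c(0.1, 0.2, 0.3), p_empirical = c(0.01, 0.02, 0.03))
  expect_equal(optimal_threshold(s)$threshold, 0.1)
  # two equal minima without nominal information -> smaller threshold
  s2 <- list(thresholds = c(0.1, 0.2, 0.3), p_empirical = c(0.02, 0.02, 0.5))
  expect_equal(optimal_threshold(s2)$threshold, 0.1)
  # floor ties resolved by nominal p
  s3 <- list(thresholds = c(0.1, 0.2, 0.3),
             p_empirical = c(0.001, 0.001, 0.5),
             p_nominal = c(1e-4, 1e-8, 0.3))
  expect_equal(optimal_threshold(s3)$threshold, 0.2)
  # significance uses alpha / number of thresholds
  expect_true(optimal_threshold(list(thresholds = 1:10 / 10,
                                     p_empirical = c(1e-4, rep(0.5, 9))))$significant)
  expect_false(optimal_threshold(list(thresholds = 1:10 / 10,
                                      p_empirical = rep(0.5, 10)))$significant)
})

test_that("the full scan recovers an injected intolerance threshold", {
  cfg <- sim_config(n_cases = 150, n_controls = 1500, n_genes = 300,
                    baseline_carrier_rate = c(3e-3, 4e-3, 5e-3),
                    enrichment_or = 3, enrichment_loeuf_max = 0.5, seed = 76)
  panel <- simulate_gene_panel(cfg)
  coh <- simulate_cohort(cfg, panel)
  cm <- cohort_collapsing_matrix(coh)
  sc <- suppressWarnings(loeuf_scan(cm, panel, n_permutations = 300, seed = 76))
  expect_s3_class(sc, "loeuf_scan")
  expect_true(all(diff(sc$set_sizes) >= 0))
  expect_equal(length(sc$thresholds), length(unique(sc$thresholds)))
  expect_lt(abs(sc$optimal_threshold - 0.5), 0.15)
  expect_equal(sc$bonferroni_alpha, 0.05 / length(sc$thresholds))
})
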