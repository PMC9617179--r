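test_that("configuration validation names the offending field", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(cluster_mixture = c(0.5, 0.4, 0.2)), "cluster_mixture")
  expect_error(sim_config(enrichment_or = 0.5), "enrichment_or")
  expect_error(sim_config(loeuf_range = c(0, 2)), "loeuf_range")
  expect_error(sim_config(ultrarare_fraction = 1.5), "ultrarare_fraction")
})

test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_cases = 30, n_controls = 100, n_genes = 100, seed = 5)
  p1 <- simulate_gene_panel(cfg); p2 <- simulate_gene_panel(cfg)
  expect_identical(p1, p2)
  c1 <- simulate_cohort(cfg, p1); c2 <- simulate_cohort(cfg, p1)
  expect_identical(c1$carrier, c2$carrier)
  expect_identical(c1$ultrarare, c2$ultrarare)
  expect_identical(c1$samples, c2$samples)
  expect_identical(simulate_trio_denovo_counts(cfg, p1, p1$gene),
                   simulate_trio_denovo_counts(cfg, p1, p1$gene))
})

test_that("LOEUF scores follow the configured uniform law", {
  cfg <- sim_config(n_genes = 10000, loeuf_range = c(0.03, 2.0), seed = 2)
  panel <- simulate_gene_panel(cfg)
  # closed form: (0.68 - 0.03) / (2.0 - 0.03) = 0.3299
  frac <- mean(panel$loeuf <= 0.68)
  se <- sqrt(0.33 * 0.67 / 10000)
  expect_lt(abs(frac - 0.3299), 3 * se + 5e-4)   # 5e-4 for the 3-dp rounding
  expect_true(all(panel$loeuf >= 0.03 & panel$loeuf <= 2.0))
})

test_that("carrier process has the configured marginal and enrichment structure", {
  # null: case and control carrier rates equal in expectation
  cfg0 <- sim_config(n_cases = 500, n_controls = 500, n_genes = 400,
                     baseline_carrier_rate = 0.05, enrichment_or = 1, seed = 3)
  panel0 <- simulate_gene_panel(cfg0)
  coh0 <- simulate_cohort(cfg0, panel0)
  is_case <- coh0$samples$phenotype == "case"
  rate_case <- mean(coh0$carrier[, is_case])
  rate_ctrl <- mean(coh0$carrier[, !is_case])
  se <- sqrt(0.05 * 0.95 / (400 * 500))
  expect_lt(abs(rate_case - rate_ctrl), 4 * se)

  # marginal per-cluster control rates match configuration within 3 SE
  cfgm <- sim_config(n_cases = 0, n_controls = 3000, n_genes = 200,
                     baseline_carrier_rate = c(0.02, 0.05, 0.1), seed = 4)
  panelm <- simulate_gene_panel(cfgm)
  cohm <- simulate_cohort(cfgm, panelm)
  for (k in 1:3) {
    in_k <- cohm$samples$cluster == paste0("C", k)
    r <- cfgm$baseline_carrier_rate[k]
    obs <- mean(cohm$carrier[, in_k])
    expect_lt(abs(obs - r), 3 * sqrt(r * (1 - r) / (200 * sum(in_k))))
  }

  # enrichment elevates case rates only below the LOEUF threshold,
  # on the configured odds scale, over 10 replicates
  ratios_lo <- ratios_hi <- numeric(10)
  for (r in 1:10) {
    cfg <- sim_config(n_cases = 400, n_controls = 400, n_genes = 300,
                      baseline_carrier_rate = 0.05, enrichment_or = 2,
                      enrichment_loeuf_max = 0.5, seed = 100 + r)
    panel <- simulate_gene_panel(cfg)
    coh <- simulate_cohort(cfg, panel)
    lo <- panel$loeuf <= 0.5
    is_case <- coh$samples$phenotype == "case"
    odds <- function(p) p / (1 - p)
    ratios_lo[r] <- odds(mean(coh$carrier[lo, is_case])) /
      odds(mean(coh$carrier[lo, !is_case]))
    ratios_hi[r] <- odds(mean(coh$carrier[!lo, is_case])) /
      odds(mean(coh$carrier[!lo, !is_case]))
  }
  expect_equal(mean(ratios_lo), 2, tolerance = 0.1)
  expect_equal(mean(ratios_hi), 1, tolerance = 0.1)

  # degenerate input: zero baseline -> all-zero matrix
  cfgz <- sim_config(n_cases = 10, n_controls = 10, n_genes = 20,
                     baseline_carrier_rate = 0, enrichment_or = 1, seed = 6)
  panelz <- simulate_gene_panel(cfgz)
  expect_true(all(simulate_cohort(cfgz, panelz)$carrier == 0L))
})

test_that("ground truth is consistent with the panel", {
  cfg <- sim_config(n_cases = 50, n_controls = 200, n_genes = 150, seed = 8)
  panel <- simulate_gene_panel(cfg)
  coh <- simulate_cohort(cfg, panel)
  expect_true(all(coh$truth$enriched_genes %in%
                    panel$gene[panel$loeuf <= coh$truth$true_threshold]))
  expect_true(all(coh$ultrarare <= coh$carrier))
  expect_setequal(names(coh$truth$cluster), coh$samples$sample_id)
})

test_that("trio de novo counts follow the Poisson identity", {
  cfg <- sim_config(n_trios = 0, n_genes = 50, seed = 9)
  panel <- simulate_gene_panel(cfg)
  expect_true(all(simulate_trio_denovo_counts(cfg, panel, panel$gene) == 0L))
  expect_error(simulate_trio_denovo_counts(cfg, panel, c(panel$gene, "NOPE")),
               "NOPE")

  # fold = 2 with expected 6.8 -> mean observed ~ 13.6 over 1000 replicates
  base <- sim_config(n_trios = 100, n_genes = 50, seed = 1)
  panel <- simulate_gene_panel(base)
  target <- 6.8 / (2 * 100 * sum(panel$mu_lof))
  obs <- vapply(1:1000, function(r) {
    cfg <- sim_config(n_trios = 100, n_genes = 50, seed = r)
    simulate_trio_denovo_counts(cfg, panel, panel$gene,
                                fold = 2 * target)[["lof"]]
  }, numeric(1))
  expect_equal(mean(obs), 13.6, tolerance = 3 * sqrt(13.6 / 1000) / 13.6 + 0.02)

  # null calibration: observed/expected -> 1 for large n_trios
  # (Poisson relative noise ~ 1/sqrt(lambda), allow 4 SD per class)
  cfgL <- sim_config(n_trios = 2e5, n_genes = 50, seed = 10)
  cnt <- simulate_trio_denovo_counts(cfgL, panel, panel$gene, fold = 1)
  expL <- 2 * 2e5 * c(sum(panel$mu_syn), sum(panel$mu_mis), sum(panel$mu_lof))
  expect_true(all(abs(cnt / expL - 1) < 4 / sqrt(expL)))
})

test_that("variant-level emitter reproduces the carrier matrix", {
  fix <- small_cohort(n_cases = 20, n_controls = 60, n_genes = 15,
                      rate = 0.05, seed = 12)
  v <- cohort_to_variants(fix$cohort, fix$panel)
  for (i in seq_len(nrow(v))) {
    g <- v$gene[i]
    for (s in v$carriers[[i]])
      expect_equal(fix$cohort$carrier[g, s], 1L)
  }
  # every carried entry appears in exactly one variant record
  carried <- sum(fix$cohort$carrier)
  expect_equal(sum(vapply(v$carriers, length, integer(1))), carried)
  # ultrarare tagging splits records by external presence
  expect_true(all(v$external_present == (v$external_af > 0)))
})
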