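# Independent oracles used across the suite.  These deliberately avoid the
# package's own convolution/lookup machinery.

# Null pmf of S = sum_k a_k by brute-force enumeration over the cartesian
# product of per-stratum supports (product of central hypergeometrics).
brute_cmh_pmf <- function(n1, n0, m1) {
  supports <- lapply(seq_along(n1), function(k)
    max(0, m1[k] - n0[k]):min(m1[k], n1[k]))
  grid <- expand.grid(supports)
  pr <- rep(1, nrow(grid))
  for (k in seq_along(n1))
    pr <- pr * dhyper(grid[[k]], n1[k], n0[k], m1[k])
  s <- rowSums(grid)
  tapply(pr, s, sum)
}

# Doubled-tail two-sided p for S = s_obs from a named pmf (names = S values).
brute_two_sided <- function(pmf_named, s_obs) {
  s <- as.integer(names(pmf_named))
  lower <- sum(pmf_named[s <= s_obs])
  upper <- sum(pmf_named[s >= s_obs])
  min(1, 2 * min(lower, upper))
}

brute_cmh_p <- function(tab) {
  n1 <- tab$a + tab$b; n0 <- tab$c + tab$d; m1 <- tab$a + tab$c
  keep <- n1 > 0 & n0 > 0 & m1 > 0 & m1 < n1 + n0
  if (!any(keep)) return(1)
  pmf <- brute_cmh_pmf(n1[keep], n0[keep], m1[keep])
  brute_two_sided(pmf, sum(tab$a[keep]))
}

# Naive scan: rebuild each cumulative gene set's table from scratch.
naive_scan_p <- function(cmat, nests) {
  vapply(seq_along(nests$thresholds), function(i) {
    gs <- nests$genes[nests$gene_loeuf <= nests$thresholds[i]]
    cmh_exact_test(collapse_to_table(cmat, gs))$p
  }, numeric(1))
}

# Small deterministic cohort fixture.
small_cohort <- function(n_cases = 60, n_controls = 300, n_genes = 40,
                         rate = c(0.02, 0.03, 0.04), or = 1, seed = 7,
                         ...) {
  cfg <- sim_config(n_cases = n_cases, n_controls = n_controls,
                    n_genes = n_genes, baseline_carrier_rate = rate,
                    enrichment_or = or, seed = seed, ...)
  panel <- simulate_gene_panel(cfg)
  cohort <- simulate_cohort(cfg, panel)
  list(cfg = cfg, panel = panel, cohort = cohort,
       cmat = cohort_collapsing_matrix(cohort))
}
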