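test_that("Mantel-Haenszel pooled OR matches hand evaluation and the crude OR", {
  # symmetric single stratum
  expect_equal(mh_pooled_odds_ratio(stratified_table(10, 90, 10, 90))$or, 1.0)
  # two strata of 20: (4,6,2,8) and (3,7,3,7) -> 2.65/1.65
  est <- mh_pooled_odds_ratio(stratified_table(c(4, 3), c(6, 7), c(2, 3), c(8, 7)))
  expect_equal(est$or, 2.65 / 1.65, tolerance = 1e-12)
  expect_lt(est$ci_low, est$or)
  expect_gt(est$ci_high, est$or)
  # single stratum reduces to ad/bc on random tables
  set.seed(42)
  for (i in 1:50) {
    t <- rbinom(4, 20, 0.5) + 1
    expect_equal(mh_pooled_odds_ratio(stratified_table(t[1], t[2], t[3], t[4]))$or,
                 t[1] * t[4] / (t[2] * t[3]), tolerance = 1e-12)
  }
})

test_that("exact CMH agrees with brute-force convolution and symmetry cases", {
  # two strata each (1,1,1,1): symmetric convolved distribution -> p = 1
  expect_equal(cmh_exact_test(stratified_table(c(1, 1), c(1, 1), c(1, 1), c(1, 1)))$p, 1)
  # perfectly balanced table
  expect_equal(cmh_exact_test(stratified_table(5, 5, 5, 5))$p, 1)
  # random stratified tables against enumeration oracle
  set.seed(11)
  for (i in 1:40) {
    k <- sample(1:4, 1)
    tab <- stratified_table(rbinom(k, 6, 0.5), rbinom(k, 8, 0.5) + 1,
                            rbinom(k, 6, 0.5), rbinom(k, 8, 0.5) + 1)
    expect_equal(cmh_exact_test(tab)$p, brute_cmh_p(tab), tolerance = 1e-10)
  }
})

test_that("point-probability exact CMH matches stats::mantelhaen.test", {
  set.seed(13)
  for (i in 1:25) {
    k <- sample(2:3, 1)
    a <- rbinom(k, 8, 0.4); b <- rbinom(k, 12, 0.6) + 1
    c <- rbinom(k, 8, 0.3); d <- rbinom(k, 12, 0.7) + 1
    arr <- array(0, c(2, 2, k))
    for (s in 1:k) arr[, , s] <- matrix(c(a[s], c[s], b[s], d[s]), 2, 2)
    ref <- tryCatch(stats::mantelhaen.test(arr, exact = TRUE)$p.value,
                    error = function(e) NA)
    if (is.na(ref)) next
    expect_equal(cmh_exact_test(stratified_table(a, b, c, d),
                                convention = "point")$p,
                 ref, tolerance = 1e-10)
  }
})

test_that("adding an empty stratum changes neither p nor OR", {
  tab <- stratified_table(c(4, 3), c(6, 7), c(2, 3), c(8, 7))
  tab2 <- stratified_table(c(4, 3, 0), c(6, 7, 0), c(2, 3, 0), c(8, 7, 0))
  expect_equal(cmh_exact_test(tab)$p, cmh_exact_test(tab2)$p)
  expect_equal(mh_pooled_odds_ratio(tab)$or, mh_pooled_odds_ratio(tab2)$or)
})

test_that("single-stratum exact CMH equals the doubled-tail Fisher p", {
  set.seed(17)
  for (i in 1:60) {
    n1 <- sample(2:12, 1); n0 <- sample(2:15, 1); m1 <- sample(1:(n1 + n0 - 1), 1)
    lo <- max(0, m1 - n0); hi <- min(m1, n1)
    a <- sample(lo:hi, 1)
    pmf <- dhyper(lo:hi, n1, n0, m1)
    pd <- min(1, 2 * min(sum(pmf[1:(a - lo + 1)]), sum(pmf[(a - lo + 1):length(pmf)])))
    expect_equal(cmh_exact_test(stratified_table(a, n1 - a, m1 - a, n0 - m1 + a))$p,
                 pd, tolerance = 1e-12)
  }
})

test_that("Fisher exact test follows the point-probability convention", {
  expect_equal(fisher_exact_test(0, 5, 0, 5)$p, 1)
  # all point probabilities of support {0,1,2,3} are <= P(obs)
  expect_equal(fisher_exact_test(2, 3, 1, 4)$p, 1)
  # cross-check against stats::fisher.test (same convention)
  set.seed(19)
  for (i in 1:100) {
    t <- rbinom(4, 15, 0.4)
    res <- fisher_exact_test(t[1], t[2], t[3], t[4])
    ref <- tryCatch(stats::fisher.test(matrix(t, 2, 2, byrow = TRUE))$p.value,
                    error = function(e) NA)
    if (!is.na(ref)) expect_equal(res$p, ref, tolerance = 1e-9)
    # within a factor of 2 of the doubled-tail convention
    n1 <- t[1] + t[2]; n0 <- t[3] + t[4]; m1 <- t[1] + t[3]
    if (n1 > 0 && n0 > 0 && m1 > 0 && m1 < n1 + n0) {
      lo <- max(0, m1 - n0); hi <- min(m1, n1)
      pmf <- dhyper(lo:hi, n1, n0, m1)
      s <- t[1] - lo + 1
      pd <- min(1, 2 * min(sum(pmf[1:s]), sum(pmf[s:length(pmf)])))
      expect_gte(2 * res$p + 1e-12, pd)
      expect_gte(2 * pd + 1e-12, res$p)
    }
  }
  # zero-cell ORs flagged
  expect_true(is.infinite(fisher_exact_test(3, 2, 0, 5)$or))
  expect_equal(fisher_exact_test(0, 5, 2, 3)$or, 0)
  expect_true(fisher_exact_test(0, 0, 0, 0)$degenerate)
})

test_that("genomic inflation factor matches chi-square quantile identities", {
  expect_equal(genomic_inflation_lambda(rep(0.5, 7)), 1.0)
  expect_equal(genomic_inflation_lambda(rep(0.01, 3)),
               qchisq(0.99, 1) / qchisq(0.5, 1), tolerance = 1e-12)
  set.seed(23)
  expect_equal(genomic_inflation_lambda(runif(1e4)), 1, tolerance = 0.05)
  expect_error(genomic_inflation_lambda(numeric(0)), "no p-values")
  expect_error(genomic_inflation_lambda(c(0.5, 0)), "in \\(0, 1\\]")
})

test_that("vectorised asymptotic CMH matches mantelhaen.test without correction", {
  set.seed(29)
  n1 <- c(40, 60); n0 <- c(400, 300)
  a <- matrix(rbinom(20, 15, 0.4), 10, 2)
  c_ <- matrix(rbinom(20, 80, 0.4), 10, 2)
  p <- cmh_chisq_p(a, c_, n1, n0)
  for (g in 1:10) {
    arr <- array(0, c(2, 2, 2))
    for (k in 1:2)
      arr[, , k] <- matrix(c(a[g, k], c_[g, k], n1[k] - a[g, k],
                             n0[k] - c_[g, k]), 2, 2)
    ref <- stats::mantelhaen.test(arr, correct = FALSE)$p.value
    expect_equal(p[g], ref, tolerance = 1e-9)
  }
})

test_that("multiplicity helpers: Bonferroni threshold and BH step-up", {
  expect_equal(signif(bonferroni_alpha(0.05, 1860), 2), 2.7e-5)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_error(bonferroni_alpha(0.05, 0), "m must be")

  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(31)
  for (i in 1:100) {
    p <- runif(sample(2:20, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
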