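#' Stratified 2x2 table object
#'
#' A `stratified_table` holds, for each ancestry cluster (stratum), the 2x2
#' case/control x carrier/non-carrier counts for one gene or gene set:
#' `a` case carriers, `b` case non-carriers, `c` control carriers, `d` control
#' non-carriers.
#'
#' @param a,b,c,d integer vectors of per-stratum counts (recycled to a common
#'   length).
#' @param cluster optional stratum labels; defaults to `"C1"`, `"C2"`, ...
#' @return a data frame of class `stratified_table` with columns `cluster`,
#'   `a`, `b`, `c`, `d`.
#' @examples
#' stratified_table(a = c(4, 3), b = c(6, 7), c = c(2, 3), d = c(8, 7))
#' @export
stratified_table <- function(a, b, c, d, cluster = NULL) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.integer(a), n); b <- rep_len(as.integer(b), n)
  c <- rep_len(as.integer(c), n); d <- rep_len(as.integer(d), n)
  if (any(is.na(c(a, b, c, d))) || any(c(a, b, c, d) < 0))
    stop("stratified_table: counts must be non-negative and non-missing")
  if (is.null(cluster)) cluster <- paste0("C", seq_len(n))
  out <- data.frame(cluster = as.character(cluster), a = a, b = b, c = c, d = d,
                    stringsAsFactors = FALSE)
  class(out) <- c("stratified_table", "data.frame")
  out
}

# Strata that carry no information about the common odds ratio: a zero
# case or control margin (a_k is then constant), or carrier counts of 0 or
# n_k (again constant).  Dropped from both estimation and testing; no
# continuity corrections are applied anywhere.
informative_strata <- function(tab) {
  n1 <- tab$a + tab$b; n0 <- tab$c + tab$d; m1 <- tab$a + tab$c
  n1 > 0 & n0 > 0 & m1 > 0 & m1 < (n1 + n0)
}

#' Mantel-Haenszel pooled odds ratio with Robins-Breslow-Greenland interval
#'
#' Pooled common odds ratio across strata,
#' \eqn{\hat{OR} = \sum_k a_k d_k / n_k \; / \; \sum_k b_k c_k / n_k},
#' with a 95% Wald interval on the log scale using the
#' Robins-Breslow-Greenland variance estimator.  Strata with a zero
#' case/control margin or with no carriers (or all carriers) are dropped.
#'
#' @param tab a [stratified_table()].
#' @param conf_level confidence level for the Wald interval (default 0.95).
#' @return a list with `or`, `ci_low`, `ci_high`, and `degenerate` (TRUE when
#'   a zero denominator or numerator makes the estimate infinite or zero, in
#'   which case the interval is `NA`).
#' @examples
#' mh_pooled_odds_ratio(stratified_table(c(4, 3), c(6, 7), c(2, 3), c(8, 7)))
#' @export
mh_pooled_odds_ratio <- function(tab, conf_level = 0.95) {
  stopifnot(inherits(tab, "stratified_table"))
  tab <- tab[informative_strata(tab), , drop = FALSE]
  if (nrow(tab) == 0L)
    return(list(or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                degenerate = TRUE))
  n <- tab$a + tab$b + tab$c + tab$d
  R <- tab$a * tab$d / n
  S <- tab$b * tab$c / n
  sR <- sum(R); sS <- sum(S)
  if (sS == 0 || sR == 0) {
    or <- if (sS == 0) Inf else 0
    return(list(or = or, ci_low = NA_real_, ci_high = NA_real_,
                degenerate = TRUE))
  }
  or <- sR / sS
  P <- (tab$a + tab$d) / n
  Q <- (tab$b + tab$c) / n
  v <- sum(P * R) / (2 * sR^2) + sum(P * S + Q * R) / (2 * sR * sS) +
    sum(Q * S) / (2 * sS^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = or, ci_low = or * exp(-z * sqrt(v)), ci_high = or * exp(z * sqrt(v)),
       degenerate = FALSE)
}

# Exact null pmf of S = sum_k a_k across informative strata, conditional on
# all margins: the convolution of per-stratum central hypergeometric pmfs.
# Returns the pmf vector and the support offset (value of S at index 1).
cmh_null_pmf <- function(n1, n0, m1) {
  pmf <- 1
  offset <- 0L
  for (k in seq_along(n1)) {
    lo <- max(0L, m1[k] - n0[k]); hi <- min(m1[k], n1[k])
    v <- stats::dhyper(lo:hi, n1[k], n0[k], m1[k])
    pmf <- if (length(pmf) == 1L) pmf * v
           else if (length(v) == 1L) pmf * v
           else stats::convolve(pmf, rev(v), type = "open")
    offset <- offset + lo
  }
  pmf <- pmax(pmf, 0)
  list(pmf = pmf / sum(pmf), offset = offset)
}

# Two-sided p-value from a discrete pmf at observed support index s_idx
# (1-based).  "doubled": twice the smaller tail, capped at 1.  "point":
# total probability of outcomes no more likely than the observed one.
two_sided_from_pmf <- function(pmf, s_idx, convention = c("doubled", "point")) {
  convention <- match.arg(convention)
  if (convention == "doubled") {
    lower <- sum(pmf[seq_len(s_idx)])
    upper <- sum(pmf[s_idx:length(pmf)])
    min(1, 2 * min(lower, upper))
  } else {
    min(1, sum(pmf[pmf <= pmf[s_idx] * (1 + 1e-7)]))
  }
}

#' Exact stratified Cochran-Mantel-Haenszel test
#'
#' Exact conditional test of a common odds ratio of 1 across the strata of a
#' [stratified_table()].  The test statistic is the total case-carrier count
#' \eqn{S = \sum_k a_k}; its exact null distribution given all margins is the
#' convolution of per-stratum central hypergeometric distributions, computed
#' by dynamic programming.  The two-sided p-value doubles the smaller tail
#' (capped at 1) by default; `convention = "point"` instead sums the
#' probabilities of all outcomes no more likely than the observed one (the
#' convention of [stats::mantelhaen.test()] with `exact = TRUE`).
#'
#' The pooled odds ratio and its 95% CI come from [mh_pooled_odds_ratio()].
#' Strata with zero margins contribute nothing and are dropped silently.
#'
#' @param tab a [stratified_table()].
#' @param convention two-sided convention, `"doubled"` (default) or `"point"`.
#' @return an object of class `cmh_result`: list with `p`, `or`, `ci_low`,
#'   `ci_high`, `s_obs`, `convention`, `table`.
#' @examples
#' cmh_exact_test(stratified_table(c(4, 3), c(6, 7), c(2, 3), c(8, 7)))
#' @seealso [fisher_exact_test()] for a single unstratified table.
#' @export
cmh_exact_test <- function(tab, convention = c("doubled", "point")) {
  stopifnot(inherits(tab, "stratified_table"))
  convention <- match.arg(convention)
  est <- mh_pooled_odds_ratio(tab)
  keep <- tab[informative_strata(tab), , drop = FALSE]
  if (nrow(keep) == 0L) {
    res <- list(p = 1, or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
                s_obs = sum(tab$a), convention = convention, table = tab,
                degenerate = TRUE)
    class(res) <- "cmh_result"
    return(res)
  }
  null <- cmh_null_pmf(keep$a + keep$b, keep$c + keep$d, keep$a + keep$c)
  s_obs <- sum(keep$a)
  p <- two_sided_from_pmf(null$pmf, s_obs - null$offset + 1L, convention)
  res <- list(p = p, or = est$or, ci_low = est$ci_low, ci_high = est$ci_high,
              s_obs = sum(tab$a), convention = convention, table = tab,
              degenerate = est$degenerate)
  class(res) <- "cmh_result"
  res
}

#' @export
print.cmh_result <- function(x, ...) {
  cat("Exact stratified CMH test (", x$convention, " two-sided)\n", sep = "")
  cat(sprintf("  strata: %d   S = %d\n", nrow(x$table), x$s_obs))
  cat(sprintf("  MH pooled OR = %.3g (95%% CI %.3g-%.3g)\n",
              x$or, x$ci_low, x$ci_high))
  cat(sprintf("  p = %.4g\n", x$p))
  invisible(x)
}

#' Fisher exact test on a single 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of all tables (with the observed margins) no
#' more likely than the observed one.  The reported odds ratio is the sample
#' conditional odds ratio `a*d / (b*c)`; a zero cell makes it 0 or infinite
#' and is flagged.  The 95% CI is a Wald interval on the log sample OR
#' (undefined with any zero cell).
#'
#' @param a,b,c,d single non-negative counts: case carriers, case
#'   non-carriers, control carriers, control non-carriers.
#' @return an object of class `fisher_result`: list with `p`, `or`, `ci_low`,
#'   `ci_high`, `degenerate`.
#' @examples
#' fisher_exact_test(2, 3, 1, 4)   # p = 1: every table is as likely
#' @export
fisher_exact_test <- function(a, b, c, d) {
  stopifnot(length(a) == 1, length(b) == 1, length(c) == 1, length(d) == 1,
            a >= 0, b >= 0, c >= 0, d >= 0)
  n1 <- a + b; n0 <- c + d; m1 <- a + c
  if (n1 + n0 == 0 || m1 == 0 || m1 == n1 + n0 || n1 == 0 || n0 == 0) {
    res <- list(p = 1, or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                degenerate = TRUE)
    class(res) <- "fisher_result"
    return(res)
  }
  lo <- max(0, m1 - n0); hi <- min(m1, n1)
  pmf <- stats::dhyper(lo:hi, n1, n0, m1)
  p <- min(1, sum(pmf[pmf <= pmf[a - lo + 1] * (1 + 1e-7)]))
  degenerate <- (b * c == 0) || (a * d == 0)
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  if (a * d == 0) or <- 0
  if (degenerate) {
    ci <- c(NA_real_, NA_real_)
  } else {
    se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
    ci <- or * exp(c(-1, 1) * stats::qnorm(0.975) * se)
  }
  res <- list(p = p, or = or, ci_low = ci[1], ci_high = ci[2],
              degenerate = degenerate)
  class(res) <- "fisher_result"
  res
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher exact test: OR = %.3g (95%% CI %.3g-%.3g), p = %.4g\n",
              x$or, x$ci_low, x$ci_high, x$p))
  invisible(x)
}

#' Asymptotic CMH chi-square p-values for many tables at once
#'
#' Continuity-correction-free Mantel-Haenszel chi-square statistic
#' \eqn{(S - E[S])^2 / V[S]} on the 1-df chi-square scale, vectorised over
#' genes.  Used for genomic-inflation diagnostics, where p-values are
#' compared against the chi-square(1) reference distribution.
#'
#' @param a,c matrices (genes x clusters) of case-carrier and control-carrier
#'   counts.
#' @param n1,n0 vectors of per-cluster case and control totals.
#' @return vector of upper-tail chi-square(1) p-values (NA for genes with no
#'   informative stratum).
#' @export
cmh_chisq_p <- function(a, c, n1, n0) {
  a <- as.matrix(a); c <- as.matrix(c)
  stopifnot(ncol(a) == length(n1), ncol(c) == length(n0))
  m1 <- a + c
  nk <- n1 + n0
  valid <- m1 > 0 & sweep(m1, 2, nk, `<`)
  E <- sweep(m1, 2, n1 / nk, `*`)
  V <- sweep(m1 * sweep(-m1, 2, nk, `+`), 2,
             n1 * n0 / (nk^2 * pmax(nk - 1, 1)), `*`)
  E[!valid] <- 0; V[!valid] <- 0
  av <- a; av[!valid] <- 0
  S <- rowSums(av); Es <- rowSums(E); Vs <- rowSums(V)
  p <- rep(NA_real_, nrow(a))
  ok <- Vs > 0
  p[ok] <- stats::pchisq((S[ok] - Es[ok])^2 / Vs[ok], df = 1,
                         lower.tail = FALSE)
  p
}

#' Genomic inflation factor
#'
#' \eqn{\lambda} = median of the chi-square(1) quantile transform of the
#' p-values divided by 0.4549 (the chi-square(1) median).  Values near 1
#' indicate well-matched case-control ancestry; inflation (> ~1.2) signals
#' residual population stratification.
#'
#' @param p numeric vector of p-values in (0, 1]; NAs dropped.
#' @return the scalar inflation factor.
#' @examples
#' genomic_inflation_lambda(rep(0.5, 10))   # exactly 1
#' @export
genomic_inflation_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("genomic_inflation_lambda: no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("genomic_inflation_lambda: p-values must be in (0, 1]")
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 1860)
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (length(m) != 1 || is.na(m) || m < 1) stop("bonferroni_alpha: m must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("bonferroni_alpha: alpha must be in (0, 1]")
  alpha / m
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone, capped at 1, original
#' order restored.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("bh_adjust: p-values must be in [0, 1] and non-missing")
  stats::p.adjust(p, method = "BH")
}
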