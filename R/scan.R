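#' Nested LOEUF-threshold gene sets
#'
#' Genes harbouring at least one qualifying variant are ordered from most to
#' least intolerant (ascending LOEUF) and one cumulative gene set is formed
#' per unique LOEUF value: the set at threshold t contains every QV-harbouring
#' gene with LOEUF <= t.
#'
#' @param panel gene panel with `gene` and `loeuf` columns.
#' @param genes_with_qv character vector of genes with >= 1 qualifying
#'   variant in a case or control.
#' @return list with `thresholds` (ascending unique LOEUF values),
#'   `genes` (genes_with_qv ordered by LOEUF), `gene_loeuf` (their scores),
#'   and `set_sizes` (cumulative set size per threshold).
#' @export
nested_genesets <- function(panel, genes_with_qv) {
  if (length(genes_with_qv) == 0)
    stop("nested_genesets: no genes with qualifying variants")
  loeuf <- panel$loeuf[match(genes_with_qv, panel$gene)]
  if (anyNA(loeuf))
    stop(sprintf("nested_genesets: missing LOEUF score for gene(s): %s",
                 paste(utils::head(genes_with_qv[is.na(loeuf)], 5), collapse = ", ")))
  ord <- order(loeuf, genes_with_qv)
  genes <- genes_with_qv[ord]
  loeuf <- loeuf[ord]
  thresholds <- unique(loeuf)
  set_sizes <- vapply(thresholds, function(t) sum(loeuf <= t), integer(1))
  list(thresholds = thresholds, genes = genes, gene_loeuf = loeuf,
       set_sizes = set_sizes)
}

# For each individual, the index of the first threshold at which it becomes
# a carrier of the cumulative set (Inf if never): the smallest threshold
# index among its carried genes.  This makes per-threshold carrier status a
# cumulative count, so one label shuffle yields the whole scan statistic
# vector in O(n + T).
first_carrier_threshold <- function(cmat, nests) {
  ind <- cmat$indicator[nests$genes, , drop = FALSE]
  t_idx <- match(nests$gene_loeuf, nests$thresholds)   # per ordered gene
  apply(ind, 2, function(col) {
    w <- which(col == 1L)
    if (length(w)) t_idx[w[1]] else Inf
  })
}

# Per-threshold exact CMH machinery shared by the observed scan and the
# permutation loop.  Because permutations shuffle labels within clusters,
# every margin (per-cluster case totals and per-cluster carrier counts per
# threshold) is permutation-invariant, so the exact null distribution of
# S(t) = total case carriers is computed once per threshold and exact
# p-values for observed and permuted labellings are table lookups.
scan_engine <- function(cmat, nests, convention = "doubled") {
  tf <- first_carrier_threshold(cmat, nests)
  df <- cmat$samples
  clusters <- sort(unique(df$cluster))
  Tn <- length(nests$thresholds)
  n1 <- n0 <- integer(length(clusters))
  # carriers per cluster per threshold (cumulative counts of first-carrier
  # threshold indices)
  m1 <- matrix(0L, Tn, length(clusters))
  for (k in seq_along(clusters)) {
    in_k <- df$cluster == clusters[k]
    n1[k] <- sum(in_k & df$phenotype == "case")
    n0[k] <- sum(in_k) - n1[k]
    tk <- tf[in_k]
    tk <- tk[is.finite(tk)]
    m1[, k] <- cumsum(tabulate(tk, nbins = Tn))
  }
  # exact p lookup per threshold: p_lookup[[t]][s+1] = two-sided p at S=s
  smax <- sum(n1)
  p_lookup <- matrix(NA_real_, Tn, smax + 1L)
  for (t in seq_len(Tn)) {
    keep <- m1[t, ] > 0 & m1[t, ] < (n1 + n0) & n1 > 0 & n0 > 0
    if (!any(keep)) { p_lookup[t, ] <- 1; next }
    null <- cmh_null_pmf(n1[keep], n0[keep], m1[t, keep])
    lo <- null$offset; hi <- lo + length(null$pmf) - 1L
    cum_lo <- cumsum(null$pmf)
    cum_hi <- rev(cumsum(rev(null$pmf)))
    pv <- if (convention == "doubled") {
      pmin(1, 2 * pmin(cum_lo, cum_hi))
    } else {
      vapply(seq_along(null$pmf), function(i)
        min(1, sum(null$pmf[null$pmf <= null$pmf[i] * (1 + 1e-7)])), numeric(1))
    }
    # degenerate strata contribute a constant to S (invariant under
    # within-cluster permutation): n1 when everyone carries, m1 when the
    # cluster is all cases, 0 otherwise
    deg <- which(!keep)
    shift <- 0L
    for (k in deg) {
      shift <- shift + if (n1[k] == 0L) 0L
        else if (n0[k] == 0L) m1[t, k]
        else if (m1[t, k] == n1[k] + n0[k]) n1[k]
        else 0L
    }
    row <- rep(NA_real_, smax + 1L)
    # S values outside support cannot occur for valid labellings
    row[(lo:hi) + 1L + shift] <- pv
    p_lookup[t, ] <- row
  }
  case_obs <- df$phenotype == "case"
  list(tf = tf, df = df, clusters = clusters, n1 = n1, n0 = n0, m1 = m1,
       p_lookup = p_lookup, Tn = Tn, case_obs = case_obs)
}

# S(t) vector for a case indicator vector over the matrix's individuals.
scan_statistic <- function(engine, is_case) {
  tk <- engine$tf[is_case]
  tk <- tk[is.finite(tk)]
  cumsum(tabulate(tk, nbins = engine$Tn))
}

lookup_p <- function(engine, S) {
  engine$p_lookup[cbind(seq_len(engine$Tn), S + 1L)]
}

#' Per-threshold exact CMH p-values for the nested scan
#'
#' Collapses each cumulative gene set to its stratified table and computes
#' the exact CMH p-value, using incremental carrier updates: an individual
#' flips 0 to 1 at the first added gene it carries, so carrier counts per
#' threshold are cumulative tallies rather than fresh recomputations.
#'
#' @param cmat a `collapsing_matrix`.
#' @param nests output of [nested_genesets()].
#' @param convention two-sided convention passed to the exact test.
#' @return numeric vector of nominal p-values, one per threshold.
#' @export
scan_cmh <- function(cmat, nests, convention = c("doubled", "point")) {
  convention <- match.arg(convention)
  engine <- scan_engine(cmat, nests, convention)
  lookup_p(engine, scan_statistic(engine, engine$case_obs))
}

#' Permutation empirical p-values for the nested scan
#'
#' Case/control labels are permuted within each cluster (preserving every
#' cluster's case count and hence all margins); each permutation yields the
#' full nominal p-vector, and the empirical p-value at threshold t is
#' `(1 + # permutations with p_perm(t) <= p_obs(t)) / (n_permutations + 1)`.
#'
#' @inheritParams scan_cmh
#' @param n_permutations number of label shuffles (>= 1).
#' @param seed integer seed.
#' @param estimator `"add_one"` for the (r+1)/(n+1) estimator (default) or
#'   `"plain"` for r/n.
#' @return list with `p_obs` (nominal), `p_empirical`, `n_permutations`.
#' @export
permutation_empirical <- function(cmat, nests, n_permutations = 1000L,
                                  seed = 1L,
                                  convention = c("doubled", "point"),
                                  estimator = c("add_one", "plain")) {
  convention <- match.arg(convention)
  estimator <- match.arg(estimator)
  if (n_permutations < 1) stop("permutation_empirical: n_permutations must be >= 1")
  engine <- scan_engine(cmat, nests, convention)
  p_obs <- lookup_p(engine, scan_statistic(engine, engine$case_obs))
  df <- engine$df
  cl_idx <- lapply(engine$clusters, function(k) which(df$cluster == k))
  n_case_k <- engine$n1
  hits <- integer(engine$Tn)
  withr_seed(seed, stream = 11L, {
    for (b in seq_len(n_permutations)) {
      is_case <- logical(nrow(df))
      for (k in seq_along(cl_idx))
        if (n_case_k[k] > 0)
          is_case[sample(cl_idx[[k]], n_case_k[k])] <- TRUE
      p_perm <- lookup_p(engine, scan_statistic(engine, is_case))
      hits <- hits + (p_perm <= p_obs + 1e-12)
    }
  })
  p_emp <- if (estimator == "add_one") (1 + hits) / (n_permutations + 1)
           else hits / n_permutations
  list(p_obs = p_obs, p_empirical = p_emp, n_permutations = n_permutations)
}

#' Gene-intolerance threshold scan
#'
#' End-to-end scan: nested LOEUF gene sets over the QV-harbouring genes,
#' exact stratified CMH per cumulative set, permutation empirical p-values,
#' Bonferroni significance over the number of unique thresholds, and the
#' optimal (minimum empirical p) threshold, ties resolved toward the
#' smaller (more intolerant) threshold.
#'
#' @param cmat a `collapsing_matrix`.
#' @param panel gene panel with `gene`, `loeuf`.
#' @param n_permutations permutations for the empirical p-values.
#' @param alpha family-wise error rate for the Bonferroni threshold
#'   (default 0.05).
#' @param seed integer seed.
#' @inheritParams scan_cmh
#' @inheritParams permutation_empirical
#' @return object of class `loeuf_scan`: list with `thresholds`,
#'   `set_sizes`, `p_nominal`, `p_empirical`, `n_permutations`,
#'   `bonferroni_alpha`, `optimal_threshold`, `optimal_p`, `significant`,
#'   `seed`.
#' @export
loeuf_scan <- function(cmat, panel, n_permutations = 1000L, alpha = 0.05,
                       seed = 1L, convention = c("doubled", "point"),
                       estimator = c("add_one", "plain")) {
  convention <- match.arg(convention)
  estimator <- match.arg(estimator)
  genes_with_qv <- rownames(cmat$indicator)[rowSums(cmat$indicator) > 0]
  nests <- nested_genesets(panel, genes_with_qv)
  bonf <- bonferroni_alpha(alpha, length(nests$thresholds))
  if (1 / (n_permutations + 1) > bonf)
    warning(sprintf(paste0("loeuf_scan: %d permutations cannot reach the ",
                           "Bonferroni threshold %.3g (floor %.3g)"),
                    n_permutations, bonf, 1 / (n_permutations + 1)))
  perm <- permutation_empirical(cmat, nests, n_permutations, seed,
                                convention, estimator)
  res <- list(thresholds = nests$thresholds, set_sizes = nests$set_sizes,
              p_nominal = perm$p_obs, p_empirical = perm$p_empirical,
              n_permutations = n_permutations, bonferroni_alpha = bonf,
              seed = seed, convention = convention)
  opt <- optimal_threshold(res, alpha = alpha)
  res$optimal_threshold <- opt$threshold
  res$optimal_p <- opt$p_empirical
  res$significant <- opt$significant
  class(res) <- "loeuf_scan"
  res
}

#' Optimal intolerance threshold of a scan
#'
#' The threshold attaining the minimum empirical p-value.  A finite
#' permutation count floors the empirical p, so strong signals tie many
#' thresholds at the floor; ties are therefore resolved by the nominal
#' exact-CMH p-value (which discriminates arbitrarily finely), and any
#' remaining ties go to the smallest (most intolerant) threshold.
#' Significant iff the minimum empirical p is below
#' `alpha / number of thresholds`.
#'
#' @param scan a `loeuf_scan` (or a list with `thresholds`, `p_empirical`,
#'   and optionally `p_nominal` for tie-breaking).
#' @param alpha family-wise error rate (default 0.05).
#' @return list with `threshold`, `p_empirical`, `significant`.
#' @export
optimal_threshold <- function(scan, alpha = 0.05) {
  pe <- scan$p_empirical
  tied <- which(pe <= min(pe) + 1e-15)
  if (!is.null(scan$p_nominal) && length(tied) > 1) {
    pn <- scan$p_nominal[tied]
    tied <- tied[pn <= min(pn) + 1e-15]
  }
  i <- tied[1]                      # thresholds ascend: first = smallest
  bonf <- bonferroni_alpha(alpha, length(scan$thresholds))
  list(threshold = scan$thresholds[i], p_empirical = pe[i],
       significant = pe[i] < bonf)
}

#' @export
print.loeuf_scan <- function(x, ...) {
  cat(sprintf("LOEUF threshold scan: %d thresholds, %d permutations\n",
              length(x$thresholds), x$n_permutations))
  cat(sprintf("  optimum at LOEUF <= %.3f: empirical p = %.3g (%ssignificant at Bonferroni %.2g)\n",
              x$optimal_threshold, x$optimal_p,
              if (x$significant) "" else "not ", x$bonferroni_alpha))
  invisible(x)
}

#' Plot a LOEUF threshold scan
#'
#' -log10 empirical p-value against the LOEUF threshold, with the Bonferroni
#' line and the optimum marked; intolerance-decile positions are ticked
#' along the top axis.
#'
#' @param x a `loeuf_scan`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_loeuf_scan <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_loeuf_scan requires ggplot2")
  df <- data.frame(threshold = x$thresholds, mlp = -log10(x$p_empirical))
  dec <- stats::quantile(x$thresholds, probs = seq(0.1, 1, 0.1), names = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$mlp)) +
    ggplot2::geom_point(size = 0.6, colour = "grey30") +
    ggplot2::geom_hline(yintercept = -log10(x$bonferroni_alpha),
                        colour = "orange") +
    ggplot2::geom_point(data = df[match(x$optimal_threshold, df$threshold), ],
                        colour = "orange", size = 2) +
    ggplot2::scale_x_continuous(sec.axis = ggplot2::sec_axis(
      ~., breaks = dec, labels = seq_len(10), name = "intolerance decile")) +
    ggplot2::labs(x = "LOEUF threshold (genes with LOEUF <= t)",
                  y = expression(-log[10] ~ "empirical p")) +
    ggplot2::theme_minimal()
}
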