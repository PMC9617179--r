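#' Expected de novo count for a gene set and variant class
#'
#' `2 * n_trios * sum(mu[geneset, class])`: per-gene per-class mutation
#' probabilities are per chromosome per generation, so each trio contributes
#' two copies.  Composite classes sum their components
#' (`missense_and_lof = missense + lof`; `all` adds synonymous too).
#'
#' @param panel gene panel with `mu_syn`, `mu_mis`, `mu_lof`.
#' @param geneset gene ids to restrict to (all must be in the panel).
#' @param n_trios number of trios (>= 0).
#' @param variant_class one of `"synonymous"`, `"missense"`, `"lof"`,
#'   `"missense_and_lof"`, `"all"`.
#' @param copies copies per trio (default 2; set 1 for rate tables already
#'   expressed per individual).
#' @return expected count (non-negative scalar).
#' @export
expected_count <- function(panel, geneset, n_trios,
                           variant_class = c("synonymous", "missense", "lof",
                                             "missense_and_lof", "all"),
                           copies = 2) {
  variant_class <- match.arg(variant_class)
  if (n_trios < 0) stop("expected_count: n_trios must be >= 0")
  missing_g <- setdiff(geneset, panel$gene)
  if (length(missing_g))
    stop(sprintf("expected_count: no mutation rate for gene(s): %s (class %s)",
                 paste(utils::head(missing_g, 5), collapse = ", "),
                 variant_class))
  sub <- panel[panel$gene %in% geneset, , drop = FALSE]
  mu <- switch(variant_class,
               synonymous = sum(sub$mu_syn),
               missense = sum(sub$mu_mis),
               lof = sum(sub$mu_lof),
               missense_and_lof = sum(sub$mu_mis) + sum(sub$mu_lof),
               all = sum(sub$mu_syn) + sum(sub$mu_mis) + sum(sub$mu_lof))
  copies * n_trios * mu
}

#' Poisson enrichment test for de novo counts
#'
#' One-sided upper-tail test of the observed count against a Poisson null
#' with the expected count as mean: `p = P(X >= observed)`.  Enrichment is
#' the observed/expected ratio.
#'
#' @param observed non-negative integer count.
#' @param expected expected count under the null (> 0 for a proper test).
#' @param variant_class label carried through to the result.
#' @return one-row data frame of class `denovo_result`: `variant_class`,
#'   `observed`, `expected`, `enrichment`, `p`.
#' @examples
#' poisson_test(14, 6.8)
#' @export
poisson_test <- function(observed, expected, variant_class = NA_character_) {
  stopifnot(length(observed) == 1, observed >= 0, observed == round(observed),
            length(expected) == 1, expected >= 0)
  if (expected == 0) {
    p <- if (observed > 0) 0 else 1
    enr <- if (observed > 0) Inf else NA_real_
    if (observed > 0)
      warning("poisson_test: expected = 0 with observed > 0 (degenerate)")
  } else {
    p <- stats::ppois(observed - 1, lambda = expected, lower.tail = FALSE)
    enr <- observed / expected
  }
  out <- data.frame(variant_class = variant_class, observed = as.integer(observed),
                    expected = expected, enrichment = enr, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("denovo_result", "data.frame")
  out
}

#' De novo enrichment battery over consequence classes
#'
#' Tallies observed de novo calls per class within the gene universe and
#' tests each class (and the composite classes) against its expected count.
#' Calls in genes outside the panel are excluded with a warning; calls in
#' panel genes outside `geneset` are excluded silently (the universe is the
#' analysis choice).
#'
#' @param panel gene panel with mutation rate columns.
#' @param geneset gene universe (e.g. genes without a known disease
#'   association).
#' @param calls data frame `trio_id`, `gene`, `class` with class in
#'   `"synonymous"`, `"missense"`, `"lof"`.
#' @param n_trios number of trios the calls came from.
#' @param copies copies per trio (see [expected_count()]).
#' @return `denovo_result` data frame with one row per class, in the order
#'   synonymous, missense, lof, missense_and_lof, all.
#' @export
denovo_battery <- function(panel, geneset, calls, n_trios, copies = 2) {
  stopifnot(all(c("gene", "class") %in% names(calls)))
  bad_class <- setdiff(unique(calls$class), c("synonymous", "missense", "lof"))
  if (length(bad_class))
    stop("denovo_battery: unknown variant class(es): ",
         paste(bad_class, collapse = ", "))
  outside <- setdiff(unique(calls$gene), panel$gene)
  if (length(outside)) {
    warning(sprintf("denovo_battery: %d call(s) in genes outside the panel excluded",
                    sum(calls$gene %in% outside)))
    calls <- calls[!calls$gene %in% outside, , drop = FALSE]
  }
  calls <- calls[calls$gene %in% geneset, , drop = FALSE]
  obs_base <- c(synonymous = sum(calls$class == "synonymous"),
                missense = sum(calls$class == "missense"),
                lof = sum(calls$class == "lof"))
  obs <- c(obs_base,
           missense_and_lof = unname(obs_base["missense"] + obs_base["lof"]),
           all = sum(obs_base))
  rows <- lapply(names(obs), function(cl)
    poisson_test(obs[[cl]], expected_count(panel, geneset, n_trios, cl, copies),
                 variant_class = cl))
  out <- do.call(rbind, rows)
  class(out) <- c("denovo_result", "data.frame")
  out
}

#' @export
print.denovo_result <- function(x, ...) {
  df <- as.data.frame(x)
  df$expected <- round(df$expected, 2)
  df$enrichment <- round(df$enrichment, 2)
  df$p <- signif(df$p, 2)
  print(df, row.names = FALSE)
  invisible(x)
}
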