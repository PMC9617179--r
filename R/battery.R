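#' Partition intolerant genes by disease association
#'
#' Genes with LOEUF at or below the intolerance cap are split by their
#' known-disease-association flag.
#'
#' @param panel gene panel with `gene`, `loeuf`, `disease_associated`.
#' @param intolerance_cap LOEUF bound (default 0.68, the intolerant-tertile
#'   scale at which LOF burden typically concentrates).
#' @return list with character vectors `disease_associated` and
#'   `no_known_association`.
#' @export
partition_by_disease_association <- function(panel, intolerance_cap = 0.68) {
  under <- !is.na(panel$loeuf) & panel$loeuf <= intolerance_cap
  if (!any(under))
    stop("partition_by_disease_association: no genes at or below the cap")
  list(disease_associated = panel$gene[under & panel$disease_associated],
       no_known_association = panel$gene[under & !panel$disease_associated])
}

battery_cell <- function(cmat, geneset, label, test_kind, n_genes_qv) {
  tab <- suppressWarnings(collapse_to_table(cmat, geneset))
  res <- if (test_kind == "fisher") {
    pooled <- colSums(tab[, c("a", "b", "c", "d")])
    fisher_exact_test(pooled[["a"]], pooled[["b"]], pooled[["c"]], pooled[["d"]])
  } else {
    cmh_exact_test(tab)
  }
  data.frame(set = label, n_genes_qv = n_genes_qv,
             case_carriers = sum(tab$a), case_total = sum(tab$a + tab$b),
             control_carriers = sum(tab$c), control_total = sum(tab$c + tab$d),
             or = res$or, ci_low = res$ci_low, ci_high = res$ci_high,
             p = res$p, test = test_kind,
             empty = sum(tab$a) + sum(tab$c) == 0,
             stringsAsFactors = FALSE)
}

#' Gene-set enrichment battery
#'
#' Runs the configured grid of carrier-burden tests: gene partitions
#' (disease-associated vs no-known-association intolerant genes, plus any
#' curated lists) crossed with variant partitions (all rare, ultrarare,
#' rare-but-present), one exact CMH (stratified) or Fisher (pooled) test per
#' cell, Benjamini-Hochberg adjustment across the battery.  Cells with no
#' carriers anywhere are flagged and excluded from the FDR adjustment.
#'
#' @param matrices named list of `collapsing_matrix` objects, one per variant
#'   partition (names out of `"all_rare"`, `"ultrarare"`,
#'   `"rare_but_present"`).
#' @param panel gene panel.
#' @param intolerance_cap LOEUF bound defining the intolerant gene universe.
#' @param test_kind `"cmh_exact"` (stratified, default) or `"fisher"`
#'   (pooled; conventional for very small cohorts).
#' @param gene_lists optional named list of curated gene-id vectors, each
#'   tested (intersected with the intolerant universe) per variant partition.
#' @return data frame of class `burden_battery`, one row per cell, ordered
#'   gene-partition-major, with `p_adjusted`.
#' @export
run_burden_battery <- function(matrices, panel, intolerance_cap = 0.68,
                               test_kind = c("cmh_exact", "fisher"),
                               gene_lists = NULL) {
  test_kind <- match.arg(test_kind)
  stopifnot(length(matrices) >= 1, !is.null(names(matrices)),
            all(names(matrices) %in% c("all_rare", "ultrarare",
                                       "rare_but_present")))
  parts <- partition_by_disease_association(panel, intolerance_cap)
  if (!is.null(gene_lists)) {
    under <- panel$gene[!is.na(panel$loeuf) & panel$loeuf <= intolerance_cap]
    for (nm in names(gene_lists)) parts[[nm]] <- intersect(gene_lists[[nm]], under)
  }
  rows <- list()
  for (gp in names(parts)) {
    for (vp in names(matrices)) {
      cmat <- matrices[[vp]]
      genes <- intersect(parts[[gp]], rownames(cmat$indicator))
      n_qv <- if (length(genes))
        sum(rowSums(cmat$indicator[genes, , drop = FALSE]) > 0) else 0L
      label <- paste(gp, vp, sep = ".")
      if (length(genes) == 0) {
        rows[[label]] <- data.frame(set = label, n_genes_qv = 0L,
                                    case_carriers = 0L, case_total = NA_integer_,
                                    control_carriers = 0L,
                                    control_total = NA_integer_,
                                    or = NA_real_, ci_low = NA_real_,
                                    ci_high = NA_real_, p = NA_real_,
                                    test = test_kind, empty = TRUE,
                                    stringsAsFactors = FALSE)
      } else {
        rows[[label]] <- battery_cell(cmat, genes, label, test_kind, n_qv)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adjusted <- NA_real_
  ok <- !out$empty & !is.na(out$p)
  if (any(ok)) out$p_adjusted[ok] <- bh_adjust(out$p[ok])
  class(out) <- c("burden_battery", "data.frame")
  out
}

#' @export
print.burden_battery <- function(x, ...) {
  cat(sprintf("Burden battery: %d cells (%d tested)\n", nrow(x), sum(!x$empty)))
  df <- as.data.frame(x)
  df$or <- signif(df$or, 3); df$p <- signif(df$p, 3)
  df$p_adjusted <- signif(df$p_adjusted, 3)
  print(df[, c("set", "n_genes_qv", "case_carriers", "control_carriers",
               "or", "p", "p_adjusted")], row.names = FALSE)
  invisible(x)
}

#' Case-only candidate genes
#'
#' Genes in the supplied set carried by at least one case and no control,
#' sorted by decreasing case carrier count then gene id.
#'
#' @param cmat a `collapsing_matrix` (conventionally built under the
#'   ultrarare model).
#' @param geneset gene universe to restrict to (e.g. intolerant genes
#'   without a known disease association).
#' @return data frame `gene`, `case_carriers`.
#' @export
case_only_candidates <- function(cmat, geneset) {
  genes <- intersect(geneset, rownames(cmat$indicator))
  is_case <- cmat$samples$phenotype == "case"
  sub <- cmat$indicator[genes, , drop = FALSE]
  n_case <- as.integer(rowSums(sub[, is_case, drop = FALSE]))
  n_ctrl <- as.integer(rowSums(sub[, !is_case, drop = FALSE]))
  keep <- n_case >= 1L & n_ctrl == 0L
  out <- data.frame(gene = genes[keep], case_carriers = n_case[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$case_carriers, out$gene), , drop = FALSE]
}
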