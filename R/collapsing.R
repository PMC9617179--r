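#' Qualifying-variant model
#'
#' A QV model names the variant filters of one collapsing analysis: the
#' allowed consequence classes and the frequency bounds.  Frequency bounds
#' are exclusive ("minor allele frequency less than" the bound); when
#' `require_absent_external` is TRUE the external bound is ignored and only
#' variants absent from external reference datasets qualify.
#'
#' Three standard models are provided:
#' \describe{
#'   \item{`qv_model_ultrarare_lof()`}{LOF variants absent from external
#'     datasets.}
#'   \item{`qv_model_flex_lof()`}{LOF variants with external MAF < 0.1%
#'     (present or absent), internal MAF < 0.1%.}
#'   \item{`qv_model_synonymous()`}{ultrarare synonymous variants — the
#'     negative-control model for inflation diagnostics.}
#' }
#'
#' @param name model label.
#' @param allowed_classes character vector of consequence classes out of
#'   `"LOF"`, `"missense"`, `"synonymous"`, `"other"`.
#' @param max_external_af exclusive external MAF bound (ignored when
#'   `require_absent_external`).
#' @param require_absent_external only variants absent from external
#'   datasets qualify.
#' @param max_internal_af exclusive internal MAF bound.
#' @return a list of class `qv_model`.
#' @export
qv_model <- function(name, allowed_classes, max_external_af = 1,
                     require_absent_external = FALSE, max_internal_af = 1) {
  stopifnot(is.character(name), length(name) == 1,
            all(allowed_classes %in% c("LOF", "missense", "synonymous", "other")),
            max_external_af >= 0, max_external_af <= 1,
            max_internal_af >= 0, max_internal_af <= 1)
  out <- list(name = name, allowed_classes = allowed_classes,
              max_external_af = max_external_af,
              require_absent_external = isTRUE(require_absent_external),
              max_internal_af = max_internal_af)
  class(out) <- "qv_model"
  out
}

#' @rdname qv_model
#' @export
qv_model_ultrarare_lof <- function() {
  qv_model("ultrarare_lof", "LOF", require_absent_external = TRUE,
           max_internal_af = 0.001)
}

#' @rdname qv_model
#' @export
qv_model_flex_lof <- function() {
  qv_model("flex_lof", "LOF", max_external_af = 0.001, max_internal_af = 0.001)
}

#' @rdname qv_model
#' @export
qv_model_synonymous <- function() {
  qv_model("synonymous", "synonymous", require_absent_external = TRUE,
           max_internal_af = 0.001)
}

#' Filter variants through a qualifying-variant model
#'
#' Retains variants whose consequence class is allowed and whose external
#' and internal frequencies satisfy the model's bounds (strict `<`; absence
#' from external datasets means `external_present == FALSE` regardless of
#' the recorded frequency).  Input order is preserved.
#'
#' @param variants variant data frame (see [read_variants()]).
#' @param model a [qv_model()].
#' @return the qualifying subset of `variants`.
#' @export
qualify_variants <- function(variants, model) {
  stopifnot(inherits(model, "qv_model"))
  keep <- variants$effect_class %in% model$allowed_classes
  if (model$require_absent_external) {
    keep <- keep & !variants$external_present
  } else {
    keep <- keep & (!variants$external_present |
                      variants$external_af < model$max_external_af)
  }
  keep <- keep & variants$internal_af < model$max_internal_af
  variants[keep, , drop = FALSE]
}

#' Build the gene x individual collapsing matrix
#'
#' Entry (g, i) is 1 iff individual i carries at least one qualifying variant
#' in gene g.  Individuals are restricted to (and ordered by) the cluster
#' assignment, which partitions the matrix into per-cluster blocks for the
#' stratified tests.
#'
#' @param variants qualifying variants (with a `carriers` list column).
#' @param samples sample table with `sample_id` and `phenotype`.
#' @param assignment a [cluster_assignment()] (or a data frame with
#'   `sample_id` and `cluster`); only assigned individuals enter the matrix.
#' @return object of class `collapsing_matrix`: list with `indicator`
#'   (genes x individuals 0/1 matrix) and `samples` (sample_id, phenotype,
#'   cluster).
#' @export
build_collapsing_matrix <- function(variants, samples, assignment) {
  asg <- as.data.frame(assignment)[, c("sample_id", "cluster")]
  samp <- merge(asg, samples[, c("sample_id", "phenotype")], by = "sample_id",
                sort = FALSE)
  samp <- samp[order(samp$cluster, samp$sample_id), , drop = FALSE]
  all_carriers <- unique(unlist(variants$carriers))
  unknown <- setdiff(all_carriers, samples$sample_id)
  if (length(unknown))
    stop(sprintf("build_collapsing_matrix: carrier id(s) not in sample table: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  genes <- sort(unique(variants$gene))
  ind <- matrix(0L, nrow = length(genes), ncol = nrow(samp),
                dimnames = list(genes, samp$sample_id))
  if (nrow(variants) > 0 && length(genes) > 0) {
    gi <- match(variants$gene, genes)
    for (v in seq_len(nrow(variants))) {
      ci <- match(intersect(variants$carriers[[v]], samp$sample_id),
                  samp$sample_id)
      if (length(ci)) ind[gi[v], ci] <- 1L
    }
  }
  out <- list(indicator = ind, samples = samp)
  class(out) <- "collapsing_matrix"
  out
}

#' Collapsing matrix from a simulated cohort
#'
#' Shortcut from a `sim_cohort` to a `collapsing_matrix`, optionally
#' restricted to ultrarare or rare-but-present carried variants and to a
#' cluster assignment other than the simulation truth.
#'
#' @param cohort a `sim_cohort`.
#' @param variant_partition one of `"all_rare"`, `"ultrarare"`,
#'   `"rare_but_present"`, or `"synonymous"` (the negative-control process).
#' @param assignment optional [cluster_assignment()]; defaults to the true
#'   simulated clusters.
#' @return a `collapsing_matrix`.
#' @export
cohort_collapsing_matrix <- function(cohort,
                                     variant_partition = c("all_rare", "ultrarare",
                                                           "rare_but_present",
                                                           "synonymous"),
                                     assignment = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  variant_partition <- match.arg(variant_partition)
  ind <- switch(variant_partition,
                all_rare = cohort$carrier,
                ultrarare = cohort$ultrarare,
                rare_but_present = cohort$carrier * (1L - cohort$ultrarare),
                synonymous = cohort$synonymous)
  if (is.null(ind))
    stop("cohort_collapsing_matrix: cohort lacks the '", variant_partition,
         "' matrix")
  samp <- cohort$samples
  if (!is.null(assignment)) {
    asg <- as.data.frame(assignment)[, c("sample_id", "cluster")]
    samp <- merge(asg, samp[, c("sample_id", "phenotype")], by = "sample_id",
                  sort = FALSE)
    ind <- ind[, samp$sample_id, drop = FALSE]
  }
  ord <- order(samp$cluster, samp$sample_id)
  samp <- samp[ord, c("sample_id", "phenotype", "cluster")]
  out <- list(indicator = ind[, samp$sample_id, drop = FALSE], samples = samp)
  class(out) <- "collapsing_matrix"
  out
}

#' @export
print.collapsing_matrix <- function(x, ...) {
  cat(sprintf("Collapsing matrix: %d genes x %d individuals (%d clusters, %d cases)\n",
              nrow(x$indicator), ncol(x$indicator),
              length(unique(x$samples$cluster)),
              sum(x$samples$phenotype == "case")))
  invisible(x)
}

#' Collapse a gene set to a stratified 2x2 table
#'
#' An individual is a carrier of the set iff it has indicator 1 in at least
#' one member gene; per cluster the case/control x carrier/non-carrier
#' counts are extracted.
#'
#' @param cmat a `collapsing_matrix`.
#' @param geneset non-empty character vector of gene ids.
#' @return a [stratified_table()] with one row per cluster.
#' @export
collapse_to_table <- function(cmat, geneset) {
  stopifnot(inherits(cmat, "collapsing_matrix"), length(geneset) > 0)
  present <- intersect(geneset, rownames(cmat$indicator))
  if (length(present) == 0) {
    warning("collapse_to_table: gene set shares no genes with the matrix")
    carrier <- rep(0L, ncol(cmat$indicator))
  } else {
    sub <- cmat$indicator[present, , drop = FALSE]
    carrier <- as.integer(colSums(sub) > 0)
  }
  df <- cmat$samples
  cl <- sort(unique(df$cluster))
  a <- b <- cc <- d <- integer(length(cl))
  for (k in seq_along(cl)) {
    in_k <- df$cluster == cl[k]
    case_k <- in_k & df$phenotype == "case"
    ctrl_k <- in_k & df$phenotype == "control"
    a[k] <- sum(carrier[case_k]); b[k] <- sum(case_k) - a[k]
    cc[k] <- sum(carrier[ctrl_k]); d[k] <- sum(ctrl_k) - cc[k]
  }
  stratified_table(a, b, cc, d, cluster = cl)
}

#' Per-gene stratified carrier counts for a whole matrix
#'
#' Vectorised extraction of case-carrier and control-carrier counts per gene
#' per cluster, for inflation diagnostics and gene-level testing.
#'
#' @param cmat a `collapsing_matrix`.
#' @return list with matrices `a`, `c` (genes x clusters) and vectors `n1`,
#'   `n0` (per-cluster case/control totals), plus `clusters`.
#' @export
per_gene_counts <- function(cmat) {
  stopifnot(inherits(cmat, "collapsing_matrix"))
  df <- cmat$samples
  cl <- sort(unique(df$cluster))
  a <- c_ <- matrix(0L, nrow(cmat$indicator), length(cl),
                    dimnames = list(rownames(cmat$indicator), cl))
  n1 <- n0 <- integer(length(cl))
  for (k in seq_along(cl)) {
    case_k <- df$cluster == cl[k] & df$phenotype == "case"
    ctrl_k <- df$cluster == cl[k] & df$phenotype == "control"
    a[, k] <- rowSums(cmat$indicator[, case_k, drop = FALSE])
    c_[, k] <- rowSums(cmat$indicator[, ctrl_k, drop = FALSE])
    n1[k] <- sum(case_k); n0[k] <- sum(ctrl_k)
  }
  list(a = a, c = c_, n1 = n1, n0 = n0, clusters = cl)
}
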