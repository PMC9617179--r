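#' Simulation configuration for synthetic stratified cohorts
#'
#' Collects every parameter of the synthetic-data generator and validates it.
#' Defaults emulate a critically-ill-children style case-control design:
#' ~231 cases against ~5322 controls spread over three ancestry clusters with
#' distinct background carrier rates and a deliberately different case/control
#' cluster mixture (so confounding by ancestry is present and stratification
#' matters), per-gene rare-LOF carrier probabilities of a few per ten
#' thousand, and case enrichment (odds ratio 2) confined to genes in the
#' intolerant range (LOEUF <= 0.68).
#'
#' @param n_cases,n_controls cohort sizes.
#' @param n_clusters number of ancestry clusters.
#' @param cluster_mixture control mixing proportions over clusters (sums to 1).
#' @param case_mixture case mixing proportions (default: distinct from
#'   `cluster_mixture`, so case/control cluster composition differs and the
#'   pooled analysis is confounded).
#' @param n_genes panel size.
#' @param loeuf_range interval from which gene LOEUF scores are drawn
#'   uniformly; lower bound must be > 0.
#' @param disease_flag_prob probability a gene carries a known
#'   disease-association flag.
#' @param baseline_carrier_rate per-gene per-individual carrier probability in
#'   controls; scalar or one value per cluster.
#' @param enrichment_or odds ratio (>= 1) applied to the case carrier odds in
#'   enriched genes.
#' @param enrichment_loeuf_max LOEUF threshold at/below which the enrichment
#'   applies.
#' @param ultrarare_fraction probability a carried qualifying variant is
#'   absent from external reference datasets.
#' @param syn_carrier_multiplier ratio of the per-gene synonymous-model
#'   carrier rate to the LOF baseline (default 50: rare synonymous variants
#'   are far more abundant per gene than rare LOF variants).  The synonymous
#'   process is the negative control and never receives case enrichment.
#' @param n_trios number of sequenced proband-parent trios.
#' @param mu_mean named vector of mean per-gene per-class de novo mutation
#'   probabilities (per chromosome per generation) for classes `syn`, `mis`,
#'   `lof`; per-gene rates are drawn lognormally around these means.
#' @param seed integer seed; all generator randomness flows from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 231L, n_controls = 5322L,
                       n_clusters = 3L,
                       cluster_mixture = c(0.45, 0.35, 0.20),
                       case_mixture = c(0.25, 0.35, 0.40),
                       n_genes = 2000L,
                       loeuf_range = c(0.03, 2.0),
                       disease_flag_prob = 0.25,
                       baseline_carrier_rate = c(4e-4, 5e-4, 6e-4),
                       enrichment_or = 2.0,
                       enrichment_loeuf_max = 0.68,
                       ultrarare_fraction = 0.6,
                       syn_carrier_multiplier = 50,
                       n_trios = 114L,
                       mu_mean = c(syn = 7.4e-6, mis = 1.6e-5, lof = 2.2e-6),
                       seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
              n_clusters = as.integer(n_clusters),
              cluster_mixture = cluster_mixture, case_mixture = case_mixture,
              n_genes = as.integer(n_genes), loeuf_range = loeuf_range,
              disease_flag_prob = disease_flag_prob,
              baseline_carrier_rate = baseline_carrier_rate,
              enrichment_or = enrichment_or,
              enrichment_loeuf_max = enrichment_loeuf_max,
              ultrarare_fraction = ultrarare_fraction,
              syn_carrier_multiplier = syn_carrier_multiplier,
              n_trios = as.integer(n_trios), mu_mean = mu_mean,
              seed = as.integer(seed))
  bad <- function(field, msg) stop(sprintf("sim_config: invalid `%s` (%s)", field, msg),
                                   call. = FALSE)
  if (cfg$n_genes < 1) bad("n_genes", "must be >= 1")
  if (cfg$n_cases < 0 || cfg$n_controls < 0) bad("n_cases/n_controls", "must be >= 0")
  if (cfg$n_clusters < 1) bad("n_clusters", "must be >= 1")
  for (f in c("cluster_mixture", "case_mixture")) {
    mx <- cfg[[f]]
    if (length(mx) != cfg$n_clusters) bad(f, "length must equal n_clusters")
    if (any(mx < 0) || abs(sum(mx) - 1) > 1e-9) bad(f, "must be non-negative and sum to 1")
  }
  if (length(cfg$loeuf_range) != 2 || cfg$loeuf_range[1] <= 0 ||
      diff(cfg$loeuf_range) <= 0)
    bad("loeuf_range", "need 0 < lower < upper")
  for (f in c("disease_flag_prob", "ultrarare_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "probability must be in [0, 1]")
  if (any(cfg$baseline_carrier_rate < 0) || any(cfg$baseline_carrier_rate > 1))
    bad("baseline_carrier_rate", "probabilities must be in [0, 1]")
  if (!length(cfg$baseline_carrier_rate) %in% c(1L, cfg$n_clusters))
    bad("baseline_carrier_rate", "scalar or one value per cluster")
  if (cfg$enrichment_or < 1) bad("enrichment_or", "odds ratio must be >= 1")
  if (cfg$syn_carrier_multiplier < 0)
    bad("syn_carrier_multiplier", "must be >= 0")
  if (cfg$n_trios < 0) bad("n_trios", "must be >= 0")
  if (any(cfg$mu_mean < 0) || !all(c("syn", "mis", "lof") %in% names(cfg$mu_mean)))
    bad("mu_mean", "need non-negative rates named syn, mis, lof")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a gene panel
#'
#' One record per gene: a LOEUF intolerance score drawn uniformly from
#' `loeuf_range`, a Bernoulli disease-association flag, and lognormal per-gene
#' de novo mutation probabilities per consequence class (`mu_syn`, `mu_mis`,
#' `mu_lof`) centred on `mu_mean`.  Deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return data frame with columns `gene`, `loeuf`, `disease_associated`,
#'   `mu_syn`, `mu_mis`, `mu_lof`.
#' @export
simulate_gene_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 1)
    stop("sim_config: invalid `n_genes` (must be >= 1)", call. = FALSE)
  withr_seed(config$seed, {
    n <- config$n_genes
    sdlog <- 1
    draw_mu <- function(m) stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
    data.frame(
      gene = sprintf("G%05d", seq_len(n)),
      # published LOEUF scores carry 3 decimals, so distinct genes share
      # scores; the scan grid is the set of unique values
      loeuf = round(stats::runif(n, config$loeuf_range[1],
                                 config$loeuf_range[2]), 3),
      disease_associated = stats::rbinom(n, 1, config$disease_flag_prob) == 1,
      mu_syn = draw_mu(config$mu_mean[["syn"]]),
      mu_mis = draw_mu(config$mu_mean[["mis"]]),
      mu_lof = draw_mu(config$mu_mean[["lof"]]),
      stringsAsFactors = FALSE)
  })
}

# Run code with a local RNG state seeded from `seed` (+ optional stream
# offset), restoring the caller's state afterwards.  All generator
# randomness flows through this, so substreams are reproducible.
withr_seed <- function(seed, code, stream = 0L) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.integer(seed) + 7919L * as.integer(stream)) %% .Machine$integer.max)
  code
}

#' Simulate a stratified case-control cohort of gene-level carriers
#'
#' Individuals are assigned ancestry clusters by the configured mixtures
#' (cases and controls separately, so ancestry confounding is realisable).
#' Carrier status is simulated directly at the gene level: for controls a
#' Bernoulli draw at the cluster's baseline rate; for cases the carrier odds
#' are multiplied by `enrichment_or` in genes with
#' `loeuf <= enrichment_loeuf_max` only.  Each carried gene is independently
#' tagged ultrarare (absent from external references) with probability
#' `ultrarare_fraction`.
#'
#' @param config a [sim_config()].
#' @param panel a gene panel from [simulate_gene_panel()].
#' @return a list of class `sim_cohort`:
#'   \describe{
#'     \item{samples}{data frame `sample_id`, `phenotype` ("case"/"control"),
#'       `cluster` (true cluster label).}
#'     \item{carrier}{genes x individuals 0/1 integer matrix.}
#'     \item{ultrarare}{same shape, 1 where the carried variant is absent
#'       from external datasets (0 wherever `carrier` is 0).}
#'     \item{synonymous}{negative-control carrier matrix at
#'       `syn_carrier_multiplier` times the baseline rate, never enriched.}
#'     \item{truth}{ground-truth labels: `true_threshold`, `enriched_genes`,
#'       `cluster`, `phenotype`.}
#'   }
#' @export
simulate_cohort <- function(config, panel) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(panel) == 0) stop("simulate_cohort: panel is empty")
  withr_seed(config$seed, stream = 1L, {
    n <- config$n_cases + config$n_controls
    phenotype <- rep(c("case", "control"), c(config$n_cases, config$n_controls))
    cl_case <- sample.int(config$n_clusters, config$n_cases, replace = TRUE,
                          prob = config$case_mixture)
    cl_ctrl <- sample.int(config$n_clusters, config$n_controls, replace = TRUE,
                          prob = config$cluster_mixture)
    cluster <- paste0("C", c(cl_case, cl_ctrl))
    samples <- data.frame(
      sample_id = sprintf("S%05d", seq_len(n)),
      phenotype = phenotype, cluster = cluster, stringsAsFactors = FALSE)

    base <- rep_len(config$baseline_carrier_rate, config$n_clusters)
    p_ind <- base[c(cl_case, cl_ctrl)]             # per-individual baseline
    enriched <- panel$loeuf <= config$enrichment_loeuf_max
    # per-gene x per-individual carrier probability
    pm <- matrix(rep(p_ind, each = nrow(panel)), nrow = nrow(panel))
    if (config$enrichment_or > 1 && any(enriched) && config$n_cases > 0) {
      idx_case <- seq_len(config$n_cases)
      pe <- pm[enriched, idx_case, drop = FALSE]
      odds <- pe / (1 - pe) * config$enrichment_or
      pm[enriched, idx_case] <- odds / (1 + odds)
    }
    carrier <- matrix(stats::rbinom(length(pm), 1L, pm), nrow = nrow(panel),
                      dimnames = list(panel$gene, samples$sample_id))
    ur <- matrix(0L, nrow(carrier), ncol(carrier), dimnames = dimnames(carrier))
    hits <- which(carrier == 1L)
    ur[hits] <- stats::rbinom(length(hits), 1L, config$ultrarare_fraction)
    # synonymous negative-control process: same cluster structure, higher
    # per-gene rates, no case enrichment anywhere
    p_syn <- pmin(1, p_ind * config$syn_carrier_multiplier)
    syn <- matrix(stats::rbinom(nrow(panel) * n, 1L,
                                rep(p_syn, each = nrow(panel))),
                  nrow = nrow(panel),
                  dimnames = list(panel$gene, samples$sample_id))
    truth <- list(true_threshold = config$enrichment_loeuf_max,
                  enriched_genes = if (config$enrichment_or > 1)
                    panel$gene[enriched] else character(0),
                  cluster = stats::setNames(samples$cluster, samples$sample_id),
                  phenotype = stats::setNames(samples$phenotype, samples$sample_id))
    out <- list(samples = samples, carrier = carrier, ultrarare = ur,
                synonymous = syn, truth = truth, config = config)
    class(out) <- "sim_cohort"
    out
  })
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cases / %d controls, %d genes, %d clusters\n",
              sum(x$samples$phenotype == "case"),
              sum(x$samples$phenotype == "control"),
              nrow(x$carrier), length(unique(x$samples$cluster))))
  invisible(x)
}

#' Simulate common-variant dosages carrying population structure
#'
#' A small panel of unlinked common variants whose allele frequencies differ
#' between clusters (Balding-Nichols style: per-variant ancestral frequency
#' Uniform(0.1, 0.9), cluster frequencies Beta-distributed around it with
#' divergence `fst`).  Input for the PCA + Louvain clustering stage.
#'
#' @param samples sample table with a `cluster` column (true labels).
#' @param n_snps number of variants (default 200).
#' @param fst divergence parameter (default 0.1).
#' @param seed integer seed.
#' @return individuals x variants dosage matrix (0/1/2).
#' @export
simulate_pca_dosage <- function(samples, n_snps = 200L, fst = 0.1, seed = 1L) {
  stopifnot(n_snps >= 1, fst > 0, fst < 1)
  withr_seed(seed, stream = 2L, {
    clusters <- sort(unique(samples$cluster))
    p_anc <- stats::runif(n_snps, 0.1, 0.9)
    shape <- (1 - fst) / fst
    freq <- sapply(clusters, function(k)
      stats::rbeta(n_snps, p_anc * shape, (1 - p_anc) * shape))
    ci <- match(samples$cluster, clusters)
    pm <- t(freq[, ci, drop = FALSE])               # individuals x snps
    dos <- matrix(stats::rbinom(length(pm), 2L, pm), nrow = nrow(pm),
                  dimnames = list(samples$sample_id,
                                  sprintf("V%04d", seq_len(n_snps))))
    dos
  })
}

#' Simulate per-class trio de novo counts
#'
#' For each consequence class, the observed count is Poisson with mean
#' `fold * 2 * n_trios * sum(mu[geneset, class])` — twice the summed per-gene
#' per-chromosome mutation probability across the gene set, times the number
#' of trios, times a configurable true enrichment `fold`.
#'
#' @param config a [sim_config()] (supplies `n_trios` and `seed`).
#' @param panel gene panel with `mu_syn`, `mu_mis`, `mu_lof` columns.
#' @param geneset character vector of gene ids to restrict to.
#' @param fold true enrichment multiplier (default 1 = null).
#' @return named integer vector of observed counts for classes
#'   `synonymous`, `missense`, `lof`.
#' @export
simulate_trio_denovo_counts <- function(config, panel, geneset, fold = 1) {
  stopifnot(inherits(config, "sim_config"), fold >= 0)
  if (config$n_trios < 0) stop("simulate_trio_denovo_counts: n_trios must be >= 0")
  missing_g <- setdiff(geneset, panel$gene)
  if (length(missing_g))
    stop(sprintf("simulate_trio_denovo_counts: no mutation rates for gene(s): %s",
                 paste(utils::head(missing_g, 5), collapse = ", ")))
  sub <- panel[panel$gene %in% geneset, , drop = FALSE]
  lam <- fold * 2 * config$n_trios *
    c(synonymous = sum(sub$mu_syn), missense = sum(sub$mu_mis), lof = sum(sub$mu_lof))
  withr_seed(config$seed, stream = 3L,
             stats::setNames(stats::rpois(3, lam), names(lam)))
}

#' Simulate individual trio de novo calls
#'
#' Emits one row per simulated de novo variant (trio id, gene, class), with
#' per-class totals Poisson as in [simulate_trio_denovo_counts()] and genes
#' chosen within the set proportionally to their class mutation rates.
#'
#' @inheritParams simulate_trio_denovo_counts
#' @return data frame `trio_id`, `gene`, `class`.
#' @export
simulate_trio_denovo_calls <- function(config, panel, geneset, fold = 1) {
  counts <- simulate_trio_denovo_counts(config, panel, geneset, fold)
  sub <- panel[panel$gene %in% geneset, , drop = FALSE]
  mu_cols <- c(synonymous = "mu_syn", missense = "mu_mis", lof = "mu_lof")
  withr_seed(config$seed, stream = 4L, {
    rows <- lapply(names(counts), function(cl) {
      k <- counts[[cl]]
      if (k == 0) return(NULL)
      data.frame(trio_id = sprintf("T%04d", sample.int(max(config$n_trios, 1), k,
                                                       replace = TRUE)),
                 gene = sample(sub$gene, k, replace = TRUE,
                               prob = sub[[mu_cols[[cl]]]]),
                 class = cl, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(trio_id = character(0), gene = character(0),
                        class = character(0), stringsAsFactors = FALSE)
    out
  })
}

#' Expand a simulated cohort to variant-level records
#'
#' Thin variant-level emitter for I/O round-trip testing: one synthetic site
#' per carried gene (1-based positions, one ALT allele per carrier).
#' External allele frequencies are 0 for ultrarare variants and a small
#' nonzero value for rare-but-present ones.
#'
#' @param cohort a `sim_cohort`.
#' @param panel the gene panel used to simulate it.
#' @param effect_class consequence class to stamp on every record
#'   (default `"LOF"`).
#' @return data frame of variant records with a `carriers` list column; see
#'   [read_variants()] for the schema.
#' @export
cohort_to_variants <- function(cohort, panel, effect_class = "LOF") {
  stopifnot(inherits(cohort, "sim_cohort"))
  genes <- rownames(cohort$carrier)
  n_samples <- ncol(cohort$carrier)
  rows <- lapply(seq_along(genes), function(gi) {
    carr <- which(cohort$carrier[gi, ] == 1L)
    if (length(carr) == 0) return(NULL)
    ur <- cohort$ultrarare[gi, carr] == 1L
    ids <- colnames(cohort$carrier)[carr]
    # one site per gene x external-presence status (<= 2 sites per gene)
    out <- list()
    for (st in unique(ur)) {
      sel <- ids[ur == st]
      out[[length(out) + 1L]] <- data.frame(
        chrom = "1", pos = gi * 1000L + as.integer(!st),
        ref = "A", alt = "T", gene = genes[gi], effect_class = effect_class,
        external_af = if (st) 0 else 1e-4, external_present = !st,
        internal_af = length(sel) / (2 * n_samples),
        carriers = I(list(sel)), stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- empty_variant_frame()
  rownames(out) <- NULL
  out
}
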