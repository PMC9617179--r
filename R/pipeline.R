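#' Pipeline run configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"files"`
#'   (read previously written inputs).
#' @param sim a [sim_config()] (simulate mode).
#' @param paths named list of input paths (files mode): `samples`, `panel`,
#'   `carrier`, `ultrarare`.
#' @param n_components,k_neighbors clustering parameters.
#' @param min_cases,min_controls cluster filtering minima.
#' @param n_permutations scan permutations (desk-scale default 2000;
#'   large-scale runs raise this).
#' @param alpha family-wise error rate for the scan.
#' @param intolerance_cap LOEUF bound for the battery gene universe.
#' @param battery_test `"cmh_exact"` or `"fisher"`.
#' @param denovo_fold true de novo enrichment multiplier for the simulated
#'   trio calls (1 = null).
#' @param use_true_clusters skip the PCA + Louvain stage and stratify by the
#'   simulated truth (simulate mode only).
#' @param seed top-level seed; every stage derives its substream from it.
#' @param out_dir output directory (NULL = don't write).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "files"), sim = sim_config(),
                       paths = NULL, n_components = 6L, k_neighbors = 20L,
                       min_cases = 1L, min_controls = 1L,
                       n_permutations = 2000L, alpha = 0.05,
                       intolerance_cap = 0.68,
                       battery_test = c("cmh_exact", "fisher"),
                       denovo_fold = 1, use_true_clusters = TRUE,
                       seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  battery_test <- match.arg(battery_test)
  if (mode == "files") {
    need <- c("samples", "panel", "carrier", "ultrarare")
    missing_p <- setdiff(need, names(paths))
    if (length(missing_p))
      stop("run_config: files mode needs paths: ", paste(missing_p, collapse = ", "))
    for (p in unlist(paths[need]))
      if (!file.exists(p)) stop("run_config: path does not exist: ", p)
  }
  out <- list(mode = mode, sim = sim, paths = paths,
              n_components = n_components, k_neighbors = k_neighbors,
              min_cases = min_cases, min_controls = min_controls,
              n_permutations = n_permutations, alpha = alpha,
              intolerance_cap = intolerance_cap, battery_test = battery_test,
              denovo_fold = denovo_fold, use_true_clusters = use_true_clusters,
              seed = as.integer(seed), out_dir = out_dir)
  class(out) <- "run_config"
  out
}

pipeline_log <- function(fmt, ...) message(sprintf(paste0("[rvburden] ", fmt), ...))

#' Run the full collapsing-analysis pipeline
#'
#' Stages, in order: cohort (simulate or load) -> ancestry clustering
#' (PCA + Louvain, or the simulated truth) -> cluster filtering -> collapsing
#' matrices per variant partition -> LOEUF threshold scan (flex model) ->
#' synonymous-control inflation diagnostic -> gene-set burden battery ->
#' case-only candidates -> trio de novo enrichment.  Each stage logs its
#' counts; result tables are written to `out_dir` as TSV with a header
#' comment recording version, seed, and key parameters.  Two runs with the
#' same configuration are identical.
#'
#' A genomic inflation factor above 1.2 on the synonymous negative-control
#' model triggers a warning (ancestry mismatch signal).
#'
#' @param config a [run_config()].
#' @return list with elements `samples`, `panel`, `assignment`, `matrices`,
#'   `scan`, `lambda_synonymous`, `battery`, `candidates`, `denovo`,
#'   `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  if (config$mode == "simulate") {
    sim <- config$sim
    sim$seed <- seed
    panel <- simulate_gene_panel(sim)
    cohort <- simulate_cohort(sim, panel)
    pipeline_log("simulated cohort: %d cases, %d controls, %d genes",
                 sum(cohort$samples$phenotype == "case"),
                 sum(cohort$samples$phenotype == "control"), nrow(panel))
  } else {
    panel <- read_gene_panel(config$paths$panel)
    samples <- read_sample_table(config$paths$samples)
    carrier <- read_carrier_matrix(config$paths$carrier)
    ur <- read_carrier_matrix(config$paths$ultrarare)
    syn <- if (!is.null(config$paths$synonymous))
      read_carrier_matrix(config$paths$synonymous) else NULL
    cohort <- list(samples = samples, carrier = carrier, ultrarare = ur,
                   synonymous = syn, truth = NULL, config = NULL)
    class(cohort) <- "sim_cohort"
    pipeline_log("loaded cohort: %d samples, %d genes", nrow(samples),
                 nrow(carrier))
  }

  if (config$use_true_clusters && !is.null(cohort$samples$cluster)) {
    assignment <- cluster_assignment(cohort$samples$sample_id,
                                     cohort$samples$cluster,
                                     cohort$samples$phenotype)
    pipeline_log("stratifying by provided cluster labels (%d clusters)",
                 length(unique(assignment$cluster)))
  } else {
    dosage <- simulate_pca_dosage(cohort$samples, seed = seed)
    coords <- project_principal_components(dosage, config$n_components)
    assignment <- louvain_cluster(coords, config$k_neighbors, seed = seed,
                                  phenotype = stats::setNames(
                                    cohort$samples$phenotype,
                                    cohort$samples$sample_id))
    pipeline_log("PCA + Louvain: %d clusters", length(unique(assignment$cluster)))
  }
  assignment <- filter_clusters(assignment, config$min_cases, config$min_controls)
  pipeline_log("analyzed after cluster filtering: %d individuals, %d clusters",
               nrow(assignment), length(unique(assignment$cluster)))

  matrices <- list(
    all_rare = cohort_collapsing_matrix(cohort, "all_rare", assignment),
    ultrarare = cohort_collapsing_matrix(cohort, "ultrarare", assignment),
    rare_but_present = cohort_collapsing_matrix(cohort, "rare_but_present",
                                                assignment))

  scan <- loeuf_scan(matrices$all_rare, panel,
                     n_permutations = config$n_permutations,
                     alpha = config$alpha, seed = seed)
  pipeline_log("scan: %d thresholds, %d permutations, optimum %.3f (p=%.3g)",
               length(scan$thresholds), scan$n_permutations,
               scan$optimal_threshold, scan$optimal_p)

  # synonymous negative control: per-gene asymptotic CMH over the
  # synonymous-model carrier matrix (never enriched, realistic carrier
  # rates), summarised as the genomic inflation factor.  Falls back to the
  # rare-model genes when no synonymous matrix is available.
  lambda_syn <- if (!is.null(cohort$synonymous)) {
    pipeline_lambda(cohort_collapsing_matrix(cohort, "synonymous", assignment),
                    panel)
  } else {
    pipeline_lambda(matrices$all_rare, panel)
  }
  pipeline_log("inflation diagnostic lambda = %.3f", lambda_syn)
  if (is.finite(lambda_syn) && lambda_syn > 1.2)
    warning(sprintf(paste0("run_pipeline: genomic inflation lambda = %.2f > 1.2 ",
                           "on the negative-control model; check ancestry ",
                           "matching"), lambda_syn))

  battery <- run_burden_battery(matrices, panel, config$intolerance_cap,
                                config$battery_test)
  parts <- partition_by_disease_association(panel, config$intolerance_cap)
  candidates <- case_only_candidates(matrices$ultrarare,
                                     parts$no_known_association)
  pipeline_log("battery: %d cells; %d case-only candidate gene(s)",
               nrow(battery), nrow(candidates))

  denovo <- NULL
  if (config$mode == "simulate" && config$sim$n_trios > 0) {
    universe <- panel$gene[!panel$disease_associated]
    calls <- simulate_trio_denovo_calls(config$sim, panel, universe,
                                        fold = config$denovo_fold)
    denovo <- denovo_battery(panel, universe, calls, config$sim$n_trios)
    pipeline_log("de novo battery: %d calls over %d trios", nrow(calls),
                 config$sim$n_trios)
  }

  out <- list(samples = cohort$samples, panel = panel, assignment = assignment,
              matrices = matrices, scan = scan,
              lambda_synonymous = lambda_syn, battery = battery,
              candidates = candidates, denovo = denovo, config = config)
  if (!is.null(config$out_dir)) write_pipeline_outputs(out, config$out_dir)
  out
}

# Per-gene asymptotic CMH p-values on the null gene universe, then lambda.
pipeline_lambda <- function(cmat, panel, exclude_below = NA) {
  counts <- per_gene_counts(cmat)
  genes <- rownames(counts$a)
  if (!is.na(exclude_below)) {
    keep <- panel$loeuf[match(genes, panel$gene)] > exclude_below
    keep[is.na(keep)] <- TRUE
  } else keep <- rep(TRUE, length(genes))
  p <- cmh_chisq_p(counts$a[keep, , drop = FALSE], counts$c[keep, , drop = FALSE],
                   counts$n1, counts$n0)
  p <- p[!is.na(p)]
  if (length(p) == 0) return(NA_real_)
  genomic_inflation_lambda(p)
}

write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hdr <- sprintf("rvburden %s | seed=%d | permutations=%d | cap=%.3g",
                 as.character(utils::packageVersion("rvburden")),
                 result$config$seed, result$config$n_permutations,
                 result$config$intolerance_cap)
  scan_df <- data.frame(threshold = result$scan$thresholds,
                        set_size = result$scan$set_sizes,
                        p_nominal = result$scan$p_nominal,
                        p_empirical = result$scan$p_empirical)
  write_tsv_with_header(scan_df, file.path(out_dir, "scan.tsv"), hdr)
  write_report_tables(result$battery, out_dir, "battery", hdr)
  write_tsv_with_header(result$candidates,
                        file.path(out_dir, "case_only_candidates.tsv"), hdr)
  if (!is.null(result$denovo))
    write_tsv_with_header(as.data.frame(result$denovo),
                          file.path(out_dir, "denovo.tsv"), hdr)
  write_tsv_with_header(as.data.frame(result$assignment),
                        file.path(out_dir, "clusters.tsv"), hdr)
  invisible(out_dir)
}

write_tsv_with_header <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
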