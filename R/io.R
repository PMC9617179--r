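#' @keywords internal
empty_variant_frame <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), gene = character(0),
             effect_class = character(0), external_af = numeric(0),
             external_present = logical(0), internal_af = numeric(0),
             carriers = I(list()), stringsAsFactors = FALSE)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(sprintf("%s: file not found: %s", what, path))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("%s: missing column(s): %s in %s", what,
                 paste(missing_cols, collapse = ", "), path))
  df
}

#' Read annotated variants with carriers
#'
#' Joins a variant/carrier file to a per-variant annotation table and a
#' sample table, producing one record per variant with its carrier set and
#' an internal allele frequency computed as
#' carrier count / (2 x analyzed samples) — at most one qualifying allele
#' per individual per gene is assumed, which leaves the binary collapsing
#' indicator unaffected.
#'
#' Two carrier formats are supported:
#' \describe{
#'   \item{carrier table}{TSV with columns `variant_id`, `sample_id` (one row
#'     per carried allele).}
#'   \item{VCF}{a sites+GT VCF (extension `.vcf`), read with the vcfR
#'     package; any non-reference genotype marks a carrier.}
#' }
#' The annotation TSV needs columns `variant_id`, `chrom`, `pos`, `ref`,
#' `alt`, `gene`, `effect_class`, `external_af` (0 when absent from external
#' datasets) and `external_present` (0/1 or true/false).  Variants that fail
#' to join to exactly one annotation row are dropped with a message; a
#' duplicated annotation key is an error.
#'
#' @param variant_file path to the carrier table or VCF.
#' @param annotation_file path to the annotation TSV.
#' @param sample_file path to the sample TSV (`sample_id`, `phenotype`).
#' @return variant data frame (schema of [cohort_to_variants()]).
#' @export
read_variants <- function(variant_file, annotation_file, sample_file) {
  samples <- read_sample_table(sample_file)
  ann <- read_tsv_checked(annotation_file,
                          c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                            "effect_class", "external_af", "external_present"),
                          "read_variants")
  if (anyDuplicated(ann$variant_id))
    stop("read_variants: duplicate variant_id in annotation file")
  ann$external_present <- parse_flag(ann$external_present)
  if (any(ann$external_af < 0 | ann$external_af > 1))
    stop("read_variants: external_af outside [0, 1]")
  if (any(!ann$external_present & ann$external_af != 0))
    stop("read_variants: external_af must be 0 when external_present is false")

  if (grepl("\\.vcf$", variant_file)) {
    carr <- read_vcf_carriers(variant_file)
  } else {
    cf <- read_tsv_checked(variant_file, c("variant_id", "sample_id"),
                           "read_variants")
    carr <- split(cf$sample_id, cf$variant_id)
  }
  if (length(carr) == 0) return(empty_variant_frame())

  unjoined <- setdiff(names(carr), ann$variant_id)
  if (length(unjoined)) {
    message(sprintf("read_variants: dropped %d variant(s) without annotation",
                    length(unjoined)))
    carr <- carr[setdiff(names(carr), unjoined)]
  }
  if (length(carr) == 0) return(empty_variant_frame())
  a <- ann[match(names(carr), ann$variant_id), , drop = FALSE]
  carriers <- lapply(carr, function(x) sort(unique(as.character(x))))
  out <- data.frame(chrom = as.character(a$chrom), pos = as.integer(a$pos),
                    ref = a$ref, alt = a$alt, gene = a$gene,
                    effect_class = a$effect_class,
                    external_af = as.numeric(a$external_af),
                    external_present = a$external_present,
                    internal_af = vapply(carriers, length, integer(1)) /
                      (2 * nrow(samples)),
                    stringsAsFactors = FALSE)
  out$carriers <- I(unname(carriers))
  if (any(out$pos < 1)) stop("read_variants: positions must be 1-based (>= 1)")
  rownames(out) <- NULL
  out
}

read_vcf_carriers <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_variants: reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) return(list())
  ids <- paste(v@fix[, "CHROM"], v@fix[, "POS"], v@fix[, "REF"],
               v@fix[, "ALT"], sep = ":")
  gt <- vcfR::extract.gt(v)
  carr <- lapply(seq_len(nrow(gt)), function(i) {
    g <- gt[i, ]
    colnames(gt)[!is.na(g) & g != "0/0" & g != "0|0"]
  })
  stats::setNames(carr, ids)
}

#' Read a sample table
#'
#' @param path TSV with columns `sample_id`, `phenotype` (and optionally
#'   `cluster`).
#' @return data frame.
#' @export
read_sample_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "phenotype"), "read_sample_table")
  if (anyDuplicated(df$sample_id)) stop("read_sample_table: duplicate sample_id")
  if (!all(df$phenotype %in% c("case", "control")))
    stop("read_sample_table: phenotype must be 'case' or 'control'")
  df
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  lx <- tolower(as.character(x))
  out <- rep(NA, length(x))
  out[lx %in% c("1", "true", "t", "yes")] <- TRUE
  out[lx %in% c("0", "false", "f", "no")] <- FALSE
  if (anyNA(out)) stop("unrecognised boolean flag value(s): ",
                       paste(utils::head(unique(x[is.na(out)]), 3), collapse = ", "))
  out
}

#' Read a gene panel
#'
#' @param path TSV with columns `gene`, `loeuf`, `disease_associated` and
#'   per-class de novo mutation rate columns `mu_syn`, `mu_mis`, `mu_lof`.
#' @return data frame with one record per gene; genes lacking a LOEUF score
#'   are flagged with a message (retained with `NA`).
#' @export
read_gene_panel <- function(path) {
  df <- read_tsv_checked(path, c("gene", "loeuf", "disease_associated",
                                 "mu_syn", "mu_mis", "mu_lof"),
                         "read_gene_panel")
  if (anyDuplicated(df$gene))
    stop(sprintf("read_gene_panel: duplicate gene id(s): %s",
                 paste(utils::head(unique(df$gene[duplicated(df$gene)]), 5),
                       collapse = ", ")))
  df$disease_associated <- parse_flag(df$disease_associated)
  if (anyNA(df$loeuf))
    message(sprintf("read_gene_panel: %d gene(s) lack a LOEUF score",
                    sum(is.na(df$loeuf))))
  if (any(df$mu_syn < 0 | df$mu_mis < 0 | df$mu_lof < 0, na.rm = TRUE))
    stop("read_gene_panel: mutation rates must be >= 0")
  df
}

#' Read a gene list
#'
#' One gene symbol per line; lines starting with `#` are comments; the
#' result is deduplicated.  Genes absent from a supplied panel are reported
#' but retained.
#'
#' @param path text file.
#' @param panel optional gene panel for the unknown-gene report.
#' @return character vector (a set) of gene ids.
#' @export
read_gene_list <- function(path, panel = NULL) {
  if (!file.exists(path)) stop("read_gene_list: file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning("read_gene_list: empty gene list: ", path)
    return(character(0))
  }
  genes <- unique(lines)
  if (!is.null(panel)) {
    unknown <- setdiff(genes, panel$gene)
    if (length(unknown))
      message(sprintf("read_gene_list: %d gene(s) not in panel (retained)",
                      length(unknown)))
  }
  genes
}

#' Write battery / scan result tables
#'
#' Tab-separated outputs with a fixed column order (set label, gene count
#' with >= 1 QV, case carriers/total, control carriers/total, OR, CI bounds,
#' p, adjusted p).  Rewriting is idempotent.
#'
#' @param battery a `burden_battery` data frame (see [run_burden_battery()]),
#'   possibly empty.
#' @param out_dir output directory (created if needed).
#' @param name file stem (default "battery").
#' @param header_comment optional `# `-prefixed provenance line(s) written
#'   before the header.
#' @return the written path, invisibly.
#' @export
write_report_tables <- function(battery, out_dir, name = "battery",
                                header_comment = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("write_report_tables: cannot create directory ", out_dir)
  path <- file.path(out_dir, paste0(name, ".tsv"))
  cols <- c("set", "n_genes_qv", "case_carriers", "case_total",
            "control_carriers", "control_total", "or", "ci_low", "ci_high",
            "p", "p_adjusted")
  df <- as.data.frame(battery)[, intersect(cols, names(as.data.frame(battery))),
                               drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Emits the sample table, the 0/1 carrier matrix (plus the ultrarare
#' indicator), and optionally a minimal sites+GT VCF with one synthetic site
#' per carried gene (1-based positions), together with an annotation TSV, so
#' the files round-trip through [read_variants()].
#'
#' @param cohort a `sim_cohort`.
#' @param panel its gene panel.
#' @param out_dir output directory.
#' @param vcf also write `cohort.vcf` + `annotation.tsv` (default TRUE).
#' @return named vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, panel, out_dir, vcf = TRUE) {
  stopifnot(inherits(cohort, "sim_cohort"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(samples = file.path(out_dir, "samples.tsv"),
             panel = file.path(out_dir, "panel.tsv"),
             carrier = file.path(out_dir, "carrier_matrix.tsv"),
             ultrarare = file.path(out_dir, "ultrarare_matrix.tsv"),
             synonymous = file.path(out_dir, "synonymous_matrix.tsv"))
  utils::write.table(cohort$samples, paths["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel, paths["panel"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$carrier, paths["carrier"], sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(cohort$ultrarare, paths["ultrarare"], sep = "\t",
                     quote = FALSE, col.names = NA)
  if (!is.null(cohort$synonymous)) {
    utils::write.table(cohort$synonymous, paths["synonymous"], sep = "\t",
                       quote = FALSE, col.names = NA)
  } else {
    paths <- paths[names(paths) != "synonymous"]
  }
  if (vcf) {
    variants <- cohort_to_variants(cohort, panel)
    paths["vcf"] <- file.path(out_dir, "cohort.vcf")
    paths["annotation"] <- file.path(out_dir, "annotation.tsv")
    write_variant_vcf(variants, cohort$samples$sample_id, paths["vcf"])
    write_variant_annotation(variants, paths["annotation"])
  }
  invisible(paths)
}

#' Write variant records as a minimal VCF
#'
#' Sites + GT only; carriers get genotype 0/1 (ALT allele count 1), everyone
#' else 0/0.
#'
#' @param variants variant data frame with a `carriers` list column.
#' @param sample_ids all analyzed sample ids (VCF columns).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_variant_vcf <- function(variants, sample_ids, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", sample_ids), collapse = "\t")), con)
  if (nrow(variants)) {
    for (i in seq_len(nrow(variants))) {
      gt <- ifelse(sample_ids %in% variants$carriers[[i]], "0/1", "0/0")
      writeLines(paste(c(variants$chrom[i], variants$pos[i], ".",
                         variants$ref[i], variants$alt[i], ".", "PASS", ".",
                         "GT", gt), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' @rdname write_variant_vcf
#' @export
write_variant_annotation <- function(variants, path) {
  ann <- data.frame(variant_id = paste(variants$chrom, variants$pos,
                                       variants$ref, variants$alt, sep = ":"),
                    chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    gene = variants$gene, effect_class = variants$effect_class,
                    external_af = variants$external_af,
                    external_present = as.integer(variants$external_present),
                    stringsAsFactors = FALSE)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a carrier matrix written by [write_cohort()]
#'
#' @param path TSV with gene rownames and sample-id columns.
#' @return integer 0/1 matrix.
#' @export
read_carrier_matrix <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  if (any(!m %in% c(0L, 1L))) stop("read_carrier_matrix: entries must be 0/1")
  m
}
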