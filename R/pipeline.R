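#' Read and validate a pipeline configuration
#'
#' The YAML configuration names the inputs (`vcf`, `sample_roles`,
#' optional `masks` with `repeats`/`cnv`/`gaps`/`indels`, optional
#' `gff3`, `pathways`, `autosomes`), the `callable_sites` denominator,
#' the output directory `out_dir`, and optional threshold overrides under
#' `filters`, `read_genotype` and `annotate` (keys mirror the
#' corresponding config constructors). Input paths are checked before any
#' stage runs.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @return validated config list with `filters`, `read_genotype` and
#'   `annotate` expanded to full config objects.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (key in c("vcf", "sample_roles", "callable_sites", "out_dir"))
    if (is.null(config[[key]]))
      stop("config is missing required key '", key, "'", call. = FALSE)
  paths <- c(vcf = config$vcf, unlist(config$masks), gff3 = config$gff3,
             pathways = config$pathways)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  config$filters <- do.call(filter_config, as.list(config$filters))
  config$read_genotype <- do.call(read_genotype_config,
                                  as.list(config$read_genotype))
  ann <- config$annotate
  config$annotate <- list(
    upstream = ann$upstream %||% 1000L,
    downstream = ann$downstream %||% 1000L,
    intergenic_max = ann$intergenic_max %||% 5000L)
  config$depth_mode <- config$depth_mode %||% "all"
  config
}

#' Run the full trio analysis pipeline
#'
#' Chains the stages in fixed order: read trio VCF, restrict to the
#' configured autosomes, site filtering (hard filters, SNP clusters,
#' region masks, depth window), two-method inheritance classification
#' with read-support retention, per-genome and trio-level statistics,
#' region annotation of retained non-Mendelian SNPs, and gene-set
#' enrichment. Writes `calls.tsv`, `summary.json`, `annotation.tsv`,
#' `region_distribution.tsv`, `enrichment.tsv` and `manifest.json` under
#' the configured output directory. `summary.json` is byte-deterministic
#' for identical inputs and configuration; run metadata with timestamps
#' lives only in the manifest.
#'
#' @param config YAML path or list, see [read_pipeline_config()].
#' @return invisibly, a list with the stage outputs (`sites`, `calls`,
#'   `tallies`, `summary`, `annotations`, `enrichment`, `counts`).
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()

  sites <- read_trio_vcf(cfg$vcf, cfg$sample_roles)
  counts$records_in <- nrow(sites)
  if (!is.null(cfg$autosomes))
    sites <- keep_autosomes(sites, cfg$autosomes)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  counts$records_autosomal <- nrow(sites)

  masks <- genome_mask_set(
    repeats = cfg$masks$repeats %||% GenomicRanges::GRanges(),
    cnv = cfg$masks$cnv %||% GenomicRanges::GRanges(),
    gaps = cfg$masks$gaps %||% GenomicRanges::GRanges(),
    indels = cfg$masks$indels %||% GenomicRanges::GRanges())
  sites <- filter_pipeline(sites, masks, cfg$filters,
                           depth_mode = cfg$depth_mode)
  passing <- sites[sites$passed & sites$is_snp, , drop = FALSE]
  counts$records_passing <- nrow(passing)

  cls <- run_trio_classification(passing, cfg$read_genotype)
  counts$calls <- nrow(cls$calls)
  write_call_table(cls$calls, file.path(cfg$out_dir, "calls.tsv"))

  genome_summaries <- lapply(c(mother = "mother", father = "father",
                               offspring = "offspring"), function(r)
    summarize_genome(passing, r, cfg$callable_sites))
  trio_summary <- trio_mutation_summary(
    cls$tallies, cfg$callable_sites,
    fold_references = cfg$fold_references %||% list())

  retained <- cls$calls[cls$calls$retained, , drop = FALSE]
  counts$retained_non_mendelian <- nrow(retained)
  annotations <- NULL
  dist_report <- NULL
  gene_classes <- NULL
  enrichment <- NULL
  if (!is.null(cfg$gff3)) {
    models <- read_gff3(cfg$gff3)
    annotations <- classify_regions(retained, models,
                                    upstream = cfg$annotate$upstream,
                                    downstream = cfg$annotate$downstream,
                                    intergenic_max =
                                      cfg$annotate$intergenic_max)
    utils::write.table(annotations,
                       file.path(cfg$out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    dist_report <- distribution_report(annotations)
    utils::write.table(dist_report,
                       file.path(cfg$out_dir, "region_distribution.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gene_classes <- genes_per_class(retained, annotations)
    if (!is.null(cfg$pathways)) {
      universe <- models$genes$gene_id
      gene_set <- sort(unique(unlist(lapply(gene_classes,
                                            function(x) x$genes))))
      enrichment <- hypergeom_enrich(gene_set, cfg$pathways, universe)
      utils::write.table(enrichment,
                         file.path(cfg$out_dir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      counts$enriched_pathways_tested <- nrow(enrichment)
    }
  }

  summary <- list(
    tallies = cls$tallies,
    genomes = lapply(genome_summaries, unclass),
    trio = unclass(trio_summary),
    region_distribution = dist_report,
    genes_per_class = if (!is.null(gene_classes))
      lapply(gene_classes, function(x) x$n_genes))
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  input_paths <- c(cfg$vcf, unlist(cfg$masks), cfg$gff3, cfg$pathways)
  manifest <- list(
    tool = "triosnp",
    version = as.character(utils::packageVersion("triosnp")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg[setdiff(names(cfg), c("filters", "read_genotype"))],
    thresholds = list(filters = unclass(cfg$filters),
                      read_genotype = unclass(cfg$read_genotype)),
    input_checksums = as.list(tools::md5sum(input_paths)),
    stage_counts = counts)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  invisible(list(sites = sites, calls = cls$calls, tallies = cls$tallies,
                 genome_summaries = genome_summaries,
                 trio_summary = trio_summary, annotations = annotations,
                 region_distribution = dist_report,
                 gene_classes = gene_classes, enrichment = enrichment,
                 counts = counts, config = cfg))
}
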