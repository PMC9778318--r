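INFO_KEYS <- c(QD = "qd", FS = "fs", MQ = "mq", MQRankSum = "mq_rank_sum",
               ReadPosRankSum = "read_pos_rank_sum",
               HaplotypeScore = "haplotype_score")

TRIO_ROLES <- c("mother", "father", "offspring")

#' Read a trio VCF into a site table
#'
#' Parses a multi-sample VCF (v4.x) and extracts, for the three samples
#' named in `sample_roles`, the genotype (GT), per-allele read depths (AD)
#' and total site depth (DP), together with QUAL and the site-level quality
#' annotations used by the hard-filter cascade (QD, FS, MQ, MQRankSum,
#' ReadPosRankSum, HaplotypeScore). Missing fields stay missing (`NA`);
#' nothing is imputed. Non-SNP records are kept with `is_snp = FALSE`.
#'
#' @param path path to a VCF file (plain text or bgzip).
#' @param sample_roles named character vector or list mapping the roles
#'   `mother`, `father`, `offspring` to sample column names in the VCF.
#' @return a data.frame with one row per record: `chrom`, `pos`, `ref`,
#'   `alt` (comma-joined), `qual`, the six INFO annotations (lower-cased
#'   column names), `is_snp`, and per-role `<role>_gt`, `<role>_ad`
#'   (comma-joined), `<role>_dp` columns.
#' @export
read_trio_vcf <- function(path, sample_roles) {
  sample_roles <- unlist(sample_roles)
  if (!all(TRIO_ROLES %in% names(sample_roles)))
    stop("sample_roles must name 'mother', 'father' and 'offspring'",
         call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  have <- colnames(v@gt)[-1]
  missing <- setdiff(unname(sample_roles[TRIO_ROLES]), have)
  if (length(missing) > 0L)
    stop("sample(s) not present in VCF: ", paste(missing, collapse = ", "),
         call. = FALSE)

  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = 7L,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER")))
  n <- nrow(fix)
  sites <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = ifelse(is.na(fix[, "ALT"]), ".", fix[, "ALT"]),
    qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
    stringsAsFactors = FALSE
  )
  if (anyNA(sites$pos))
    stop("malformed VCF record: non-numeric POS at record ",
         which(is.na(sites$pos))[1], call. = FALSE)

  for (key in names(INFO_KEYS)) {
    sites[[INFO_KEYS[[key]]]] <-
      if (n > 0L) suppressWarnings(
        as.numeric(vcfR::extract.info(v, element = key))) else numeric(0)
  }

  alt_split <- strsplit(ifelse(sites$alt == ".", "", sites$alt), ",",
                        fixed = TRUE)
  sites$is_snp <- nchar(sites$ref) == 1L & sites$ref %in% DNA_BASES &
    vapply(alt_split, function(a)
      length(a) > 0L && all(nchar(a) == 1L & a %in% DNA_BASES), logical(1))

  gt <- vcfR::extract.gt(v, element = "GT")
  ad <- vcfR::extract.gt(v, element = "AD")
  dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  for (role in TRIO_ROLES) {
    s <- sample_roles[[role]]
    g <- gt[, s]
    sites[[paste0(role, "_gt")]] <- ifelse(is.na(g), "./.", unname(g))
    a <- ad[, s]
    sites[[paste0(role, "_ad")]] <- ifelse(is.na(a), ".", unname(a))
    sites[[paste0(role, "_dp")]] <- as.integer(unname(dp[, s]))
  }
  rownames(sites) <- NULL
  validate_trio_sites(sites)
  sites
}

# invariant checks on a site table (spec'd on the record type)
validate_trio_sites <- function(sites) {
  if (any(sites$pos < 1L)) stop("position must be >= 1", call. = FALSE)
  for (role in TRIO_ROLES) {
    ads <- split_int_field(sites[[paste0(role, "_ad")]])
    n_all <- vapply(seq_len(nrow(sites)), function(i)
      length(site_alleles(sites$ref[i], sites$alt[i])), integer(1))
    has_ad <- !vapply(ads, function(a) length(a) == 1L && anyNA(a), logical(1))
    bad <- has_ad & lengths(ads) != n_all
    if (any(bad))
      stop(sprintf("AD length mismatch for %s at %s:%d", role,
                   sites$chrom[bad][1], sites$pos[bad][1]), call. = FALSE)
    dpv <- sites[[paste0(role, "_dp")]]
    mx <- vapply(ads, function(a) if (anyNA(a)) NA_integer_ else max(a),
                 NA_integer_)
    bad <- !is.na(dpv) & !is.na(mx) & dpv < mx
    if (any(bad))
      stop(sprintf("DP below max allele depth for %s at %s:%d", role,
                   sites$chrom[bad][1], sites$pos[bad][1]), call. = FALSE)
  }
  invisible(sites)
}

#' Write a trio site table as VCF
#'
#' Emits a minimal VCF v4.2 file carrying exactly the fields the pipeline
#' models (QUAL, the six INFO annotations, GT:AD:DP per sample). Output is
#' byte-deterministic for identical input.
#'
#' @param sites site table as returned by [read_trio_vcf()].
#' @param path output path.
#' @param sample_names character vector of length 3 giving the column names
#'   to use for mother, father and offspring (in that order).
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(sites, path,
                           sample_names = c("mother", "father", "offspring")) {
  stopifnot(length(sample_names) == 3L)
  con <- file(path, open = "wt")
  on.exit(close(con))
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(sites$chrom)),
    sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
            names(INFO_KEYS), names(INFO_KEYS)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )
  writeLines(hdr, con)
  if (nrow(sites) == 0L) return(invisible(path))

  fmt_num <- function(x) ifelse(is.na(x), NA, formatC(x, format = "g",
                                                      digits = 8))
  info_parts <- lapply(names(INFO_KEYS), function(key) {
    v <- fmt_num(sites[[INFO_KEYS[[key]]]])
    ifelse(is.na(v), NA, paste0(key, "=", v))
  })
  info <- apply(do.call(cbind, info_parts), 1L, function(row) {
    row <- row[!is.na(row)]
    if (length(row) == 0L) "." else paste(row, collapse = ";")
  })
  cols <- list(sites$chrom, sites$pos, ".", sites$ref, sites$alt,
               ifelse(is.na(sites$qual), ".", fmt_num(sites$qual)), ".", info,
               "GT:AD:DP")
  for (role in TRIO_ROLES) {
    dpv <- sites[[paste0(role, "_dp")]]
    cols[[length(cols) + 1L]] <- paste(
      sites[[paste0(role, "_gt")]],
      sites[[paste0(role, "_ad")]],
      ifelse(is.na(dpv), ".", dpv), sep = ":")
  }
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

#' Read a BED3 mask track
#'
#' Reads 0-based half-open BED intervals, converts them to 1-based closed
#' `GRanges`, and merges overlapping or adjacent intervals per chromosome.
#'
#' @param path BED3 file path.
#' @return merged, sorted `GRanges`.
#' @export
read_mask_bed <- function(path) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0L)
    return(GenomicRanges::GRanges())
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end")[1:3])
  if (any(bed$start >= bed$end))
    stop("malformed BED: start >= end at line ",
         which(bed$start >= bed$end)[1], call. = FALSE)
  gr <- GenomicRanges::GRanges(bed$chrom,
                               IRanges::IRanges(bed$start + 1L, bed$end))
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Bundle the four mask tracks used by the region filters
#'
#' @param repeats,cnv,gaps,indels `GRanges` (as from [read_mask_bed()]) or
#'   BED3 paths; `indels` holds single-position indel anchors.
#' @return an object of class `genome_mask_set`.
#' @export
genome_mask_set <- function(repeats = GenomicRanges::GRanges(),
                            cnv = GenomicRanges::GRanges(),
                            gaps = GenomicRanges::GRanges(),
                            indels = GenomicRanges::GRanges()) {
  as_track <- function(x) {
    if (is.character(x)) x <- read_mask_bed(x)
    stopifnot(methods::is(x, "GRanges"))
    GenomicRanges::reduce(GenomicRanges::sort(x))
  }
  structure(list(repeats = as_track(repeats), cnv = as_track(cnv),
                 gaps = as_track(gaps), indels = as_track(indels)),
            class = "genome_mask_set")
}

#' Read GFF3 gene models
#'
#' Imports gene/mRNA/ncRNA/exon/CDS/UTR features from a GFF3 file
#' (1-based inclusive coordinates) into an indexed gene-model set.
#' Validates that every exon/CDS has a known parent transcript and that
#' CDS intervals fall inside exons.
#'
#' @param path GFF3 file path.
#' @return an object of class `gene_model_set` with `GRanges` components
#'   `genes` (mcols `gene_id`, `biotype`), `tx`, `exons`, `cds`, `utr5`,
#'   `utr3` (each carrying `gene_id`).
#' @export
read_gff3 <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gff$type)
  ids <- as.character(gff$ID)
  parent <- vapply(as.list(gff$Parent), function(p)
    if (length(p) == 0L) NA_character_ else p[[1]], character(1))

  is_gene <- type == "gene"
  genes <- gff[is_gene]
  gene_ids <- ids[is_gene]
  biotype <- if (!is.null(genes$biotype)) as.character(genes$biotype)
             else rep("protein_coding", sum(is_gene))
  biotype[is.na(biotype)] <- "protein_coding"
  S4Vectors::mcols(genes) <- S4Vectors::DataFrame(
    gene_id = gene_ids,
    biotype = ifelse(biotype == "protein_coding", "coding", "noncoding"))

  is_tx <- type %in% c("mRNA", "transcript", "ncRNA")
  tx <- gff[is_tx]
  tx_ids <- ids[is_tx]
  tx_gene <- parent[is_tx]
  if (anyNA(tx_gene) || !all(tx_gene %in% gene_ids))
    stop("GFF3: transcript without a known gene parent", call. = FALSE)
  S4Vectors::mcols(tx) <- S4Vectors::DataFrame(
    tx_id = tx_ids, gene_id = tx_gene)

  pick <- function(types) {
    sel <- type %in% types
    feats <- gff[sel]
    par <- parent[sel]
    if (anyNA(par) || !all(par %in% tx_ids))
      stop(sprintf("GFF3: orphan %s without a known transcript parent",
                   paste(types, collapse = "/")), call. = FALSE)
    S4Vectors::mcols(feats) <- S4Vectors::DataFrame(
      gene_id = tx_gene[match(par, tx_ids)])
    feats
  }
  exons <- pick("exon")
  cds <- pick("CDS")
  utr5 <- pick(c("five_prime_UTR", "5UTR"))
  utr3 <- pick(c("three_prime_UTR", "3UTR"))

  # CDS must sit inside exons of the same gene
  if (length(cds) > 0L) {
    cov <- GenomicRanges::countOverlaps(cds, exons, type = "within")
    if (any(cov == 0L))
      stop("GFF3: CDS extends beyond exon boundaries", call. = FALSE)
  }
  structure(list(genes = genes, tx = tx, exons = exons, cds = cds,
                 utr5 = utr5, utr3 = utr3),
            class = "gene_model_set")
}

#' Restrict a site table to a configured autosome set
#'
#' Records on other sequences are dropped with a logged count; the
#' chromosome set is supplied, never hard-coded.
#'
#' @param sites site table.
#' @param autosomes character vector of chromosome names to keep.
#' @return the filtered site table.
#' @export
keep_autosomes <- function(sites, autosomes) {
  keep <- sites$chrom %in% autosomes
  if (any(!keep))
    message(sum(!keep), " record(s) dropped: not on configured autosomes")
  sites[keep, , drop = FALSE]
}

CALL_TABLE_COLS <- c("chrom", "pos", "ref", "alt", "state", "origin",
                     "method_agreement", "retained", "reason",
                     "mother_gt", "father_gt", "offspring_gt",
                     "mother_dp", "father_dp", "offspring_dp",
                     "offspring_ad", "tripped")

#' Write / read the classified-call table
#'
#' Tab-separated, fixed column order, header row; byte-deterministic for
#' identical input. An empty call set yields a header-only file.
#'
#' @param calls data.frame of inheritance calls (see
#'   [run_trio_classification()]).
#' @param path output TSV path.
#' @return `path` invisibly (writer); the call data.frame (reader).
#' @export
write_call_table <- function(calls, path) {
  out <- as.data.frame(calls, stringsAsFactors = FALSE)
  for (col in CALL_TABLE_COLS)
    if (is.null(out[[col]])) out[[col]] <- rep(NA, nrow(out))
  out <- out[, CALL_TABLE_COLS, drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_call_table
#' @export
read_call_table <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE, na.strings = ".",
                           stringsAsFactors = FALSE,
                           colClasses = c(pos = "integer"))
  out$retained <- as.logical(out$retained)
  out
}
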