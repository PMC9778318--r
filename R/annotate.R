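REGION_LEVELS <- c("exonic", "UTR5", "UTR3", "intronic", "ncRNA_exonic",
                   "ncRNA_intronic", "upstream", "downstream", "intergenic")

#' Classify SNP positions into genomic region classes
#'
#' Assigns each site exactly one region label by feature overlap against
#' the gene models, with precedence exonic > UTR5 > UTR3 > intronic >
#' ncRNA_exonic > ncRNA_intronic > upstream > downstream > intergenic.
#' "Exonic" means coding sequence; intronic/ncRNA_intronic are positions
#' inside a transcript span not hit by a higher class; upstream and
#' downstream are strand-aware windows off the gene's 5' and 3' ends.
#' Gene assignment lists every gene whose feature produced the label;
#' intergenic sites are assigned the nearest gene(s) only when within
#' `intergenic_max` bp, otherwise no gene.
#'
#' @param sites data.frame with `chrom` and `pos` columns.
#' @param models a [read_gff3()] gene-model set.
#' @param upstream,downstream window sizes (bp) for the flanking classes.
#' @param intergenic_max maximum distance (bp) for intergenic gene
#'   assignment.
#' @return data.frame: `chrom`, `pos`, `region` (factor over the nine
#'   classes), `genes` (comma-joined gene ids, may be empty), `distance`
#'   (bp to nearest gene, intergenic sites only).
#' @export
classify_regions <- function(sites, models, upstream = 1000L,
                             downstream = 1000L, intergenic_max = 5000L) {
  stopifnot(inherits(models, "gene_model_set"))
  n <- nrow(sites)
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, sites$pos))
  genes <- models$genes
  coding <- genes$gene_id[genes$biotype == "coding"]
  noncoding <- genes$gene_id[genes$biotype == "noncoding"]
  tx_span <- models$tx

  feature_sets <- list(
    exonic = models$cds,
    UTR5 = models$utr5,
    UTR3 = models$utr3,
    intronic = tx_span[tx_span$gene_id %in% coding],
    ncRNA_exonic = models$exons[models$exons$gene_id %in% noncoding],
    ncRNA_intronic = tx_span[tx_span$gene_id %in% noncoding],
    upstream = GenomicRanges::promoters(genes, upstream = upstream,
                                        downstream = 0L),
    downstream = GenomicRanges::flank(genes, width = downstream,
                                      start = FALSE))
  feature_sets$upstream$gene_id <- genes$gene_id
  feature_sets$downstream$gene_id <- genes$gene_id

  region <- rep("intergenic", n)
  gene_list <- vector("list", n)
  assigned <- logical(n)
  for (cls in names(feature_sets)) {
    feats <- feature_sets[[cls]]
    if (length(feats) == 0L) next
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, feats, ignore.strand = TRUE))
    q <- S4Vectors::queryHits(hits)
    keep <- !assigned[q]
    if (!any(keep)) next
    hit_genes <- split(feats$gene_id[S4Vectors::subjectHits(hits)[keep]],
                       q[keep])
    idx <- as.integer(names(hit_genes))
    region[idx] <- cls
    gene_list[idx] <- lapply(hit_genes, function(g) sort(unique(g)))
    assigned[idx] <- TRUE
  }

  distance <- rep(NA_real_, n)
  inter <- which(!assigned)
  if (length(inter) > 0L && length(genes) > 0L) {
    near <- suppressWarnings(
      GenomicRanges::distanceToNearest(gr[inter], genes,
                                       ignore.strand = TRUE))
    qh <- S4Vectors::queryHits(near)
    # positional distance: GRanges distance() counts bases strictly
    # between ranges (intergenic sites never overlap a gene span)
    dist <- S4Vectors::mcols(near)$distance + 1L
    distance[inter[qh]] <- dist
    # all genes tied at the nearest distance, if within the 5 kb rule
    all_near <- suppressWarnings(
      GenomicRanges::nearest(gr[inter], genes, select = "all",
                             ignore.strand = TRUE))
    ok_q <- qh[dist <= intergenic_max]
    if (length(ok_q) > 0L) {
      an_q <- S4Vectors::queryHits(all_near)
      sel <- an_q %in% ok_q
      hit_genes <- split(genes$gene_id[S4Vectors::subjectHits(all_near)[sel]],
                         an_q[sel])
      idx <- inter[as.integer(names(hit_genes))]
      gene_list[idx] <- lapply(hit_genes, function(g) sort(unique(g)))
    }
  }
  gene_list[!vapply(gene_list, is.character, logical(1))] <-
    list(character(0))
  data.frame(
    chrom = sites$chrom, pos = sites$pos,
    region = factor(region, levels = REGION_LEVELS),
    genes = vapply(gene_list, paste, character(1), collapse = ","),
    distance = distance, stringsAsFactors = FALSE)
}

#' Region distribution report
#'
#' Counts and percentages per region class; percentages are
#' `count / total * 100` rounded half-even to two decimals.
#'
#' @param annotations data.frame from [classify_regions()], or a named
#'   numeric vector of already-tallied counts per region.
#' @param total percentage denominator; defaults to the sum of the
#'   counts. Supply it explicitly when some classified SNPs are not
#'   represented in the tallied categories.
#' @return data.frame `region`, `count`, `pct`, in decreasing count
#'   order; empty for empty input.
#' @export
distribution_report <- function(annotations, total = NULL) {
  counts <- if (is.data.frame(annotations)) {
    if (nrow(annotations) == 0L) integer(0)
    else table(annotations$region)
  } else annotations
  counts <- counts[counts > 0]
  if (length(counts) == 0L)
    return(data.frame(region = character(0), count = integer(0),
                      pct = numeric(0)))
  if (is.null(total)) total <- sum(counts)
  out <- data.frame(region = names(counts), count = as.integer(counts),
                    pct = round(as.numeric(counts) / total * 100, 2),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$region), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Gene sets per non-Mendelian class
#'
#' Unions the assigned genes of each retained non-Mendelian SNP by class
#' (MIE inherited from the mother, MIE inherited from the father, de
#' novo). A gene hit by several SNPs counts once per class; a gene may
#' appear in several classes.
#'
#' @param calls call table carrying `chrom`, `pos`, `state`, `origin`.
#' @param annotations matching [classify_regions()] output.
#' @return named list (`MIE_mother`, `MIE_father`, `DENOVO`) of lists
#'   with `genes` (sorted character vector) and `n_genes`.
#' @export
genes_per_class <- function(calls, annotations) {
  key_c <- paste(calls$chrom, calls$pos)
  key_a <- paste(annotations$chrom, annotations$pos)
  genes_of <- function(sel) {
    g <- annotations$genes[match(key_c[sel], key_a)]
    g <- unlist(strsplit(g[!is.na(g) & g != ""], ",", fixed = TRUE))
    sort(unique(g))
  }
  classes <- list(
    MIE_mother = calls$state == "MIE" & !is.na(calls$origin) &
      calls$origin == "MOTHER",
    MIE_father = calls$state == "MIE" & !is.na(calls$origin) &
      calls$origin == "FATHER",
    DENOVO = calls$state == "DENOVO")
  lapply(classes, function(sel) {
    g <- genes_of(sel)
    list(genes = g, n_genes = length(g))
  })
}
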