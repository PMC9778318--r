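# Independent oracles, deliberately written as plain enumerations and
# per-base scans, sharing no code with the package implementation.

# inheritance state by exhaustive enumeration of the four one-allele-from-
# each-parent transmissions
oracle_classify <- function(gm, gf, gc) {
  if (anyNA(gm) || anyNA(gf) || anyNA(gc))
    return(list(state = "UNCLASSIFIED", origin = NA_character_))
  novel <- setdiff(gc, union(gm, gf))
  if (length(novel) > 0L) return(list(state = "DENOVO",
                                      origin = NA_character_))
  for (i in 1:2) for (j in 1:2) {
    if (setequal_multiset(c(gm[i], gf[j]), gc))
      return(list(state = "MENDELIAN", origin = NA_character_))
  }
  mom <- all(gc %in% gm); dad <- all(gc %in% gf)
  origin <- if (mom && !dad) "MOTHER" else if (dad && !mom) "FATHER"
            else "UNDETERMINED"
  list(state = "MIE", origin = origin)
}

setequal_multiset <- function(a, b) identical(sort(a), sort(b))

# all diploid genotypes over allele indices 0..(n_alleles-1)
all_genotypes <- function(n_alleles) {
  out <- list()
  for (i in 0:(n_alleles - 1)) for (j in i:(n_alleles - 1))
    out[[length(out) + 1L]] <- c(i, j)
  out
}

# direct re-evaluation of each printed hard-filter expression
oracle_hard_filters <- function(row, cfg) {
  tripped <- character(0)
  chk <- function(val, op, thr, name) {
    if (!is.na(val) && op(val, thr)) tripped <<- c(tripped, name)
  }
  chk(row$qual, `<`, cfg$qual_min, "LowQual")
  chk(row$qd, `<`, cfg$qd_min, "FilterQD")
  chk(row$fs, `>`, cfg$fs_max, "FilterFS")
  chk(row$mq, `<`, cfg$mq_min, "FilterMQ")
  chk(row$mq_rank_sum, `<`, cfg$mqranksum_min, "FilterMQRankSum")
  chk(row$read_pos_rank_sum, `<`, cfg$readposranksum_min,
      "FilterReadPosRankSum")
  chk(row$haplotype_score, `>`, cfg$haplotypescore_max, "HaplotypeScore")
  tripped
}

# brute-force cluster flagging: slide a window of `w` bp over every
# possible start and flag all SNPs of any window holding >= k SNPs
oracle_cluster <- function(pos, k, w) {
  flagged <- logical(length(pos))
  if (length(pos) == 0L) return(flagged)
  for (x in (min(pos) - w):max(pos)) {
    inside <- which(pos >= x & pos <= x + w - 1L)
    if (length(inside) >= k) flagged[inside] <- TRUE
  }
  flagged
}

# per-site loops over mask interval data.frames (chrom, start, end; 1-based
# closed) for the region filters
oracle_region_filters <- function(row, tracks, cfg, depth_mode = "all") {
  tripped <- character(0)
  dist_to <- function(df) {
    df <- df[df$chrom == row$chrom, , drop = FALSE]
    if (nrow(df) == 0L) return(Inf)
    min(ifelse(row$pos >= df$start & row$pos <= df$end, 0,
               pmin(abs(row$pos - df$start), abs(row$pos - df$end))))
  }
  if (dist_to(tracks$repeats) == 0) tripped <- c(tripped, "RepeatMask")
  if (dist_to(tracks$cnv) == 0) tripped <- c(tripped, "CNVMask")
  dps <- if (depth_mode == "offspring") row$offspring_dp
         else c(row$mother_dp, row$father_dp, row$offspring_dp)
  if (any(!is.na(dps) & (dps < cfg$depth_min | dps > cfg$depth_max)))
    tripped <- c(tripped, "DepthWindow")
  if (dist_to(tracks$indels) <= cfg$indel_flank)
    tripped <- c(tripped, "NearIndel")
  if (dist_to(tracks$gaps) <= cfg$gap_core + cfg$gap_flank)
    tripped <- c(tripped, "NearGap")
  tripped
}

# naive per-base region lookup against a flat feature table
# (data.frame: chrom, start, end, class, gene_id, strand), applying the
# same precedence order by scanning classes one by one
oracle_region_lookup <- function(chrom, pos, feats, genes, upstream = 1000,
                                 downstream = 1000, intergenic_max = 5000) {
  classes <- c("exonic", "UTR5", "UTR3", "intronic", "ncRNA_exonic",
               "ncRNA_intronic")
  for (cls in classes) {
    f <- feats[feats$class == cls & feats$chrom == chrom &
                 feats$start <= pos & feats$end >= pos, , drop = FALSE]
    if (nrow(f) > 0L)
      return(list(region = cls, genes = sort(unique(f$gene_id))))
  }
  up <- character(0); down <- character(0)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$chrom != chrom) next
    if (g$strand == "+") {
      if (pos >= g$start - upstream && pos <= g$start - 1)
        up <- c(up, g$gene_id)
      if (pos >= g$end + 1 && pos <= g$end + downstream)
        down <- c(down, g$gene_id)
    } else {
      if (pos >= g$end + 1 && pos <= g$end + upstream)
        up <- c(up, g$gene_id)
      if (pos >= g$start - downstream && pos <= g$start - 1)
        down <- c(down, g$gene_id)
    }
  }
  if (length(up) > 0L) return(list(region = "upstream",
                                   genes = sort(unique(up))))
  if (length(down) > 0L) return(list(region = "downstream",
                                     genes = sort(unique(down))))
  same <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(same) == 0L)
    return(list(region = "intergenic", genes = character(0)))
  d <- ifelse(pos >= same$start & pos <= same$end, 0,
              pmin(abs(pos - same$start), abs(pos - same$end)))
  nearest <- same$gene_id[d == min(d)]
  list(region = "intergenic",
       genes = if (min(d) <= intergenic_max) sort(unique(nearest))
               else character(0))
}

# exact combinatorial hypergeometric upper tail
oracle_hyper_tail <- function(N, K, n, k) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}
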