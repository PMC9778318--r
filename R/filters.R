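#' Hard-filter and region-filter thresholds
#'
#' Defaults reproduce the published trio filtering cascade: QUAL < 30,
#' QD < 2, FS > 20, MQ < 20, MQRankSum < -3, ReadPosRankSum < -3,
#' HaplotypeScore > 13 (all strict inequalities), a 3-SNP/10-bp cluster
#' rule, a 4-50x inclusive depth window, a 50 bp indel exclusion flank,
#' and a 3 + 10 bp assembly-gap exclusion zone.
#'
#' @param qual_min,qd_min,fs_max,mq_min,mqranksum_min,readposranksum_min,haplotypescore_max
#'   hard-filter thresholds on the site annotations.
#' @param cluster_size,cluster_window SNP-cluster rule: flag any
#'   `cluster_size` SNPs spanning at most `cluster_window` bp.
#' @param depth_min,depth_max inclusive per-sample depth window.
#' @param indel_flank bp around an indel anchor to exclude.
#' @param gap_core,gap_flank bp around an assembly-gap edge to exclude
#'   (applied as a single `gap_core + gap_flank` exclusion distance).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(qual_min = 30.0, qd_min = 2.0, fs_max = 20.0,
                          mq_min = 20.0, mqranksum_min = -3.0,
                          readposranksum_min = -3.0,
                          haplotypescore_max = 13.0,
                          cluster_size = 3L, cluster_window = 10L,
                          depth_min = 4L, depth_max = 50L,
                          indel_flank = 50L, gap_core = 3L,
                          gap_flank = 10L) {
  cfg <- list(qual_min = qual_min, qd_min = qd_min, fs_max = fs_max,
              mq_min = mq_min, mqranksum_min = mqranksum_min,
              readposranksum_min = readposranksum_min,
              haplotypescore_max = haplotypescore_max,
              cluster_size = as.integer(cluster_size),
              cluster_window = as.integer(cluster_window),
              depth_min = as.integer(depth_min),
              depth_max = as.integer(depth_max),
              indel_flank = as.integer(indel_flank),
              gap_core = as.integer(gap_core),
              gap_flank = as.integer(gap_flank))
  for (nm in names(cfg)) stopifnot_scalar_number(cfg[[nm]], nm)
  if (cfg$cluster_size < 2L) stop("cluster_size must be >= 2", call. = FALSE)
  if (cfg$depth_min > cfg$depth_max)
    stop("depth_min must be <= depth_max", call. = FALSE)
  structure(cfg, class = "filter_config")
}

HARD_FILTER_NAMES <- c("LowQual", "FilterQD", "FilterFS", "FilterMQ",
                       "FilterMQRankSum", "FilterReadPosRankSum",
                       "HaplotypeScore")
ALL_FILTER_NAMES <- c(HARD_FILTER_NAMES, "SnpCluster", "RepeatMask",
                      "CNVMask", "DepthWindow", "NearIndel", "NearGap")

#' Evaluate the hard-filter cascade on site quality annotations
#'
#' Each predicate uses the strict inequality of the published expression;
#' an absent annotation never trips its filter (rank-sum statistics are
#' undefined at sites without both homozygous classes).
#'
#' @param sites site table (one or more rows).
#' @param cfg a [filter_config()].
#' @return list (one element per site) of character vectors of tripped
#'   filter names, empty when the site passes every hard filter.
#' @export
apply_hard_filters <- function(sites, cfg = filter_config()) {
  lt <- function(x, thr) !is.na(x) & x < thr
  gt <- function(x, thr) !is.na(x) & x > thr
  trips <- cbind(
    LowQual = lt(sites$qual, cfg$qual_min),
    FilterQD = lt(sites$qd, cfg$qd_min),
    FilterFS = gt(sites$fs, cfg$fs_max),
    FilterMQ = lt(sites$mq, cfg$mq_min),
    FilterMQRankSum = lt(sites$mq_rank_sum, cfg$mqranksum_min),
    FilterReadPosRankSum = lt(sites$read_pos_rank_sum,
                              cfg$readposranksum_min),
    HaplotypeScore = gt(sites$haplotype_score, cfg$haplotypescore_max))
  lapply(seq_len(nrow(sites)), function(i)
    HARD_FILTER_NAMES[trips[i, ]])
}

#' Flag SNPs in dense clusters
#'
#' A position is flagged when it belongs to any run of `cluster_size`
#' consecutive SNPs whose span is at most `cluster_window - 1` bp (i.e. at
#' least `cluster_size` SNPs inside a `cluster_window`-bp window). All
#' members of a qualifying window are flagged.
#'
#' @param chrom chromosome of each position.
#' @param pos positions, sorted ascending within each chromosome.
#' @param cfg a [filter_config()].
#' @return logical vector, `TRUE` where clustered.
#' @export
flag_snp_clusters <- function(chrom, pos, cfg = filter_config()) {
  stopifnot(length(chrom) == length(pos))
  flagged <- logical(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    p <- pos[idx]
    if (is.unsorted(p))
      stop("positions must be sorted ascending within each chromosome",
           call. = FALSE)
    k <- cfg$cluster_size
    if (length(p) >= k) {
      for (i in seq_len(length(p) - k + 1L)) {
        if (p[i + k - 1L] - p[i] <= cfg$cluster_window - 1L)
          flagged[idx[i:(i + k - 1L)]] <- TRUE
      }
    }
  }
  flagged
}

# positional distance (bp) from each site to the nearest interval of a
# track: 0 inside, |pos - edge| outside, Inf when the track has no
# interval on that chromosome. GRanges distance() counts bases strictly
# between ranges, hence the +1 for non-overlapping hits.
dist_to_track <- function(chrom, pos, track) {
  d <- rep(Inf, length(pos))
  if (length(track) == 0L) return(d)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  inside <- GenomicRanges::countOverlaps(gr, track) > 0L
  hits <- GenomicRanges::distanceToNearest(gr, track)
  q <- S4Vectors::queryHits(hits)
  d[q] <- S4Vectors::mcols(hits)$distance + 1L
  d[inside] <- 0
  d
}

#' Evaluate region and depth filters against mask tracks
#'
#' Trips `RepeatMask` / `CNVMask` on overlap with the respective track,
#' `NearIndel` within `indel_flank` bp of an indel anchor, `NearGap`
#' within `gap_core + gap_flank` bp of an assembly gap, and `DepthWindow`
#' when the total depth leaves the inclusive `[depth_min, depth_max]`
#' window — for the offspring only (`depth_mode = "offspring"`) or for any
#' of the three samples (`depth_mode = "all"`, the default used for trio
#' classification).
#'
#' @param sites site table.
#' @param masks a [genome_mask_set()].
#' @param cfg a [filter_config()].
#' @param depth_mode `"all"` or `"offspring"`.
#' @return list of character vectors of tripped filter names per site.
#' @export
apply_region_filters <- function(sites, masks, cfg = filter_config(),
                                 depth_mode = c("all", "offspring")) {
  depth_mode <- match.arg(depth_mode)
  stopifnot(inherits(masks, "genome_mask_set"))
  in_repeat <- dist_to_track(sites$chrom, sites$pos, masks$repeats) == 0
  in_cnv <- dist_to_track(sites$chrom, sites$pos, masks$cnv) == 0
  near_indel <- dist_to_track(sites$chrom, sites$pos, masks$indels) <=
    cfg$indel_flank
  near_gap <- dist_to_track(sites$chrom, sites$pos, masks$gaps) <=
    cfg$gap_core + cfg$gap_flank

  out_of_window <- function(dp)
    !is.na(dp) & (dp < cfg$depth_min | dp > cfg$depth_max)
  depth_bad <- if (depth_mode == "offspring") {
    out_of_window(sites$offspring_dp)
  } else {
    out_of_window(sites$mother_dp) | out_of_window(sites$father_dp) |
      out_of_window(sites$offspring_dp)
  }

  trips <- cbind(RepeatMask = in_repeat, CNVMask = in_cnv,
                 DepthWindow = depth_bad, NearIndel = near_indel,
                 NearGap = near_gap)
  nm <- colnames(trips)
  lapply(seq_len(nrow(sites)), function(i) nm[trips[i, ]])
}

#' Run the full site-filter cascade
#'
#' Combines hard filters, SNP-cluster flagging (over the SNP records, in
#' position order per chromosome) and region/depth filters into one
#' verdict per site. A site passes iff no filter trips.
#'
#' @param sites site table sorted by (chrom, pos).
#' @param masks a [genome_mask_set()].
#' @param cfg a [filter_config()].
#' @param depth_mode passed to [apply_region_filters()].
#' @param verbose log per-filter trip counts.
#' @return `sites` with list-column `tripped` and logical column `passed`.
#' @export
filter_pipeline <- function(sites, masks = genome_mask_set(),
                            cfg = filter_config(),
                            depth_mode = c("all", "offspring"),
                            verbose = FALSE) {
  depth_mode <- match.arg(depth_mode)
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites))))
    stop("sites must be sorted by (chrom, pos)", call. = FALSE)
  hard <- apply_hard_filters(sites, cfg)
  region <- apply_region_filters(sites, masks, cfg, depth_mode)
  clustered <- logical(nrow(sites))
  snp_idx <- which(sites$is_snp)
  clustered[snp_idx] <- flag_snp_clusters(sites$chrom[snp_idx],
                                          sites$pos[snp_idx], cfg)
  tripped <- lapply(seq_len(nrow(sites)), function(i) {
    t <- c(hard[[i]], if (clustered[i]) "SnpCluster", region[[i]])
    ALL_FILTER_NAMES[ALL_FILTER_NAMES %in% t]
  })
  sites$tripped <- tripped
  sites$passed <- lengths(tripped) == 0L
  if (verbose) {
    counts <- table(factor(unlist(tripped), levels = ALL_FILTER_NAMES))
    message("filter trip counts: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  sites
}
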