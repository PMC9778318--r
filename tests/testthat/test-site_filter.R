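cfg <- filter_config()

test_that("hard filters trip on the printed strict inequalities", {
  expect_equal(apply_hard_filters(make_site(qd = 1.5), cfg)[[1]],
               "FilterQD")
  # boundary value does not trip a strict inequality
  expect_equal(apply_hard_filters(make_site(qd = 2.0), cfg)[[1]],
               character(0))
  expect_equal(apply_hard_filters(make_site(fs = 25, mq = 10), cfg)[[1]],
               c("FilterFS", "FilterMQ"))
  expect_equal(apply_hard_filters(make_site(qual = 29.9), cfg)[[1]],
               "LowQual")
  expect_equal(
    apply_hard_filters(make_site(mq_rank_sum = -3.5,
                                 read_pos_rank_sum = -4,
                                 haplotype_score = 13.1), cfg)[[1]],
    c("FilterMQRankSum", "FilterReadPosRankSum", "HaplotypeScore"))
})

test_that("absent INFO annotations never trip their filter", {
  site <- make_site(qd = NA, fs = NA, mq = NA, mq_rank_sum = NA,
                    read_pos_rank_sum = NA, haplotype_score = NA)
  expect_equal(apply_hard_filters(site, cfg)[[1]], character(0))
})

test_that("hard filters agree with per-expression re-evaluation on random sites", {
  sites <- random_sites(1000, seed = 101)
  got <- apply_hard_filters(sites, cfg)
  for (i in seq_len(nrow(sites)))
    expect_equal(got[[i]], oracle_hard_filters(sites[i, ], cfg),
                 info = paste("site", i))
})

test_that("SNP clusters flag every member of a qualifying window", {
  expect_equal(flag_snp_clusters(rep("chr1", 3), c(100L, 105L, 109L), cfg),
               rep(TRUE, 3))
  expect_equal(flag_snp_clusters(rep("chr1", 3), c(100L, 200L, 300L), cfg),
               rep(FALSE, 3))
  expect_equal(flag_snp_clusters(rep("chr1", 2), c(100L, 105L), cfg),
               rep(FALSE, 2))
  # window membership, not just window interiors: 4 SNPs, middle window
  expect_equal(flag_snp_clusters(rep("chr1", 4), c(100L, 120L, 125L, 129L),
                                 cfg), c(FALSE, TRUE, TRUE, TRUE))
  expect_error(flag_snp_clusters(rep("chr1", 2), c(105L, 100L), cfg),
               "sorted")
})

test_that("cluster flagging equals the brute-force sliding-window oracle", {
  set.seed(77)
  for (rep in 1:20) {
    pos <- sort(sample(500L, 30L))
    got <- flag_snp_clusters(rep("chr1", 30), pos, cfg)
    expect_equal(got, oracle_cluster(pos, cfg$cluster_size,
                                     cfg$cluster_window),
                 info = paste("rep", rep))
  }
})

test_that("region filters trip on mask proximity and the depth window", {
  masks <- genome_mask_set(indels = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1040, 1040)))
  expect_equal(apply_region_filters(make_site(pos = 1000L), masks,
                                    cfg)[[1]], "NearIndel")
  # inclusive depth bounds: 4 and 50 pass, 3 and 51 fail
  nomask <- genome_mask_set()
  ok <- make_site(offspring_dp = 4L, offspring_ad = "2,2")
  expect_equal(apply_region_filters(ok, nomask, cfg)[[1]], character(0))
  low <- make_site(offspring_dp = 3L, offspring_ad = "2,1")
  expect_equal(apply_region_filters(low, nomask, cfg)[[1]], "DepthWindow")
  hi <- make_site(offspring_dp = 51L, offspring_ad = "26,25")
  expect_equal(apply_region_filters(hi, nomask, cfg)[[1]], "DepthWindow")
  # offspring mode ignores a parent's out-of-window depth
  pd <- make_site(mother_dp = 3L, mother_ad = "3,0")
  expect_equal(apply_region_filters(pd, nomask, cfg)[[1]], "DepthWindow")
  expect_equal(apply_region_filters(pd, nomask, cfg,
                                    depth_mode = "offspring")[[1]],
               character(0))
  # gap rule: within gap_core + gap_flank = 13 bp of a gap edge
  gaps <- genome_mask_set(gaps = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(2000, 2100)))
  expect_equal(apply_region_filters(make_site(pos = 1987L), gaps,
                                    cfg)[[1]], "NearGap")
  expect_equal(apply_region_filters(make_site(pos = 1986L), gaps,
                                    cfg)[[1]], character(0))
})

test_that("indel flank boundary is inclusive at 50 bp", {
  masks <- genome_mask_set(indels = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1050, 1050)))
  expect_equal(apply_region_filters(make_site(pos = 1000L), masks,
                                    cfg)[[1]], "NearIndel")
  masks2 <- genome_mask_set(indels = GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1051, 1051)))
  expect_equal(apply_region_filters(make_site(pos = 1000L), masks2,
                                    cfg)[[1]], character(0))
})

test_that("the filter cascade is order-independent, monotone, and matches
           brute-force re-evaluation on 1000 random sites", {
  sites <- random_sites(1000, seed = 202)
  rm_ <- random_masks(seed = 203)
  out <- filter_pipeline(sites, rm_$masks, cfg)

  # brute-force re-evaluation of every site, filter by filter
  snp_pos <- split(seq_len(nrow(sites)), sites$chrom)
  clustered <- logical(nrow(sites))
  for (idx in snp_pos)
    clustered[idx] <- oracle_cluster(sites$pos[idx], cfg$cluster_size,
                                     cfg$cluster_window)
  for (i in seq_len(nrow(sites))) {
    expected <- c(oracle_hard_filters(sites[i, ], cfg),
                  if (clustered[i]) "SnpCluster",
                  oracle_region_filters(sites[i, ], rm_$dfs, cfg))
    expect_setequal(out$tripped[[i]], expected)
  }
  expect_equal(out$passed, lengths(out$tripped) == 0L)

  # order independence: trip sets are unions of independent predicates —
  # recomposing from separately computed components changes nothing
  hard <- apply_hard_filters(sites, cfg)
  region <- apply_region_filters(sites, rm_$masks, cfg)
  recomposed <- lapply(seq_len(nrow(sites)), function(i)
    sort(unique(c(region[[i]], if (clustered[i]) "SnpCluster", hard[[i]]))))
  expect_equal(lapply(out$tripped, sort), recomposed)

  # monotonicity: relaxing any single threshold never trips more sites
  n_tripped <- sum(!out$passed)
  relaxations <- list(filter_config(qual_min = 10),
                      filter_config(qd_min = 1),
                      filter_config(fs_max = 40),
                      filter_config(mq_min = 10),
                      filter_config(mqranksum_min = -6),
                      filter_config(readposranksum_min = -6),
                      filter_config(haplotypescore_max = 26),
                      filter_config(depth_min = 2, depth_max = 60),
                      filter_config(indel_flank = 10),
                      filter_config(gap_core = 1, gap_flank = 2),
                      filter_config(cluster_window = 5))
  for (rcfg in relaxations) {
    relaxed <- filter_pipeline(sites, rm_$masks, rcfg)
    expect_lte(sum(!relaxed$passed), n_tripped)
  }
})

test_that("planted simulator violations are the only hard-filter trips", {
  sim <- small_sim()
  sites <- sim$sites
  key <- paste(sites$chrom, sites$pos)
  truth <- sim$truth[match(key, paste(sim$truth$chrom, sim$truth$pos)), ]
  got <- apply_hard_filters(sites, cfg)
  planted <- truth$planted_qc_violation
  expect_equal(vapply(got, function(t)
    if (length(t) == 0L) "" else t, character(1)), planted)
})
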