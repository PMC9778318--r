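# Fixture builders: everything is generated in code at test time.

# one or more site-table rows with nominal pass-range defaults
make_site <- function(chrom = "chr1", pos = 1000L, ref = "A", alt = "G",
                      qual = 500, qd = 20, fs = 1, mq = 50,
                      mq_rank_sum = 0, read_pos_rank_sum = 0,
                      haplotype_score = 1,
                      mother_gt = "0/0", mother_ad = "30,0", mother_dp = 30L,
                      father_gt = "0/0", father_ad = "30,0", father_dp = 30L,
                      offspring_gt = "0/1", offspring_ad = "15,15",
                      offspring_dp = 30L) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                   alt = alt, qual = qual, qd = qd, fs = fs, mq = mq,
                   mq_rank_sum = mq_rank_sum,
                   read_pos_rank_sum = read_pos_rank_sum,
                   haplotype_score = haplotype_score,
                   mother_gt = mother_gt, mother_ad = mother_ad,
                   mother_dp = as.integer(mother_dp),
                   father_gt = father_gt, father_ad = father_ad,
                   father_dp = as.integer(father_dp),
                   offspring_gt = offspring_gt,
                   offspring_ad = offspring_ad,
                   offspring_dp = as.integer(offspring_dp),
                   stringsAsFactors = FALSE)
  alts <- strsplit(ifelse(df$alt == ".", "", df$alt), ",", fixed = TRUE)
  df$is_snp <- nchar(df$ref) == 1L &
    vapply(alts, function(a) length(a) > 0L && all(nchar(a) == 1L),
           logical(1))
  df
}

# random site table for property tests: QC values straddle thresholds,
# depths straddle the window
random_sites <- function(n, seed) {
  set.seed(seed)
  dp <- function() as.integer(sample(c(2:8, 20:40, 48:55), n,
                                     replace = TRUE))
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), character(1))
  sites <- make_site(
    chrom = sample(paste0("chr", 1:3), n, replace = TRUE),
    pos = as.integer(sample(1e6, n)),
    ref = ref, alt = alt, qual = round(runif(n, 0, 100), 1),
    qd = round(runif(n, 0, 6), 2), fs = round(runif(n, 0, 40), 2),
    mq = round(runif(n, 0, 60), 2),
    mq_rank_sum = round(runif(n, -6, 2), 2),
    read_pos_rank_sum = round(runif(n, -6, 2), 2),
    haplotype_score = round(runif(n, 0, 26), 2),
    mother_dp = dp(), father_dp = dp(), offspring_dp = dp())
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

# random mask tracks as plain data.frames (1-based closed) plus the
# corresponding genome_mask_set
random_masks <- function(seed, n_per_track = 8L, chroms = paste0("chr", 1:3),
                         max_pos = 1e6) {
  set.seed(seed)
  track_df <- function(width_max) {
    start <- sample(max_pos, n_per_track)
    data.frame(chrom = sample(chroms, n_per_track, replace = TRUE),
               start = start,
               end = start + sample(width_max, n_per_track, replace = TRUE))
  }
  dfs <- list(repeats = track_df(5000), cnv = track_df(10000),
              gaps = track_df(500), indels = NULL)
  p <- sample(max_pos, n_per_track)
  dfs$indels <- data.frame(chrom = sample(chroms, n_per_track,
                                          replace = TRUE),
                           start = p, end = p)
  to_gr <- function(df)
    GenomicRanges::reduce(GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end)))
  masks <- genome_mask_set(repeats = to_gr(dfs$repeats),
                           cnv = to_gr(dfs$cnv), gaps = to_gr(dfs$gaps),
                           indels = to_gr(dfs$indels))
  list(dfs = dfs, masks = masks)
}

# a small deterministic GFF3 written to disk: returns path plus flat
# feature tables for the per-base oracle
tiny_gff3 <- function(dir = file.path(tempdir(), "triosnp-tiny-gff")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "tiny.gff3")
  lines <- c(
    "##gff-version 3",
    # coding + strand gene: UTR5 1000-1199, CDS 1200-1999 & 3000-3799,
    # UTR3 3800-3999; intron 2000-2999
    "chr1\ttest\tgene\t1000\t3999\t.\t+\t.\tID=geneA;biotype=protein_coding",
    "chr1\ttest\tmRNA\t1000\t3999\t.\t+\t.\tID=geneA.t1;Parent=geneA",
    "chr1\ttest\texon\t1000\t1999\t.\t+\t.\tParent=geneA.t1",
    "chr1\ttest\texon\t3000\t3999\t.\t+\t.\tParent=geneA.t1",
    "chr1\ttest\tfive_prime_UTR\t1000\t1199\t.\t+\t.\tParent=geneA.t1",
    "chr1\ttest\tCDS\t1200\t1999\t.\t+\t.\tParent=geneA.t1",
    "chr1\ttest\tCDS\t3000\t3799\t.\t+\t.\tParent=geneA.t1",
    "chr1\ttest\tthree_prime_UTR\t3800\t3999\t.\t+\t.\tParent=geneA.t1",
    # noncoding - strand gene with two exons
    "chr1\ttest\tgene\t20000\t22999\t.\t-\t.\tID=geneB;biotype=ncRNA",
    "chr1\ttest\tncRNA\t20000\t22999\t.\t-\t.\tID=geneB.t1;Parent=geneB",
    "chr1\ttest\texon\t20000\t20999\t.\t-\t.\tParent=geneB.t1",
    "chr1\ttest\texon\t22000\t22999\t.\t-\t.\tParent=geneB.t1",
    # second coding gene on - strand, single exon fully coding
    "chr2\ttest\tgene\t5000\t6999\t.\t-\t.\tID=geneC;biotype=protein_coding",
    "chr2\ttest\tmRNA\t5000\t6999\t.\t-\t.\tID=geneC.t1;Parent=geneC",
    "chr2\ttest\texon\t5000\t6999\t.\t-\t.\tParent=geneC.t1",
    "chr2\ttest\tCDS\t5000\t6999\t.\t-\t.\tParent=geneC.t1")
  writeLines(lines, path)
  genes <- data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000, 20000, 5000), end = c(3999, 22999, 6999),
    strand = c("+", "-", "-"), stringsAsFactors = FALSE)
  feats <- rbind(
    data.frame(chrom = "chr1", start = 1200, end = 1999, class = "exonic",
               gene_id = "geneA"),
    data.frame(chrom = "chr1", start = 3000, end = 3799, class = "exonic",
               gene_id = "geneA"),
    data.frame(chrom = "chr1", start = 1000, end = 1199, class = "UTR5",
               gene_id = "geneA"),
    data.frame(chrom = "chr1", start = 3800, end = 3999, class = "UTR3",
               gene_id = "geneA"),
    data.frame(chrom = "chr1", start = 1000, end = 3999, class = "intronic",
               gene_id = "geneA"),
    data.frame(chrom = "chr1", start = 20000, end = 20999,
               class = "ncRNA_exonic", gene_id = "geneB"),
    data.frame(chrom = "chr1", start = 22000, end = 22999,
               class = "ncRNA_exonic", gene_id = "geneB"),
    data.frame(chrom = "chr1", start = 20000, end = 22999,
               class = "ncRNA_intronic", gene_id = "geneB"),
    data.frame(chrom = "chr2", start = 5000, end = 6999, class = "exonic",
               gene_id = "geneC"))
  list(path = path, genes = genes, feats = feats)
}

trio_roles <- list(mother = "horse", father = "donkey", offspring = "mule")

# small simulated trio shared by several test files (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_sites = 5e4, n_chrom = 2L,
                        n_genes = 20L, n_pathways = 8L,
                        mie_injection_rate = 2e-3,
                        denovo_injection_rate = 5e-4)
      cache <<- simulate_trio(cfg, dir = file.path(tempdir(),
                                                   "triosnp-small-sim"))
    }
    cache
  }
})
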