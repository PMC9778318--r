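#' Synthetic trio simulation settings
#'
#' Defaults emulate a hybrid trio with strongly divergent parental SNP
#' densities against the reference: the mother's genome carries variants
#' at 0.20% of sites with about two thirds heterozygous, the father's at
#' 0.95% of sites with about 8% heterozygous (the reference being of the
#' maternal species), 30x mean Poisson depth, and low planted rates of
#' Mendelian-error and de novo events. Sites are simulated independently
#' on a regular coordinate grid; SNP-cluster test cases are planted
#' explicitly by tests rather than emerging from linkage.
#'
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @param n_sites number of simulated genome sites (callable genome).
#' @param n_chrom number of autosomes (named `chr1..chrK`, K <= 9).
#' @param site_spacing bp between consecutive simulated sites.
#' @param mother_snp_rate,father_snp_rate per-site probability that the
#'   parent's genome differs from the reference.
#' @param mother_het_fraction,father_het_fraction fraction of that
#'   parent's variant sites that are heterozygous.
#' @param mean_depth mean Poisson site depth per sample.
#' @param base_error_rate per-read probability of reading a wrong base.
#' @param mie_injection_rate per-site probability of a planted Mendelian
#'   inheritance error (both offspring alleles copied from one parent,
#'   parents forced to divergent homozygotes so the violation is real).
#' @param denovo_injection_rate per-site probability of a planted de novo
#'   allele absent from both parents.
#' @param qc_violation_rate per-variant-site probability of planting one
#'   hard-filter violation in the QC annotations.
#' @param repeat_density,cnv_density,gap_density approximate fraction of
#'   the genome covered by each mask track.
#' @param repeat_mean_len,cnv_mean_len,gap_mean_len mean interval length.
#' @param indel_rate per-bp rate of indel anchor positions.
#' @param n_genes,n_pathways size of the synthetic annotation.
#' @param coding_fraction fraction of genes that are protein coding.
#' @param sample_names VCF column names for mother, father, offspring.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_sites = 1e6, n_chrom = 5L,
                       site_spacing = 100L,
                       mother_snp_rate = 0.0020, father_snp_rate = 0.0095,
                       mother_het_fraction = 0.67,
                       father_het_fraction = 0.08,
                       mean_depth = 30, base_error_rate = 0.01,
                       mie_injection_rate = 1e-4,
                       denovo_injection_rate = 2e-5,
                       qc_violation_rate = 0.02,
                       repeat_density = 0.02, repeat_mean_len = 500L,
                       cnv_density = 0.005, cnv_mean_len = 2000L,
                       gap_density = 0.001, gap_mean_len = 200L,
                       indel_rate = 1e-5,
                       n_genes = 200L, n_pathways = 20L,
                       coding_fraction = 0.8,
                       sample_names = c("horse", "donkey", "mule")) {
  cfg <- as.list(environment())
  rates <- c("mother_snp_rate", "father_snp_rate", "mother_het_fraction",
             "father_het_fraction", "mie_injection_rate",
             "denovo_injection_rate", "qc_violation_rate", "repeat_density",
             "cnv_density", "gap_density", "indel_rate", "base_error_rate",
             "coding_fraction")
  for (nm in rates) {
    stopifnot_scalar_number(cfg[[nm]], nm)
    if (cfg[[nm]] < 0 || cfg[[nm]] > 1)
      stop(sprintf("'%s' must be in [0, 1]", nm), call. = FALSE)
  }
  if (cfg$mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  if (cfg$n_chrom > 9L) stop("n_chrom must be <= 9", call. = FALSE)
  stopifnot(length(cfg$sample_names) == 3L)
  cfg$n_sites <- as.integer(cfg$n_sites)
  cfg$n_chrom <- as.integer(cfg$n_chrom)
  structure(cfg, class = "sim_config")
}

# one base different from each element of `ref`
other_base <- function(ref) {
  shift <- sample.int(3L, length(ref), replace = TRUE)
  DNA_BASES[(match(ref, DNA_BASES) - 1L + shift) %% 4L + 1L]
}

# multinomial draws over the 4 bases via sequential binomials (vectorised)
draw_base_counts <- function(dp, prob) {
  m <- length(dp)
  counts <- matrix(0L, m, 4L)
  rem <- dp
  ptot <- rep(1, m)
  for (b in 1:3) {
    ratio <- ifelse(ptot > 0, pmin(pmax(prob[, b] / ptot, 0), 1), 0)
    counts[, b] <- stats::rbinom(m, rem, ratio)
    rem <- rem - counts[, b]
    ptot <- ptot - prob[, b]
  }
  counts[, 4L] <- rem
  counts
}

#' Simulate a parent-offspring trio with ground truth
#'
#' Generates a trio VCF (GT:AD:DP with QUAL and the six hard-filter INFO
#' annotations), the four BED mask tracks, GFF3 gene models, a
#' gene-to-pathway map and a per-site truth table. Parental genotypes are
#' drawn per the configured rates, the offspring receives one uniformly
#' chosen allele from each parent, planted MIE events copy both alleles
#' from one parent at forced divergent-homozygote sites, planted de novo
#' events substitute one offspring allele with a base absent from both
#' parents, depths are Poisson and allele depths multinomial with a
#' per-read error channel. Output is deterministic for a fixed seed.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with `paths` (vcf, repeats, cnv, gaps, indels, gff3,
#'   pathways, truth), `truth` (data.frame), `sites` (the variant site
#'   table as written), and `cfg`.
#' @export
simulate_trio <- function(cfg = sim_config(), dir = tempfile("simtrio")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  n <- cfg$n_sites

  is_mie <- stats::runif(n) < cfg$mie_injection_rate
  is_dn <- !is_mie & stats::runif(n) < cfg$denovo_injection_rate
  mother_var <- !is_mie & stats::runif(n) < cfg$mother_snp_rate
  father_var <- !is_mie & stats::runif(n) < cfg$father_snp_rate
  variant <- is_mie | is_dn | mother_var | father_var
  idx <- which(variant)
  m <- length(idx)

  sites_per_chrom <- ceiling(n / cfg$n_chrom)
  chrom_all <- paste0("chr", (idx - 1L) %/% sites_per_chrom + 1L)
  pos_all <- as.integer(((idx - 1L) %% sites_per_chrom + 1L)) *
    cfg$site_spacing
  chrom_len <- as.integer(sites_per_chrom) * cfg$site_spacing

  ref <- sample(DNA_BASES, m, replace = TRUE)
  mv <- mother_var[idx]; fv <- father_var[idx]
  mie <- is_mie[idx]; dnv <- is_dn[idx]

  alt_m <- other_base(ref)
  m_het <- stats::runif(m) < cfg$mother_het_fraction
  m1 <- ifelse(mv, ifelse(m_het, ref, alt_m), ref)
  m2 <- ifelse(mv, alt_m, ref)
  alt_f <- other_base(ref)
  f_het <- stats::runif(m) < cfg$father_het_fraction
  f1 <- ifelse(fv, ifelse(f_het, ref, alt_f), ref)
  f2 <- ifelse(fv, alt_f, ref)

  # planted MIE: donor parent becomes hom-alt, the other hom-ref, and the
  # offspring copies the donor's pair
  donor_mother <- stats::runif(m) < 0.5
  mie_alt <- other_base(ref)
  sel <- mie & donor_mother
  m1[sel] <- mie_alt[sel]; m2[sel] <- mie_alt[sel]
  f1[sel] <- ref[sel]; f2[sel] <- ref[sel]
  sel <- mie & !donor_mother
  f1[sel] <- mie_alt[sel]; f2[sel] <- mie_alt[sel]
  m1[sel] <- ref[sel]; m2[sel] <- ref[sel]

  from_m <- ifelse(stats::runif(m) < 0.5, m1, m2)
  from_f <- ifelse(stats::runif(m) < 0.5, f1, f2)
  c1 <- ifelse(mie, ifelse(donor_mother, m1, f1), from_m)
  c2 <- ifelse(mie, ifelse(donor_mother, m2, f2), from_f)

  # planted de novo: one offspring allele becomes a base absent from
  # both parents
  dn_slot1 <- stats::runif(m) < 0.5
  for (i in which(dnv)) {
    candidates <- setdiff(DNA_BASES, c(m1[i], m2[i], f1[i], f2[i]))
    novel <- candidates[sample.int(length(candidates), 1L)]
    if (dn_slot1[i]) c1[i] <- novel else c2[i] <- novel
  }

  # per-site allele list: reference first, then first-appearance order
  geno <- cbind(m1, m2, f1, f2, c1, c2)
  alleles <- lapply(seq_len(m), function(i) {
    g <- geno[i, ]
    c(ref[i], unique(g[g != ref[i]]))
  })
  gt_string <- function(b1, b2) {
    vapply(seq_len(m), function(i) {
      a <- sort(c(match(b1[i], alleles[[i]]), match(b2[i], alleles[[i]])))
      paste(a - 1L, collapse = "/")
    }, character(1))
  }
  gt_m <- gt_string(m1, m2)
  gt_f <- gt_string(f1, f2)
  gt_c <- gt_string(c1, c2)

  # read depths and allele depths with error channel
  e <- cfg$base_error_rate
  sample_ad <- function(b1, b2) {
    dp <- stats::rpois(m, cfg$mean_depth)
    dos <- (outer(b1, DNA_BASES, "==") + outer(b2, DNA_BASES, "==")) / 2
    prob <- dos * (1 - e) + (1 - dos) * e / 3
    counts <- draw_base_counts(dp, prob)
    ad <- vapply(seq_len(m), function(i)
      paste(counts[i, match(alleles[[i]], DNA_BASES)], collapse = ","),
      character(1))
    list(dp = dp, ad = ad)
  }
  rm_ <- sample_ad(m1, m2)
  rf_ <- sample_ad(f1, f2)
  rc_ <- sample_ad(c1, c2)

  # QC annotations from pass-range distributions, with planted violations
  qual <- round(stats::runif(m, 100, 1000), 1)
  qd <- round(stats::runif(m, 5, 35), 3)
  fs <- round(stats::runif(m, 0, 10), 3)
  mq <- round(stats::runif(m, 40, 60), 3)
  mqrs <- round(stats::runif(m, -1, 1), 3)
  rprs <- round(stats::runif(m, -1, 1), 3)
  hs <- round(stats::runif(m, 0, 5), 3)
  violate <- stats::runif(m) < cfg$qc_violation_rate
  which_filter <- sample(HARD_FILTER_NAMES, m, replace = TRUE)
  planted_qc <- ifelse(violate, which_filter, "")
  qual[violate & which_filter == "LowQual"] <- 10
  qd[violate & which_filter == "FilterQD"] <- 1.0
  fs[violate & which_filter == "FilterFS"] <- 30
  mq[violate & which_filter == "FilterMQ"] <- 10
  mqrs[violate & which_filter == "FilterMQRankSum"] <- -5
  rprs[violate & which_filter == "FilterReadPosRankSum"] <- -5
  hs[violate & which_filter == "HaplotypeScore"] <- 20

  sites <- data.frame(
    chrom = chrom_all, pos = pos_all, ref = ref,
    alt = vapply(alleles, function(a)
      if (length(a) == 1L) "." else paste(a[-1], collapse = ","),
      character(1)),
    qual = qual, qd = qd, fs = fs, mq = mq, mq_rank_sum = mqrs,
    read_pos_rank_sum = rprs, haplotype_score = hs,
    is_snp = TRUE,
    mother_gt = gt_m, mother_ad = rm_$ad, mother_dp = rm_$dp,
    father_gt = gt_f, father_ad = rf_$ad, father_dp = rf_$dp,
    offspring_gt = gt_c, offspring_ad = rc_$ad, offspring_dp = rc_$dp,
    stringsAsFactors = FALSE)
  # sites with no alternate allele observed anywhere are not variant
  # records (can only happen when a planted event resampled the reference)
  sites <- sites[sites$alt != ".", , drop = FALSE]

  truth <- data.frame(
    chrom = chrom_all, pos = pos_all, ref = ref,
    mother_gt_true = gt_m, father_gt_true = gt_f,
    offspring_gt_true = gt_c,
    event = ifelse(mie, "MIE", ifelse(dnv, "DENOVO", "none")),
    origin = ifelse(mie, ifelse(donor_mother, "MOTHER", "FATHER"), NA),
    planted_qc_violation = planted_qc,
    stringsAsFactors = FALSE)

  paths <- list(
    vcf = file.path(dir, "trio.vcf"),
    repeats = file.path(dir, "repeats.bed"),
    cnv = file.path(dir, "cnv.bed"),
    gaps = file.path(dir, "gaps.bed"),
    indels = file.path(dir, "indels.bed"),
    gff3 = file.path(dir, "genes.gff3"),
    pathways = file.path(dir, "pathways.tsv"),
    truth = file.path(dir, "truth.tsv"))

  write_trio_vcf(sites, paths$vcf, sample_names = cfg$sample_names)
  chroms <- paste0("chr", seq_len(cfg$n_chrom))
  write_interval_bed <- function(path, density, mean_len) {
    rows <- lapply(chroms, function(ch) {
      k <- round(density * chrom_len / mean_len)
      if (k < 1L) return(NULL)
      start <- sort(sample.int(chrom_len - mean_len * 2L, k))
      width <- pmax(1L, stats::rpois(k, mean_len))
      data.frame(chrom = ch, start = start, end = pmin(start + width,
                                                       chrom_len))
    })
    bed <- do.call(rbind, rows)
    if (is.null(bed)) bed <- data.frame(chrom = character(0),
                                        start = integer(0),
                                        end = integer(0))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
  }
  write_interval_bed(paths$repeats, cfg$repeat_density, cfg$repeat_mean_len)
  write_interval_bed(paths$cnv, cfg$cnv_density, cfg$cnv_mean_len)
  write_interval_bed(paths$gaps, cfg$gap_density, cfg$gap_mean_len)
  n_indel <- round(cfg$indel_rate * chrom_len)
  indel_rows <- do.call(rbind, lapply(chroms, function(ch) {
    if (n_indel < 1L) return(NULL)
    p <- sort(sample.int(chrom_len, n_indel))
    data.frame(chrom = ch, start = p - 1L, end = p)
  }))
  if (is.null(indel_rows)) indel_rows <- data.frame(chrom = character(0),
                                                    start = integer(0),
                                                    end = integer(0))
  utils::write.table(indel_rows, paths$indels, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  write_sim_gff3(cfg, chroms, chrom_len, paths$gff3)
  write_sim_pathways(cfg, paths$pathways)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")

  list(paths = paths, truth = truth, sites = sites, cfg = cfg)
}

# simple 3-exon gene models tiled along the chromosomes
write_sim_gff3 <- function(cfg, chroms, chrom_len, path) {
  per_chrom <- ceiling(cfg$n_genes / length(chroms))
  pitch <- floor(chrom_len / (per_chrom + 1L))
  glen <- min(4000L, pitch - 1000L)
  if (glen < 1200L) stop("genome too small for gene models", call. = FALSE)
  exon_w <- floor(glen / 5L)
  lines <- character(0)
  g <- 0L
  for (ch in chroms) {
    for (j in seq_len(per_chrom)) {
      g <- g + 1L
      if (g > cfg$n_genes) break
      id <- sprintf("gene%03d", g)
      s <- j * pitch
      eend <- s + glen - 1L
      strand <- if (g %% 2L == 0L) "-" else "+"
      coding <- stats::runif(1) < cfg$coding_fraction
      bt <- if (coding) "protein_coding" else "ncRNA"
      tx <- paste0(id, ".t1")
      ex <- list(c(s, s + exon_w), c(s + 2L * exon_w, s + 3L * exon_w),
                 c(s + 4L * exon_w, eend))
      row <- function(type, a, b, attrs)
        sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s", ch, type, a, b,
                strand, attrs)
      lines <- c(lines,
                 row("gene", s, eend,
                     sprintf("ID=%s;biotype=%s", id, bt)),
                 row(if (coding) "mRNA" else "ncRNA", s, eend,
                     sprintf("ID=%s;Parent=%s", tx, id)),
                 vapply(ex, function(e)
                   row("exon", e[1], e[2],
                       sprintf("Parent=%s", tx)), character(1)))
      if (coding) {
        utr_w <- 200L
        if (strand == "+") {
          lines <- c(lines,
                     row("five_prime_UTR", ex[[1]][1],
                         ex[[1]][1] + utr_w - 1L, sprintf("Parent=%s", tx)),
                     row("CDS", ex[[1]][1] + utr_w, ex[[1]][2],
                         sprintf("Parent=%s", tx)),
                     row("CDS", ex[[2]][1], ex[[2]][2],
                         sprintf("Parent=%s", tx)),
                     row("CDS", ex[[3]][1], ex[[3]][2] - utr_w,
                         sprintf("Parent=%s", tx)),
                     row("three_prime_UTR", ex[[3]][2] - utr_w + 1L,
                         ex[[3]][2], sprintf("Parent=%s", tx)))
        } else {
          lines <- c(lines,
                     row("three_prime_UTR", ex[[1]][1],
                         ex[[1]][1] + utr_w - 1L, sprintf("Parent=%s", tx)),
                     row("CDS", ex[[1]][1] + utr_w, ex[[1]][2],
                         sprintf("Parent=%s", tx)),
                     row("CDS", ex[[2]][1], ex[[2]][2],
                         sprintf("Parent=%s", tx)),
                     row("CDS", ex[[3]][1], ex[[3]][2] - utr_w,
                         sprintf("Parent=%s", tx)),
                     row("five_prime_UTR", ex[[3]][2] - utr_w + 1L,
                         ex[[3]][2], sprintf("Parent=%s", tx)))
        }
      }
    }
  }
  writeLines(c("##gff-version 3", lines), path)
  path
}

write_sim_pathways <- function(cfg, path) {
  gene_ids <- sprintf("gene%03d", seq_len(cfg$n_genes))
  rows <- lapply(gene_ids, function(g) {
    k <- sample(0:3, 1L)
    if (k == 0L) return(NULL)
    data.frame(gene_id = g,
               pathway_id = sample(sprintf("path%02d", seq_len(cfg$n_pathways)),
                                   k))
  })
  map <- do.call(rbind, rows)
  if (is.null(map)) map <- data.frame(gene_id = character(0),
                                      pathway_id = character(0))
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Analytic expectations for simulated tallies
#'
#' Closed-form expected counts under a [sim_config()], for use in
#' recovery and calibration tests: expected variant positions, planted
#' event counts, per-parent variant/het/hom counts, and planted
#' QC-violation count.
#'
#' @param cfg a [sim_config()].
#' @return named list of expectations.
#' @export
expected_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_sites
  mie <- cfg$mie_injection_rate
  dn <- cfg$denovo_injection_rate
  mr <- cfg$mother_snp_rate
  fr <- cfg$father_snp_rate
  p_var_nonevent <- 1 - (1 - dn) * (1 - mr) * (1 - fr)
  parent <- function(rate, het) list(
    n_variant = n * (1 - mie) * rate + n * mie * 0.5,
    n_het = n * (1 - mie) * rate * het,
    n_hom = n * (1 - mie) * rate * (1 - het) + n * mie * 0.5)
  list(
    n_variant_positions = n * (mie + (1 - mie) * p_var_nonevent),
    n_mie = n * mie,
    n_denovo = n * (1 - mie) * dn,
    mother = parent(mr, cfg$mother_het_fraction),
    father = parent(fr, cfg$father_het_fraction),
    n_qc_violations = n * (mie + (1 - mie) * p_var_nonevent) *
      cfg$qc_violation_rate)
}
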