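rg <- read_genotype_config()

test_that("genotype trios classify into the three inheritance states", {
  # one allele from each parent
  expect_equal(classify_by_genotype(c(0L, 0L), c(1L, 1L), c(0L, 1L)),
               list(state = "MENDELIAN", origin = NA_character_))
  # both alleles from one parent
  expect_equal(classify_by_genotype(c(0L, 0L), c(1L, 1L), c(1L, 1L)),
               list(state = "MIE", origin = "FATHER"))
  expect_equal(classify_by_genotype(c(1L, 1L), c(0L, 0L), c(1L, 1L)),
               list(state = "MIE", origin = "MOTHER"))
  # an allele absent from both parents
  expect_equal(classify_by_genotype(c(0L, 0L), c(0L, 0L), c(0L, 1L)),
               list(state = "DENOVO", origin = NA_character_))
  # missing genotype
  expect_equal(classify_by_genotype(NA, c(0L, 0L), c(0L, 0L))$state,
               "UNCLASSIFIED")
})

test_that("classification equals transmission enumeration for every
           genotype trio with up to three alleles", {
  gts <- all_genotypes(3L)
  n_biallelic_checked <- 0L
  for (gm in gts) for (gf in gts) for (gc in gts) {
    got <- classify_by_genotype(gm, gf, gc)
    expect_equal(got, oracle_classify(gm, gf, gc),
                 info = sprintf("m=%s f=%s c=%s", toString(gm),
                                toString(gf), toString(gc)))
    # de novo precedence: novel allele is never labeled MIE
    if (length(setdiff(gc, c(gm, gf))) > 0L)
      expect_equal(got$state, "DENOVO")
    # at biallelic sites MIE origin is always a single parent
    if (all(c(gm, gf, gc) <= 1L)) {
      n_biallelic_checked <- n_biallelic_checked + 1L
      if (got$state == "MIE")
        expect_true(got$origin %in% c("MOTHER", "FATHER"))
    }
  }
  expect_equal(n_biallelic_checked, 27L)
})

test_that("swapping parents swaps MIE origin and preserves other states", {
  gts <- all_genotypes(3L)
  for (gm in gts) for (gf in gts) for (gc in gts) {
    a <- classify_by_genotype(gm, gf, gc)
    b <- classify_by_genotype(gf, gm, gc)
    expect_equal(a$state, b$state)
    if (a$state == "MIE") {
      flip <- c(MOTHER = "FATHER", FATHER = "MOTHER",
                UNDETERMINED = "UNDETERMINED")
      expect_equal(b$origin, unname(flip[a$origin]))
    }
  }
})

test_that("read-based genotyping applies coverage, frequency and
           binomial-significance rules", {
  expect_equal(genotype_from_reads(c(18L, 0L), rg), c(0L, 0L))
  # het at 50% frequency: one-sided binomial tail computed independently
  p_tail <- sum(dbinom(9:18, 18, 0.01))
  expect_lt(p_tail, 0.05)
  expect_equal(genotype_from_reads(c(9L, 9L), rg), c(0L, 1L))
  # below minimum coverage
  expect_true(is.na(genotype_from_reads(c(9L, 0L), rg)[1]))
  expect_true(is.na(genotype_from_reads(c(0L, 0L), rg)[1]))
  # frequency above threshold but read count consistent with base error:
  # 2 alt reads of 10 at error 0.2 would pass frequency, fail the test
  cfg_hi_err <- read_genotype_config(base_error_rate = 0.2)
  expect_equal(genotype_from_reads(c(8L, 2L), cfg_hi_err), c(0L, 0L))
  # three alleles: the two highest-frequency present alleles win
  expect_equal(genotype_from_reads(c(10L, 9L, 1L), rg), c(0L, 1L))
  # frequency tie between two alts breaks deterministically (toward the
  # lexicographically smaller base)
  expect_equal(genotype_from_reads(c(2L, 9L, 9L), rg,
                                   alleles = c("A", "T", "C")),
               c(1L, 2L))
  expect_equal(genotype_from_reads(c(2L, 9L, 9L), rg,
                                   alleles = c("A", "C", "T")),
               c(1L, 2L))
  # reference wins a tie against an alt
  expect_equal(genotype_from_reads(c(9L, 9L, 2L), rg,
                                   alleles = c("T", "A", "C")),
               c(0L, 1L))
})

test_that("relaxed thresholds admit low-frequency alleles only in
           adjudication mode", {
  # 8% alt: below 0.20, above 0.05
  expect_equal(genotype_from_reads(c(46L, 4L), rg), c(0L, 0L))
  expect_equal(genotype_from_reads(c(46L, 4L), rg, relaxed = TRUE),
               c(0L, 1L))
})

test_that("both classifiers must agree for a non-Mendelian call", {
  # concordant MIE: GT says father-origin MIE, reads agree
  site <- make_site(mother_gt = "0/0", mother_ad = "30,0",
                    father_gt = "1/1", father_ad = "0,28", father_dp = 28L,
                    offspring_gt = "1/1", offspring_ad = "1,29")
  res <- reconcile_trio(site, rg)
  expect_equal(res$state, "MIE")
  expect_equal(res$origin, "FATHER")
  expect_equal(res$method_agreement, "both")

  # GT says de novo but the novel allele is at 3% in the reads: the
  # relaxed re-call still finds no allele, so the call resolves Mendelian
  site <- make_site(mother_gt = "0/0", mother_ad = "30,0",
                    father_gt = "0/0", father_ad = "30,0",
                    offspring_gt = "0/1", offspring_ad = "97,3",
                    offspring_dp = 100L)
  res <- reconcile_trio(site, rg)
  expect_equal(res$state, "MENDELIAN")
  expect_equal(res$method_agreement, "reads")

  # novel allele at 8% (< 0.20, >= 0.05): the single relaxed re-call
  # confirms the genotype-based de novo
  site <- make_site(mother_gt = "0/0", mother_ad = "30,0",
                    father_gt = "0/0", father_ad = "30,0",
                    offspring_gt = "0/1", offspring_ad = "46,4",
                    offspring_dp = 50L)
  res <- reconcile_trio(site, rg)
  expect_equal(res$state, "DENOVO")
  expect_equal(res$method_agreement, "adjudicated")

  # missing AD makes the site unclassifiable, never a guess
  site <- make_site(mother_ad = ".")
  res <- reconcile_trio(site, rg)
  expect_equal(res$state, "UNCLASSIFIED")
  expect_equal(res$reason, "missing_AD")
})

test_that("read-support retention enforces the ten-read and five-read rules", {
  het <- function(ad) make_site(offspring_gt = "0/1", offspring_ad = ad)
  expect_true(apply_support_filters("MIE", het("6,7")))
  expect_false(apply_support_filters("MIE", het("12,4")))
  hom <- make_site(offspring_gt = "1/1", offspring_ad = "0,10")
  expect_true(apply_support_filters("DENOVO", hom))
  hom9 <- make_site(offspring_gt = "1/1", offspring_ad = "0,9")
  expect_false(apply_support_filters("DENOVO", hom9))
  # parental depth requirement
  thin_parent <- make_site(offspring_gt = "0/1", offspring_ad = "6,7",
                           mother_dp = 9L, mother_ad = "9,0")
  expect_false(apply_support_filters("MIE", thin_parent))
})

test_that("tallies partition the input and zero input gives zero tallies", {
  empty <- make_site()[0, ]
  res <- run_trio_classification(empty, rg)
  expect_equal(res$tallies$n_sites_variant_vs_reference, 0L)
  expect_equal(res$tallies$n_mendelian + res$tallies$n_mie +
                 res$tallies$n_denovo + res$tallies$n_unclassified, 0L)

  sim <- small_sim()
  res <- run_trio_classification(sim$sites, rg)
  t <- res$tallies
  expect_equal(t$n_mendelian + t$n_mie + t$n_denovo + t$n_unclassified,
               nrow(sim$sites))
  expect_equal(t$n_mie, t$n_mie_from_mother + t$n_mie_from_father +
                 t$n_mie_undetermined)
})

test_that("reported non-Mendelian sites are the intersection of the two
           independent classifiers on simulated data", {
  sim <- small_sim()
  sites <- sim$sites
  res <- run_trio_classification(sites, rg)

  # method (a): genotype-based, run independently
  state_a <- vapply(seq_len(nrow(sites)), function(i) {
    oracle_classify(parse_genotypes(sites$mother_gt[i])[[1]],
                    parse_genotypes(sites$father_gt[i])[[1]],
                    parse_genotypes(sites$offspring_gt[i])[[1]])$state
  }, character(1))
  # method (b): read-count re-genotyping, run independently
  state_b <- vapply(seq_len(nrow(sites)), function(i) {
    ad <- lapply(c("mother_ad", "father_ad", "offspring_ad"),
                 function(col)
                   as.integer(strsplit(sites[[col]][i], ",")[[1]]))
    g <- lapply(ad, genotype_from_reads, cfg = rg)
    oracle_classify(g[[1]], g[[2]], g[[3]])$state
  }, character(1))

  non_mendelian <- res$calls$state %in% c("MIE", "DENOVO")
  strict_intersection <- state_a == state_b &
    state_a %in% c("MIE", "DENOVO")
  # every strict-intersection site is reported
  expect_true(all(non_mendelian[strict_intersection]))
  # any extra reported site was resolved by the documented single relaxed
  # re-call, never by one method alone
  extra <- non_mendelian & !strict_intersection
  expect_true(all(res$calls$method_agreement[extra] == "adjudicated"))
  expect_true(all(state_a[extra] == res$calls$state[extra]))
})

test_that("high-depth simulated events are recovered and no truthful
           Mendelian site is called non-Mendelian", {
  sim <- small_sim()
  sites <- sim$sites
  res <- run_trio_classification(sites, rg)
  key <- paste(sites$chrom, sites$pos)
  truth <- sim$truth[match(key, paste(sim$truth$chrom, sim$truth$pos)), ]

  planted <- truth$event != "none"
  expect_gte(mean(res$calls$state[planted] == truth$event[planted]), 0.95)
  mie <- planted & truth$event == "MIE"
  expect_true(all(res$calls$origin[mie & res$calls$state == "MIE"] ==
                    truth$origin[mie & res$calls$state == "MIE"]))
  # exact-logic regime: truthful genotypes at high depth yield zero false
  # non-Mendelian calls
  clean <- !planted & sites$mother_dp >= 10 & sites$father_dp >= 10 &
    sites$offspring_dp >= 10
  expect_equal(sum(res$calls$state[clean] %in% c("MIE", "DENOVO")), 0L)
})
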