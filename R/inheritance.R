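#' Read-based re-genotyping thresholds
#'
#' Mirrors the published trio re-genotyping parameters: minimum site
#' coverage 10, minimum variant allele frequency 0.20 at significance
#' 0.05, with relaxed thresholds (frequency 0.05, significance 0.15)
#' applied once when the two classifiers disagree. The significance test
#' is a one-sided binomial test of the allele's read count against a
#' per-read base error rate.
#'
#' @param min_coverage minimum total reads to call a genotype.
#' @param min_var_freq minimum allele frequency for an allele call.
#' @param p_value one-sided binomial significance threshold.
#' @param adj_var_freq,adj_p_value relaxed thresholds for re-adjudication.
#' @param base_error_rate assumed per-read error probability.
#' @return an object of class `read_genotype_config`.
#' @export
read_genotype_config <- function(min_coverage = 10L, min_var_freq = 0.20,
                                 p_value = 0.05, adj_var_freq = 0.05,
                                 adj_p_value = 0.15,
                                 base_error_rate = 0.01) {
  cfg <- list(min_coverage = as.integer(min_coverage),
              min_var_freq = min_var_freq, p_value = p_value,
              adj_var_freq = adj_var_freq, adj_p_value = adj_p_value,
              base_error_rate = base_error_rate)
  for (nm in names(cfg)) stopifnot_scalar_number(cfg[[nm]], nm)
  for (nm in c("min_var_freq", "p_value", "adj_var_freq", "adj_p_value"))
    if (cfg[[nm]] <= 0 || cfg[[nm]] >= 1)
      stop(sprintf("'%s' must be in (0, 1)", nm), call. = FALSE)
  structure(cfg, class = "read_genotype_config")
}

INHERITANCE_STATES <- c("MENDELIAN", "MIE", "DENOVO", "UNCLASSIFIED")

#' Classify a genotype trio into an inheritance state
#'
#' De novo takes precedence: any offspring allele absent from both
#' parental genotypes makes the site de novo. Otherwise the site is
#' Mendelian if some choice of one allele from each parent reproduces the
#' offspring genotype; otherwise it is a Mendelian inheritance error whose
#' origin is the parent whose genotype contains every offspring allele
#' (both offspring alleles received from one parent).
#'
#' @param gm,gf,gc mother/father/offspring genotypes as integer
#'   allele-index pairs (as from [parse_genotypes()]), or `NA` if missing.
#' @return list with `state` (one of `r paste(INHERITANCE_STATES,
#'   collapse = ", ")`) and `origin` (`MOTHER`, `FATHER`, `UNDETERMINED`,
#'   or `NA` for non-MIE states).
#' @export
classify_by_genotype <- function(gm, gf, gc) {
  miss <- function(g) length(g) != 2L || anyNA(g)
  if (miss(gm) || miss(gf) || miss(gc))
    return(list(state = "UNCLASSIFIED", origin = NA_character_))
  if (!all(gc %in% c(gm, gf)))
    return(list(state = "DENOVO", origin = NA_character_))
  target <- sort(gc)
  for (a in gm) for (b in gf)
    if (identical(sort(c(a, b)), target))
      return(list(state = "MENDELIAN", origin = NA_character_))
  from_mother <- all(gc %in% gm)
  from_father <- all(gc %in% gf)
  origin <- if (from_mother && !from_father) "MOTHER"
            else if (from_father && !from_mother) "FATHER"
            else "UNDETERMINED"
  list(state = "MIE", origin = origin)
}

#' Call a genotype from per-allele read depths
#'
#' An allele is called present when its frequency reaches `min_var_freq`
#' and a one-sided binomial test of its read count against
#' `base_error_rate` is significant at `p_value`. The genotype is formed
#' from the two highest-frequency present alleles (duplicated when only
#' one allele is present). Frequency ties break toward the reference
#' allele, then lexicographically by allele base.
#'
#' @param allele_depths integer read counts aligned to the site allele
#'   list (reference first).
#' @param cfg a [read_genotype_config()].
#' @param alleles optional character vector of allele bases (for the
#'   lexicographic tie-break); defaults to allele-index order.
#' @param relaxed use the relaxed (`adj_*`) thresholds.
#' @return integer allele-index pair (0-based, sorted), or `NA` when the
#'   site has insufficient coverage or no callable allele.
#' @export
genotype_from_reads <- function(allele_depths, cfg = read_genotype_config(),
                                alleles = NULL, relaxed = FALSE) {
  if (length(allele_depths) == 0L || anyNA(allele_depths)) return(NA)
  total <- sum(allele_depths)
  if (total < cfg$min_coverage || total == 0L) return(NA)
  freq_min <- if (relaxed) cfg$adj_var_freq else cfg$min_var_freq
  p_max <- if (relaxed) cfg$adj_p_value else cfg$p_value
  freq <- allele_depths / total
  pval <- stats::pbinom(allele_depths - 1L, total, cfg$base_error_rate,
                        lower.tail = FALSE)
  present <- which(freq >= freq_min & pval <= p_max)
  if (length(present) == 0L) return(NA)
  tie_key <- if (is.null(alleles)) as.character(seq_along(allele_depths))
             else alleles
  tie_key[1L] <- ""  # reference allele wins ties
  ord <- present[order(-freq[present], tie_key[present])]
  top <- if (length(ord) == 1L) c(ord, ord) else ord[1:2]
  sort(as.integer(top) - 1L)
}

# classify a trio of read-called genotypes, tolerating missing calls
classify_read_trio <- function(rm, rf, rc) {
  classify_by_genotype(rm, rf, rc)
}

#' Reconcile the genotype-based and read-based classifiers at one site
#'
#' Runs [classify_by_genotype()] on (a) the VCF genotypes and (b)
#' genotypes re-called from allele depths by [genotype_from_reads()]. A
#' non-Mendelian state (MIE or de novo) is reported only when both
#' methods agree; when the genotype-based call is non-Mendelian but the
#' read-based call disagrees, the samples whose read-based genotype
#' differs from their VCF genotype are re-called once under the relaxed
#' thresholds before final adjudication. Sites the two methods still
#' disagree on resolve to Mendelian (when the read-based call is
#' Mendelian) or unclassified.
#'
#' @param site one row of a site table (see [read_trio_vcf()]).
#' @param cfg a [read_genotype_config()].
#' @return list with `state`, `origin`, `method_agreement` (`both`,
#'   `genotype`, `reads`, `adjudicated`, or `none`) and `reason`.
#' @export
reconcile_trio <- function(site, cfg = read_genotype_config()) {
  alleles <- site_alleles(site$ref, site$alt)
  vcf_gt <- lapply(TRIO_ROLES, function(r)
    parse_genotypes(site[[paste0(r, "_gt")]])[[1]])
  names(vcf_gt) <- TRIO_ROLES
  if (any(vapply(vcf_gt, function(g) length(g) != 2L || anyNA(g),
                 logical(1))))
    return(list(state = "UNCLASSIFIED", origin = NA_character_,
                method_agreement = "none", reason = "missing_genotype"))
  ads <- lapply(TRIO_ROLES, function(r)
    split_int_field(site[[paste0(r, "_ad")]])[[1]])
  names(ads) <- TRIO_ROLES
  if (any(vapply(ads, function(a) length(a) == 0L || anyNA(a), logical(1))))
    return(list(state = "UNCLASSIFIED", origin = NA_character_,
                method_agreement = "none", reason = "missing_AD"))

  a <- classify_by_genotype(vcf_gt$mother, vcf_gt$father, vcf_gt$offspring)
  read_gt <- lapply(ads, genotype_from_reads, cfg = cfg, alleles = alleles)
  b <- classify_read_trio(read_gt$mother, read_gt$father, read_gt$offspring)

  if (a$state == "MENDELIAN")
    return(list(state = "MENDELIAN", origin = NA_character_,
                method_agreement = if (b$state == "MENDELIAN") "both"
                                   else "genotype",
                reason = NA_character_))
  # a is MIE or DENOVO (UNCLASSIFIED was handled above)
  if (b$state == a$state)
    return(list(state = a$state, origin = a$origin,
                method_agreement = "both", reason = NA_character_))

  # one relaxed re-call of the samples whose read genotype disagrees
  # with their VCF genotype (or could not be called)
  read_gt2 <- read_gt
  for (r in TRIO_ROLES) {
    same <- length(read_gt[[r]]) == 2L && !anyNA(read_gt[[r]]) &&
      identical(sort(read_gt[[r]]), sort(vcf_gt[[r]]))
    if (!same)
      read_gt2[[r]] <- genotype_from_reads(ads[[r]], cfg, alleles,
                                           relaxed = TRUE)
  }
  b2 <- classify_read_trio(read_gt2$mother, read_gt2$father,
                           read_gt2$offspring)
  if (b2$state == a$state)
    return(list(state = a$state, origin = a$origin,
                method_agreement = "adjudicated", reason = NA_character_))
  if (b2$state == "MENDELIAN")
    return(list(state = "MENDELIAN", origin = NA_character_,
                method_agreement = "reads", reason = "method_disagreement"))
  list(state = "UNCLASSIFIED", origin = NA_character_,
       method_agreement = "none", reason = "method_disagreement")
}

#' Read-support retention filter for non-Mendelian calls
#'
#' A Mendelian-error or de novo call is retained only when the offspring
#' reads supporting its genotype total at least `min_total`, each allele
#' of a heterozygous offspring is supported by at least `min_per_allele`
#' reads (a homozygous offspring needs `min_total` on its single allele),
#' and each parent's site depth reaches `parent_min_depth`.
#'
#' @param state inheritance state of the call (`MIE` or `DENOVO`).
#' @param site the site-table row for the call.
#' @param min_total minimum offspring reads over its genotype alleles.
#' @param min_per_allele minimum reads per heterozygous allele.
#' @param parent_min_depth minimum parental site depth.
#' @return `TRUE` when the call is retained.
#' @export
apply_support_filters <- function(state, site, min_total = 10L,
                                  min_per_allele = 5L,
                                  parent_min_depth = 10L) {
  stopifnot(state %in% c("MIE", "DENOVO"))
  gc <- parse_genotypes(site$offspring_gt)[[1]]
  ad <- split_int_field(site$offspring_ad)[[1]]
  if (length(gc) != 2L || anyNA(gc) || length(ad) == 0L || anyNA(ad))
    return(FALSE)
  counts <- ad[gc + 1L]
  if (sum(ad[unique(gc) + 1L]) < min_total) return(FALSE)
  if (gc[1] != gc[2]) {
    if (any(counts < min_per_allele)) return(FALSE)
  } else {
    if (counts[1] < min_total) return(FALSE)
  }
  for (r in c("mother", "father")) {
    dp <- site[[paste0(r, "_dp")]]
    if (is.na(dp) || dp < parent_min_depth) return(FALSE)
  }
  TRUE
}

#' Classify every filtered site and tally inheritance states
#'
#' Applies [reconcile_trio()] to each passing site and the read-support
#' retention filter to every resulting non-Mendelian call.
#'
#' @param sites filtered site table (rows that passed [filter_pipeline()]);
#'   a `tripped` list-column, if present, is propagated to the call table.
#' @param cfg a [read_genotype_config()].
#' @param min_total,min_per_allele passed to [apply_support_filters()].
#' @return list with `calls` (one row per site: state, origin,
#'   method_agreement, retained, support columns) and `tallies` (named
#'   list of counts; states partition the input).
#' @export
run_trio_classification <- function(sites, cfg = read_genotype_config(),
                                    min_total = 10L, min_per_allele = 5L) {
  n <- nrow(sites)
  state <- character(n); origin <- character(n)
  agreement <- character(n); reason <- character(n)
  retained <- logical(n)
  for (i in seq_len(n)) {
    res <- reconcile_trio(sites[i, , drop = FALSE], cfg)
    state[i] <- res$state
    origin[i] <- if (is.na(res$origin)) NA_character_ else res$origin
    agreement[i] <- res$method_agreement
    reason[i] <- if (is.na(res$reason)) NA_character_ else res$reason
    retained[i] <- if (state[i] %in% c("MIE", "DENOVO"))
      apply_support_filters(state[i], sites[i, , drop = FALSE], min_total,
                            min_per_allele,
                            parent_min_depth = cfg$min_coverage)
    else FALSE
  }
  calls <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = sites$ref, alt = sites$alt,
    state = state, origin = origin, method_agreement = agreement,
    retained = retained, reason = reason,
    mother_gt = sites$mother_gt, father_gt = sites$father_gt,
    offspring_gt = sites$offspring_gt,
    mother_dp = sites$mother_dp, father_dp = sites$father_dp,
    offspring_dp = sites$offspring_dp,
    offspring_ad = sites$offspring_ad,
    tripped = if (!is.null(sites$tripped))
      vapply(sites$tripped, paste, character(1), collapse = ";")
    else character(n),
    stringsAsFactors = FALSE)
  tallies <- list(
    n_sites_variant_vs_reference = n,
    n_mendelian = sum(state == "MENDELIAN"),
    n_mie = sum(state == "MIE"),
    n_mie_from_mother = sum(state == "MIE" & origin == "MOTHER",
                            na.rm = TRUE),
    n_mie_from_father = sum(state == "MIE" & origin == "FATHER",
                            na.rm = TRUE),
    n_mie_undetermined = sum(state == "MIE" & origin == "UNDETERMINED",
                             na.rm = TRUE),
    n_denovo = sum(state == "DENOVO"),
    n_unclassified = sum(state == "UNCLASSIFIED"),
    n_mie_retained = sum(state == "MIE" & retained),
    n_denovo_retained = sum(state == "DENOVO" & retained))
  list(calls = calls, tallies = tallies)
}
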