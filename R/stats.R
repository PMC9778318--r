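#' Is a substitution a transition?
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); the eight remaining base pairs are transversions.
#'
#' @param ref,alt single bases in `A,C,G,T`; vectorised.
#' @return logical vector.
#' @export
is_transition <- function(ref, alt) {
  if (any(!ref %in% DNA_BASES) || any(!alt %in% DNA_BASES))
    stop("bases must be one of A, C, G, T", call. = FALSE)
  if (any(ref == alt)) stop("ref and alt must differ", call. = FALSE)
  purine <- c("A", "G")
  (ref %in% purine) == (alt %in% purine)
}

new_genome_summary <- function(sample, n_het, n_hom, n_ti, n_tv,
                               callable_sites) {
  n_total <- n_het + n_hom
  structure(list(
    sample = sample, n_het = n_het, n_hom = n_hom, n_total = n_total,
    pct_snp = round(n_total / callable_sites * 100, 6),
    pct_heterozygosity = round(n_het / callable_sites * 100, 4),
    n_transitions = n_ti, n_transversions = n_tv,
    titv = if (n_tv > 0) round(n_ti / n_tv, 2) else NA_real_,
    callable_sites = callable_sites), class = "genome_snp_summary")
}

#' @export
print.genome_snp_summary <- function(x, ...) {
  cat(sprintf(
    "SNP summary [%s]: %s het + %s hom = %s SNPs (%%SNP %.4f, %%het %.4f); Ti/Tv %s\n",
    x$sample, format(x$n_het, big.mark = ","),
    format(x$n_hom, big.mark = ","), format(x$n_total, big.mark = ","),
    x$pct_snp, x$pct_heterozygosity,
    if (is.na(x$titv)) "undefined" else sprintf("%.2f", x$titv)))
  invisible(x)
}

#' Per-genome SNP summary from a site table
#'
#' Counts heterozygous (two distinct alleles) and homozygous-nonreference
#' SNPs for one trio member over passing biallelic SNP records, tallies
#' transitions and transversions of the carried substitution, and reports
#' %SNP and %heterozygosity against an explicit callable-site denominator.
#' Ratios are rounded half-even to two decimals.
#'
#' @param sites site table of passing biallelic SNP records.
#' @param sample one of `"mother"`, `"father"`, `"offspring"`.
#' @param callable_sites denominator for the percentage rows (> 0).
#' @return an object of class `genome_snp_summary`.
#' @export
summarize_genome <- function(sites, sample = c("mother", "father",
                                               "offspring"),
                             callable_sites) {
  sample <- match.arg(sample)
  stopifnot_scalar_number(callable_sites, "callable_sites")
  if (callable_sites <= 0) stop("callable_sites must be > 0", call. = FALSE)
  gts <- parse_genotypes(sites[[paste0(sample, "_gt")]])
  ok <- sites$is_snp & !grepl(",", sites$alt, fixed = TRUE) &
    !vapply(gts, function(g) anyNA(g) || length(g) != 2L, logical(1))
  has_alt <- vapply(gts, function(g) !anyNA(g) && any(g > 0L), logical(1))
  keep <- which(ok & has_alt)
  het <- vapply(gts[keep], function(g) g[1] != g[2], logical(1))
  alt1 <- vapply(strsplit(sites$alt[keep], ",", fixed = TRUE),
                 function(a) a[1], character(1))
  ti <- is_transition(sites$ref[keep], alt1)
  new_genome_summary(sample, n_het = sum(het), n_hom = sum(!het),
                     n_ti = sum(ti), n_tv = sum(!ti), callable_sites)
}

#' Per-genome SNP summary from published count rows
#'
#' Builds the same summary object as [summarize_genome()] directly from
#' already-tallied counts (e.g. the het/hom and transition/transversion
#' rows of a published per-genome SNP table).
#'
#' @param sample label for the genome.
#' @param n_het,n_hom heterozygous / homozygous-nonreference SNP counts.
#' @param n_transitions,n_transversions substitution-class counts.
#' @param callable_sites percentage denominator (> 0).
#' @return an object of class `genome_snp_summary`.
#' @export
genome_summary_from_counts <- function(sample, n_het, n_hom,
                                       n_transitions, n_transversions,
                                       callable_sites) {
  if (callable_sites <= 0) stop("callable_sites must be > 0", call. = FALSE)
  new_genome_summary(sample, n_het, n_hom, n_transitions, n_transversions,
                     callable_sites)
}

#' De novo mutation rate per site per generation
#'
#' The rate is the retained de novo count divided by the number of
#' callable sites — per (haploid reference) site per generation, with no
#' factor of two. `callable_sites` is always an explicit input.
#'
#' @param n_denovo retained de novo SNP count.
#' @param callable_sites callable-site denominator (> 0).
#' @return the rate (numeric); display at 3 significant digits.
#' @export
denovo_rate <- function(n_denovo, callable_sites) {
  stopifnot_scalar_number(n_denovo, "n_denovo")
  stopifnot_scalar_number(callable_sites, "callable_sites")
  if (callable_sites <= 0) stop("callable_sites must be > 0", call. = FALSE)
  if (n_denovo < 0) stop("n_denovo must be >= 0", call. = FALSE)
  n_denovo / callable_sites
}

#' Fold comparison against a reference count
#'
#' @param n observed count.
#' @param reference reference count (> 0).
#' @return list with `fold` (floor of the quotient) and `quotient`.
#' @export
fold_vs_reference <- function(n, reference) {
  stopifnot_scalar_number(n, "n")
  stopifnot_scalar_number(reference, "reference")
  if (reference <= 0) stop("reference must be > 0", call. = FALSE)
  list(fold = floor(n / reference), quotient = n / reference)
}

#' Trio-level mutation summary
#'
#' Aggregates classification tallies into the trio-level report: MIE
#' counts by parental origin, retained de novo count, the per-site
#' per-generation de novo rate, and fold comparisons against supplied
#' reference counts.
#'
#' @param tallies tally list from [run_trio_classification()], or any list
#'   with the same names.
#' @param callable_sites callable-site denominator for the rate.
#' @param fold_references optional named list of reference counts; each is
#'   compared against the matching observed count (`n_mie` references use
#'   the retained MIE count, `n_denovo` references the retained de novo
#'   count).
#' @return an object of class `trio_mutation_summary`.
#' @export
trio_mutation_summary <- function(tallies, callable_sites,
                                  fold_references = list()) {
  n_mie <- tallies$n_mie_retained %||% tallies$n_mie
  n_dn <- tallies$n_denovo_retained %||% tallies$n_denovo
  folds <- lapply(names(fold_references), function(nm) {
    obs <- if (grepl("mie", nm, ignore.case = TRUE)) n_mie else n_dn
    c(list(n = obs, reference = fold_references[[nm]]),
      fold_vs_reference(obs, fold_references[[nm]]))
  })
  names(folds) <- names(fold_references)
  structure(list(
    n_variant_positions = tallies$n_sites_variant_vs_reference,
    n_mendelian = tallies$n_mendelian,
    n_mie = n_mie,
    n_mie_by_origin = list(mother = tallies$n_mie_from_mother,
                           father = tallies$n_mie_from_father,
                           undetermined = tallies$n_mie_undetermined %||% 0L),
    n_denovo = n_dn,
    callable_sites = callable_sites,
    denovo_rate = denovo_rate(n_dn, callable_sites),
    fold_vs_reference = folds), class = "trio_mutation_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.trio_mutation_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Trio mutation summary: %s variant positions; %s Mendelian; ",
           "%s MIE (mother %s / father %s); %s de novo; rate %.3g per ",
           "site per generation\n"),
    format(x$n_variant_positions, big.mark = ","),
    format(x$n_mendelian, big.mark = ","), format(x$n_mie, big.mark = ","),
    format(x$n_mie_by_origin$mother, big.mark = ","),
    format(x$n_mie_by_origin$father, big.mark = ","),
    format(x$n_denovo, big.mark = ","), x$denovo_rate))
  invisible(x)
}
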