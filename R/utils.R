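#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

#' Parse diploid genotype strings
#'
#' Converts VCF-style genotype strings ("0/1", "1|1", "./.") into integer
#' allele-index pairs. Half-missing genotypes (e.g. "./1") are treated as
#' fully missing.
#'
#' @param gt character vector of genotype strings.
#' @return list of integer vectors of length 2, or `NA` for missing entries.
#' @export
parse_genotypes <- function(gt) {
  lapply(gt, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA)
    parts <- strsplit(g, "[/|]")[[1]]
    if (length(parts) != 2L || any(parts == ".")) return(NA)
    a <- suppressWarnings(as.integer(parts))
    if (any(is.na(a)) || any(a < 0L)) return(NA)
    a
  })
}

#' Format allele-index pairs back to genotype strings
#' @param gt_list list of integer pairs or NA.
#' @return character vector ("a/b" or "./.").
#' @export
format_genotypes <- function(gt_list) {
  vapply(gt_list, function(g) {
    if (length(g) != 2L || anyNA(g)) "./." else paste(g, collapse = "/")
  }, character(1))
}

# comma-joined integer fields ("11,9") -> list of integer vectors, NA kept
split_int_field <- function(x) {
  lapply(x, function(v) {
    if (is.na(v) || v == ".") return(NA)
    suppressWarnings(as.integer(strsplit(v, ",", fixed = TRUE)[[1]]))
  })
}

join_int_field <- function(lst) {
  vapply(lst, function(v) {
    if (length(v) == 0L || anyNA(v)) "." else paste(v, collapse = ",")
  }, character(1))
}

# alleles of a site as a character vector: ref first then alts
site_alleles <- function(ref, alt) {
  if (is.na(alt) || alt == ".") return(ref)
  c(ref, strsplit(alt, ",", fixed = TRUE)[[1]])
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}
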