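#' Hypergeometric gene-set over-representation test
#'
#' For each pathway with at least one member in the universe, computes
#' the upper-tail hypergeometric probability of observing at least `k`
#' pathway genes in a gene set of size `n` drawn from a universe of size
#' `N` containing `K` pathway genes, then applies Benjamini-Hochberg
#' adjustment across all tested pathways.
#'
#' @param gene_set character vector of genes of interest (subset of the
#'   universe; genes outside the universe are dropped).
#' @param pathway_map data.frame with columns `gene_id`, `pathway_id`
#'   (one row per membership), or a path to such a TSV.
#' @param universe character vector of all genes considered.
#' @return data.frame sorted by p-value: `pathway_id`, `k`, `K`, `n`,
#'   `N`, `p_value`, `q_value`.
#' @export
hypergeom_enrich <- function(gene_set, pathway_map, universe) {
  if (is.character(pathway_map) && length(pathway_map) == 1L)
    pathway_map <- utils::read.table(pathway_map, sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "pathway_id") %in% colnames(pathway_map)))
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  gene_set <- unique(gene_set[gene_set %in% universe])
  pm <- pathway_map[pathway_map$gene_id %in% universe, , drop = FALSE]
  pm <- unique(pm[, c("gene_id", "pathway_id")])
  N <- length(universe)
  n <- length(gene_set)
  if (nrow(pm) == 0L)
    return(data.frame(pathway_id = character(0), k = integer(0),
                      K = integer(0), n = integer(0), N = integer(0),
                      p_value = numeric(0), q_value = numeric(0)))
  K <- tapply(pm$gene_id, pm$pathway_id, function(g) length(unique(g)))
  hit <- pm[pm$gene_id %in% gene_set, , drop = FALSE]
  k <- tapply(hit$gene_id, factor(hit$pathway_id, levels = names(K)),
              function(g) length(unique(g)))
  k[is.na(k)] <- 0L
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(pathway_id = names(K), k = as.integer(k),
                    K = as.integer(K), n = n, N = N, p_value = as.numeric(p),
                    q_value = stats::p.adjust(as.numeric(p), method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
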