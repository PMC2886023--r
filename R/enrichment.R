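#' Hypergeometric over-representation of annotation terms
#'
#' Tests each annotation term for over-representation among the
#' differentially expressed genes relative to the fixed background of all
#' analysed genes. For a term annotated to `K` of the `N` background genes,
#' with `k` of the `n` DE genes carrying it, the p-value is the upper tail
#' of the hypergeometric distribution, `P[X >= k]`. Annotation is taken as
#' flat gene-to-term pairs; no ontology-graph propagation is performed.
#'
#' @param de_genes Character vector of DE gene ids (must be a subset of
#'   `background`).
#' @param background Character vector of all analysed gene ids.
#' @param annotation Data frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`; pairs outside the background are dropped.
#' @param alpha Significance level for the `significant` flag (default
#'   0.01, raw p as in the study; a Benjamini-Hochberg column is also
#'   emitted).
#' @return Data frame sorted by ascending p: `term_id`, `term_name`, `k`,
#'   `K`, `n`, `N`, `p_value`, `p_bh`, `significant`.
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g2", "g3"), term_id = "GO:1")
#' over_representation(c("g1", "g2"), paste0("g", 1:10), ann)
#' @export
over_representation <- function(de_genes, background, annotation,
                                alpha = 0.01) {
  de_genes <- unique(de_genes)
  background <- unique(background)
  extra <- setdiff(de_genes, background)
  if (length(extra))
    .stopf("DE gene(s) not in the background list: %s",
           paste(head(extra, 5L), collapse = ", "))
  if (!"term_name" %in% names(annotation))
    annotation$term_name <- annotation$term_id
  annotation <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  annotation <- unique(annotation[, c("gene_id", "term_id", "term_name")])
  empty <- data.frame(term_id = character(0L), term_name = character(0L),
                      k = integer(0L), K = integer(0L), n = integer(0L),
                      N = integer(0L), p_value = numeric(0L),
                      p_bh = numeric(0L), significant = logical(0L))
  if (!length(de_genes) || !nrow(annotation)) return(empty)

  N <- length(background)
  n <- length(de_genes)
  by_term <- split(annotation$gene_id, annotation$term_id)
  term_name <- annotation$term_name[match(names(by_term), annotation$term_id)]
  K <- vapply(by_term, length, integer(1L))
  k <- vapply(by_term, function(g) sum(g %in% de_genes), integer(1L))
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(by_term), term_name = term_name,
                    k = k, K = K, n = n, N = N, p_value = p,
                    p_bh = p.adjust(p, "BH"),
                    significant = p < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
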