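#' Hypergeometric upper-tail probability
#'
#' Probability of drawing at least \code{k} marked genes when \code{n}
#' genes are drawn without replacement from a universe of \code{N} genes
#' of which \code{K} are marked:
#' \deqn{p = \sum_{i=k}^{\min(K,n)} \binom{K}{i}\binom{N-K}{n-i} /
#'   \binom{N}{n}}
#' Terms are accumulated in log space for numerical stability.
#'
#' @param k observed overlap.
#' @param K marked genes in the universe.
#' @param n draw (query) size.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k < 0 || K > N || n > N || k > min(K, n)) {
    stop2("invalid hypergeometric parameters (need 0 <= k <= min(K, n), ",
          "K <= N, n <= N)")
  }
  if (k == 0) return(1)
  i <- k:min(K, n)
  lt <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lt)
  exp(m + log(sum(exp(lt - m))))
}

#' Gene-set over-representation of a query gene list
#'
#' Hypergeometric upper-tail test of each set against the universe.  The
#' query is first filtered to genes with |log2fc| above \code{fc_filter}
#' (the study rule: |log2FC| > 1 before pathway analysis) and intersected
#' with the universe; the universe defaults to all genes present in both
#' the expression table and the set collection.
#'
#' @param query_genes character vector of query gene ids (e.g. the
#'   GAIN-associated DEGs).
#' @param sets gene-set collection from \code{\link{read_gene_sets}}.
#' @param expression expression table (provides log2fc for the filter and
#'   the default universe).
#' @param universe optional explicit universe of gene ids.
#' @param alpha significance gate on the raw P (study rule: 0.05).
#' @param fc_filter |log2fc| filter applied to the query (set to 0 to
#'   disable).
#' @return data.frame sorted by P: \code{set, k, K, n, N, p, q,
#'   significant, members} (query members in the set, comma-separated with
#'   their log2fc); dropped-gene count in attribute \code{"n_dropped"}.
#' @export
enrich_gene_sets <- function(query_genes, sets, expression, universe = NULL,
                             alpha = 0.05, fc_filter = 1.0) {
  if (is.null(universe)) {
    universe <- intersect(expression$gene_id, unique(unlist(sets)))
  }
  if (!length(universe)) stop2("empty universe")
  if (fc_filter > 0) {
    fc <- expression$log2fc[match(query_genes, expression$gene_id)]
    query_genes <- query_genes[!is.na(fc) & abs(fc) > fc_filter]
  }
  n_before <- length(query_genes)
  query <- intersect(unique(query_genes), universe)
  n_dropped <- n_before - length(query)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    hit <- intersect(query, members)
    k <- length(hit)
    if (k == 0L) return(NULL)
    fc <- expression$log2fc[match(hit, expression$gene_id)]
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p = hypergeom_upper_tail(k, K, n, N),
               members = paste(sprintf("%s(%.2f)", hit, fc), collapse = ","),
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    out <- data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric(), significant = logical(),
                      members = character())
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, "BH")
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$set),
             c("set", "k", "K", "n", "N", "p", "q", "significant", "members")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Top-ranked enriched sets
#'
#' @param enrichment output of \code{\link{enrich_gene_sets}}.
#' @param n_top how many sets to keep.
#' @export
top_enriched <- function(enrichment, n_top = 10L) {
  head(enrichment, n_top)
}
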