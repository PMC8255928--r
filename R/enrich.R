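#' Fold-enrichment score
#'
#' (m/n) / (M/N): the fraction of query genes carrying a term relative to
#' the fraction of background genes carrying it. `N` counts annotated
#' background genes, `n` annotated query genes, `M` background genes with
#' the term, `m` query genes with the term.
#'
#' @param m,n,M,N counts with m <= n <= N and m <= M <= N; n and M must be
#'   positive.
#' @return fold enrichment (>= 0).
#' @examples
#' fold_score(m = 5, n = 10, M = 20, N = 100) # 2.5
#' @export
fold_score <- function(m, n, M, N) {
  if (n <= 0 || M <= 0 || N <= 0)
    stop("n, M and N must be positive", call. = FALSE)
  if (m > n || n > N || m > M || M > N)
    stop("inconsistent counts: need m <= n <= N and m <= M <= N",
         call. = FALSE)
  (m / n) / (M / N)
}

#' Hypergeometric upper-tail enrichment p value
#'
#' P(X >= m) for X ~ Hypergeometric(N, M, n): the chance that a random
#' query of `n` annotated genes contains at least `m` of the term's `M`
#' genes. Evaluated through the survival function of [stats::phyper()],
#' which works in log space internally; m = 0 gives exactly 1.
#'
#' @inheritParams fold_score
#' @return p value in (0, 1].
#' @export
hypergeom_p <- function(m, n, M, N) {
  if (m > n || n > N || m > M || M > N || m < 0)
    stop("inconsistent counts", call. = FALSE)
  if (m == 0) return(1)
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE)
}

#' Gene-set enrichment of a query gene list
#'
#' Hypergeometric enrichment of `query_genes` against each gene set, with
#' the fold-enrichment score. Only annotated genes (members of at least
#' one set) enter the universe: `N` is the annotated background and `n`
#' the annotated query, matching the convention that un-annotated genes
#' are uninformative for term enrichment.
#'
#' @param query_genes character vector (must be a subset of `background`).
#' @param gene_sets list of gene sets (`term_id`, `term_name`, `members`),
#'   as from [read_gmt()].
#' @param background character vector of all assayed genes.
#' @param adjust p adjustment method for the optional `p_adj` column
#'   (default `"none"`: the raw hypergeometric p is what is reported).
#' @return data.frame sorted by p ascending: `term_id`, `term_name`, `m`,
#'   `n`, `M`, `N`, `fold_enrichment`, `p` (and `p_adj` unless adjust is
#'   "none").
#' @export
enrich <- function(query_genes, gene_sets, background, adjust = "none") {
  if (!length(background)) stop("empty background", call. = FALSE)
  if (!all(query_genes %in% background))
    stop("query genes must be contained in the background", call. = FALSE)
  annotated <- unique(unlist(lapply(gene_sets, `[[`, "members")))
  bg <- intersect(background, annotated)
  q <- intersect(query_genes, annotated)
  N <- length(bg); n <- length(q)
  if (N == 0) stop("no background gene is annotated", call. = FALSE)
  rows <- lapply(gene_sets, function(s) {
    M <- length(intersect(s$members, bg))
    m <- length(intersect(s$members, q))
    if (M == 0) return(NULL)
    data.frame(term_id = s$term_id, term_name = s$term_name,
               m = m, n = n, M = M, N = N,
               fold_enrichment = if (n > 0) fold_score(m, n, M, N) else NA_real_,
               p = hypergeom_p(m, n, M, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (!identical(adjust, "none")) out$p_adj <- stats::p.adjust(out$p, adjust)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
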