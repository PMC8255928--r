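#' lncRNA-mRNA coexpression edges
#'
#' Computes the Pearson correlation of every lncRNA x mRNA pair across
#' samples and keeps pairs with |r| >= `r_min` and p < `p_max` (p from the
#' t distribution with n - 2 df). Genes with zero variance are excluded
#' with a warning. The correlation-0.8 cutoff follows the convention that
#' coefficients of 0.8 or greater mark a coexpression link.
#'
#' @param mat an [expression_matrix()], >= 3 samples.
#' @param lnc_ids,mrna_ids disjoint gene-id sets, both present in `mat`.
#' @param r_min minimum |r| (inclusive). Set `positive_only = TRUE` to
#'   require r >= r_min instead of |r| >= r_min.
#' @param p_max p-value cutoff (exclusive).
#' @param positive_only restrict to positive correlations.
#' @return data.frame of edges: `lnc_id`, `mrna_id`, `r`, `p`.
#' @export
correlate_pairs <- function(mat, lnc_ids, mrna_ids, r_min = 0.8,
                            p_max = 0.05, positive_only = FALSE) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (length(intersect(lnc_ids, mrna_ids)))
    stop("lnc and mRNA id sets must be disjoint", call. = FALSE)
  n <- ncol(mat$values)
  if (n < 3L) stop("need >= 3 samples", call. = FALSE)
  x <- log2(mat$values + 1)
  drop_const <- function(ids) {
    v <- apply(x[ids, , drop = FALSE], 1L, stats::var)
    if (any(v == 0)) {
      warning("excluding zero-variance gene(s): ",
              paste(ids[v == 0], collapse = ", "), call. = FALSE)
      ids <- ids[v > 0]
    }
    ids
  }
  lnc_ids <- drop_const(intersect(lnc_ids, mat$gene_ids))
  mrna_ids <- drop_const(intersect(mrna_ids, mat$gene_ids))
  if (!length(lnc_ids) || !length(mrna_ids))
    return(data.frame(lnc_id = character(0), mrna_id = character(0),
                      r = numeric(0), p = numeric(0)))
  r <- stats::cor(t(x[lnc_ids, , drop = FALSE]),
                  t(x[mrna_ids, , drop = FALSE]))
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  p[abs(r) >= 1] <- 0
  keep <- if (positive_only) r >= r_min else abs(r) >= r_min
  keep <- keep & p < p_max
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(lnc_id = lnc_ids[idx[, 1L]],
                    mrna_id = mrna_ids[idx[, 2L]],
                    r = r[idx], p = p[idx], stringsAsFactors = FALSE)
  out <- out[order(out$lnc_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deterministic top-k edge selection
#'
#' Orders edges by p ascending, then |r| descending, then lnc id, then
#' mRNA id, and returns the first `k`. The ordering is a total order, so
#' the result does not depend on the input permutation.
#'
#' @param edges data.frame from [correlate_pairs()].
#' @param k number of edges to keep (default 500).
#' @return the selected edges, in rank order.
#' @export
select_top_edges <- function(edges, k = 500) {
  o <- order(edges$p, -abs(edges$r), edges$lnc_id, edges$mrna_id)
  out <- edges[utils::head(o, k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Markov clustering (MCL) of a weighted coexpression network
#'
#' From-scratch MCL: the |r|-weighted adjacency matrix (optionally with a
#' self-loop of weight equal to each node's maximum incident |r|) is made
#' column-stochastic and iterated through expansion (matrix power),
#' inflation (entrywise power followed by column renormalisation) and
#' pruning (entries below `prune_threshold` zeroed, columns renormalised)
#' until the maximum entry change drops below `tol` or `max_iter` is
#' reached. Clusters are the connected components of the support of the
#' limit matrix; when attractor systems overlap, a node follows the
#' attractor holding its largest steady-state mass (ties to the lowest
#' cluster index). Deterministic.
#'
#' @param edges data.frame with columns `lnc_id`/`mrna_id` (or `from`/
#'   `to`) and `r` (edge weight, used as |r|).
#' @param expansion integer matrix power (>= 2, default 2).
#' @param inflation inflation exponent (> 1, default 2).
#' @param prune_threshold entries below this are zeroed (default 1e-5).
#' @param max_iter iteration cap (default 100).
#' @param tol convergence bound on the max entry change (default 1e-8).
#' @param add_self_loops add max-incident-weight self-loops (default TRUE).
#' @return list of class `mcl_clustering`: `membership` (named integer,
#'   cluster per node), `n_clusters`, `sizes`, `converged`, `iterations`,
#'   and `limit` (the converged column-stochastic flow matrix).
#' @export
mcl <- function(edges, expansion = 2, inflation = 2,
                prune_threshold = 1e-5, max_iter = 100, tol = 1e-8,
                add_self_loops = TRUE) {
  if (!nrow(edges)) stop("empty edge list", call. = FALSE)
  if (expansion < 2 || expansion != floor(expansion))
    stop("'expansion' must be an integer >= 2", call. = FALSE)
  if (inflation <= 1) stop("'inflation' must be > 1", call. = FALSE)
  from <- edges[[if ("lnc_id" %in% names(edges)) "lnc_id" else "from"]]
  to <- edges[[if ("mrna_id" %in% names(edges)) "mrna_id" else "to"]]
  w <- abs(if ("r" %in% names(edges)) edges$r else edges$weight)
  nodes <- sort(unique(c(from, to)))
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  A[cbind(match(from, nodes), match(to, nodes))] <- w
  A <- pmax(A, t(A))
  if (add_self_loops) diag(A) <- apply(A, 1L, max)
  normalize <- function(M) sweep(M, 2L, pmax(colSums(M), .Machine$double.xmin),
                                 `/`)
  M <- normalize(A)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M_prev <- M
    Mx <- M
    for (e in seq_len(expansion - 1L)) Mx <- Mx %*% M
    Mx <- normalize(Mx^inflation)
    Mx[Mx < prune_threshold] <- 0
    M <- normalize(Mx)
    if (max(abs(M - M_prev)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within max_iter", call. = FALSE)
  # clusters: connected components of the limit-matrix support
  supp <- (M > 0) | t(M > 0)
  g <- igraph::graph_from_adjacency_matrix(supp, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # relabel components deterministically by first node occurrence
  relabel <- match(comp, unique(comp[order(seq_along(comp))]))
  # overlap resolution: a node goes with the component holding its largest
  # steady-state mass (only relevant if pruning split support asymmetrically)
  membership <- setNames(integer(n), nodes)
  for (i in seq_len(n)) {
    mass <- tapply(M[, i], relabel, sum)
    best <- as.integer(names(mass)[which.max(mass)])
    membership[i] <- if (M[i, i] > 0 || mass[[as.character(relabel[i])]] >=
                         max(mass)) relabel[i] else best
  }
  membership <- match(membership, unique(membership))
  names(membership) <- nodes
  structure(list(membership = membership,
                 n_clusters = length(unique(membership)),
                 sizes = as.integer(table(membership)),
                 converged = converged, iterations = it,
                 limit = M),
            class = "mcl_clustering")
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat(sprintf("MCL clustering: %d nodes in %d clusters (%s after %d iterations)\n",
              length(x$membership), x$n_clusters,
              if (x$converged) "converged" else "not converged",
              x$iterations))
  invisible(x)
}
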