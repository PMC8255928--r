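#' FPKM from fragment counts
#'
#' fragments x 10^9 / (exonic_length x total_mapped).
#'
#' @param fragments fragment count (>= 0).
#' @param exonic_length exonic length in bp (> 0).
#' @param total_mapped total mapped fragments in the library (> 0).
#' @return FPKM value(s); vectorised over `fragments`/`exonic_length`.
#' @examples
#' fpkm(10, 1000, 1e6) # 10
#' @export
fpkm <- function(fragments, exonic_length, total_mapped) {
  if (any(exonic_length <= 0)) stop("exonic_length must be > 0",
                                    call. = FALSE)
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0",
                                   call. = FALSE)
  if (any(fragments < 0)) stop("fragments must be >= 0", call. = FALSE)
  fragments * 1e9 / (exonic_length * total_mapped)
}

#' Differential expression between case and control groups
#'
#' Per gene: a Welch t test on log2(x + 1) and a two-sided fold change
#' (mean_case + eps) / (mean_control + eps) with a pseudo-abundance
#' eps = 1. A gene is called `up` when the ratio is >= `fc` with p < `alpha`
#' and case > control, `down` symmetrically (ratio <= 1/fc), otherwise
#' `ns`. Zero within-group variance in both groups with equal means yields
#' p = 1; with different means p = 0 (the degenerate exactly-replicated
#' case).
#'
#' @param mat an [expression_matrix()] (count or FPKM unit).
#' @param alpha p-value threshold (default 0.05, unadjusted).
#' @param fc fold-change threshold (default 2).
#' @param eps pseudo-abundance added to group means for the ratio.
#' @param adjust optional p adjustment passed to [stats::p.adjust()]
#'   (e.g. `"BH"`); `"none"` (default) filters on raw p, as when raw
#'   p < 0.05 is the published criterion.
#' @return data.frame: `gene_id`, `mean_case`, `mean_control`, `log2fc`,
#'   `p`, `direction`.
#' @export
de_test <- function(mat, alpha = 0.05, fc = 2, eps = 1, adjust = "none") {
  stopifnot(inherits(mat, "expr_matrix"))
  cs <- group_samples(mat, "case"); ct <- group_samples(mat, "control")
  if (length(cs) < 2L || length(ct) < 2L)
    stop("each group needs >= 2 samples", call. = FALSE)
  x <- log2(mat$values + 1)
  a <- x[, cs, drop = FALSE]; b <- x[, ct, drop = FALSE]
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, stats::var); vb <- apply(b, 1L, stats::var)
  se2 <- va / length(cs) + vb / length(ct)
  t <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (va^2 / (length(cs)^2 * (length(cs) - 1)) +
                        vb^2 / (length(ct)^2 * (length(ct) - 1))),
               length(cs) + length(ct) - 2)
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0 & ma != mb] <- 0   # exact replication at different levels
  p[se2 == 0 & ma == mb] <- 1
  p_use <- if (identical(adjust, "none")) p else stats::p.adjust(p, adjust)
  mean_case <- rowMeans(mat$values[, cs, drop = FALSE])
  mean_control <- rowMeans(mat$values[, ct, drop = FALSE])
  ratio <- (mean_case + eps) / (mean_control + eps)
  direction <- rep("ns", nrow(x))
  direction[p_use < alpha & ratio >= fc] <- "up"
  direction[p_use < alpha & ratio <= 1 / fc] <- "down"
  data.frame(gene_id = mat$gene_ids, mean_case = mean_case,
             mean_control = mean_control, log2fc = log2(ratio),
             p = p_use, direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Sample-sample Pearson correlation map
#'
#' Pearson correlation of log2(x + 1) profiles across genes, the usual QC
#' heatmap input; the diagonal is exactly 1.
#'
#' @param mat an [expression_matrix()] with >= 2 genes.
#' @return symmetric sample x sample correlation matrix.
#' @export
sample_correlation <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (nrow(mat$values) < 2L) stop("need >= 2 genes", call. = FALSE)
  r <- stats::cor(log2(mat$values + 1))
  diag(r) <- 1
  r
}

#' PCA sample scores
#'
#' SVD of the gene-centred log2(x + 1) matrix. Scores are ordered by
#' decreasing singular value; each component's sign is fixed so its
#' largest-magnitude gene loading is positive.
#'
#' @param mat an [expression_matrix()].
#' @param k number of components (default 2).
#' @return list with `scores` (sample x k), `loadings` (gene x k),
#'   `sdev` (singular values / sqrt(n - 1)), `var_explained`.
#' @export
pca_scores <- function(mat, k = 2) {
  stopifnot(inherits(mat, "expr_matrix"))
  x <- log2(mat$values + 1)
  if (k > min(dim(x))) stop("k exceeds matrix rank bound", call. = FALSE)
  xc <- x - rowMeans(x)
  sv <- svd(xc)
  sign_fix <- vapply(seq_len(ncol(sv$u)), function(j) {
    l <- sv$u[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, 0)
  scores <- sweep(sv$v, 2L, sign_fix * sv$d, `*`)[, seq_len(k), drop = FALSE]
  loadings <- sweep(sv$u, 2L, sign_fix, `*`)[, seq_len(k), drop = FALSE]
  rownames(scores) <- mat$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  dimnames(loadings) <- list(mat$gene_ids, colnames(scores))
  list(scores = scores, loadings = loadings,
       sdev = sv$d / sqrt(ncol(x) - 1),
       var_explained = sv$d^2 / sum(sv$d^2))
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Items (samples or genes) are clustered on d = 1 - r with average
#' linkage via [stats::hclust()], whose agglomeration breaks ties by the
#' smallest item index.
#'
#' @param x numeric matrix, items in columns (correlated pairwise), or a
#'   precomputed `dist`.
#' @return an object of class `hclust`.
#' @export
hclust_average <- function(x) {
  d <- if (inherits(x, "dist")) x else {
    if (ncol(x) < 2L) stop("need >= 2 items", call. = FALSE)
    stats::as.dist(1 - stats::cor(x))
  }
  stats::hclust(d, method = "average")
}
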