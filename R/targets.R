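#' Cis target candidates of one lncRNA
#'
#' Genes on the same chromosome whose transcript span lies within `window`
#' bp of the lncRNA's span (gap of exactly `window` included; overlapping
#' spans have distance 0). Optionally restricted to pairs present in a
#' coexpression edge set, with either sign of r.
#'
#' @param lnc a single transcript record (one-row data.frame).
#' @param genes transcript records of potential targets.
#' @param window cis window in bp (default 300 kb), inclusive.
#' @param require_coexpr restrict to coexpressed pairs.
#' @param edges coexpression edges (needed when `require_coexpr`).
#' @return data.frame: `lnc_id`, `mrna_id`, `distance`, `same_chrom`.
#' @export
cis_targets <- function(lnc, genes, window = 300000,
                        require_coexpr = FALSE, edges = NULL) {
  stopifnot(nrow(lnc) == 1L)
  genes <- genes[genes$gene_id != lnc$gene_id, , drop = FALSE]
  same <- genes$chrom == lnc$chrom
  d <- span_gap(lnc$start, lnc$end, genes$start, genes$end)
  keep <- same & d <= window
  out <- data.frame(lnc_id = rep(lnc$gene_id, sum(keep)),
                    mrna_id = genes$gene_id[keep],
                    distance = d[keep],
                    same_chrom = rep(TRUE, sum(keep)),
                    stringsAsFactors = FALSE)
  if (require_coexpr) {
    if (is.null(edges)) stop("'edges' required when require_coexpr",
                             call. = FALSE)
    out <- out[paste(out$lnc_id, out$mrna_id) %in%
                 paste(edges$lnc_id, edges$mrna_id), , drop = FALSE]
  }
  out <- out[order(out$distance, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gap between two closed intervals; 0 when they touch or overlap.
# Symmetric in its arguments by construction.
span_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2) - 1)
}

# Pair score of one antiparallel base pair (more negative = stronger):
# G-C -3, A-T -2, G-T wobble -1, anything else +4.
pair_score_lookup <- local({
  sc <- matrix(4, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T")))
  sc["G", "C"] <- sc["C", "G"] <- -3
  sc["A", "T"] <- sc["T", "A"] <- -2
  sc["G", "T"] <- sc["T", "G"] <- -1
  sc
})

#' Best ungapped RNA-RNA duplex between two sequences
#'
#' Scans every antiparallel ungapped alignment of `seq_a` against `seq_b`
#' for the minimum-energy stretch that contains a seed of at least 6
#' consecutive exact Watson-Crick pairs, extending the seed in both
#' directions as far as the score improves. Pair energies: G-C -3, A-T -2,
#' G-T (wobble) -1, mismatch +4; the energy of a stretch is the sum, so
#' internal mismatches are tolerated only when flanking pairs more than
#' recover their penalty. The search is exact: it returns the global
#' optimum over all substring pairs, which is what an exhaustive scorer
#' finds.
#'
#' @param seq_a,seq_b DNA strings over A/C/G/T.
#' @param min_pairs minimum paired bases for a reportable hit (default
#'   10); hits below this are still returned with `passes = FALSE`.
#' @param seed_len exact Watson-Crick seed length (default 6).
#' @return list: `found`, `passes`, `paired_bases`, `energy`, `a_span`,
#'   `b_span` (1-based inclusive positions in each input).
#' @export
duplex_scan <- function(seq_a, seq_b, min_pairs = 10, seed_len = 6) {
  a <- strsplit(toupper(seq_a), "")[[1L]]
  rb <- rev(strsplit(toupper(seq_b), "")[[1L]])  # b read 3'->5'
  na <- length(a); nb <- length(rb)
  no_hit <- list(found = FALSE, passes = FALSE, paired_bases = 0L,
                 energy = 0, a_span = NULL, b_span = NULL)
  if (na < seed_len || nb < seed_len) return(no_hit)
  best <- NULL
  for (d in (-(na - seed_len)):(nb - seed_len)) {
    i0 <- max(1L, 1L - d)                 # a-index range on this diagonal
    i1 <- min(na, nb - d)
    L <- i1 - i0 + 1L
    if (L < seed_len) next
    ai <- a[i0:i1]; bi <- rb[(i0 + d):(i1 + d)]
    s <- pair_score_lookup[cbind(match(ai, rownames(pair_score_lookup)),
                                 match(bi, colnames(pair_score_lookup)))]
    s[is.na(s)] <- 4
    wc <- s <= -2                          # exact Watson-Crick positions
    run <- cumsum_reset(wc)
    seed_ends <- which(run >= seed_len)
    if (!length(seed_ends)) next
    P <- c(0, cumsum(s))
    # leftmost prefix max of P[1..x] (best left cut) and leftmost suffix
    # min of P[x..end] (best right cut), both as indices into P
    pref_arg <- which_cummax(P)
    suf_arg <- which_sufmin(P)
    lefts <- pref_arg[seed_ends - seed_len + 1L]  # window start (local pos)
    rights <- suf_arg[seed_ends + 1L]             # window end = right - 1
    ens <- P[rights] - P[lefts]
    lens <- rights - lefts
    k <- order(ens, -lens)[1L]
    if (is.null(best) || ens[k] < best$energy ||
        (ens[k] == best$energy && lens[k] > best$len))
      best <- list(energy = ens[k], i_from = i0 + lefts[k] - 1L,
                   i_to = i0 + rights[k] - 2L, d = d, s = s,
                   off = lefts[k], len = lens[k])
  }
  if (is.null(best)) return(no_hit)
  seg <- best$s[best$off:(best$off + best$len - 1L)]
  paired <- sum(seg < 0)
  j_hi <- nb - (best$i_to + best$d) + 1L  # back to b coordinates
  j_lo <- nb - (best$i_from + best$d) + 1L
  list(found = TRUE, passes = paired >= min_pairs,
       paired_bases = as.integer(paired), energy = best$energy,
       a_span = c(best$i_from, best$i_to), b_span = c(j_hi, j_lo))
}

# Run length of consecutive TRUEs ending at each position (vectorised).
cumsum_reset <- function(x) {
  idx <- seq_along(x)
  as.integer((idx - cummax(idx * !x)) * x)
}

# Index (1-based) of the leftmost maximum of P[1..x], per prefix x.
which_cummax <- function(P) {
  idx <- seq_along(P)
  record <- P > c(-Inf, utils::head(cummax(P), -1L))  # strict new maxima
  cummax(idx * record)
}

# Index (1-based) of the leftmost minimum of P[x..end], per suffix x.
which_sufmin <- function(P) {
  Q <- rev(P)
  idx <- seq_along(Q)
  record <- Q <= cummin(Q)   # ties update: prefers later in Q = earlier in P
  rev(length(P) + 1L - cummax(idx * record))
}

#' Duplex hits for a set of candidate pairs
#'
#' @param pairs data.frame with `lnc_id`, `mrna_id`.
#' @param sequences named character vector covering all ids in `pairs`.
#' @param min_pairs passed to [duplex_scan()].
#' @return data.frame: pair ids, `paired_bases`, `energy`.
#' @export
duplex_hits <- function(pairs, sequences, min_pairs = 10) {
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    h <- duplex_scan(sequences[[pairs$lnc_id[i]]],
                     sequences[[pairs$mrna_id[i]]], min_pairs = min_pairs)
    data.frame(lnc_id = pairs$lnc_id[i], mrna_id = pairs$mrna_id[i],
               paired_bases = h$paired_bases,
               energy = if (h$found) h$energy else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Trans target calls
#'
#' A pair is a trans target when it satisfies all of: a coexpression edge
#' with |r| > `r_min` and p < `p_max`; a duplex hit with at least
#' `min_pairs` paired bases; duplex energy at most `energy_max` (binding
#' energies are negative, so the default -50 keeps magnitude-50-or-stronger
#' duplexes); and it is not a cis pair (same chromosome within `window`,
#' judged from `records` when provided).
#'
#' @param edges coexpression edges (`lnc_id`, `mrna_id`, `r`, `p`).
#' @param hits duplex hits from [duplex_hits()].
#' @param energy_max maximum (most positive) admissible energy.
#' @param min_pairs minimum paired bases.
#' @param r_min coexpression |r| bound (strict).
#' @param p_max coexpression p bound (strict).
#' @param records optional transcript records for the cis exclusion.
#' @param window cis window used for the exclusion.
#' @return data.frame of trans pairs with `r`, `p`, `paired_bases`,
#'   `energy`.
#' @export
trans_targets <- function(edges, hits, energy_max = -50, min_pairs = 10,
                          r_min = 0.8, p_max = 0.05, records = NULL,
                          window = 300000) {
  key <- function(d) paste(d$lnc_id, d$mrna_id)
  m <- merge(edges, hits, by = c("lnc_id", "mrna_id"))
  m <- m[abs(m$r) > r_min & m$p < p_max &
           m$paired_bases >= min_pairs &
           !is.na(m$energy) & m$energy <= energy_max, , drop = FALSE]
  if (!is.null(records) && nrow(m)) {
    loc <- records[match(m$lnc_id, records$gene_id), c("chrom", "start", "end")]
    loc2 <- records[match(m$mrna_id, records$gene_id), c("chrom", "start", "end")]
    is_cis <- !is.na(loc$chrom) & !is.na(loc2$chrom) &
      loc$chrom == loc2$chrom &
      span_gap(loc$start, loc$end, loc2$start, loc2$end) <= window
    m <- m[!is_cis, , drop = FALSE]
  }
  m <- m[order(m$lnc_id, m$mrna_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}
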