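# Shared fixtures and independent oracles, built in code at test time.

# Small expression matrix with explicit values.
toy_matrix <- function(values, n_control = ncol(values) / 2) {
  samples <- colnames(values)
  groups <- setNames(rep(c("control", "case"),
                         c(n_control, ncol(values) - n_control)), samples)
  expression_matrix(values, groups, unit = "FPKM")
}

# Complete graph on `nodes` with constant edge weight.
clique_edges <- function(nodes, r = 0.9) {
  d <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  d <- d[d$from < d$to, , drop = FALSE]
  d$r <- r
  rownames(d) <- NULL
  d
}

# --- independent duplex oracle -------------------------------------------
# Exhaustive all-substring-pair scorer: every antiparallel ungapped pairing
# of a substring of `a` with an equal-length substring of `b`, scored with
# its own lookup; a pairing qualifies only if it contains >= seed_len
# consecutive exact Watson-Crick pairs. Returns the minimum energy (or NULL).
oracle_pair_score <- function(x, y) {
  key <- paste0(x, y)
  if (key %in% c("GC", "CG")) return(-3)
  if (key %in% c("AT", "TA")) return(-2)
  if (key %in% c("GT", "TG")) return(-1)
  4
}

oracle_best_duplex <- function(seq_a, seq_b, seed_len = 6) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  na <- length(a); nb <- length(b)
  best <- NULL
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    # a[i..i+len-1] pairs b[j+len-1..j] (antiparallel)
    max_len <- min(na - i + 1, j)
    if (max_len < seed_len) next
    for (len in seed_len:max_len) {
      sc <- vapply(0:(len - 1), function(k)
        oracle_pair_score(a[i + k], b[j - k]), 0)
      run <- 0; seed_ok <- FALSE
      for (s in sc) {
        run <- if (s <= -2) run + 1 else 0
        if (run >= seed_len) seed_ok <- TRUE
      }
      if (seed_ok) {
        en <- sum(sc)
        if (is.null(best) || en < best) best <- en
      }
    }
  }
  best
}

random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Longest antiparallel complementary (exact WC) run between two sequences.
longest_complement_run <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    k <- 0
    while (i + k <= length(a) && j - k >= 1 &&
           comp[[a[i + k]]] == b[j - k]) k <- k + 1
    best <- max(best, k)
  }
  best
}

# --- independent hypergeometric oracle -----------------------------------
# P(X >= m) by direct enumeration with binomial coefficients.
oracle_hyper_tail <- function(m, n, M, N) {
  ks <- max(m, 0):min(n, M)
  if (!length(ks) || m > min(n, M)) return(if (m <= 0) 1 else 0)
  sum(choose(M, ks) * choose(N - M, n - ks)) / choose(N, n)
}

# --- clinical raw columns (cohort table, used across tests) ---------------
clinical_fixture <- function() {
  read_clinical(system.file("extdata", "sapho_clinical.tsv",
                            package = "lncnet"))
}

control_summaries <- function() {
  list(wbc = list(n = 12, mean = 6.30, sd = 1.25),
       neutrophil = list(n = 12, mean = 3.29, sd = 0.81))
}
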