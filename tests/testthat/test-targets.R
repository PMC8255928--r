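rec <- function(id, chrom, start, end, strand = "+") {
  data.frame(transcript_id = paste0(id, ".1"), gene_id = id, chrom = chrom,
             start = start, end = end, strand = strand,
             biotype = "candidate", length = end - start + 1,
             stringsAsFactors = FALSE)
}

test_that("the cis window is inclusive at exactly 300 kb", {
  lnc <- rec("L", "chr1", 1000, 2000)
  at_window <- rec("m_at", "chr1", 302001, 303000)     # gap 300,000
  beyond <- rec("m_beyond", "chr1", 302002, 303000)    # gap 300,001
  overlap <- rec("m_ov", "chr1", 1500, 2500)           # distance 0
  other_chr <- rec("m_chr2", "chr2", 2100, 2200)
  out <- cis_targets(lnc, rbind(at_window, beyond, overlap, other_chr))
  expect_setequal(out$mrna_id, c("m_at", "m_ov"))
  expect_equal(out$distance[out$mrna_id == "m_at"], 300000)
  expect_equal(out$distance[out$mrna_id == "m_ov"], 0)
})

test_that("span distance is symmetric", {
  set.seed(3)
  for (i in 1:20) {
    s1 <- sample(1e6, 1); e1 <- s1 + sample(5000, 1)
    s2 <- sample(1e6, 1); e2 <- s2 + sample(5000, 1)
    a <- cis_targets(rec("A", "chr1", s1, e1),
                     rec("B", "chr1", s2, e2), window = Inf)
    b <- cis_targets(rec("B", "chr1", s2, e2),
                     rec("A", "chr1", s1, e1), window = Inf)
    expect_equal(a$distance, b$distance)
  }
})

test_that("planted cis pairs are recovered and never cross chromosomes", {
  cfg <- sim_config(n_genes = 60, n_lnc = 20, seed = 15,
                    module_spec = list(list(size = 12, r = 0.9)),
                    n_cis_pairs = 3, n_duplex_pairs = 3)
  s <- simulate_expression(cfg)
  ann <- simulate_annotation(cfg, s$truth)
  mrnas <- ann[ann$biotype == "mRNA", ]
  pc <- s$truth$planted_cis_pairs
  for (i in seq_len(nrow(pc))) {
    lnc <- ann[ann$gene_id == pc$lnc_id[i], ]
    got <- cis_targets(lnc, mrnas)
    expect_true(pc$mrna_id[i] %in% got$mrna_id)
    chroms <- mrnas$chrom[match(got$mrna_id, mrnas$gene_id)]
    expect_true(all(chroms == lnc$chrom))
  }
})

test_that("duplex_scan finds planted complements and honours min_pairs", {
  a <- random_dna(60, seed = 1)
  stretch <- substr(a, 20, 31)  # 12 nt
  b <- paste0(random_dna(20, seed = 2), reverse_complement(stretch),
              random_dna(20, seed = 3))
  h <- duplex_scan(a, b)
  expect_true(h$found)
  expect_gte(h$paired_bases, 12)
  expect_true(h$passes)
  # an 8-nt perfect complement alone cannot reach 10 paired bases
  a8 <- paste0(strrep("A", 20), "GCGCATAT", strrep("A", 20))
  b8 <- paste0(strrep("C", 18), reverse_complement("GCGCATAT"),
               strrep("C", 18))
  h8 <- duplex_scan(a8, b8)
  expect_true(h8$found)
  expect_false(h8$passes)
  expect_lt(h8$paired_bases, 10)
  # shorter than the seed: no hit
  expect_false(duplex_scan("ACGTA", "TACGT")$found)
})

test_that("duplex_scan matches the exhaustive all-substring-pair oracle", {
  set.seed(8)
  for (i in 1:30) {
    a <- random_dna(sample(15:40, 1), seed = 3000 + i)
    b <- random_dna(sample(15:40, 1), seed = 4000 + i)
    # plant a seed in half the cases so hits are common
    if (i %% 2 == 0) {
      k <- sample(6:12, 1)
      p <- sample(nchar(a) - k + 1, 1)
      sub <- substr(a, p, p + k - 1)
      b <- paste0(substr(b, 1, 5), reverse_complement(sub),
                  substr(b, 6 + k, nchar(b)))
    }
    want <- oracle_best_duplex(a, b)
    got <- duplex_scan(a, b)
    if (is.null(want)) {
      expect_false(got$found, info = paste("case", i))
    } else {
      expect_true(got$found, info = paste("case", i))
      expect_equal(got$energy, want, info = paste("case", i))
    }
  }
})

test_that("a sequence against its reverse complement pairs fully", {
  s <- random_dna(30, seed = 77)
  h <- duplex_scan(s, reverse_complement(s))
  expect_equal(h$paired_bases, 30)
  # minimum possible energy: every base in a perfect pair
  base_counts <- table(strsplit(s, "")[[1]])
  gc <- sum(base_counts[c("G", "C")], na.rm = TRUE)
  at <- sum(base_counts[c("A", "T")], na.rm = TRUE)
  expect_equal(h$energy, -3 * gc - 2 * at)
  expect_equal(h$a_span, c(1L, 30L))
  expect_equal(h$b_span, c(1L, 30L))
})

test_that("trans calls require coexpression, duplex support and distance", {
  edges <- data.frame(lnc_id = c("L1", "L2"), mrna_id = c("M1", "M2"),
                      r = c(0.95, 0.9), p = c(0.001, 0.002))
  hits <- data.frame(lnc_id = c("L1", "L3"), mrna_id = c("M1", "M3"),
                     paired_bases = c(20L, 25L), energy = c(-60, -70))
  out <- trans_targets(edges, hits)
  expect_identical(out$lnc_id, "L1")  # L2 has no duplex, L3 no edge
  # weak duplex or weak energy fail
  hits2 <- hits; hits2$paired_bases[1] <- 8L
  expect_equal(nrow(trans_targets(edges, hits2)), 0)
  hits3 <- hits; hits3$energy[1] <- -40
  expect_equal(nrow(trans_targets(edges, hits3)), 0)
  # cis pairs are excluded from trans calls
  recs <- rbind(rec("L1", "chr1", 1000, 2000),
                rec("M1", "chr1", 50000, 51000))
  expect_equal(nrow(trans_targets(edges, hits, records = recs)), 0)
  recs_far <- rbind(rec("L1", "chr1", 1000, 2000),
                    rec("M1", "chr2", 50000, 51000))
  expect_equal(nrow(trans_targets(edges, hits, records = recs_far)), 1)
})

test_that("planted duplex pairs surface as trans targets, disjoint from cis", {
  cfg <- sim_config(n_genes = 60, n_lnc = 20, de_fraction = 0.3,
                    module_spec = list(list(size = 16, r = 0.95)),
                    seed = 25, n_cis_pairs = 2, n_duplex_pairs = 4,
                    complement_len = 25)
  s <- simulate_expression(cfg)
  ann <- simulate_annotation(cfg, s$truth)
  lens <- setNames(ann$length, ann$gene_id)
  seqs <- simulate_sequences(s$truth, lens, seed = 6)
  mem <- names(s$truth$module_assignments)
  edges <- correlate_pairs(s$matrix, mem[startsWith(mem, "LNC")],
                           mem[startsWith(mem, "MRNA")], r_min = 0.8)
  hits <- duplex_hits(edges[, c("lnc_id", "mrna_id")], seqs)
  tr <- trans_targets(edges, hits, records = ann)
  pd <- s$truth$planted_duplex_pairs
  in_edges <- paste(pd$lnc_id, pd$mrna_id) %in%
    paste(edges$lnc_id, edges$mrna_id)
  recovered <- paste(pd$lnc_id, pd$mrna_id) %in%
    paste(tr$lnc_id, tr$mrna_id)
  expect_true(all(recovered[in_edges]))
  # trans and cis are disjoint by construction
  cis_all <- do.call(rbind, lapply(unique(edges$lnc_id), function(l)
    cis_targets(ann[ann$gene_id == l, ][1, ],
                ann[ann$biotype == "mRNA", ])))
  if (!is.null(cis_all) && nrow(cis_all) && nrow(tr))
    expect_length(intersect(paste(tr$lnc_id, tr$mrna_id),
                            paste(cis_all$lnc_id, cis_all$mrna_id)), 0)
})
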