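#' Configuration for the synthetic cohort generator
#'
#' Builds the parameter set that drives every synthetic-data generator in
#' the package. Defaults emulate the study design the analysis assumes: two
#' groups of six RNA-seq samples, thousands of genes of which a fraction is
#' differentially expressed at a >= 2-fold effect, planted lncRNA-mRNA
#' coexpression modules with high pairwise correlation, genomic coordinates
#' that admit within-300 kb cis pairs, and transcript sequences carrying
#' planted reverse-complementary stretches.
#'
#' @param n_genes number of protein-coding (mRNA) genes.
#' @param n_lnc number of lncRNA genes.
#' @param n_per_group samples per group (sequenced cohort: 6 vs 6).
#' @param de_fraction fraction of all genes with a true group effect.
#' @param log2fc_effect absolute log2 fold change of DE genes (>= 1).
#' @param module_spec list of planted coexpression modules, each a list
#'   with `size` (genes, split evenly lncRNA/mRNA) and `r` (target pairwise
#'   Pearson correlation, in (-1, 1)).
#' @param seed integer root seed; the same config is bit-reproducible.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd mean and SD of per-gene
#'   baseline log2 FPKM.
#' @param genome_len chromosome length in bp.
#' @param n_chroms number of chromosomes.
#' @param n_cis_pairs,n_duplex_pairs planted cis / duplex pair counts;
#'   drawn from module members so the pairs also coexpress.
#' @param complement_len length (nt) of the planted reverse-complementary
#'   stretch in each duplex pair.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1500, n_lnc = 500, n_per_group = 6,
                       de_fraction = 0.2, log2fc_effect = 2,
                       module_spec = rep(list(list(size = 12, r = 0.9)), 4),
                       seed = 1, noise_sd = 0.3,
                       baseline_log2_mean = 4, baseline_log2_sd = 1,
                       genome_len = 2.5e8, n_chroms = 4,
                       n_cis_pairs = 8, n_duplex_pairs = 8,
                       complement_len = 25) {
  for (nm in c("n_genes", "n_lnc", "n_per_group", "n_chroms"))
    stop_if_not_scalar_count(get(nm), nm)
  if (de_fraction < 0 || de_fraction >= 1)
    stop("'de_fraction' must be in [0, 1)", call. = FALSE)
  if (log2fc_effect < 0) stop("'log2fc_effect' must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("'noise_sd' must be positive", call. = FALSE)
  module_spec <- lapply(module_spec, function(m) {
    m <- as.list(m)
    if (is.null(names(m)) || !all(c("size", "r") %in% names(m)))
      m <- list(size = m[[1]], r = m[[2]])
    if (m$size > n_genes + n_lnc)
      stop("module size exceeds total gene count", call. = FALSE)
    if (abs(m$r) >= 1) stop("module target r must be in (-1, 1)",
                            call. = FALSE)
    m
  })
  cfg <- list(n_genes = as.integer(n_genes), n_lnc = as.integer(n_lnc),
              n_per_group = as.integer(n_per_group),
              de_fraction = de_fraction, log2fc_effect = log2fc_effect,
              module_spec = module_spec, seed = as.integer(seed),
              noise_sd = noise_sd,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              genome_len = genome_len, n_chroms = as.integer(n_chroms),
              n_cis_pairs = as.integer(n_cis_pairs),
              n_duplex_pairs = as.integer(n_duplex_pairs),
              complement_len = as.integer(complement_len))
  class(cfg) <- "sim_config"
  cfg
}

# Planted ground truth layout: which genes are DE and in which direction,
# module membership, and which module lnc-mRNA pairs are reserved for cis
# placement vs duplex planting. Deterministic given cfg.
plan_truth <- function(cfg) {
  ids_mrna <- sprintf("MRNA%04d", seq_len(cfg$n_genes))
  ids_lnc <- sprintf("LNC%04d", seq_len(cfg$n_lnc))
  with_seed(child_seed(cfg$seed, 101L), {
    module_assignments <- integer(0)
    module_members <- list()
    lnc_cursor <- 0L; mrna_cursor <- 0L
    for (k in seq_along(cfg$module_spec)) {
      sz <- cfg$module_spec[[k]]$size
      n_l <- ceiling(sz / 2); n_m <- sz - n_l
      if (lnc_cursor + n_l > cfg$n_lnc || mrna_cursor + n_m > cfg$n_genes)
        stop("module_spec requires more genes than configured",
             call. = FALSE)
      mem <- c(ids_lnc[lnc_cursor + seq_len(n_l)],
               ids_mrna[mrna_cursor + seq_len(n_m)])
      lnc_cursor <- lnc_cursor + n_l; mrna_cursor <- mrna_cursor + n_m
      module_members[[k]] <- mem
      module_assignments[mem] <- k
    }
    all_ids <- c(ids_lnc, ids_mrna)
    n_de <- round(cfg$de_fraction * length(all_ids))
    de <- character(0)
    if (n_de > 0) {
      # module members are DE first (the network stage only sees DE genes),
      # then a random draw tops the set up to the configured fraction
      de <- unlist(module_members, use.names = FALSE)
      de <- de[seq_len(min(length(de), n_de))]
      pool <- setdiff(all_ids, de)
      extra <- n_de - length(de)
      if (extra > 0) de <- c(de, sample(pool, extra))
    }
    # one direction per module (a module's genes move together); alternating
    # directions across modules and for the remaining DE genes
    dir <- setNames(rep(NA_character_, length(de)), de)
    for (k in seq_along(module_members)) {
      mm <- intersect(module_members[[k]], de)
      dir[mm] <- if (k %% 2 == 1) "down" else "up"
    }
    loose <- names(dir)[is.na(dir)]
    dir[loose] <- rep_len(c("up", "down"), length(loose))

    pair_from_module <- function(k, slot) {
      mem <- module_members[[k]]
      l <- mem[startsWith(mem, "LNC")]; m <- mem[startsWith(mem, "MRNA")]
      if (slot > min(length(l), length(m))) return(NULL)
      c(l[slot], m[slot])
    }
    max_slot <- if (length(module_members))
      max(vapply(module_members, function(mem)
        min(sum(startsWith(mem, "LNC")), sum(startsWith(mem, "MRNA"))),
        0L)) else 0L
    take_pairs <- function(n) {
      out <- list()
      for (slot in seq_len(max_slot)) for (k in seq_along(module_members)) {
        p <- pair_from_module(k, slot)
        if (!is.null(p) && length(out) < n) out[[length(out) + 1L]] <- p
      }
      if (length(out) < n)
        stop("not enough module lnc-mRNA pairs to plant; enlarge modules",
             call. = FALSE)
      data.frame(lnc_id = vapply(out, `[`, "", 1L),
                 mrna_id = vapply(out, `[`, "", 2L),
                 stringsAsFactors = FALSE)
    }
    cis <- take_pairs(cfg$n_cis_pairs)
    dup <- take_pairs(cfg$n_cis_pairs + cfg$n_duplex_pairs)
    dup <- dup[!(paste(dup$lnc_id, dup$mrna_id) %in%
                   paste(cis$lnc_id, cis$mrna_id)), , drop = FALSE]
    dup <- utils::head(dup, cfg$n_duplex_pairs)
    dup$complement_len <- rep(cfg$complement_len, nrow(dup))
    rownames(dup) <- NULL

    structure(list(de_gene_ids = de,
                   de_direction = dir,
                   module_assignments = module_assignments,
                   planted_cis_pairs = cis,
                   planted_duplex_pairs = dup,
                   lnc_ids = ids_lnc, mrna_ids = ids_mrna),
              class = "sim_truth")
  })
}

#' Simulate a case-control expression matrix with planted structure
#'
#' Generates log-normal FPKM abundances for a two-group cohort. DE genes are
#' shifted by `log2fc_effect` in the case group; genes of a planted module
#' share one latent factor per sample, scaled so the expected pairwise
#' Pearson correlation equals the module's target `r` (lncRNA members carry
#' the negative loading when `r < 0`). Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (an [expression_matrix()], unit FPKM) and
#'   `truth` (class `sim_truth`: `de_gene_ids`, `de_direction`,
#'   `module_assignments`, `planted_cis_pairs`, `planted_duplex_pairs`).
#' @export
simulate_expression <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  truth <- plan_truth(cfg)
  all_ids <- c(truth$lnc_ids, truth$mrna_ids)
  n_gene <- length(all_ids)
  n_samp <- 2L * cfg$n_per_group
  samples <- c(sprintf("C%d", seq_len(cfg$n_per_group)),
               sprintf("S%d", seq_len(cfg$n_per_group)))
  groups <- setNames(rep(c("control", "case"), each = cfg$n_per_group),
                     samples)
  z <- with_seed(child_seed(cfg$seed, 202L), {
    mu <- stats::rnorm(n_gene, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    names(mu) <- all_ids
    eps <- matrix(stats::rnorm(n_gene * n_samp), n_gene, n_samp,
                  dimnames = list(all_ids, samples))
    z <- eps # residual component, N(0,1) per cell for now
    for (k in seq_along(cfg$module_spec)) {
      mem <- names(truth$module_assignments)[truth$module_assignments == k]
      rho <- abs(cfg$module_spec[[k]]$r)
      f <- stats::rnorm(n_samp)
      load <- rep(sqrt(rho), length(mem))
      if (cfg$module_spec[[k]]$r < 0)
        load[startsWith(mem, "LNC")] <- -sqrt(rho)
      z[mem, ] <- load %o% f + sqrt(1 - rho) * z[mem, , drop = FALSE]
    }
    z <- cfg$noise_sd * z + mu
    if (length(truth$de_gene_ids)) {
      shift <- ifelse(truth$de_direction == "up", 1, -1) * cfg$log2fc_effect
      z[truth$de_gene_ids, groups[samples] == "case"] <-
        z[truth$de_gene_ids, groups[samples] == "case", drop = FALSE] + shift
    }
    z
  })
  list(matrix = expression_matrix(2^z, groups, unit = "FPKM"),
       truth = truth)
}

#' Simulate genomic annotation compatible with the planted cis pairs
#'
#' Places one single-exon transcript per gene on `cfg$n_chroms` chromosomes
#' (1-based inclusive coordinates, GTF convention). Members of a planted cis
#' pair land on the same chromosome with a span gap below the window;
#' all other neighbouring transcripts are separated by more than the window
#' or sit on different chromosomes.
#'
#' @param cfg a [sim_config()].
#' @param truth the `sim_truth` from [simulate_expression()].
#' @param window cis window in bp the placement must respect.
#' @return data.frame of transcript records: `transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `biotype`, `length`.
#' @export
simulate_annotation <- function(cfg, truth, window = 300000) {
  stopifnot(inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  all_ids <- c(truth$lnc_ids, truth$mrna_ids)
  with_seed(child_seed(cfg$seed, 303L), {
    len <- ifelse(startsWith(all_ids, "LNC"),
                  sample(200:2000, length(all_ids), replace = TRUE),
                  sample(500:3000, length(all_ids), replace = TRUE))
    names(len) <- all_ids
    strand <- sample(c("+", "-"), length(all_ids), replace = TRUE)
    names(strand) <- all_ids

    # placement units: cis-pair partners stay adjacent, everyone else alone
    paired_with <- setNames(truth$planted_cis_pairs$mrna_id,
                            truth$planted_cis_pairs$lnc_id)
    in_pair <- c(truth$planted_cis_pairs$lnc_id,
                 truth$planted_cis_pairs$mrna_id)
    units <- list()
    for (id in all_ids) {
      if (id %in% in_pair && !(id %in% names(paired_with))) next
      units[[length(units) + 1L]] <-
        if (id %in% names(paired_with)) c(id, paired_with[[id]]) else id
    }
    pair_gap <- sample(500:(window - 500), length(truth$planted_cis_pairs$lnc_id),
                       replace = TRUE)
    spacing <- window + 10000  # neighbouring units are never within window

    chrom_i <- 1L; pos <- 1
    rec <- vector("list", length(all_ids)); ri <- 0L; pi <- 0L
    for (u in units) {
      need <- sum(len[u]) + if (length(u) == 2L) max(pair_gap) else 0
      if (pos + need > cfg$genome_len) {
        chrom_i <- chrom_i + 1L; pos <- 1
        if (chrom_i > cfg$n_chroms)
          stop("placement infeasible: genome too short for the configured ",
               "gene count and window", call. = FALSE)
      }
      for (j in seq_along(u)) {
        id <- u[j]
        if (j == 2L) { pi <- pi + 1L; pos <- pos + pair_gap[pi] }
        ri <- ri + 1L
        rec[[ri]] <- data.frame(
          transcript_id = paste0(id, ".1"), gene_id = id,
          chrom = paste0("chr", chrom_i),
          start = pos, end = pos + len[[id]] - 1, strand = strand[[id]],
          biotype = if (startsWith(id, "MRNA")) "mRNA"
                    else if (match(id, truth$lnc_ids) %% 2L == 0L)
                      "lncRNA_known" else "lncRNA_novel",
          length = len[[id]], stringsAsFactors = FALSE)
        pos <- pos + len[[id]] - 1 + if (j < length(u)) 0 else spacing
      }
    }
    out <- do.call(rbind, rec)
    rownames(out) <- NULL
    out
  })
}

#' Simulate transcript sequences with planted RNA-RNA duplex sites
#'
#' Random A/C/G/T sequences of the requested lengths; each planted duplex
#' pair receives an exact reverse-complementary stretch of the recorded
#' length (inserted mid-sequence in both partners). Deterministic under
#' `seed`.
#'
#' @param truth `sim_truth` with `planted_duplex_pairs`.
#' @param lengths named integer vector, sequence length per gene id.
#' @param seed integer seed.
#' @return named character vector of DNA sequences.
#' @export
simulate_sequences <- function(truth, lengths, seed = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  pd <- truth$planted_duplex_pairs
  if (nrow(pd) &&
      any(pd$complement_len > pmin(lengths[pd$lnc_id], lengths[pd$mrna_id])))
    stop("complement length exceeds a transcript length", call. = FALSE)
  with_seed(seed, {
    seqs <- vapply(lengths, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), "")
    names(seqs) <- names(lengths)
    for (i in seq_len(nrow(pd))) {
      l <- pd$lnc_id[i]; m <- pd$mrna_id[i]; k <- pd$complement_len[i]
      p_l <- max(1L, (nchar(seqs[[l]]) - k) %/% 2L)
      stretch <- substr(seqs[[l]], p_l, p_l + k - 1L)
      rc <- reverse_complement(stretch)
      p_m <- max(1L, (nchar(seqs[[m]]) - k) %/% 2L)
      substr(seqs[[m]], p_m, p_m + k - 1L) <- rc
    }
    seqs
  })
}

#' Reverse complement of a DNA string
#' @param x character scalar over A/C/G/T.
#' @return character scalar.
#' @export
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate a qRT-PCR Ct table
#'
#' Emits three technical-replicate Ct values per (sample, gene) for a set of
#' assayed genes plus a near-constant reference gene. Case samples of DE
#' genes are shifted in delta-Ct by the planted log2 effect (down-regulated
#' gene: higher Ct).
#'
#' @param truth `sim_truth`.
#' @param genes gene ids to assay (default: the planted duplex-pair genes).
#' @param n_per_group samples per group (validation cohort: 12 vs 12).
#' @param seed integer seed.
#' @param log2fc_effect planted effect on the delta-Ct scale.
#' @param bio_sd between-sample biological SD of delta-Ct.
#' @param replicate_sd technical replicate SD of Ct.
#' @param reference_gene,ref_ct reference gene id and its nominal Ct.
#' @param base_dct nominal delta-Ct of the targets in controls.
#' @return data.frame with columns `sample`, `gene`, `replicate`, `ct` and
#'   a `group` column (control/case).
#' @export
simulate_ct_table <- function(truth, genes = NULL, n_per_group = 12,
                              seed = 1, log2fc_effect = 1, bio_sd = 0.8,
                              replicate_sd = 0.15,
                              reference_gene = "ACTB", ref_ct = 20,
                              base_dct = 5) {
  stopifnot(inherits(truth, "sim_truth"), n_per_group > 1)
  if (is.null(genes))
    genes <- unique(c(truth$planted_duplex_pairs$lnc_id,
                      truth$planted_duplex_pairs$mrna_id))
  samples <- c(sprintf("HC%02d", seq_len(n_per_group)),
               sprintf("PT%02d", seq_len(n_per_group)))
  group <- rep(c("control", "case"), each = n_per_group)
  with_seed(seed, {
    rows <- list()
    ref_sample <- ref_ct + stats::rnorm(length(samples), 0, 0.1)
    for (si in seq_along(samples)) {
      for (g in c(reference_gene, genes)) {
        if (g == reference_gene) {
          mu <- ref_sample[si]
        } else {
          shift <- 0
          if (g %in% truth$de_gene_ids && group[si] == "case")
            shift <- if (truth$de_direction[[g]] == "down")
              log2fc_effect else -log2fc_effect
          mu <- ref_sample[si] + base_dct + shift +
            stats::rnorm(1, 0, bio_sd)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[si], gene = g, replicate = 1:3,
          ct = mu + stats::rnorm(3, 0, replicate_sd),
          group = group[si], stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}

# Synthetic gene-set annotation built around the planted modules: one term
# per module (its mRNA members plus random annotated filler) and additional
# random terms, so enrichment of module genes is detectable by construction.
simulate_gene_sets <- function(truth, n_random_terms = 20, term_size = 25,
                               seed = 1) {
  with_seed(seed, {
    universe <- truth$mrna_ids
    sets <- list()
    mods <- sort(unique(truth$module_assignments))
    for (k in mods) {
      mem <- names(truth$module_assignments)[truth$module_assignments == k]
      mem <- mem[startsWith(mem, "MRNA")]
      filler <- sample(setdiff(universe, mem),
                       max(0, term_size - length(mem)))
      sets[[sprintf("MOD%03d", k)]] <- list(
        term_id = sprintf("MOD%03d", k),
        term_name = sprintf("planted module %d", k),
        members = sort(c(mem, filler)))
    }
    for (j in seq_len(n_random_terms)) {
      id <- sprintf("RND%03d", j)
      sets[[id]] <- list(term_id = id,
                         term_name = sprintf("random term %d", j),
                         members = sort(sample(universe, term_size)))
    }
    unname(sets)
  })
}
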