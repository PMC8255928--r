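#' Default pipeline configuration
#'
#' Threshold defaults follow the analysis conventions the package
#' implements: DE at fold change >= 2 with raw p < 0.05; coexpression at
#' |r| >= 0.8 with p < 0.05, top 500 edges; cis window 300 kb; trans
#' duplex screen at >= 10 paired bases and energy <= -50; MCL at
#' expansion 2 / inflation 2.
#'
#' @param seed root seed for every stochastic stage.
#' @param sim a [sim_config()] for the simulate stage (NULL to disable
#'   and read `paths` instead).
#' @param paths named list of input paths (`expression`, `groups` implied
#'   by the expression reader, `gtf`, `fasta`, `gmt`, `clinical`, `ct`)
#'   when not simulating.
#' @param clinical_path optional clinical TSV analysed by the clinical
#'   stage (defaults to the bundled cohort table).
#' @param alpha,fc DE thresholds.
#' @param r_min,top_k coexpression threshold and edge budget.
#' @param window cis window (bp).
#' @param min_pairs,energy_max trans duplex thresholds.
#' @param mcl_inflation,mcl_expansion MCL parameters.
#' @return list of class `lncnet_config`.
#' @export
pipeline_config <- function(seed = 1, sim = sim_config(seed = seed),
                            paths = NULL,
                            clinical_path = system.file(
                              "extdata", "sapho_clinical.tsv",
                              package = "lncnet"),
                            alpha = 0.05, fc = 2, r_min = 0.8,
                            top_k = 500, window = 300000, min_pairs = 10,
                            energy_max = -50, mcl_inflation = 2,
                            mcl_expansion = 2) {
  stopifnot(alpha > 0, alpha <= 1, fc >= 1, r_min >= 0, r_min <= 1,
            top_k > 0, window >= 0, min_pairs >= 0, mcl_inflation > 1,
            mcl_expansion >= 2)
  structure(list(seed = as.integer(seed), sim = sim, paths = paths,
                 clinical_path = clinical_path, alpha = alpha, fc = fc,
                 r_min = r_min, top_k = as.integer(top_k), window = window,
                 min_pairs = min_pairs, energy_max = energy_max,
                 mcl_inflation = mcl_inflation,
                 mcl_expansion = mcl_expansion),
            class = "lncnet_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim`
#' block is passed to [sim_config()].
#'
#' @param path YAML file.
#' @return list of class `lncnet_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- if (!is.null(y$sim)) do.call(sim_config, y$sim) else NULL
  args <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config, c(args, list(sim = sim)))
}

#' Run the integrative lncRNA-mRNA pipeline end to end
#'
#' Stage order: simulate (or load) inputs, lncRNA catalog, differential
#' expression, coexpression network, MCL clustering, cis/trans target
#' inference, gene-set enrichment, qRT-PCR/ROC validation, clinical
#' summaries. All result tables are written under `outdir` together with a
#' `manifest.json` recording the configuration, per-stage row counts and
#' an md5 per output file. Re-running the same configuration reproduces
#' byte-identical outputs.
#'
#' @param cfg a [pipeline_config()] (or path to a YAML config).
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "lncnet_config"))
  if (is.null(cfg$sim)) {
    need <- c("expression", "gtf", "fasta", "gmt", "ct")
    miss <- need[!vapply(cfg$paths[need], function(p)
      !is.null(p) && file.exists(p), TRUE)]
    if (length(miss))
      stop("missing input path(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- list(); counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # --- inputs -------------------------------------------------------------
  if (!is.null(cfg$sim)) {
    sim <- stage("simulate", {
      s <- simulate_expression(cfg$sim)
      ann <- simulate_annotation(cfg$sim, s$truth, window = cfg$window)
      lens <- setNames(ann$length, ann$gene_id)
      seqs <- simulate_sequences(s$truth, lens,
                                 seed = child_seed(cfg$seed, 404L))
      names(seqs) <- ann$transcript_id[match(names(seqs), ann$gene_id)]
      gmt <- simulate_gene_sets(s$truth, seed = child_seed(cfg$seed, 505L))
      ct <- simulate_ct_table(s$truth, seed = child_seed(cfg$seed, 606L),
                              log2fc_effect = cfg$sim$log2fc_effect)
      write_expression(s$matrix, file.path(outdir, "expression.tsv"))
      write_gtf(ann, file.path(outdir, "annotation.gtf"))
      write_fasta(seqs, file.path(outdir, "transcripts.fa"))
      write_gmt(gmt, file.path(outdir, "gene_sets.gmt"))
      write_tsv(ct, file.path(outdir, "ct_table.tsv"))
      list(matrix = s$matrix, truth = s$truth, annotation = ann,
           sequences = seqs, gene_sets = gmt, ct = ct)
    })
    counts$simulate <- nrow(sim$matrix$values)
  } else {
    sim <- stage("load", {
      groups <- utils::read.delim(cfg$paths$groups,
                                  stringsAsFactors = FALSE)
      gm <- setNames(groups$group, groups$sample)
      ann <- parse_gtf(cfg$paths$gtf)
      seqs <- parse_fasta(cfg$paths$fasta)
      ct <- utils::read.delim(cfg$paths$ct, stringsAsFactors = FALSE)
      list(matrix = read_expression(cfg$paths$expression, gm),
           truth = NULL, annotation = ann, sequences = seqs,
           gene_sets = read_gmt(cfg$paths$gmt), ct = ct)
    })
    counts$load <- nrow(sim$matrix$values)
  }
  ann <- sim$annotation
  gene_seqs <- sim$sequences
  names(gene_seqs) <- ann$gene_id[match(names(gene_seqs),
                                        ann$transcript_id)]

  # --- catalog ------------------------------------------------------------
  res$catalog <- stage("catalog", {
    cand <- ann[ann$biotype != "mRNA", , drop = FALSE]
    coding <- ann[ann$biotype == "mRNA", , drop = FALSE]
    ref <- cand[cand$biotype == "lncRNA_known", , drop = FALSE]
    catalog <- build_catalog(cand, sim$sequences, reference = ref,
                             coding = coding)
    write_tsv(catalog, file.path(outdir, "catalog.tsv"))
    catalog
  })
  counts$catalog <- nrow(res$catalog)

  # --- differential expression + QC --------------------------------------
  res$de <- stage("de", {
    de <- de_test(sim$matrix, alpha = cfg$alpha, fc = cfg$fc)
    write_tsv(de, file.path(outdir, "de_results.tsv"))
    de
  })
  counts$de <- sum(res$de$direction != "ns")
  res$qc <- stage("qc", {
    sc <- sample_correlation(sim$matrix)
    pc <- pca_scores(sim$matrix, k = 2)
    hc <- hclust_average(log2(sim$matrix$values + 1))
    write_tsv(data.frame(sample = rownames(sc), sc, check.names = FALSE),
              file.path(outdir, "sample_correlation.tsv"))
    write_tsv(data.frame(sample = rownames(pc$scores), pc$scores,
                         check.names = FALSE),
              file.path(outdir, "pca_scores.tsv"))
    list(sample_correlation = sc, pca = pc, hclust = hc)
  })
  counts$qc <- ncol(sim$matrix$values)

  # --- coexpression network + clustering ---------------------------------
  is_lnc <- startsWith(res$de$gene_id, "LNC") |
    res$de$gene_id %in% ann$gene_id[ann$biotype != "mRNA"]
  de_lnc <- res$de$gene_id[res$de$direction != "ns" & is_lnc]
  de_mrna <- res$de$gene_id[res$de$direction != "ns" & !is_lnc]
  res$edges <- stage("network", {
    e <- correlate_pairs(sim$matrix, de_lnc, de_mrna, r_min = cfg$r_min)
    e <- select_top_edges(e, k = cfg$top_k)
    write_tsv(e, file.path(outdir, "edges.tsv"))
    e
  })
  counts$network <- nrow(res$edges)
  res$clusters <- stage("cluster", {
    if (nrow(res$edges)) {
      cl <- mcl(res$edges, expansion = cfg$mcl_expansion,
                inflation = cfg$mcl_inflation)
      write_tsv(data.frame(node = names(cl$membership),
                           cluster = as.integer(cl$membership),
                           stringsAsFactors = FALSE),
                file.path(outdir, "clusters.tsv"))
      cl
    } else NULL
  })
  counts$cluster <- if (is.null(res$clusters)) 0L else
    res$clusters$n_clusters

  # --- cis / trans targets ------------------------------------------------
  res$cis <- stage("targets_cis", {
    lncs <- unique(res$edges$lnc_id)
    cis <- do.call(rbind, lapply(lncs, function(l)
      cis_targets(ann[ann$gene_id == l, ][1, ],
                  ann[ann$biotype == "mRNA", ], window = cfg$window,
                  require_coexpr = TRUE, edges = res$edges)))
    cis <- cis %||% data.frame(lnc_id = character(0),
                               mrna_id = character(0),
                               distance = numeric(0),
                               same_chrom = logical(0))
    write_tsv(cis, file.path(outdir, "cis_targets.tsv"))
    cis
  })
  counts$targets_cis <- nrow(res$cis)
  res$trans <- stage("targets_trans", {
    hits <- duplex_hits(res$edges[, c("lnc_id", "mrna_id")], gene_seqs,
                        min_pairs = cfg$min_pairs)
    tr <- trans_targets(res$edges, hits, energy_max = cfg$energy_max,
                        min_pairs = cfg$min_pairs, records = ann,
                        window = cfg$window)
    write_tsv(tr, file.path(outdir, "trans_targets.tsv"))
    tr
  })
  counts$targets_trans <- nrow(res$trans)

  # --- enrichment ---------------------------------------------------------
  res$enrichment <- stage("enrich", {
    targets <- unique(c(res$cis$mrna_id, res$trans$mrna_id,
                        res$edges$mrna_id))
    background <- ann$gene_id[ann$biotype == "mRNA"]
    en <- enrich(intersect(targets, background), sim$gene_sets, background)
    en <- en %||% data.frame()
    write_tsv(en, file.path(outdir, "enrichment.tsv"))
    en
  })
  counts$enrich <- nrow(res$enrichment)

  # --- qRT-PCR / ROC validation ------------------------------------------
  res$validation <- stage("validate", {
    genes <- setdiff(unique(sim$ct$gene), "ACTB")
    rel <- lapply(genes, function(g)
      ddct_relative_expression(sim$ct, g))
    names(rel) <- genes
    rel_tab <- do.call(rbind, lapply(genes, function(g)
      cbind(gene = g, rel[[g]], stringsAsFactors = FALSE)))
    write_tsv(rel_tab, file.path(outdir, "relative_expression.tsv"))
    rocs <- lapply(rel, function(d) roc_auc(d$rel_expr, d$group))
    auc_tab <- data.frame(gene = genes,
                          auc = vapply(rocs, `[[`, 0, "auc"),
                          stringsAsFactors = FALSE)
    comb <- NULL
    if (length(genes) >= 2L) {
      top2 <- auc_tab$gene[order(-auc_tab$auc)][1:2]
      s1 <- rel[[top2[1]]]; s2 <- rel[[top2[2]]]
      stopifnot(identical(s1$sample, s2$sample))
      comb <- combined_roc(s1$rel_expr, s2$rel_expr, s1$group)
      auc_tab <- rbind(auc_tab, data.frame(
        gene = paste(top2, collapse = "+"), auc = comb$auc))
    }
    write_tsv(auc_tab, file.path(outdir, "auc.tsv"))
    list(rel_expr = rel, auc = auc_tab, combined = comb)
  })
  counts$validate <- nrow(res$validation$auc)

  # --- clinical -----------------------------------------------------------
  res$clinical <- stage("clinical", {
    if (!is.null(cfg$clinical_path) && nzchar(cfg$clinical_path) &&
        file.exists(cfg$clinical_path)) {
      cs <- clinical_summary_table(read_clinical(cfg$clinical_path))
      write_tsv(cs, file.path(outdir, "clinical_summary.tsv"))
      cs
    } else NULL
  })
  counts$clinical <- if (is.null(res$clinical)) 0L else nrow(res$clinical)

  # --- manifest -----------------------------------------------------------
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  manifest <- list(
    package = "lncnet",
    version = as.character(utils::packageVersion("lncnet")),
    config = cfg_fingerprint(cfg),
    stages = counts,
    files = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}

# Stable fingerprint of a configuration: serialised fields plus an md5.
cfg_fingerprint <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  plain <- strip(cfg)
  json <- jsonlite::toJSON(plain, auto_unbox = TRUE, digits = NA,
                           null = "null")
  list(hash = tools::md5sum(local({
    f <- tempfile(); writeLines(as.character(json), f); f
  }))[[1]], seed = cfg$seed)
}
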