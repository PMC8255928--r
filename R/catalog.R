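#' Length and location filter for candidate lncRNAs
#'
#' Keeps transcripts whose exonic length is at least `min_len` (the
#' standard >= 200 nt lncRNA definition) and removes candidates fully
#' contained, on the same strand, within the span of an annotated
#' protein-coding transcript — such fragments are usually mRNA debris.
#'
#' @param records candidate transcript records (data.frame as from
#'   [parse_gtf()]).
#' @param coding optional records of protein-coding transcripts used for
#'   the location filter; `NULL` skips it.
#' @param min_len minimum exonic length in nt (inclusive).
#' @return the retained subset of `records`.
#' @export
filter_candidates <- function(records, coding = NULL, min_len = 200) {
  keep <- records$length >= min_len
  if (!is.null(coding) && nrow(coding)) {
    contained <- vapply(seq_len(nrow(records)), function(i) {
      r <- records[i, ]
      any(coding$chrom == r$chrom & coding$strand == r$strand &
            coding$start <= r$start & coding$end >= r$end)
    }, TRUE)
    keep <- keep & !contained
  }
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Consensus of coding-potential predictors
#'
#' A transcript is retained as noncoding only when every listed predictor
#' calls it noncoding — the intersection of the predictors' noncoding sets.
#'
#' @param calls data.frame with columns `transcript_id`, `predictor`,
#'   `is_coding` (one row per transcript/predictor).
#' @param predictors character vector of predictor names that must all
#'   have been run.
#' @return character vector of transcript ids called noncoding by all
#'   predictors.
#' @export
consensus_noncoding <- function(calls, predictors) {
  ids <- unique(calls$transcript_id)
  calls <- calls[calls$predictor %in% predictors, , drop = FALSE]
  tab <- table(factor(calls$transcript_id, levels = ids),
               factor(calls$predictor, levels = predictors))
  if (any(tab != 1L))
    stop("every transcript needs exactly one call per predictor",
         call. = FALSE)
  ok <- vapply(ids, function(id) {
    sub <- calls[calls$transcript_id == id, ]
    !any(sub$is_coding)
  }, TRUE)
  ids[ok]
}

#' Known vs novel classification against a reference annotation
#'
#' A candidate is `known` when its same-strand overlap with any reference
#' lncRNA transcript covers at least `min_overlap_frac` of the candidate's
#' exonic length; otherwise `novel`.
#'
#' @param candidates,reference transcript records (data.frames).
#' @param min_overlap_frac minimum overlap fraction (of the candidate).
#' @return character vector (`"known"`/`"novel"`) named by candidate
#'   transcript id.
#' @export
classify_novelty <- function(candidates, reference, min_overlap_frac = 0.5) {
  out <- vapply(seq_len(nrow(candidates)), function(i) {
    r <- candidates[i, ]
    hit <- reference$chrom == r$chrom & reference$strand == r$strand
    if (!any(hit)) return("novel")
    ov <- pmax(0, pmin(reference$end[hit], r$end) -
                  pmax(reference$start[hit], r$start) + 1)
    if (any(ov / r$length >= min_overlap_frac)) "known" else "novel"
  }, "")
  names(out) <- candidates$transcript_id
  out
}

#' Built-in ORF-length coding-potential call
#'
#' Pluggable stand-in for external coding-potential tools: a sequence is
#' called coding when its longest open reading frame (ATG to in-frame stop,
#' any of the three forward frames) is at least `min_orf` nt including the
#' stop codon. Deterministic.
#'
#' @param sequence DNA string (A/C/G/T; other letters never match a codon).
#' @param min_orf minimum ORF length in nt (default 300).
#' @param predictor label recorded in the call.
#' @return data.frame row: `transcript_id` (NA, fill in by caller),
#'   `predictor`, `is_coding`, `longest_orf`.
#' @export
builtin_coding_stub <- function(sequence, min_orf = 300,
                                predictor = "orf300") {
  data.frame(transcript_id = NA_character_, predictor = predictor,
             is_coding = longest_orf(sequence) >= min_orf,
             longest_orf = longest_orf(sequence),
             stringsAsFactors = FALSE)
}

#' Longest ORF length (nt) across the three forward frames
#' @param sequence DNA string.
#' @return integer length (0 if no complete ORF).
#' @export
longest_orf <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  best <- 0L
  codons_at <- function(off) {
    k <- (n - off) %/% 3L
    if (k < 1L) return(character(0))
    substring(s, off + 1L + 3L * (seq_len(k) - 1L),
              off + 3L * seq_len(k))
  }
  stops <- c("TAA", "TAG", "TGA")
  for (off in 0:2) {
    cod <- codons_at(off)
    open_at <- NA_integer_
    for (j in seq_along(cod)) {
      if (is.na(open_at) && cod[j] == "ATG") open_at <- j
      if (!is.na(open_at) && cod[j] %in% stops) {
        best <- max(best, 3L * (j - open_at + 1L))
        open_at <- NA_integer_
      }
    }
  }
  best
}

#' Run the full lncRNA identification scheme
#'
#' Assembled candidates are length/location filtered, passed through the
#' coding-potential consensus (all predictors must call noncoding), and the
#' survivors classified as known or novel against the reference annotation.
#' The consensus output is by construction a subset of the filter output.
#'
#' @param candidates candidate transcript records.
#' @param sequences named character vector of candidate sequences.
#' @param reference reference lncRNA transcript records.
#' @param coding protein-coding transcript records for the location filter.
#' @param predictors list of predictor functions `f(sequence) -> logical`
#'   (is_coding); default: the built-in ORF stub under four predictor
#'   names, mirroring a multi-tool consensus with a single method.
#' @param min_len,min_overlap_frac see [filter_candidates()],
#'   [classify_novelty()].
#' @return data.frame catalog: transcript records plus `novelty`.
#' @export
build_catalog <- function(candidates, sequences, reference = NULL,
                          coding = NULL,
                          predictors = NULL, min_len = 200,
                          min_overlap_frac = 0.5) {
  if (is.null(predictors))
    predictors <- setNames(
      rep(list(function(s) longest_orf(s) >= 300), 4L),
      c("pfam_like", "cnci_like", "plek_like", "cpc_like"))
  filtered <- filter_candidates(candidates, coding, min_len)
  calls <- do.call(rbind, lapply(names(predictors), function(pn) {
    data.frame(transcript_id = filtered$transcript_id, predictor = pn,
               is_coding = vapply(sequences[filtered$transcript_id],
                                  predictors[[pn]], TRUE),
               stringsAsFactors = FALSE)
  }))
  nc <- consensus_noncoding(calls, names(predictors))
  out <- filtered[filtered$transcript_id %in% nc, , drop = FALSE]
  out$novelty <- if (!is.null(reference) && nrow(out))
    unname(classify_novelty(out, reference, min_overlap_frac))
  else rep("novel", nrow(out))
  rownames(out) <- NULL
  out
}
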