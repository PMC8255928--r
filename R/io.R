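#' Parse a GTF/GFF annotation into transcript records
#'
#' Reads a 9-column tab-delimited annotation and aggregates rows per
#' transcript: the record span is the min start / max end over its rows,
#' and `length` is the summed exonic length (all coordinates 1-based
#' inclusive). Attribute parsing accepts both the GTF `key "value";` and
#' the GFF `key=value` dialects. Rows other than `transcript` and `exon`
#' are ignored.
#'
#' @param path file path.
#' @return data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `biotype`, `length`.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- which(keep)
  if (!length(rows)) stop("empty GTF: ", path, call. = FALSE)
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stop(sprintf("GTF line %d does not have 9 tab-separated fields",
                 rows[which(nf != 9L)[1L]]), call. = FALSE)
  attr_get <- function(attrs, key) {
    m <- regmatches(attrs, regexec(
      paste0(key, '[ =]+"?([^";]+)"?'), attrs))[[1L]]
    if (length(m) < 2L) NA_character_ else m[2L]
  }
  recs <- lapply(seq_along(rows), function(i) {
    f <- fields[[i]]
    if (!(f[3L] %in% c("transcript", "exon"))) return(NULL)
    tid <- attr_get(f[9L], "transcript_id")
    if (is.na(tid))
      stop(sprintf("GTF line %d: missing transcript_id attribute", rows[i]),
           call. = FALSE)
    data.frame(transcript_id = tid,
               gene_id = attr_get(f[9L], "gene_id"),
               chrom = f[1L], feature = f[3L],
               start = as.numeric(f[4L]), end = as.numeric(f[5L]),
               strand = f[7L],
               biotype = attr_get(f[9L], "biotype"),
               stringsAsFactors = FALSE)
  })
  recs <- do.call(rbind, recs)
  if (is.null(recs)) stop("GTF has no transcript/exon rows", call. = FALSE)
  if (any(recs$start > recs$end))
    stop("GTF record with start > end", call. = FALSE)
  out <- lapply(split(recs, recs$transcript_id), function(d) {
    ex <- d[d$feature == "exon", , drop = FALSE]
    if (!nrow(ex)) ex <- d  # single transcript row, no exon rows
    data.frame(transcript_id = d$transcript_id[1L],
               gene_id = d$gene_id[1L],
               chrom = d$chrom[1L],
               start = min(d$start), end = max(d$end),
               strand = d$strand[1L],
               biotype = if (all(is.na(d$biotype))) "candidate"
                         else d$biotype[!is.na(d$biotype)][1L],
               length = sum(ex$end - ex$start + 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$transcript_id, recs$transcript_id)), ]
  rownames(out) <- NULL
  out
}

#' Write transcript records as GTF
#'
#' One `transcript` and one `exon` row per record (single-exon model),
#' `key "value";` attributes, UTF-8, LF line endings.
#'
#' @param records data.frame as returned by [parse_gtf()] or
#'   [simulate_annotation()].
#' @param path output path.
#' @export
write_gtf <- function(records, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; biotype "%s";',
                   records$gene_id, records$transcript_id, records$biotype)
  line1 <- sprintf("%s\tlncnet\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                   records$chrom, as.integer(records$start),
                   as.integer(records$end), records$strand, attrs)
  line2 <- sub("\ttranscript\t", "\texon\t", line1, fixed = TRUE)
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(as.vector(rbind(line1, line2)), con, sep = "\n")
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and RNA `U` is normalised to `T`; the id is the
#' first whitespace token of the header. Duplicate ids are an error.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
parse_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L], call. = FALSE)
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  names(seqs) <- ids
  seqs
}

#' Write sequences as wrapped FASTA
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60) {
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a gene-by-sample expression TSV
#'
#' The first column holds gene ids, the header row sample ids. Values must
#' be numeric and complete; missing or (for count/FPKM units) negative
#' values are an error — no imputation is performed.
#'
#' @param path file path.
#' @param group_map named character vector sample -> control/case; every
#'   sample in the header must be present.
#' @param unit abundance unit of the file.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, group_map,
                            unit = c("FPKM", "count", "log2FPKM")) {
  unit <- match.arg(unit)
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("expression table needs >= 2 columns",
                         call. = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values", call. = FALSE)
  rownames(m) <- d[[1L]]
  expression_matrix(m, group_map, unit = unit)
}

#' Write an expression matrix as TSV (gene id column + sample columns)
#' @param mat an [expression_matrix()].
#' @param path output path.
#' @export
write_expression <- function(mat, path) {
  d <- data.frame(gene_id = mat$gene_ids, mat$values,
                  check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(d, path)
  invisible(path)
}

# TSV writer shared by all pipeline outputs: UTF-8, LF endings, no quotes,
# deterministic formatting (15 significant digits).
write_tsv <- function(d, path) {
  num <- vapply(d, is.numeric, TRUE) & !vapply(d, is.integer, TRUE)
  d[num] <- lapply(d[num], function(x) format(x, digits = 15, trim = TRUE,
                                              scientific = FALSE))
  con <- file(path, "wb"); on.exit(close(con))
  utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one term per line, tab-separated `term_id`, description,
#' then member gene ids. Lines with fewer than three fields (i.e. an empty
#' member list) are an error.
#'
#' @param path file path.
#' @return list of gene sets, each a list with `term_id`, `term_name`,
#'   `members`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    list(term_id = f[1L], term_name = f[2L], members = unique(f[-(1:2)]))
  })
  out
}

#' Write gene sets to GMT
#' @param sets list as returned by [read_gmt()].
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(vapply(sets, function(s)
    paste(c(s$term_id, s$term_name, s$members), collapse = "\t"), ""),
    con, sep = "\n")
  invisible(path)
}

#' Read a clinical table
#'
#' Expects a TSV shaped like the cohort's clinical table: a `patient`
#' column plus the numeric columns `esr`, `hscrp`, `osteocalcin`, `vas`,
#' `wbc`, `neutrophil`.
#'
#' @param path file path.
#' @return data.frame, one row per patient.
#' @export
read_clinical <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("patient", "esr", "hscrp", "osteocalcin", "vas", "wbc",
            "neutrophil")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("clinical table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  d
}
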