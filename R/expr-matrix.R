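#' Expression matrix with sample group labels
#'
#' A light container for a gene-by-sample abundance grid together with the
#' case/control label of every sample and the abundance unit. All pipeline
#' stages that consume expression data take one of these.
#'
#' @param values numeric matrix, genes in rows, samples in columns; must
#'   carry row and column names. Non-negative when `unit` is `"count"` or
#'   `"FPKM"`.
#' @param groups named character vector mapping every sample id (column
#'   name) to `"control"` or `"case"`.
#' @param unit abundance unit, one of `"count"`, `"FPKM"`, `"log2FPKM"`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_ids`, `sample_ids`, `groups`, `unit`.
#' @examples
#' m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' expression_matrix(m, c(s1 = "control", s2 = "case"), unit = "count")
#' @export
expression_matrix <- function(values, groups,
                              unit = c("FPKM", "count", "log2FPKM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have gene row names and sample column names",
         call. = FALSE)
  if (anyNA(values))
    stop("expression matrix contains missing values; imputation is not ",
         "supported", call. = FALSE)
  if (unit != "log2FPKM" && any(values < 0))
    stop(sprintf("negative values are invalid for unit '%s'", unit),
         call. = FALSE)
  samples <- colnames(values)
  if (!all(samples %in% names(groups)))
    stop("samples missing from 'groups': ",
         paste(setdiff(samples, names(groups)), collapse = ", "),
         call. = FALSE)
  groups <- groups[samples]
  if (!all(groups %in% c("control", "case")))
    stop("group labels must be 'control' or 'case'", call. = FALSE)
  structure(list(values = values,
                 gene_ids = rownames(values),
                 sample_ids = samples,
                 groups = groups,
                 unit = unit),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat(sprintf("  groups: %d control, %d case\n",
              sum(x$groups == "control"), sum(x$groups == "case")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# Internal: samples of one group, in column order.
group_samples <- function(mat, group) {
  mat$sample_ids[mat$groups == group]
}
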