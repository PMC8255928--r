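#' Mean and sample SD summary of a clinical variable
#'
#' Summaries are reported as mean +/- SD with the sample (n-1) denominator;
#' rounding happens only at the presentation layer.
#'
#' @param values numeric vector, at least two finite values.
#' @param variable optional variable name carried into the result.
#' @return list with `variable`, `n`, `mean`, `sd`.
#' @examples
#' summarize_clinical(c(2, 2, 5, 7, 8, 3, 8, 9, 9, 1, 4, 6), "VAS")
#' @export
summarize_clinical <- function(values, variable = NA_character_) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("need >= 2 finite values for a mean +/- SD summary", call. = FALSE)
  list(variable = variable, n = length(values),
       mean = mean(values), sd = stats::sd(values))
}

# Normalise a group argument: either raw values or an (n, mean, sd) summary.
as_group_summary <- function(g) {
  if (is.numeric(g)) {
    if (length(g) < 2L) stop("each group needs n >= 2", call. = FALSE)
    list(n = length(g), mean = mean(g), sd = stats::sd(g))
  } else if (is.list(g) && all(c("n", "mean", "sd") %in% names(g))) {
    if (g$n < 2L) stop("each group needs n >= 2", call. = FALSE)
    g[c("n", "mean", "sd")]
  } else stop("group must be a numeric vector or a list(n, mean, sd)",
              call. = FALSE)
}

#' Two-sample t test from raw values or (n, mean, sd) summaries
#'
#' Student's variant pools the variance (df = n1 + n2 - 2); Welch uses the
#' Satterthwaite df. Either group may be given as a summary, which is how
#' published control-group statistics are compared against raw case data.
#' Two groups with zero variance and equal means return t = 0, p = 1 by
#' convention.
#'
#' @param group_a,group_b numeric vectors or `list(n =, mean =, sd =)`.
#' @param variant `"student"` (default) or `"welch"`.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(group_a, group_b,
                         variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as_group_summary(group_a); b <- as_group_summary(group_b)
  if (variant == "student") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    se <- sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    v <- a$sd^2 / a$n + b$sd^2 / b$n
    se <- sqrt(v)
    df <- if (v == 0) a$n + b$n - 2 else
      v^2 / (a$sd^4 / (a$n^2 * (a$n - 1)) + b$sd^4 / (b$n^2 * (b$n - 1)))
  }
  if (se == 0) {
    # both variances zero: equal means give the degenerate t = 0, p = 1;
    # different means are an infinite standardised difference
    if (a$mean == b$mean) return(list(t = 0, df = df, p = 1))
    return(list(t = sign(a$mean - b$mean) * Inf, df = df, p = 0))
  }
  t <- (a$mean - b$mean) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pearson correlation with a t-based two-sided p value
#'
#' p is computed from t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 df;
#' |r| = 1 returns p = 0.
#'
#' @param x,y numeric vectors of equal length, n >= 3, non-zero variance.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need n >= 3 for a correlation p value", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance input", call. = FALSE)
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Summarise every numeric clinical variable of a cohort table
#'
#' @param clinical data.frame from [read_clinical()].
#' @return data.frame with columns `variable`, `n`, `mean`, `sd` and the
#'   presentation string `mean_sd` (2 decimals).
#' @export
clinical_summary_table <- function(clinical) {
  vars <- names(clinical)[vapply(clinical, is.numeric, TRUE)]
  out <- do.call(rbind, lapply(vars, function(v) {
    s <- summarize_clinical(clinical[[v]], v)
    data.frame(variable = v, n = s$n, mean = s$mean, sd = s$sd,
               mean_sd = sprintf("%.2f ± %.2f", s$mean, s$sd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
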