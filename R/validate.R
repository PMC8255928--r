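#' Relative expression by the 2^-ddCt method
#'
#' Technical replicates are averaged per (sample, gene); delta-Ct is the
#' target Ct minus the reference-gene Ct of the same sample; delta-delta-Ct
#' subtracts the mean delta-Ct of the calibrator group; relative expression
#' is 2^(-ddCt). Adding a constant to every Ct (a consistent efficiency
#' shift) leaves the result unchanged.
#'
#' @param cts Ct table: data.frame with `sample`, `gene`, `replicate`,
#'   `ct`, and `group`.
#' @param target target gene id.
#' @param reference_gene reference (housekeeping) gene id, e.g. beta-actin.
#' @param calibrator_group group whose mean delta-Ct is the calibrator
#'   (default `"control"`, the healthy-control mean).
#' @return data.frame per sample: `sample`, `group`, `dct`, `ddct`,
#'   `rel_expr`.
#' @export
ddct_relative_expression <- function(cts, target, reference_gene = "ACTB",
                                     calibrator_group = "control") {
  if (!reference_gene %in% cts$gene)
    stop("reference gene absent from the Ct table: ", reference_gene,
         call. = FALSE)
  if (!target %in% cts$gene)
    stop("target gene absent from the Ct table: ", target, call. = FALSE)
  mean_ct <- function(g) {
    d <- cts[cts$gene == g, , drop = FALSE]
    tapply(d$ct, d$sample, mean)
  }
  tc <- mean_ct(target); rc <- mean_ct(reference_gene)
  samples <- intersect(names(tc), names(rc))
  if (!setequal(names(tc), names(rc)))
    stop("every sample needs both target and reference Cts", call. = FALSE)
  grp <- cts$group[match(samples, cts$sample)]
  dct <- tc[samples] - rc[samples]
  cal <- mean(dct[grp == calibrator_group])
  if (!is.finite(cal)) stop("no samples in the calibrator group",
                            call. = FALSE)
  ddct <- dct - cal
  data.frame(sample = samples, group = grp, dct = as.numeric(dct),
             ddct = as.numeric(ddct), rel_expr = 2^(-as.numeric(ddct)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' ROC curve and AUC with half-credit ties
#'
#' AUC is the Mann-Whitney U statistic (ties counted 1/2) divided by
#' n_case * n_control — the probability that a random case scores above a
#' random control. The score direction is auto-oriented so AUC >= 0.5 and
#' the orientation is recorded; the curve is computed on the oriented
#' scores and runs from (0, 0) to (1, 1).
#'
#' @param scores numeric marker values, one per sample.
#' @param labels `"case"`/`"control"` per sample; both classes required.
#' @return list of class `roc_result`: `auc`, `direction` (`1` if cases
#'   score high, `-1` if the scores were flipped), `thresholds`, `tpr`,
#'   `fpr`, `n_case`, `n_control`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  is_case <- labels == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop("both classes must be present",
                               call. = FALSE)
  auc_of <- function(s) {
    r <- rank(s)  # midranks give the tie-half-credit U
    (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_of(scores)
  direction <- 1
  if (auc < 0.5) { direction <- -1; scores <- -scores; auc <- auc_of(scores) }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[is_case] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!is_case] >= t), 0)
  structure(list(auc = auc, direction = direction, thresholds = thr,
                 tpr = tpr, fpr = fpr, n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC %.3f (%d case vs %d control%s)\n", x$auc,
              x$n_case, x$n_control,
              if (x$direction < 0) ", score orientation flipped" else ""))
  invisible(x)
}

# Binomial logistic fit by iteratively reweighted least squares.
# X includes the intercept column. Returns coef and a separation flag.
irls_logistic <- function(X, y, max_iter = 50, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  converged <- FALSE
  singular <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(drop(solve(XtW %*% X, XtW %*% z)),
                         error = function(e) NULL)
    if (is.null(beta_new)) { singular <- TRUE; break }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  # perfect separation: the fitted score splits the classes with no overlap
  # and the likelihood keeps improving instead of converging
  separated <- singular ||
    ((!converged || max(abs(beta)) > 30) &&
       min(eta[y == 1]) > max(eta[y == 0]))
  list(coef = beta, separated = separated, converged = converged)
}

#' Combined two-marker ROC via logistic scoring
#'
#' Fits a two-feature binomial logistic model (internally, by IRLS; 50
#' iterations, tolerance 1e-10) and evaluates the ROC of its linear
#' predictor — the standard way to combine two diagnostic markers into one
#' score. Constant markers are dropped before fitting; under perfect
#' separation the fit is abandoned and the better single marker is used,
#' with `separated = TRUE` recorded.
#'
#' @param marker_a,marker_b numeric marker values over the same samples.
#' @param labels `"case"`/`"control"` per sample.
#' @return a `roc_result` with extra fields `coef` (or NULL under the
#'   fallback) and `separated`.
#' @export
combined_roc <- function(marker_a, marker_b, labels) {
  stopifnot(length(marker_a) == length(marker_b),
            length(marker_a) == length(labels))
  y <- as.numeric(labels == "case")
  feats <- list(a = marker_a, b = marker_b)
  feats <- feats[vapply(feats, function(f) stats::sd(f) > 0, TRUE)]
  if (!length(feats)) stop("both markers are constant", call. = FALSE)
  X <- cbind(1, do.call(cbind, lapply(feats, scale)))
  fit <- irls_logistic(X, y)
  if (fit$separated) {
    rocs <- lapply(feats, roc_auc, labels = labels)
    best <- rocs[[which.max(vapply(rocs, `[[`, 0, "auc"))]]
    best$coef <- NULL
    best$separated <- TRUE
    return(best)
  }
  out <- roc_auc(drop(X %*% fit$coef), labels)
  out$coef <- drop(fit$coef)
  out$separated <- FALSE
  out
}

#' Correlation of a marker with a clinical variable
#'
#' Pearson correlation (with t-based p) between per-sample relative
#' expression and a clinical covariate, over patient samples only.
#'
#' @param rel_expr data.frame from [ddct_relative_expression()].
#' @param clinical_values named numeric vector (names = sample ids) of the
#'   clinical variable.
#' @param group which sample group to correlate over (default `"case"`).
#' @return list with `r`, `p`, `n` (see [pearson_with_p()]).
#' @export
marker_clinical_correlation <- function(rel_expr, clinical_values,
                                        group = "case") {
  d <- rel_expr[rel_expr$group == group, , drop = FALSE]
  common <- intersect(d$sample, names(clinical_values))
  if (length(common) < 3L)
    stop("need >= 3 samples with both marker and clinical values",
         call. = FALSE)
  pearson_with_p(d$rel_expr[match(common, d$sample)],
                 as.numeric(clinical_values[common]))
}
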