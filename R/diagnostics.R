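#' Cochran's Q heterogeneity statistic
#'
#' Weighted sum of squared deviations of the per-SNP Wald ratios from the
#' fixed-effects IVW estimate, with weights
#' \eqn{w_i = \beta_{X,i}^2/\sigma_{Y,i}^2}. Excess Q relative to a
#' chi-square with k − 1 degrees of freedom signals heterogeneity between
#' instruments, a symptom of pleiotropy or other assumption violations.
#'
#' @param ds An [mr_dataset()] with at least 2 SNPs.
#' @return Object of class `mr_heterogeneity`: list with `q`, `df`,
#'   `pvalue`, and `contributions` (named per-SNP terms summing to `q`).
#' @export
cochran_q <- function(ds) {
  stopifnot(inherits(ds, "mr_dataset"))
  .need_pairs(ds, 2L, "Cochran's Q")
  p <- .ratio_parts(ds)
  est <- sum(p$w * p$r) / sum(p$w)
  contrib <- setNames(p$w * (p$r - est)^2, ds$rsid)
  q <- sum(contrib)
  df <- nrow(ds) - 1L
  structure(list(q = q, df = df,
                 pvalue = pchisq(q, df, lower.tail = FALSE),
                 contributions = contrib),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n",
              x$q, x$df, x$pvalue))
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Recomputes the IVW estimate with each SNP excluded in turn, to reveal
#' whether the pooled result is driven disproportionately by any single
#' instrument.
#'
#' @param ds An [mr_dataset()] with at least 3 SNPs.
#' @param effects_model Passed to [mr_ivw()].
#' @return Data frame with one row per excluded SNP (ordered by rsid):
#'   `excluded_rsid` followed by the pooled-result columns computed on the
#'   remaining k − 1 SNPs.
#' @export
leave_one_out <- function(ds, effects_model = "multiplicative_random") {
  stopifnot(inherits(ds, "mr_dataset"))
  .need_pairs(ds, 3L, "leave-one-out analysis")
  ds <- .sort_ds(ds)
  rows <- lapply(seq_len(nrow(ds)), function(i)
    cbind(excluded_rsid = ds$rsid[i],
          mr_ivw(subset_dataset(ds, -i), effects_model),
          stringsAsFactors = FALSE))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Flag outlier instruments by their heterogeneity contribution
#'
#' Each SNP's contribution to Cochran's Q is referred to a chi-square
#' distribution with 1 degree of freedom; SNPs whose contribution p-value
#' falls below `alpha/k` (Bonferroni, the default) or `alpha` are flagged
#' as outliers and likely sources of heterogeneity.
#'
#' @param ds An [mr_dataset()] with at least 3 SNPs.
#' @param alpha Significance level (default 0.05).
#' @param correction `"bonferroni"` (default) or `"none"`.
#' @return Character vector of flagged rsids, sorted by contribution in
#'   descending order, with attribute `pvalues` giving every SNP's
#'   contribution p-value.
#' @export
flag_outliers <- function(ds, alpha = 0.05,
                          correction = c("bonferroni", "none")) {
  stopifnot(inherits(ds, "mr_dataset"))
  correction <- match.arg(correction)
  .need_pairs(ds, 3L, "outlier flagging")
  het <- cochran_q(ds)
  pvals <- pchisq(het$contributions, df = 1, lower.tail = FALSE)
  cut <- if (correction == "bonferroni") alpha / nrow(ds) else alpha
  flagged <- names(het$contributions)[pvals < cut]
  flagged <- flagged[order(-het$contributions[flagged])]
  structure(flagged, pvalues = pvals)
}

#' Forest, funnel and leave-one-out tables for sensitivity reporting
#'
#' Assembles the plot-ready tables behind the standard two-sample MR
#' figure panels: a forest table (per-SNP Wald estimates followed by one
#' row per pooled method), a funnel table (per-SNP estimate against the
#' inverse of its standard error, with the pooled estimates as vertical
#' references), the leave-one-out table, and the flagged outliers.
#'
#' @param ds An [mr_dataset()].
#' @param pooled Data frame of pooled results (e.g. `mr_fit(ds, ...)$results`);
#'   must be non-empty.
#' @param ... Passed to [flag_outliers()] when k >= 3.
#' @return Object of class `mr_sensitivity`: list with `forest`, `funnel`,
#'   `leave_one_out` (`NULL` when k < 3), `outliers`, and
#'   `funnel_references` (the pooled estimates).
#' @export
sensitivity_tables <- function(ds, pooled, ...) {
  stopifnot(inherits(ds, "mr_dataset"), is.data.frame(pooled),
            nrow(pooled) > 0)
  snp <- wald_ratio(ds)
  forest <- rbind(
    data.frame(label = snp$rsid, type = "snp", estimate = snp$estimate,
               se = snp$se, ci_low = snp$ci_low, ci_high = snp$ci_high,
               pvalue = snp$pvalue, stringsAsFactors = FALSE),
    data.frame(label = pooled$method, type = "pooled",
               estimate = pooled$estimate, se = pooled$se,
               ci_low = pooled$ci_low, ci_high = pooled$ci_high,
               pvalue = pooled$pvalue, stringsAsFactors = FALSE))
  funnel <- data.frame(rsid = snp$rsid, estimate = snp$estimate,
                       precision = 1 / snp$se, stringsAsFactors = FALSE)
  structure(list(
    forest = forest,
    funnel = funnel,
    leave_one_out = if (nrow(ds) >= 3) leave_one_out(ds) else NULL,
    outliers = if (nrow(ds) >= 3) flag_outliers(ds, ...) else character(0),
    funnel_references = setNames(pooled$estimate, pooled$method)),
    class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  n_snp <- sum(x$forest$type == "snp")
  cat(sprintf("MR sensitivity report: %d SNP(s), %d pooled method(s)\n",
              n_snp, sum(x$forest$type == "pooled")))
  if (length(x$outliers))
    cat("  flagged outliers:", paste(x$outliers, collapse = ", "), "\n")
  else cat("  no outliers flagged\n")
  invisible(x)
}
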