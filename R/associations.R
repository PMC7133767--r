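#' Convert an odds-ratio confidence interval to a log-scale standard error
#'
#' GWAS consortia commonly publish binary-trait associations as an odds
#' ratio with a 95% confidence interval rather than as a log-odds beta and
#' standard error. The SE on the log-odds scale is recovered as
#' \eqn{(\log CI_{high} - \log CI_{low}) / (2 z)} with \eqn{z} the standard
#' normal quantile at \eqn{(1 + level)/2}.
#'
#' @param point_or Point odds ratio(s), strictly positive.
#' @param ci_low,ci_high Lower and upper confidence bounds, strictly
#'   positive, with `ci_low <= point_or <= ci_high`.
#' @param level Coverage of the interval (default 0.95, for which
#'   `z = 1.959964`).
#' @return Standard error(s) of `log(point_or)`, strictly positive.
#' @examples
#' ci_to_log_se(1.00, 0.96, 1.04)  # ~0.0204
#' @export
ci_to_log_se <- function(point_or, ci_low, ci_high, level = 0.95) {
  stopifnot(is.numeric(point_or), is.numeric(ci_low), is.numeric(ci_high),
            length(level) == 1L, level > 0, level < 1)
  if (any(point_or <= 0 | ci_low <= 0 | ci_high <= 0))
    stop("odds ratios and confidence bounds must be strictly positive")
  if (any(ci_low > point_or | point_or > ci_high))
    stop("inverted confidence interval: require ci_low <= point_or <= ci_high")
  z <- if (identical(level, 0.95)) .z95 else qnorm((1 + level) / 2)
  (log(ci_high) - log(ci_low)) / (2 * z)
}

.required_cols <- function(trait_kind) {
  base <- c("rsid", "effect_allele", "other_allele")
  if (trait_kind == "continuous") c(base, "beta", "se") else base
}

#' Read a per-SNP association table
#'
#' Reads a tab-separated table of single-SNP association statistics with a
#' header row. Continuous traits require `beta` and `se` columns; binary
#' traits may carry either `beta`/`se` (log-odds scale) or `or`, `ci_low`,
#' `ci_high`, which are converted via [ci_to_log_se()]. A `chr` column is
#' accepted as an alias for `chrom`. Optional columns `eaf`, `pvalue`, `n`,
#' `source`, `proxy_rsid`, `proxy_r2` are carried through; missing ones are
#' filled with `NA`. Row order is preserved.
#'
#' @param file Path to a TSV file, or a connection.
#' @param trait_kind `"continuous"` or `"binary"`.
#' @return A data frame of variant associations with standardized columns
#'   `rsid`, `chrom`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `pvalue`, `n`, `source`, `proxy_rsid`, `proxy_r2` and attribute
#'   `trait_kind`.
#' @export
read_association_table <- function(file, trait_kind = c("continuous", "binary")) {
  trait_kind <- match.arg(trait_kind)
  df <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  as_association_table(df, trait_kind)
}

#' Standardize an in-memory association data frame
#'
#' Validation and column normalization behind [read_association_table()],
#' usable directly on a data frame (e.g. one produced by
#' [simulate_two_sample()]).
#'
#' @inheritParams read_association_table
#' @param df Data frame with the columns described in
#'   [read_association_table()].
#' @return See [read_association_table()].
#' @export
as_association_table <- function(df, trait_kind = c("continuous", "binary")) {
  trait_kind <- match.arg(trait_kind)
  stopifnot(is.data.frame(df))
  names(df)[names(df) == "chr"] <- "chrom"

  miss <- setdiff(.required_cols(trait_kind), names(df))
  if (length(miss))
    stop("association table is missing required column(s): ",
         paste(miss, collapse = ", "))

  if (trait_kind == "binary" && !all(c("beta", "se") %in% names(df))) {
    or_cols <- c("or", "ci_low", "ci_high")
    if (!all(or_cols %in% names(df)))
      stop("binary association table needs either columns beta, se or ",
           "columns or, ci_low, ci_high")
    if (nrow(df)) {
      bad <- which(df$or <= 0 | df$ci_low <= 0 | df$ci_high <= 0)
      if (length(bad))
        stop("non-positive odds ratio or confidence bound for SNP(s): ",
             paste(df$rsid[bad], collapse = ", "))
      df$beta <- log(df$or)
      df$se <- ci_to_log_se(df$or, df$ci_low, df$ci_high)
    } else {
      df$beta <- numeric(0)
      df$se <- numeric(0)
    }
  }

  opt <- c("chrom", "eaf", "pvalue", "n", "source", "proxy_rsid", "proxy_r2")
  for (col in opt) if (!col %in% names(df)) df[[col]] <- rep(NA, nrow(df))

  if (nrow(df)) {
    bad <- which(!is.na(df$se) & df$se <= 0)
    if (length(bad))
      stop("non-positive standard error for SNP(s): ",
           paste(df$rsid[bad], collapse = ", "))
    same <- which(toupper(df$effect_allele) == toupper(df$other_allele))
    if (length(same))
      stop("effect and other allele identical for SNP(s): ",
           paste(df$rsid[same], collapse = ", "))
    if (any(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1)))
      stop("effect-allele frequency outside [0, 1]")
    df$effect_allele <- toupper(df$effect_allele)
    df$other_allele <- toupper(df$other_allele)
  }

  keep <- c("rsid", "chrom", "effect_allele", "other_allele", "eaf",
            "beta", "se", "pvalue", "n", "source", "proxy_rsid", "proxy_r2")
  out <- df[, keep]
  rownames(out) <- NULL
  attr(out, "trait_kind") <- trait_kind
  out
}

#' Write an association table to TSV
#'
#' @param df Association data frame (as from [as_association_table()] or
#'   [simulate_two_sample()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
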