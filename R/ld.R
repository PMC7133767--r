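#' Construct a pairwise LD table
#'
#' Sparse symmetric table of pairwise linkage-disequilibrium r-squared
#' values. Pairs absent from the table are treated as independent
#' (r² = 0); a variant's r² with itself is 1.
#'
#' @param rsid_a,rsid_b Character vectors of variant identifiers.
#' @param r2 r-squared values in \[0, 1\].
#' @return An object of class `ld_table`.
#' @export
ld_table <- function(rsid_a = character(0), rsid_b = character(0),
                     r2 = numeric(0)) {
  stopifnot(length(rsid_a) == length(rsid_b), length(rsid_b) == length(r2))
  if (any(r2 < 0 | r2 > 1)) stop("r2 values must lie in [0, 1]")
  df <- data.frame(rsid_a = as.character(rsid_a),
                   rsid_b = as.character(rsid_b),
                   r2 = as.numeric(r2), stringsAsFactors = FALSE)
  structure(df, class = c("ld_table", "data.frame"))
}

#' Read an LD table from TSV
#'
#' @param file Path to a tab-separated file with columns
#'   `rsid_a`, `rsid_b`, `r2`.
#' @return An [ld_table()].
#' @export
read_ld_table <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  miss <- setdiff(c("rsid_a", "rsid_b", "r2"), names(df))
  if (length(miss))
    stop("LD table is missing required column(s): ", paste(miss, collapse = ", "))
  ld_table(df$rsid_a, df$rsid_b, df$r2)
}

#' Look up pairwise r-squared values
#'
#' @param ld An [ld_table()].
#' @param a,b Variant identifiers (recycled to a common length).
#' @return Numeric vector of r² values; 0 for absent pairs, 1 on the
#'   diagonal.
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_table"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  key <- function(x, y) paste(pmin(x, y), pmax(x, y), sep = "\r")
  lut <- setNames(ld$r2, key(ld$rsid_a, ld$rsid_b))
  out <- unname(lut[key(a, b)])
  out[is.na(out)] <- 0
  out[a == b] <- 1
  out
}

#' Prune instruments by linkage disequilibrium
#'
#' Greedy LD clumping: candidates are visited in ascending association
#' p-value (ties broken by rsid), and a SNP is retained only if its r² with
#' every already-retained SNP does not exceed `r2_max`. The returned table
#' preserves the input row order of the retained SNPs, so the result does
#' not depend on how the input was sorted.
#'
#' @param assocs Association data frame with columns `rsid` and `pvalue`.
#' @param ld An [ld_table()]; absent pairs count as independent.
#' @param r2_max Maximum allowed pairwise r² (default 0.01).
#' @return `assocs` restricted to the retained SNPs.
#' @export
prune_ld <- function(assocs, ld, r2_max = 0.01) {
  stopifnot(is.data.frame(assocs))
  if (!nrow(assocs)) return(assocs)
  p <- assocs$pvalue
  p[is.na(p)] <- 1
  visit <- order(p, assocs$rsid)
  retained <- character(0)
  for (i in visit) {
    if (all(ld_r2(ld, assocs$rsid[i], retained) <= r2_max))
      retained <- c(retained, assocs$rsid[i])
  }
  out <- assocs[assocs$rsid %in% retained, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find proxy variants for SNPs absent from the outcome data
#'
#' For each target SNP missing from the outcome study, searches the
#' supplied outcome panel(s) for the candidate in highest LD with the
#' target, requiring r² of at least `r2_min` (ties broken by rsid). When
#' several panels are given they are searched in priority order and the
#' first panel yielding a qualifying proxy wins. Targets with no
#' qualifying candidate are reported unproxied (`NA` proxy), not an error.
#'
#' @param missing Association data frame of target SNPs needing a proxy.
#' @param ld An [ld_table()] relating targets to candidates.
#' @param outcome_panel A single association data frame or a list of them
#'   in priority order.
#' @param r2_min Minimum qualifying r² (default 0.8).
#' @return Data frame with one row per target: `rsid`, `proxy_rsid`,
#'   `proxy_r2`, `panel` (priority index of the supplying panel; `NA`
#'   when unproxied).
#' @export
substitute_proxies <- function(missing, ld, outcome_panel, r2_min = 0.8) {
  stopifnot(is.data.frame(missing))
  panels <- if (is.data.frame(outcome_panel)) list(outcome_panel) else outcome_panel
  out <- data.frame(rsid = missing$rsid,
                    proxy_rsid = NA_character_, proxy_r2 = NA_real_,
                    panel = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(missing))) {
    target <- missing$rsid[i]
    for (pi in seq_along(panels)) {
      cand <- setdiff(panels[[pi]]$rsid, target)
      if (!length(cand)) next
      r2 <- ld_r2(ld, target, cand)
      ok <- r2 >= r2_min
      if (!any(ok)) next
      cand <- cand[ok]; r2 <- r2[ok]
      best <- order(-r2, cand)[1L]
      out$proxy_rsid[i] <- cand[best]
      out$proxy_r2[i] <- r2[best]
      out$panel[i] <- pi
      break
    }
  }
  out
}
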