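#' Variance in the exposure explained by each instrument
#'
#' Under Hardy-Weinberg equilibrium an additive biallelic variant with
#' effect-allele frequency p and per-allele effect beta explains
#' \eqn{2 p (1-p) \beta^2 / \sigma^2} of the variance of a phenotype with
#' standard deviation \eqn{\sigma}.
#'
#' @param assocs Exposure association data frame (or an [mr_dataset()],
#'   whose exposure-side columns are used) with `rsid`, `eaf`, `beta`.
#' @param pheno_sd Phenotype standard deviation in exposure units
#'   (default 1.31 mg/dl, calibrated for the serum-urate panel; the source
#'   urate GWAS reports per-study SDs of 0.92-1.68 mg/dl).
#' @return List with `per_snp_r2` (named), `total_r2`, `pheno_sd`, and
#'   `excluded` (rsids lacking an allele frequency, reported rather than
#'   silently dropped).
#' @export
variance_explained <- function(assocs, pheno_sd = 1.31) {
  stopifnot(is.data.frame(assocs), pheno_sd > 0)
  if (inherits(assocs, "mr_dataset")) {
    beta <- assocs$beta_exposure
  } else {
    beta <- assocs$beta
  }
  eaf <- assocs$eaf
  ok <- !is.na(eaf)
  r2 <- setNames(2 * eaf[ok] * (1 - eaf[ok]) * beta[ok]^2 / pheno_sd^2,
                 assocs$rsid[ok])
  list(per_snp_r2 = r2, total_r2 = sum(r2), pheno_sd = pheno_sd,
       excluded = assocs$rsid[!ok])
}

#' Instrument F statistic
#'
#' Strength of a set of k instruments jointly explaining a fraction r² of
#' exposure variance in a GWAS of n individuals:
#' \eqn{F = r^2 (n - k - 1) / ((1 - r^2) k)}. Values above ~10 are
#' conventionally taken to indicate negligible weak-instrument bias.
#'
#' @param r2 Variance fraction in (0, 1).
#' @param n Exposure GWAS sample size, with `n > k + 1`.
#' @param k Number of instruments, at least 1.
#' @return The F value.
#' @examples
#' f_statistic(0.05, 110347, 18)  # ~322.6
#' @export
f_statistic <- function(r2, n, k) {
  stopifnot(length(r2) == 1, length(n) == 1, length(k) == 1)
  if (!(r2 > 0 && r2 < 1)) stop("r2 must lie strictly between 0 and 1")
  if (k < 1) stop("k must be at least 1")
  if (n <= k + 1) stop("sample size must exceed k + 1")
  r2 * (n - k - 1) / ((1 - r2) * k)
}

#' Combined instrument-strength summary
#'
#' @param assocs Exposure associations (see [variance_explained()]).
#' @param n Exposure GWAS sample size.
#' @param pheno_sd Phenotype SD (see [variance_explained()]).
#' @return Object of class `mr_strength`: list with `per_snp_r2`,
#'   `total_r2`, `f_stat`, `n`, `k`, `pheno_sd`.
#' @export
instrument_strength <- function(assocs, n, pheno_sd = 1.31) {
  ve <- variance_explained(assocs, pheno_sd)
  k <- length(ve$per_snp_r2)
  structure(list(per_snp_r2 = ve$per_snp_r2, total_r2 = ve$total_r2,
                 f_stat = f_statistic(ve$total_r2, n, k),
                 n = n, k = k, pheno_sd = pheno_sd),
            class = "mr_strength")
}

#' @export
print.mr_strength <- function(x, ...) {
  cat(sprintf(
    "Instrument strength: %d SNPs, total r2 = %.4f, F = %.1f (n = %d)\n",
    x$k, x$total_r2, x$f_stat, x$n))
  invisible(x)
}

.ncp_scale <- function(n_outcome, case_fraction, r2) {
  stopifnot(n_outcome > 0, case_fraction > 0, case_fraction < 1,
            r2 > 0, r2 < 1)
  sqrt(n_outcome * r2 * case_fraction * (1 - case_fraction))
}

#' Power of a two-sample MR analysis with a binary outcome
#'
#' Noncentrality approximation for the power of a two-sided Wald test of
#' the IVW estimate: \eqn{\Phi(|\log OR| \sqrt{n r^2 c (1-c)} - z_{1-\alpha/2})}
#' with n the outcome sample size, c the case fraction and r² the variance
#' of the exposure explained by the instruments.
#'
#' @param or_alt Alternative-hypothesis odds ratio per unit exposure
#'   (> 0).
#' @param n_outcome Total outcome-study sample size.
#' @param case_fraction Cases / total, in (0, 1).
#' @param r2 Instrumented exposure variance fraction, in (0, 1).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power as a fraction in (0, 1).
#' @examples
#' power_binary(1.14, 38589, 14498 / 38589, 0.05)  # ~0.80
#' @export
power_binary <- function(or_alt, n_outcome, case_fraction, r2, alpha = 0.05) {
  stopifnot(or_alt > 0, alpha > 0, alpha < 1)
  s <- .ncp_scale(n_outcome, case_fraction, r2)
  pnorm(abs(log(or_alt)) * s - qnorm(1 - alpha / 2))
}

#' Smallest detectable odds ratio at a target power
#'
#' Inverts [power_binary()]: the odds ratio detectable with probability
#' `power` is \eqn{\exp((z_{power} + z_{1-\alpha/2})/\sqrt{n r^2 c(1-c)})};
#' the protective-direction bound is its reciprocal.
#'
#' @param power Target power, in (alpha/2, 1).
#' @inheritParams power_binary
#' @return Named numeric vector `c(or_above_1, or_below_1)`, reciprocal of
#'   one another. `power_binary()` at `or_above_1` returns `power`
#'   exactly (round trip).
#' @examples
#' detectable_or(0.8, 38589, 14498 / 38589, 0.05)  # ~1.14 and ~0.88
#' @export
detectable_or <- function(power, n_outcome, case_fraction, r2, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (!(power > alpha / 2 && power < 1))
    stop("target power must lie in (alpha/2, 1)")
  s <- .ncp_scale(n_outcome, case_fraction, r2)
  or_hi <- exp((qnorm(power) + qnorm(1 - alpha / 2)) / s)
  c(or_above_1 = or_hi, or_below_1 = 1 / or_hi)
}
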