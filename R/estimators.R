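# assemble one pooled-result row; df = NULL for normal inference, an
# integer for t inference (CI uses the matching quantile)
pooled_row <- function(method, n_snps, estimate, se, df = NULL) {
  if (is.null(df)) {
    pvalue <- 2 * pnorm(-abs(estimate / se))
    q <- .z95
  } else {
    pvalue <- 2 * pt(-abs(estimate / se), df)
    q <- stats::qt(0.975, df)
  }
  data.frame(method = method, n_snps = n_snps,
             estimate = estimate, se = se,
             ci_low = estimate - q * se, ci_high = estimate + q * se,
             pvalue = pvalue,
             or = exp(estimate),
             or_ci_low = exp(estimate - q * se),
             or_ci_high = exp(estimate + q * se),
             stringsAsFactors = FALSE)
}

.need_pairs <- function(ds, k, what) {
  if (nrow(ds) < k)
    stop(sprintf("%s requires at least %d instrument(s), got %d",
                 what, k, nrow(ds)))
}

# canonical order for bootstrap reproducibility under input permutation
.sort_ds <- function(ds) subset_dataset(ds, order(ds$rsid))

#' Per-SNP Wald ratio estimates
#'
#' The single-instrument causal estimate: the SNP-outcome effect divided by
#' the SNP-exposure effect, with a first-order delta-method standard error
#' `se_outcome / |beta_exposure|`. Setting `second_order = TRUE` adds the
#' exposure-side uncertainty term
#' \eqn{\beta_Y^2 \sigma_X^2 / \beta_X^4} under the square root.
#'
#' @param ds An [mr_dataset()].
#' @param second_order Include the exposure-error term in the SE
#'   (default `FALSE`).
#' @return Data frame with one row per SNP: `rsid`, `estimate` (log-odds of
#'   outcome per exposure unit), `se`, `ci_low`, `ci_high`, `pvalue`, plus
#'   odds-ratio-scale columns.
#' @export
wald_ratio <- function(ds, second_order = FALSE) {
  stopifnot(inherits(ds, "mr_dataset"))
  zero <- ds$rsid[ds$beta_exposure == 0]
  if (length(zero))
    stop("Wald ratio undefined (beta_exposure = 0) for SNP(s): ",
         paste(zero, collapse = ", "))
  est <- ds$beta_outcome / ds$beta_exposure
  se <- ds$se_outcome / abs(ds$beta_exposure)
  if (second_order)
    se <- sqrt(se^2 + ds$beta_outcome^2 * ds$se_exposure^2 / ds$beta_exposure^4)
  data.frame(rsid = ds$rsid, estimate = est, se = se,
             ci_low = est - .z95 * se, ci_high = est + .z95 * se,
             pvalue = 2 * pnorm(-abs(est / se)),
             or = exp(est), or_ci_low = exp(est - .z95 * se),
             or_ci_high = exp(est + .z95 * se),
             stringsAsFactors = FALSE)
}

# ratios and inverse-variance weights shared by IVW / median / Q
.ratio_parts <- function(ds) {
  list(r = ds$beta_outcome / ds$beta_exposure,
       w = ds$beta_exposure^2 / ds$se_outcome^2,
       se_r = ds$se_outcome / abs(ds$beta_exposure))
}

#' Inverse-variance weighted causal estimate
#'
#' Pools the per-SNP Wald ratios with weights
#' \eqn{w_i = \beta_{X,i}^2 / \sigma_{Y,i}^2}. Under
#' `"multiplicative_random"` effects the fixed-effects standard error is
#' inflated by \eqn{\max(1, \sqrt{Q/(k-1)})}, where Q is Cochran's
#' heterogeneity statistic about the pooled estimate; the point estimate is
#' identical under both effects models. Fixed-effects inference is
#' normal-based; random-effects inference uses a t distribution with k − 1
#' degrees of freedom, matching the degrees of freedom the dispersion
#' multiplier is estimated from.
#'
#' @param ds An [mr_dataset()] (at least 1 SNP for fixed effects, 2 for
#'   random effects).
#' @param effects_model `"multiplicative_random"` (default, allowing each
#'   SNP its own mean effect) or `"fixed"`.
#' @return A one-row pooled-result data frame (`method`, `n_snps`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `pvalue`, and odds-ratio scale
#'   columns).
#' @export
mr_ivw <- function(ds, effects_model = c("multiplicative_random", "fixed")) {
  stopifnot(inherits(ds, "mr_dataset"))
  effects_model <- match.arg(effects_model)
  .need_pairs(ds, if (effects_model == "fixed") 1L else 2L, "IVW")
  p <- .ratio_parts(ds)
  k <- nrow(ds)
  est <- sum(p$w * p$r) / sum(p$w)
  se_fixed <- 1 / sqrt(sum(p$w))
  if (effects_model == "fixed") {
    return(pooled_row("ivw_fixed", k, est, se_fixed))
  }
  q <- sum(p$w * (p$r - est)^2)
  se <- se_fixed * max(1, sqrt(q / (k - 1)))
  # the dispersion multiplier is estimated from k - 1 residual degrees of
  # freedom, so t rather than normal inference keeps the test calibrated
  pooled_row("ivw_random", k, est, se, df = k - 1L)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with a free intercept, each pair first oriented so the exposure effect is
#' positive. The slope estimates the causal effect even when every
#' instrument is pleiotropic, provided pleiotropic effects are independent
#' of instrument strength (InSIDE); the intercept estimates the average
#' directional pleiotropy per SNP. Weights are `1/se_outcome^2`; standard
#' errors are inflated by `max(1, residual scale)` so under-dispersion never
#' shrinks them, and p-values use a t distribution with k − 2 degrees of
#' freedom.
#'
#' @param ds An [mr_dataset()] with at least 3 SNPs.
#' @return An object of class `mr_egger_fit`: list with `slope` (pooled-result
#'   row, method `"egger"`), `intercept` (data frame with `estimate`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`), `n_snps`, and `residual_scale`.
#' @export
mr_egger <- function(ds) {
  stopifnot(inherits(ds, "mr_dataset"))
  .need_pairs(ds, 3L, "MR-Egger")
  sgn <- ifelse(ds$beta_exposure < 0, -1, 1)
  bx <- ds$beta_exposure * sgn
  bo <- ds$beta_outcome * sgn
  if (length(unique(bx)) < 2L)
    stop("MR-Egger requires variation in the exposure effect sizes")
  w <- 1 / ds$se_outcome^2
  fit <- lm(bo ~ bx, weights = w)
  sm <- summary(fit)
  k <- nrow(ds)
  # lm's coefficient SEs are scaled by the residual standard deviation;
  # rescale so the multiplier is floored at 1
  infl <- max(1, sm$sigma) / sm$sigma
  slope <- sm$coefficients["bx", "Estimate"]
  slope_se <- sm$coefficients["bx", "Std. Error"] * infl
  int <- sm$coefficients["(Intercept)", "Estimate"]
  int_se <- sm$coefficients["(Intercept)", "Std. Error"] * infl
  out <- list(
    slope = pooled_row("egger", k, slope, slope_se, df = k - 2L),
    intercept = data.frame(
      estimate = int, se = int_se,
      ci_low = int - .z95 * int_se, ci_high = int + .z95 * int_se,
      pvalue = 2 * pt(-abs(int / int_se), k - 2L)),
    n_snps = k, residual_scale = sm$sigma)
  class(out) <- "mr_egger_fit"
  out
}

#' @export
print.mr_egger_fit <- function(x, ...) {
  cat(sprintf("MR-Egger regression on %d SNPs\n", x$n_snps))
  cat(sprintf("  slope:     OR %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$slope$or, x$slope$or_ci_low, x$slope$or_ci_high,
              x$slope$pvalue))
  cat(sprintf("  intercept: %.4f (SE %.4f), p = %.3g\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue))
  invisible(x)
}

# one weighted-median evaluation on ratio/weight vectors
.weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

# parametric bootstrap SE of an estimator point function
.boot_se <- function(ds, n_boot, seed, point_fun) {
  if (n_boot < 100)
    warning("n_boot < 100 gives an unstable bootstrap standard error")
  with_seed(seed, {
    k <- nrow(ds)
    reps <- vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(k, ds$beta_exposure, ds$se_exposure)
      bo <- rnorm(k, ds$beta_outcome, ds$se_outcome)
      point_fun(bx, bo, ds$se_outcome)
    }, numeric(1))
    sd(reps)
  })
}

#' Weighted-median causal estimate
#'
#' The 50% quantile of the per-SNP Wald ratios under normalized cumulative
#' weights (midpoint convention, linear interpolation). Consistent as long
#' as valid instruments contribute at least half the total weight. The
#' standard error comes from a seeded parametric bootstrap that redraws each
#' SNP's exposure and outcome effects from normal distributions centred on
#' the observed values.
#'
#' @param ds An [mr_dataset()] with at least 3 SNPs.
#' @param weighting `"inverse_variance"` (default; weights
#'   `beta_exposure^2 / se_outcome^2`) or `"equal"`.
#' @param n_boot Bootstrap resamples (default 1000; fewer than 100 triggers
#'   a warning).
#' @param seed Integer seed for the bootstrap (required for
#'   reproducibility). Applied after a canonical sort of the SNPs, so the
#'   result does not depend on input order.
#' @return A one-row pooled-result data frame (method
#'   `"weighted_median"`).
#' @export
mr_weighted_median <- function(ds, weighting = c("inverse_variance", "equal"),
                               n_boot = 1000, seed) {
  stopifnot(inherits(ds, "mr_dataset"))
  weighting <- match.arg(weighting)
  .need_pairs(ds, 3L, "weighted median")
  if (missing(seed)) stop("a bootstrap seed is required")
  ds <- .sort_ds(ds)
  wt <- function(bx, so) {
    if (weighting == "equal") rep(1, length(bx)) else bx^2 / so^2
  }
  p <- .ratio_parts(ds)
  est <- .weighted_median(p$r, wt(ds$beta_exposure, ds$se_outcome))
  se <- .boot_se(ds, n_boot, seed,
                 function(bx, bo, so) .weighted_median(bo / bx, wt(bx, so)))
  pooled_row("weighted_median", nrow(ds), est, se)
}

# one mode-based evaluation; grid maximizer of a kernel-smoothed ratio
# density, ties resolved toward the smallest magnitude
.mode_point <- function(r, se_r, phi, weighted, grid_n) {
  k <- length(r)
  h <- phi * 0.9 * min(sd(r), mad(r)) * k^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    if (length(unique(r)) == 1L) return(r[1])
    h <- phi * 0.9 * sd(r) * k^(-1 / 5)  # MAD degenerate but ratios differ
  }
  kw <- if (weighted) 1 / se_r^2 else rep(1, k)
  grid <- seq(min(r), max(r), length.out = grid_n)
  dens <- vapply(grid, function(g) sum(kw * dnorm((g - r) / h)), numeric(1))
  cand <- grid[dens == max(dens)]
  cand[which.min(abs(cand))]
}

#' Mode-based causal estimate
#'
#' The maximizer of a normal-kernel-smoothed density of the per-SNP Wald
#' ratios: SNPs with similar ratios form clusters, and the estimate follows
#' the largest cluster, so it is consistent when the biggest group of
#' instruments is valid even if most instruments are not. Bandwidth is
#' `phi * 0.9 * min(sd, mad) * k^(-1/5)` over the ratios (`mad` is the
#' normal-consistent median absolute deviation); the weighted variant
#' weights each kernel by the ratio's inverse variance. The maximizer is
#' located on a dense grid spanning the ratio range, with ties broken
#' toward the value of smallest magnitude. If all ratios coincide the
#' common ratio is returned with the fixed-effects IVW standard error.
#'
#' @param ds An [mr_dataset()] with at least 3 SNPs.
#' @param phi Bandwidth multiplier (default 1).
#' @param weighted Weight kernels by inverse ratio variance
#'   (default `TRUE`).
#' @param n_boot,seed Parametric bootstrap settings as in
#'   [mr_weighted_median()].
#' @param grid_n Grid resolution for the density maximizer (default 512).
#' @return A one-row pooled-result data frame (method `"mode_based"`).
#' @export
mr_mode <- function(ds, phi = 1, weighted = TRUE, n_boot = 1000, seed,
                    grid_n = 512) {
  stopifnot(inherits(ds, "mr_dataset"))
  .need_pairs(ds, 3L, "mode-based estimator")
  if (missing(seed)) stop("a bootstrap seed is required")
  ds <- .sort_ds(ds)
  p <- .ratio_parts(ds)
  if (length(unique(p$r)) == 1L) {
    se <- 1 / sqrt(sum(p$w))  # IVW fixed-effects SE for the degenerate case
    return(pooled_row("mode_based", nrow(ds), p$r[1], se))
  }
  est <- .mode_point(p$r, p$se_r, phi, weighted, grid_n)
  se <- .boot_se(ds, n_boot, seed, function(bx, bo, so)
    .mode_point(bo / bx, so / abs(bx), phi, weighted, grid_n))
  pooled_row("mode_based", nrow(ds), est, se)
}
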