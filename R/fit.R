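#' Fit two-sample Mendelian randomization models
#'
#' The central fitting function: runs the requested causal estimators on a
#' harmonized dataset and collects pooled results, the MR-Egger pleiotropy
#' intercept, and Cochran's Q heterogeneity into a single model object.
#'
#' @param ds An [mr_dataset()].
#' @param methods Estimators to run; any of `"ivw_fixed"`, `"ivw_random"`,
#'   `"egger"`, `"weighted_median"`, `"mode_based"`.
#' @param weighting Weighting for the median estimator (see
#'   [mr_weighted_median()]).
#' @param phi Bandwidth multiplier for the mode-based estimator.
#' @param n_boot Bootstrap resamples for median/mode standard errors.
#' @param seed Integer bootstrap seed; required whenever a bootstrap
#'   estimator is requested.
#' @return An object of class `mr_fit`: list with `results` (one
#'   pooled-result row per method), `egger_intercept`, `heterogeneity`
#'   (a [cochran_q()] result when k >= 2), `snp_estimates` (per-SNP Wald
#'   ratios), `dataset`, and `call`. Methods: `print`, `summary`, `coef`,
#'   `confint`, `plot`.
#' @examples
#' fit <- mr_fit(ua_ms_snps()$dataset, seed = 1)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(ds,
                   methods = c("ivw_fixed", "ivw_random", "egger",
                               "weighted_median", "mode_based"),
                   weighting = "inverse_variance", phi = 1,
                   n_boot = 1000, seed = NULL) {
  stopifnot(inherits(ds, "mr_dataset"))
  methods <- match.arg(methods, several.ok = TRUE)
  needs_boot <- any(c("weighted_median", "mode_based") %in% methods)
  if (needs_boot && is.null(seed))
    stop("a bootstrap seed is required for the median/mode estimators")

  rows <- list()
  egger_intercept <- NULL
  for (m in methods) {
    rows[[m]] <- switch(m,
      ivw_fixed = mr_ivw(ds, "fixed"),
      ivw_random = mr_ivw(ds, "multiplicative_random"),
      egger = {
        eg <- mr_egger(ds)
        egger_intercept <- eg$intercept
        eg$slope
      },
      weighted_median = mr_weighted_median(ds, weighting = weighting,
                                           n_boot = n_boot, seed = seed),
      mode_based = mr_mode(ds, phi = phi, n_boot = n_boot, seed = seed))
  }

  out <- list(
    results = do.call(rbind, c(rows, list(make.row.names = FALSE))),
    egger_intercept = egger_intercept,
    heterogeneity = if (nrow(ds) >= 2) cochran_q(ds) else NULL,
    snp_estimates = wald_ratio(ds),
    dataset = ds,
    n_boot = n_boot, seed = seed,
    call = match.call())
  class(out) <- "mr_fit"
  out
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample MR fit: %d SNP(s), %d method(s)\n\n",
              nrow(x$dataset), nrow(x$results)))
  tab <- x$results
  disp <- data.frame(method = tab$method, n_snps = tab$n_snps,
                     OR = round(tab$or, digits),
                     ci_low = round(tab$or_ci_low, digits),
                     ci_high = round(tab$or_ci_high, digits),
                     p = signif(tab$pvalue, digits))
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(object, class = c("summary.mr_fit", "mr_fit"))
}

#' @export
print.summary.mr_fit <- function(x, digits = 3, ...) {
  print.mr_fit(x, digits = digits, ...)
  if (!is.null(x$egger_intercept))
    cat(sprintf("\nEgger intercept: %.4f (SE %.4f), p = %.3g\n",
                x$egger_intercept$estimate, x$egger_intercept$se,
                x$egger_intercept$pvalue))
  if (!is.null(x$heterogeneity))
    cat(sprintf("Cochran's Q = %.2f on %d df, p = %.3g\n",
                x$heterogeneity$q, x$heterogeneity$df,
                x$heterogeneity$pvalue))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  setNames(object$results$estimate, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  tab <- object$results
  if (!missing(parm)) tab <- tab[tab$method %in% parm, , drop = FALSE]
  if (identical(level, 0.95)) {
    out <- cbind(tab$ci_low, tab$ci_high)  # as stored (t- or normal-based)
  } else {
    # each method's stored CI fixes its 0.975 quantile; rescale it
    q <- (tab$ci_high - tab$estimate) / (tab$se * .z95)
    z <- qnorm((1 + level) / 2) * q
    out <- cbind(tab$estimate - z * tab$se, tab$estimate + z * tab$se)
  }
  dimnames(out) <- list(tab$method,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             (1 + level) / 2) * 100))
  out
}

#' @export
plot.mr_fit <- function(x, ...) {
  ds <- x$dataset
  sgn <- ifelse(ds$beta_exposure < 0, -1, 1)
  bx <- ds$beta_exposure * sgn
  bo <- ds$beta_outcome * sgn
  graphics::plot(bx, bo,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome (log odds)",
                 pch = 19, ...)
  graphics::segments(bx, bo - .z95 * ds$se_outcome,
                     bx, bo + .z95 * ds$se_outcome, col = "grey60")
  graphics::segments(bx - .z95 * ds$se_exposure, bo,
                     bx + .z95 * ds$se_exposure, bo, col = "grey60")
  tab <- x$results
  cols <- setNames(seq_len(nrow(tab)) + 1L, tab$method)
  for (m in tab$method) {
    icpt <- if (m == "egger" && !is.null(x$egger_intercept))
      x$egger_intercept$estimate else 0
    graphics::abline(icpt, tab$estimate[tab$method == m], col = cols[[m]])
  }
  graphics::legend("topleft", legend = tab$method, col = cols, lty = 1,
                   bty = "n", cex = 0.8)
  invisible(x)
}
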