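#' Simulate two-sample GWAS summary statistics with known causal truth
#'
#' Generates per-SNP exposure and outcome association tables the way a
#' two-sample design produces them: true instrument effects on the exposure
#' are drawn once, the true outcome effect of each SNP is
#' `theta * beta_exposure` plus an optional horizontal-pleiotropy term, and
#' the observed effects add independent normal estimation noise with the
#' stated standard errors in each of the two (non-overlapping) samples.
#' Pleiotropy modes: `"none"`; `"balanced"` (mean-zero normal direct
#' effects); `"directional"` (nonzero-mean normal, independent of
#' instrument strength, so InSIDE holds); `"inside_violating"` (direct
#' effects proportional to the standardized instrument strength, breaking
#' InSIDE). Defaults mirror the bundled serum-urate instrument panel:
#' 18 SNPs with per-allele exposure effects between 0.03 and 0.37,
#' exposure SE 0.006 and outcome SE 0.02.
#'
#' @param theta True causal effect (outcome log-odds per exposure unit;
#'   default 0).
#' @param k Number of SNPs (default 18).
#' @param beta_exposure Either a length-2 range to draw true exposure
#'   effects uniformly from, or a length-k vector of fixed true effects.
#' @param eaf_range Range for uniform effect-allele frequencies.
#' @param se_exposure,se_outcome Per-SNP standard errors, recycled to
#'   length k.
#' @param pleiotropy One of `"none"`, `"balanced"`, `"directional"`,
#'   `"inside_violating"`.
#' @param pleiotropy_mean Mean per-SNP direct effect for the directional
#'   and InSIDE-violating modes (log-odds; default 0.05).
#' @param pleiotropy_sd SD of per-SNP direct effects (default 0.02).
#' @param invalid_fraction Share of SNPs receiving a pleiotropic direct
#'   effect (default 1 when `pleiotropy != "none"`).
#' @param n_exposure,n_outcome Nominal GWAS sample sizes recorded in the
#'   tables.
#' @param seed Integer seed; identical inputs give byte-identical outputs.
#' @return List with `exposure` (continuous-trait association table),
#'   `outcome` (binary-trait table carrying `or`/`ci_low`/`ci_high`),
#'   and `truth` (list recording every generative parameter plus the true
#'   per-SNP effects and pleiotropy terms).
#' @export
simulate_two_sample <- function(theta = 0, k = 18,
                                beta_exposure = c(0.03, 0.37),
                                eaf_range = c(0.1, 0.9),
                                se_exposure = 0.006, se_outcome = 0.02,
                                pleiotropy = c("none", "balanced",
                                               "directional",
                                               "inside_violating"),
                                pleiotropy_mean = 0.05,
                                pleiotropy_sd = 0.02,
                                invalid_fraction = 1,
                                n_exposure = 110347, n_outcome = 38589,
                                seed) {
  pleiotropy <- match.arg(pleiotropy)
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  stopifnot(k >= 1, invalid_fraction >= 0, invalid_fraction <= 1,
            all(se_exposure >= 0), all(se_outcome >= 0))
  se_x <- rep_len(se_exposure, k)
  se_y <- rep_len(se_outcome, k)

  with_seed(seed, {
    bx_true <- if (length(beta_exposure) == k && k != 2) beta_exposure
               else if (length(beta_exposure) == 2)
                 runif(k, beta_exposure[1], beta_exposure[2])
               else rep_len(beta_exposure, k)
    eaf <- runif(k, eaf_range[1], eaf_range[2])

    alpha <- rep(0, k)
    if (pleiotropy != "none") {
      n_invalid <- round(invalid_fraction * k)
      idx <- if (n_invalid >= 1) sample.int(k, n_invalid) else integer(0)
      alpha[idx] <- switch(pleiotropy,
        balanced = rnorm(length(idx), 0, pleiotropy_sd),
        directional = rnorm(length(idx), pleiotropy_mean, pleiotropy_sd),
        inside_violating = {
          z <- (bx_true[idx] - mean(bx_true)) / max(sd(bx_true), 1e-12)
          pleiotropy_mean + pleiotropy_sd * z
        })
    }
    bo_true <- theta * bx_true + alpha

    bx_obs <- bx_true + rnorm(k, 0, se_x)
    bo_obs <- bo_true + rnorm(k, 0, se_y)

    rsid <- sprintf("snp%04d", seq_len(k))
    exposure <- data.frame(
      rsid = rsid, chrom = rep(1L, k),
      effect_allele = rep("A", k), other_allele = rep("G", k),
      eaf = eaf, beta = bx_obs, se = se_x,
      pvalue = 2 * pnorm(-abs(bx_obs / pmax(se_x, 1e-300))),
      n = n_exposure, source = "sim_exposure",
      stringsAsFactors = FALSE)
    outcome <- data.frame(
      rsid = rsid, chrom = rep(1L, k),
      effect_allele = rep("A", k), other_allele = rep("G", k),
      eaf = eaf,
      or = exp(bo_obs),
      ci_low = exp(bo_obs - .z95 * se_y),
      ci_high = exp(bo_obs + .z95 * se_y),
      pvalue = 2 * pnorm(-abs(bo_obs / pmax(se_y, 1e-300))),
      n = n_outcome, source = "sim_outcome",
      stringsAsFactors = FALSE)
    if (any(se_y == 0)) {  # noise-free limit: CI conversion needs se > 0
      outcome$beta <- bo_obs
      outcome$se <- se_y
    }
    truth <- list(theta = theta, k = k, beta_exposure_true = bx_true,
                  pleiotropy = pleiotropy, alpha = alpha,
                  eaf = eaf, se_exposure = se_x, se_outcome = se_y,
                  invalid_fraction = invalid_fraction, seed = seed)
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Harmonized dataset straight from a simulation
#'
#' Convenience wrapper: simulate with [simulate_two_sample()] and return
#' the harmonized [mr_dataset()] alongside the generative truth.
#'
#' @param ... Passed to [simulate_two_sample()].
#' @return List with `dataset` (an `mr_dataset`) and `truth`.
#' @export
simulate_dataset <- function(...) {
  sim <- simulate_two_sample(...)
  noise_free <- "beta" %in% names(sim$outcome) && any(sim$outcome$se == 0)
  if (noise_free) {
    ds <- mr_dataset(rsid = sim$exposure$rsid,
                     beta_exposure = sim$exposure$beta,
                     se_exposure = pmax(sim$exposure$se, 1e-300),
                     beta_outcome = sim$outcome$beta,
                     se_outcome = pmax(sim$outcome$se, 1e-300),
                     eaf = sim$exposure$eaf,
                     effect_allele = sim$exposure$effect_allele,
                     other_allele = sim$exposure$other_allele,
                     source = sim$outcome$source)
  } else {
    ds <- harmonize(as_association_table(sim$exposure, "continuous"),
                    as_association_table(sim$outcome, "binary"))
  }
  list(dataset = ds, truth = sim$truth)
}

#' Simulate an LD panel with proxy candidates
#'
#' Builds a block-diagonal LD structure: `k_targets` target SNPs, each with
#' `k_proxies_per_target` candidate proxies at the r² values in
#' `r2_levels` (recycled across candidates), and zero LD across blocks.
#' Also emits a binary-trait outcome association table containing only the
#' proxy candidates, so that [substitute_proxies()] and [prune_ld()] can be
#' exercised end to end.
#'
#' @param k_targets Number of target SNPs.
#' @param k_proxies_per_target Candidate proxies per target (default 1).
#' @param r2_levels r² values linking each candidate to its target.
#' @param seed Integer seed.
#' @return List with `ld` (an [ld_table()]), `targets` (exposure-style
#'   association table of the targets), and `panel` (outcome association
#'   table holding the proxy candidates).
#' @export
simulate_ld_panel <- function(k_targets, k_proxies_per_target = 1,
                              r2_levels = 0.9, seed) {
  if (missing(seed)) stop("a seed is required for reproducible simulation")
  stopifnot(k_targets >= 1, k_proxies_per_target >= 1)
  with_seed(seed, {
    tgt <- sprintf("tgt%03d", seq_len(k_targets))
    rows <- list(); cand_rows <- list()
    for (i in seq_len(k_targets)) {
      for (j in seq_len(k_proxies_per_target)) {
        px <- sprintf("%s_px%02d", tgt[i], j)
        r2 <- rep_len(r2_levels, k_proxies_per_target)[j]
        rows[[length(rows) + 1L]] <- data.frame(
          rsid_a = tgt[i], rsid_b = px, r2 = r2,
          stringsAsFactors = FALSE)
        b <- rnorm(1, 0, 0.05)
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          rsid = px, chrom = i, effect_allele = "A", other_allele = "G",
          eaf = runif(1, 0.1, 0.9),
          or = exp(b), ci_low = exp(b - .z95 * 0.02),
          ci_high = exp(b + .z95 * 0.02),
          pvalue = 2 * pnorm(-abs(b / 0.02)), n = 38589,
          source = "sim_panel", stringsAsFactors = FALSE)
      }
    }
    ldf <- do.call(rbind, rows)
    targets <- data.frame(
      rsid = tgt, chrom = seq_len(k_targets),
      effect_allele = "A", other_allele = "G",
      eaf = runif(k_targets, 0.1, 0.9),
      beta = runif(k_targets, 0.03, 0.37), se = 0.006,
      pvalue = 1e-10, n = 110347, source = "sim_exposure",
      stringsAsFactors = FALSE)
    list(ld = ld_table(ldf$rsid_a, ldf$rsid_b, ldf$r2),
         targets = as_association_table(targets, "continuous"),
         panel = as_association_table(do.call(rbind, cand_rows), "binary"))
  })
}
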