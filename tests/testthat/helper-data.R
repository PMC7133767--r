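# quick harmonized dataset from effect vectors (alleles A/G throughout)
make_ds <- function(bx, bo, so, sx = rep(0.006, length(bx)),
                    rsid = sprintf("snp%04d", seq_along(bx)), ...) {
  mr_dataset(rsid = rsid, beta_exposure = bx, se_exposure = sx,
             beta_outcome = bo, se_outcome = so,
             effect_allele = "A", other_allele = "G", ...)
}

# random dataset with positive weights for property-style checks
random_ds <- function(seed, k = 12) {
  set.seed(seed)
  make_ds(bx = runif(k, 0.05, 0.4) * sample(c(-1, 1), k, replace = TRUE),
          bo = rnorm(k, 0, 0.05),
          so = runif(k, 0.01, 0.05),
          sx = runif(k, 0.004, 0.01))
}

# mr_dataset straight from simulate_two_sample() output, exercising the
# OR/CI -> log-scale conversion
sim_to_ds <- function(sim) {
  out <- sim$outcome
  if ("beta" %in% names(out)) {
    bo <- out$beta; so <- pmax(out$se, 1e-300)
  } else {
    bo <- log(out$or)
    so <- ci_to_log_se(out$or, out$ci_low, out$ci_high)
  }
  make_ds(bx = sim$exposure$beta, bo = bo, so = so,
          sx = pmax(sim$exposure$se, 1e-300), rsid = sim$exposure$rsid,
          eaf = sim$exposure$eaf)
}

# random exposure/outcome association-table pair with mixed allele
# orientations and strand flips, for harmonization property tests
random_tables <- function(seed, k = 10) {
  set.seed(seed)
  pairs <- list(c("A", "G"), c("T", "C"), c("A", "C"), c("T", "G"))
  al <- pairs[sample.int(4, k, replace = TRUE)]
  ea <- vapply(al, `[`, "", 1); oa <- vapply(al, `[`, "", 2)
  exposure <- data.frame(
    rsid = sprintf("rs%04d", seq_len(k)), chrom = 1,
    effect_allele = ea, other_allele = oa,
    eaf = runif(k, 0.05, 0.95), beta = rnorm(k, 0, 0.1),
    se = runif(k, 0.004, 0.01), pvalue = runif(k, 1e-30, 1e-8), n = 1e5,
    stringsAsFactors = FALSE)
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  swap <- sample(c(TRUE, FALSE), k, replace = TRUE)
  strand <- sample(c(TRUE, FALSE), k, replace = TRUE)
  ea_o <- ifelse(swap, oa, ea); oa_o <- ifelse(swap, ea, oa)
  ea_o <- ifelse(strand, comp[ea_o], ea_o)
  oa_o <- ifelse(strand, comp[oa_o], oa_o)
  bo <- rnorm(k, 0, 0.05)
  outcome <- data.frame(
    rsid = exposure$rsid, chrom = 1,
    effect_allele = ea_o, other_allele = oa_o,
    eaf = ifelse(swap, 1 - exposure$eaf, exposure$eaf),
    beta = ifelse(swap, -bo, bo),
    se = runif(k, 0.01, 0.04), pvalue = runif(k), n = 4e4,
    stringsAsFactors = FALSE)
  list(exposure = as_association_table(exposure, "continuous"),
       outcome = as_association_table(outcome, "binary"),
       beta_outcome_aligned = bo)
}
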