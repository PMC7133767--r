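#' The serum-urate / multiple-sclerosis instrument panel
#'
#' Returns the published panel of 18 genome-wide significant serum-urate
#' SNPs (per-allele effects in mg/dl from a urate GWAS meta-analysis of
#' 110,347 Europeans) together with their multiple-sclerosis associations
#' (odds ratios with 95% CIs from two MS case-control GWAS: an ImmunoChip
#' study of 38,589 individuals and an earlier GWAS of 27,148). Nine of the
#' outcome associations come from proxy variants in high LD with the
#' target (three on the ImmunoChip side, six on the other); their effects
#' are stored already aligned to the target's effect allele. Outcome CIs
#' are converted to log-odds standard errors at load time via
#' [ci_to_log_se()], so the returned object is byte-stable across calls.
#'
#' @return List with `exposure` (continuous association table),
#'   `outcome` (binary association table), and `dataset` (the harmonized
#'   [mr_dataset()] of all 18 SNPs).
#' @examples
#' panel <- ua_ms_snps()
#' nrow(panel$dataset)           # 18
#' sum(!is.na(panel$dataset$proxy_rsid))  # 9
#' @export
ua_ms_snps <- function() {
  path <- function(f) system.file("extdata", f, package = "mr2s",
                                  mustWork = TRUE)
  exposure <- read_association_table(path("ua_ms_exposure.tsv"),
                                     "continuous")
  outcome <- read_association_table(path("ua_ms_outcome.tsv"), "binary")
  list(exposure = exposure, outcome = outcome,
       dataset = harmonize(exposure, outcome))
}
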