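.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) unname(.complement[ea] == oa)

#' Construct a harmonized two-sample MR dataset
#'
#' Low-level constructor for the container used by every estimator: one row
#' per SNP carrying exposure and outcome effects expressed on the same
#' effect allele. Most users obtain one from [harmonize()] or
#' [ua_ms_snps()]; this constructor is useful for simulations and tests.
#'
#' @param rsid Character vector of SNP identifiers, unique.
#' @param beta_exposure,se_exposure Per-allele effect on the exposure and
#'   its standard error (exposure units, e.g. mg/dl).
#' @param beta_outcome,se_outcome Per-allele effect on the outcome and its
#'   standard error (log-odds for a binary outcome), on the same effect
#'   allele as the exposure effect.
#' @param eaf Effect-allele frequency (optional).
#' @param effect_allele,other_allele Allele labels (optional).
#' @param proxy_rsid,proxy_r2 Outcome-side proxy annotation (optional).
#' @param source Outcome study tag (optional).
#' @param flipped Whether the outcome record was reoriented during
#'   harmonization.
#' @param audit Per-input-SNP disposition record (data frame with columns
#'   `rsid`, `disposition`); attached as an attribute.
#' @return An object of class `mr_dataset` (a data frame).
#' @export
mr_dataset <- function(rsid, beta_exposure, se_exposure, beta_outcome,
                       se_outcome, eaf = NA_real_,
                       effect_allele = NA_character_,
                       other_allele = NA_character_,
                       proxy_rsid = NA_character_, proxy_r2 = NA_real_,
                       source = NA_character_, flipped = FALSE,
                       audit = NULL) {
  pairs <- data.frame(
    rsid = as.character(rsid),
    effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf,
    beta_exposure = beta_exposure, se_exposure = se_exposure,
    beta_outcome = beta_outcome, se_outcome = se_outcome,
    proxy_rsid = proxy_rsid, proxy_r2 = proxy_r2,
    source = source, flipped = flipped,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(pairs$rsid))
    stop("duplicate rsid in harmonized dataset: ",
         paste(unique(pairs$rsid[duplicated(pairs$rsid)]), collapse = ", "))
  if (any(pairs$se_exposure <= 0) || any(pairs$se_outcome <= 0))
    stop("standard errors must be strictly positive")
  if (is.null(audit))
    audit <- data.frame(rsid = pairs$rsid, disposition = "kept",
                        stringsAsFactors = FALSE)
  structure(pairs, audit = audit, class = c("mr_dataset", "data.frame"))
}

#' @export
print.mr_dataset <- function(x, ...) {
  audit <- attr(x, "audit")
  cat(sprintf("Harmonized two-sample MR dataset: %d SNP(s)\n", nrow(x)))
  if (!is.null(audit)) {
    tab <- table(audit$disposition)
    cat("  dispositions:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
  }
  print(as.data.frame(x), ...)
  invisible(x)
}

# subset a dataset by a logical/index vector, keeping class and trimming audit
subset_dataset <- function(ds, idx) {
  out <- as.data.frame(ds)[idx, , drop = FALSE]
  rownames(out) <- NULL
  audit <- attr(ds, "audit")
  if (!is.null(audit)) audit <- audit[audit$rsid %in% out$rsid, , drop = FALSE]
  structure(out, audit = audit, class = c("mr_dataset", "data.frame"))
}

#' Harmonize exposure and outcome association tables
#'
#' Aligns each outcome record onto the exposure's effect allele. Records
#' matching with identical allele pairs are kept as-is; records with the
#' allele pair in swapped orientation have their outcome beta negated and
#' allele frequency complemented; allele pairs matching only after strand
#' complementation are complemented first. Palindromic SNPs (A/T or G/C)
#' whose minor-allele frequency is within `palindrome_eaf_window` of 0.5
#' are strand-ambiguous and dropped when `drop_palindromic` is set;
#' irreconcilable allele pairs are dropped as incompatible. Every input
#' exposure SNP receives exactly one disposition in the audit record:
#' `kept`, `flipped`, `proxied`, `palindromic-dropped`,
#' `incompatible-dropped`, or `missing-outcome`.
#'
#' @param exposure,outcome Association data frames (see
#'   [as_association_table()]); outcome rows may carry `proxy_rsid` /
#'   `proxy_r2` annotations, in which case the disposition is `proxied`.
#' @param palindrome_eaf_window Half-width of the ambiguous frequency zone
#'   around 0.5 (default 0.08, i.e. EAF in \[0.42, 0.58\] is ambiguous).
#' @param drop_palindromic Drop strand-ambiguous palindromic SNPs
#'   (default `TRUE`).
#' @return An [mr_dataset()] with an `audit` attribute.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                      drop_palindromic = TRUE) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  if (anyDuplicated(exposure$rsid))
    stop("duplicate rsid in exposure table: ",
         paste(unique(exposure$rsid[duplicated(exposure$rsid)]), collapse = ", "))
  if (anyDuplicated(outcome$rsid))
    stop("duplicate rsid in outcome table: ",
         paste(unique(outcome$rsid[duplicated(outcome$rsid)]), collapse = ", "))

  n <- nrow(exposure)
  disposition <- character(n)
  keep_row <- vector("list", n)

  for (i in seq_len(n)) {
    ex <- exposure[i, ]
    j <- match(ex$rsid, outcome$rsid)
    if (is.na(j)) {
      disposition[i] <- "missing-outcome"
      next
    }
    out <- outcome[j, ]
    ea_x <- ex$effect_allele; oa_x <- ex$other_allele
    ea_y <- out$effect_allele; oa_y <- out$other_allele

    pal <- .is_palindromic(ea_x, oa_x)
    if (pal && drop_palindromic) {
      f <- if (!is.na(ex$eaf)) ex$eaf else out$eaf
      if (!is.na(f) && min(f, 1 - f) >= 0.5 - palindrome_eaf_window) {
        disposition[i] <- "palindromic-dropped"
        next
      }
    }

    flipped <- FALSE
    if (ea_y == ea_x && oa_y == oa_x) {
      beta_o <- out$beta
      eaf_o <- out$eaf
    } else if (ea_y == oa_x && oa_y == ea_x) {
      beta_o <- -out$beta
      eaf_o <- 1 - out$eaf
      flipped <- TRUE
    } else if (!pal && identical(unname(.complement[ea_y]), ea_x) &&
               identical(unname(.complement[oa_y]), oa_x)) {
      beta_o <- out$beta
      eaf_o <- out$eaf
    } else if (!pal && identical(unname(.complement[ea_y]), oa_x) &&
               identical(unname(.complement[oa_y]), ea_x)) {
      beta_o <- -out$beta
      eaf_o <- 1 - out$eaf
      flipped <- TRUE
    } else {
      disposition[i] <- "incompatible-dropped"
      next
    }

    proxied <- !is.na(out$proxy_rsid)
    disposition[i] <- if (proxied) "proxied" else if (flipped) "flipped" else "kept"
    keep_row[[i]] <- data.frame(
      rsid = ex$rsid,
      effect_allele = ea_x, other_allele = oa_x,
      eaf = if (!is.na(ex$eaf)) ex$eaf else eaf_o,
      beta_exposure = ex$beta, se_exposure = ex$se,
      beta_outcome = beta_o, se_outcome = out$se,
      proxy_rsid = if (proxied) out$proxy_rsid else NA_character_,
      proxy_r2 = if (proxied) out$proxy_r2 else NA_real_,
      source = out$source, flipped = flipped,
      stringsAsFactors = FALSE
    )
  }

  audit <- data.frame(rsid = exposure$rsid, disposition = disposition,
                      stringsAsFactors = FALSE)
  kept <- do.call(rbind, keep_row[!vapply(keep_row, is.null, logical(1))])
  if (is.null(kept))
    kept <- data.frame(rsid = character(0), effect_allele = character(0),
                       other_allele = character(0), eaf = numeric(0),
                       beta_exposure = numeric(0), se_exposure = numeric(0),
                       beta_outcome = numeric(0), se_outcome = numeric(0),
                       proxy_rsid = character(0), proxy_r2 = numeric(0),
                       source = character(0), flipped = logical(0),
                       stringsAsFactors = FALSE)
  rownames(kept) <- NULL
  structure(kept, audit = audit, class = c("mr_dataset", "data.frame"))
}

#' Recover the two association tables of a harmonized dataset
#'
#' Splits an [mr_dataset()] back into exposure-side and outcome-side
#' association tables on the shared effect allele (used e.g. to check that
#' harmonization is idempotent).
#'
#' @param ds An `mr_dataset`.
#' @return List with elements `exposure` and `outcome`.
#' @export
dataset_tables <- function(ds) {
  stopifnot(inherits(ds, "mr_dataset"))
  base <- data.frame(rsid = ds$rsid, chrom = NA, effect_allele = ds$effect_allele,
                     other_allele = ds$other_allele, eaf = ds$eaf,
                     pvalue = NA, n = NA, source = NA,
                     proxy_rsid = NA_character_, proxy_r2 = NA_real_,
                     stringsAsFactors = FALSE)
  exposure <- cbind(base, beta = ds$beta_exposure, se = ds$se_exposure)
  outcome <- cbind(base, beta = ds$beta_outcome, se = ds$se_outcome)
  outcome$proxy_rsid <- ds$proxy_rsid
  outcome$proxy_r2 <- ds$proxy_r2
  outcome$source <- ds$source
  list(exposure = as_association_table(exposure, "continuous"),
       outcome = as_association_table(outcome, "binary"))
}
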