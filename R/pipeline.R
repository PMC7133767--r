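#' Build a per-stage selection audit
#'
#' Reconciles instrument counts across the filtering stages of a run:
#' every input SNP must be accounted for as either analyzed or excluded at
#' a named stage.
#'
#' @param n_input Number of candidate instruments entering the pipeline.
#' @param excluded Named integer vector of exclusion counts per stage, in
#'   stage order (e.g. `c(ld_pruned = 7, unmatched = 13, palindromic = 9)`).
#' @param n_analyzed Optional expected count of analyzed SNPs; an error is
#'   raised if it does not equal `n_input - sum(excluded)`.
#' @return Data frame with columns `stage`, `n_in`, `n_excluded`, `n_out`;
#'   the final row is the `analyzed` stage. Attribute `n_analyzed` carries
#'   the final count.
#' @examples
#' selection_funnel(110, c(ld_pruned = 7, unmatched = 13, palindromic = 9))
#' @export
selection_funnel <- function(n_input, excluded = integer(0),
                             n_analyzed = NULL) {
  stopifnot(length(n_input) == 1, n_input >= 0)
  if (length(excluded) && is.null(names(excluded)))
    stop("excluded counts must be named by stage")
  if (any(excluded < 0)) stop("exclusion counts cannot be negative")
  kept <- n_input - sum(excluded)
  if (kept < 0)
    stop("counts do not reconcile: exclusions exceed the input count")
  if (!is.null(n_analyzed) && n_analyzed != kept)
    stop(sprintf(
      "counts do not reconcile: input %d - excluded %d != analyzed %d",
      n_input, sum(excluded), n_analyzed))
  n_in <- n_input - c(0, cumsum(excluded))
  out <- data.frame(
    stage = c(names(excluded), "analyzed"),
    n_in = n_in,
    n_excluded = c(as.integer(excluded), 0L),
    n_out = n_in - c(as.integer(excluded), 0L),
    stringsAsFactors = FALSE)
  attr(out, "n_analyzed") <- kept
  out
}

# fit + heterogeneity + Egger intercept on a subset, tolerating subsets
# too small to estimate
analyze_subset <- function(ds, label, effects_model, n_boot, seed, phi) {
  if (nrow(ds) < 3)
    return(list(label = label, estimable = FALSE, n_snps = nrow(ds),
                reason = "fewer than 3 instruments"))
  fit <- mr_fit(ds, n_boot = n_boot, seed = seed, phi = phi)
  list(label = label, estimable = TRUE, n_snps = nrow(ds),
       results = fit$results,
       egger_intercept = fit$egger_intercept,
       heterogeneity = fit$heterogeneity)
}

# read a config entry that may be an in-memory table or a file path
.load_assoc <- function(cfg, key, kind) {
  if (!is.null(cfg[[key]])) return(as_association_table(cfg[[key]], kind))
  path_key <- paste0(key, "_path")
  if (!is.null(cfg[[path_key]]))
    return(read_association_table(cfg[[path_key]], kind))
  NULL
}

.load_panels <- function(cfg, kind) {
  if (!is.null(cfg[["outcome"]])) {
    panels <- cfg[["outcome"]]
    if (is.data.frame(panels)) panels <- list(panels)
    return(lapply(panels, as_association_table, trait_kind = kind))
  }
  if (!is.null(cfg[["outcome_paths"]]))
    return(lapply(cfg[["outcome_paths"]], read_association_table,
                  trait_kind = kind))
  stop("config supplies no outcome table(s)")
}

run_direction <- function(direction, dcfg, cfg, ld) {
  exposure_kind <- if (direction == "forward") "continuous" else "binary"
  outcome_kind <- if (direction == "forward") "binary" else "continuous"
  exposure <- .load_assoc(dcfg, "exposure", exposure_kind)
  if (is.null(exposure)) stop("config supplies no exposure table")
  panels <- .load_panels(dcfg, outcome_kind)

  n_input <- nrow(exposure)
  excluded <- integer(0)

  if (!is.null(ld)) {
    kept <- prune_ld(exposure, ld, cfg$r2_prune)
    excluded["ld_pruned"] <- n_input - nrow(kept)
    exposure <- kept
  }

  # direct lookup through the panels in priority order, then proxy search
  panel_of <- vapply(exposure$rsid, function(rs) {
    hit <- which(vapply(panels, function(p) rs %in% p$rsid, logical(1)))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  outcome_rows <- list()
  for (i in which(!is.na(panel_of))) {
    row <- panels[[panel_of[i]]][panels[[panel_of[i]]]$rsid ==
                                   exposure$rsid[i], , drop = FALSE]
    outcome_rows[[length(outcome_rows) + 1L]] <- row
  }
  missing <- exposure[is.na(panel_of), , drop = FALSE]
  n_unmatched <- 0L
  if (nrow(missing)) {
    if (is.null(ld)) {
      n_unmatched <- nrow(missing)
    } else {
      prox <- substitute_proxies(missing, ld, panels, cfg$r2_proxy)
      for (i in seq_len(nrow(prox))) {
        if (is.na(prox$proxy_rsid[i])) next
        src <- panels[[prox$panel[i]]]
        row <- src[src$rsid == prox$proxy_rsid[i], , drop = FALSE]
        # proxy statistics stand in for the target; effects are taken as
        # pre-aligned to the target's effect allele via the LD reference
        tgt <- missing[missing$rsid == prox$rsid[i], , drop = FALSE]
        row$rsid <- prox$rsid[i]
        row$effect_allele <- tgt$effect_allele
        row$other_allele <- tgt$other_allele
        row$proxy_rsid <- prox$proxy_rsid[i]
        row$proxy_r2 <- prox$proxy_r2[i]
        outcome_rows[[length(outcome_rows) + 1L]] <- row
      }
      n_unmatched <- sum(is.na(prox$proxy_rsid))
    }
    excluded["unmatched"] <- n_unmatched
  }
  outcome <- if (length(outcome_rows))
    do.call(rbind, c(outcome_rows, list(make.row.names = FALSE)))
  else panels[[1]][0, , drop = FALSE]

  ds <- harmonize(exposure[exposure$rsid %in% outcome$rsid, , drop = FALSE],
                  outcome,
                  palindrome_eaf_window = cfg$palindrome_eaf_window,
                  drop_palindromic = cfg$drop_palindromic)
  audit <- attr(ds, "audit")
  n_pal <- sum(audit$disposition == "palindromic-dropped")
  n_inc <- sum(audit$disposition == "incompatible-dropped")
  if (n_pal) excluded["palindromic"] <- n_pal
  if (n_inc) excluded["incompatible"] <- n_inc
  funnel <- selection_funnel(n_input, excluded, n_analyzed = nrow(ds))

  units <- if (direction == "forward")
    "outcome log-odds per unit exposure"
  else "exposure units per unit outcome log-odds"

  if (nrow(ds) < 3)
    return(list(direction = direction, estimable = FALSE, units = units,
                n_snps = nrow(ds), dataset = ds, audit = audit,
                selection = funnel, reason = "fewer than 3 instruments"))

  fit <- mr_fit(ds, n_boot = cfg$n_boot, seed = cfg$seed, phi = cfg$phi)
  outliers <- flag_outliers(ds, alpha = cfg$outlier_alpha)
  sens <- sensitivity_tables(ds, fit$results, alpha = cfg$outlier_alpha)

  subsets <- list(
    all_snps = analyze_subset(ds, "all_snps", cfg$effects_model,
                              cfg$n_boot, cfg$seed, cfg$phi),
    proxy_excluded = analyze_subset(
      subset_dataset(ds, is.na(ds$proxy_rsid)), "proxy_excluded",
      cfg$effects_model, cfg$n_boot, cfg$seed, cfg$phi),
    outlier_excluded = analyze_subset(
      subset_dataset(ds, !ds$rsid %in% outliers), "outlier_excluded",
      cfg$effects_model, cfg$n_boot, cfg$seed, cfg$phi))
  for (src in sort(unique(ds$source[!is.na(ds$source)])))
    subsets[[paste0("source_", src)]] <- analyze_subset(
      subset_dataset(ds, !is.na(ds$source) & ds$source == src),
      paste0("source_", src), cfg$effects_model, cfg$n_boot, cfg$seed,
      cfg$phi)

  n_gwas <- dcfg$n_exposure
  if (is.null(n_gwas))
    n_gwas <- if (all(is.na(exposure$n))) NA_integer_
              else max(exposure$n, na.rm = TRUE)
  strength <- if (is.na(n_gwas) || !any(!is.na(ds$eaf))) NULL
              else instrument_strength(
                subset_dataset(ds, !is.na(ds$eaf)), n = n_gwas,
                pheno_sd = cfg$pheno_sd)

  power <- NULL
  pw <- cfg$power
  if (!is.null(pw)) {
    r2 <- if (!is.null(pw$r2)) pw$r2 else strength$total_r2
    alpha <- if (!is.null(pw$alpha)) pw$alpha else 0.05
    power <- list(r2 = r2, alpha = alpha)
    if (!is.null(pw$target_power))
      power$detectable_or <- detectable_or(pw$target_power, pw$n_outcome,
                                           pw$case_fraction, r2, alpha)
    if (!is.null(pw$or_alt))
      power$power <- power_binary(pw$or_alt, pw$n_outcome,
                                  pw$case_fraction, r2, alpha)
  }

  list(direction = direction, estimable = TRUE, units = units,
       n_snps = nrow(ds), dataset = ds, audit = audit, selection = funnel,
       fit = fit, snp_estimates = fit$snp_estimates,
       heterogeneity = fit$heterogeneity,
       egger_intercept = fit$egger_intercept,
       outliers = outliers, sensitivity = sens, subsets = subsets,
       strength = strength, power = power)
}

.default_config <- list(
  direction = "forward", r2_prune = 0.01, r2_proxy = 0.8,
  palindrome_eaf_window = 0.08, drop_palindromic = TRUE,
  outlier_alpha = 0.05, effects_model = "multiplicative_random",
  n_boot = 1000, phi = 1, pheno_sd = 1.31)

#' Run a complete two-sample MR study
#'
#' Orchestrates the full workflow in one or both causal directions: parse
#' the association tables, LD-prune the instruments, search the outcome
#' panels in priority order (substituting proxies for SNPs absent from
#' all panels), harmonize, run every estimator, compute heterogeneity,
#' outlier, leave-one-out and plot tables, re-analyze the standard
#' sensitivity subsets (proxies excluded, outliers excluded, per source
#' study), and attach instrument-strength and power calculations. Subsets
#' with fewer than 3 instruments are marked not estimable; the run
#' continues.
#'
#' @param config A named list, or a path to a YAML/JSON file holding one.
#'   Top-level settings (with defaults): `direction`
#'   (`"forward"`/`"reverse"`/`"both"`), `r2_prune` (0.01), `r2_proxy`
#'   (0.8), `palindrome_eaf_window` (0.08), `drop_palindromic` (`TRUE`),
#'   `outlier_alpha` (0.05), `n_boot` (1000), `seed` (required), `phi`
#'   (1), `pheno_sd` (1.31), `ld` / `ld_path`, and `power` (list with
#'   `n_outcome`, `case_fraction`, optional `r2`, `alpha`, `target_power`,
#'   `or_alt`). Data per direction live in `forward` / `reverse` sublists
#'   (each with `exposure`/`exposure_path`, `outcome`/`outcome_paths`,
#'   optional `n_exposure`); for a single forward run they may sit at the
#'   top level instead.
#' @return Object of class `mr_report`: list with one entry per direction
#'   plus the resolved `config`.
#' @export
run_analysis <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the 'yaml' package")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  cfg <- utils::modifyList(.default_config, config)
  if (is.null(cfg$seed))
    stop("config must carry an integer seed for the bootstrap estimators")
  direction <- match.arg(cfg$direction, c("forward", "reverse", "both"))

  ld <- NULL
  if (!is.null(cfg[["ld"]])) {
    raw <- cfg[["ld"]]
    ld <- if (inherits(raw, "ld_table")) raw
          else ld_table(raw$rsid_a, raw$rsid_b, raw$r2)
  } else if (!is.null(cfg[["ld_path"]])) ld <- read_ld_table(cfg[["ld_path"]])

  dirs <- if (direction == "both") c("forward", "reverse") else direction
  runs <- list()
  for (d in dirs) {
    dcfg <- if (!is.null(cfg[[d]])) cfg[[d]] else cfg
    runs[[d]] <- run_direction(d, dcfg, cfg, ld)
  }
  report <- structure(list(directions = runs, config = cfg),
                      class = "mr_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

#' @export
print.mr_report <- function(x, ...) {
  cat("Two-sample MR analysis report\n")
  for (run in x$directions) {
    cat(sprintf("\n[%s] %d SNP(s) analyzed (%s)\n", run$direction,
                run$n_snps, run$units))
    if (!run$estimable) {
      cat("  not estimable:", run$reason, "\n")
      next
    }
    print(run$fit)
    if (length(run$outliers))
      cat("  flagged outliers:", paste(run$outliers, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Serialize an analysis report to disk
#'
#' Writes, per direction: `methods.tsv` (method, n_snps, OR, CI, p),
#' `forest.tsv`, `funnel.tsv`, `loo.tsv`, `audit.json` (harmonization
#' dispositions plus the selection funnel), and a combined `report.json`
#' carrying log-scale values at full precision.
#'
#' @param report An `mr_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mr_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, f) write.table(df, f, sep = "\t", quote = FALSE,
                                     row.names = FALSE)
  json_blob <- list()
  for (run in report$directions) {
    d <- file.path(dir, run$direction)
    dir.create(d, showWarnings = FALSE)
    json_blob[[run$direction]] <- list(
      estimable = run$estimable, n_snps = run$n_snps, units = run$units,
      selection = run$selection, audit = run$audit)
    if (!run$estimable) next
    res <- run$fit$results
    tsv(data.frame(method = res$method, n_snps = res$n_snps, or = res$or,
                   ci_low = res$or_ci_low, ci_high = res$or_ci_high,
                   p = res$pvalue), file.path(d, "methods.tsv"))
    tsv(run$sensitivity$forest, file.path(d, "forest.tsv"))
    tsv(run$sensitivity$funnel, file.path(d, "funnel.tsv"))
    tsv(run$sensitivity$leave_one_out, file.path(d, "loo.tsv"))
    jsonlite::write_json(
      list(audit = run$audit, selection = run$selection,
           thresholds = report$config[c("r2_prune", "r2_proxy",
                                        "palindrome_eaf_window",
                                        "outlier_alpha")],
           seed = report$config$seed),
      file.path(d, "audit.json"), auto_unbox = TRUE, digits = NA)
    json_blob[[run$direction]] <- c(
      json_blob[[run$direction]],
      list(pooled = res,
           egger_intercept = run$egger_intercept,
           heterogeneity = run$heterogeneity[c("q", "df", "pvalue")],
           outliers = as.character(run$outliers),
           subsets = lapply(run$subsets, function(s)
             s[setdiff(names(s), "heterogeneity")]),
           strength = if (!is.null(run$strength))
             run$strength[c("total_r2", "f_stat", "n", "k", "pheno_sd")],
           power = run$power))
  }
  jsonlite::write_json(json_blob, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(dir)
}
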