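test_that("odds-ratio CIs convert to log-scale standard errors", {
  expect_equal(ci_to_log_se(0.95, 0.92, 0.98),
               (log(0.98) - log(0.92)) / (2 * 1.959964))
  expect_equal(ci_to_log_se(0.95, 0.92, 0.98), 0.01612, tolerance = 1e-3)
  expect_equal(ci_to_log_se(1.00, 0.96, 1.04), 0.02042, tolerance = 1e-3)
  expect_equal(ci_to_log_se(1, exp(-1.959964), exp(1.959964)), 1.0)
  expect_error(ci_to_log_se(1.0, 1.1, 0.9), "inverted")
  expect_error(ci_to_log_se(-1, 0.5, 2), "positive")
})

test_that("association tables parse, convert and validate", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchr\teffect_allele\tother_allele\teaf\tbeta\tse\tpvalue\tn",
               "rs2231142\t4\tT\tG\t0.11\t0.217\t0.009\t1e-134\t110347"), tmp)
  tab <- read_association_table(tmp, "continuous")
  expect_equal(tab$beta, 0.217)
  expect_equal(tab$se, 0.009)
  expect_identical(tab$chrom, 4L)

  bin <- as_association_table(
    data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
               or = 1.00, ci_low = 0.96, ci_high = 1.04), "binary")
  expect_equal(bin$beta, 0)
  expect_equal(bin$se, (log(1.04) - log(0.96)) / (2 * 1.959964))

  # empty data section: no rows, no error
  writeLines("rsid\teffect_allele\tother_allele\tbeta\tse", tmp)
  expect_equal(nrow(read_association_table(tmp, "continuous")), 0)

  expect_error(
    as_association_table(data.frame(rsid = "rs1", beta = 1), "continuous"),
    "effect_allele")
  expect_error(
    as_association_table(
      data.frame(rsid = "rsBad", effect_allele = "A", other_allele = "G",
                 beta = 1, se = -0.1), "continuous"),
    "rsBad")
  expect_error(
    as_association_table(
      data.frame(rsid = "rsSame", effect_allele = "A", other_allele = "A",
                 beta = 1, se = 0.1), "continuous"),
    "rsSame")
})

test_that("harmonization reorients, complements, and drops as specified", {
  expo <- as_association_table(
    data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"),
               effect_allele = c("A", "A", "A", "A"),
               other_allele = c("G", "T", "G", "G"),
               eaf = c(0.3, 0.47, 0.2, 0.2),
               beta = c(0.1, 0.1, 0.1, 0.1), se = rep(0.01, 4)),
    "continuous")
  outc <- as_association_table(
    data.frame(rsid = c("rs1", "rs2", "rs3", "rs4"),
               effect_allele = c("G", "A", "T", "A"),
               other_allele = c("A", "T", "C", "C"),
               eaf = c(0.7, 0.47, 0.3, 0.2),
               beta = c(0.05, 0.02, 0.03, 0.04), se = rep(0.02, 4)),
    "binary")
  ds <- harmonize(expo, outc)
  audit <- attr(ds, "audit")

  # rs1: swapped orientation -> sign flip
  expect_equal(ds$beta_outcome[ds$rsid == "rs1"], -0.05)
  expect_true(ds$flipped[ds$rsid == "rs1"])
  expect_equal(audit$disposition[audit$rsid == "rs1"], "flipped")
  # rs2: palindromic at intermediate frequency -> dropped
  expect_false("rs2" %in% ds$rsid)
  expect_equal(audit$disposition[audit$rsid == "rs2"],
               "palindromic-dropped")
  # rs3: strand complement (T/C -> A/G), same orientation
  expect_equal(ds$beta_outcome[ds$rsid == "rs3"], 0.03)
  expect_false(ds$flipped[ds$rsid == "rs3"])
  # rs4: A/C cannot be reconciled with A/G
  expect_equal(audit$disposition[audit$rsid == "rs4"],
               "incompatible-dropped")
  # audit covers every input SNP exactly once
  expect_setequal(audit$rsid, expo$rsid)

  # palindromic SNP away from 0.5 is kept when frequencies are informative
  expo$eaf[2] <- 0.1
  ds2 <- harmonize(expo, outc)
  expect_true("rs2" %in% ds2$rsid)

  expect_error(harmonize(rbind(expo, expo[1, ]), outc), "duplicate")
})

test_that("harmonization is idempotent and an orientation involution", {
  for (seed in 1:5) {
    rt <- random_tables(seed)
    ds <- harmonize(rt$exposure, rt$outcome)
    expect_equal(ds$beta_outcome, rt$beta_outcome_aligned[match(
      ds$rsid, rt$exposure$rsid)])

    # idempotence: re-harmonizing the harmonized tables changes nothing
    tabs <- dataset_tables(ds)
    ds2 <- harmonize(tabs$exposure, tabs$outcome)
    cols <- c("rsid", "eaf", "beta_exposure", "se_exposure",
              "beta_outcome", "se_outcome")
    expect_equal(as.data.frame(ds2)[cols], as.data.frame(ds)[cols])

    # involution: swapping EA/OA and negating every outcome beta yields
    # the same dataset up to flipped flags
    sw <- rt$outcome
    tmp <- sw$effect_allele
    sw$effect_allele <- sw$other_allele
    sw$other_allele <- tmp
    sw$beta <- -sw$beta
    sw$eaf <- 1 - sw$eaf
    ds3 <- harmonize(rt$exposure, sw)
    expect_equal(as.data.frame(ds3)[cols], as.data.frame(ds)[cols])
  }
})

test_that("audit conservation: every matched SNP is kept or dropped", {
  for (seed in 6:10) {
    rt <- random_tables(seed)
    # knock some outcome rows out to create missing-outcome dispositions
    outc <- rt$outcome[-seq_len(seed %% 3 + 1), , drop = FALSE]
    ds <- harmonize(rt$exposure, outc)
    audit <- attr(ds, "audit")
    matched <- sum(rt$exposure$rsid %in% outc$rsid)
    dropped <- sum(audit$disposition %in%
                     c("palindromic-dropped", "incompatible-dropped"))
    expect_equal(nrow(ds) + dropped, matched)
    expect_equal(nrow(audit), nrow(rt$exposure))
  }
})

test_that("LD pruning follows the greedy p-value rule", {
  assoc <- function(rsid, p) as_association_table(
    data.frame(rsid = rsid, effect_allele = "A", other_allele = "G",
               beta = 0.1, se = 0.01, pvalue = p), "continuous")

  two <- assoc(c("rsA", "rsB"), c(1e-40, 1e-9))
  expect_equal(prune_ld(two, ld_table("rsA", "rsB", 0.02))$rsid, "rsA")
  expect_equal(prune_ld(two, ld_table("rsA", "rsB", 0.005))$rsid,
               c("rsA", "rsB"))

  three <- assoc(c("rsA", "rsB", "rsC"), c(1e-30, 1e-20, 1e-10))
  ld <- ld_table(c("rsA", "rsB"), c("rsB", "rsC"), c(0.5, 0.5))
  expect_equal(prune_ld(three, ld)$rsid, c("rsA", "rsC"))

  # result independent of input ordering
  shuf <- three[c(3, 1, 2), ]
  expect_setequal(prune_ld(shuf, ld)$rsid, c("rsA", "rsC"))
})

test_that("proxy substitution picks the best qualifying candidate per panel", {
  target <- as_association_table(
    data.frame(rsid = "rs12498742", effect_allele = "A", other_allele = "G",
               beta = 0.373, se = 0.006), "continuous")
  panel <- as_association_table(
    data.frame(rsid = c("rs7442295", "rsOther"),
               effect_allele = "A", other_allele = "G",
               beta = 0, se = 0.02), "binary")

  hit <- substitute_proxies(target, ld_table("rs12498742", "rs7442295", 0.95),
                            panel)
  expect_equal(hit$proxy_rsid, "rs7442295")
  expect_equal(hit$proxy_r2, 0.95)

  none <- substitute_proxies(
    target, ld_table(rep("rs12498742", 2), c("rs7442295", "rsOther"),
                     c(0.7, 0.75)), panel)
  expect_true(is.na(none$proxy_rsid))

  best <- substitute_proxies(
    target, ld_table(rep("rs12498742", 2), c("rs7442295", "rsOther"),
                     c(0.85, 0.92)), panel)
  expect_equal(best$proxy_rsid, "rsOther")
  expect_equal(best$proxy_r2, 0.92)

  # earlier panels win even when a later panel has a higher-r2 candidate
  p1 <- panel[panel$rsid == "rs7442295", , drop = FALSE]
  p2 <- panel[panel$rsid == "rsOther", , drop = FALSE]
  first <- substitute_proxies(
    target, ld_table(rep("rs12498742", 2), c("rs7442295", "rsOther"),
                     c(0.85, 0.92)), list(p1, p2))
  expect_equal(first$proxy_rsid, "rs7442295")
  expect_equal(first$panel, 1L)
})
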