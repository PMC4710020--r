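# Delta-Ct computation, allele calling, QC gating, genotype combination,
# SNP-pair translation and the risk-annotation lookup.

test_that("delta_ct subtracts HEX from FAM and substitutes the ceiling for undetermined FAM", {
  expect_equal(delta_ct(25.0, 20.0), 5.0)
  expect_equal(delta_ct(NA, 20.0), 20.0)   # undetermined FAM counts as cycle 40
  expect_equal(delta_ct(24.0, 24.0), 0.0)
  expect_equal(delta_ct(NA, 20.0, max_cycles = 45), 25.0)
  expect_error(delta_ct(25.0, NA), class = "apoetyper_validation_error")

  # substitution consistency: the undetermined penalty relative to a
  # determined FAM Ct f is exactly max_cycles - f, for any f and hex
  set.seed(1)
  f <- runif(50, 15, 39)
  h <- runif(50, 18, 30)
  expect_equal(delta_ct(NA, h) - delta_ct(f, h), 40 - f)
})

test_that("call_allele is negative strictly above the cut-off and positive at it", {
  expect_equal(call_allele(5.0, 9.2), "POSITIVE")
  expect_equal(call_allele(9.3, 9.2), "NEGATIVE")
  expect_equal(call_allele(9.2, 9.2), "POSITIVE")  # tie policy: equality is positive
  expect_equal(call_allele(9.2, 9.2, tie_positive = FALSE), "NEGATIVE")

  # monotonicity: increasing delta-Ct never flips NEGATIVE -> POSITIVE
  dct <- sort(runif(100, 0, 20))
  calls <- call_allele(dct, 9.2)
  expect_false(any(calls == "NEGATIVE" & dplyr::lead(calls, default = "NEGATIVE") == "POSITIVE"))
})

test_that("combine_calls matches the one-or-two-positives rule on all 8 patterns", {
  states <- c("POSITIVE", "NEGATIVE")
  grid <- expand.grid(e2 = states, e3 = states, e4 = states,
                      stringsAsFactors = FALSE)
  got <- combine_calls(grid$e2, grid$e3, grid$e4)
  # oracle: apply the rule directly from the positive set
  expected <- apply(grid, 1, function(row) {
    pos <- c("E2", "E3", "E4")[row == "POSITIVE"]
    if (length(pos) == 1) paste(pos, pos, sep = "/")
    else if (length(pos) == 2) paste(pos, collapse = "/")
    else "NO_CALL"
  })
  expect_equal(got$genotype, unname(expected))
  expect_match(got$reason[got$genotype == "NO_CALL" &
                            grid$e2 == "NEGATIVE"], "no allele")
  expect_match(got$reason[got$genotype == "NO_CALL" &
                            grid$e2 == "POSITIVE"], "three alleles")
  # an INVALID input propagates to NO_CALL
  inv <- combine_calls("INVALID", "POSITIVE", "NEGATIVE")
  expect_equal(inv$genotype, "NO_CALL")
})

test_that("genotype_samples runs the delta-Ct -> call -> combine pipeline", {
  res <- genotype_samples(make_measurements(2.1, 1.8, 19.5))
  expect_equal(res$genotype, "E2/E3")
  expect_equal(res$dct_e2, 2.1)

  expect_equal(genotype_samples(make_measurements(15.0, 2.0, 15.1))$genotype,
               "E3/E3")
  expect_equal(genotype_samples(make_measurements(2.0, 2.0, 2.0))$genotype,
               "NO_CALL")
})

test_that("QC gates force NO_CALL and name the failure", {
  # clean sample with nominal controls: no flags
  plate <- dplyr::bind_rows(
    make_measurements(2.0, 18, 19, sample_id = "S1"),
    tibble::tibble(plate_id = "P1", well = "B1", sample_id = "P1_PC_E2",
                   reaction = "E2", role = "POSITIVE_CONTROL_E2",
                   fam_ct = 26, hex_ct = 24),
    tibble::tibble(plate_id = "P1", well = "B2", sample_id = "P1_NTC",
                   reaction = "E2", role = "NTC",
                   fam_ct = NA_real_, hex_ct = NA_real_)
  )
  res <- genotype_samples(plate)
  expect_equal(res$qc_flags, "")
  expect_equal(res$genotype, "E2/E2")

  # undetermined HEX in one reaction invalidates the sample
  hexfail <- make_measurements(2.0, 2.5, 18)
  hexfail$hex_ct[2] <- NA
  res <- genotype_samples(hexfail)
  expect_equal(res$qc_flags, "HEX_FAIL")
  expect_equal(res$genotype, "NO_CALL")

  # an early FAM signal in the NTC flags every sample on the plate
  contaminated <- plate
  contaminated$fam_ct[contaminated$role == "NTC"] <- 28
  res <- genotype_samples(contaminated)
  expect_equal(res$qc_flags, "NTC_CONTAMINATION")
  expect_equal(res$genotype, "NO_CALL")

  # a positive control failing its own reaction flags the plate
  pcfail <- plate
  pcfail$fam_ct[pcfail$role == "POSITIVE_CONTROL_E2"] <- NA
  res <- genotype_samples(pcfail)
  expect_equal(res$qc_flags, "POSCTRL_FAIL")

  # fewer than three reactions
  res <- genotype_samples(make_measurements(2.0, 3.0, 18)[1:2, ])
  expect_equal(res$qc_flags, "MISSING_REACTION")
  expect_equal(res$genotype, "NO_CALL")
})

test_that("translate_snp_pair maps all nine site-genotype combinations correctly", {
  # haplotypes: e2 = (T,T), e3 = (T,C), e4 = (C,C) at (rs429358, rs7412);
  # expected genotype per combination derived by enumerating haplotype
  # pairs consistent with both unphased site genotypes
  cases <- tibble::tribble(
    ~rs429358, ~rs7412, ~genotype, ~ambiguous,
    "T/T", "T/T", "E2/E2", FALSE,
    "T/T", "C/T", "E2/E3", FALSE,
    "T/T", "C/C", "E3/E3", FALSE,
    "C/T", "C/C", "E3/E4", FALSE,
    "C/C", "C/C", "E4/E4", FALSE,
    "C/T", "C/T", "E2/E4", TRUE,   # {e2,e4} wins over the rare {e1,e3}
    "C/T", "T/T", "NO_CALL", FALSE,  # forces an e1 haplotype
    "C/C", "T/T", "NO_CALL", FALSE,
    "C/C", "C/T", "NO_CALL", FALSE
  )
  got <- translate_snp_pair(cases$rs429358, cases$rs7412)
  expect_equal(got$genotype, cases$genotype)
  expect_equal(got$ambiguous, cases$ambiguous)
  expect_match(got$reason[7], "e1")

  # separator and order insensitivity
  expect_equal(translate_snp_pair("TC", "CC")$genotype, "E3/E4")
  expect_equal(translate_snp_pair("c|t", "c c")$genotype, "E3/E4")
  expect_error(translate_snp_pair("A/T", "C/C"),
               class = "apoetyper_validation_error")
})

test_that("annotate_risk returns the literature odds ratios with e3/e3 as reference", {
  ann <- annotate_risk(apoe_genotypes())
  expect_equal(ann$odds_ratio, c(0.6, 0.6, 2.6, NA, 3.2, 14.9))
  expect_match(ann$source_note[ann$genotype == "E3/E3"], "reference")
  expect_true(is.na(annotate_risk("NO_CALL")$odds_ratio))
  expect_error(annotate_risk("E5/E5"), class = "apoetyper_validation_error")
})
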