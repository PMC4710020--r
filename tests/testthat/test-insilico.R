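# 3'-clamp primer binding, amplification simulation and the assay's
# allele-specificity matrix.

test_that("a primer identical to a template substring is found at that offset", {
  template <- paste0("AAAAACCCCC", "GATTACAGATTACAGATTAC", "GGGGGTTTTT")
  primer <- "GATTACAGATTACAGATTAC"
  sites <- primer_sites(primer, template)
  plus <- dplyr::filter(sites, strand == "+")
  expect_equal(plus$position, 10)
  expect_equal(plus$mismatches, 0)
})

test_that("a 3'-terminal mismatch blocks binding everywhere", {
  # template is poly-A except where the primer would land; a primer whose
  # final base can never match gives no sites at all
  template <- strrep("A", 60)
  primer <- paste0(strrep("A", 19), "C")   # 3' C never matches
  expect_equal(nrow(primer_sites(primer, template)), 0)
  # the same primer with a matching 3' base binds everywhere
  expect_gt(nrow(primer_sites(strrep("A", 20), template)), 0)
})

test_that("primer_sites equals the exhaustive-offset oracle on random instances", {
  set.seed(17)
  for (i in 1:30) {
    template <- random_dna(sample(80:500, 1))
    # half the time plant the primer (possibly mutated), else random
    if (i %% 2 == 0) {
      start <- sample(1:(nchar(template) - 20), 1)
      primer <- substr(template, start, start + 19)
      pos <- sample(1:20, 1)
      substr(primer, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
    } else {
      primer <- random_dna(sample(15:25, 1))
    }
    expect_equal(as.data.frame(primer_sites(primer, template)),
                 as.data.frame(oracle_primer_sites(primer, template)),
                 info = paste(i, primer))
  }
})

test_that("each allele reaction amplifies and probe-detects only its own template", {
  oligos <- apoe_assay_oligos()
  tpl <- apoe_templates()
  e2f <- oligos$sequence[oligos$name == "e2-Forward"]
  e2r <- oligos$sequence[oligos$name == "e2-Reverse"]
  probe <- oligos$sequence[oligos$name == "APOE-probe"]

  on_e2 <- simulate_amplification(e2f, e2r, probe,
                                  tpl$sequence[tpl$label == "E2"])
  expect_true(on_e2$amplified)
  expect_true(on_e2$probe_detected)
  expect_equal(on_e2$product_len,
               on_e2$product_end - on_e2$product_start)

  # rs429358: the e2 forward primer ends in T, the e4 template carries C
  on_e4 <- simulate_amplification(e2f, e2r, probe,
                                  tpl$sequence[tpl$label == "E4"])
  expect_false(on_e4$amplified)
  expect_false(on_e4$probe_detected)
})

test_that("products longer than max_product_len are not amplified", {
  oligos <- apoe_assay_oligos()
  tpl <- apoe_templates()$sequence[1]
  e2f <- oligos$sequence[oligos$name == "e2-Forward"]
  e2r <- oligos$sequence[oligos$name == "e2-Reverse"]
  probe <- oligos$sequence[oligos$name == "APOE-probe"]
  # stretch the template between the primer sites beyond the budget
  set.seed(3)
  long_tpl <- sub("CATTGGATCAAGTCC",
                  paste0("CATTGGATCAAGTCC", random_dna(1500)), tpl,
                  fixed = TRUE)
  res <- simulate_amplification(e2f, e2r, probe, long_tpl)
  expect_false(res$amplified)
  res2 <- simulate_amplification(e2f, e2r, probe, long_tpl,
                                 binding_rules(max_product_len = 2000))
  expect_true(res2$amplified)
})

test_that("amplification is invariant under template reverse-complement with swapped primers", {
  oligos <- apoe_assay_oligos()
  tpl <- apoe_templates()
  probe <- oligos$sequence[oligos$name == "APOE-probe"]
  for (a in c("E2", "E3", "E4")) {
    fwd <- oligos$sequence[oligos$reaction == a & oligos$role == "FORWARD"]
    rev_ <- oligos$sequence[oligos$reaction == a & oligos$role == "REVERSE"]
    for (t in c("E2", "E3", "E4")) {
      seq_top <- tpl$sequence[tpl$label == t]
      fwd_res <- simulate_amplification(fwd, rev_, probe, seq_top)
      rc <- oracle_revcomp(seq_top)
      swapped <- simulate_amplification(rev_, fwd, probe, rc)
      expect_equal(swapped$amplified, fwd_res$amplified,
                   info = paste(a, "on", t))
      expect_equal(swapped$probe_detected, fwd_res$probe_detected,
                   info = paste(a, "on", t))
    }
  }
})

test_that("the bundled assay gives the identity specificity matrix", {
  mat <- specificity_matrix()
  expect_equal(unname(mat), diag(3) == 1)

  # degenerate fixture: every template replaced by the e3 template
  tpl <- apoe_templates(include_actb = FALSE)
  tpl$sequence <- tpl$sequence[tpl$label == "E3"]
  mat3 <- specificity_matrix(templates = tpl)
  expect_equal(unname(rowSums(mat3)), c(0, 3, 0))

  # scrambled probe: amplification may occur but nothing is detected
  oligos <- apoe_assay_oligos()
  oligos$sequence[oligos$name == "APOE-probe"] <- "ACGTACGTACGTACGTACGT"
  expect_false(any(specificity_matrix(oligos = oligos)))
})

test_that("oligo and template FASTA files round-trip and match the bundled fixtures", {
  tdir <- withr::local_tempdir()
  of <- file.path(tdir, "oligos.fasta")
  tf <- file.path(tdir, "templates.fasta")
  write_oligos_fasta(apoe_assay_oligos(), of)
  write_templates_fasta(apoe_templates(), tf)
  expect_equal(read_oligos_fasta(of), apoe_assay_oligos())
  expect_equal(read_templates_fasta(tf), apoe_templates())

  # the files shipped with the package are exactly these tables
  bundled_o <- system.file("extdata", "apoe_assay_oligos.fasta",
                           package = "apoetyper")
  bundled_t <- system.file("extdata", "apoe_templates_synthetic.fasta",
                           package = "apoetyper")
  expect_equal(read_oligos_fasta(bundled_o), apoe_assay_oligos())
  expect_equal(read_templates_fasta(bundled_t), apoe_templates())
})
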