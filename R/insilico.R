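# In-silico allele specificity of the assay oligos.
#
# Allele discrimination in this assay is positional: each allele-specific
# primer places its 3'-terminal base on one of the two APOE SNPs
# (rs429358 under the forward primers, rs7412 under the reverse primers),
# and Taq polymerase cannot extend a 3'-terminal mismatch. The binding
# model is deliberately minimal - a perfect-match 3' clamp plus a mismatch
# budget elsewhere, full-length ungapped alignment only - and makes no
# attempt at melting-temperature thermodynamics.
#
# Coordinates are 0-based, half-open, on the template top strand.

#' Primer-binding rules for the 3'-clamp extension model
#'
#' @param clamp_len Number of 3'-terminal primer bases that must match the
#'   template perfectly (extension blocking).
#' @param max_mismatches_outside_clamp Mismatches tolerated in the rest of
#'   the primer (and in the probe, which has no clamp).
#' @param max_product_len Longest amplifiable product (bases).
#' @return A list of class `binding_rules`.
#' @export
binding_rules <- function(clamp_len = 3, max_mismatches_outside_clamp = 1,
                          max_product_len = 1000) {
  stopifnot(clamp_len >= 1, max_mismatches_outside_clamp >= 0,
            max_product_len >= 1)
  structure(list(clamp_len = clamp_len,
                 max_mismatches_outside_clamp = max_mismatches_outside_clamp,
                 max_product_len = max_product_len),
            class = "binding_rules")
}

#' The published oligo set of the APOE genotyping assay
#'
#' The three allele-specific primer pairs, the shared FAM-labelled APOE
#' TaqMan probe, and the ACTB internal-control primers and HEX-labelled
#' probe. The allele-discriminating 3'-terminal bases sit on rs429358
#' (forward primers: T for e2/e3, C for e4) and rs7412 (reverse primers:
#' A complementing the e2 T allele, G complementing the C allele); the
#' e3 and e4 reactions share one reverse primer.
#'
#' @return A tibble with columns `name`, `reaction` (`E2`/`E3`/`E4`/
#'   `ACTB`), `role` (`FORWARD`/`REVERSE`/`PROBE`), `sequence` (5'->3'),
#'   `reporter`, `quencher`.
#' @examples
#' apoe_assay_oligos()
#' @export
apoe_assay_oligos <- function() {
  tibble(
    name = c("e2-Forward", "e2-Reverse", "e3-Forward", "e3-Reverse",
             "e4-Forward", "e4-Reverse", "APOE-probe",
             "ACTB-Forward", "ACTB-Reverse", "ACTB-probe"),
    reaction = c("E2", "E2", "E3", "E3", "E4", "E4", "APOE",
                 "ACTB", "ACTB", "ACTB"),
    role = c("FORWARD", "REVERSE", "FORWARD", "REVERSE", "FORWARD",
             "REVERSE", "PROBE", "FORWARD", "REVERSE", "PROBE"),
    sequence = c("GCGGACATGGAGGACGTGT", "CCTGGTACACTGCCAGGCA",
                 "CGGACATGGAGGACGTGT",  "CTGGTACACTGCCAGGCG",
                 "CGGACATGGAGGACGTGC",  "CTGGTACACTGCCAGGCG",
                 "CAGCTCCTCGGTGCTCTGGC",
                 "GACGTGGACATCCGCAAAGAC", "CAGGTCAGCTCAGGCAGGAA",
                 "TGCTGTCTGGCGGCACCACCATGTACC"),
    reporter = c(NA, NA, NA, NA, NA, NA, "FAM", NA, NA, "HEX"),
    quencher = c(NA, NA, NA, NA, NA, NA, "BHQ1", NA, NA, "BHQ1")
  )
}

#' Synthetic allele template sequences
#'
#' Constructed (synthetic) double-stranded templates, given as top
#' strands, that embed the assay's primer and probe binding sites with
#' the correct allele bases at the two SNP positions: rs429358 under the
#' forward primers' 3' ends (T for e2/e3, C for e4) and rs7412 under the
#' reverse primers' 3' ends (T for e2, C for e3/e4), with the shared
#' probe site between them and fixed neutral padding around them.
#'
#' These are not the real 197-bp plasmid inserts used on the bench (those
#' sequences are unpublished); they reproduce the assay's combinatorial
#' allele logic, not the genomic context. An analogous synthetic ACTB
#' internal-control template is included.
#'
#' @param include_actb Include the ACTB control template row.
#' @return A tibble with columns `label` (`E2`/`E3`/`E4`/`ACTB`) and
#'   `sequence`.
#' @examples
#' apoe_templates()
#' @export
apoe_templates <- function(include_actb = TRUE) {
  pad5 <- "ATTGCAACGTGGATCCTTAG"
  spacer1 <- "CATTGGATCAAGTCC"
  spacer2 <- "GTTAACCTGATCGGA"
  pad3 <- "CCATGAATTCGGTACGTTAA"
  fwd_core <- "GCGGACATGGAGGACGTG"      # + rs429358 base at the 3' end
  rev_core <- "CCTGGTACACTGCCAGGC"      # + base complementary to rs7412
  probe <- "CAGCTCCTCGGTGCTCTGGC"
  top <- function(rs429358, rs7412_primer_base) {
    paste0(pad5, fwd_core, rs429358, spacer1, probe, spacer2,
           revcomp(paste0(rev_core, rs7412_primer_base)), pad3)
  }
  out <- tibble(
    label = c("E2", "E3", "E4"),
    sequence = c(top("T", "A"),   # e2: rs429358 T, rs7412 T
                 top("T", "G"),   # e3: rs429358 T, rs7412 C
                 top("C", "G"))   # e4: rs429358 C, rs7412 C
  )
  if (include_actb) {
    actb <- paste0(pad5, "GACGTGGACATCCGCAAAGAC", spacer1,
                   "TGCTGTCTGGCGGCACCACCATGTACC", spacer2,
                   revcomp("CAGGTCAGCTCAGGCAGGAA"), pad3)
    out <- bind_rows(out, tibble(label = "ACTB", sequence = actb))
  }
  out
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

check_dna <- function(x, what) {
  if (length(x) != 1 || is.na(x) || !nzchar(x) ||
      grepl("[^ACGT]", toupper(x))) {
    abort(paste0(what, " must be a non-empty A/C/G/T sequence",
                 " (degenerate bases are not supported)"),
          class = "apoetyper_validation_error")
  }
  toupper(x)
}

#' Find primer binding sites on a template
#'
#' Scans every offset of the template top strand for full-length ungapped
#' alignments of the primer in either orientation. A plus-strand site is
#' one where the primer equals the top-strand substring (the primer
#' anneals to the bottom strand and extends rightward); a minus-strand
#' site is one where the primer's reverse complement equals the substring
#' (the primer anneals to the top strand and extends leftward). A site
#' requires zero mismatches in the primer's 3'-terminal `clamp_len` bases
#' and at most `max_mismatches_outside_clamp` elsewhere.
#'
#' @param primer Primer sequence, 5'->3'.
#' @param template Template top-strand sequence.
#' @param rules A [binding_rules()] list.
#' @return A tibble with one row per site: `position` (0-based start of
#'   the footprint on the top strand), `strand` (`"+"`/`"-"`),
#'   `mismatches` (outside the clamp). Empty when the primer does not
#'   bind.
#' @export
primer_sites <- function(primer, template, rules = binding_rules()) {
  primer <- check_dna(primer, "primer")
  template <- check_dna(template, "template")
  m <- nchar(primer)
  L <- nchar(template)
  if (m > L) {
    return(tibble(position = integer(), strand = character(),
                  mismatches = integer()))
  }
  subject <- Biostrings::DNAString(template)
  scan_strand <- function(pattern, clamp_at_start) {
    pat <- Biostrings::DNAString(pattern)
    starts <- seq_len(L - m + 1)
    total <- Biostrings::neditStartingAt(pat, subject, starting.at = starts,
                                         with.indels = FALSE)
    clamp_len <- min(rules$clamp_len, m)
    if (clamp_at_start) {
      clamp_pat <- Biostrings::subseq(pat, 1, clamp_len)
      clamp_starts <- starts
    } else {
      clamp_pat <- Biostrings::subseq(pat, m - clamp_len + 1, m)
      clamp_starts <- starts + m - clamp_len
    }
    clamp_mm <- Biostrings::neditStartingAt(clamp_pat, subject,
                                            starting.at = clamp_starts,
                                            with.indels = FALSE)
    outside <- total - clamp_mm
    hit <- clamp_mm == 0 & outside <= rules$max_mismatches_outside_clamp
    tibble(position = starts[hit] - 1L, mismatches = as.integer(outside[hit]))
  }
  # plus strand: primer read as-is; 3' clamp at the END of the footprint
  plus <- scan_strand(primer, clamp_at_start = FALSE) |> mutate(strand = "+")
  # minus strand: footprint is revcomp(primer); the primer 3' end maps to
  # the START of the footprint on the top strand
  minus <- scan_strand(revcomp(primer), clamp_at_start = TRUE) |>
    mutate(strand = "-")
  bind_rows(plus, minus) |>
    select("position", "strand", "mismatches") |>
    arrange(.data$position, .data$strand)
}

#' Simulate one allele-specific TaqMan reaction on a template
#'
#' A product is amplified when a forward-primer site (plus strand) and a
#' reverse-primer site (minus strand) face each other in convergent
#' orientation within `max_product_len` bases. The probe is detected when
#' it (or its reverse complement) matches inside an amplified product,
#' strictly between the two primer 3' ends, within the mismatch budget
#' (the probe has no clamp: it is hydrolysed, not extended).
#'
#' @param fwd,rev,probe Oligo sequences, 5'->3'.
#' @param template Template top-strand sequence.
#' @param rules A [binding_rules()] list.
#' @return A one-row tibble: `amplified`, `product_start`, `product_end`
#'   (0-based half-open on the top strand; `NA` when not amplified),
#'   `product_len`, `probe_detected`.
#' @examples
#' oligos <- apoe_assay_oligos()
#' tpl <- apoe_templates()
#' simulate_amplification(
#'   fwd = oligos$sequence[1], rev = oligos$sequence[2],
#'   probe = oligos$sequence[7], template = tpl$sequence[1]
#' )
#' @export
simulate_amplification <- function(fwd, rev, probe, template,
                                   rules = binding_rules()) {
  probe <- check_dna(probe, "probe")
  fsites <- primer_sites(fwd, template, rules) |> filter(.data$strand == "+")
  rsites <- primer_sites(rev, template, rules) |> filter(.data$strand == "-")
  len_f <- nchar(fwd)
  len_r <- nchar(rev)
  no_product <- tibble(amplified = FALSE, product_start = NA_integer_,
                       product_end = NA_integer_, product_len = NA_integer_,
                       probe_detected = FALSE)
  if (nrow(fsites) == 0 || nrow(rsites) == 0) return(no_product)

  pairs <- tidyr::expand_grid(f = fsites$position, r = rsites$position) |>
    mutate(product_start = .data$f,
           product_end = .data$r + len_r,
           product_len = .data$product_end - .data$product_start) |>
    filter(.data$r >= .data$f,                      # convergent
           .data$product_end >= .data$f + len_f,    # both primers inside
           .data$product_len <= rules$max_product_len)
  if (nrow(pairs) == 0) return(no_product)

  probe_hits <- probe_matches(probe, template, rules)
  pairs <- pairs |>
    mutate(probe_detected = map2_lgl(
      .data$f + len_f, .data$r,
      function(lo, hi) any(probe_hits$position >= lo &
                             probe_hits$position + nchar(probe) <= hi)
    )) |>
    arrange(dplyr::desc(.data$probe_detected), .data$product_len)
  best <- pairs[1, ]
  tibble(amplified = TRUE,
         product_start = as.integer(best$product_start),
         product_end = as.integer(best$product_end),
         product_len = as.integer(best$product_len),
         probe_detected = best$probe_detected)
}

# probe match positions (0-based starts) in either orientation, no clamp
probe_matches <- function(probe, template, rules) {
  m <- nchar(probe)
  L <- nchar(template)
  if (m > L) return(tibble(position = integer()))
  subject <- Biostrings::DNAString(template)
  starts <- seq_len(L - m + 1)
  hit_for <- function(pattern) {
    mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pattern), subject,
                                      starting.at = starts,
                                      with.indels = FALSE)
    starts[mm <= rules$max_mismatches_outside_clamp] - 1L
  }
  tibble(position = sort(unique(c(hit_for(probe), hit_for(revcomp(probe))))))
}

#' Allele-specificity matrix of the assay
#'
#' Runs every allele-specific reaction (primer pair plus the shared APOE
#' probe) against every allele template and reports whether the probe
#' detects a product. For the bundled oligos and templates the result is
#' the identity matrix: each reaction amplifies only its own allele.
#'
#' @param oligos Oligo tibble in the shape of [apoe_assay_oligos()].
#' @param templates Template tibble in the shape of [apoe_templates()]
#'   (the ACTB row, if present, is ignored here).
#' @param rules A [binding_rules()] list.
#' @return A logical matrix, rows = reactions (E2, E3, E4), columns =
#'   templates.
#' @examples
#' specificity_matrix()
#' @export
specificity_matrix <- function(oligos = apoe_assay_oligos(),
                               templates = apoe_templates(include_actb = FALSE),
                               rules = binding_rules()) {
  templates <- templates |> filter(.data$label != "ACTB")
  probe <- oligos$sequence[oligos$role == "PROBE" & oligos$reaction != "ACTB"][1]
  mat <- matrix(FALSE, nrow = 3, ncol = nrow(templates),
                dimnames = list(apoe_alleles(), templates$label))
  for (a in apoe_alleles()) {
    fwd <- oligos$sequence[oligos$reaction == a & oligos$role == "FORWARD"]
    rev <- oligos$sequence[oligos$reaction == a & oligos$role == "REVERSE"]
    stopifnot(length(fwd) == 1, length(rev) == 1)
    for (j in seq_len(nrow(templates))) {
      res <- simulate_amplification(fwd, rev, probe,
                                    templates$sequence[j], rules)
      mat[a, j] <- res$probe_detected
    }
  }
  mat
}

#' Read and write oligo and template FASTA files
#'
#' Templates use plain FASTA with the label as the record name. Oligos
#' carry their metadata in the description line as `key=value` tokens,
#' e.g. `>e2-Forward reaction=E2 role=FORWARD`; probes add
#' `reporter=FAM quencher=BHQ1`.
#'
#' @param file Path to a FASTA file.
#' @return `read_templates_fasta()` returns a `label`/`sequence` tibble;
#'   `read_oligos_fasta()` returns the [apoe_assay_oligos()] shape.
#' @export
read_templates_fasta <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file)
  tibble(label = sub(" .*", "", names(seqs)),
         sequence = unname(as.character(seqs)))
}

#' @rdname read_templates_fasta
#' @param templates,oligos Tibbles to write.
#' @export
write_templates_fasta <- function(templates, file) {
  seqs <- Biostrings::DNAStringSet(setNames(templates$sequence,
                                            templates$label))
  Biostrings::writeXStringSet(seqs, file, width = 70)
  invisible(file)
}

#' @rdname read_templates_fasta
#' @export
read_oligos_fasta <- function(file) {
  seqs <- Biostrings::readDNAStringSet(file)
  parse_field <- function(desc, key) {
    has <- grepl(paste0(key, "="), desc, fixed = TRUE)
    out <- rep(NA_character_, length(desc))
    out[has] <- sub(paste0(".*", key, "=([^ ]+).*"), "\\1", desc[has])
    out
  }
  desc <- names(seqs)
  tibble(
    name = sub(" .*", "", desc),
    reaction = parse_field(desc, "reaction"),
    role = parse_field(desc, "role"),
    sequence = unname(as.character(seqs)),
    reporter = parse_field(desc, "reporter"),
    quencher = parse_field(desc, "quencher")
  )
}

#' @rdname read_templates_fasta
#' @export
write_oligos_fasta <- function(oligos, file) {
  desc <- pmap(oligos, function(name, reaction, role, sequence,
                                reporter, quencher, ...) {
    extra <- c(
      paste0("reaction=", reaction),
      paste0("role=", role),
      if (!is.na(reporter)) paste0("reporter=", reporter),
      if (!is.na(quencher)) paste0("quencher=", quencher)
    )
    paste(name, paste(extra, collapse = " "))
  })
  seqs <- Biostrings::DNAStringSet(setNames(oligos$sequence,
                                            unlist(desc)))
  Biostrings::writeXStringSet(seqs, file, width = 70)
  invisible(file)
}
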