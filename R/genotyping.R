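# Delta-Ct allele calling and genotype combination.
#
# Each sample is run in three allele-specific reactions (E2, E3, E4). In a
# reaction, FAM reports the allele-specific APOE amplicon and HEX the ACTB
# internal control; delta-Ct = Ct(FAM) - Ct(HEX). An allele-positive sample
# amplifies early (small delta-Ct); an allele-negative sample gives no FAM
# curve (Ct treated as the 40-cycle ceiling) or a very late one. Each
# reaction's delta-Ct is compared with a fixed per-reaction cut-off and the
# three binary calls are combined into one of the six APOE genotypes.

QC_FLAGS <- c("HEX_FAIL", "NTC_CONTAMINATION", "POSCTRL_FAIL", "MISSING_REACTION")

#' Per-reaction delta-Ct cut-offs
#'
#' The published ROC-calibrated cut-offs for the three reactions: a sample
#' whose delta-Ct is higher than the cut-off is negative for that allele.
#' Defaults are the assay's published values (9.2 / 10.4 / 11.1 cycles for
#' the e2 / e3 / e4 reaction); they are shipped as constants because the
#' training delta-Ct values behind them are not public. Use
#' [calibrate_cutoffs()] to re-derive cut-offs from your own labelled data.
#'
#' @param e2,e3,e4 Cut-off delta-Ct (cycles) for each reaction; finite,
#'   positive, below `max_cycles`.
#' @param max_cycles Cycle ceiling used for validation.
#' @return A named numeric vector of class `apoe_cutoffs`.
#' @examples
#' apoe_cutoffs()
#' @export
apoe_cutoffs <- function(e2 = 9.2, e3 = 10.4, e4 = 11.1, max_cycles = 40) {
  x <- c(E2 = e2, E3 = e3, E4 = e4)
  if (any(!is.finite(x)) || any(x <= 0) || any(x >= max_cycles)) {
    abort("Cut-offs must be finite, > 0 and < max_cycles",
          class = "apoetyper_validation_error")
  }
  structure(x, class = c("apoe_cutoffs", "numeric"))
}

#' QC policy bounds for plate and sample gating
#'
#' The published protocol specifies the controls (per-allele positive plasmid templates
#' and a water NTC in every panel, HEX/ACTB as internal control) but not
#' numeric validity bounds, so these are package defaults: a reaction's
#' internal control must amplify by `hex_ceiling` cycles, and a determined
#' FAM signal in an NTC earlier than `ntc_fam_floor` cycles flags
#' contamination.
#'
#' @param hex_ceiling Latest acceptable HEX Ct (cycles) for a valid
#'   reaction; an undetermined or later HEX sets `HEX_FAIL`.
#' @param ntc_fam_floor Earliest innocuous FAM Ct (cycles) in an NTC well;
#'   a determined NTC FAM Ct below it sets `NTC_CONTAMINATION`.
#' @param max_cycles Cycle ceiling (the assay runs 40 cycles).
#' @param tie_positive Call a delta-Ct exactly equal to the cut-off
#'   positive (`TRUE`, the strict reading of "negative when higher than
#'   the cut-off") or negative.
#' @return A list of class `qc_policy`.
#' @export
qc_policy <- function(hex_ceiling = 35, ntc_fam_floor = 38, max_cycles = 40,
                      tie_positive = TRUE) {
  structure(list(hex_ceiling = hex_ceiling, ntc_fam_floor = ntc_fam_floor,
                 max_cycles = max_cycles, tie_positive = tie_positive),
            class = "qc_policy")
}

#' Compute delta-Ct for a reaction
#'
#' delta-Ct is the FAM (allele-specific APOE) Ct minus the HEX (ACTB
#' internal control) Ct of the same well. When no FAM amplification curve
#' appeared (`fam_ct = NA`), the FAM Ct is taken as `max_cycles` (the
#' assay's 40-cycle ceiling) before subtracting. An undetermined HEX is a
#' failed reaction and must be gated upstream (`HEX_FAIL`), not fed here.
#'
#' @param fam_ct,hex_ct Numeric vectors of Ct values; `NA` in `fam_ct`
#'   means undetermined.
#' @param max_cycles Cycle ceiling substituted for undetermined FAM.
#' @return Numeric vector of delta-Ct values (cycles).
#' @examples
#' delta_ct(25, 20)       # 5
#' delta_ct(NA, 20)       # 20: undetermined FAM counts as cycle 40
#' @export
delta_ct <- function(fam_ct, hex_ct, max_cycles = 40) {
  if (any(is.na(hex_ct))) {
    abort("hex_ct must be determined; gate HEX failures before delta_ct()",
          class = "apoetyper_validation_error")
  }
  ifelse(is.na(fam_ct), max_cycles, fam_ct) - hex_ct
}

#' Call an allele from its delta-Ct
#'
#' A sample is negative for an allele when the reaction's delta-Ct is
#' higher than the cut-off; otherwise positive. A delta-Ct exactly at the
#' cut-off is positive under the default tie policy.
#'
#' @param dct Numeric vector of delta-Ct values.
#' @param cutoff Scalar cut-off for the reaction.
#' @param tie_positive Treat equality as positive (default) or negative.
#' @return Character vector, `"POSITIVE"` or `"NEGATIVE"`.
#' @examples
#' call_allele(c(5, 9.2, 9.3), cutoff = 9.2)
#' @export
call_allele <- function(dct, cutoff, tie_positive = TRUE) {
  stopifnot(is.finite(cutoff), all(is.finite(dct)))
  pos <- if (tie_positive) dct <= cutoff else dct < cutoff
  ifelse(pos, "POSITIVE", "NEGATIVE")
}

#' Combine the three allele calls into an APOE genotype
#'
#' With one positive reaction the sample is homozygous for that allele;
#' with two it is the corresponding heterozygote (alleles ordered
#' e2 < e3 < e4). Zero or three positives cannot arise from a valid
#' two-allele genotype and yield `"NO_CALL"` with a reason rather than an
#' error: in practice they come from QC failures or contamination and a
#' reporting tool must report them.
#'
#' @param call_e2,call_e3,call_e4 Character vectors of `"POSITIVE"` /
#'   `"NEGATIVE"` (or `"INVALID"` for a QC-failed reaction).
#' @return A tibble with columns `genotype` (one of [apoe_genotypes()] or
#'   `"NO_CALL"`) and `reason` (empty when called).
#' @examples
#' combine_calls("POSITIVE", "POSITIVE", "NEGATIVE")   # E2/E3
#' @export
combine_calls <- function(call_e2, call_e3, call_e4) {
  n <- length(call_e2)
  stopifnot(length(call_e3) == n, length(call_e4) == n)
  calls <- cbind(call_e2, call_e3, call_e4)
  out <- tibble(genotype = character(n), reason = character(n))
  for (i in seq_len(n)) {
    row <- calls[i, ]
    if (any(row == "INVALID")) {
      out$genotype[i] <- NO_CALL
      out$reason[i] <- "invalid allele call (QC failure)"
      next
    }
    pos <- apoe_alleles()[row == "POSITIVE"]
    if (length(pos) == 1) {
      out$genotype[i] <- paste(pos, pos, sep = "/")
    } else if (length(pos) == 2) {
      out$genotype[i] <- paste(pos[1], pos[2], sep = "/")
    } else if (length(pos) == 0) {
      out$genotype[i] <- NO_CALL
      out$reason[i] <- "no allele detected"
    } else {
      out$genotype[i] <- NO_CALL
      out$reason[i] <- "three alleles positive"
    }
  }
  out
}

# Plate-level QC from control wells: NTC contamination and positive-control
# failure apply to every sample on the affected plate.
plate_qc_flags <- function(measurements, cutoffs, policy) {
  plates <- unique(measurements$plate_id)
  flags <- setNames(vector("list", length(plates)), plates)
  for (p in plates) {
    m <- measurements[measurements$plate_id == p, ]
    f <- character(0)
    ntc <- m[m$role == "NTC", ]
    if (nrow(ntc) > 0 &&
        any(!is.na(ntc$fam_ct) & ntc$fam_ct < policy$ntc_fam_floor)) {
      f <- c(f, "NTC_CONTAMINATION")
    }
    for (a in apoe_alleles()) {
      pc <- m[m$role == paste0("POSITIVE_CONTROL_", a) & m$reaction == a, ]
      if (nrow(pc) > 0) {
        ok <- !is.na(pc$hex_ct) & pc$hex_ct <= policy$hex_ceiling
        ok[ok] <- call_allele(
          delta_ct(pc$fam_ct[ok], pc$hex_ct[ok], policy$max_cycles),
          cutoffs[[a]], policy$tie_positive) == "POSITIVE"
        if (!all(ok)) f <- c(f, "POSCTRL_FAIL")
      }
    }
    flags[[p]] <- unique(f)
  }
  flags
}

#' Genotype samples from paired reaction measurements
#'
#' The full calling pipeline: per-reaction delta-Ct, allele calls against
#' the per-reaction cut-offs, QC gating, and combination into a genotype.
#' Control wells (roles `NTC` and `POSITIVE_CONTROL_*`) drive plate-level
#' QC and are not themselves reported as samples.
#'
#' QC flags set per sample: `HEX_FAIL` when any reaction's internal
#' control is undetermined or later than the policy ceiling;
#' `MISSING_REACTION` when fewer than three reactions are present;
#' `NTC_CONTAMINATION` / `POSCTRL_FAIL` when the sample's plate has a
#' contaminated NTC or a failed positive control. Any flag forces
#' `"NO_CALL"`.
#'
#' @param measurements Paired measurements from [pair_channels()].
#' @param cutoffs An [apoe_cutoffs()] set.
#' @param policy A [qc_policy()].
#' @return A tibble with one row per sample: `sample_id`, `dct_e2`,
#'   `dct_e3`, `dct_e4`, `call_e2`, `call_e3`, `call_e4`, `genotype`,
#'   `reason`, `qc_flags` (`;`-joined, empty when clean).
#' @examples
#' m <- tibble::tibble(
#'   plate_id = "P1", well = c("A1", "A2", "A3"), sample_id = "S1",
#'   reaction = c("E2", "E3", "E4"), role = "SAMPLE",
#'   fam_ct = c(26.1, 25.8, NA), hex_ct = c(24.0, 24.1, 23.9)
#' )
#' genotype_samples(m)
#' @export
genotype_samples <- function(measurements, cutoffs = apoe_cutoffs(),
                             policy = qc_policy()) {
  stopifnot(inherits(cutoffs, "apoe_cutoffs"), inherits(policy, "qc_policy"))
  plate_flags <- plate_qc_flags(measurements, cutoffs, policy)
  samples <- measurements |> filter(.data$role == "SAMPLE")
  if (nrow(samples) == 0) {
    return(tibble(sample_id = character(), dct_e2 = double(),
                  dct_e3 = double(), dct_e4 = double(),
                  call_e2 = character(), call_e3 = character(),
                  call_e4 = character(), genotype = character(),
                  reason = character(), qc_flags = character()))
  }
  samples |>
    group_by(.data$sample_id) |>
    group_map(function(m, key) {
      genotype_one(key$sample_id, m, cutoffs, policy, plate_flags)
    }) |>
    list_rbind() |>
    arrange(.data$sample_id)
}

genotype_one <- function(sample_id, m, cutoffs, policy, plate_flags) {
  flags <- character(0)
  for (p in unique(m$plate_id)) flags <- c(flags, plate_flags[[p]])

  dct <- setNames(rep(NA_real_, 3), apoe_alleles())
  calls <- setNames(rep("INVALID", 3), apoe_alleles())
  present <- unique(m$reaction)
  if (length(present) < 3 || nrow(m) != 3) {
    flags <- c(flags, "MISSING_REACTION")
  }
  for (a in intersect(apoe_alleles(), present)) {
    row <- m[m$reaction == a, ][1, ]
    hex_ok <- !is.na(row$hex_ct) && row$hex_ct <= policy$hex_ceiling
    if (!hex_ok) {
      flags <- c(flags, "HEX_FAIL")
      next
    }
    dct[[a]] <- delta_ct(row$fam_ct, row$hex_ct, policy$max_cycles)
    calls[[a]] <- call_allele(dct[[a]], cutoffs[[a]], policy$tie_positive)
  }
  flags <- intersect(QC_FLAGS, unique(flags))  # canonical order
  combined <- combine_calls(calls[["E2"]], calls[["E3"]], calls[["E4"]])
  if (length(flags) > 0) {
    combined$genotype <- NO_CALL
    combined$reason <- paste("QC:", paste(flags, collapse = ";"))
  }
  tibble(sample_id = sample_id,
         dct_e2 = dct[["E2"]], dct_e3 = dct[["E3"]], dct_e4 = dct[["E4"]],
         call_e2 = calls[["E2"]], call_e3 = calls[["E3"]],
         call_e4 = calls[["E4"]],
         genotype = combined$genotype, reason = combined$reason,
         qc_flags = paste(flags, collapse = ";"))
}

#' Translate diploid base calls at rs429358 and rs7412 into an APOE genotype
#'
#' The three common APOE alleles are haplotypes of two coding SNPs:
#' e2 = (rs429358 T, rs7412 T), e3 = (T, C), e4 = (C, C) - i.e. Cys/Arg
#' status at residues 112 and 158. Given unphased diploid base calls at
#' the two sites (e.g. from Sanger sequencing), this returns the genotype
#' consistent with both sites.
#'
#' Two site-genotype combinations deserve care. The double heterozygote
#' (C/T at both sites) is phase-ambiguous between \{e2, e4\} and the rare
#' \{e1, e3\}; it is resolved as `"E2/E4"` with `ambiguous = TRUE`, the
#' population-frequency convention (e1 is vanishingly rare and outside
#' this assay's design space). Combinations that force an e1 = (C, T)
#' haplotype (e.g. C/C at rs429358 with a T at rs7412) return `"NO_CALL"`.
#'
#' @param rs429358,rs7412 Character vectors of unordered diploid base
#'   pairs over \{C, T\}, e.g. `"T/T"`, `"TC"`, `"C/T"` (separator
#'   optional, order ignored).
#' @return A tibble with columns `genotype`, `ambiguous`, `reason`.
#' @examples
#' translate_snp_pair("T/T", "C/C")   # E3/E3
#' translate_snp_pair("T/C", "C/C")   # E3/E4
#' translate_snp_pair("C/T", "C/T")   # E2/E4, ambiguous
#' @export
translate_snp_pair <- function(rs429358, rs7412) {
  n <- length(rs429358)
  stopifnot(length(rs7412) == n)
  g1 <- normalize_site_genotype(rs429358, "rs429358")
  g2 <- normalize_site_genotype(rs7412, "rs7412")
  key <- paste(g1, g2)
  # site genotypes sorted as C-before-T strings; haplotypes e2=(T,T),
  # e3=(T,C), e4=(C,C); e1=(C,T) unsupported by the assay
  map <- c(
    "TT TT" = "E2/E2",  "TT CT" = "E2/E3",  "TT CC" = "E3/E3",
    "CT TT" = "E1",     "CT CT" = "AMBIG",  "CT CC" = "E3/E4",
    "CC TT" = "E1",     "CC CT" = "E1",     "CC CC" = "E4/E4"
  )
  raw <- unname(map[key])
  tibble(
    genotype = case_when(raw == "E1" ~ NO_CALL,
                         raw == "AMBIG" ~ "E2/E4",
                         TRUE ~ raw),
    ambiguous = raw == "AMBIG",
    reason = case_when(
      raw == "E1" ~ "requires the e1 (Arg112, Cys158) haplotype, outside the assay's design space",
      TRUE ~ ""
    )
  )
}

normalize_site_genotype <- function(x, site) {
  bases <- toupper(gsub("[/|: ]", "", x))
  ok <- grepl("^[CT]{2}$", bases)
  if (any(!ok)) {
    abort(paste0("Invalid ", site, " genotype ", dQuote(x[which(!ok)[1]]),
                 "; expected two bases over {C, T}"),
          class = "apoetyper_validation_error")
  }
  map_chr(strsplit(bases, ""), ~ paste(sort(.x), collapse = ""))
}

#' Literature Alzheimer's-disease odds ratios by APOE genotype
#'
#' A read-only lookup of published late-onset Alzheimer's disease odds
#' ratios relative to the e3/e3 reference genotype: protective 0.6 for
#' e2/e2 and e2/e3, 2.6 for e2/e4, 3.2 for e3/e4 and 14.9 for e4/e4.
#' These are literature values attached as annotation, not computed from
#' the data.
#'
#' @param genotype Character vector of genotype labels from
#'   [apoe_genotypes()]; `"NO_CALL"` yields an absent (NA) annotation.
#' @return A tibble with columns `genotype`, `odds_ratio` (`NA` for the
#'   e3/e3 reference and for `NO_CALL`) and `source_note`.
#' @examples
#' annotate_risk(c("E4/E4", "E3/E3", "E2/E3"))
#' @export
annotate_risk <- function(genotype) {
  ors <- c("E2/E2" = 0.6, "E2/E3" = 0.6, "E2/E4" = 2.6,
           "E3/E3" = NA_real_, "E3/E4" = 3.2, "E4/E4" = 14.9)
  known <- genotype %in% c(names(ors), NO_CALL)
  if (any(!known)) {
    abort(paste0("Unknown genotype ", dQuote(genotype[which(!known)[1]])),
          class = "apoetyper_validation_error")
  }
  tibble(
    genotype = genotype,
    odds_ratio = unname(ors[genotype]),
    source_note = case_when(
      genotype == NO_CALL ~ NA_character_,
      genotype == "E3/E3" ~ "reference genotype",
      TRUE ~ "literature AD odds ratio vs E3/E3"
    )
  )
}
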