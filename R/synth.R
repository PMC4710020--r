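# Synthetic qPCR cohort generator.
#
# Emulates the Ct-level behaviour the assay assumes: every reaction's ACTB
# internal control (HEX) amplifies near a common cycle; an allele-positive
# reaction's FAM signal follows the HEX signal by a small offset (so
# delta-Ct is small); an allele-negative reaction usually gives no FAM
# curve at all and otherwise a very late non-specific one. The generator
# draws genotypes from cohort proportions, writes a plate export in the
# package's well-record schema, and emits a sequencing-truth table whose
# rs429358/rs7412 base pairs are consistent with each generated genotype
# by construction.

#' Noise model for synthetic qPCR cohorts
#'
#' All parameters are invented (the assay's Ct distributions are not
#' published) and chosen so that allele-positive delta-Ct stays well below
#' and allele-negative delta-Ct well above every published cut-off, the
#' operating regime the assay reports. Positive reactions: FAM = HEX +
#' Normal(`pos_offset_mu`, `pos_offset_sd`). Negative reactions: FAM is
#' undetermined with probability `neg_dropout_prob`, otherwise a late
#' non-specific Normal(`late_mu`, `late_sd`) truncated to
#' `(HEX, max_cycles]`. The late-amplification parameters sit close to the
#' cycle ceiling (38.5 +/- 0.5) so that residual non-specific signal never
#' mimics true allele amplification - the separation the published
#' cut-offs presuppose.
#'
#' @param hex_mu,hex_sd ACTB internal-control Ct distribution (cycles).
#' @param pos_offset_mu,pos_offset_sd FAM-minus-HEX offset for
#'   allele-positive reactions (cycles).
#' @param neg_dropout_prob Probability that an allele-negative reaction
#'   shows no FAM amplification at all.
#' @param late_mu,late_sd Ct distribution of late non-specific FAM
#'   amplification in negative reactions (cycles).
#' @param max_cycles Cycle ceiling of the run.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(hex_mu = 24, hex_sd = 0.3,
                        pos_offset_mu = 2, pos_offset_sd = 0.5,
                        neg_dropout_prob = 0.95,
                        late_mu = 38.5, late_sd = 0.5,
                        max_cycles = 40) {
  stopifnot(hex_sd >= 0, pos_offset_sd >= 0, late_sd >= 0,
            neg_dropout_prob >= 0, neg_dropout_prob <= 1,
            late_mu < max_cycles)
  structure(list(hex_mu = hex_mu, hex_sd = hex_sd,
                 pos_offset_mu = pos_offset_mu, pos_offset_sd = pos_offset_sd,
                 neg_dropout_prob = neg_dropout_prob,
                 late_mu = late_mu, late_sd = late_sd,
                 max_cycles = max_cycles),
            class = "noise_model")
}

#' Default genotype proportions for simulated cohorts
#'
#' The six-genotype proportions of the 1158-sample Chinese Han cohort
#' (counts 7, 153, 16, 814, 163, 5 for E2/E2 ... E4/E4), used as the
#' default sampling distribution.
#'
#' @return A named numeric vector over [apoe_genotypes()] summing to 1.
#' @export
apoe_genotype_freqs <- function() {
  counts <- c(7, 153, 16, 814, 163, 5)
  setNames(counts / sum(counts), apoe_genotypes())
}

# genotype label -> the two haplotype alleles
genotype_alleles <- function(genotype) {
  strsplit(genotype, "/", fixed = TRUE)
}

# haplotypes: e2 = (T, T), e3 = (T, C), e4 = (C, C) at (rs429358, rs7412)
HAPLOTYPE_BASES <- list(E2 = c("T", "T"), E3 = c("T", "C"), E4 = c("C", "C"))

# genotype -> unordered diploid base calls at the two sites, written with
# the bases in alphabetical order ("C/T", never "T/C")
genotype_to_snp_pair <- function(genotype) {
  out <- map(genotype_alleles(genotype), function(al) {
    b1 <- sort(c(HAPLOTYPE_BASES[[al[1]]][1], HAPLOTYPE_BASES[[al[2]]][1]))
    b2 <- sort(c(HAPLOTYPE_BASES[[al[1]]][2], HAPLOTYPE_BASES[[al[2]]][2]))
    c(paste(b1, collapse = "/"), paste(b2, collapse = "/"))
  })
  tibble(rs429358 = map_chr(out, 1), rs7412 = map_chr(out, 2))
}

#' Simulate the three reaction measurements of one sample
#'
#' For each of the three allele-specific reactions: HEX ~ Normal(hex_mu,
#' hex_sd); if the reaction's allele is part of the genotype, FAM = HEX +
#' Normal(pos_offset_mu, pos_offset_sd); otherwise FAM is undetermined
#' (`NA`) with probability `neg_dropout_prob`, else a late non-specific
#' Ct drawn from Normal(late_mu, late_sd) truncated to `(HEX, max_cycles]`
#' by rejection (bounded retries, then dropout).
#'
#' Uses the current RNG state; seed upstream (see [simulate_cohort()]).
#'
#' @param genotype One of [apoe_genotypes()].
#' @param model A [noise_model()].
#' @return A tibble with three rows: `reaction`, `fam_ct`, `hex_ct`.
#' @export
simulate_sample <- function(genotype, model = noise_model()) {
  stopifnot(genotype %in% apoe_genotypes())
  alleles_in <- genotype_alleles(genotype)[[1]]
  hex <- rnorm(3, model$hex_mu, model$hex_sd)
  fam <- numeric(3)
  for (i in 1:3) {
    a <- apoe_alleles()[i]
    if (a %in% alleles_in) {
      fam[i] <- hex[i] + rnorm(1, model$pos_offset_mu, model$pos_offset_sd)
    } else if (stats::runif(1) < model$neg_dropout_prob) {
      fam[i] <- NA_real_
    } else {
      fam[i] <- rtrunc_late(model, hex[i])
    }
  }
  tibble(reaction = apoe_alleles(), fam_ct = fam, hex_ct = hex)
}

# truncated-normal late Ct by rejection; falls back to dropout (NA)
rtrunc_late <- function(model, lower, retries = 100) {
  for (i in seq_len(retries)) {
    x <- rnorm(1, model$late_mu, model$late_sd)
    if (x > lower && x <= model$max_cycles) return(x)
  }
  NA_real_
}

#' Simulate a full qPCR cohort with sequencing truth
#'
#' Draws `n` genotypes from `genotype_freqs`, simulates each sample's
#' three reactions, lays the wells out on 96-well plates (three wells per
#' sample, FAM + HEX rows per well) and returns both the plate export (in
#' the [read_plate()] schema) and a truth table whose rs429358/rs7412
#' diploid base calls are derived from the generating genotype, so
#' [translate_snp_pair()] recovers it by construction.
#'
#' With `include_controls`, each plate carries one positive-control well
#' per allele (the allele's plasmid template in its own reaction) and one
#' NTC well per reaction; control wells use plate-scoped pseudo-sample
#' ids and carry the corresponding `role`.
#'
#' @param n Number of samples.
#' @param genotype_freqs Named sampling proportions over
#'   [apoe_genotypes()].
#' @param seed Integer seed; identical `n`/`freqs`/`model`/`seed` give
#'   identical output.
#' @param model A [noise_model()].
#' @param include_controls Add control wells per plate.
#' @return A list with `plate` (well-record tibble) and `truth` (tibble
#'   of `sample_id`, `rs429358`, `rs7412`, `genotype`).
#' @examples
#' sim <- simulate_cohort(n = 5, seed = 1)
#' sim$truth
#' @export
simulate_cohort <- function(n, genotype_freqs = apoe_genotype_freqs(),
                            seed = NULL, model = noise_model(),
                            include_controls = TRUE) {
  stopifnot(n >= 1, abs(sum(genotype_freqs) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  genotype_freqs <- genotype_freqs[apoe_genotypes()]
  genotypes <- sample(apoe_genotypes(), n, replace = TRUE,
                      prob = genotype_freqs)
  sample_ids <- sprintf("S%04d", seq_len(n))

  # plate layout: 96 wells, 6 reserved for controls, 3 wells per sample
  per_plate <- if (include_controls) 30L else 32L
  plate_of <- (seq_len(n) - 1L) %/% per_plate + 1L
  slot_of <- (seq_len(n) - 1L) %% per_plate

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- simulate_sample(genotypes[i], model)
    offset <- if (include_controls) 6L else 0L
    wells <- well_label(offset + slot_of[i] * 3L + 0:2)
    rows[[i]] <- tibble(
      plate_id = paste0("P", plate_of[i]),
      well = wells,
      sample_id = sample_ids[i],
      reaction = m$reaction,
      fam_ct = m$fam_ct,
      hex_ct = m$hex_ct,
      role = "SAMPLE"
    )
  }
  plate <- list_rbind(rows)

  if (include_controls) {
    ctrl <- map(unique(plate_of), function(p) {
      pid <- paste0("P", p)
      pos <- imap(setNames(apoe_alleles(), apoe_alleles()), function(a, nm) {
        m <- simulate_sample(paste(a, a, sep = "/"), model) |>
          filter(.data$reaction == a)
        tibble(plate_id = pid, well = well_label(match(a, apoe_alleles()) - 1L),
               sample_id = paste0(pid, "_PC_", a), reaction = a,
               fam_ct = m$fam_ct, hex_ct = m$hex_ct,
               role = paste0("POSITIVE_CONTROL_", a))
      }) |> list_rbind()
      ntc <- tibble(plate_id = pid,
                    well = well_label(3:5),
                    sample_id = paste0(pid, "_NTC"),
                    reaction = apoe_alleles(),
                    fam_ct = NA_real_, hex_ct = NA_real_,
                    role = "NTC")
      bind_rows(pos, ntc)
    }) |> list_rbind()
    plate <- bind_rows(ctrl, plate)
  }

  # long format: one row per channel
  plate_long <- plate |>
    tidyr::pivot_longer(c("fam_ct", "hex_ct"), names_to = "channel",
                        values_to = "ct") |>
    mutate(channel = ifelse(.data$channel == "fam_ct", "FAM", "HEX")) |>
    select("plate_id", "well", "sample_id", "reaction", "channel",
           "ct", "role")

  truth <- bind_cols(tibble(sample_id = sample_ids),
                     genotype_to_snp_pair(genotypes)) |>
    mutate(genotype = genotypes)
  list(plate = as_well_records(plate_long, max_cycles = model$max_cycles),
       truth = truth)
}

# 0-based well index -> plate coordinate label (row-major on 12 columns)
well_label <- function(idx) {
  paste0(LETTERS[idx %/% 12L + 1L], idx %% 12L + 1L)
}

#' Write a simulated cohort to plate-export and truth files
#'
#' @param sim A list from [simulate_cohort()].
#' @param plate_file,truth_file Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(sim, plate_file, truth_file) {
  plate <- sim$plate |>
    rename(plate = "plate_id", sample = "sample_id") |>
    mutate(ct = ifelse(is.na(.data$ct), "Undetermined",
                       sprintf("%.4f", .data$ct)))
  readr::write_csv(plate, plate_file, na = "")
  readr::write_csv(sim$truth, truth_file, na = "")
  invisible(c(plate_file, truth_file))
}
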