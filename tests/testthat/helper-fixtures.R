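# Fixture builders and independent oracles used across the suite.
# Oracles are deliberately naive re-derivations, kept separate from the
# implementation paths they check.

# -- fixtures -----------------------------------------------------------

# one sample's three paired measurements with chosen delta-Ct values
# (hex fixed, fam = hex + dct; dct = NA means undetermined FAM)
make_measurements <- function(dct_e2, dct_e3, dct_e4, sample_id = "S1",
                              hex = 24, plate_id = "P1") {
  dct <- c(dct_e2, dct_e3, dct_e4)
  tibble::tibble(
    plate_id = plate_id,
    well = paste0("A", 1:3),
    sample_id = sample_id,
    reaction = c("E2", "E3", "E4"),
    role = "SAMPLE",
    fam_ct = ifelse(is.na(dct), NA_real_, hex + dct),
    hex_ct = hex
  )
}

# well-record rows (long format) for one well
make_well_rows <- function(plate = "P1", well = "A1", sample = "S1",
                           reaction = "E2", fam = 26, hex = 24,
                           role = "SAMPLE") {
  tibble::tibble(
    plate_id = plate, well = well, sample_id = sample, reaction = reaction,
    channel = c("FAM", "HEX"), ct = c(fam, hex), role = role
  )
}

write_plate_csv <- function(df, path,
                            header = c("plate", "well", "sample", "reaction",
                                       "channel", "ct", "role")) {
  names(df) <- header
  readr::write_csv(df, path)
  path
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# -- ROC oracle ---------------------------------------------------------

# AUC by explicit pair counting: positives score LOW, so credit a (pos,
# neg) pair when score_pos < score_neg, half for ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p < q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# best Youden threshold by brute-force scan over the same candidate set,
# recomputing sensitivity/specificity from first principles
oracle_youden <- function(scores, labels) {
  s <- sort(unique(scores))
  cands <- c(s[1] - 1, if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
             s[length(s)] + 1)
  j <- vapply(cands, function(t) {
    mean(scores[labels] <= t) + mean(scores[!labels] > t) - 1
  }, numeric(1))
  max(cands[j == max(j)])
}

# -- primer-site oracle -------------------------------------------------

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(unname(comp[strsplit(x, "")[[1]]])), collapse = "")
}

# naive per-offset scan with character vectors
oracle_primer_sites <- function(primer, template, clamp_len = 3, max_mm = 1) {
  tv <- strsplit(template, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else oracle_revcomp(primer)
    pv <- strsplit(pat, "")[[1]]
    m <- length(pv)
    if (m > length(tv)) next
    # clamp = primer 3' end: footprint end on "+", footprint start on "-"
    clamp_idx <- if (strand == "+") (m - clamp_len + 1):m else 1:clamp_len
    for (off in 0:(length(tv) - m)) {
      mm <- pv != tv[(off + 1):(off + m)]
      if (any(mm[clamp_idx])) next
      outside <- sum(mm[-clamp_idx])
      if (outside <= max_mm) {
        hits[[length(hits) + 1]] <-
          tibble::tibble(position = off, strand = strand,
                         mismatches = as.integer(outside))
      }
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) {
    return(tibble::tibble(position = integer(), strand = character(),
                          mismatches = integer()))
  }
  dplyr::arrange(out, position, strand)
}

# -- Hardy-Weinberg oracles --------------------------------------------

# genotype index helpers: order E2/E2, E2/E3, E2/E4, E3/E3, E3/E4, E4/E4
oracle_pair_to_index <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "/")
  match(key, c("E2/E2", "E2/E3", "E2/E4", "E3/E3", "E3/E4", "E4/E4"))
}

oracle_allele_margin <- function(counts) {
  c(2 * counts[1] + counts[2] + counts[3],
    counts[2] + 2 * counts[4] + counts[5],
    counts[3] + counts[5] + 2 * counts[6])
}

# Exact conditional distribution by full enumeration of perfect matchings
# of labelled allele copies (feasible for n <= 5). Returns the p-value of
# `counts` under probability ordering.
oracle_hwe_matchings <- function(counts) {
  margins <- oracle_allele_margin(counts)
  tokens <- rep(c("E2", "E3", "E4"), margins)
  table_counts <- new.env()
  recurse <- function(remaining, tab) {
    if (length(remaining) == 0) {
      key <- paste(tab, collapse = ",")
      cur <- mget(key, envir = table_counts, ifnotfound = 0)[[1]]
      assign(key, cur + 1, envir = table_counts)
      return(invisible())
    }
    first <- remaining[1]
    rest <- remaining[-1]
    for (j in seq_along(rest)) {
      tab2 <- tab
      idx <- oracle_pair_to_index(first, rest[j])
      tab2[idx] <- tab2[idx] + 1
      recurse(rest[-j], tab2)
    }
  }
  recurse(tokens, rep(0, 6))
  keys <- ls(table_counts)
  freq <- vapply(keys, function(k) get(k, envir = table_counts), numeric(1))
  prob <- freq / sum(freq)
  obs_key <- paste(counts, collapse = ",")
  p_obs <- prob[[obs_key]]
  sum(prob[prob <= p_obs * (1 + 1e-9)])
}

# Exact conditional p-value for n <= ~20 by enumeration over HOMOZYGOTE
# counts (heterozygote counts are then determined by the allele margins),
# with table probabilities from exact factorials. Structurally different
# from both the implementation (loops over heterozygotes) and the
# matching oracle above.
oracle_hwe_exact <- function(counts) {
  margins <- oracle_allele_margin(counts)
  n <- sum(counts)
  prob_of <- function(tab) {
    het <- tab[2] + tab[3] + tab[5]
    factorial(n) / prod(factorial(tab)) * 2^het *
      prod(factorial(margins)) / factorial(2 * n)
  }
  tabs <- list()
  for (n22 in 0:(margins[1] %/% 2)) {
    for (n33 in 0:(margins[2] %/% 2)) {
      for (n44 in 0:(margins[3] %/% 2)) {
        r2 <- margins[1] - 2 * n22
        r3 <- margins[2] - 2 * n33
        r4 <- margins[3] - 2 * n44
        # r2 = n23 + n24, r3 = n23 + n34, r4 = n24 + n34
        n23 <- (r2 + r3 - r4) / 2
        n24 <- (r2 + r4 - r3) / 2
        n34 <- (r3 + r4 - r2) / 2
        if (n23 < 0 || n24 < 0 || n34 < 0) next
        if (n23 != round(n23) || n24 != round(n24) || n34 != round(n34)) next
        tabs[[length(tabs) + 1]] <- c(n22, n23, n24, n33, n34, n44)
      }
    }
  }
  probs <- vapply(tabs, prob_of, numeric(1))
  p_obs <- prob_of(counts)
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# random genotype-count table with n samples
random_genotype_table <- function(n) {
  as.integer(table(factor(sample.int(6, n, replace = TRUE), levels = 1:6)))
}
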