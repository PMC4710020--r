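# Cohort genotype counting, allele frequencies, Hardy-Weinberg testing and
# caller-vs-truth concordance.

#' Summarise a cohort of genotype calls
#'
#' Counts the six APOE genotypes, derives allele counts (a homozygote
#' contributes 2 copies of its allele, a heterozygote 1 of each) and
#' allele frequencies as 100 * count / (2n), printed to 2 decimals by
#' largest-remainder rounding so the three frequencies sum to exactly
#' 100.00 - the convention of published allele-frequency tables.
#' `NO_CALL` entries are excluded from the denominators and reported in
#' `n_no_call`.
#'
#' @param genotypes Character vector of genotype labels
#'   ([apoe_genotypes()] or `"NO_CALL"`).
#' @param cohort_name Label for the cohort row.
#' @return A one-row tibble of class `apoe_cohort_summary`: `cohort`, `n`,
#'   `n_no_call`, the six genotype counts (`n_e2e2` ... `n_e4e4`), allele
#'   counts (`alleles_e2`, `alleles_e3`, `alleles_e4`) and frequencies in
#'   percent (`freq_e2`, `freq_e3`, `freq_e4`).
#' @examples
#' summarize_cohort(c("E3/E3", "E3/E4", "E2/E3"), "demo")
#' @export
summarize_cohort <- function(genotypes, cohort_name = "cohort") {
  if (length(genotypes) == 0) {
    abort("Cannot summarise an empty cohort",
          class = "apoetyper_validation_error")
  }
  known <- genotypes %in% c(apoe_genotypes(), NO_CALL)
  if (any(!known)) {
    abort(paste0("Unknown genotype ", dQuote(genotypes[which(!known)[1]])),
          class = "apoetyper_validation_error")
  }
  called <- genotypes[genotypes != NO_CALL]
  counts <- table(factor(called, levels = apoe_genotypes()))
  cohort_from_counts(as.integer(counts), cohort_name,
                     n_no_call = sum(genotypes == NO_CALL))
}

#' Build a cohort summary directly from genotype counts
#'
#' Accepts the six genotype counts in the order of [apoe_genotypes()]
#' (E2/E2, E2/E3, E2/E4, E3/E3, E3/E4, E4/E4) - the shape of a published
#' cohort table row - and computes allele counts and frequencies.
#'
#' @param counts Integer vector of six genotype counts, optionally named
#'   by genotype.
#' @param cohort_name Label for the cohort row.
#' @param n_no_call Number of samples excluded as `NO_CALL`.
#' @return A one-row `apoe_cohort_summary` tibble; see
#'   [summarize_cohort()].
#' @examples
#' cohort_from_counts(c(7, 153, 16, 814, 163, 5), "total")
#' @export
cohort_from_counts <- function(counts, cohort_name = "cohort", n_no_call = 0L) {
  stopifnot(length(counts) == 6, all(counts >= 0), all(counts == round(counts)))
  if (!is.null(names(counts))) {
    stopifnot(setequal(names(counts), apoe_genotypes()))
    counts <- counts[apoe_genotypes()]
  }
  counts <- as.integer(counts)
  n <- sum(counts)
  alleles <- unname(allele_counts_from_genotype_counts(counts))
  freq <- if (n > 0) round_percentages(100 * alleles / (2 * n)) else rep(NA_real_, 3)
  out <- tibble(
    cohort = cohort_name, n = n, n_no_call = as.integer(n_no_call),
    n_e2e2 = counts[1], n_e2e3 = counts[2], n_e2e4 = counts[3],
    n_e3e3 = counts[4], n_e3e4 = counts[5], n_e4e4 = counts[6],
    alleles_e2 = alleles[1], alleles_e3 = alleles[2], alleles_e4 = alleles[3],
    freq_e2 = freq[1], freq_e3 = freq[2], freq_e4 = freq[3]
  )
  class(out) <- c("apoe_cohort_summary", class(out))
  out
}

# Round a percentage vector to 2 decimals by largest remainder, so the
# printed frequencies sum to exactly 100.00 - the convention of published
# allele-frequency tables. Ties in remainder break toward the earlier
# allele.
round_percentages <- function(pct, digits = 2) {
  p <- 10^digits
  floor_pct <- floor(pct * p) / p
  deficit <- round((100 - sum(floor_pct)) * p)
  if (deficit > 0) {
    order_by_remainder <- order(-(pct - floor_pct))
    bump <- order_by_remainder[seq_len(deficit)]
    floor_pct[bump] <- floor_pct[bump] + 1 / p
  }
  round(floor_pct, digits)
}

# genotype counts (6, apoe_genotypes() order) -> allele copy counts (E2, E3, E4)
allele_counts_from_genotype_counts <- function(counts) {
  c(E2 = 2L * counts[1] + counts[2] + counts[3],
    E3 = counts[2] + 2L * counts[4] + counts[5],
    E4 = counts[3] + counts[5] + 2L * counts[6])
}

#' Merge cohort summaries into a combined row
#'
#' Counts add across cohorts and the allele frequencies are recomputed
#' from the merged counts (never averaged), reproducing the "Total" row
#' of a multi-site cohort table.
#'
#' @param summaries A tibble of cohort summary rows (e.g. from
#'   `dplyr::bind_rows()` of [summarize_cohort()] outputs), or a list of
#'   such rows.
#' @param cohort_name Label for the merged row.
#' @return A one-row `apoe_cohort_summary` tibble.
#' @examples
#' a <- summarize_cohort(c("E3/E3", "E3/E4"), "site1")
#' b <- summarize_cohort(c("E2/E3"), "site2")
#' merge_summaries(dplyr::bind_rows(a, b), "total")
#' @export
merge_summaries <- function(summaries, cohort_name = "total") {
  if (is.list(summaries) && !is.data.frame(summaries)) {
    summaries <- bind_rows(summaries)
  }
  if (nrow(summaries) == 0) {
    abort("Cannot merge an empty list of summaries",
          class = "apoetyper_validation_error")
  }
  counts <- c(sum(summaries$n_e2e2), sum(summaries$n_e2e3),
              sum(summaries$n_e2e4), sum(summaries$n_e3e3),
              sum(summaries$n_e3e4), sum(summaries$n_e4e4))
  cohort_from_counts(counts, cohort_name,
                     n_no_call = sum(summaries$n_no_call))
}

#' Hardy-Weinberg equilibrium test for the three-allele APOE system
#'
#' For cohorts up to `exact_max_n` samples, an exact conditional test:
#' all six-genotype tables with the observed allele counts are enumerated
#' and the p-value is the total conditional probability (Levene's
#' distribution, which weights a table by its number of distinct allele
#' pairings) of tables no more probable than the observed one. Larger
#' cohorts fall back to a chi-square test of the six observed counts
#' against their Hardy-Weinberg expectations with 3 degrees of freedom
#' (6 categories - 2 free allele frequencies - 1).
#'
#' A monomorphic cohort carries no information about random mating and
#' returns p = 1 with a note.
#'
#' @param genotype_counts Six genotype counts in [apoe_genotypes()] order
#'   (optionally named).
#' @param exact_max_n Largest cohort size for the exact test.
#' @return A list of class `apoe_hwe`: `method` (`"exact"` or
#'   `"chi_square"`), `p_value`, `expected` (named Hardy-Weinberg
#'   expected counts), `statistic` (chi-square only), `note`.
#' @examples
#' hwe_test(c(1, 2, 0, 1, 0, 0))
#' @export
hwe_test <- function(genotype_counts, exact_max_n = 200) {
  stopifnot(length(genotype_counts) == 6, all(genotype_counts >= 0))
  if (!is.null(names(genotype_counts))) {
    stopifnot(setequal(names(genotype_counts), apoe_genotypes()))
    genotype_counts <- genotype_counts[apoe_genotypes()]
  }
  counts <- as.integer(genotype_counts)
  n <- sum(counts)
  if (n < 1) {
    abort("Hardy-Weinberg test needs at least one sample",
          class = "apoetyper_validation_error")
  }
  alleles <- allele_counts_from_genotype_counts(counts)
  p <- alleles / (2 * n)
  expected <- c(n * p[1]^2, 2 * n * p[1] * p[2], 2 * n * p[1] * p[3],
                n * p[2]^2, 2 * n * p[2] * p[3], n * p[3]^2)
  names(expected) <- apoe_genotypes()
  if (sum(alleles > 0) <= 1) {
    return(structure(list(method = "exact", p_value = 1, expected = expected,
                          statistic = NA_real_,
                          note = "monomorphic cohort: test degenerate"),
                     class = "apoe_hwe"))
  }
  if (n <= exact_max_n) {
    pval <- hwe_exact_pvalue(counts, alleles)
    structure(list(method = "exact", p_value = pval, expected = expected,
                   statistic = NA_real_, note = ""),
              class = "apoe_hwe")
  } else {
    keep <- expected > 0
    stat <- sum((counts[keep] - expected[keep])^2 / expected[keep])
    structure(list(method = "chi_square",
                   p_value = pchisq(stat, df = 3, lower.tail = FALSE),
                   expected = expected, statistic = stat, note = ""),
              class = "apoe_hwe")
  }
}

# Exact conditional p-value: enumerate every genotype table with the given
# allele counts. Conditional log-probability of a table (Levene):
#   log P = log n! - sum log n_ij! + H log 2 + sum log c_i! - log (2n)!
# with H the number of heterozygous samples. The constant terms cancel in
# the ordering, but are kept so probabilities sum to 1 (checked in tests).
hwe_exact_pvalue <- function(counts, alleles) {
  tabs <- hwe_enumerate_tables(alleles)
  logp <- hwe_table_logprob(tabs, alleles)
  obs <- match(paste(counts, collapse = ","),
               apply(tabs, 1, paste, collapse = ","))
  # observed table is always enumerable by construction
  tol <- 1e-9
  sum(exp(logp[logp <= logp[obs] + tol]))
}

# All (n22, n23, n24, n33, n34, n44) tables with allele margins `alleles`
# (copies of E2, E3, E4). Free loop over the three heterozygote counts;
# homozygote counts are fixed by the margins and must be non-negative even
# remainders.
hwe_enumerate_tables <- function(alleles) {
  c2 <- alleles[1]; c3 <- alleles[2]; c4 <- alleles[3]
  out <- list()
  k <- 0
  for (n23 in 0:min(c2, c3)) {
    for (n24 in 0:min(c2 - n23, c4)) {
      r2 <- c2 - n23 - n24
      if (r2 %% 2 != 0) next
      n34_max <- min(c3 - n23, c4 - n24)
      if (n34_max < 0) next
      n34 <- 0:n34_max
      r3 <- c3 - n23 - n34
      r4 <- c4 - n24 - n34
      ok <- r3 %% 2 == 0 & r4 %% 2 == 0 & r3 >= 0 & r4 >= 0
      if (!any(ok)) next
      k <- k + 1
      out[[k]] <- cbind(r2 / 2, n23, n24, r3[ok] / 2, n34[ok], r4[ok] / 2)
    }
  }
  m <- do.call(rbind, out)
  colnames(m) <- apoe_genotypes()
  m
}

hwe_table_logprob <- function(tabs, alleles) {
  n <- sum(alleles) / 2
  het <- tabs[, 2] + tabs[, 3] + tabs[, 5]
  lgamma(n + 1) - rowSums(lgamma(tabs + 1)) + het * log(2) +
    sum(lgamma(alleles + 1)) - lgamma(2 * n + 1)
}

#' @export
print.apoe_hwe <- function(x, ...) {
  cat("Hardy-Weinberg ", x$method, " test: p = ",
      format(x$p_value, digits = 4), "\n", sep = "")
  if (nzchar(x$note)) cat(x$note, "\n")
  invisible(x)
}

#' Concordance between called and truth genotypes
#'
#' Exact-match comparison of two aligned genotype vectors (e.g. the
#' qPCR calls against sequencing-derived truth). `NO_CALL` in either
#' vector counts as discordant and is tallied separately; discordant
#' pairs are cross-tabulated.
#'
#' @param called,truth Equal-length character vectors of genotype labels,
#'   aligned by sample.
#' @return A list of class `apoe_concordance`: `n_compared`,
#'   `n_concordant`, `concordance_pct` (half-up, 2 decimals),
#'   `n_no_call_called`, `n_no_call_truth`, `discordance` (tibble of
#'   mismatched `called`/`truth` pairs with counts).
#' @examples
#' concordance(c("E3/E3", "E3/E4"), c("E3/E3", "E3/E3"))
#' @export
concordance <- function(called, truth) {
  if (length(called) != length(truth)) {
    abort("called and truth must have the same length (aligned by sample)",
          class = "apoetyper_validation_error")
  }
  if (length(called) == 0) {
    abort("Cannot compute concordance on an empty cohort",
          class = "apoetyper_validation_error")
  }
  match_ok <- called == truth & called != NO_CALL
  disc <- tibble(called = called, truth = truth)[!match_ok, ] |>
    count(.data$called, .data$truth, name = "count")
  structure(
    list(n_compared = length(called),
         n_concordant = sum(match_ok),
         concordance_pct = round_half_up(100 * mean(match_ok), 2),
         n_no_call_called = sum(called == NO_CALL),
         n_no_call_truth = sum(truth == NO_CALL),
         discordance = disc),
    class = "apoe_concordance")
}

#' @export
print.apoe_concordance <- function(x, ...) {
  cat("Concordance: ", x$n_concordant, "/", x$n_compared, " (",
      sprintf("%.2f", x$concordance_pct), "%)\n", sep = "")
  if (nrow(x$discordance) > 0) print(x$discordance)
  invisible(x)
}

#' Plot a cohort summary as an allele-frequency bar chart
#'
#' @param object An `apoe_cohort_summary` tibble (one or more rows).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apoe_cohort_summary
#' @export
autoplot.apoe_cohort_summary <- function(object, ...) {
  long <- as_tibble(object) |>
    select("cohort", "freq_e2", "freq_e3", "freq_e4") |>
    tidyr::pivot_longer(-"cohort", names_to = "allele",
                        names_prefix = "freq_",
                        values_to = "frequency") |>
    mutate(allele = toupper(.data$allele))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$allele, y = .data$frequency,
                                     fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "APOE allele", y = "Frequency (%)", fill = "Cohort") +
    ggplot2::theme_minimal()
}
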