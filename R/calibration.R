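# ROC re-calibration of the per-reaction delta-Ct cut-offs.
#
# Allele-positive reactions have LOW delta-Ct, so the ROC is computed with
# "score <= threshold" as the positive prediction. Candidate thresholds are
# midpoints between consecutive distinct observed delta-Ct values plus one
# sentinel below the minimum and one above the maximum, which makes the
# selected cut-off independent of instrument reporting precision.

#' Compute a ROC curve over delta-Ct values
#'
#' Builds the ROC curve for a set of delta-Ct scores with boolean
#' allele-present labels, treating low scores as positive: sensitivity at
#' threshold t is P(score <= t | positive) and specificity is
#' P(score > t | negative). The AUC is the Mann-Whitney statistic
#' P(score_pos < score_neg) with half credit for ties.
#'
#' @param scores Numeric vector of delta-Ct values (finite).
#' @param labels Logical vector, `TRUE` = allele present (by sequencing).
#' @return An object of class `apoe_roc`: a list with `points` (tibble of
#'   `threshold`, `sensitivity`, `specificity`, `youden_j`), `auc`,
#'   `n_pos`, `n_neg`.
#' @examples
#' roc <- roc_points(c(1, 2, 13, 14), c(TRUE, TRUE, FALSE, FALSE))
#' roc$auc
#' @export
roc_points <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            is.logical(labels), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort(paste0("ROC needs both classes; no ",
                 if (n_pos == 0) "positive" else "negative",
                 " labels present"),
          class = "apoetyper_calibration_error")
  }
  s <- sort(unique(scores))
  thresholds <- c(s[1] - 1,
                  if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
                  s[length(s)] + 1)
  sens <- map_dbl(thresholds, ~ mean(scores[labels] <= .x))
  spec <- map_dbl(thresholds, ~ mean(scores[!labels] > .x))
  # AUC via midranks: U counts (neg, pos) pairs with score_neg > score_pos,
  # ties at half weight
  r <- rank(scores)
  u <- sum(r[!labels]) - n_neg * (n_neg + 1) / 2
  auc <- u / (n_pos * n_neg)
  structure(
    list(points = tibble(threshold = thresholds, sensitivity = sens,
                         specificity = spec,
                         youden_j = sens + spec - 1),
         auc = auc, n_pos = n_pos, n_neg = n_neg),
    class = "apoe_roc")
}

#' Select a delta-Ct cut-off from a ROC curve
#'
#' The default criterion is Youden's J = sensitivity + specificity - 1,
#' the standard ROC operating-point optimum; `"min_specificity"` instead
#' picks the largest threshold whose specificity is at least
#' `target_specificity` (largest = most sensitive, since positives are
#' low). Ties in J are broken toward the larger threshold, favouring
#' sensitivity for allele detection.
#'
#' @param curve An `apoe_roc` from [roc_points()].
#' @param criterion `"youden"` or `"min_specificity"`.
#' @param target_specificity Floor used by `"min_specificity"`.
#' @return The selected threshold (delta-Ct cycles). A curve with no
#'   discrimination (max J = 0) returns the largest candidate with a
#'   warning.
#' @export
select_cutoff <- function(curve, criterion = c("youden", "min_specificity"),
                          target_specificity = 0.95) {
  stopifnot(inherits(curve, "apoe_roc"))
  criterion <- match.arg(criterion)
  pts <- curve$points
  if (criterion == "youden") {
    if (max(pts$youden_j) <= 0) {
      warn("Degenerate ROC curve: no threshold discriminates the classes")
    }
    best <- pts$threshold[pts$youden_j == max(pts$youden_j)]
    return(max(best))
  }
  eligible <- pts$threshold[pts$specificity >= target_specificity]
  if (length(eligible) == 0) {
    abort("No threshold reaches the requested specificity",
          class = "apoetyper_calibration_error")
  }
  max(eligible)
}

#' Label per-reaction delta-Ct values with sequencing truth
#'
#' Converts a merged training table (one row per sample per reaction with
#' FAM/HEX Ct and the two SNP genotypes) into labelled delta-Ct records:
#' the label is whether the reaction's allele appears in the genotype
#' derived from the rs429358/rs7412 calls via [translate_snp_pair()],
#' never asserted manually.
#'
#' @param training Data frame with columns `sample_id`, `reaction`,
#'   `fam_ct`, `hex_ct`, `rs429358`, `rs7412`.
#' @param max_cycles Ceiling substituted for undetermined FAM.
#' @return Tibble with `sample_id`, `reaction`, `delta_ct`,
#'   `allele_present`, `truth_genotype`.
#' @export
label_delta_ct <- function(training, max_cycles = 40) {
  needed <- c("sample_id", "reaction", "fam_ct", "hex_ct", "rs429358", "rs7412")
  missing <- setdiff(needed, names(training))
  if (length(missing) > 0) {
    abort(paste0("Training table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "apoetyper_format_error")
  }
  truth <- training |>
    distinct(.data$sample_id, .data$rs429358, .data$rs7412)
  if (anyDuplicated(truth$sample_id)) {
    abort("Conflicting SNP genotypes for one sample in the training table",
          class = "apoetyper_validation_error")
  }
  truth$truth_genotype <-
    translate_snp_pair(truth$rs429358, truth$rs7412)$genotype
  if (any(truth$truth_genotype == NO_CALL)) {
    abort("Training truth contains genotypes outside the assay's design space",
          class = "apoetyper_validation_error")
  }
  training |>
    left_join(truth[c("sample_id", "truth_genotype")], by = "sample_id") |>
    mutate(
      delta_ct = delta_ct(.data$fam_ct, .data$hex_ct, max_cycles),
      allele_present = map2_lgl(.data$reaction, .data$truth_genotype,
                                ~ grepl(.x, .y, fixed = TRUE))
    ) |>
    select("sample_id", "reaction", "delta_ct", "allele_present",
           "truth_genotype")
}

#' Calibrate the three per-reaction cut-offs from labelled training data
#'
#' Re-implements the assay's calibration: per reaction, a ROC curve over
#' the training delta-Ct values (labels from sequencing truth) and a
#' cut-off selected by the chosen criterion (Youden's J by default).
#'
#' @inheritParams label_delta_ct
#' @inheritParams select_cutoff
#' @return An object of class `apoe_calibration`: list with `cutoffs`
#'   (an [apoe_cutoffs()] set), `reactions` (tibble of per-reaction
#'   cut-off, AUC, Youden's J, class sizes), `curves` (named list of
#'   `apoe_roc`), `n_train`. Supports [tidy()], [glance()] and
#'   [ggplot2::autoplot()].
#' @examples
#' \donttest{
#' sim <- simulate_cohort(n = 40, seed = 7)
#' train <- pair_channels(sim$plate) |>
#'   dplyr::filter(role == "SAMPLE") |>
#'   dplyr::left_join(sim$truth, by = "sample_id")
#' cal <- calibrate_cutoffs(train)
#' tidy(cal)
#' }
#' @export
calibrate_cutoffs <- function(training, criterion = c("youden", "min_specificity"),
                              target_specificity = 0.95, max_cycles = 40) {
  criterion <- match.arg(criterion)
  labelled <- label_delta_ct(training, max_cycles = max_cycles)
  curves <- list()
  rows <- list()
  for (a in apoe_alleles()) {
    d <- labelled |> filter(.data$reaction == a)
    if (nrow(d) == 0) {
      abort(paste0("No training measurements for the ", a, " reaction"),
            class = "apoetyper_calibration_error")
    }
    curve <- withCallingHandlers(
      roc_points(d$delta_ct, d$allele_present),
      apoetyper_calibration_error = function(e) {
        abort(paste0(a, " reaction: ", conditionMessage(e)),
              class = "apoetyper_calibration_error")
      })
    cut <- select_cutoff(curve, criterion, target_specificity)
    j <- curve$points$youden_j[match(cut, curve$points$threshold)]
    curves[[a]] <- curve
    rows[[a]] <- tibble(reaction = a, cutoff = cut, auc = curve$auc,
                        youden_j = j, n_pos = curve$n_pos,
                        n_neg = curve$n_neg)
  }
  reactions <- list_rbind(rows)
  structure(
    list(cutoffs = apoe_cutoffs(reactions$cutoff[1], reactions$cutoff[2],
                                reactions$cutoff[3], max_cycles = max_cycles),
         reactions = reactions, curves = curves,
         n_train = length(unique(labelled$sample_id))),
    class = "apoe_calibration")
}

#' Evaluate a cut-off set on a labelled test cohort
#'
#' Computes per-reaction sensitivity and specificity of the allele calls
#' at the supplied cut-offs, and the genotype-level concordance between
#' the combined calls and the sequencing-derived truth. `NO_CALL` counts
#' as discordant.
#'
#' @param test A merged labelled table as in [label_delta_ct()].
#' @param cutoffs An [apoe_cutoffs()] set.
#' @param tie_positive Tie policy passed to [call_allele()].
#' @inheritParams label_delta_ct
#' @return A list of class `apoe_evaluation`: `reactions` (tibble of
#'   per-reaction sensitivity/specificity), `concordance` (fraction),
#'   `n` (samples compared).
#' @export
evaluate_cutoffs <- function(test, cutoffs, tie_positive = TRUE,
                             max_cycles = 40) {
  stopifnot(inherits(cutoffs, "apoe_cutoffs"))
  labelled <- label_delta_ct(test, max_cycles = max_cycles)
  if (nrow(labelled) == 0) {
    abort("Empty test set", class = "apoetyper_validation_error")
  }
  labelled <- labelled |>
    mutate(call = call_allele(.data$delta_ct,
                              unname(cutoffs[.data$reaction]),
                              tie_positive) == "POSITIVE")
  reactions <- labelled |>
    group_by(.data$reaction) |>
    summarise(
      sensitivity = mean(.data$call[.data$allele_present]),
      specificity = mean(!.data$call[!.data$allele_present]),
      .groups = "drop"
    )
  wide <- labelled |>
    mutate(call = ifelse(.data$call, "POSITIVE", "NEGATIVE")) |>
    select("sample_id", "reaction", "call", "truth_genotype") |>
    tidyr::pivot_wider(names_from = "reaction", values_from = "call")
  combined <- combine_calls(wide$E2, wide$E3, wide$E4)
  conc <- concordance(combined$genotype, wide$truth_genotype)
  structure(list(reactions = reactions,
                 concordance = conc$n_concordant / conc$n_compared,
                 n = nrow(wide)),
            class = "apoe_evaluation")
}

#' @export
print.apoe_calibration <- function(x, ...) {
  cat("APOE delta-Ct calibration (", x$n_train, " training samples)\n",
      sep = "")
  print(x$reactions)
  invisible(x)
}

#' @export
print.apoe_roc <- function(x, ...) {
  cat("ROC curve: ", x$n_pos, " positive / ", x$n_neg,
      " negative; AUC = ", format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
print.apoe_evaluation <- function(x, ...) {
  cat("Cut-off evaluation on", x$n, "samples; genotype concordance",
      sprintf("%.2f%%", 100 * x$concordance), "\n")
  print(x$reactions)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Turn calibration objects into tidy tibbles
#'
#' Broom-style accessors: `tidy()` returns one row per reaction (or per
#' ROC point), `glance()` a one-row model summary.
#'
#' @param x An `apoe_calibration` or `apoe_roc` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy apoe_calibration
#' @export
tidy.apoe_calibration <- function(x, ...) x$reactions

#' @rdname tidy.apoe_calibration
#' @method glance apoe_calibration
#' @export
glance.apoe_calibration <- function(x, ...) {
  tibble(n_train = x$n_train,
         min_auc = min(x$reactions$auc),
         min_youden_j = min(x$reactions$youden_j))
}

#' @rdname tidy.apoe_calibration
#' @method tidy apoe_roc
#' @export
tidy.apoe_roc <- function(x, ...) x$points

#' @rdname tidy.apoe_calibration
#' @method glance apoe_roc
#' @export
glance.apoe_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot ROC curves and calibration results
#'
#' `autoplot()` on an `apoe_roc` draws the ROC curve (1 - specificity vs
#' sensitivity); on an `apoe_calibration` it overlays the three
#' per-reaction curves with their selected operating points.
#'
#' @param object An `apoe_roc` or `apoe_calibration`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot apoe_roc
#' @export
autoplot.apoe_roc <- function(object, ...) {
  pts <- object$points |> arrange(dplyr::desc(.data$threshold))
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC over delta-Ct (AUC = %.3f)",
                                  object$auc)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.apoe_roc
#' @method autoplot apoe_calibration
#' @export
autoplot.apoe_calibration <- function(object, ...) {
  pts <- imap(object$curves, function(c, a) {
    c$points |> mutate(reaction = a)
  }) |> list_rbind() |> arrange(dplyr::desc(.data$threshold))
  sel <- object$reactions |>
    left_join(pts, by = c("reaction", cutoff = "threshold"))
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity,
                                    colour = .data$reaction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = sel, size = 3, shape = 21, stroke = 1) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  colour = "Reaction",
                  title = "Per-reaction ROC with selected cut-offs") +
    ggplot2::theme_minimal()
}
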