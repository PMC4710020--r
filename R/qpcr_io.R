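# Reading qPCR plate exports and writing results tables.
#
# A "well record" is one channel reading (FAM or HEX) of one well: the
# instrument reports a threshold cycle (Ct) or no amplification at all.
# Undetermined readings are represented as NA in the `ct` column and are
# meaningful (the assay reads them as "allele absent"), so they are never
# dropped.

WELL_COLS <- c("plate_id", "well", "sample_id", "reaction", "channel", "ct", "role")
REACTIONS <- c("E2", "E3", "E4")
CHANNELS <- c("FAM", "HEX")
ROLES <- c("SAMPLE", "POSITIVE_CONTROL_E2", "POSITIVE_CONTROL_E3",
           "POSITIVE_CONTROL_E4", "NTC")

#' Map plate-export column names to the fields the package needs
#'
#' Instrument exports differ in their header names; `plate_columns()`
#' declares which column in the file holds each logical field. The `role`
#' column is optional in the file; absent rows default to `"SAMPLE"`.
#'
#' @param plate,well,sample,reaction,channel,ct,role Column names in the
#'   export file for the corresponding logical field.
#' @return A named character vector used by [read_plate()].
#' @examples
#' plate_columns(ct = "Cp")
#' @export
plate_columns <- function(plate = "plate", well = "well", sample = "sample",
                          reaction = "reaction", channel = "channel",
                          ct = "ct", role = "role") {
  c(plate_id = plate, well = well, sample_id = sample, reaction = reaction,
    channel = channel, ct = ct, role = role)
}

#' Read a qPCR plate export into validated well records
#'
#' Reads a delimited text export (comma or tab; sniffed from the header
#' line unless `delim` is given) with one row per well per channel and
#' returns a tibble of well records. Ct values are positive reals up to
#' `max_cycles` (default 40, the assay's cycle count); the configured
#' undetermined tokens (case-insensitive) map to `NA`, meaning no
#' amplification curve was observed.
#'
#' The instrument's spelling of an undetermined Ct is not standardised
#' across export dialects, so the accepted token list is configurable;
#' the default accepts `"Undetermined"`, `"N/A"`, `"NA"` and an empty cell.
#'
#' @param file Path to the delimited export.
#' @param col_map Column-name mapping from [plate_columns()].
#' @param delim Field delimiter; `NULL` sniffs `","` vs `"\t"`.
#' @param max_cycles Cycle ceiling; Ct must lie in `(0, max_cycles]`.
#' @param undetermined_tokens Character tokens (matched case-insensitively
#'   after trimming) read as "no amplification".
#' @return A tibble with columns `plate_id`, `well`, `sample_id`,
#'   `reaction` (`"E2"/"E3"/"E4"`), `channel` (`"FAM"/"HEX"`), `ct`
#'   (double, `NA` = undetermined) and `role`, one row per input data row,
#'   in file order.
#' @seealso [pair_channels()], [as_well_records()]
#' @export
read_plate <- function(file, col_map = plate_columns(), delim = NULL,
                       max_cycles = 40,
                       undetermined_tokens = c("Undetermined", "N/A", "NA", "")) {
  if (is.null(delim)) {
    header <- readLines(file, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(file, delim = delim, col_types = readr::cols(.default = "c"),
                           trim_ws = TRUE, na = character(), progress = FALSE)
  required <- col_map[setdiff(names(col_map), "role")]
  missing <- required[!required %in% names(raw)]
  if (length(missing) > 0) {
    abort(paste0("Plate export is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "apoetyper_format_error")
  }
  df <- tibble(
    plate_id = raw[[col_map[["plate_id"]]]],
    well = raw[[col_map[["well"]]]],
    sample_id = raw[[col_map[["sample_id"]]]],
    reaction = toupper(raw[[col_map[["reaction"]]]]),
    channel = toupper(raw[[col_map[["channel"]]]]),
    ct_raw = raw[[col_map[["ct"]]]],
    role = if (col_map[["role"]] %in% names(raw)) {
      toupper(raw[[col_map[["role"]]]])
    } else {
      "SAMPLE"
    }
  )
  df$role[is.na(df$role) | df$role == ""] <- "SAMPLE"

  tok <- tolower(trimws(undetermined_tokens))
  ct_chr <- tolower(trimws(df$ct_raw))
  is_undet <- ct_chr %in% tok | is.na(df$ct_raw)
  ct <- suppressWarnings(as.numeric(df$ct_raw))
  bad_token <- !is_undet & is.na(ct)
  if (any(bad_token)) {
    abort(paste0("Unparseable Ct value ", dQuote(df$ct_raw[which(bad_token)[1]]),
                 " at data row ", which(bad_token)[1]),
          class = "apoetyper_validation_error")
  }
  ct[is_undet] <- NA_real_
  df$ct <- ct
  df$ct_raw <- NULL
  as_well_records(df, max_cycles = max_cycles)
}

#' Validate a data frame of well records
#'
#' Checks the invariants every downstream step assumes: known reaction and
#' channel labels, plate-coordinate well names (letter + number, e.g.
#' `"A1"`), Ct in `(0, max_cycles]` when determined, known roles, and no
#' duplicate `(plate_id, well, channel)` reading.
#'
#' @param wells A data frame with the [read_plate()] columns (`role`
#'   optional, defaulting to `"SAMPLE"`; `ct` numeric with `NA` =
#'   undetermined).
#' @inheritParams read_plate
#' @return The validated tibble of well records.
#' @export
as_well_records <- function(wells, max_cycles = 40) {
  wells <- as_tibble(wells)
  if (!"role" %in% names(wells)) wells$role <- "SAMPLE"
  missing <- setdiff(WELL_COLS, names(wells))
  if (length(missing) > 0) {
    abort(paste0("Well records are missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "apoetyper_format_error")
  }
  wells <- wells[WELL_COLS]
  wells$ct <- as.numeric(wells$ct)

  bad <- which(!wells$reaction %in% REACTIONS)
  if (length(bad) > 0) {
    abort(paste0("Unknown reaction label ", dQuote(wells$reaction[bad[1]]),
                 " at data row ", bad[1], " (expected E2, E3 or E4)"),
          class = "apoetyper_validation_error")
  }
  bad <- which(!wells$channel %in% CHANNELS)
  if (length(bad) > 0) {
    abort(paste0("Unknown channel ", dQuote(wells$channel[bad[1]]),
                 " at data row ", bad[1], " (expected FAM or HEX)"),
          class = "apoetyper_validation_error")
  }
  bad <- which(!wells$role %in% ROLES)
  if (length(bad) > 0) {
    abort(paste0("Unknown role ", dQuote(wells$role[bad[1]]),
                 " at data row ", bad[1]),
          class = "apoetyper_validation_error")
  }
  bad <- which(!grepl("^[A-Pa-p][0-9]{1,2}$", wells$well))
  if (length(bad) > 0) {
    abort(paste0("Well ", dQuote(wells$well[bad[1]]), " at data row ", bad[1],
                 " is not a plate coordinate (letter + number, e.g. A1)"),
          class = "apoetyper_validation_error")
  }
  bad <- which(!is.na(wells$ct) & (wells$ct <= 0 | wells$ct > max_cycles))
  if (length(bad) > 0) {
    abort(paste0("Ct value ", wells$ct[bad[1]], " at data row ", bad[1],
                 " is outside (0, ", max_cycles, "]"),
          class = "apoetyper_validation_error")
  }
  dup <- duplicated(wells[c("plate_id", "well", "channel")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(paste0("Duplicate reading for plate ", wells$plate_id[i], ", well ",
                 wells$well[i], ", channel ", wells$channel[i]),
          class = "apoetyper_duplicate_error")
  }
  wells
}

#' Pair the FAM and HEX readings of each well into reaction measurements
#'
#' The assay reads two dyes from every well: FAM reports the APOE
#' allele-specific amplicon and HEX the ACTB internal control. Pairing the
#' two channels of a well yields one measurement per (sample, reaction),
#' the unit consumed by the delta-Ct computation.
#'
#' @param wells Validated well records (see [read_plate()] /
#'   [as_well_records()]).
#' @return A tibble with one row per (sample, reaction): `plate_id`,
#'   `well`, `sample_id`, `reaction`, `role`, `fam_ct`, `hex_ct` (each
#'   `NA` when undetermined), ordered by sample then reaction.
#' @export
pair_channels <- function(wells) {
  wells <- as_well_records(wells)
  wide <- wells |>
    tidyr::pivot_wider(
      id_cols = c("plate_id", "well", "sample_id", "reaction", "role"),
      names_from = "channel", values_from = "ct"
    )
  # an undetermined reading still has a row (ct = NA); a missing channel has
  # no row at all, so count distinct channels per well to catch it

  chan_count <- wells |>
    distinct(.data$plate_id, .data$well, .data$channel) |>
    count(.data$plate_id, .data$well)
  incomplete <- chan_count |> filter(.data$n < 2)
  if (nrow(incomplete) > 0) {
    abort(paste0("Incomplete well(s) with a single channel: ",
                 paste(head(paste(incomplete$plate_id, incomplete$well), 5),
                       collapse = ", ")),
          class = "apoetyper_pairing_error")
  }
  dup_meas <- wide |> count(.data$sample_id, .data$reaction) |> filter(.data$n > 1)
  if (nrow(dup_meas) > 0) {
    abort(paste0("More than one well for sample ", dup_meas$sample_id[1],
                 ", reaction ", dup_meas$reaction[1],
                 "; one measurement per (sample, reaction) is required"),
          class = "apoetyper_duplicate_error")
  }
  wide |>
    rename(fam_ct = "FAM", hex_ct = "HEX") |>
    select("plate_id", "well", "sample_id", "reaction", "role",
           "fam_ct", "hex_ct") |>
    arrange(.data$sample_id, .data$reaction)
}

#' Write and re-read a genotyping results table
#'
#' `write_results()` writes one comma-delimited row per sample: the three
#' delta-Ct values (printed with 2 decimals), the three allele calls, the
#' combined genotype, the NO_CALL reason and the QC flags.
#' `read_results()` reads such a file back into the same tibble shape, so
#' a written table round-trips (delta-Ct to 2 decimals).
#'
#' @param results A results tibble from [genotype_samples()].
#' @param file Path to write to / read from.
#' @return `write_results()` returns `file` invisibly; `read_results()`
#'   returns the results tibble.
#' @export
write_results <- function(results, file) {
  out <- results
  for (col in c("dct_e2", "dct_e3", "dct_e4")) {
    out[[col]] <- sprintf("%.2f", round_half_up(out[[col]], 2))
    out[[col]][out[[col]] == "NA"] <- ""
  }
  readr::write_csv(out, file, na = "")
  invisible(file)
}

#' @rdname write_results
#' @export
read_results <- function(file) {
  readr::read_csv(
    file,
    col_types = readr::cols(
      sample_id = "c", dct_e2 = "d", dct_e3 = "d", dct_e4 = "d",
      call_e2 = "c", call_e3 = "c", call_e4 = "c",
      genotype = "c", reason = "c", qc_flags = "c"
    ),
    na = "", progress = FALSE
  ) |>
    mutate(
      reason = ifelse(is.na(.data$reason), "", .data$reason),
      qc_flags = ifelse(is.na(.data$qc_flags), "", .data$qc_flags)
    )
}
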