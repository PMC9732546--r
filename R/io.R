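# Readers and writers for the two tabular interchange formats:
#  - Measurement CSV (long format): mouse_id, arm, day, diameter_a_mm,
#    diameter_b_mm, volume_mm3 (either both diameters or the volume filled)
#  - Ct CSV: sample_id, group, gene, species_tag, ct
# UTF-8, comma-separated, '.' decimal.

measurement_columns <- c("mouse_id", "arm", "day",
                         "diameter_a_mm", "diameter_b_mm", "volume_mm3")
ct_columns <- c("sample_id", "group", "gene", "species_tag", "ct")

#' Read a measurement CSV into a study
#'
#' Validates the long-format measurement table (required header, numeric
#' fields, no duplicate mouse/day pairs, day 1 present per mouse), computes
#' volumes from caliper diameters where the volume column is empty, and
#' assembles arms into a [pdx_study()]. Baseline (day-1) volumes outside
#' the enrollment window trigger a warning, or exclusion of the mouse when
#' the hard filter is on (the emulated protocol excludes animals outside
#' 60-150 mm^3).
#'
#' @param path CSV file path.
#' @param volume_convention passed to [volume_from_diameters()].
#' @param control control-arm name (default `"control"` if present).
#' @param enrollment_window baseline-volume window, mm^3.
#' @param enrollment_filter `FALSE` (warn only, default) or `TRUE` (exclude
#'   out-of-window mice).
#' @return a [pdx_study()].
#' @export
read_measurements <- function(path,
                              volume_convention = c("as-printed", "conventional"),
                              control = NULL,
                              enrollment_window = c(60, 150),
                              enrollment_filter = FALSE) {
  volume_convention <- match.arg(volume_convention)
  d <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(measurement_columns, names(d))
  if (length(miss) > 0L)
    pdx_validation_error(sprintf("measurement CSV missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (nrow(d) == 0L) pdx_validation_error("measurement CSV is empty")
  for (col in c("day", "diameter_a_mm", "diameter_b_mm", "volume_mm3"))
    d[[col]] <- suppressWarnings(as.numeric(d[[col]]))
  bad_day <- which(!is_whole(d$day) | d$day < 1)
  if (length(bad_day) > 0L)
    pdx_validation_error(sprintf("invalid day in row(s): %s",
                                 paste(bad_day, collapse = ", ")))
  dup <- which(duplicated(d[, c("mouse_id", "day")]))
  if (length(dup) > 0L)
    pdx_validation_error(sprintf("duplicate (mouse_id, day) in row(s): %s",
                                 paste(dup, collapse = ", ")))
  no_vol <- is.na(d$volume_mm3)
  need <- no_vol & (is.na(d$diameter_a_mm) | is.na(d$diameter_b_mm))
  if (any(need))
    pdx_validation_error(sprintf(
      "row(s) %s have neither a volume nor both diameters",
      paste(which(need), collapse = ", ")))
  if (any(no_vol))
    d$volume_mm3[no_vol] <- volume_from_diameters(
      d$diameter_a_mm[no_vol], d$diameter_b_mm[no_vol],
      convention = volume_convention)
  if (any(d$volume_mm3 <= 0, na.rm = TRUE))
    pdx_validation_error("volumes must be positive")

  curves <- lapply(split(d, d$mouse_id), function(m) {
    m <- m[order(m$day), , drop = FALSE]
    if (length(unique(m$arm)) != 1L)
      pdx_validation_error(sprintf("mouse '%s' appears in several arms",
                                   m$mouse_id[1]))
    growth_curve(m$mouse_id[1], m$day, m$volume_mm3, arm_label = m$arm[1])
  })
  base <- vapply(curves, `[[`, 0, "baseline_volume")
  out_of_window <- base < enrollment_window[1] | base > enrollment_window[2]
  if (any(out_of_window)) {
    ids <- vapply(curves[out_of_window], `[[`, "", "mouse_id")
    if (enrollment_filter) {
      warning(sprintf("excluding mouse/mice outside enrollment window [%g, %g] mm^3: %s",
                      enrollment_window[1], enrollment_window[2],
                      paste(ids, collapse = ", ")))
      curves <- curves[!out_of_window]
      if (length(curves) == 0L)
        pdx_validation_error("no mice left after enrollment filtering")
    } else {
      warning(sprintf("baseline volume outside [%g, %g] mm^3 for: %s",
                      enrollment_window[1], enrollment_window[2],
                      paste(ids, collapse = ", ")))
    }
  }
  labels <- vapply(curves, `[[`, "", "arm_label")
  arms <- lapply(unique(labels), function(a) study_arm(a, unname(curves[labels == a])))
  pdx_study(arms, control = control)
}

#' Write a study to the measurement CSV format
#'
#' @param study a [pdx_study()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(study, path) {
  curves <- unlist(lapply(study$arms, `[[`, "curves"), recursive = FALSE)
  d <- do.call(rbind, lapply(curves, function(gc)
    data.frame(mouse_id = gc$mouse_id, arm = gc$arm_label, day = gc$days,
               diameter_a_mm = NA_real_, diameter_b_mm = NA_real_,
               volume_mm3 = gc$volumes)))
  write_table_exact(d, path)
  invisible(path)
}

validate_ct_table <- function(ct) {
  if (is.character(ct) && length(ct) == 1L)
    pdx_validation_error("pass a data.frame; use read_ct_table() for files")
  miss <- setdiff(ct_columns, names(ct))
  if (length(miss) > 0L)
    pdx_validation_error(sprintf("Ct table missing column(s): %s",
                                 paste(miss, collapse = ", ")))
  if (nrow(ct) == 0L) pdx_validation_error("Ct table is empty")
  if (!is.numeric(ct$ct)) {
    conv <- suppressWarnings(as.numeric(ct$ct))
    if (any(is.na(conv) & !is.na(ct$ct) & ct$ct != ""))
      pdx_validation_error("non-numeric Ct values")
    ct$ct <- conv
  }
  if (any(ct$ct <= 0, na.rm = TRUE))
    pdx_validation_error("Ct values must be positive")
  ct
}

#' Read an RT-qPCR Ct CSV
#'
#' Columns: `sample_id`, `group`, `gene`, `species_tag`, `ct`; TBP
#' reference rows use `gene = "TBP"` with `species_tag` distinguishing the
#' human and murine transcripts. Empty Ct fields are read as undetected.
#'
#' @param path CSV file path.
#' @return validated Ct data.frame.
#' @export
read_ct_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  validate_ct_table(d)
}

#' Write a Ct table CSV
#'
#' @param ct Ct data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(ct, path) {
  write_table_exact(ct, path)
  invisible(path)
}

# Deterministic, lossless CSV writer: doubles are rendered with %.17g so
# reading the file back reproduces the binary values exactly, and repeated
# writes of the same data are byte-identical.
write_table_exact <- function(d, path) {
  f <- d
  for (j in seq_along(f)) {
    if (is.double(f[[j]])) {
      v <- sprintf("%.17g", f[[j]])
      v[is.na(f[[j]])] <- ""
      f[[j]] <- v
    } else if (is.logical(f[[j]])) {
      f[[j]] <- ifelse(f[[j]], "TRUE", "FALSE")
    }
  }
  con <- file(path, open = "wb")  # binary: identical bytes on any platform
  on.exit(close(con))
  writeLines(paste(names(f), collapse = ","), con, sep = "\n")
  if (nrow(f) > 0L) {
    cells <- vapply(f, as.character, character(nrow(f)))
    if (nrow(f) == 1L) cells <- matrix(cells, nrow = 1L)
    cells[is.na(cells)] <- ""
    writeLines(apply(cells, 1L, paste, collapse = ","), con, sep = "\n")
  }
  invisible(path)
}
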