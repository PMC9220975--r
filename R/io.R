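#' Read a signal clip from a delimited-text file
#'
#' The clip format is UTF-8 text: `#key=value` header lines carrying
#' `clip_id`, `subject_id`, `channel`, `sampling_rate` (and optionally
#' `t0_offset`), followed by one sample value per line.
#'
#' @param path path to a clip file written by [write_clip()].
#' @return An [signal_clip()] object.
#' @export
read_clip <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_header <- grepl("^#", lines)
  if (any(is_header) && !all(which(is_header) == seq_len(sum(is_header)))) {
    scg_abort("clip header lines (#key=value) must precede all samples",
              "scg_parse_error")
  }
  header <- lines[is_header]
  body <- lines[!is_header]
  body <- body[nzchar(trimws(body))]
  kv <- regmatches(header, regexec("^#\\s*([^=]+)=(.*)$", header))
  bad <- which(lengths(kv) != 3L)
  if (length(bad) > 0L) {
    scg_abort(sprintf("malformed header line %d: '%s'", bad[1], header[bad[1]]),
              "scg_parse_error")
  }
  keys <- trimws(vapply(kv, `[`, "", 2L))
  vals <- trimws(vapply(kv, `[`, "", 3L))
  meta <- stats::setNames(as.list(vals), keys)
  for (field in c("clip_id", "subject_id", "channel", "sampling_rate")) {
    if (is.null(meta[[field]])) {
      scg_abort(sprintf("clip file is missing required header field '%s'", field),
                "scg_parse_error")
    }
  }
  rate <- suppressWarnings(as.numeric(meta$sampling_rate))
  if (is.na(rate)) {
    scg_abort(sprintf("sampling_rate is not numeric: '%s'", meta$sampling_rate),
              "scg_parse_error")
  }
  if (length(body) == 0L) {
    scg_abort("clip file has an empty body (no samples)", "scg_parse_error")
  }
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    first_bad <- which(is.na(samples))[1]
    line_no <- sum(is_header) + first_bad
    scg_abort(sprintf("non-numeric sample at line %d: '%s'",
                      line_no, body[first_bad]), "scg_parse_error")
  }
  t0 <- if (is.null(meta$t0_offset)) 0 else as.numeric(meta$t0_offset)
  signal_clip(samples, rate, channel = meta$channel, clip_id = meta$clip_id,
              subject_id = meta$subject_id, t0_offset = t0)
}

#' Write a signal clip to a delimited-text file
#'
#' Samples are printed with 17 significant digits so a write/read round trip
#' reproduces them bit-exactly; writing the same clip twice produces
#' byte-identical files.
#'
#' @param clip an [signal_clip()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clip <- function(clip, path) {
  stopifnot(inherits(clip, "scg_clip"))
  header <- c(
    sprintf("#clip_id=%s", clip$clip_id),
    sprintf("#subject_id=%s", clip$subject_id),
    sprintf("#channel=%s", clip$channel),
    sprintf("#sampling_rate=%.17g", clip$sampling_rate),
    sprintf("#t0_offset=%.17g", clip$t0_offset)
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, sprintf("%.17g", clip$samples)), con, sep = "\n")
  invisible(path)
}

#' Write an annotation object to JSON
#'
#' Beat annotations, echo annotations and fiducial sets share one JSON
#' layout with a `type` discriminator, so [read_annotation()] can
#' reconstruct any of them.
#'
#' @param x an `scg_beats`, `scg_echo` or `scg_fiducials` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(x, path) {
  type <- if (inherits(x, "scg_beats")) "beat_annotation"
          else if (inherits(x, "scg_echo")) "echo_annotation"
          else if (inherits(x, "scg_fiducials")) "fiducial_set"
          else scg_abort("not an annotation object", "scg_invalid_annotation")
  payload <- c(list(type = type), unclass(x))
  if (type %in% c("echo_annotation", "fiducial_set")) {
    key <- if (type == "echo_annotation") "events" else "times"
    payload[[key]] <- as.list(payload[[key]])
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an annotation object from JSON
#'
#' @param path a JSON file written by [write_annotation()].
#' @return the reconstructed annotation object.
#' @export
read_annotation <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$type)) {
    scg_abort("annotation JSON is missing the 'type' field", "scg_parse_error")
  }
  switch(obj$type,
    beat_annotation = beat_annotation(
      clip_id = obj$clip_id, r_peaks = obj$r_peaks,
      sampling_rate = obj$sampling_rate,
      q_points = obj$q_points, t_bounds = obj$t_bounds,
      rr_interval_ms = obj$rr_interval_ms
    ),
    echo_annotation = echo_annotation(
      image_id = obj$image_id, subject_id = obj$subject_id,
      modality = obj$modality, r1_ms = obj$r1_ms, r2_ms = obj$r2_ms,
      events = unlist(obj$events)
    ),
    fiducial_set = fiducial_set(
      clip_id = obj$clip_id, times = unlist(obj$times),
      provenance = obj$provenance, check_order = FALSE
    ),
    scg_abort(sprintf("unknown annotation type '%s'", obj$type), "scg_parse_error")
  )
}

#' Load the packaged 56-subject cohort table
#'
#' Returns the study cohort used for validation: per subject the clinical
#' LVEF assessment, disease label, number of analysed SCG cycles and the
#' per-subject mean and SD of the two SCG-derived indexes (PEP/LVET ratio
#' and Tei index). LVEF is returned as a fraction (29.0\% -> 0.29).
#'
#' @return A tibble with 56 rows and columns `subject_id`, `sex`, `age`,
#'   `lvef`, `disease`, `cycles`, `pep_lvet_avg`, `pep_lvet_sd`, `tei_avg`,
#'   `tei_sd`.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "table1_subjects.tsv", package = "scgalign")
  if (!nzchar(path) || !file.exists(path)) {
    scg_abort("packaged cohort table not found", "scg_fixture_error")
  }
  raw <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "sex", "age", "lvef_pct", "disease", "cycles",
              "pep_lvet_avg", "pep_lvet_sd", "tei_avg", "tei_sd")
  if (!all(needed %in% names(raw))) {
    scg_abort("packaged cohort table is corrupt (missing columns)",
              "scg_fixture_error")
  }
  records <- tibble::tibble(
    subject_id = raw$subject_id, sex = raw$sex, age = raw$age,
    lvef = raw$lvef_pct / 100, disease = raw$disease, cycles = raw$cycles,
    pep_lvet_avg = raw$pep_lvet_avg, pep_lvet_sd = raw$pep_lvet_sd,
    tei_avg = raw$tei_avg, tei_sd = raw$tei_sd
  )
  if (nrow(records) != 56L) {
    scg_abort(sprintf("packaged cohort table has %d rows, expected 56",
                      nrow(records)), "scg_fixture_error")
  }
  validate_subject_records(records)
  records
}
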