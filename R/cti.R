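#' Construct a set of cardiac time intervals
#'
#' @param pep_ms pre-ejection period (AO - Q).
#' @param lvet_ms left ventricular ejection time (AC - AO).
#' @param ivct_ms isovolumic contraction time (AO - MC).
#' @param ivrt_ms isovolumic relaxation time (MO - AC).
#' @param strict require all four intervals strictly positive (the
#'   physiological case)? With `strict = FALSE` the isovolumic intervals may
#'   be zero (degenerate but representable).
#' @return An object of class `scg_cti`.
#' @export
cti_set <- function(pep_ms, lvet_ms, ivct_ms, ivrt_ms, strict = FALSE) {
  v <- c(PEP = pep_ms, LVET = lvet_ms, IVCT = ivct_ms, IVRT = ivrt_ms)
  if (!all(is.finite(v))) {
    scg_abort("all intervals must be finite", "scg_invalid_interval")
  }
  bad <- if (strict) {
    names(v)[v <= 0]  # physiological ordering: all four strictly positive
  } else {
    names(v)[c(v[1] < 0, v[2] <= 0, v[3] < 0, v[4] < 0)]
  }
  if (length(bad) > 0L) {
    scg_abort(paste("nonpositive interval(s):", paste(bad, collapse = ", ")),
              "scg_invalid_interval")
  }
  structure(list(pep_ms = pep_ms, lvet_ms = lvet_ms,
                 ivct_ms = ivct_ms, ivrt_ms = ivrt_ms),
            class = "scg_cti")
}

#' Cardiac time intervals from a fiducial set
#'
#' `PEP = AO - Q`, `LVET = AC - AO`, `IVCT = AO - MC`, `IVRT = MO - AC`,
#' all in ms. Requires all five events; any missing event or nonpositive
#' interval raises a classed error naming the offender.
#'
#' @param fiducials an [fiducial_set()] containing `Q`, `MC`, `AO`, `AC`,
#'   `MO`.
#' @return An `scg_cti` object.
#' @export
compute_ctis <- function(fiducials) {
  t <- fiducials$times
  missing <- setdiff(EVENT_LABELS, names(t))
  if (length(missing) > 0L) {
    scg_abort(paste("missing fiducial event(s):", paste(missing, collapse = ", ")),
              "scg_missing_event")
  }
  intervals <- c(
    PEP = unname(t["AO"] - t["Q"]),
    LVET = unname(t["AC"] - t["AO"]),
    IVCT = unname(t["AO"] - t["MC"]),
    IVRT = unname(t["MO"] - t["AC"])
  )
  bad <- names(intervals)[intervals <= 0]
  if (length(bad) > 0L) {
    pairs <- c(PEP = "AO - Q", LVET = "AC - AO", IVCT = "AO - MC",
               IVRT = "MO - AC")
    scg_abort(paste("invalid fiducial ordering, nonpositive interval(s):",
                    paste(sprintf("%s (%s)", bad, pairs[bad]), collapse = ", ")),
              "scg_invalid_interval")
  }
  cti_set(unname(intervals["PEP"]), unname(intervals["LVET"]),
          unname(intervals["IVCT"]), unname(intervals["IVRT"]), strict = TRUE)
}

#' Diagnostic indexes from cardiac time intervals
#'
#' The contractility coefficient `PEP/LVET` and the Tei index (myocardial
#' performance index) `(IVCT + IVRT)/LVET`, both dimensionless and
#' heart-rate independent.
#'
#' @param cti an `scg_cti` (or any list with the four `_ms` fields).
#' @return A list with `pep_over_lvet` and `tei`.
#' @export
compute_indexes <- function(cti) {
  if (!is.finite(cti$lvet_ms) || cti$lvet_ms <= 0) {
    scg_abort("LVET must be positive to form the indexes", "scg_invalid_interval")
  }
  list(pep_over_lvet = cti$pep_ms / cti$lvet_ms,
       tei = (cti$ivct_ms + cti$ivrt_ms) / cti$lvet_ms)
}

#' Per-subject index statistics
#'
#' Mean and sample SD (n - 1 denominator; 0 when n = 1) of the per-beat
#' diagnostic indexes — the per-subject summary used for cohort analysis.
#'
#' @param per_beat a list of index pairs from [compute_indexes()], or a
#'   data frame with columns `pep_over_lvet` and `tei`.
#' @return A one-row tibble: `n`, `pep_lvet_avg`, `pep_lvet_sd`, `tei_avg`,
#'   `tei_sd`.
#' @export
subject_statistics <- function(per_beat) {
  if (is.data.frame(per_beat)) {
    pep <- per_beat$pep_over_lvet
    tei <- per_beat$tei
  } else {
    pep <- vapply(per_beat, `[[`, numeric(1), "pep_over_lvet")
    tei <- vapply(per_beat, `[[`, numeric(1), "tei")
  }
  n <- length(pep)
  if (n < 1L) scg_abort("need at least one beat", "scg_parameter_error")
  sd0 <- function(x) if (length(x) == 1L) 0 else sd(x)
  tibble::tibble(
    n = n,
    pep_lvet_avg = mean(pep), pep_lvet_sd = sd0(pep),
    tei_avg = mean(tei), tei_sd = sd0(tei)
  )
}
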