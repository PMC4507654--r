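#' Cuff-deflation recording container
#'
#' A raw cuff-pressure time series with ECG R-peak annotations and optional
#' reference (expert-scored) SBP/DBP.
#'
#' @param cp cuff-pressure series, mmHg.
#' @param fs sampling rate, Hz.
#' @param r_peaks strictly increasing sample indices of ECG R-peaks (1-based);
#'   in the simulator these mark each pulse onset.
#' @param reference_sbp,reference_dbp optional reference pressures, mmHg.
#' @param meta list of identifiers and provenance (`id`, `subject`,
#'   `artifact_intervals`, simulator metadata).
#' @return object of class `cuff_recording`.
#' @export
cuff_recording <- function(cp, fs, r_peaks,
                           reference_sbp = NA_real_,
                           reference_dbp = NA_real_,
                           meta = list()) {
  cp <- as.numeric(cp)
  r_peaks <- as.integer(r_peaks)
  if (!all(is.finite(cp))) stop("cuff pressure must be finite")
  if (fs <= 0) stop("fs must be positive")
  if (length(r_peaks) && (any(diff(r_peaks) <= 0) ||
                          r_peaks[1] < 1L || max(r_peaks) > length(cp)))
    stop("r_peaks must be strictly increasing sample indices inside the signal")
  if (is.null(meta$artifact_intervals)) meta$artifact_intervals <- list()
  structure(list(cp = cp, fs = fs, r_peaks = r_peaks,
                 reference_sbp = reference_sbp,
                 reference_dbp = reference_dbp, meta = meta),
            class = "cuff_recording")
}

#' @export
print.cuff_recording <- function(x, ...) {
  cat(sprintf("<cuff_recording %s: %.1f s @ %g Hz, %d R-peaks",
              if (is.null(x$meta$id)) "" else x$meta$id,
              (length(x$cp) - 1) / x$fs, x$fs, length(x$r_peaks)))
  if (is.finite(x$reference_sbp))
    cat(sprintf(", reference %g/%g mmHg", x$reference_sbp, x$reference_dbp))
  na <- length(x$meta$artifact_intervals)
  if (na) cat(sprintf(", %d artifact(s)", na))
  cat(">\n")
  invisible(x)
}

#' Write / read a cuff recording as CSV plus JSON sidecar
#'
#' The CSV holds columns `time_s` and `cuff_pressure_mmHg`; the JSON sidecar
#' holds the sampling rate, R-peak indices, reference pressures, artifact
#' intervals and any identifiers. Simulator internals are not serialized.
#'
#' @param rec a `cuff_recording`.
#' @param dir output directory (created if missing).
#' @param id file stem; defaults to `rec$meta$id`.
#' @return `write_recording` invisibly returns the file stem path;
#'   `read_recording` returns a `cuff_recording`.
#' @export
write_recording <- function(rec, dir, id = rec$meta$id) {
  stopifnot(inherits(rec, "cuff_recording"))
  if (is.null(id)) id <- "recording"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, id)
  t <- (seq_along(rec$cp) - 1) / rec$fs
  utils::write.csv(data.frame(time_s = t, cuff_pressure_mmHg = rec$cp),
                   paste0(stem, ".csv"), row.names = FALSE)
  side <- list(fs = rec$fs, r_peak_indices = rec$r_peaks,
               reference_sbp = rec$reference_sbp,
               reference_dbp = rec$reference_dbp,
               id = id, subject = rec$meta$subject,
               artifact_intervals = rec$meta$artifact_intervals)
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(stem)
}

#' @rdname write_recording
#' @param stem path stem (without extension) of a recording written by
#'   [write_recording()].
#' @export
read_recording <- function(stem) {
  csv <- utils::read.csv(paste0(stem, ".csv"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE,
                              simplifyDataFrame = FALSE,
                              simplifyMatrix = FALSE)
  ref_s <- if (is.null(side$reference_sbp)) NA_real_ else side$reference_sbp
  ref_d <- if (is.null(side$reference_dbp)) NA_real_ else side$reference_dbp
  arts <- side$artifact_intervals
  if (is.null(arts) || length(arts) == 0L) arts <- list()
  cuff_recording(cp = csv$cuff_pressure_mmHg, fs = side$fs,
                 r_peaks = side$r_peak_indices,
                 reference_sbp = ref_s, reference_dbp = ref_d,
                 meta = list(id = side$id, subject = side$subject,
                             artifact_intervals = arts))
}
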