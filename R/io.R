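# Plain-text interchange: delimited matrices + JSON sidecars, tidy TSVs.

atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Write an EEG recording as delimited matrix + JSON sidecar
#'
#' `<prefix>.tsv` holds a time x channel matrix with a header row;
#' `<prefix>.json` holds `{labels, rate}`.
#'
#' @param rec An `eeg_recording`.
#' @param prefix Path prefix (no extension).
#' @return The prefix, invisibly.
#' @export
write_eeg_matrix <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  m <- t(rec$samples)
  colnames(m) <- rec$labels
  atomic_write(paste0(prefix, ".tsv"), function(p)
    utils::write.table(m, p, sep = "\t", row.names = FALSE,
                       quote = FALSE))
  atomic_write(paste0(prefix, ".json"), function(p)
    jsonlite::write_json(list(labels = rec$labels, rate = rec$rate), p,
                         auto_unbox = TRUE, digits = NA))
  invisible(prefix)
}

#' Read an EEG recording written by [write_eeg_matrix()]
#' @param prefix Path prefix (no extension).
#' @return An `eeg_recording`.
#' @export
read_eeg_matrix <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(paste0(prefix, ".tsv"), header = TRUE,
                                   sep = "\t", check.names = FALSE))
  structure(list(samples = t(m), rate = side$rate, labels = side$labels),
            class = "eeg_recording")
}

#' Write a ROI session as delimited tables + JSON sidecar
#'
#' Writes `<prefix>_roi.tsv`, `<prefix>_noise.tsv`, `<prefix>_motion.tsv`
#' and `<prefix>.json` (`{tr, labels, tissues}`).
#'
#' @param session A `roi_session`.
#' @param prefix Path prefix.
#' @return The prefix, invisibly.
#' @export
write_roi_session <- function(session, prefix) {
  stopifnot(inherits(session, "roi_session"))
  wt <- function(x, suffix) atomic_write(paste0(prefix, suffix), function(p)
    utils::write.table(x, p, sep = "\t", row.names = FALSE, quote = FALSE))
  wt(session$roi, "_roi.tsv")
  wt(session$noise, "_noise.tsv")
  wt(session$motion, "_motion.tsv")
  atomic_write(paste0(prefix, ".json"), function(p)
    jsonlite::write_json(list(tr = session$tr, labels = session$labels,
                              tissues = attr(session$noise, "tissues")),
                         p, auto_unbox = TRUE, digits = NA))
  invisible(prefix)
}

#' Read a ROI session written by [write_roi_session()]
#' @param prefix Path prefix.
#' @return A `roi_session` (without generative ground truth).
#' @export
read_roi_session <- function(prefix) {
  side <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  rd <- function(suffix) as.matrix(
    utils::read.table(paste0(prefix, suffix), header = TRUE, sep = "\t",
                      check.names = FALSE))
  noise <- rd("_noise.tsv")
  attr(noise, "tissues") <- side$tissues
  structure(list(roi = rd("_roi.tsv"), noise = noise,
                 motion = rd("_motion.tsv"), tr = side$tr,
                 labels = side$labels, truth = NULL),
            class = "roi_session")
}

#' Write / read a cohort table (CSV or TSV by extension)
#' @param cohort Cohort data.frame.
#' @param path File path ending in .csv or .tsv.
#' @return The path, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  atomic_write(path, function(p)
    utils::write.table(cohort, p, sep = sep, row.names = FALSE,
                       quote = FALSE))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE)
}
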