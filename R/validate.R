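#' Match scored nuclei to generator ground truth by centroid
#'
#' Pairs each scored nucleus with the nearest ground-truth nucleus within a
#' tolerance, for recovery studies against the synthetic generator.
#'
#' @param records data.frame with \code{center_x_um}, \code{center_y_um}
#'   (e.g. from \code{\link{buildNucleusRecords}} or a segmentation table).
#' @param truth data.frame with \code{center_x_um}, \code{center_y_um} (from
#'   the generator; one rendered field).
#' @param tol_um maximum centroid distance for a match.
#' @return integer vector along \code{records}: row index into \code{truth},
#'   or NA when nothing lies within tolerance.
#' @export
matchNucleiToTruth <- function(records, truth, tol_um = 2) {
  vapply(seq_len(nrow(records)), function(i) {
    d <- sqrt((truth$center_x_um - records$center_x_um[i])^2 +
              (truth$center_y_um - records$center_y_um[i])^2)
    j <- which.min(d)
    if (length(j) && d[j] <= tol_um) j else NA_integer_
  }, integer(1))
}

#' Score every field of a simulated case and join with its truth
#'
#' Convenience wrapper for recovery studies: runs
#' \code{\link{scoreIfField}} on each rendered field of a
#' \code{\link{simulateIfCase}} result and matches the per-nucleus records
#' to the generator truth.
#'
#' @param sim result of \code{\link{simulateIfCase}}.
#' @param ... forwarded to \code{\link{scoreIfField}}.
#' @return data.frame of per-nucleus records with appended truth columns
#'   \code{true_pattern_class} and \code{true_focus_count} (NA where
#'   unmatched); attribute \code{n_truth} gives the number of ground-truth
#'   nuclei.
#' @export
scoreSimulatedCase <- function(sim, ...) {
  out <- list()
  for (f in sim$fields) {
    tr <- sim$truth[sim$truth$field == f@fieldId, , drop = FALSE]
    sc <- scoreIfField(f, case_id = tr$case_id[1], ...)
    rec <- sc$records
    if (is.null(rec)) next
    m <- matchNucleiToTruth(rec, tr)
    rec$true_pattern_class <- ifelse(is.na(m), NA, tr$true_pattern_class[m])
    rec$true_focus_count <- ifelse(is.na(m), NA, tr$true_focus_count[m])
    rec$field <- f@fieldId
    out[[f@fieldId]] <- rec
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_truth") <- nrow(sim$truth)
  res
}
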