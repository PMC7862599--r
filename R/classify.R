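#' Pattern classifier parameters
#'
#' Operational thresholds for the five-class 53BP1 pattern assignment:
#' stable (no foci, sub-threshold diffuse metrics), lowDDR (1-2 discrete
#' foci < 1 um), highDDR (>= 3 discrete foci < 1 um), largeFocus (any focus
#' >= 1 um), diffuse (intense heterogeneous pan-nuclear staining).
#'
#' @param large_focus_min_diameter um; foci at or above it are "large".
#' @param low_ddr_max_count maximum focus count of the lowDDR class.
#' @param high_ddr_min_count minimum focus count of the highDDR class; must
#'   equal \code{low_ddr_max_count + 1}.
#' @param diffuse_min_coverage minimum supra-threshold coverage fraction.
#' @param diffuse_min_heterogeneity minimum intensity coefficient of variation.
#' @return list of class \code{classifierParams}.
#' @export
classifierParams <- function(large_focus_min_diameter = 1.0,
                             low_ddr_max_count = 2L,
                             high_ddr_min_count = 3L,
                             diffuse_min_coverage = 0.4,
                             diffuse_min_heterogeneity = 0.3) {
  if (high_ddr_min_count != low_ddr_max_count + 1L)
    stop("high_ddr_min_count must equal low_ddr_max_count + 1")
  if (large_focus_min_diameter <= 0)
    stop("large_focus_min_diameter must be > 0")
  structure(list(large_focus_min_diameter = large_focus_min_diameter,
                 low_ddr_max_count = as.integer(low_ddr_max_count),
                 high_ddr_min_count = as.integer(high_ddr_min_count),
                 diffuse_min_coverage = diffuse_min_coverage,
                 diffuse_min_heterogeneity = diffuse_min_heterogeneity),
            class = "classifierParams")
}

#' Classify one nucleus into a 53BP1 expression pattern
#'
#' Applies the five-class rule with precedence
#' diffuse > largeFocus > focus-count classes: a nucleus whose staining is
#' both extensive (coverage) and heterogeneous (coefficient of variation) is
#' diffuse regardless of its discrete foci; otherwise any focus at or above
#' the large-focus diameter makes it largeFocus; otherwise the discrete
#' focus count decides stable (0), lowDDR (1-2) or highDDR (>= 3).
#'
#' @param diameters_um numeric vector of detected focus diameters (um) for
#'   the nucleus; may be empty.
#' @param coverage supra-threshold coverage fraction.
#' @param heterogeneity intensity coefficient of variation.
#' @param params \code{\link{classifierParams}}.
#' @return one of \code{patternClasses()}.
#' @examples
#' classifyNucleus(c(0.4, 0.4, 0.5), 0.05, 0.2)  # highDDR
#' classifyNucleus(c(1.2, 0.3), 0.05, 0.2)       # largeFocus
#' @export
classifyNucleus <- function(diameters_um, coverage = 0, heterogeneity = 0,
                            params = classifierParams()) {
  if (length(diameters_um) &&
      (any(!is.finite(diameters_um)) || any(diameters_um < 0)))
    stop("focus diameters must be finite and non-negative (um)")
  if (coverage >= params$diffuse_min_coverage &&
      heterogeneity >= params$diffuse_min_heterogeneity)
    return("diffuse")
  if (length(diameters_um) &&
      any(diameters_um >= params$large_focus_min_diameter))
    return("largeFocus")
  n <- length(diameters_um)
  if (n >= params$high_ddr_min_count) return("highDDR")
  if (n >= 1) return("lowDDR")
  "stable"
}

#' Build per-nucleus records from detection results
#'
#' Joins segmented nuclei with their detected foci and diffuse metrics and
#' assigns each nucleus its pattern class.
#'
#' @param masks \code{nucleusMasks} from \code{\link{segmentNuclei}}.
#' @param foci data.frame from \code{\link{detectFoci}}.
#' @param diffuse data.frame from \code{\link{diffuseMetrics}}.
#' @param case_id case identifier stored in the records.
#' @param params \code{\link{classifierParams}}.
#' @param region optional data.frame (\code{nucleus_id},
#'   \code{region_label}) from \code{\link{assignRegion}}.
#' @return data.frame, one row per nucleus: \code{nucleus_id},
#'   \code{case_id}, \code{region_label}, \code{n_small_foci},
#'   \code{n_large_foci}, \code{coverage}, \code{heterogeneity},
#'   \code{pattern_class}, \code{center_x_um}, \code{center_y_um}.
#' @export
buildNucleusRecords <- function(masks, foci, diffuse, case_id = "case",
                                params = classifierParams(), region = NULL) {
  nuc <- masks$nuclei
  recs <- lapply(seq_len(nrow(nuc)), function(i) {
    id <- nuc$nucleus_id[i]
    d <- foci$diameter_um[foci$nucleus_id == id]
    dm <- diffuse[diffuse$nucleus_id == id, ]
    cov <- if (nrow(dm)) dm$coverage else 0
    het <- if (nrow(dm)) dm$heterogeneity else 0
    cls <- classifyNucleus(d, cov, het, params)
    n_large <- sum(d >= params$large_focus_min_diameter)
    data.frame(nucleus_id = id, case_id = case_id,
               region_label = "unassigned",
               n_small_foci = length(d) - n_large, n_large_foci = n_large,
               coverage = cov, heterogeneity = het, pattern_class = cls,
               center_x_um = nuc$center_x_um[i],
               center_y_um = nuc$center_y_um[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (!is.null(region)) {
    j <- match(out$nucleus_id, region$nucleus_id)
    out$region_label <- ifelse(is.na(j), "unassigned", region$region_label[j])
  }
  out
}

#' Region assignment parameters
#'
#' @param fdc_threshold,bcl2_threshold mean per-nucleus intensity above
#'   which the marker counts as positive.
#' @param ring_um width of the mantle-marginal ring around a germinal
#'   center: an FDC-negative, BCL2-positive nucleus within this distance of
#'   a GC nucleus is MM, otherwise LA.
#' @param fdc_channel,bcl2_channel channel names.
#' @return list of class \code{regionParams}.
#' @export
regionParams <- function(fdc_threshold = 60, bcl2_threshold = 60,
                         ring_um = 30, fdc_channel = "FDC",
                         bcl2_channel = "BCL2") {
  structure(list(fdc_threshold = fdc_threshold,
                 bcl2_threshold = bcl2_threshold, ring_um = ring_um,
                 fdc_channel = fdc_channel, bcl2_channel = bcl2_channel),
            class = "regionParams")
}

#' Gate nuclei to anatomical regions by FDC/BCL2 staining
#'
#' GC: FDC-positive, BCL2-negative. PF: FDC-positive, BCL2-positive.
#' MM: FDC-negative, BCL2-positive, within the ring distance of a GC
#' nucleus. LA: FDC-negative otherwise (variable BCL2).
#'
#' @param field an \linkS4class{ImageField}; must carry the gating channels,
#'   otherwise all nuclei are returned unassigned with a warning.
#' @param masks \code{nucleusMasks}.
#' @param cfg \code{\link{regionParams}}.
#' @return data.frame: \code{nucleus_id}, \code{region_label},
#'   \code{mean_fdc}, \code{mean_bcl2}.
#' @export
assignRegion <- function(field, masks, cfg = regionParams()) {
  nuc <- masks$nuclei
  if (!all(c(cfg$fdc_channel, cfg$bcl2_channel) %in% channelNames(field))) {
    warning("gating channels missing: all nuclei unassigned")
    return(data.frame(nucleus_id = nuc$nucleus_id,
                      region_label = "unassigned",
                      mean_fdc = NA_real_, mean_bcl2 = NA_real_))
  }
  labels <- masks$labels
  in_mask <- labels > 0
  labv <- labels[in_mask]
  fdc <- vapply(split(getChannel(field, cfg$fdc_channel)[in_mask], labv),
                mean, numeric(1))
  bcl2 <- vapply(split(getChannel(field, cfg$bcl2_channel)[in_mask], labv),
                 mean, numeric(1))
  ids <- as.integer(names(fdc))
  j <- match(nuc$nucleus_id, ids)
  fdc <- fdc[j]; bcl2 <- bcl2[j]
  fdc_pos <- fdc >= cfg$fdc_threshold
  bcl2_pos <- bcl2 >= cfg$bcl2_threshold
  lab <- ifelse(fdc_pos & !bcl2_pos, "GC",
         ifelse(fdc_pos & bcl2_pos, "PF", "LA"))
  # MM: FDC-negative BCL2-positive nuclei within ring distance of a GC nucleus
  gc_idx <- which(lab == "GC")
  cand <- which(!fdc_pos & bcl2_pos)
  if (length(gc_idx) && length(cand)) {
    for (i in cand) {
      d <- sqrt((nuc$center_x_um[gc_idx] - nuc$center_x_um[i])^2 +
                (nuc$center_y_um[gc_idx] - nuc$center_y_um[i])^2)
      if (min(d) <= cfg$ring_um) lab[i] <- "MM"
    }
  }
  data.frame(nucleus_id = nuc$nucleus_id, region_label = lab,
             mean_fdc = unname(fdc), mean_bcl2 = unname(bcl2),
             stringsAsFactors = FALSE)
}

#' Summarize the pattern-class composition of one case
#'
#' @param records per-nucleus records (one case) from
#'   \code{\link{buildNucleusRecords}}; must contain \code{pattern_class}.
#' @param lesion_label optional lesion annotation carried through.
#' @return one-row data.frame: \code{case_id}, \code{lesion_label},
#'   \code{n_nuclei}, one percent column per pattern class
#'   (\code{pct_stable} ... \code{pct_diffuse}) and
#'   \code{abnormal_fraction} (percent).
#' @examples
#' r <- data.frame(case_id = "c", pattern_class =
#'   rep(c("highDDR", "largeFocus", "stable"), c(10, 5, 15)))
#' summarizeCase(r)$abnormal_fraction  # 50
#' @export
summarizeCase <- function(records, lesion_label = NA_character_) {
  if (is.null(records) || nrow(records) == 0)
    stop("cannot summarize a case with zero nuclei")
  bad <- setdiff(unique(records$pattern_class), PATTERN_CLASSES)
  if (length(bad)) stop("unknown pattern class: ", paste(bad, collapse = ", "))
  n <- nrow(records)
  counts <- vapply(PATTERN_CLASSES,
                   function(k) sum(records$pattern_class == k), numeric(1))
  pct <- 100 * counts / n
  out <- data.frame(case_id = as.character(records$case_id[1]),
                    lesion_label = lesion_label, n_nuclei = n,
                    stringsAsFactors = FALSE)
  for (k in PATTERN_CLASSES) out[[paste0("pct_", k)]] <- pct[[k]]
  out$abnormal_fraction <- sum(pct[ABNORMAL_CLASSES])
  out
}
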