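#' Specify a synthetic cohort
#'
#' A cohort specification lists the cases to simulate (identifier, lesion
#' type, number of scored nuclei) together with the per-lesion abnormal
#' fraction distributions and class mixes, and a seed.
#'
#' @param cases data.frame with columns \code{case_id}, \code{lesion_label}
#'   and optionally \code{n_nuclei} (default filled with \code{n_nuclei}).
#' @param params lesion parameter table as from \code{\link{lesionParams}}.
#' @param n_nuclei default number of nuclei scored per case.
#' @param seed integer seed.
#' @return list of class \code{cohortSpec}.
#' @examples
#' sp <- cohortSpec(data.frame(case_id = c("c1", "c2"),
#'                             lesion_label = c("GC", "FL1")), seed = 1)
#' @export
cohortSpec <- function(cases, params = lesionParams(), n_nuclei = 300,
                       seed = 1) {
  stopifnot(is.data.frame(cases),
            all(c("case_id", "lesion_label") %in% names(cases)))
  if (is.null(cases$n_nuclei)) cases$n_nuclei <- n_nuclei
  if (any(cases$n_nuclei < 1)) stop("n_nuclei must be >= 1 for every case")
  missing <- setdiff(unique(cases$lesion_label), params$lesion_label)
  if (length(missing))
    stop("no parameters for lesion_label(s): ", paste(missing, collapse = ", "))
  structure(list(cases = cases, params = params, seed = as.integer(seed)),
            class = "cohortSpec")
}

#' Sample per-case abnormal fractions for a cohort
#'
#' Draws each case's true abnormal 53BP1 fraction from the bounded Beta
#' distribution fitted to its lesion type's published median and
#' interquartile range. Reproducible for a fixed spec seed.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return data.frame with columns \code{case_id}, \code{lesion_label},
#'   \code{n_nuclei}, \code{true_abnormal_fraction} (percent) and
#'   \code{is_malignant}.
#' @examples
#' sp <- cohortSpec(data.frame(case_id = c("c1", "c2"),
#'                             lesion_label = c("GC", "FL1")), seed = 1)
#' sampleCohort(sp)
#' @export
sampleCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  p <- spec$params
  fits <- lapply(unique(spec$cases$lesion_label), function(lab) {
    row <- p[p$lesion_label == lab, ]
    fitBetaQuantiles(row$abnormal_median, row$abnormal_iqr_lo,
                     row$abnormal_iqr_hi, label = lab)
  })
  names(fits) <- unique(spec$cases$lesion_label)
  out <- spec$cases
  withr::with_seed(spec$seed, {
    out$true_abnormal_fraction <- vapply(seq_len(nrow(out)), function(i) {
      rAbnormalFraction(1, fits[[out$lesion_label[i]]])
    }, numeric(1))
  })
  out$is_malignant <-
    p$is_malignant[match(out$lesion_label, p$lesion_label)]
  rownames(out) <- NULL
  out
}

# per-class focus-count / diameter sampling rules; diameters in um.
# Small foci sit well below the 1-um class boundary and large foci well
# above it, mirroring the visually unambiguous patterns being emulated.
.sampleClassFoci <- function(class) {
  switch(class,
    stable = list(n = 0L, diams = numeric(0)),
    lowDDR = {
      n <- sample(1:2, 1)
      list(n = n, diams = runif(n, 0.35, 0.7))
    },
    highDDR = {
      n <- sample(3:7, 1)
      list(n = n, diams = runif(n, 0.35, 0.7))
    },
    largeFocus = {
      nsmall <- sample(0:2, 1)
      list(n = nsmall + 1L,
           diams = c(runif(1, 1.25, 1.8), runif(nsmall, 0.35, 0.6)))
    },
    diffuse = list(n = 0L, diams = numeric(0)),
    stop("unknown pattern class: ", class)
  )
}

#' Realize per-nucleus ground truth for one case
#'
#' Allocates a case's nuclei over the five 53BP1 pattern classes by a
#' multinomial draw whose abnormal-class probabilities total the case's true
#' abnormal fraction, then samples per-nucleus focus counts and diameters
#' consistent with each class definition (lowDDR: 1-2 foci < 1 um; highDDR:
#' >= 3 foci < 1 um; largeFocus: one focus >= 1 um plus 0-2 small; diffuse:
#' pan-nuclear texture, no discrete foci).
#'
#' @param case_row one row of the \code{\link{sampleCohort}} output (list or
#'   single-row data.frame with \code{case_id}, \code{n_nuclei},
#'   \code{true_abnormal_fraction}).
#' @param params single lesion row of \code{\link{lesionParams}} supplying
#'   the class mixes.
#' @param seed integer seed.
#' @param nucleus_radius_range nucleus radius range in um.
#' @return data.frame (one row per nucleus): \code{nucleus_id},
#'   \code{case_id}, \code{true_pattern_class}, \code{true_focus_count},
#'   \code{radius_um}, and list-column \code{true_focus_diameters};
#'   attribute \code{true_fractions} gives the realized class fractions
#'   (percent, summing to 100).
#' @export
composeNucleusTruths <- function(case_row, params, seed = 1,
                                 nucleus_radius_range = c(2.6, 3.8)) {
  fr <- case_row$true_abnormal_fraction
  if (is.na(fr) || fr < 0 || fr > 100)
    stop("true_abnormal_fraction must lie in [0, 100]")
  n <- as.integer(case_row$n_nuclei)
  p_ab <- fr / 100
  probs <- c(stable = (1 - p_ab) * params$mix_stable,
             lowDDR = (1 - p_ab) * params$mix_lowDDR,
             highDDR = p_ab * params$mix_highDDR,
             largeFocus = p_ab * params$mix_largeFocus,
             diffuse = p_ab * params$mix_diffuse)
  withr::with_seed(seed, {
    counts <- as.vector(rmultinom(1, n, probs))
    cls <- sample(rep(PATTERN_CLASSES, counts))
    foci <- lapply(cls, .sampleClassFoci)
    radii <- runif(n, nucleus_radius_range[1], nucleus_radius_range[2])
  })
  truth <- data.frame(
    nucleus_id = seq_len(n),
    case_id = rep(as.character(case_row$case_id), n),
    true_pattern_class = cls,
    true_focus_count = vapply(foci, function(f) f$n, integer(1)),
    radius_um = radii,
    stringsAsFactors = FALSE
  )
  truth$true_focus_diameters <- I(lapply(foci, function(f) f$diams))
  fracs <- 100 * counts / n
  names(fracs) <- PATTERN_CLASSES
  attr(truth, "true_fractions") <- fracs
  attr(truth, "true_abnormal_fraction") <- sum(fracs[ABNORMAL_CLASSES])
  truth
}
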