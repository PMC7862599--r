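#' Reference abnormal-fraction distributions per lesion type
#'
#' Published per-case distributions of the abnormal 53BP1 fraction (percent of
#' nuclei classified high DDR, large focus or diffuse), as median and
#' interquartile range, for benign lymphoid regions (GC, PF, MM, LA) and
#' lymphoma entities (MALT, MCL, FL grades 1/2/3A, DLBCL, small- and
#' large-cell T-cell lymphoma: TS, TL). These drive the synthetic cohort
#' generator.
#'
#' @param abnormal_mix proportions over (highDDR, largeFocus, diffuse) within
#'   the abnormal compartment; must sum to 1.
#' @param normal_mix proportions over (stable, lowDDR) within the normal
#'   compartment; must sum to 1.
#' @return data.frame with columns \code{lesion_label}, \code{abnormal_median},
#'   \code{abnormal_iqr_lo}, \code{abnormal_iqr_hi}, \code{n_cases},
#'   \code{is_malignant}, and the class-mix columns \code{mix_highDDR},
#'   \code{mix_largeFocus}, \code{mix_diffuse}, \code{mix_stable},
#'   \code{mix_lowDDR}.
#' @examples
#' lesionParams()[, 1:5]
#' @export
lesionParams <- function(abnormal_mix = c(0.6, 0.3, 0.1),
                         normal_mix = c(0.6, 0.4)) {
  stopifnot(length(abnormal_mix) == 3, length(normal_mix) == 2)
  if (abs(sum(abnormal_mix) - 1) > 1e-9 || abs(sum(normal_mix) - 1) > 1e-9)
    stop("abnormal_mix and normal_mix must each sum to 1")
  df <- data.frame(
    lesion_label = c("GC", "PF", "MM", "LA",
                     "MALT", "MCL", "FL1", "FL2", "FL3A", "DLBCL", "TS", "TL"),
    abnormal_median = c(15.6, 20.8, 23.9, 23.3,
                        19.3, 44.5, 52.1, 41.9, 29.8, 27.6, 29.9, 30),
    abnormal_iqr_lo = c(9.3, 18.9, 19, 18.8,
                        14.7, 32, 40.6, 35.2, 26.4, 20.3, 25.5, 20.6),
    abnormal_iqr_hi = c(19.9, 23.6, 26.3, 27.7,
                        34.1, 52.9, 56, 51.5, 33, 34.8, 37.2, 38.8),
    n_cases = c(25, 48, 44, 28, 19, 11, 14, 18, 6, 29, 5, 5),
    is_malignant = c(FALSE, FALSE, FALSE, FALSE,
                     TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  df$mix_highDDR    <- abnormal_mix[1]
  df$mix_largeFocus <- abnormal_mix[2]
  df$mix_diffuse    <- abnormal_mix[3]
  df$mix_stable     <- normal_mix[1]
  df$mix_lowDDR     <- normal_mix[2]
  df
}

#' Fit a bounded Beta distribution to a (median, IQR) percent summary
#'
#' Finds a location-scale Beta distribution on a sub-interval [L, U] of
#' [0, 100] percent whose 25th/50th/75th percentiles match the given median
#' and interquartile range. Shapes and support are fitted jointly by
#' multi-start Nelder-Mead least squares on the three quantiles; a plain Beta
#' on [0, 100] has only two free parameters and cannot reproduce the skewed
#' summaries observed for several lesion types, whereas the four-parameter
#' family recovers all three quantiles essentially exactly. A zero-width
#' summary (lo == median == hi) returns a degenerate point distribution.
#'
#' @param median,iqr_lo,iqr_hi percent summaries, 0 <= lo <= median <= hi <= 100.
#' @param label optional lesion label used in error messages.
#' @return list with elements \code{degenerate} (logical) and either
#'   \code{value} (percent; degenerate case) or \code{shape1}, \code{shape2},
#'   \code{support_lo}, \code{support_hi} (percent) and \code{fitted_q}
#'   (fitted 25/50/75 percentiles in percent).
#' @examples
#' f <- fitBetaQuantiles(52.1, 40.6, 56)
#' round(f$fitted_q, 2)
#' @export
fitBetaQuantiles <- function(median, iqr_lo, iqr_hi, label = NULL) {
  lab <- if (is.null(label)) "" else paste0(" for lesion_label '", label, "'")
  if (any(!is.finite(c(median, iqr_lo, iqr_hi))) ||
      iqr_lo < 0 || iqr_hi > 100 ||
      iqr_lo > median || median > iqr_hi)
    stop("unfittable abnormal-fraction parameters", lab,
         ": need 0 <= iqr_lo <= median <= iqr_hi <= 100, got (",
         iqr_lo, ", ", median, ", ", iqr_hi, ")")
  if (iqr_hi - iqr_lo < 1e-12)
    return(list(degenerate = TRUE, value = median))

  target <- c(iqr_lo, median, iqr_hi) / 100
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    L <- 1 / (1 + exp(-p[3])); W <- (1 - L) / (1 + exp(-p[4]))
    q <- L + W * suppressWarnings(qbeta(c(0.25, 0.5, 0.75), a, b))
    # tiny ridge keeps shapes near 2 among equivalent exact fits
    sum((q - target)^2) + 1e-7 * sum((p[1:2] - log(2))^2)
  }
  best <- NULL
  for (wm in c(1.5, 3, 6, 12)) {
    for (loff in c(0, 0.5, 1)) {
      w0 <- min(1, wm * (iqr_hi - iqr_lo) / 100)
      L0 <- max(1e-3, min(median / 100 - loff * w0 / 2, 1 - w0))
      start <- c(log(2), log(2), log(L0 / (1 - L0)),
                 log(max(w0 / ((1 - L0) - w0 + 1e-6), 1e-3)))
      f <- try(suppressWarnings(
        optim(start, obj, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-14))), silent = TRUE)
      if (!inherits(f, "try-error") && (is.null(best) || f$value < best$value))
        best <- f
    }
  }
  if (is.null(best))
    stop("Beta quantile fit failed", lab)
  p <- best$par
  a <- exp(p[1]); b <- exp(p[2])
  L <- 1 / (1 + exp(-p[3])); W <- (1 - L) / (1 + exp(-p[4]))
  list(degenerate = FALSE, shape1 = a, shape2 = b,
       support_lo = 100 * L, support_hi = 100 * (L + W),
       fitted_q = 100 * (L + W * qbeta(c(0.25, 0.5, 0.75), a, b)))
}

#' Draw abnormal fractions from a fitted lesion distribution
#'
#' @param n number of draws.
#' @param fit result of \code{\link{fitBetaQuantiles}}.
#' @return numeric vector of percent values in [0, 100].
#' @export
rAbnormalFraction <- function(n, fit) {
  if (isTRUE(fit$degenerate)) return(rep(fit$value, n))
  fit$support_lo + (fit$support_hi - fit$support_lo) *
    rbeta(n, fit$shape1, fit$shape2)
}
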