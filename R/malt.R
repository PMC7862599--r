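#' Diagnostic cutoffs for the abnormal 53BP1 fraction
#'
#' Youden-optimal cutoffs (percent abnormal nuclei) reported for the three
#' lesion contrasts: follicular-shape lesions (FL vs GC/PF), small-cell
#' lesions (MCL/FL vs PF/MM/LA) and large-cell lesions (DLBCL vs GC).
#'
#' @param follicular_cutoff,small_cell_cutoff,large_cell_cutoff percent.
#' @return list of class \code{diagnosticThresholds}.
#' @export
diagnosticThresholds <- function(follicular_cutoff = 27.2,
                                 small_cell_cutoff = 33.6,
                                 large_cell_cutoff = 22.9) {
  for (v in c(follicular_cutoff, small_cell_cutoff, large_cell_cutoff))
    if (!is.finite(v) || v <= 0 || v >= 100)
      stop("cutoffs must lie in (0, 100) percent")
  structure(list(follicular_cutoff = follicular_cutoff,
                 small_cell_cutoff = small_cell_cutoff,
                 large_cell_cutoff = large_cell_cutoff),
            class = "diagnosticThresholds")
}

#' Load the packaged MALT lymphoma case table
#'
#' Nineteen MALT lymphoma cases with their abnormal 53BP1 fraction, FISH
#' status for t(11;18)(q21;q21) and trisomy 18q21 (+, -, +/- equivocal,
#' NS no signals), H. pylori eradication and radiation therapy, and
#' response (+, -, ND no data, DT during therapy).
#'
#' @return data.frame with 19 rows.
#' @export
maltTable <- function() {
  path <- system.file("extdata", "table4.csv", package = "ddrFoci",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(abnormal_pct = "numeric"))
}

.VALID_STATUS <- c("+", "-", "+/-", "NS", "ND", "DT")

#' Association analysis of abnormal 53BP1 fraction with FISH status and
#' therapy response in MALT lymphoma
#'
#' Splits cases into high- and low-abnormal groups at the small-cell
#' cutoff (high: abnormal fraction strictly above it), cross-tabulates the
#' high group with FISH aberration status, tests the association between
#' abnormal fraction and chromosomal aberration by the exact Wilcoxon
#' rank-sum test, and summarizes therapy response in each group excluding
#' cases with no data (ND) or still during therapy (DT).
#'
#' The primary association test compares t(11;18)(q21;q21)-positive against
#' t(11;18)-negative cases (NS cases excluded): recomputing the exact test
#' on the packaged table shows this grouping is the one behind the
#' published association p-value. A secondary comparison of
#' aberration-positive cases (t(11;18) positive or trisomy
#' positive/equivocal) against fully wild-type cases is also reported.
#'
#' @param table data.frame with columns \code{abnormal_pct}, \code{t1118},
#'   \code{trisomy18q21}, \code{eradication}, \code{radiation},
#'   \code{response} (status tokens +, -, +/-, NS, ND, DT); defaults to the
#'   packaged case table.
#' @param thresholds \code{\link{diagnosticThresholds}}.
#' @return list of class \code{maltAssociation} with components:
#'   \code{n_cases}; \code{n_high}, \code{pct_high}; \code{n_high_t1118},
#'   \code{pct_high_t1118}; \code{n_high_trisomy};
#'   \code{low_group} (counts translocated / wild / no_signal);
#'   \code{wilcoxon} (exact test, t(11;18)+ vs t(11;18)-, NS excluded);
#'   \code{wilcoxon_aberration_wild} (exact test, aberration+ vs wild);
#'   \code{n_aberration_pos}, \code{n_wild};
#'   \code{therapy} (per group: n evaluable, responders, percent).
#' @examples
#' maltAssociation()
#' @export
maltAssociation <- function(table = maltTable(),
                            thresholds = diagnosticThresholds()) {
  req <- c("abnormal_pct", "t1118", "trisomy18q21", "response")
  if (!all(req %in% names(table)))
    stop("table must contain columns: ", paste(req, collapse = ", "))
  toks <- unique(c(table$t1118, table$trisomy18q21, table$eradication,
                   table$radiation, table$response))
  bad <- setdiff(toks, .VALID_STATUS)
  if (length(bad))
    stop("unknown status token(s): ", paste(bad, collapse = ", "))

  cutoff <- thresholds$small_cell_cutoff
  high <- table$abnormal_pct > cutoff
  aber_pos <- table$t1118 == "+" | table$trisomy18q21 %in% c("+", "+/-")
  wild <- table$t1118 == "-" & table$trisomy18q21 == "-"
  ns <- table$t1118 == "NS"

  null_cmp <- function(na, nb)
    structure(list(statistic = NA_real_, p_two_sided = 1, exact = TRUE,
                   n_a = na, n_b = nb), class = "groupComparison")
  t_pos <- table$t1118 == "+"
  t_neg <- table$t1118 == "-"
  wil <- if (any(t_pos) && any(t_neg))
    exactWilcoxon(table$abnormal_pct[t_pos], table$abnormal_pct[t_neg])
  else null_cmp(sum(t_pos), sum(t_neg))
  wil_aw <- if (any(aber_pos) && any(wild))
    exactWilcoxon(table$abnormal_pct[aber_pos], table$abnormal_pct[wild])
  else null_cmp(sum(aber_pos), sum(wild))

  evaluable <- !(table$response %in% c("ND", "DT"))
  ther <- function(sel) {
    n <- sum(sel & evaluable)
    r <- sum(sel & evaluable & table$response == "+")
    list(n = n, responders = r, pct = if (n) 100 * r / n else NA_real_)
  }
  structure(list(
    cutoff = cutoff,
    n_cases = nrow(table),
    n_high = sum(high), pct_high = 100 * mean(high),
    n_high_t1118 = sum(high & table$t1118 == "+"),
    pct_high_t1118 = if (sum(high)) 100 * sum(high & table$t1118 == "+") / sum(high) else NA_real_,
    n_high_trisomy = sum(high & table$trisomy18q21 == "+"),
    low_group = list(translocated = sum(!high & table$t1118 == "+"),
                     wild = sum(!high & wild),
                     no_signal = sum(!high & ns)),
    n_aberration_pos = sum(aber_pos), n_wild = sum(wild),
    wilcoxon = wil,
    wilcoxon_aberration_wild = wil_aw,
    therapy = list(high = ther(high), low = ther(!high))
  ), class = "maltAssociation")
}

#' @export
print.maltAssociation <- function(x, ...) {
  cat(sprintf("MALT lymphoma association analysis (%d cases, cutoff %.1f%%)\n",
              x$n_cases, x$cutoff))
  cat(sprintf("  high-abnormal: %d (%.1f%%); of these t(11;18)+: %d (%.1f%%), trisomy+: %d\n",
              x$n_high, x$pct_high, x$n_high_t1118, x$pct_high_t1118,
              x$n_high_trisomy))
  cat(sprintf("  low-abnormal: %d translocated, %d wild, %d no-signal\n",
              x$low_group$translocated, x$low_group$wild,
              x$low_group$no_signal))
  cat(sprintf("  t(11;18)+ (n=%d) vs t(11;18)- (n=%d): exact Wilcoxon p = %.4f\n",
              x$wilcoxon$n_a, x$wilcoxon$n_b, x$wilcoxon$p_two_sided))
  cat(sprintf("  aberration+ (n=%d) vs wild (n=%d): exact Wilcoxon p = %.4f\n",
              x$n_aberration_pos, x$n_wild,
              x$wilcoxon_aberration_wild$p_two_sided))
  cat(sprintf("  responders: high %d/%d (%.1f%%), low %d/%d (%.1f%%)\n",
              x$therapy$high$responders, x$therapy$high$n, x$therapy$high$pct,
              x$therapy$low$responders, x$therapy$low$n, x$therapy$low$pct))
  invisible(x)
}

#' Decision-flow suggestion for a follicular-shape B-cell lymphoid lesion
#'
#' Configurable rule engine mirroring the proposed diagnostic flow:
#' follicular-shape lesions are compared against the follicular cutoff
#' (FL-suspect vs benign GC/PF); small-cell lesions against the small-cell
#' cutoff (MCL/FL-suspect vs benign PF/MM/LA); large-cell lesions against
#' the large-cell cutoff; MALT cases are routed to FISH and labeled
#' high-risk (eradication-therapy-resistant) when the slide carries the
#' t(11;18)(q21;q21) translocation, low-risk otherwise. Scores at or above
#' the cutoff are called positive. Every decision is recorded in the trace.
#'
#' @param shape lesion presentation: one of \code{"follicular"},
#'   \code{"small_cell"}, \code{"large_cell"}, \code{"malt"}.
#' @param abnormal_pct abnormal 53BP1 fraction, percent.
#' @param thresholds \code{\link{diagnosticThresholds}}.
#' @param fish optional one-row result of \code{\link{summarizeFishCase}};
#'   required for \code{shape = "malt"}.
#' @return list: \code{label}, \code{trace} (character vector of applied
#'   rules).
#' @examples
#' diagnoseLesion("follicular", 52.1)$label
#' @export
diagnoseLesion <- function(shape = c("follicular", "small_cell",
                                     "large_cell", "malt"),
                           abnormal_pct,
                           thresholds = diagnosticThresholds(),
                           fish = NULL) {
  shape <- match.arg(shape)
  if (!is.finite(abnormal_pct) || abnormal_pct < 0 || abnormal_pct > 100)
    stop("abnormal_pct must lie in [0, 100]")
  trace <- character(0)
  note <- function(...) trace <<- c(trace, sprintf(...))
  cmp <- function(cut, pos, neg) {
    note("abnormal fraction %.1f%% vs cutoff %.1f%%", abnormal_pct, cut)
    if (abnormal_pct >= cut) { note("above cutoff -> %s", pos); pos }
    else { note("below cutoff -> %s", neg); neg }
  }
  label <- switch(shape,
    follicular = cmp(thresholds$follicular_cutoff,
                     "FL-suspect", "benign-GC/PF-consistent"),
    small_cell = cmp(thresholds$small_cell_cutoff,
                     "small-B-cell-lymphoma-suspect",
                     "benign-PF/MM/LA-consistent"),
    large_cell = cmp(thresholds$large_cell_cutoff,
                     "large-B-cell-lymphoma-suspect", "benign-GC-consistent"),
    malt = {
      if (is.null(fish))
        stop("shape = 'malt' requires a FISH case result")
      note("MALT lesion routed to FISH; case call: %s", fish$case_call)
      if (identical(fish$case_call, "translocation")) {
        note("t(11;18)(q21;q21) present -> eradication-resistant")
        "high-risk MALT"
      } else "low-risk MALT"
    })
  list(label = label, trace = trace)
}
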