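#' FISH signal-calling parameters
#'
#' @param green_channel,orange_channel channel names of the two probes.
#' @param diam_range detectable signal diameter range, um.
#' @param max_pair_distance colocalization radius: a green-orange pair
#'   within this centroid distance (um) counts as one fusion signal.
#' @param min_nuclei minimum informative nuclei for a case call.
#' @param case_fraction_threshold percent of informative nuclei at or above
#'   which a slide is called translocation- or trisomy-positive.
#' @param n_scales,rel_threshold,min_snr forwarded to the blob detector.
#' @return list of class \code{fishParams}.
#' @export
fishParams <- function(green_channel = "green", orange_channel = "orange",
                       diam_range = c(0.2, 1.2), max_pair_distance = 0.6,
                       min_nuclei = 150, case_fraction_threshold = 10,
                       n_scales = 5, rel_threshold = 0.2, min_snr = 6) {
  structure(list(green_channel = green_channel,
                 orange_channel = orange_channel, diam_range = diam_range,
                 max_pair_distance = max_pair_distance,
                 min_nuclei = min_nuclei,
                 case_fraction_threshold = case_fraction_threshold,
                 n_scales = n_scales, rel_threshold = rel_threshold,
                 min_snr = min_snr), class = "fishParams")
}

#' Detect dual-color FISH signals per nucleus
#'
#' Runs the multiscale LoG blob detector (\code{\link{detectFoci}}) on the
#' green and orange probe channels within segmented nuclei.
#'
#' @param field an \linkS4class{ImageField} with green and orange channels.
#' @param masks \code{nucleusMasks}.
#' @param cfg \code{\link{fishParams}}.
#' @return data.frame: \code{nucleus_id}, \code{color}, \code{x_um},
#'   \code{y_um}, \code{diameter_um}.
#' @export
detectFishSignals <- function(field, masks, cfg = fishParams()) {
  for (ch in c(cfg$green_channel, cfg$orange_channel))
    if (!ch %in% channelNames(field))
      stop("required FISH channel '", ch, "' missing")
  one <- function(channel, color) {
    f <- detectFoci(field, masks,
                    fociParams(channel = channel, diam_range = cfg$diam_range,
                               n_scales = cfg$n_scales,
                               rel_threshold = cfg$rel_threshold,
                               min_snr = cfg$min_snr))
    if (nrow(f) == 0)
      return(data.frame(nucleus_id = integer(0), color = character(0),
                        x_um = numeric(0), y_um = numeric(0),
                        diameter_um = numeric(0)))
    data.frame(nucleus_id = f$nucleus_id, color = color, x_um = f$x_um,
               y_um = f$y_um, diameter_um = f$diameter_um,
               stringsAsFactors = FALSE)
  }
  rbind(one(cfg$green_channel, "green"), one(cfg$orange_channel, "orange"))
}

#' Pair green and orange signals into fusion signals
#'
#' Greedy minimum-distance matching: green-orange centroid pairs are
#' accepted in increasing distance order while both partners are unused and
#' the distance does not exceed the colocalization radius. Matched pairs
#' count as fusion signals and leave the singleton counts.
#'
#' @param signals data.frame of one nucleus's signals
#'   (\code{color}, \code{x_um}, \code{y_um}).
#' @param max_pair_distance colocalization radius, um.
#' @return list: \code{n_fusion}, \code{n_green}, \code{n_orange}
#'   (residual singletons).
#' @examples
#' s <- data.frame(color = c("green", "orange"), x_um = c(0, 0.1),
#'                 y_um = c(0, 0))
#' pairFusions(s, 0.6)
#' @export
pairFusions <- function(signals, max_pair_distance = 0.6) {
  g <- which(signals$color == "green")
  o <- which(signals$color == "orange")
  if (length(g) == 0 || length(o) == 0)
    return(list(n_fusion = 0L, n_green = length(g), n_orange = length(o)))
  d <- outer(seq_along(g), seq_along(o), function(i, j)
    sqrt((signals$x_um[g[i]] - signals$x_um[o[j]])^2 +
         (signals$y_um[g[i]] - signals$y_um[o[j]])^2))
  ord <- order(d)
  used_g <- logical(length(g)); used_o <- logical(length(o))
  nf <- 0L
  for (k in ord) {
    if (d[k] > max_pair_distance) break
    i <- (k - 1) %% length(g) + 1
    j <- (k - 1) %/% length(g) + 1
    if (!used_g[i] && !used_o[j]) {
      used_g[i] <- TRUE; used_o[j] <- TRUE; nf <- nf + 1L
    }
  }
  list(n_fusion = nf, n_green = sum(!used_g), n_orange = sum(!used_o))
}

#' Call the genotype of one nucleus from its signal counts
#'
#' uninformative: no signals at all. fusion: one or two fusion signals.
#' trisomy18q21: no fusion, three orange and two green signals. wild: no
#' fusion and at most two signals of each color (signal loss through
#' truncation tolerated). Everything else: other.
#'
#' @param n_green,n_orange residual singleton counts after fusion pairing.
#' @param n_fusion fusion-signal count.
#' @return genotype string.
#' @examples
#' callNucleusGenotype(2, 2, 0)  # wild
#' callNucleusGenotype(1, 1, 1)  # fusion
#' callNucleusGenotype(2, 3, 0)  # trisomy18q21
#' @export
callNucleusGenotype <- function(n_green, n_orange, n_fusion) {
  stopifnot(n_green >= 0, n_orange >= 0, n_fusion >= 0)
  total <- n_green + n_orange + 2 * n_fusion
  if (total == 0) return("uninformative")
  if (n_fusion %in% c(1L, 2L)) return("fusion")
  if (n_fusion == 0 && n_orange == 3 && n_green == 2) return("trisomy18q21")
  if (n_fusion == 0 && n_green <= 2 && n_orange <= 2) return("wild")
  "other"
}

#' Per-nucleus FISH calls for a whole field or slide
#'
#' @param signals data.frame from \code{\link{detectFishSignals}} (may span
#'   several nuclei).
#' @param nucleus_ids nuclei to call (defaults to all segmented nuclei
#'   present in \code{signals}; pass the full segmentation id list so
#'   signal-free nuclei are recorded as uninformative).
#' @param cfg \code{\link{fishParams}}.
#' @return data.frame: \code{nucleus_id}, \code{n_green}, \code{n_orange},
#'   \code{n_fusion}, \code{genotype}.
#' @export
callFishNuclei <- function(signals, nucleus_ids = NULL, cfg = fishParams()) {
  if (is.null(nucleus_ids)) nucleus_ids <- sort(unique(signals$nucleus_id))
  rows <- lapply(nucleus_ids, function(id) {
    s <- signals[signals$nucleus_id == id, , drop = FALSE]
    p <- pairFusions(s, cfg$max_pair_distance)
    data.frame(nucleus_id = id, n_green = p$n_green, n_orange = p$n_orange,
               n_fusion = p$n_fusion,
               genotype = callNucleusGenotype(p$n_green, p$n_orange,
                                              p$n_fusion),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarize a FISH slide into a case call
#'
#' Informative nuclei are those with at least one hybridization signal.
#' Fusion and trisomy fractions are computed over informative nuclei only.
#' The slide is NS (no signals / not scorable) when fewer than
#' \code{min_nuclei} informative nuclei were evaluated; otherwise it is
#' called translocation if the fusion fraction reaches the case threshold,
#' else trisomy if the trisomy fraction does, else wild. A nonzero
#' sub-threshold trisomy fraction is flagged as equivocal.
#'
#' @param calls data.frame from \code{\link{callFishNuclei}} (one slide).
#' @param cfg \code{\link{fishParams}}.
#' @param case_id case identifier.
#' @return one-row data.frame: \code{case_id}, \code{n_nuclei},
#'   \code{n_informative}, \code{fusion_fraction}, \code{trisomy_fraction}
#'   (percent), \code{case_call} in \{translocation, trisomy, wild, NS\},
#'   \code{trisomy_equivocal} flag.
#' @export
summarizeFishCase <- function(calls, cfg = fishParams(), case_id = "case") {
  if (is.null(calls) || nrow(calls) == 0)
    stop("no nucleus calls supplied")
  inf <- calls[calls$genotype != "uninformative", , drop = FALSE]
  n_inf <- nrow(inf)
  fus <- if (n_inf) 100 * mean(inf$genotype == "fusion") else 0
  tri <- if (n_inf) 100 * mean(inf$genotype == "trisomy18q21") else 0
  call <- if (n_inf < cfg$min_nuclei) "NS"
    else if (fus >= cfg$case_fraction_threshold) "translocation"
    else if (tri >= cfg$case_fraction_threshold) "trisomy"
    else "wild"
  data.frame(case_id = case_id, n_nuclei = nrow(calls),
             n_informative = n_inf, fusion_fraction = fus,
             trisomy_fraction = tri, case_call = call,
             trisomy_equivocal = call != "NS" && tri > 0 &&
               tri < cfg$case_fraction_threshold,
             stringsAsFactors = FALSE)
}
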