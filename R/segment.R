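#' Maximum-intensity projection of a Z-stack
#'
#' Collapses a stack of equally shaped 2-D frames into one frame by the
#' per-pixel maximum, the projection under which every focus present in any
#' optical section remains visible.
#'
#' @param stack list of numeric matrices, or a 3-D array with the third
#'   dimension indexing frames.
#' @return numeric matrix of the same 2-D shape.
#' @examples
#' projectZstack(list(matrix(1, 2, 2), matrix(0, 2, 2)))
#' @export
projectZstack <- function(stack) {
  if (is.array(stack) && length(dim(stack)) == 3)
    stack <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  if (!is.list(stack) || length(stack) == 0)
    stop("stack must be a non-empty list of frames or a 3-D array")
  d <- dim(stack[[1]])
  if (!all(vapply(stack, function(m) identical(dim(m), d), logical(1))))
    stop("all frames must share the same shape")
  Reduce(pmax, stack)
}

#' Nucleus segmentation parameters
#'
#' @param min_area_um2 minimum nucleus area kept, in square micrometres.
#' @param exclude_border drop nuclei touching the field border (partial
#'   nuclei bias focus counts).
#' @param dapi_channel name of the DAPI channel.
#' @param smooth_sigma_px Gaussian pre-smoothing sigma in pixels.
#' @param watershed_tolerance tolerance of the distance-transform watershed.
#' @return list of class \code{segmentationParams}.
#' @export
segmentationParams <- function(min_area_um2 = 15, exclude_border = TRUE,
                               dapi_channel = "DAPI", smooth_sigma_px = 1.5,
                               watershed_tolerance = 1) {
  structure(list(min_area_um2 = min_area_um2, exclude_border = exclude_border,
                 dapi_channel = dapi_channel, smooth_sigma_px = smooth_sigma_px,
                 watershed_tolerance = watershed_tolerance),
            class = "segmentationParams")
}

#' Segment nuclei from the DAPI channel
#'
#' Otsu threshold on the lightly smoothed DAPI channel, hole filling,
#' distance-transform watershed to split touching nuclei, then removal of
#' regions below the minimum area and (optionally) touching the border.
#' Labels are renumbered in raster-scan order, so segmentation is
#' deterministic for a given field.
#'
#' @param field an \linkS4class{ImageField} with a DAPI channel.
#' @param cfg \code{\link{segmentationParams}}.
#' @return list of class \code{nucleusMasks}: \code{labels} (integer matrix,
#'   0 = background), \code{nuclei} (data.frame with \code{nucleus_id},
#'   \code{center_x_um}, \code{center_y_um}, \code{area_um2}), and
#'   \code{pixel_size}.
#' @export
segmentNuclei <- function(field, cfg = segmentationParams()) {
  dapi <- getChannel(field, cfg$dapi_channel)
  ps <- pixelSize(field)
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(dapi), ncol(dapi)),
                   nuclei = data.frame(nucleus_id = integer(0),
                                       center_x_um = numeric(0),
                                       center_y_um = numeric(0),
                                       area_um2 = numeric(0)),
                   pixel_size = ps), class = "nucleusMasks")
  }
  rng <- range(dapi)
  if (!is.finite(diff(rng)) || diff(rng) <= 0) {
    warning("blank DAPI channel: no nuclei segmented")
    return(empty())
  }
  norm <- (dapi - rng[1]) / diff(rng)
  if (cfg$smooth_sigma_px > 0) {
    k <- EBImage::makeBrush(2 * ceiling(3 * cfg$smooth_sigma_px) + 1,
                            shape = "gaussian", sigma = cfg$smooth_sigma_px)
    norm <- EBImage::filter2(norm, k)
  }
  thr <- EBImage::otsu(EBImage::Image(norm))
  bw <- norm > thr
  if (!any(bw)) {
    warning("no foreground after Otsu threshold: no nuclei segmented")
    return(empty())
  }
  bw <- EBImage::fillHull(bw)
  dm <- EBImage::distmap(bw)
  labels <- EBImage::imageData(EBImage::watershed(dm, tolerance = cfg$watershed_tolerance))
  # drop small regions and border-touching regions
  tab <- tabulate(labels)
  min_px <- cfg$min_area_um2 / ps^2
  drop <- which(tab < min_px)
  if (cfg$exclude_border) {
    border <- unique(c(labels[1, ], labels[nrow(labels), ],
                       labels[, 1], labels[, ncol(labels)]))
    drop <- union(drop, border[border > 0])
  }
  if (length(drop)) labels[labels %in% drop] <- 0L
  # deterministic renumbering in raster (column-major) order
  ids <- unique(labels[labels > 0])
  if (length(ids) == 0) {
    warning("no nuclei passed the area/border filters")
    return(empty())
  }
  remap <- integer(max(ids)); remap[ids] <- seq_along(ids)
  labels[labels > 0] <- remap[labels[labels > 0]]
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  rows <- row(labels)[labels > 0]; cols <- col(labels)[labels > 0]
  lab <- labels[labels > 0]
  cy <- vapply(split(rows, lab), mean, numeric(1))
  cx <- vapply(split(cols, lab), mean, numeric(1))
  ar <- vapply(split(lab, lab), length, numeric(1))
  structure(list(labels = labels,
                 nuclei = data.frame(nucleus_id = as.integer(names(cy)),
                                     center_x_um = (cx - 1) * ps,
                                     center_y_um = (cy - 1) * ps,
                                     area_um2 = ar * ps^2,
                                     row.names = NULL),
                 pixel_size = ps),
            class = "nucleusMasks")
}

#' Focus detection parameters
#'
#' @param channel intensity channel to detect in.
#' @param diam_range detectable focus diameter range, um.
#' @param n_scales number of logarithmically spaced detection scales.
#' @param rel_threshold blob peak contrast required, as a fraction of the
#'   per-nucleus dynamic range above its background level.
#' @param min_snr blob peak contrast required, in units of the per-nucleus
#'   robust noise (MAD of the smoothed channel); guards focus-free nuclei
#'   whose dynamic range is pure noise.
#' @param merge_min_um minimum center distance (um) below which two
#'   detections are always merged, whatever their scales.
#' @return list of class \code{fociParams}.
#' @export
fociParams <- function(channel = "B53BP1", diam_range = c(0.2, 3.0),
                       n_scales = 8, rel_threshold = 0.2, min_snr = 6,
                       merge_min_um = 0.5) {
  structure(list(channel = channel, diam_range = diam_range,
                 n_scales = n_scales, rel_threshold = rel_threshold,
                 min_snr = min_snr, merge_min_um = merge_min_um),
            class = "fociParams")
}

# scale-normalized negative-LoG kernel: positive response at bright blobs
.logKernel <- function(sigma) {
  half <- ceiling(3.5 * sigma)
  x <- -half:half
  d2 <- outer(x^2, x^2, "+")
  g <- exp(-d2 / (2 * sigma^2)) / (2 * pi * sigma^2)
  k <- -sigma^2 * (d2 - 2 * sigma^2) / sigma^4 * g
  k - mean(k)   # zero-mean: flat regions give zero response
}

.localMax <- function(m) {
  mx <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(m), EBImage::makeBrush(3, "box")))
  m >= mx
}

#' Detect foci as multiscale Laplacian-of-Gaussian blobs
#'
#' Runs scale-normalized LoG filtering over logarithmically spaced scales
#' spanning \code{diam_range}, keeps candidates that are local maxima in
#' space and scale inside a nucleus, discards candidates whose peak contrast
#' fails both the relative (fraction of per-nucleus dynamic range) and the
#' noise-based (MAD multiples) thresholds, merges overlapping detections
#' keeping the strongest, and reports each focus diameter as the
#' area-equivalent diameter of its half-maximum region in micrometres.
#'
#' @param field an \linkS4class{ImageField}.
#' @param masks \code{nucleusMasks} from \code{\link{segmentNuclei}}.
#' @param cfg \code{\link{fociParams}}.
#' @return data.frame: \code{nucleus_id}, \code{x_um}, \code{y_um},
#'   \code{diameter_um}, \code{peak_intensity}, \code{response}.
#' @export
detectFoci <- function(field, masks, cfg = fociParams()) {
  ps <- pixelSize(field)
  if (!is.finite(ps) || ps <= 0)
    stop("pixel size missing or non-positive: physical focus sizes undefined")
  img <- getChannel(field, cfg$channel)
  labels <- masks$labels
  if (nrow(masks$nuclei) == 0)
    return(data.frame(nucleus_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), diameter_um = numeric(0),
                      peak_intensity = numeric(0), response = numeric(0)))
  fwhm <- 2 * sqrt(2 * log(2))
  diams <- exp(seq(log(cfg$diam_range[1]), log(cfg$diam_range[2]),
                   length.out = cfg$n_scales))
  sigmas <- pmax(diams / fwhm / ps, 0.6)
  resp <- array(0, c(nrow(img), ncol(img), length(sigmas)))
  for (s in seq_along(sigmas))
    resp[, , s] <- EBImage::filter2(img, .logKernel(sigmas[s]))
  g1 <- EBImage::filter2(img, EBImage::makeBrush(7, "gaussian", sigma = 1))

  # per-nucleus background / contrast / noise statistics
  in_mask <- labels > 0
  vals <- img[in_mask]; labv <- labels[in_mask]; g1v <- g1[in_mask]
  bg <- vapply(split(vals, labv), median, numeric(1))
  hi <- vapply(split(vals, labv), quantile, numeric(1), probs = 0.999,
               names = FALSE)
  nz <- vapply(split(g1v, labv), mad, numeric(1))
  idmap <- as.integer(names(bg))

  cand <- NULL
  for (s in seq_along(sigmas)) {
    m <- resp[, , s]
    ok <- .localMax(m) & (m > 0) & in_mask
    if (s > 1) ok <- ok & (m >= resp[, , s - 1])
    if (s < length(sigmas)) ok <- ok & (m >= resp[, , s + 1])
    if (!any(ok)) next
    rr <- row(m)[ok]; cc <- col(m)[ok]
    cand <- rbind(cand, data.frame(r = rr, c = cc, s = s,
                                   resp = m[ok], lab = labels[ok]))
  }
  out <- data.frame(nucleus_id = integer(0), x_um = numeric(0),
                    y_um = numeric(0), diameter_um = numeric(0),
                    peak_intensity = numeric(0), response = numeric(0))
  if (is.null(cand) || nrow(cand) == 0) return(out)

  j <- match(cand$lab, idmap)
  peak <- g1[cbind(cand$r, cand$c)]
  need <- pmax(cfg$rel_threshold * (hi[j] - bg[j]), cfg$min_snr * nz[j])
  # a blob center must also be a near-maximum of the smoothed intensity in
  # its 5x5 neighborhood: LoG maxima on the shoulders or saddles between
  # adjacent foci fail this while true peaks pass within noise tolerance
  g1max <- EBImage::imageData(
    EBImage::dilate(EBImage::Image(g1), EBImage::makeBrush(5, "box")))
  at_peak <- g1[cbind(cand$r, cand$c)] >=
    g1max[cbind(cand$r, cand$c)] - 0.05 * pmax(peak - bg[j], 0)
  sel <- (peak - bg[j]) >= need & at_peak
  cand <- cand[sel, , drop = FALSE]
  peak <- peak[sel]
  if (nrow(cand) == 0) return(out)

  # greedy merge of overlapping detections, strongest first;
  # merge radius = the larger of the two blob radii (px)
  ord <- order(-cand$resp)
  cand <- cand[ord, , drop = FALSE]; peak <- peak[ord]
  rad_px <- diams[cand$s] / 2 / ps
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ki <- which(keep)
    if (length(ki) == 0) { keep[i] <- TRUE; next }
    same <- ki[cand$lab[ki] == cand$lab[i]]
    if (length(same) == 0) { keep[i] <- TRUE; next }
    d <- sqrt((cand$r[same] - cand$r[i])^2 + (cand$c[same] - cand$c[i])^2)
    if (all(d > pmax(rad_px[same], rad_px[i], cfg$merge_min_um / ps)))
      keep[i] <- TRUE
  }
  cand <- cand[keep, , drop = FALSE]; peak <- peak[keep]

  # half-maximum area-equivalent diameter on the lightly smoothed channel
  diam_um <- numeric(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    j1 <- match(cand$lab[i], idmap)
    half <- ceiling(1.5 * diams[cand$s[i]] / ps) + 3
    rows <- max(1, cand$r[i] - half):min(nrow(img), cand$r[i] + half)
    cols <- max(1, cand$c[i] - half):min(ncol(img), cand$c[i] + half)
    thr_half <- bg[j1] + 0.5 * (peak[i] - bg[j1])
    bw <- (g1[rows, cols] >= thr_half) & (labels[rows, cols] == cand$lab[i])
    cc <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw)))
    comp <- cc[cand$r[i] - rows[1] + 1, cand$c[i] - cols[1] + 1]
    area <- if (comp > 0) sum(cc == comp) else 1
    diam_um[i] <- 2 * sqrt(area / pi) * ps
  }
  data.frame(nucleus_id = cand$lab,
             x_um = (cand$c - 1) * ps, y_um = (cand$r - 1) * ps,
             diameter_um = diam_um, peak_intensity = peak,
             response = cand$resp, row.names = NULL)
}

#' Diffuse-staining metrics per nucleus
#'
#' Coverage is the fraction of a nucleus's pixels at or above the
#' focus-level intensity threshold (a fixed fraction of the dynamic range of
#' all nuclear pixels in the field, so a focus-free noisy nucleus does not
#' normalize itself into high coverage); heterogeneity is the coefficient of
#' variation (sd/mean) of the channel inside the nucleus.
#'
#' @param field an \linkS4class{ImageField}.
#' @param masks \code{nucleusMasks}.
#' @param channel channel name.
#' @param rel_threshold threshold position within the field's nuclear
#'   dynamic range.
#' @return data.frame: \code{nucleus_id}, \code{coverage},
#'   \code{heterogeneity}.
#' @export
diffuseMetrics <- function(field, masks, channel = "B53BP1",
                           rel_threshold = 0.2) {
  img <- getChannel(field, channel)
  labels <- masks$labels
  in_mask <- labels > 0
  if (!any(in_mask))
    return(data.frame(nucleus_id = integer(0), coverage = numeric(0),
                      heterogeneity = numeric(0)))
  vals <- img[in_mask]; labv <- labels[in_mask]
  lo <- quantile(vals, 0.01, names = FALSE)
  hi <- quantile(vals, 0.999, names = FALSE)
  thr <- lo + rel_threshold * (hi - lo)
  sp <- split(vals, labv)
  cov <- vapply(sp, function(v) mean(v >= thr & v > 0), numeric(1))
  het <- vapply(sp, function(v) {
    m <- mean(v)
    if (m <= 0) 0 else sd(v) / m
  }, numeric(1))
  data.frame(nucleus_id = as.integer(names(sp)), coverage = cov,
             heterogeneity = het, row.names = NULL)
}
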