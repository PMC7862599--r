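#' Rendering parameters for synthetic fields
#'
#' Controls the geometry and photometry of rendered immunofluorescence and
#' FISH fields. Intensities are photon-count-like arbitrary units; noise is
#' Poisson (shot) plus additive Gaussian (read) noise.
#'
#' @param pixel_size um per pixel.
#' @param image_shape field size in pixels (rows, cols).
#' @param nucleus_radius_range nucleus radius range, um.
#' @param focus_diameter_small,focus_diameter_large default focus FWHM
#'   diameters (um) used when a truth table carries no diameters; the large
#'   class boundary is 1 um.
#' @param focus_amplitude peak focus intensity above the nuclear baseline.
#' @param background_level extranuclear background intensity.
#' @param noise_sd Gaussian read-noise standard deviation.
#' @param diffuse_coverage minimum fraction of nuclear area covered by
#'   supra-threshold signal in rendered diffuse nuclei.
#' @param dapi_level DAPI fill intensity inside nuclei.
#' @param nuclear_baseline_frac weak pan-nuclear 53BP1 baseline as a fraction
#'   of \code{focus_amplitude}.
#' @param signal_diameter FISH spot FWHM diameter, um.
#' @return list of class \code{renderParams}.
#' @export
renderParams <- function(pixel_size = 0.1, image_shape = c(640L, 640L),
                         nucleus_radius_range = c(2.6, 3.8),
                         focus_diameter_small = 0.5,
                         focus_diameter_large = 1.4,
                         focus_amplitude = 150, background_level = 20,
                         noise_sd = 5, diffuse_coverage = 0.6,
                         dapi_level = 120, nuclear_baseline_frac = 0.15,
                         signal_diameter = 0.5) {
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  if (!(focus_diameter_large >= 1.0 && 1.0 > focus_diameter_small &&
        focus_diameter_small > 0))
    stop("need focus_diameter_large >= 1 um > focus_diameter_small > 0")
  structure(list(pixel_size = pixel_size,
                 image_shape = as.integer(image_shape),
                 nucleus_radius_range = nucleus_radius_range,
                 focus_diameter_small = focus_diameter_small,
                 focus_diameter_large = focus_diameter_large,
                 focus_amplitude = focus_amplitude,
                 background_level = background_level,
                 noise_sd = noise_sd, diffuse_coverage = diffuse_coverage,
                 dapi_level = dapi_level,
                 nuclear_baseline_frac = nuclear_baseline_frac,
                 signal_diameter = signal_diameter),
            class = "renderParams")
}

# rejection-sample non-overlapping nucleus centers (>= 1 px gap).
# Returns cx/cy in 0-based pixel units plus per-nucleus semi-axes (px).
.placeNuclei <- function(radii_um, rp, max_tries = 4000) {
  ps <- rp$pixel_size
  h <- rp$image_shape[1]; w <- rp$image_shape[2]
  n <- length(radii_um)
  r_px <- radii_um / ps
  ratio <- runif(n, 0.88, 1.0)              # mild ellipticity
  ax <- r_px * sqrt(ratio); ay <- r_px / sqrt(ratio)
  cx <- cy <- numeric(n)
  for (i in seq_len(n)) {
    m <- max(ax[i], ay[i]) + 2
    placed <- FALSE
    for (k in seq_len(max_tries)) {
      x <- runif(1, m, w - 1 - m); y <- runif(1, m, h - 1 - m)
      if (i == 1L) { ok <- TRUE } else {
        j <- seq_len(i - 1L)
        ok <- all(sqrt((cx[j] - x)^2 + (cy[j] - y)^2) >
                    pmax(ax[j], ay[j]) + max(ax[i], ay[i]) + 1)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; placed <- TRUE; break }
    }
    if (!placed)
      stop("could not place nucleus ", i, " of ", n,
           " without overlap; field too crowded (", n, " nuclei in ",
           h, "x", w, " px)")
  }
  data.frame(cx = cx, cy = cy, ax = ax, ay = ay)
}

# add one Gaussian spot of given FWHM (um) and amplitude at (x0, y0) px
.addSpot <- function(img, x0, y0, fwhm_um, amp, ps) {
  sigma <- fwhm_um / (2 * sqrt(2 * log(2))) / ps
  half <- ceiling(4 * sigma)
  rows <- max(1, round(y0) + 1 - half):min(nrow(img), round(y0) + 1 + half)
  cols <- max(1, round(x0) + 1 - half):min(ncol(img), round(x0) + 1 + half)
  dx2 <- outer(rep(1, length(rows)), (cols - 1 - x0)^2)
  dy2 <- outer((rows - 1 - y0)^2, rep(1, length(cols)))
  img[rows, cols] <- img[rows, cols] + amp * exp(-(dx2 + dy2) / (2 * sigma^2))
  img
}

# logical mask of one elliptical nucleus (matrix indices)
.nucleusIdx <- function(pl, i, shape) {
  half_x <- ceiling(pl$ax[i]) + 1; half_y <- ceiling(pl$ay[i]) + 1
  rows <- max(1, round(pl$cy[i]) + 1 - half_y):min(shape[1], round(pl$cy[i]) + 1 + half_y)
  cols <- max(1, round(pl$cx[i]) + 1 - half_x):min(shape[2], round(pl$cx[i]) + 1 + half_x)
  ex <- outer(rep(1, length(rows)), ((cols - 1 - pl$cx[i]) / pl$ax[i])^2)
  ey <- outer(((rows - 1 - pl$cy[i]) / pl$ay[i])^2, rep(1, length(cols)))
  list(rows = rows, cols = cols, inside = (ex + ey) <= 1)
}

# uniform points inside ellipse i with margin (um), min pairwise dist (um)
.pointsInNucleus <- function(pl, i, n, margin_um, min_dist_um, ps,
                             max_tries = 400) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  mx <- pmax(pl$ax[i] - margin_um / ps, 0.5)
  my <- pmax(pl$ay[i] - margin_um / ps, 0.5)
  pts <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(n)) {
    for (t in seq_len(max_tries)) {
      repeat {
        u <- runif(2, -1, 1)
        if (sum(u^2) <= 1) break
      }
      x <- pl$cx[i] + u[1] * mx; y <- pl$cy[i] + u[2] * my
      if (nrow(pts) == 0 ||
          all(sqrt((pts[, 1] - x)^2 + (pts[, 2] - y)^2) * ps >= min_dist_um) ||
          t == max_tries) {
        pts <- rbind(pts, c(x, y)); break
      }
    }
  }
  colnames(pts) <- c("x", "y")
  pts
}

# heterogeneous supra-threshold texture for diffuse nuclei: smoothed uniform
# field, rank-normalized inside the nucleus, contrast-stretched so coverage
# and coefficient of variation exceed the classifier's diffuse gates
.diffuseTexture <- function(idx, amp) {
  h <- length(idx$rows); w <- length(idx$cols)
  u <- matrix(runif(h * w), h, w)
  k <- EBImage::makeBrush(15, shape = "gaussian", sigma = 2)
  us <- EBImage::filter2(u, k)
  vals <- us[idx$inside]
  rk <- rank(vals, ties.method = "average") / (length(vals) + 1)
  tex <- matrix(0, h, w)
  tex[idx$inside] <- amp * (0.12 + 1.35 * rk^1.5)
  tex
}

.addNoise <- function(img, noise_sd) {
  n <- length(img)
  out <- rpois(n, pmax(img, 0)) + rnorm(n, 0, noise_sd)
  matrix(out, nrow(img), ncol(img))
}

#' Render an immunofluorescence field from per-nucleus ground truth
#'
#' Draws each nucleus as a filled ellipse in the DAPI channel and paints the
#' 53BP1 channel according to the per-nucleus truth: discrete foci become
#' 2-D Gaussian spots whose full width at half maximum equals the true focus
#' diameter; diffuse nuclei receive heterogeneous supra-threshold texture
#' over most of their area; all other nuclei carry a weak pan-nuclear
#' baseline. Poisson shot noise plus Gaussian read noise is applied unless
#' \code{noise = FALSE}. When the truth carries a \code{true_region_label}
#' column, FDC and BCL2 gating channels are painted per nucleus
#' (GC: FDC+/BCL2-; PF: FDC+/BCL2+; MM: FDC-/BCL2+; LA: FDC-, variable BCL2).
#'
#' @param truth data.frame from \code{\link{composeNucleusTruths}}.
#' @param rp \code{\link{renderParams}}.
#' @param seed integer seed; fixed seed gives a bit-identical field.
#' @param noise logical; disable to obtain the noiseless expectation image.
#' @return list: \code{field} (an \linkS4class{ImageField}) and \code{truth}
#'   (input truth with appended \code{center_x_um}, \code{center_y_um}).
#' @export
renderIfImage <- function(truth, rp = renderParams(), seed = 1, noise = TRUE) {
  ps <- rp$pixel_size
  shape <- rp$image_shape
  withr::with_seed(seed, {
    pl <- .placeNuclei(truth$radius_um, rp)
    dapi <- matrix(0, shape[1], shape[2])
    b53 <- matrix(0, shape[1], shape[2])
    fx <- fy <- fd <- fnuc <- list()
    for (i in seq_len(nrow(truth))) {
      idx <- .nucleusIdx(pl, i, shape)
      dapi[idx$rows, idx$cols][idx$inside] <- rp$dapi_level
      cls <- truth$true_pattern_class[i]
      if (cls == "diffuse") {
        b53[idx$rows, idx$cols] <- b53[idx$rows, idx$cols] +
          .diffuseTexture(idx, rp$focus_amplitude)
      } else {
        b53[idx$rows, idx$cols][idx$inside] <-
          b53[idx$rows, idx$cols][idx$inside] +
          rp$nuclear_baseline_frac * rp$focus_amplitude
        diams <- truth$true_focus_diameters[[i]]
        if (length(diams)) {
          pts <- .pointsInNucleus(pl, i, length(diams),
                                  margin_um = max(diams) / 2 + 0.25,
                                  min_dist_um = max(diams) + 0.3, ps = ps)
          for (k in seq_along(diams))
            b53 <- .addSpot(b53, pts[k, 1], pts[k, 2], diams[k],
                            rp$focus_amplitude, ps)
          fx <- c(fx, list(pts[, 1])); fy <- c(fy, list(pts[, 2]))
          fd <- c(fd, list(diams)); fnuc <- c(fnuc, list(rep(i, length(diams))))
        }
      }
    }
    channels <- list(DAPI = dapi, B53BP1 = b53 + rp$background_level)
    if (!is.null(truth$true_region_label)) {
      fdc <- matrix(0, shape[1], shape[2])
      bcl2 <- matrix(0, shape[1], shape[2])
      hiv <- 150; lov <- 8
      for (i in seq_len(nrow(truth))) {
        idx <- .nucleusIdx(pl, i, shape)
        lab <- truth$true_region_label[i]
        fdc[idx$rows, idx$cols][idx$inside] <-
          if (lab %in% c("GC", "PF")) hiv else lov
        bcl2[idx$rows, idx$cols][idx$inside] <-
          if (lab %in% c("PF", "MM")) hiv
          else if (lab == "LA") sample(c(hiv, lov), 1) else lov
      }
      channels$FDC <- fdc + rp$background_level
      channels$BCL2 <- bcl2 + rp$background_level
    }
    if (noise)
      channels <- lapply(channels, .addNoise, noise_sd = rp$noise_sd)
  })
  truth$center_x_um <- pl$cx * ps
  truth$center_y_um <- pl$cy * ps
  attr(truth, "focus_positions") <- if (length(fx))
    data.frame(nucleus_id = truth$nucleus_id[unlist(fnuc)],
               x_um = unlist(fx) * ps, y_um = unlist(fy) * ps,
               diameter_um = unlist(fd)) else NULL
  list(field = ImageField(channels, pixelSize = ps,
                          fieldId = as.character(truth$case_id[1])),
       truth = truth)
}

#' Sample FISH genotype ground truth for one slide
#'
#' @param n_nuclei number of nuclei.
#' @param genotype_mix named proportions over \code{wild}, \code{fusion},
#'   \code{trisomy}; must sum to 1.
#' @param seed integer seed.
#' @param nucleus_radius_range nucleus radius range, um.
#' @return data.frame: \code{nucleus_id}, \code{true_genotype},
#'   \code{true_n_green}, \code{true_n_orange}, \code{true_n_fusion} (fusion
#'   nuclei carry one or two green-orange fusion pairs plus one residual
#'   singleton of each color; trisomy nuclei three orange and two green
#'   separated signals; wild nuclei two of each), \code{radius_um}.
#' @export
sampleFishTruth <- function(n_nuclei,
                            genotype_mix = c(wild = 1, fusion = 0, trisomy = 0),
                            seed = 1, nucleus_radius_range = c(2.6, 3.8)) {
  stopifnot(abs(sum(genotype_mix) - 1) < 1e-9,
            all(names(genotype_mix) %in% c("wild", "fusion", "trisomy")))
  withr::with_seed(seed, {
    g <- sample(names(genotype_mix), n_nuclei, replace = TRUE,
                prob = genotype_mix)
    nf <- ifelse(g == "fusion", sample(1:2, n_nuclei, replace = TRUE), 0L)
    radii <- runif(n_nuclei, nucleus_radius_range[1], nucleus_radius_range[2])
  })
  data.frame(
    nucleus_id = seq_len(n_nuclei),
    true_genotype = g,
    true_n_green = ifelse(g == "fusion", 1L, 2L),
    true_n_orange = ifelse(g == "trisomy", 3L,
                           ifelse(g == "fusion", 1L, 2L)),
    true_n_fusion = as.integer(nf),
    radius_um = radii,
    stringsAsFactors = FALSE
  )
}

#' Render a dual-color FISH field
#'
#' Nuclei are ellipses in DAPI; hybridization signals are Gaussian spots in
#' the green and orange channels. Wild-type nuclei get two separated signals
#' per color; trisomy nuclei three orange and two green separated signals;
#' fusion nuclei place their fusion pairs as green-orange doublets within
#' \code{fusion_offset_um} of each other plus one separated singleton of
#' each color. All non-fused signals are at least \code{min_sep_um} apart.
#'
#' @param truth data.frame from \code{\link{sampleFishTruth}}.
#' @param rp \code{\link{renderParams}}.
#' @param seed integer seed.
#' @param noise logical.
#' @param fusion_offset_um maximum green-orange offset within a fusion pair.
#' @param min_sep_um minimum separation between distinct signals.
#' @return list: \code{field} (channels DAPI, green, orange) and \code{truth}
#'   with appended centers.
#' @export
renderFishImage <- function(truth, rp = renderParams(), seed = 1,
                            noise = TRUE, fusion_offset_um = 0.15,
                            min_sep_um = 1.2) {
  ps <- rp$pixel_size
  shape <- rp$image_shape
  withr::with_seed(seed, {
    pl <- .placeNuclei(truth$radius_um, rp)
    dapi <- matrix(0, shape[1], shape[2])
    green <- matrix(0, shape[1], shape[2])
    orange <- matrix(0, shape[1], shape[2])
    for (i in seq_len(nrow(truth))) {
      idx <- .nucleusIdx(pl, i, shape)
      dapi[idx$rows, idx$cols][idx$inside] <- rp$dapi_level
      nf <- truth$true_n_fusion[i]
      ng <- truth$true_n_green[i]; no <- truth$true_n_orange[i]
      # anchor points: one per fusion pair + each singleton, all separated
      n_anchor <- nf + ng + no
      pts <- .pointsInNucleus(pl, i, n_anchor,
                              margin_um = rp$signal_diameter / 2 + 0.3,
                              min_dist_um = min_sep_um, ps = ps)
      a <- 1L
      if (nf > 0) for (k in seq_len(nf)) {
        th <- runif(1, 0, 2 * pi); d <- runif(1, 0, fusion_offset_um) / ps
        green <- .addSpot(green, pts[a, 1], pts[a, 2], rp$signal_diameter,
                          rp$focus_amplitude, ps)
        orange <- .addSpot(orange, pts[a, 1] + d * cos(th),
                           pts[a, 2] + d * sin(th), rp$signal_diameter,
                           rp$focus_amplitude, ps)
        a <- a + 1L
      }
      if (ng > 0) for (k in seq_len(ng)) {
        green <- .addSpot(green, pts[a, 1], pts[a, 2], rp$signal_diameter,
                          rp$focus_amplitude, ps)
        a <- a + 1L
      }
      if (no > 0) for (k in seq_len(no)) {
        orange <- .addSpot(orange, pts[a, 1], pts[a, 2], rp$signal_diameter,
                           rp$focus_amplitude, ps)
        a <- a + 1L
      }
    }
    channels <- list(DAPI = dapi, green = green + rp$background_level,
                     orange = orange + rp$background_level)
    if (noise)
      channels <- lapply(channels, .addNoise, noise_sd = rp$noise_sd)
  })
  truth$center_x_um <- pl$cx * ps
  truth$center_y_um <- pl$cy * ps
  list(field = ImageField(channels, pixelSize = ps, fieldId = "fish"),
       truth = truth)
}

# deterministic sub-seed for field i of a run (kept below 2^31)
.subSeed <- function(seed, i) (as.numeric(seed) * 7919 + 104729 * i) %% 2147483647

#' Simulate all fields of one immunofluorescence case
#'
#' Splits a case's nuclei over as many fields as needed and renders each.
#'
#' @param case_row one row of \code{\link{sampleCohort}} output.
#' @param params single lesion row of \code{\link{lesionParams}}.
#' @param rp \code{\link{renderParams}}.
#' @param seed integer seed.
#' @param nuclei_per_field maximum nuclei rendered per field.
#' @param noise logical.
#' @return list: \code{fields} (list of ImageField), \code{truth} (row-bound
#'   truth with \code{field} column); attributes \code{true_fractions} and
#'   \code{true_abnormal_fraction} give realized class fractions (percent).
#' @export
simulateIfCase <- function(case_row, params, rp = renderParams(), seed = 1,
                           nuclei_per_field = 32, noise = TRUE) {
  truth <- composeNucleusTruths(case_row, params, seed = .subSeed(seed, 0))
  n <- nrow(truth)
  splits <- split(seq_len(n), ceiling(seq_len(n) / nuclei_per_field))
  fields <- list(); truths <- list()
  for (i in seq_along(splits)) {
    ti <- truth[splits[[i]], , drop = FALSE]
    r <- renderIfImage(ti, rp, seed = .subSeed(seed, i), noise = noise)
    r$field@fieldId <- paste0(case_row$case_id, "_f", i)
    ti <- r$truth
    ti$field <- r$field@fieldId
    fields[[i]] <- r$field
    truths[[i]] <- ti
  }
  out <- do.call(rbind, truths)
  attr(out, "true_fractions") <- attr(truth, "true_fractions")
  attr(out, "true_abnormal_fraction") <- attr(truth, "true_abnormal_fraction")
  list(fields = fields, truth = out)
}

#' Simulate all fields of one FISH slide
#'
#' @param n_nuclei total nuclei on the slide.
#' @param genotype_mix named proportions over wild/fusion/trisomy.
#' @param rp \code{\link{renderParams}}.
#' @param seed integer seed.
#' @param nuclei_per_field maximum nuclei per field.
#' @param noise logical.
#' @return list: \code{fields}, \code{truth} (with \code{field} column).
#' @export
simulateFishSlide <- function(n_nuclei, genotype_mix, rp = renderParams(),
                              seed = 1, nuclei_per_field = 32, noise = TRUE) {
  truth <- sampleFishTruth(n_nuclei, genotype_mix, seed = .subSeed(seed, 0))
  splits <- split(seq_len(n_nuclei), ceiling(seq_len(n_nuclei) / nuclei_per_field))
  fields <- list(); truths <- list()
  for (i in seq_along(splits)) {
    ti <- truth[splits[[i]], , drop = FALSE]
    r <- renderFishImage(ti, rp, seed = .subSeed(seed, i), noise = noise)
    r$field@fieldId <- paste0("fish_f", i)
    ti <- r$truth
    ti$field <- r$field@fieldId
    fields[[i]] <- r$field
    truths[[i]] <- ti
  }
  list(fields = fields, truth = do.call(rbind, truths))
}
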