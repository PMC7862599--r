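oneNucleusTruth <- function(class = "highDDR", diams = c(0.5, 0.5, 0.5),
                            radius = 3.5) {
  data.frame(nucleus_id = 1L, case_id = "t", true_pattern_class = class,
             true_focus_count = length(diams), radius_um = radius,
             true_focus_diameters = I(list(diams)))
}

test_that("rendered spot width at half maximum matches the requested size", {
  tr <- oneNucleusTruth(diams = c(0.5))
  r <- renderIfImage(tr, smallRender(noise_sd = 0), seed = 2, noise = FALSE)
  img <- getChannel(r$field, "B53BP1")
  rp <- smallRender()
  base <- rp$background_level + rp$nuclear_baseline_frac * rp$focus_amplitude
  peak <- max(img)
  area <- sum(img >= base + 0.5 * (peak - base))
  fwhm <- 2 * sqrt(area / pi) * pixelSize(r$field)
  expect_lt(abs(fwhm - 0.5) / 0.5, 0.2)
})

test_that("noiseless focus-free nuclei are identically at background", {
  tr <- oneNucleusTruth(class = "stable", diams = numeric(0))
  rp <- smallRender(background_level = 0, noise_sd = 0,
                    nuclear_baseline_frac = 0)
  r <- renderIfImage(tr, rp, seed = 2, noise = FALSE)
  expect_true(all(getChannel(r$field, "B53BP1") == 0))
})

test_that("a fixed seed renders bit-identical images", {
  tr <- oneNucleusTruth()
  a <- renderIfImage(tr, smallRender(), seed = 5)
  b <- renderIfImage(tr, smallRender(), seed = 5)
  expect_identical(a$field@channels, b$field@channels)
  c <- renderIfImage(tr, smallRender(), seed = 6)
  expect_false(identical(a$field@channels, c$field@channels))
})

test_that("every rendered focus lies strictly inside its nucleus", {
  params <- mclParams()
  tr <- composeNucleusTruths(list(case_id = "c", n_nuclei = 10,
                                  true_abnormal_fraction = 80), params, seed = 21)
  r <- renderIfImage(tr, smallRender(), seed = 21, noise = FALSE)
  fp <- attr(r$truth, "focus_positions")
  expect_gt(nrow(fp), 0)
  for (k in seq_len(nrow(fp))) {
    i <- match(fp$nucleus_id[k], r$truth$nucleus_id)
    d <- sqrt((fp$x_um[k] - r$truth$center_x_um[i])^2 +
              (fp$y_um[k] - r$truth$center_y_um[i])^2)
    expect_lt(d + fp$diameter_um[k] / 2, r$truth$radius_um[i])
  }
})

test_that("overcrowded fields fail with a placement error", {
  params <- mclParams()
  tr <- composeNucleusTruths(list(case_id = "crowd", n_nuclei = 60,
                                  true_abnormal_fraction = 0), params, seed = 1)
  expect_error(renderIfImage(tr, renderParams(image_shape = c(160L, 160L)),
                             seed = 1),
               "crowded")
})

test_that("FISH genotype configurations are rendered as specified", {
  rp <- smallRender()
  cfg <- fishParams(min_snr = 4)
  # wild: two separated signals per color
  tw <- sampleFishTruth(4, c(wild = 1, fusion = 0, trisomy = 0), seed = 3)
  rw <- renderFishImage(tw, rp, seed = 3, noise = FALSE)
  masks <- segmentNuclei(rw$field)
  sig <- detectFishSignals(rw$field, masks, cfg)
  counts <- table(sig$nucleus_id, sig$color)
  expect_true(all(counts[, "green"] == 2))
  expect_true(all(counts[, "orange"] == 2))
  for (id in unique(sig$nucleus_id)) {
    s <- sig[sig$nucleus_id == id, ]
    expect_gt(min(dist(cbind(s$x_um, s$y_um))), cfg$max_pair_distance)
  }
  # trisomy: three orange, two green
  tt <- sampleFishTruth(4, c(wild = 0, fusion = 0, trisomy = 1), seed = 4)
  rt <- renderFishImage(tt, rp, seed = 4, noise = FALSE)
  sig <- detectFishSignals(rt$field, segmentNuclei(rt$field), cfg)
  counts <- table(sig$nucleus_id, sig$color)
  expect_true(all(counts[, "orange"] == 3))
  expect_true(all(counts[, "green"] == 2))
})

test_that("a zero-offset fusion pair renders as one overlapping doublet", {
  tf <- sampleFishTruth(2, c(wild = 0, fusion = 1, trisomy = 0), seed = 8)
  r <- renderFishImage(tf, smallRender(), seed = 8, noise = FALSE,
                       fusion_offset_um = 0)
  masks <- segmentNuclei(r$field)
  sig <- detectFishSignals(r$field, masks, fishParams(min_snr = 4))
  m <- matchNucleiToTruth(masks$nuclei, r$truth)
  for (k in seq_len(nrow(masks$nuclei))) {
    id <- masks$nuclei$nucleus_id[k]
    s <- sig[sig$nucleus_id == id, ]
    p <- pairFusions(s, max_pair_distance = 0.3)
    expect_identical(p$n_fusion, r$truth$true_n_fusion[m[k]])
  }
})
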