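fieldWithFoci <- function(diams_per_nucleus, seed = 13, noise = TRUE,
                          n_extra_stable = 0) {
  classes <- c(rep("highDDR", length(diams_per_nucleus)),
               rep("stable", n_extra_stable))
  n <- length(classes)
  tr <- data.frame(nucleus_id = seq_len(n), case_id = "t",
                   true_pattern_class = classes,
                   true_focus_count = c(vapply(diams_per_nucleus, length,
                                               integer(1)),
                                        rep(0L, n_extra_stable)),
                   radius_um = rep(3.4, n))
  tr$true_focus_diameters <- I(c(diams_per_nucleus,
                                 rep(list(numeric(0)), n_extra_stable)))
  renderIfImage(tr, smallRender(), seed = seed, noise = noise)
}

test_that("small foci are recovered with correct count and diameter", {
  r <- fieldWithFoci(list(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5)), seed = 41)
  masks <- segmentNuclei(r$field)
  foci <- detectFoci(r$field, masks)
  counts <- table(factor(foci$nucleus_id, levels = masks$nuclei$nucleus_id))
  expect_true(all(counts == 3))
  expect_true(all(foci$diameter_um >= 0.35 & foci$diameter_um <= 0.65))
})

test_that("focus-free nuclei yield no detections", {
  r <- fieldWithFoci(list(c(0.5)), seed = 43, n_extra_stable = 5)
  masks <- segmentNuclei(r$field)
  foci <- detectFoci(r$field, masks)
  expect_identical(nrow(foci), 1L)
})

test_that("a large focus is measured at or above the one-micron boundary", {
  tr <- data.frame(nucleus_id = 1L, case_id = "t",
                   true_pattern_class = "largeFocus", true_focus_count = 1L,
                   radius_um = 3.5,
                   true_focus_diameters = I(list(1.4)))
  r <- renderIfImage(tr, smallRender(), seed = 47)
  foci <- detectFoci(r$field, segmentNuclei(r$field))
  expect_identical(nrow(foci), 1L)
  expect_gte(foci$diameter_um, 1.0)
  expect_lt(foci$diameter_um, 2.0)
})

test_that("detection is equivariant under whole-pixel translations", {
  r <- fieldWithFoci(list(c(0.5, 0.6)), seed = 53, noise = FALSE)
  img <- getChannel(r$field, "B53BP1")
  dapi <- getChannel(r$field, "DAPI")
  shift <- function(m, dr, dc, fill) {
    out <- matrix(fill, nrow(m), ncol(m))
    rs <- seq_len(nrow(m) - abs(dr)); cs <- seq_len(ncol(m) - abs(dc))
    out[rs + max(dr, 0), cs + max(dc, 0)] <-
      m[rs + max(-dr, 0), cs + max(-dc, 0)]
    out
  }
  rp <- smallRender()
  # shift toward the emptier half so the nucleus never reaches the border
  dr <- if (r$truth$center_y_um[1] / rp$pixel_size < nrow(img) / 2) 7 else -7
  dc <- if (r$truth$center_x_um[1] / rp$pixel_size < ncol(img) / 2) 5 else -5
  f2 <- ImageField(list(DAPI = shift(dapi, dr, dc, 0),
                        B53BP1 = shift(img, dr, dc, rp$background_level)),
                   pixelSize = pixelSize(r$field))
  a <- detectFoci(r$field, segmentNuclei(r$field))
  b <- detectFoci(f2, segmentNuclei(f2))
  expect_identical(nrow(a), nrow(b))
  ps <- pixelSize(r$field)
  expect_equal(sort(b$x_um), sort(a$x_um + dc * ps), tolerance = 1e-8)
  expect_equal(sort(b$y_um), sort(a$y_um + dr * ps), tolerance = 1e-8)
  expect_equal(sort(b$diameter_um), sort(a$diameter_um), tolerance = 1e-8)
})

test_that("doubling intensities leaves detections unchanged under relative thresholds", {
  r <- fieldWithFoci(list(c(0.5, 0.5, 0.5), c(0.4)), seed = 59)
  masks <- segmentNuclei(r$field)
  a <- detectFoci(r$field, masks)
  f2 <- ImageField(list(DAPI = getChannel(r$field, "DAPI"),
                        B53BP1 = 2 * getChannel(r$field, "B53BP1")),
                   pixelSize = pixelSize(r$field))
  b <- detectFoci(f2, masks)
  expect_identical(nrow(a), nrow(b))
  expect_equal(a$x_um, b$x_um)
  expect_equal(a$diameter_um, b$diameter_um, tolerance = 1e-8)
})

test_that("every detected focus lies inside its parent nucleus", {
  r <- fieldWithFoci(list(c(0.5, 0.5, 0.5), c(0.6, 0.4), c(0.5)), seed = 61)
  masks <- segmentNuclei(r$field)
  foci <- detectFoci(r$field, masks)
  ps <- masks$pixel_size
  for (k in seq_len(nrow(foci))) {
    rr <- round(foci$y_um[k] / ps) + 1
    cc <- round(foci$x_um[k] / ps) + 1
    expect_identical(masks$labels[rr, cc], foci$nucleus_id[k])
  }
})

test_that("missing pixel size is rejected", {
  expect_error(ImageField(list(DAPI = matrix(0, 4, 4)), pixelSize = -1),
               "pixelSize")
})

test_that("diffuse metrics behave at the degenerate extremes", {
  z <- squareMasks(0)
  m0 <- diffuseMetrics(z$field, z$masks)
  expect_identical(m0$coverage, 0)
  p <- squareMasks(200)
  m1 <- diffuseMetrics(p$field, p$masks)
  expect_identical(m1$coverage, 1)
  expect_identical(m1$heterogeneity, 0)
})

test_that("rendered diffuse nuclei pass the coverage and heterogeneity gates", {
  params <- mclParams()
  params$mix_highDDR <- 0; params$mix_largeFocus <- 0; params$mix_diffuse <- 1
  tr <- composeNucleusTruths(list(case_id = "d", n_nuclei = 8,
                                  true_abnormal_fraction = 50), params,
                             seed = 67)
  r <- renderIfImage(tr, smallRender(), seed = 67)
  masks <- segmentNuclei(r$field)
  dm <- diffuseMetrics(r$field, masks)
  m <- matchNucleiToTruth(masks$nuclei, r$truth)
  diff_idx <- which(r$truth$true_pattern_class[m] == "diffuse")
  cls <- classifierParams()
  rp <- smallRender()
  expect_true(all(dm$coverage[diff_idx] >= rp$diffuse_coverage))
  expect_true(all(dm$heterogeneity[diff_idx] >=
                    cls$diffuse_min_heterogeneity))
  norm_idx <- which(r$truth$true_pattern_class[m] != "diffuse")
  expect_true(all(dm$coverage[norm_idx] < cls$diffuse_min_coverage |
                  dm$heterogeneity[norm_idx] < cls$diffuse_min_heterogeneity))
})
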