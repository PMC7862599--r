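test_that("fusion pairing handles the boundary cases", {
  s <- data.frame(color = c("green", "orange"), x_um = c(0, 0), y_um = c(0, 0))
  expect_identical(pairFusions(s, 0.6),
                   list(n_fusion = 1L, n_green = 0L, n_orange = 0L))
  far <- data.frame(color = c("green", "green", "orange", "orange"),
                    x_um = c(0, 0, 5, 6), y_um = c(0, 1, 5, 6))
  expect_identical(pairFusions(far, 0.6)$n_fusion, 0L)
  expect_identical(pairFusions(far, 0.6)$n_green, 2L)
  # zero radius pairs only exactly coincident centroids
  near <- data.frame(color = c("green", "orange"), x_um = c(0, 1e-6),
                     y_um = c(0, 0))
  expect_identical(pairFusions(near, 0)$n_fusion, 0L)
  coin <- data.frame(color = c("green", "orange"), x_um = c(0.3, 0.3),
                     y_um = c(1, 1))
  expect_identical(pairFusions(coin, 0)$n_fusion, 1L)
})

test_that("two close pairs plus far singletons give two fusions", {
  s <- data.frame(color = c("green", "orange", "green", "orange",
                            "green", "orange"),
                  x_um = c(0, 0.1, 3, 3.1, 0, 6),
                  y_um = c(0, 0, 3, 3, 6, 0))
  p <- pairFusions(s, 0.6)
  expect_identical(p$n_fusion, 2L)
  expect_identical(p$n_green, 1L)
  expect_identical(p$n_orange, 1L)
})

test_that("greedy pairing matches the exhaustive optimum on separated configurations", {
  set.seed(31)
  for (i in 1:200) {
    n_pair <- sample(0:2, 1); ng <- sample(0:2, 1); no <- sample(0:2, 1)
    pts <- NULL
    # anchors far apart, fusion partners close together
    anchors <- cbind(runif(n_pair + ng + no, 0, 50),
                     runif(n_pair + ng + no, 0, 50))
    while (n_pair + ng + no >= 2 &&
           min(dist(anchors)) < 2) {
      anchors <- cbind(runif(n_pair + ng + no, 0, 50),
                       runif(n_pair + ng + no, 0, 50))
    }
    a <- 1
    rows <- list()
    if (n_pair > 0) for (k in seq_len(n_pair)) {
      rows[[length(rows) + 1]] <- data.frame(color = "green",
                                             x_um = anchors[a, 1],
                                             y_um = anchors[a, 2])
      rows[[length(rows) + 1]] <- data.frame(color = "orange",
                                             x_um = anchors[a, 1] + runif(1, 0, 0.3),
                                             y_um = anchors[a, 2])
      a <- a + 1
    }
    if (ng > 0) for (k in seq_len(ng)) {
      rows[[length(rows) + 1]] <- data.frame(color = "green",
                                             x_um = anchors[a, 1],
                                             y_um = anchors[a, 2]); a <- a + 1
    }
    if (no > 0) for (k in seq_len(no)) {
      rows[[length(rows) + 1]] <- data.frame(color = "orange",
                                             x_um = anchors[a, 1],
                                             y_um = anchors[a, 2]); a <- a + 1
    }
    if (length(rows) == 0) next
    s <- do.call(rbind, rows)
    expect_identical(pairFusions(s, 0.6)$n_fusion,
                     bruteMaxFusions(s, 0.6))
  }
})

test_that("nucleus genotypes follow the count rules", {
  expect_identical(callNucleusGenotype(0, 0, 0), "uninformative")
  expect_identical(callNucleusGenotype(2, 2, 0), "wild")
  expect_identical(callNucleusGenotype(1, 1, 1), "fusion")
  expect_identical(callNucleusGenotype(1, 1, 2), "fusion")
  expect_identical(callNucleusGenotype(2, 3, 0), "trisomy18q21")
  expect_identical(callNucleusGenotype(3, 3, 0), "other")
  expect_identical(callNucleusGenotype(0, 0, 3), "other")
  expect_identical(callNucleusGenotype(1, 0, 0), "wild")
})

test_that("case summaries apply the informativeness and threshold rules", {
  mk <- function(genos) data.frame(nucleus_id = seq_along(genos),
                                   n_green = 2, n_orange = 2, n_fusion = 0,
                                   genotype = genos)
  # 149 informative nuclei: not scorable
  c1 <- mk(c(rep("wild", 149), rep("uninformative", 30)))
  expect_identical(summarizeFishCase(c1)$case_call, "NS")
  # 200 informative, 40 fusion: 20 percent, translocation
  c2 <- mk(c(rep("fusion", 40), rep("wild", 160)))
  s2 <- summarizeFishCase(c2)
  expect_identical(s2$fusion_fraction, 20)
  expect_identical(s2$case_call, "translocation")
  # 200 informative, 12 trisomy (6 percent): wild with equivocal flag
  c3 <- mk(c(rep("trisomy18q21", 12), rep("wild", 188)))
  s3 <- summarizeFishCase(c3)
  expect_identical(s3$case_call, "wild")
  expect_true(s3$trisomy_equivocal)
  # exactly at threshold: trisomy call
  c4 <- mk(c(rep("trisomy18q21", 20), rep("wild", 180)))
  expect_identical(summarizeFishCase(c4)$case_call, "trisomy")
  expect_error(summarizeFishCase(mk("wild")[0, , drop = FALSE]),
               "no nucleus calls")
})

test_that("genotypes are recovered from rendered noiseless fields", {
  sim <- simulateFishSlide(24, c(wild = 0.4, fusion = 0.4, trisomy = 0.2),
                           rp = smallRender(), seed = 77,
                           nuclei_per_field = 8, noise = FALSE)
  hits <- 0; tot <- 0
  for (f in sim$fields) {
    tr <- sim$truth[sim$truth$field == f@fieldId, ]
    masks <- segmentNuclei(f)
    sig <- detectFishSignals(f, masks)
    calls <- callFishNuclei(sig, masks$nuclei$nucleus_id)
    m <- matchNucleiToTruth(masks$nuclei, tr)
    truth_g <- ifelse(tr$true_genotype[m] == "trisomy", "trisomy18q21",
                      tr$true_genotype[m])
    hits <- hits + sum(calls$genotype == truth_g, na.rm = TRUE)
    tot <- tot + sum(!is.na(m))
  }
  expect_gte(tot, 22)
  expect_gte(hits / tot, 0.98)
})

test_that("missing FISH channels are rejected", {
  f <- ImageField(list(DAPI = matrix(100, 32, 32)))
  masks <- structure(list(labels = matrix(1L, 32, 32),
                          nuclei = data.frame(nucleus_id = 1L,
                                              center_x_um = 1.6,
                                              center_y_um = 1.6,
                                              area_um2 = 10),
                          pixel_size = 0.1), class = "nucleusMasks")
  expect_error(detectFishSignals(f, masks), "missing")
})
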