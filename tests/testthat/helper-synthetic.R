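# shared fixture builders (everything is generated in code at test time)

# small fields keep unit tests fast; acceptance tests use the defaults
smallRender <- function(...) renderParams(image_shape = c(320L, 320L), ...)

mclParams <- function() {
  p <- lesionParams()
  p[p$lesion_label == "MCL", ]
}

# one simulated case at a chosen abnormal fraction, small fields
simSmallCase <- function(n_nuclei = 16, fraction = 44.5, seed = 7,
                         noise = TRUE, nuclei_per_field = 8, rp = smallRender()) {
  case <- list(case_id = "case1", lesion_label = "MCL", n_nuclei = n_nuclei,
               true_abnormal_fraction = fraction)
  simulateIfCase(case, mclParams(), rp = rp, seed = seed,
                 nuclei_per_field = nuclei_per_field, noise = noise)
}

# hand-built single-nucleus mask set (square region) for metric unit tests
squareMasks <- function(value, size = 40, margin = 10, pixel_size = 0.1) {
  dim <- size + 2 * margin
  labels <- matrix(0L, dim, dim)
  labels[(margin + 1):(margin + size), (margin + 1):(margin + size)] <- 1L
  img <- matrix(0, dim, dim)
  img[labels == 1L] <- value
  field <- ImageField(list(DAPI = labels * 100, B53BP1 = img),
                      pixelSize = pixel_size)
  masks <- structure(list(labels = labels,
                          nuclei = data.frame(nucleus_id = 1L,
                                              center_x_um = (margin + size / 2) * pixel_size,
                                              center_y_um = (margin + size / 2) * pixel_size,
                                              area_um2 = size^2 * pixel_size^2),
                          pixel_size = pixel_size), class = "nucleusMasks")
  list(field = field, masks = masks)
}

# brute-force oracles -----------------------------------------------------

# AUC by explicit positive-negative pair counting (ties 1/2)
bruteAuc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (x in pos) for (y in neg) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(pos) * length(neg))
}

# Youden by exhaustive threshold search (predict positive at score >= t)
bruteYouden <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  best <- NULL
  for (t in sort(unique(scores))) {
    j <- mean(pos >= t) + mean(neg < t) - 1
    if (is.null(best) || j > best$j + 1e-12) best <- list(t = t, j = j)
  }
  best
}

# exact two-sided Wilcoxon p by full enumeration of group assignments
bruteWilcoxonP <- function(a, b) {
  v <- c(a, b); n <- length(v); na <- length(a)
  r <- rank(v)
  e <- na * (n + 1) / 2
  s_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(n, na)
  s_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(abs(s_all - e) >= abs(s_obs - e) - 1e-9)
}

# maximum-cardinality green-orange matching under a distance cap, by
# exhaustive recursion (for <= 3 signals per color)
bruteMaxFusions <- function(signals, max_dist) {
  g <- which(signals$color == "green"); o <- which(signals$color == "orange")
  if (!length(g) || !length(o)) return(0L)
  d <- outer(g, o, function(i, j)
    sqrt((signals$x_um[i] - signals$x_um[j])^2 +
         (signals$y_um[i] - signals$y_um[j])^2))
  best <- 0L
  rec <- function(gi, used_o, count) {
    best <<- max(best, count)
    if (gi > length(g)) return()
    rec(gi + 1L, used_o, count)                     # leave this green single
    for (j in seq_along(o))
      if (!used_o[j] && d[gi, j] <= max_dist) {
        used_o[j] <- TRUE
        rec(gi + 1L, used_o, count + 1L)
        used_o[j] <- FALSE
      }
  }
  rec(1L, logical(length(o)), 0L)
  best
}
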