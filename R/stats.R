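#' ROC area under the curve with DeLong confidence interval
#'
#' Computes the AUC through the Mann-Whitney relation (ties counted 1/2),
#' its 95\% DeLong confidence interval clipped to [0, 1], and the
#' Youden-optimal operating point (see \code{\link{youdenCutoff}}).
#'
#' @param scores numeric predictor (here: abnormal fraction, percent).
#' @param labels binary outcome (logical, or 0/1), 1 = positive class.
#' @param conf_level confidence level of the DeLong interval.
#' @return a \linkS4class{RocResult}.
#' @examples
#' r <- rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' auc(r)  # 1
#' @export
rocAuc <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  if (length(unique(labels)) < 2)
    stop("both classes must be present to compute a ROC curve")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  n1 <- length(pos); n0 <- length(neg)
  r <- rank(c(pos, neg))
  a <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # DeLong variance from placement values
  psi <- function(x, y) (x > y) + 0.5 * (x == y)
  v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
  v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  z <- qnorm(1 - (1 - conf_level) / 2)
  # with a single observation in a class the DeLong variance is undefined;
  # report the uninformative interval rather than a spurious one
  ci <- if (is.finite(se)) c(max(0, a - z * se), min(1, a + z * se))
        else c(0, 1)
  yc <- youdenCutoff(scores, labels)
  new("RocResult", auc = a, ciLo = min(ci[1], a), ciHi = max(ci[2], a),
      cutoff = yc$cutoff, sensitivity = yc$sensitivity,
      specificity = yc$specificity, youden = yc$youden)
}

#' @importFrom stats qnorm var
NULL

#' Youden-optimal cutoff
#'
#' Evaluates Youden's J = sensitivity + specificity - 1 at every observed
#' score used as a threshold (predict positive when score >= threshold) and
#' returns the maximizer; ties are broken toward the lowest threshold,
#' which maximizes sensitivity among equal-J cutoffs.
#'
#' @param scores numeric predictor.
#' @param labels binary outcome, 1 = positive class.
#' @return list: \code{cutoff}, \code{sensitivity} and \code{specificity}
#'   (percent), \code{youden}.
#' @export
youdenCutoff <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2)
    stop("both classes must be present")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)[1]   # lowest threshold among ties
  list(cutoff = thr[best], sensitivity = 100 * sens[best],
       specificity = 100 * spec[best], youden = j[best])
}

# exact null distribution of the rank-sum of a size-m group, over mid-ranks:
# dynamic-programming convolution on doubled ranks (integers even with ties)
.ranksumNull <- function(ranks2, m) {
  n <- length(ranks2)
  total <- sum(ranks2)
  # f[k+1, s+1] = number of k-subsets with doubled-rank sum s
  f <- matrix(0, m + 1, total + 1)
  f[1, 1] <- 1
  for (x in ranks2) {
    kmax <- min(m, n)  # iterate k downwards to avoid reuse
    for (k in seq(min(m, n), 1)) {
      idx <- which(f[k, ] > 0)
      if (length(idx))
        f[k + 1, idx + x] <- f[k + 1, idx + x] + f[k, idx]
    }
  }
  f[m + 1, ]
}

#' Exact Wilcoxon rank-sum test (permutation null, mid-ranks)
#'
#' Two-sided exact test of identical distributions: with mid-ranks for
#' ties, the achieved rank-sum S of the first sample is compared with its
#' full permutation null distribution (all assignments of the pooled values
#' into groups of the observed sizes), and
#' p = P(|S - E[S]| >= |s_obs - E[S]|). The null distribution is computed
#' exactly by dynamic-programming convolution, so ties are handled without
#' approximation. For pooled sizes above \code{exact_limit} a normal
#' approximation with tie correction is used and flagged.
#'
#' @param sample_a,sample_b numeric samples.
#' @param exact_limit largest pooled size for which the exact null is used.
#' @return list of class \code{groupComparison}: \code{statistic} (rank sum
#'   of \code{sample_a}), \code{p_two_sided}, \code{exact} (logical),
#'   \code{n_a}, \code{n_b}.
#' @examples
#' exactWilcoxon(c(1, 2), c(3, 4))$p_two_sided  # 1/3
#' @export
exactWilcoxon <- function(sample_a, sample_b, exact_limit = 30) {
  if (length(sample_a) == 0 || length(sample_b) == 0)
    stop("both samples must be non-empty")
  na <- length(sample_a); nb <- length(sample_b); n <- na + nb
  r <- rank(c(sample_a, sample_b))       # mid-ranks
  s_obs <- sum(r[seq_len(na)])
  e <- na * (n + 1) / 2
  if (n <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    null <- .ranksumNull(r2, na)
    s_vals <- (seq_along(null) - 1) / 2   # undo doubling
    tot <- sum(null)
    p <- sum(null[abs(s_vals - e) >= abs(s_obs - e) - 1e-9]) / tot
    exact <- TRUE
  } else {
    ties <- table(r)
    sig2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (abs(s_obs - e) - 0.5) / sqrt(sig2)   # continuity-corrected
    p <- min(1, 2 * pnorm(-max(z, 0)))
    exact <- FALSE
  }
  structure(list(statistic = s_obs, p_two_sided = p, exact = exact,
                 n_a = na, n_b = nb), class = "groupComparison")
}

#' @export
print.groupComparison <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum (%s): S = %g (n = %d vs %d), two-sided p = %.4g\n",
              if (x$exact) "exact" else "normal approximation",
              x$statistic, x$n_a, x$n_b, x$p_two_sided))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with mid-ranks for ties; the p-value uses the
#' t-distribution approximation on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list: \code{rho}, \code{p}.
#' @export
spearmanRank <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rho <- cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1) return(list(rho = rho, p = 0))
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  list(rho = rho, p = 2 * pt(-abs(t), df = n - 2))
}

#' Linear trend of a response over ordered grades
#'
#' Least-squares regression of the response on the grade order score
#' (1..k); returns the slope and its two-sided t-test p-value. Used to test
#' whether the abnormal fraction declines with increasing histological
#' grade.
#'
#' @param values numeric response.
#' @param grades ordered factor or integer grade scores.
#' @return list: \code{slope}, \code{p}.
#' @export
ordinalTrend <- function(values, grades) {
  score <- if (is.factor(grades)) as.numeric(grades) else as.numeric(grades)
  if (length(unique(score)) < 2) stop("need >= 2 distinct grades")
  fit <- lm(values ~ score)
  sm <- summary(fit)$coefficients
  list(slope = unname(coef(fit)[2]), p = unname(sm[2, 4]))
}
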