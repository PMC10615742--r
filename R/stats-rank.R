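#' Mann-Whitney U test with rank-based effect size r
#'
#' Two-sided U test comparing two independent samples. For small samples
#' (`n1 + n2 <= exactMax`, no ties) the p-value is exact, computed by full
#' enumeration of all rank assignments; otherwise a tie-corrected normal
#' approximation (no continuity correction) is used. The effect size is
#' r = |Z| / sqrt(N), where Z is always taken from the (tie-corrected)
#' normal approximation so that r is comparable across branches. The
#' rank-biserial correlation `1 - 2U/(n1 n2)` is reported in `details`.
#'
#' @param x,y Numeric vectors.
#' @param exactMax Largest `n1 + n2` for which the exact enumeration is
#'   used (ties always force the approximation).
#' @return A [TestResult-class] with statistic `U` (the number of (x, y)
#'   pairs with x preceding y in rank, i.e. the Wilcoxon W for `x`).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
#' @export
mannWhitneyU <- function(x, y, exactMax = 12) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tab <- table(c(x, y))
  tieTerm <- sum(tab^3 - tab)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
  if (sigma2 <= 0)
    stop("all values are tied across both groups: zero rank variance")
  Z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  hasTies <- tieTerm > 0
  exact <- N <= exactMax && !hasTies
  if (exact) {
    sets <- utils::combn(N, n1)
    u <- colSums(sets) - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(u <= U), mean(u >= U)))
  } else {
    p <- 2 * pnorm(-abs(Z))
  }
  TestResult("Mann-Whitney U test", statistic = c(U = U), pValue = p,
             nPerGroup = c(n1, n2),
             effect = EffectSize("rank_r", abs(Z) / sqrt(N), sign = sign(Z)),
             details = list(Z = Z, exact = exact, ties = hasTies,
                            rank_biserial = 1 - 2 * U / (n1 * n2)))
}

## Exact null distribution of the signed-rank statistic W for ranks 1..n
## (counts of subset sums, by dynamic programming over 0..n(n+1)/2).
.signedRankCounts <- function(n) {
  maxW <- n * (n + 1) / 2
  cnt <- numeric(maxW + 1)
  cnt[1] <- 1
  for (k in seq_len(n)) {
    shifted <- c(numeric(k), cnt[seq_len(maxW + 1 - k)])
    cnt <- cnt + shifted
  }
  cnt  # index i holds count of sign assignments with W = i - 1
}

#' Wilcoxon signed-rank test for paired observations
#'
#' Two-sided paired rank test (the paired analogue of the U test). Zero
#' differences are dropped before ranking. For `n <= exactMax` effective
#' pairs without ties among the absolute differences the p-value is exact,
#' by enumeration over all 2^n sign assignments; otherwise a tie-corrected
#' normal approximation is used. Effect size r = |Z| / sqrt(n_effective).
#'
#' @param before,after Numeric vectors of equal length. Differences are
#'   `after - before`; a positive direction means an increase.
#' @param exactMax Largest effective n for which the exact branch is used.
#' @return A [TestResult-class] with statistic `W` (sum of positive ranks).
#' @examples
#' wilcoxonSignedRank(rep(0, 6), 1:6)  # all differences positive
#' @export
wilcoxonSignedRank <- function(before, after, exactMax = 12) {
  if (length(before) != length(after))
    stop("'before' and 'after' must have equal length")
  d <- as.numeric(after) - as.numeric(before)
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (n == 0L)
    stop("all differences are zero: signed-rank test is undefined")
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  tab <- table(abs(d))
  tieTerm <- sum(tab^3 - tab)
  mu <- n * (n + 1) / 4
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - tieTerm / 48
  if (sigma2 <= 0)
    stop("zero variance of signed ranks")
  Z <- (W - mu) / sqrt(sigma2)
  hasTies <- tieTerm > 0
  exact <- n <= exactMax && !hasTies
  if (exact) {
    cnt <- .signedRankCounts(n)
    tot <- sum(cnt)
    pLow <- sum(cnt[seq_len(floor(W) + 1)]) / tot
    pHigh <- sum(cnt[(floor(W) + 1):length(cnt)]) / tot
    p <- min(1, 2 * min(pLow, pHigh))
  } else {
    p <- 2 * pnorm(-abs(Z))
  }
  TestResult("Wilcoxon signed-rank test", statistic = c(W = W), pValue = p,
             nPerGroup = n,
             effect = EffectSize("rank_r", abs(Z) / sqrt(n), sign = sign(Z)),
             details = list(Z = Z, exact = exact, ties = hasTies,
                            n_effective = n))
}

#' Fisher's exact test for a 2x2 table with phi effect size
#'
#' Two-sided exact test: the p-value is the sum of hypergeometric point
#' probabilities no larger than that of the observed table (the standard
#' two-sided convention). The effect size is the phi coefficient
#' `(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`; when a row or column margin is
#' zero the table carries no association, the p-value is 1 and phi is
#' reported as 0 with `details$phi_undefined = TRUE`.
#'
#' @param tab A 2x2 matrix of non-negative integer counts.
#' @return A [TestResult-class] with the sample odds ratio in `details`.
#' @examples
#' fisherExact2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("'tab' must be a 2x2 matrix")
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  N <- a + b + c + d
  if (N == 0) stop("the table is empty")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (min(r1, r2, c1, c2) == 0) {
    return(TestResult("Fisher's exact test", statistic = c(a = a),
                      pValue = 1, nPerGroup = c(r1, r2),
                      effect = EffectSize("phi", 0),
                      details = list(odds_ratio = NA_real_,
                                     phi_undefined = TRUE,
                                     table = tab)))
  }
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  pObs <- dhyper(a, r1, r2, c1)
  p <- min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
  phi <- (a * d - b * c) / sqrt(r1 * r2 * c1 * c2)
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  TestResult("Fisher's exact test", statistic = c(a = a), pValue = p,
             nPerGroup = c(r1, r2),
             effect = EffectSize("phi", phi),
             details = list(odds_ratio = or, phi_undefined = FALSE,
                            table = tab))
}
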