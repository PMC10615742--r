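# Independent brute-force oracles used to validate the rank tests and
# Fisher's exact test, plus small shared helpers. These deliberately share
# no code with the package implementations.

# Exact two-sided Mann-Whitney p by enumeration over all rank assignments.
oracleUTestP <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  r <- rank(c(x, y))
  Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(N, n1)
  us <- apply(combs, 2, function(id) sum(id) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(us <= Uobs), mean(us >= Uobs)))
}

# Exact two-sided signed-rank p by enumeration over all sign assignments.
oracleSignedRankP <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  Wobs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  ws <- as.vector(signs %*% rk)
  min(1, 2 * min(mean(ws <= Wobs), mean(ws >= Wobs)))
}

# Exact two-sided Fisher p by direct hypergeometric summation over all
# tables with the observed margins.
oracleFisherP <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
  r1 <- a + b; r2 <- cc + dd; c1 <- a + cc
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(xs, function(x) {
    choose(r1, x) * choose(r2, c1 - x) / choose(r1 + r2, c1)
  }, 0)
  pobs <- pr[match(a, xs)]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# Jaccard overlap of two half-open integer intervals.
jaccardInterval <- function(s1, e1, s2, e2) {
  inter <- max(0, min(e1, e2) - max(s1, s2))
  if (inter == 0) return(0)
  inter / (max(e1, e2) - min(s1, s2))
}

# Small two-genotype lipid cohort used by several multivariate tests.
makeEffectLipidTable <- function(seed, groupSizes = c(8, 8),
                                 target = "class:PC", d = 2) {
  simulateLipidomics(groupSizes = groupSizes,
                     effects = list(list(target = target, d = d)),
                     seed = seed)
}
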