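## Independent brute-force oracles used to validate the analytical code.

## hypergeometric upper tail P(X >= x) by explicit enumeration of the
## sampling distribution (population N, K successes, n draws)
hyperTailOracle <- function(N, K, n, x) {
  js <- max(0, n - (N - K)):min(K, n)
  pr <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
  sum(pr[js >= x])
}

## exact two-sided Wilcoxon rank-sum p by enumeration of all group splits,
## reproducing the convention of the standard exact test: twice the smaller
## tail of the U statistic, capped at 1
rankSumOracle <- function(x, y) {
  nx <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(length(pool), nx)
  ws <- apply(splits, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  if (wObs > nx * length(y) / 2) {
    min(1, 2 * mean(ws >= wObs))
  } else {
    min(1, 2 * mean(ws <= wObs))
  }
}

## topological overlap by triple loop, straight from the definition
tomBrute <- function(A) {
  n <- nrow(A)
  out <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + A[i, u] * A[u, j]
    ki <- sum(A[i, -i]); kj <- sum(A[j, -j])
    out[i, j] <- (l + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
  }
  out
}

## NB exact double-tail p by direct summation over all splits of the total
nbExactOracle <- function(ya, yb, na, nb, phi) {
  t <- ya + yb
  if (t == 0) return(1)
  mu0 <- t / (na + nb)
  pr <- vapply(0:t, function(x)
    dnbinom(x, size = na / phi, mu = na * mu0) *
      dnbinom(t - x, size = nb / phi, mu = nb * mu0), numeric(1))
  sum(pr[pr <= pr[ya + 1] * (1 + 1e-10)]) / sum(pr)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
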