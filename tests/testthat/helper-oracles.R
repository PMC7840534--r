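## Independent oracles, deliberately implemented with different algorithms
## than the package code they check.

## Brute-force 1-D optimal transport between two discrete distributions by
## quantile coupling: walk the two cumulative-probability ladders and pay
## |x - y| for each shared probability mass sliver. Independent of the
## CDF-area formula used by dsd().
ot_cost_oracle <- function(x, px, y, py) {
  ox <- order(x); x <- x[ox]; px <- px[ox] / sum(px)
  oy <- order(y); y <- y[oy]; py <- py[oy] / sum(py)
  cost <- 0; i <- 1L; j <- 1L; ri <- px[1]; rj <- py[1]
  while (i <= length(x) && j <= length(y)) {
    m <- min(ri, rj)
    cost <- cost + m * abs(x[i] - y[j])
    ri <- ri - m; rj <- rj - m
    if (ri <= 1e-14) { i <- i + 1L; if (i <= length(x)) ri <- px[i] }
    if (rj <= 1e-14) { j <- j + 1L; if (j <= length(y)) rj <- py[j] }
  }
  cost
}

## DSD oracle: transport cost between the unweighted and fitness-weighted
## empirical distributions of z.
dsd_oracle <- function(z, w) {
  ot_cost_oracle(z, rep(1, length(z)), z, w)
}

## p-value oracle: plain stats::lm + summary on a formula interface.
lm_pvalues_oracle <- function(df, formula) {
  cf <- summary(stats::lm(formula, data = df))$coefficients
  cf[-1, "Pr(>|t|)"]
}

## Mutually orthogonal, mean-zero, unit-sample-variance trait matrix built
## from principal component scores of a random matrix.
orthogonal_traits <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  S <- prcomp(X, center = TRUE, scale. = FALSE)$x[, 1:p]
  Z <- scale(S, center = TRUE, scale = apply(S, 2, sd))
  colnames(Z) <- paste0("t", 1:p)
  Z
}
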