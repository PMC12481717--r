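# Independent oracles used by the unit and acceptance tests. These share no
# code with the package implementation.

# ANCOVA Type III F statistics by explicit design-matrix least squares: each
# effect's F from the residual-SS difference between the full model and the
# model with that effect's (sum-contrast) columns removed.
ancovaOracle <- function(d) {
  d$group <- factor(d$group); d$level <- factor(d$level)
  contrasts(d$group) <- contr.sum(nlevels(d$group))
  contrasts(d$level) <- contr.sum(nlevels(d$level))
  X <- model.matrix(~ group * level + age, d)
  y <- d$amplitude_uV
  rss <- function(M) {
    beta <- qr.solve(qr(M), y)
    sum((y - M %*% beta)^2)
  }
  full <- rss(X)
  asg <- attr(X, "assign")   # 0 intercept, 1 group, 2 level, 3 age, 4 g:l
  dfe <- nrow(X) - ncol(X)
  out <- numeric(4)
  for (k in 1:4) {
    r0 <- rss(X[, asg != k, drop = FALSE])
    out[k] <- ((r0 - full) / sum(asg == k)) / (full / dfe)
  }
  names(out) <- c("Group", "Level", "Age", "Group:Level")
  list(F = out, dfe = dfe)
}

# ICC(2,1) from explicit elementwise sums of squares.
iccOracle <- function(m) {
  n <- nrow(m); k <- ncol(m); g <- mean(m)
  SSR <- 0; SSC <- 0; SST <- 0
  for (i in 1:n) SSR <- SSR + k * (mean(m[i, ]) - g)^2
  for (j in 1:k) SSC <- SSC + n * (mean(m[, j]) - g)^2
  for (i in 1:n) for (j in 1:k) SST <- SST + (m[i, j] - g)^2
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1)
  MSE <- (SST - SSR - SSC) / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

# Hand-applied Benjamini-Hochberg step-up: p_(i) * m / i, then a cumulative
# minimum from the largest p downward, mapped back to the input order.
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  stepped <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  pmin(adj, 1)[order(o)]
}
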