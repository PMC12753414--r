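# Brute-force oracles: explicit formulas, hand-built design matrices and the
# step-up definition, independent of the code paths they check.

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); syy <- sum(y^2); sxy <- sum(x * y)
  r <- (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
  if (1 - r^2 <= .Machine$double.eps) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(t), n - 2)
  }
  list(r = r, p = p)
}

oracle_ols_slope <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
}

rss_of <- function(X, y) {
  beta <- qr.solve(X, y)
  sum((y - X %*% beta)^2)
}

# interaction F for y ~ x + arm + x:arm, arm two-level
oracle_interaction_F <- function(x, arm, y) {
  z <- as.numeric(arm == sort(unique(arm))[2])
  X_full <- cbind(1, x, z, x * z)
  X_red <- cbind(1, x, z)
  rss1 <- rss_of(X_full, y)
  rss0 <- rss_of(X_red, y)
  df2 <- length(y) - 4
  F <- (rss0 - rss1) / (rss1 / df2)
  list(F = F, p = pf(F, 1, df2, lower.tail = FALSE))
}

dummy_cols <- function(f) {
  f <- factor(f)
  lv <- levels(f)[-1]
  sapply(lv, function(l) as.numeric(f == l))
}

# Type II sums of squares for a two-way layout with interaction
oracle_type2_anova <- function(y, A, B) {
  dA <- dummy_cols(A); dB <- dummy_cols(B)
  dAB <- matrix(apply(expand.grid(a = seq_len(ncol(dA)), b = seq_len(ncol(dB))),
                      1, function(i) dA[, i[1]] * dB[, i[2]]),
                nrow = length(y))
  one <- rep(1, length(y))
  rss_ab <- rss_of(cbind(one, dA, dB), y)
  rss_a <- rss_of(cbind(one, dA), y)
  rss_b <- rss_of(cbind(one, dB), y)
  rss_full <- rss_of(cbind(one, dA, dB, dAB), y)
  a <- nlevels(factor(A)); b <- nlevels(factor(B))
  df <- c(a - 1, b - 1, (a - 1) * (b - 1))
  df_res <- length(y) - a * b
  ss <- c(rss_b - rss_ab, rss_a - rss_ab, rss_ab - rss_full)
  F <- (ss / df) / (rss_full / df_res)
  list(ss = ss, F = F, p = pf(F, df, df_res, lower.tail = FALSE),
       rss = rss_full, df_res = df_res)
}

oracle_welch <- function(x, y) {
  nx <- length(x); ny <- length(y)
  vx <- var(x); vy <- var(y)
  se2 <- vx / nx + vy / ny
  t <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  if (m >= 2) {
    for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  }
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
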