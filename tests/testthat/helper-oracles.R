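# Independent oracles used across the suite. These re-derive each quantity
# from first principles (closed forms, brute-force enumeration, textbook
# sums of squares) and must stay independent of the package code paths
# they check.

# Pearson chi-squared on a 2x2 from the closed form.
oracle_chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Sliding-window 3-point median, endpoints passed through.
oracle_median3 <- function(f) {
  n <- length(f)
  if (n < 3) return(f)
  out <- f
  for (i in 2:(n - 1)) out[i] <- median(f[(i - 1):(i + 1)])
  out
}

# Textbook paired t.
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, df = n - 1, p = 2 * pt(-abs(t_stat), n - 1))
}

# One-way repeated-measures ANOVA with Greenhouse-Geisser epsilon from
# orthonormalized within-subject contrasts (n x k response matrix).
oracle_rm_anova <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  C <- qr.Q(qr(stats::contr.helmert(k)))     # k x (k-1), orthonormal
  Z <- Y %*% C
  ss_eff <- n * sum(colMeans(Z)^2)
  ss_err <- sum(sweep(Z, 2, colMeans(Z))^2)
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  f_val <- (ss_eff / df1) / (ss_err / df2)
  S <- stats::cov(Z)
  eps <- sum(diag(S))^2 / (df1 * sum(S^2))
  list(F = f_val, df1 = df1, df2 = df2, eps = eps,
       p = pf(f_val, df1, df2, lower.tail = FALSE),
       p_gg = pf(f_val, eps * df1, eps * df2, lower.tail = FALSE))
}

# Classic balanced split-plot sums of squares for a two-group (n per
# group) by k-condition design. Y: (2n x k), grp: factor length 2n.
oracle_split_plot <- function(Y, grp) {
  k <- ncol(Y); N <- nrow(Y)
  g_lv <- levels(grp)
  grand <- mean(Y)
  sub_means <- rowMeans(Y)
  grp_means <- tapply(sub_means, grp, mean)
  cond_means <- colMeans(Y)
  cell_means <- apply(Y, 2, function(col) tapply(col, grp, mean))
  n_g <- table(grp)
  ss_group <- k * sum(n_g * (grp_means - grand)^2)
  ss_subj <- k * sum((sub_means - grp_means[grp])^2)
  ss_cond <- N * sum((cond_means - grand)^2)
  dev <- cell_means                      # groups x conditions
  for (g in seq_along(g_lv)) {
    dev[g, ] <- cell_means[g, ] - grp_means[g] - cond_means + grand
  }
  ss_int <- sum(n_g * rowSums(dev^2))
  resid <- Y
  for (j in seq_len(k)) {
    resid[, j] <- Y[, j] - cell_means[as.integer(grp), j] -
      (sub_means - grp_means[grp])
  }
  ss_resid <- sum(resid^2)
  df_group <- length(g_lv) - 1
  df_subj <- N - length(g_lv)
  df_cond <- k - 1
  df_int <- df_group * df_cond
  df_resid <- df_subj * df_cond
  list(
    F_group = (ss_group / df_group) / (ss_subj / df_subj),
    F_cond = (ss_cond / df_cond) / (ss_resid / df_resid),
    F_int = (ss_int / df_int) / (ss_resid / df_resid),
    ms_subj = ss_subj / df_subj, ms_resid = ss_resid / df_resid,
    df_subj = df_subj, df_resid = df_resid
  )
}

# Count spikes per half-open bin by direct comparison.
oracle_bin_counts <- function(t, edges) {
  vapply(seq_len(length(edges) - 1),
         function(i) sum(t >= edges[i] & t < edges[i + 1]), integer(1))
}

# Build an if_series directly from times and frequencies.
mk_if <- function(time, freq) pruriphys:::new_if_series(time, freq)

# Build a rating_series quickly from magnitudes on the 0.5-min grid.
mk_series <- function(mags, subject = "s1", stimulus = "ALA",
                      quality = "itch") {
  rating_series(subject, stimulus, quality,
                seq(0.5, by = 0.5, length.out = length(mags)), mags)
}
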