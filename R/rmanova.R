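#' Repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Univariate repeated-measures ANOVA for designs with one or two
#' within-subject factors and an optional between-subjects factor, as used
#' for the gLMS rating metrics (stimulus x sensory quality, optionally
#' by sex) and for the net-response split-plot design. For each
#' within-subject effect the Greenhouse-Geisser epsilon is estimated from
#' the sample covariance of the orthonormalized within-subject contrasts,
#' and the F-test degrees of freedom are multiplied by epsilon. Effects
#' with a single numerator degree of freedom (two-level factors) have
#' epsilon identically 1 and no correction. Subjects with missing cells
#' are excluded listwise with a warning.
#'
#' The model is fit as a multivariate linear model on the subject-by-cell
#' matrix and decomposed with [car::Anova()] (type III).
#'
#' @param data Long-format data frame, one row per subject x cell.
#' @param dv Name of the response column.
#' @param subject Name of the subject identifier column.
#' @param within Character vector (length 1 or 2) of within-subject factor
#'   columns.
#' @param between Optional name of a between-subjects factor column.
#' @return A data frame with one row per effect: `effect`, `df1`, `df2`,
#'   `statistic` (F), `p` (uncorrected), `gg_eps`, `df1_gg`, `df2_gg`,
#'   `p_gg`. For the pure between-subjects effect sphericity does not
#'   apply and `gg_eps` is `NA` with `p_gg = p`. Attribute `n_subjects`
#'   records the number of complete subjects analyzed.
#' @examples
#' d <- expand.grid(subject = factor(1:8), stim = factor(c("a", "b", "c")))
#' d$y <- rnorm(nrow(d)) + as.integer(d$stim)
#' rmanova_gg(d, dv = "y", subject = "subject", within = "stim")
#' @export
rmanova_gg <- function(data, dv, subject, within, between = NULL) {
  stopifnot(length(within) >= 1, length(within) <= 2)
  for (v in c(dv, subject, within, between)) {
    if (!v %in% names(data)) stop("column not found in data: ", v)
  }
  sub <- factor(data[[subject]])
  wf <- lapply(data[within], function(z) factor(z))
  idata <- do.call(expand.grid, lapply(wf, levels))
  names(idata) <- within
  for (v in within) idata[[v]] <- factor(idata[[v]], levels(wf[[v]]))

  cell_data <- interaction(wf, drop = FALSE, lex.order = FALSE)
  cell_idata <- interaction(idata, drop = FALSE, lex.order = FALSE)

  wide <- tapply(data[[dv]], list(sub, cell_data), mean)
  wide <- wide[, as.character(cell_idata), drop = FALSE]
  keep <- stats::complete.cases(wide)
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) with missing cells excluded listwise")
    wide <- wide[keep, , drop = FALSE]
  }
  n <- nrow(wide)
  if (n < 2) stop("need at least two complete subjects")
  Y <- unname(as.matrix(wide))
  colnames(Y) <- paste0("cell", seq_len(ncol(Y)))

  if (is.null(between)) {
    mlm <- stats::lm(Y ~ 1)
  } else {
    g_by_sub <- tapply(as.character(data[[between]]), sub, function(z) z[1])
    G <- factor(g_by_sub[rownames(wide)])
    if (nlevels(G) < 2) stop("between factor has fewer than two levels")
    # sum-to-zero contrasts so the type-III within effects are tested at
    # the unweighted grand mean (required when group sizes differ)
    mlm <- stats::lm(Y ~ G, contrasts = list(G = "contr.sum"))
  }

  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  s <- suppressWarnings(summary(av, multivariate = FALSE))

  ut <- s$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  adj <- s$pval.adjustments
  out <- data.frame(
    effect = effects,
    df1 = ut[effects, "num Df"],
    df2 = ut[effects, "den Df"],
    statistic = ut[effects, "F value"],
    p = ut[effects, "Pr(>F)"],
    gg_eps = NA_real_, df1_gg = NA_real_, df2_gg = NA_real_,
    p_gg = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(between)) {
    # report the between effect under its real column name, not "G"
    out$effect <- sub("^G($|:)", paste0(between, "\\1"), out$effect)
    rn_map <- sub("^G($|:)", paste0(between, "\\1"), rownames(ut))
  } else {
    rn_map <- rownames(ut)
  }
  is_within <- vapply(out$effect, function(e) {
    any(vapply(within, function(wn) grepl(wn, e, fixed = TRUE), logical(1)))
  }, logical(1))

  for (i in seq_len(nrow(out))) {
    eff <- out$effect[i]
    if (!is_within[i]) {
      out$p_gg[i] <- out$p[i]   # sphericity not applicable between subjects
      next
    }
    eps <- 1
    if (!is.null(adj)) {
      raw_name <- rownames(ut)[match(eff, rn_map)]
      j <- match(raw_name, rownames(adj))
      if (!is.na(j)) eps <- adj[j, "GG eps"]
      if (is.na(eps)) eps <- 1   # 1-df effects: sphericity trivially holds
    }
    out$gg_eps[i] <- eps
    out$df1_gg[i] <- eps * out$df1[i]
    out$df2_gg[i] <- eps * out$df2[i]
    out$p_gg[i] <- stats::pf(out$statistic[i], out$df1_gg[i], out$df2_gg[i],
                             lower.tail = FALSE)
  }
  # a design with zero variance everywhere has F = 0/0 (reported as noise
  # over noise); call it 0, no evidence of any effect
  degenerate <- !is.finite(out$statistic) |
    (ut[effects, "Sum Sq"] < 1e-10 & ut[effects, "Error SS"] < 1e-10)
  out$statistic[degenerate] <- 0
  out$p[degenerate] <- 1
  out$p_gg[degenerate] <- 1
  attr(out, "n_subjects") <- n
  out
}

#' Bonferroni-adjusted pairwise post hoc comparisons
#'
#' All pairwise paired t-tests between the levels of one within-subject
#' factor (collapsing over any other factors by the subject-level mean),
#' with Bonferroni adjustment over the family of all pairwise comparisons
#' within that factor.
#'
#' @inheritParams rmanova_gg
#' @param factor_name The within-subject factor whose levels are compared.
#' @return Data frame with `level_1`, `level_2`, `estimate`, `statistic`,
#'   `df`, `p`, `p_bonferroni`.
#' @export
bonferroni_posthoc <- function(data, dv, subject, factor_name) {
  sub <- factor(data[[subject]])
  f <- factor(data[[factor_name]])
  wide <- tapply(data[[dv]], list(sub, f), mean)
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  lv <- colnames(wide)
  pairs <- utils::combn(length(lv), 2)
  res <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    tt <- paired_t(wide[, i1], wide[, i2])
    res[[j]] <- data.frame(
      level_1 = lv[i1], level_2 = lv[i2],
      estimate = mean(wide[, i1]) - mean(wide[, i2]),
      statistic = tt$statistic, df = tt$df, p = tt$p.value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_bonferroni <- stats::p.adjust(out$p, method = "bonferroni")
  out
}
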