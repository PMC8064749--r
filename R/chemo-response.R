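#' Intradermal injection recording
#'
#' One intradermal injection into the receptive field of a fiber: the
#' spontaneous-activity count during the 1 min baseline before the
#' injection, the injection interval, and the AP timestamps after injection
#' onset.
#'
#' @param fiber_id Fiber identifier.
#' @param compound Compound injected, e.g. `"ALA"`, `"BAM8_22"`, `"HIS"`,
#'   or a vehicle (`"ECF"`, `"BAM8_18"`).
#' @param baseline_count AP count in the 60 s pre-injection baseline.
#' @param injection_interval Numeric length-2, start and end of the
#'   injection in seconds relative to injection onset (start is usually 0).
#' @param post_spikes AP timestamps in seconds relative to injection onset,
#'   strictly increasing. Recordings terminated early under the
#'   three-silent-minutes stopping rule simply contain no late spikes; they
#'   are implicitly zero-padded by the scoring window.
#' @param observation_duration Total observation time after injection, s.
#' @param baseline_window Baseline duration, s (60 by protocol).
#' @return An object of class `injection_recording`.
#' @export
injection_recording <- function(fiber_id, compound, baseline_count,
                                injection_interval, post_spikes,
                                observation_duration = 300,
                                baseline_window = 60) {
  if (length(injection_interval) != 2 ||
      injection_interval[2] <= injection_interval[1]) {
    stop("injection_interval must be (start, end) with end > start")
  }
  if (baseline_count < 0) stop("baseline_count must be non-negative")
  post_spikes <- as.numeric(post_spikes)
  if (length(post_spikes) > 1 && any(diff(post_spikes) <= 0)) {
    stop("post_spikes must be strictly increasing")
  }
  structure(
    list(fiber_id = fiber_id, compound = compound,
         baseline_count = baseline_count,
         injection_interval = as.numeric(injection_interval),
         post_spikes = post_spikes,
         observation_duration = observation_duration,
         baseline_window = baseline_window),
    class = "injection_recording"
  )
}

#' Prorate a baseline spike count to a response window
#'
#' Spontaneous activity counted over the pre-injection baseline is scaled
#' linearly to the duration of the scored response window so it can be
#' subtracted from the evoked count.
#'
#' @param baseline_count AP count in the baseline window.
#' @param window Response-window duration in seconds.
#' @param baseline_window Baseline duration in seconds (default 60).
#' @return Expected count over `window` (may be fractional).
#' @examples
#' prorated_baseline(6, 300)   # 30
#' @export
prorated_baseline <- function(baseline_count, window, baseline_window = 60) {
  if (any(baseline_count < 0)) stop("baseline_count must be non-negative")
  if (window <= 0) stop("window must be positive")
  baseline_count * window / baseline_window
}

# Count post-injection spikes in the scoring window. The window starts at
# the end of the injection interval by default (the injection period itself
# is shaded separately in recordings); set from_injection_end = FALSE to
# start at injection onset.
count_response_spikes <- function(rec, window = 300, from_injection_end = TRUE) {
  start <- if (from_injection_end) rec$injection_interval[2] else
    rec$injection_interval[1]
  sum(rec$post_spikes >= start & rec$post_spikes < start + window)
}

#' Net response of a fiber to a pruritogen
#'
#' The net response is the post-injection AP count in the scoring window,
#' minus the prorated spontaneous baseline, minus the same quantity for the
#' vehicle injection that preceded the pruritogen in the same fiber. A unit
#' is classified as responsive when the net response is at least
#' `threshold` APs over the 5 min window. Negative nets are retained.
#'
#' @param pruritogen,vehicle [injection_recording()] objects for the same
#'   fiber.
#' @param window Scoring window in seconds (default 300 = 5 min).
#' @param threshold Responsiveness threshold in net APs (default 10).
#' @param from_injection_end Start the scoring window at the end of the
#'   injection (default) rather than at injection onset, so that spikes
#'   evoked by needle insertion and fluid injection are excluded.
#' @return A list of class `net_response` with `fiber_id`, `compound`,
#'   `total_aps`, `prorated_baseline`, `vehicle_net`, `net_aps`,
#'   `responsive`.
#' @export
net_response <- function(pruritogen, vehicle, window = 300, threshold = 10,
                         from_injection_end = TRUE) {
  if (!identical(pruritogen$fiber_id, vehicle$fiber_id)) {
    stop("pruritogen and vehicle recordings are from different fibers: ",
         pruritogen$fiber_id, " vs ", vehicle$fiber_id)
  }
  comp_net <- function(rec) {
    count_response_spikes(rec, window, from_injection_end) -
      prorated_baseline(rec$baseline_count, window, rec$baseline_window)
  }
  total <- count_response_spikes(pruritogen, window, from_injection_end)
  pb <- prorated_baseline(pruritogen$baseline_count, window,
                          pruritogen$baseline_window)
  vn <- comp_net(vehicle)
  net <- (total - pb) - vn
  structure(
    list(fiber_id = pruritogen$fiber_id, compound = pruritogen$compound,
         total_aps = total, prorated_baseline = pb, vehicle_net = vn,
         net_aps = net, responsive = net >= threshold),
    class = "net_response"
  )
}

#' Bin a post-injection response into a time course
#'
#' Counts APs in half-open bins `[k*bin, (k+1)*bin)` over the scoring
#' window, the representation used for population time-course plots
#' (10 s bins over 5 min).
#'
#' @inheritParams net_response
#' @param rec An [injection_recording()].
#' @param bin_s Bin width in seconds; must divide `duration_s`.
#' @param duration_s Total binned duration in seconds.
#' @return A list of class `time_course` with `bin_edges` (length
#'   `n_bins + 1`) and `counts` (length `n_bins`).
#' @export
bin_time_course <- function(rec, bin_s = 10, duration_s = 300,
                            from_injection_end = TRUE) {
  if (bin_s <= 0) stop("bin width must be positive")
  if (duration_s %% bin_s != 0) stop("bin width must divide the duration")
  start <- if (from_injection_end) rec$injection_interval[2] else
    rec$injection_interval[1]
  t <- rec$post_spikes - start
  t <- t[t >= 0 & t < duration_s]
  n_bins <- duration_s / bin_s
  idx <- floor(t / bin_s) + 1L
  counts <- tabulate(idx, nbins = n_bins)
  structure(
    list(bin_edges = seq(0, duration_s, by = bin_s), counts = counts,
         fiber_id = rec$fiber_id, compound = rec$compound),
    class = "time_course"
  )
}

#' Build a 2x2 joint-responsiveness table
#'
#' Cross-classifies fibers by responsiveness to two agonists.
#'
#' @param both,a_only,b_only,neither Non-negative counts of fibers
#'   responsive to both agonists, to A only, to B only, and to neither.
#' @return A 2x2 integer matrix with informative dimnames.
#' @export
contingency_2x2 <- function(both, a_only, b_only, neither) {
  cells <- c(both, a_only, b_only, neither)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) stop("empty table")
  matrix(as.integer(cells), nrow = 2, byrow = TRUE,
         dimnames = list(A = c("A+", "A-"), B = c("B+", "B-")))
}

#' Chi-squared test of association on a 2x2 responsiveness table
#'
#' Pearson chi-squared without continuity correction,
#' `X2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` on one degree of freedom,
#' applied to the joint responsiveness of the fiber sample to two agonists.
#'
#' @param table A 2x2 matrix (e.g. from [contingency_2x2()]).
#' @return A list of class `pruriphys_test` with `statistic`, `df`,
#'   `p.value`, `method`.
#' @examples
#' association_chi_square(contingency_2x2(28, 11, 26, 1))
#' @export
association_chi_square <- function(table) {
  if (!is.matrix(table) || !all(dim(table) == c(2, 2))) {
    stop("table must be a 2x2 matrix")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a margin is zero")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(
    list(statistic = unname(ht$statistic), df = 1L,
         p.value = unname(ht$p.value),
         method = "Pearson chi-squared (no continuity correction)"),
    class = "pruriphys_test"
  )
}

#' @export
print.pruriphys_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.4g, df = %s, p = %.4g\n", x$method,
              x$statistic, paste(signif(unlist(x$df), 4), collapse = ", "),
              x$p.value))
  invisible(x)
}

#' Paired t-test on per-fiber responses
#'
#' Two-sided paired t-test on the per-fiber difference between two
#' conditions (e.g. net response to two pruritogens across all CMHs), with
#' group means and SEMs reported as effect descriptors.
#'
#' If all differences are exactly zero the statistic is 0 and p = 1 (the
#' two conditions are identical); a constant non-zero difference has no
#' within-pair variance and is an error.
#'
#' @param x,y Numeric vectors of equal length (>= 2), paired by fiber.
#' @return A `pruriphys_test` list with `statistic`, `df`, `p.value`,
#'   `method`, and `means`/`sems` of the two conditions.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2) stop("need at least two pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    if (all(d == 0)) {
      return(structure(
        list(statistic = 0, df = length(x) - 1L, p.value = 1,
             method = "Paired t-test",
             means = c(x = mean(x), y = mean(y)),
             sems = c(x = stats::sd(x) / sqrt(length(x)),
                      y = stats::sd(y) / sqrt(length(y)))),
        class = "pruriphys_test"))
    }
    stop("zero variance of paired differences")
  }
  ht <- stats::t.test(x, y, paired = TRUE)
  structure(
    list(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p.value = unname(ht$p.value), method = "Paired t-test",
         means = c(x = mean(x), y = mean(y)),
         sems = c(x = stats::sd(x) / sqrt(length(x)),
                  y = stats::sd(y) / sqrt(length(y)))),
    class = "pruriphys_test"
  )
}

#' Mixed (split-plot) ANOVA of net responses: fiber type x pruritogen
#'
#' Repeated-measures ANOVA with fiber type (QC/SC) as the between-subjects
#' factor and pruritogen as the within-subjects factor, on per-fiber net
#' responses. With a two-level within factor the sphericity correction is
#' identically 1. Fibers missing one of the within conditions are excluded
#' with a warning.
#'
#' @param data Long-format data frame with columns `fiber_id`,
#'   `fiber_type`, `compound` (the pruritogen), and the response column
#'   `dv` — the schema produced by [generate_injection_cohort()].
#' @param dv Name of the response column (default `"net_aps"`).
#' @param within Name of the pruritogen (within-subject) column.
#' @return A data frame of effects as returned by [rmanova_gg()].
#' @export
mixed_anova_fiber_pruritogen <- function(data, dv = "net_aps",
                                         within = "compound") {
  rmanova_gg(data, dv = dv, subject = "fiber_id", within = within,
             between = "fiber_type")
}

# Split-plot decomposition used by the Scheffe post hoc: returns the
# between-subject error (subjects within groups) and the within-subject
# residual (subject x condition), each with df, plus cell statistics.
split_plot_errors <- function(data, dv, subject, within, between) {
  sub <- factor(data[[subject]])
  w <- factor(data[[within]])
  g_by_sub <- tapply(as.character(data[[between]]), sub, function(z) z[1])
  k <- nlevels(w)
  wide <- tapply(data[[dv]], list(sub, w), mean)
  keep <- stats::complete.cases(wide)
  if (!all(keep)) {
    warning(sum(!keep), " subject(s) missing a within condition; excluded")
    wide <- wide[keep, , drop = FALSE]
  }
  grp <- factor(g_by_sub[rownames(wide)])
  n_g <- table(grp)
  sub_means <- rowMeans(wide)
  cell_means <- apply(wide, 2, function(col) tapply(col, grp, mean))
  # cell_means: groups x conditions
  grp_means <- tapply(sub_means, grp, mean)
  ss_subj <- k * sum((sub_means - grp_means[grp])^2)
  df_subj <- nrow(wide) - nlevels(grp)
  # residual: y_ic - cellmean_g(i),c - (subjmean_i - groupmean_g(i))
  resid <- wide
  for (j in seq_len(k)) {
    resid[, j] <- wide[, j] - cell_means[as.integer(grp), j] -
      (sub_means - grp_means[grp])
  }
  ss_resid <- sum(resid^2)
  df_resid <- df_subj * (k - 1)
  list(cell_means = cell_means, n_g = n_g, k = k,
       ms_subj = ss_subj / df_subj, df_subj = df_subj,
       ms_resid = ss_resid / df_resid, df_resid = df_resid,
       groups = levels(grp), conditions = levels(w))
}

#' Scheffe post hoc contrasts for the fiber type x pruritogen design
#'
#' Scheffe-adjusted pairwise comparisons among the four cell means of the
#' split-plot design (QC-ALA, QC-BAM, SC-ALA, SC-BAM). Contrasts between
#' conditions within the same fiber type use the subject-by-pruritogen
#' residual error; contrasts that cross fiber types use the pooled error
#' `(MS_subjects + (k-1) MS_residual)/k` with Satterthwaite degrees of
#' freedom, as the variance of a cell mean involves both the
#' between-subject and the within-subject variance components.
#'
#' @inheritParams mixed_anova_fiber_pruritogen
#' @param subject,within,between Column names (defaults match
#'   [mixed_anova_fiber_pruritogen()]).
#' @return A data frame with one row per pairwise cell contrast:
#'   `cell_1`, `cell_2`, `estimate`, `se`, `F_scheffe`, `df1`, `df2`, `p`.
#' @export
scheffe_posthoc <- function(data, dv = "net_aps", subject = "fiber_id",
                            within = "compound", between = "fiber_type") {
  sp <- split_plot_errors(data, dv, subject, within, between)
  cells <- expand.grid(group = sp$groups, condition = sp$conditions,
                       stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  df1 <- n_cells - 1
  pairs <- utils::combn(n_cells, 2)
  res <- vector("list", ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    g1 <- cells$group[i1]; c1 <- cells$condition[i1]
    g2 <- cells$group[i2]; c2 <- cells$condition[i2]
    m1 <- sp$cell_means[g1, c1]; m2 <- sp$cell_means[g2, c2]
    est <- m1 - m2
    n1 <- sp$n_g[[g1]]; n2 <- sp$n_g[[g2]]
    if (identical(g1, g2)) {
      se2 <- sp$ms_resid * (1 / n1 + 1 / n2)
      df2 <- sp$df_resid
    } else {
      ms_pool <- (sp$ms_subj + (sp$k - 1) * sp$ms_resid) / sp$k
      se2 <- ms_pool * (1 / n1 + 1 / n2)
      df2 <- ms_pool^2 * sp$k^2 /
        (sp$ms_subj^2 / sp$df_subj +
           ((sp$k - 1) * sp$ms_resid)^2 / sp$df_resid)
    }
    f_stat <- est^2 / se2
    p <- stats::pf(f_stat / df1, df1, df2, lower.tail = FALSE)
    res[[j]] <- data.frame(
      cell_1 = paste(g1, c1, sep = ":"), cell_2 = paste(g2, c2, sep = ":"),
      estimate = est, se = sqrt(se2), F_scheffe = f_stat,
      df1 = df1, df2 = df2, p = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Summarize a table of net responses
#'
#' Computes, from a tidy net-response table (columns `fiber_id`,
#' `compound`, `net_aps`), the per-compound mean and SEM and the paired
#' t-test between two compounds across fibers tested with both. This is
#' the population summary reported for the CMH sample (mean net APs per
#' 5 min, paired t on the per-fiber differences).
#'
#' @param net_table Data frame with columns `fiber_id`, `compound`,
#'   `net_aps`.
#' @param compounds Length-2 character vector naming the compounds to
#'   compare (default the two MRGPR agonists).
#' @return A list with `means` (data frame: compound, n, mean, sem) and
#'   `paired_t` (a `pruriphys_test`, difference `compounds[1] -
#'   compounds[2]`).
#' @export
summarize_net_table <- function(net_table, compounds = c("ALA", "BAM8_22")) {
  stopifnot(all(c("fiber_id", "compound", "net_aps") %in% names(net_table)))
  tab <- net_table[net_table$compound %in% compounds, ]
  means <- do.call(rbind, lapply(split(tab$net_aps, tab$compound), function(v) {
    data.frame(n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)))
  }))
  means <- cbind(compound = rownames(means), means)
  rownames(means) <- NULL
  wide <- tapply(tab$net_aps, list(tab$fiber_id, tab$compound), mean)
  wide <- wide[stats::complete.cases(wide), compounds, drop = FALSE]
  tt <- paired_t(wide[, 1], wide[, 2])
  list(means = means, paired_t = tt)
}

#' Responsiveness cross-classification of a scored cohort
#'
#' Builds the 2x2 joint-responsiveness table for two compounds from a tidy
#' table of scored fibers.
#'
#' @param net_table Data frame with columns `fiber_id`, `compound`,
#'   `responsive` (logical).
#' @param compounds Length-2 character vector (A, B).
#' @return A 2x2 matrix as from [contingency_2x2()].
#' @export
responsiveness_table <- function(net_table, compounds = c("ALA", "BAM8_22")) {
  stopifnot(all(c("fiber_id", "compound", "responsive") %in% names(net_table)))
  tab <- net_table[net_table$compound %in% compounds, ]
  wide <- tapply(tab$responsive, list(tab$fiber_id, tab$compound), any)
  wide <- wide[stats::complete.cases(wide), compounds, drop = FALSE]
  a <- wide[, 1]; b <- wide[, 2]
  contingency_2x2(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
}
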