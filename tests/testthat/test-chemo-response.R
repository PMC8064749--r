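mk_rec <- function(spikes, baseline = 0, fiber = "f1", compound = "ALA",
                   inj = c(0, 10)) {
  injection_recording(fiber, compound, baseline, inj, spikes)
}

test_that("baseline prorating is linear in the window", {
  expect_equal(prorated_baseline(6, 300), 30)
  expect_equal(prorated_baseline(0, 123), 0)
  expect_equal(prorated_baseline(7, 200), 7 * 200 / 60)
  expect_error(prorated_baseline(-1, 300), "non-negative")
})

test_that("net response subtracts prorated baseline and vehicle net", {
  # pruritogen: 60 APs in the window, baseline 6/min -> prorated 30;
  # vehicle: 10 APs net -> net = (60 - 30) - 10 = 20, responsive
  pru <- mk_rec(10 + sort(runif(60, 0, 299.9)), baseline = 6)
  veh <- mk_rec(10 + sort(runif(10, 0, 299.9)), baseline = 0,
                compound = "ECF")
  nr <- net_response(pru, veh)
  expect_equal(nr$net_aps, 20)
  expect_true(nr$responsive)

  # identical recordings cancel exactly
  same <- mk_rec(10 + c(1, 5, 20), baseline = 3)
  nr0 <- net_response(same, same)
  expect_equal(nr0$net_aps, 0)
  expect_false(nr0$responsive)

  # responsiveness boundary: 9 is not responsive, 10 is
  veh0 <- mk_rec(numeric(0))
  expect_false(net_response(mk_rec(10 + seq_len(9)), veh0)$responsive)
  expect_true(net_response(mk_rec(10 + seq_len(10)), veh0)$responsive)

  expect_error(net_response(mk_rec(1, fiber = "a"), mk_rec(1, fiber = "b")),
               "different fibers")
})

test_that("net response is additive in spike counts", {
  set.seed(2)
  sp <- 10 + sort(runif(25, 0, 300))
  veh_sp <- 10 + sort(runif(5, 0, 300))
  n1 <- net_response(mk_rec(sp, baseline = 4), mk_rec(veh_sp))$net_aps
  # doubling every count doubles the net
  sp2 <- sort(c(sp, sp + 1e-4))
  veh2 <- sort(c(veh_sp, veh_sp + 1e-4))
  n2 <- net_response(mk_rec(sp2, baseline = 8), mk_rec(veh2))$net_aps
  expect_equal(n2, 2 * n1)
})

test_that("time-course binning uses half-open bins and conserves spikes", {
  rec <- mk_rec(10 + c(1, 9.99, 10.0), inj = c(0, 10))
  tc <- bin_time_course(rec)
  expect_equal(tc$counts[1:3], c(2, 1, 0))
  expect_equal(sum(tc$counts), 3)

  expect_equal(sum(bin_time_course(mk_rec(numeric(0)))$counts), 0)

  set.seed(8)
  for (i in 1:20) {
    sp <- 10 + sort(runif(sample(5:80, 1), 0, 310))
    rec <- mk_rec(sp)
    tc <- bin_time_course(rec)
    expect_equal(tc$counts, oracle_bin_counts(sp - 10, tc$bin_edges))
    expect_equal(sum(tc$counts), sum(sp - 10 >= 0 & sp - 10 < 300))
  }
  expect_error(bin_time_course(mk_rec(1), bin_s = -1), "positive")
  expect_error(bin_time_course(mk_rec(1), bin_s = 7), "divide")
})

test_that("chi-squared association equals the closed form and flags degenerate tables", {
  # the generic Pearson observed-vs-expected computation and the 2x2
  # closed form must agree to 1e-9 on random tables
  set.seed(14)
  for (i in 1:200) {
    cells <- rpois(4, lambda = sample(2:30, 1)) + 1
    res <- association_chi_square(contingency_2x2(cells[1], cells[2],
                                                  cells[3], cells[4]))
    expect_equal(res$statistic,
                 oracle_chi2_2x2(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-9)
  }
  expect_equal(association_chi_square(contingency_2x2(10, 0, 0, 10))$statistic,
               20)
  # independence: ad = bc
  expect_equal(association_chi_square(contingency_2x2(4, 8, 2, 4))$statistic,
               0, tolerance = 1e-12)
  expect_error(association_chi_square(contingency_2x2(5, 5, 0, 0)),
               "degenerate")
})

test_that("paired t matches the textbook formula; degenerate cases handled", {
  set.seed(15)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    x <- rnorm(n, 10, 4); y <- rnorm(n, 11, 4)
    res <- paired_t(x, y)
    orc <- oracle_paired_t(x, y)
    expect_equal(res$statistic, orc$t, tolerance = 1e-9)
    expect_equal(res$df, orc$df)
    expect_equal(res$p.value, orc$p, tolerance = 1e-9)
  }
  identical_res <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(identical_res$statistic, 0)
  expect_equal(identical_res$p.value, 1)
  expect_error(paired_t(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(paired_t(1:3, 1:4), "paired")
})

test_that("mixed ANOVA agrees with hand-computed split-plot sums of squares", {
  # balanced toy: 4 fibers (2 QC, 2 SC) x 2 compounds
  Y <- matrix(c(80, 50,
                90, 60,
                12, 88,
                18, 96), nrow = 4, byrow = TRUE)
  grp <- factor(c("QC", "QC", "SC", "SC"))
  d <- data.frame(
    fiber_id = rep(paste0("f", 1:4), each = 2),
    fiber_type = rep(grp, each = 2),
    compound = rep(c("ALA", "BAM8_22"), 4),
    net_aps = as.vector(t(Y)))
  res <- mixed_anova_fiber_pruritogen(d)
  orc <- oracle_split_plot(Y, grp)
  expect_equal(res$statistic[res$effect == "fiber_type"], orc$F_group,
               tolerance = 1e-9)
  expect_equal(res$statistic[res$effect == "compound"], orc$F_cond,
               tolerance = 1e-9)
  expect_equal(res$statistic[res$effect == "fiber_type:compound"], orc$F_int,
               tolerance = 1e-9)
  # two-level within factor: no sphericity correction possible
  expect_equal(res$gg_eps[res$effect == "compound"], 1)
  expect_equal(res$p_gg, res$p)
})

test_that("mixed ANOVA on constant data reports zero F throughout", {
  d <- data.frame(fiber_id = rep(paste0("f", 1:6), each = 2),
                  fiber_type = rep(rep(c("QC", "SC"), each = 3), each = 2),
                  compound = rep(c("ALA", "BAM8_22"), 6),
                  net_aps = 5)
  res <- mixed_anova_fiber_pruritogen(d)
  expect_true(all(res$statistic == 0))
  expect_true(all(res$p == 1))
})

test_that("mixed ANOVA detects a built-in fiber-type x pruritogen interaction", {
  set.seed(19)
  net <- generate_injection_cohort(29, 31)
  res <- mixed_anova_fiber_pruritogen(net)
  p_int <- res$p_gg[res$effect == "fiber_type:compound"]
  expect_lt(p_int, 0.001)
})

test_that("Scheffe post hoc matches a hand-computed within-group contrast", {
  Y <- matrix(c(80, 50, 90, 60, 74, 58,
                12, 88, 18, 96, 15, 90), nrow = 6, byrow = TRUE)
  grp <- factor(rep(c("QC", "SC"), each = 3))
  d <- data.frame(
    fiber_id = rep(paste0("f", 1:6), each = 2),
    fiber_type = rep(grp, each = 2),
    compound = rep(c("ALA", "BAM8_22"), 6),
    net_aps = as.vector(t(Y)))
  sch <- scheffe_posthoc(d)
  orc <- oracle_split_plot(Y, grp)
  # SC:ALA vs SC:BAM8_22 uses the residual (within) error term with n = 3
  row <- sch[sch$cell_1 == "SC:ALA" & sch$cell_2 == "SC:BAM8_22", ]
  psi <- mean(Y[4:6, 1]) - mean(Y[4:6, 2])
  f_hand <- psi^2 / (orc$ms_resid * (2 / 3))
  expect_equal(row$F_scheffe, f_hand, tolerance = 1e-9)
  expect_equal(row$df2, orc$df_resid)
  expect_equal(row$p, pf(f_hand / 3, 3, orc$df_resid, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("Scheffe contrasts are null on equal cell means and detect large ones", {
  set.seed(23)
  d_null <- data.frame(
    fiber_id = rep(paste0("f", 1:20), each = 2),
    fiber_type = rep(rep(c("QC", "SC"), each = 10), each = 2),
    compound = rep(c("ALA", "BAM8_22"), 20),
    net_aps = rnorm(40, 50, 5))
  sch <- scheffe_posthoc(d_null)
  expect_true(all(sch$p > 0.05))

  net <- generate_injection_cohort(29, 31, seed = 31)
  sch2 <- scheffe_posthoc(net)
  row <- sch2[sch2$cell_1 == "SC:ALA" & sch2$cell_2 == "SC:BAM8_22", ]
  expect_lt(row$p, 0.001)   # SC respond far more to BAM8-22 than to ALA
})

test_that("net-table summary returns per-compound means, SEM and the paired t", {
  set.seed(29)
  net <- generate_injection_cohort(10, 10)
  s <- summarize_net_table(net)
  ala <- net$net_aps[net$compound == "ALA"]
  expect_equal(s$means$mean[s$means$compound == "ALA"], mean(ala))
  expect_equal(s$means$sem[s$means$compound == "ALA"],
               sd(ala) / sqrt(length(ala)))
  wide <- tapply(net$net_aps, list(net$fiber_id, net$compound), mean)
  orc <- oracle_paired_t(wide[, "ALA"], wide[, "BAM8_22"])
  expect_equal(s$paired_t$statistic, orc$t, tolerance = 1e-9)
})

test_that("responsiveness table cross-classifies fibers correctly", {
  d <- data.frame(
    fiber_id = rep(c("a", "b", "c", "d"), each = 2),
    compound = rep(c("ALA", "BAM8_22"), 4),
    responsive = c(TRUE, TRUE,  TRUE, FALSE,  FALSE, TRUE,  FALSE, FALSE))
  tab <- responsiveness_table(d)
  expect_equal(as.vector(t(tab)), c(1, 1, 1, 1))
})
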