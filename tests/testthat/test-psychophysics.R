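test_that("rating series validate the 0.5-min grid and magnitude range", {
  s <- mk_series(c(0, 6, 17, 6, 0))
  expect_s3_class(s, "rating_series")
  expect_error(rating_series("s", "ALA", "itch", c(0.5, 1.5), c(1, 2)),
               "grid")
  expect_error(mk_series(c(0, 120)), "\\[0, 100\\]")
})

test_that("peak rating is the session maximum", {
  expect_equal(peak_rating(mk_series(c(0, 6, 17, 6, 0))), 17)
  expect_equal(peak_rating(mk_series(rep(0, 10))), 0)
  set.seed(61)
  for (i in 1:20) {
    m <- runif(sample(10:40, 1), 0, 60)
    expect_equal(peak_rating(mk_series(m)), max(m))
  }
})

test_that("sensation duration runs from onset to the first zero after the last nonzero", {
  # nonzero 0.5-3.0 min, zeros after -> first zero at 3.5, duration 3.0
  d <- sensation_duration(mk_series(c(5, 8, 9, 6, 4, 2, 0, 0, 0, 0)))
  expect_equal(d$duration, 3.0)
  expect_false(d$censored)

  # waxing and waning: nonzero 0.5-1.0, zero 1.5, nonzero 2.0-2.5,
  # zeros from 3.0 -> duration 3.0 - 0.5 = 2.5
  d <- sensation_duration(mk_series(c(4, 3, 0, 5, 2, 0, 0, 0, 0, 0)))
  expect_equal(d$duration, 2.5)
  expect_false(d$censored)

  # nonzero through the 20-min cap -> censored at 19.5
  d <- sensation_duration(mk_series(rep(5, 40)))
  expect_equal(d$duration, 19.5)
  expect_true(d$censored)

  expect_error(sensation_duration(mk_series(rep(0, 12))), "no sensation")
})

test_that("rating AUC is the trapezoid with an implicit leading zero", {
  # single nonzero sample of 10 at t = 1.0: triangle up + down = 5
  expect_equal(rating_auc(mk_series(c(0, 10, 0, 0, 0, 0, 0, 0, 0, 0))), 5)

  # constant 10 over 2.0-4.0 min flanked by zeros = 25
  m <- rep(0, 12); m[4:8] <- 10
  expect_equal(rating_auc(mk_series(m)), 25)

  # random series against an independent trapezoid implementation
  set.seed(67)
  for (i in 1:20) {
    m <- pmax(0, rnorm(14, 6, 6)); m[1] <- 0; m[12:14] <- 0
    if (all(m == 0)) m[3] <- 5
    s <- mk_series(m)
    t <- s$time_min
    nz <- which(m > 0)
    i_off <- which(m == 0 & seq_along(m) > max(nz))[1]
    sel <- seq(nz[1], i_off)
    expect_equal(rating_auc(s),
                 pracma::trapz(c(t[nz[1]] - 0.5, t[sel]), c(0, m[sel])),
                 tolerance = 1e-12)
  }

  # AUC scales linearly with magnitude
  m <- c(0, 3, 8, 5, 0, 0, 0, 0, 0, 0)
  expect_equal(rating_auc(mk_series(3 * m)), 3 * rating_auc(mk_series(m)))
  expect_error(rating_auc(mk_series(rep(0, 10))), "no sensation")
})

test_that("metrics for all-zero series are excluded from duration and AUC", {
  m <- sensation_metrics(mk_series(rep(0, 10)))
  expect_equal(m$peak, 0)
  expect_true(is.na(m$duration) && is.na(m$auc))
})

test_that("session validation enforces the protocol stopping rules", {
  z <- function(n) rep(0, n)
  mk3 <- function(n, tail_zeros = TRUE) {
    m <- c(5, 4, 3, rep(0, n - 3))
    if (!tail_zeros) m[n] <- 2
    lapply(c("itch", "pricking_stinging", "burning"),
           function(q) mk_series(m, quality = q))
  }
  # all-zero 5-min session is valid
  v <- validate_session(lapply(1:3, function(i) mk_series(z(10))))
  expect_true(v$valid)
  # ending at 4.5 min violates the minimum
  v <- validate_session(lapply(1:3, function(i) mk_series(z(9))))
  expect_false(v$valid)
  # early stop without three trailing zeros on a quality is flagged
  v <- validate_session(mk3(12, tail_zeros = FALSE))
  expect_false(v$valid)
  # still nonzero at 20 min: valid but censored
  v <- validate_session(lapply(1:3, function(i) mk_series(rep(4, 40))))
  expect_true(v$valid)
  expect_true(v$censored)
})

test_that("the all-nonzero filter keeps exactly the subjects with sensations everywhere", {
  set.seed(71)
  ratings <- generate_rating_cohort(20)
  metrics <- compute_metrics(ratings)
  keep <- filter_all_nonzero(metrics)
  # matches the direct definition
  for (s in unique(metrics$subject_id)) {
    all_nz <- all(metrics$peak[metrics$subject_id == s] > 0)
    expect_equal(s %in% keep, all_nz)
  }
  # idempotent on the filtered subset
  sub <- metrics[metrics$subject_id %in% keep, ]
  expect_setequal(filter_all_nonzero(sub), keep)
})

test_that("the balanced-itch filter applies the 50% min/max rule inclusively", {
  mk_metrics <- function(peaks) {
    data.frame(subject_id = "s1", stimulus = c("ALA", "BAM", "HIS"),
               quality = "itch", peak = peaks, duration_min = 1,
               censored = FALSE, auc = 1)
  }
  expect_equal(filter_balanced_itch(mk_metrics(c(10, 20, 20))), "s1")
  expect_equal(length(filter_balanced_itch(mk_metrics(c(4, 20, 20)))), 0)
  expect_equal(filter_balanced_itch(mk_metrics(c(5, 10, 7))), "s1")
})

test_that("area analysis runs one GG-corrected RM-ANOVA per measure", {
  # identical areas across stimuli: F = 0
  d0 <- expand.grid(subject_id = paste0("s", 1:8),
                    stimulus = c("ALA", "BAM", "HIS"),
                    measure = "wheal", stringsAsFactors = FALSE)
  d0$area_cm2 <- 2
  res <- area_analysis(d0, posthoc = FALSE)
  expect_equal(res$wheal$anova$statistic, 0)

  # histamine-driven enlargement is detected in every measure
  set.seed(73)
  areas <- generate_area_cohort(20)
  res <- area_analysis(areas)
  for (m in names(res)) {
    expect_lt(res[[m]]$anova$p_gg, 0.01)
  }
  # and the HIS vs ALA post hoc contrast is significant for flare
  ph <- res$flare$posthoc
  row <- ph[(ph$level_1 == "HIS" & ph$level_2 == "ALA") |
              (ph$level_1 == "ALA" & ph$level_2 == "HIS"), ]
  expect_lt(row$p_bonferroni, 0.05)
})

test_that("gLMS anchors are strictly increasing from 0 to 100", {
  expect_equal(unname(glms_anchors[c("no sensation", "strongest imaginable")]),
               c(0, 100))
  expect_true(all(diff(glms_anchors) > 0))
})
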