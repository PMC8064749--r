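test_that("instantaneous frequency is 1/ISI assigned to the later spike", {
  s <- instantaneous_frequency(spike_train(c(1.0, 1.5, 2.0)))
  expect_equal(s$time, c(1.5, 2.0))
  expect_equal(s$freq, c(2, 2))

  expect_equal(nrow(instantaneous_frequency(spike_train(0.7))), 0)
  expect_equal(nrow(instantaneous_frequency(spike_train(numeric(0)))), 0)

  set.seed(11)
  ts <- sort(runif(50, 0, 5))
  s <- instantaneous_frequency(ts)
  expect_equal(s$time, ts[-1])
  expect_equal(s$freq, 1 / diff(ts))

  expect_error(instantaneous_frequency(c(1, 1, 2)), "strictly increasing")
  expect_error(spike_train(c(1, 1, 2)), "strictly increasing")
})

test_that("median smoothing matches the sliding-window oracle and preserves shape", {
  const <- instantaneous_frequency(cumsum(rep(0.2, 5)))
  expect_equal(median_smooth3(const)$freq, const$freq)

  spike <- mk_if(c(0.1, 0.2, 0.3), c(1, 100, 1))
  expect_equal(median_smooth3(spike)$freq, c(1, 1, 1))

  set.seed(7)
  for (n in c(0, 1, 2, 3, 20)) {
    s <- mk_if(cumsum(runif(n, 0.01, 0.2)), runif(n, 1, 80))
    sm <- median_smooth3(s)
    expect_equal(sm$freq, oracle_median3(s$freq))
    expect_equal(sm$time, s$time)
    expect_equal(nrow(sm), n)
  }

  # idempotent on a monotone series
  mono <- mk_if(1:6 / 10, c(2, 4, 8, 16, 32, 64))
  expect_equal(median_smooth3(mono)$freq, mono$freq)
  twice <- median_smooth3(median_smooth3(mono))
  expect_equal(twice$freq, mono$freq)
})

test_that("time of peak discharge is the argmax with earliest-tie break", {
  expect_equal(time_of_peak_discharge(mk_if(c(0.1, 0.3, 1.2), c(10, 40, 20))), 0.3)
  expect_equal(time_of_peak_discharge(mk_if(c(0.2, 0.9), c(30, 30))), 0.2)
  expect_error(time_of_peak_discharge(mk_if(numeric(0), numeric(0))),
               "no discharge")

  set.seed(21)
  for (i in 1:20) {
    s <- mk_if(sort(runif(15, 0, 3)), sample(1:5, 15, replace = TRUE))
    expect_equal(time_of_peak_discharge(s),
                 s$time[which(s$freq == max(s$freq))[1]])
  }
})

test_that("onset-burst detection separates QC from SC archetypes", {
  stim <- heat_stimulus()
  qc <- generate_heat_train("QC", stim, latency = 0.25, noise = FALSE)
  sc <- generate_heat_train("SC", stim, latency = 0.25, noise = FALSE)
  sm_qc <- median_smooth3(instantaneous_frequency(qc$train))
  sm_sc <- median_smooth3(instantaneous_frequency(sc$train))
  expect_true(detect_onset_burst(sm_qc, stim, latency = 0.25))
  expect_false(detect_onset_burst(sm_sc, stim, latency = 0.25))
  expect_false(detect_onset_burst(mk_if(numeric(0), numeric(0)), stim))
})

test_that("heat-response classification follows the line-of-equality rule", {
  stim <- heat_stimulus()
  meta <- fiber_metadata(conduction_latency_skin = 0.25)

  qc <- generate_heat_train("QC", stim, latency = 0.25, noise = FALSE)
  cl <- classify_heat_response(qc$train, stim, meta)
  expect_identical(cl$label, "QC")
  expect_true(cl$burst_at_onset)

  sc <- generate_heat_train("SC", stim, latency = 0.25, noise = FALSE)
  cl <- classify_heat_response(sc$train, stim, meta)
  expect_identical(cl$label, "SC")
  expect_false(cl$burst_at_onset)
  expect_gt(cl$peak_time, cl$equality_line_value)

  # peak exactly on the line, no burst -> unclassified; ISIs widen after
  # the spike at E so the peak IF lands exactly at E
  e <- stim$rise_time + meta$conduction_latency_skin   # 0.45
  tr <- spike_train(c(0.10, e, 0.90, 1.45, 2.10))
  cl <- classify_heat_response(tr, stim, meta, tolerance = 0.1)
  expect_equal(cl$peak_time, e)
  expect_false(cl$burst_at_onset)
  expect_identical(cl$label, "UNCLASSIFIED")

  # fewer than two spikes in the window -> unclassified, empty diagnostics
  cl <- classify_heat_response(spike_train(1.0), stim, meta)
  expect_identical(cl$label, "UNCLASSIFIED")
  expect_equal(nrow(cl$diagnostics), 0)

  expect_error(
    classify_heat_response(qc$train, stim,
                           fiber_metadata(conduction_latency_skin = NA)),
    "conduction latency")
})

test_that("with zero tolerance and no burst rule, labels partition by sign(P - E)", {
  stim <- heat_stimulus()
  no_burst <- burst_params(min_spikes = 1e6)   # burst can never trigger
  set.seed(33)
  for (i in 1:40) {
    e <- generate_heat_train(sample(c("QC", "SC"), 1), stim)
    meta <- e$train$metadata
    cl <- classify_heat_response(e$train, stim, meta, tolerance = 0,
                                 burst = no_burst)
    if (cl$label == "UNCLASSIFIED" && is.na(cl$peak_time)) next
    expected <- if (cl$peak_time > cl$equality_line_value) "SC"
      else if (cl$peak_time == cl$equality_line_value) "UNCLASSIFIED"
      else "QC"
    expect_identical(cl$label, expected)
  }
})

test_that("classification is invariant to a uniform time translation", {
  stim <- heat_stimulus()
  set.seed(44)
  for (i in 1:10) {
    e <- generate_heat_train(sample(c("QC", "SC"), 1), stim)
    shift <- runif(1, -3, 3)
    # express the same recording relative to a shifted stimulus onset and
    # shift the timestamps identically: the relative times are unchanged
    shifted <- spike_train((e$train$timestamps + shift) - shift,
                           metadata = e$train$metadata)
    a <- classify_heat_response(e$train, stim, e$train$metadata)
    b <- classify_heat_response(shifted, stim, e$train$metadata)
    expect_identical(a$label, b$label)
    expect_equal(a$peak_time, b$peak_time)
  }
})

test_that("conduction-velocity classes use the 2 and 20 m/s boundaries", {
  expect_identical(classify_by_cv(1.2), "C")
  expect_identical(classify_by_cv(10), "A_DELTA")
  expect_identical(classify_by_cv(2.0), "A_DELTA")
  expect_identical(classify_by_cv(20.0), "A_DELTA")
  expect_identical(classify_by_cv(25), "OUT_OF_RANGE")
  expect_error(classify_by_cv(0), "positive")
  expect_error(classify_by_cv(-1), "positive")
})

test_that("von Frey threshold is the smallest filament with 2/4 positives", {
  expect_equal(von_frey_threshold(c(4, 6, 8.9), c(1, 2, 4)), 6)
  expect_equal(von_frey_threshold(c(4, 6, 8.9), c(0, 0, 0)), Inf)
  expect_equal(von_frey_threshold(c(1, 4), c(2, 0)), 1)
  expect_error(von_frey_threshold(c(4, 6), c(2, 5)), "0..4")
  expect_error(von_frey_threshold(c(6, 4), c(2, 2)), "ascending")
})

test_that("mechanosensitivity splits at 6 bar, inclusive, with MIA for not reached", {
  expect_identical(classify_mechanosensitivity(1.5), "MSA")
  expect_identical(classify_mechanosensitivity(6), "MSA")
  expect_identical(classify_mechanosensitivity(8.9), "MIA")
  expect_identical(classify_mechanosensitivity(Inf), "MIA")
})
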