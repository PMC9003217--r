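test_that("HRV features reproduce hand computations", {
  expect_equal(sdnn(c(800, 800, 800)), 0)
  expect_equal(sdnn(c(790, 810)), 20 / sqrt(2))       # sd of 2 pts = |d|/sqrt(2)
  expect_equal(sdsd(c(800, 850, 800)), sqrt(5000))    # diffs +50, -50
  expect_equal(sdsd(c(800, 810, 820, 830)), 0)        # arithmetic progression
  expect_equal(rmssd(c(800, 850, 800)), 50)
  expect_equal(rmssd(rep(725, 10)), 0)
  expect_equal(pnn50(c(800, 851, 800)), 100)
  expect_equal(pnn50(c(800, 850, 800)), 0)            # 50 is not > 50
  expect_equal(pnn50(rep(800, 5)), 0)

  expect_error(sdnn(800), "at least 2")
  expect_error(sdsd(c(800, 850)), "at least 3")
  expect_error(rmssd(800), "at least 2")
  expect_error(pnn50(800), "at least 2")
})

test_that("HRV features match the naive oracle and the moment inequality", {
  set.seed(31)
  for (i in 1:250) {
    n <- sample(3:120, 1)
    bb <- stats::runif(n, 400, 1200)
    expect_equal(sdnn(bb), naive_sdnn(bb), tolerance = 1e-9)
    expect_equal(sdsd(bb), naive_sdsd(bb), tolerance = 1e-9)
    expect_equal(rmssd(bb), naive_rmssd(bb), tolerance = 1e-9)
    expect_equal(pnn50(bb), naive_pnn50(bb), tolerance = 1e-12)
    # centered second moment never exceeds the uncentered one
    nd <- n - 1
    expect_lte(sdsd(bb), rmssd(bb) * sqrt(nd / (nd - 1)) + 1e-12)
  }
})

test_that("calibration: baseline thresholds, clamping, defaults", {
  info <- subject_info(age = 25)

  # constant baseline: raw stats are 0, clamped up to the demographic floor
  prof <- calibrate(info, flat_physio(200))
  expect_true(all(prof$clamped))
  expect_equal(prof$threshold_sdnn, demographic_bands(info)$lo)

  # baseline drawn from the attentive regime recovers its sd parameter
  spec <- subject_spec(seed = 101)
  sched <- regime_schedule(600, "attentive")
  base <- simulate_bb_stream(sched, spec)
  prof <- calibrate(info, base, baseline_s = 600)
  expect_equal(prof$threshold_sdnn, 15, tolerance = 0.25)

  # two disjoint baselines from the same stationary process agree
  spec2 <- subject_spec(seed = 202)
  long <- simulate_bb_stream(regime_schedule(1200, "attentive"), spec2)
  b1 <- physio_stream(long$t_s[1:600], long$hr_bpm[1:600],
                      long$bb_ms[1:600])
  b2 <- physio_stream(long$t_s[601:1200], long$hr_bpm[601:1200],
                      long$bb_ms[601:1200])
  p1 <- calibrate(info, b1, baseline_s = 600)
  p2 <- calibrate(info, b2, baseline_s = 600)
  expect_equal(p1$threshold_sdnn, p2$threshold_sdnn, tolerance = 0.2)
  expect_equal(p1$threshold_rmssd, p2$threshold_rmssd, tolerance = 0.2)

  # no baseline: demographic midpoint default; short baseline: error
  prof <- calibrate(info, NULL)
  expect_false(prof$from_baseline)
  expect_equal(prof$threshold_sdnn, (5 + 250) / 2)
  expect_error(calibrate(info, flat_physio(50)), "baseline covers")
})

test_that("grade of attention: forced extremes, bounds, fairness", {
  info <- subject_info(age = 25)
  prof <- calibrate(info, flat_physio(200))  # thresholds at floor, below
  params <- ga_params(ws = 100, inner_len = 30)

  # constant window: all stats 0, strictly below any positive threshold
  expect_equal(grade_of_attention(flat_physio(100), prof, params), 300)

  # random windows never exceed 3*ws
  set.seed(32)
  for (i in 1:10) {
    bb <- stats::runif(100, 500, 1100)
    ga <- grade_of_attention(bb, prof, params)
    expect_gte(ga, 0); expect_lte(ga, 300)
  }
  expect_error(grade_of_attention(flat_physio(50), prof, params),
               "!= ws")

  # windows drawn from the calibration process: comparisons behave like a
  # (slightly loaded) coin, so mean GA sits near the 1.5*ws midpoint.
  # Short inner windows underestimate dispersion relative to the long
  # baseline, which loads the "below" side; the band reflects that.
  spec <- subject_spec(seed = 303)
  base <- simulate_bb_stream(regime_schedule(600, "attentive"), spec)
  prof2 <- calibrate(info, base, baseline_s = 600)
  spec2 <- subject_spec(seed = 404)
  s <- simulate_bb_stream(regime_schedule(2000, "attentive"), spec2)
  cs <- cumsum(c(0, attnfusion:::.attention_votes(s$bb_ms, prof2, params)))
  mean_ga <- mean(cs[101:2001] - cs[1:1901])
  expect_gt(mean_ga, 1.0 * 100)
  expect_lt(mean_ga, 2.3 * 100)
})

test_that("grade of attention equals a naive per-window recount", {
  info <- subject_info(age = 25)
  spec <- subject_spec(seed = 707)
  base <- simulate_bb_stream(regime_schedule(300, "attentive"), spec)
  prof <- calibrate(info, base, baseline_s = 300)
  params <- ga_params(ws = 60, inner_len = 10)
  thr <- c(prof$threshold_sdnn, prof$threshold_rmssd, prof$threshold_sdsd)
  set.seed(34)
  for (i in 1:10) {
    bb <- stats::runif(60, 500, 1100)
    naive <- 0
    for (s_i in 1:60) {
      w <- if (s_i < params$inner_len) bb[1:params$inner_len]
           else bb[(s_i - params$inner_len + 1):s_i]
      stats3 <- c(naive_sdnn(w), naive_rmssd(w), naive_sdsd(w))
      naive <- naive + sum(stats3 < thr)
    }
    expect_equal(grade_of_attention(bb, prof, params), naive)
  }
})

test_that("GA monotonicity: damping variability toward the attention side", {
  info <- subject_info(age = 25)
  spec <- subject_spec(seed = 505)
  base <- simulate_bb_stream(regime_schedule(300, "attentive"), spec)
  prof <- calibrate(info, base, baseline_s = 300)  # direction below
  params <- ga_params(ws = 100, inner_len = 30)
  set.seed(33)
  bb <- 800 + stats::rnorm(100, 0, 40)
  damped <- 800 + 0.5 * (bb - 800)  # every inner-window stat halves
  expect_gte(grade_of_attention(damped, prof, params),
             grade_of_attention(bb, prof, params))
})

test_that("physio attention array: cadence, strict Tp, regime flip", {
  info <- subject_info(age = 25)
  prof <- calibrate(info, flat_physio(200))
  params <- ga_params(ws = 100, inner_len = 30)

  s <- flat_physio(250)
  aa <- physio_attention_array(s, prof, params)
  expect_equal(nrow(aa), 151)          # n - ws + 1
  expect_equal(aa$t_s, 100:250)
  expect_true(all(aa$label == "Attention"))  # GA = 300 > 150 everywhere

  # GA exactly at Tp must read Distraction: half the samples vote 3
  # (constant segment), half vote 0 (huge swings above any threshold)
  p3 <- ga_params(ws = 60, inner_len = 3)
  bb <- c(rep(800, 30), rep(c(400, 1600), 15))
  aa3 <- physio_attention_array(physio_stream(0:59, 60000 / bb, bb),
                                prof, p3)
  ga <- grade_of_attention(bb, prof, p3)
  expect_equal(ga, p3$t_p)             # 90 = 1.5 * 60, the boundary
  expect_equal(as.character(aa3$label[1]), "Distraction")

  expect_error(physio_attention_array(flat_physio(50), prof, params),
               "shorter than window")
})

test_that("array flips regime near the true change point", {
  spec <- subject_spec(seed = 606)
  sched <- regime_schedule(c(600, 600), c("attentive", "distracted"))
  s <- simulate_bb_stream(sched, spec)
  base <- simulate_baseline_stream(spec, 300)
  prof <- calibrate(subject_info(age = 25), base, baseline_s = 300)
  params <- ga_params(ws = 100, inner_len = 30)
  aa <- physio_attention_array(s, prof, params)
  # settled before the switch: attentive; settled after: distracted
  pre <- aa$label[aa$t_s >= 500 & aa$t_s <= 600]
  post <- aa$label[aa$t_s >= 600 + params$ws + params$inner_len]
  expect_true(mean(pre == "Attention") > 0.9)
  expect_true(mean(post == "Distraction") > 0.9)
})

test_that("threshold formulas hold across a window-size sweep", {
  for (ws in c(25, 50, 100, 200, 300)) {
    expect_equal(ga_params(ws = ws, inner_len = min(30, ws))$t_p, 1.5 * ws)
    expect_equal(activation_params(window_s = ws)$t_fe, 100)
  }
})
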