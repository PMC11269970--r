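test_that("samplewise scoring matches hand-computed fixtures", {
  r <- samplewise_prf(bs_events(0, 100), bs_events(0, 100), 1000)
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 1, 1))
  r <- samplewise_prf(bs_events(0, 100), bs_events(50, 150), 1000)
  expect_equal(c(r$tp, r$fp, r$fn), c(50, 50, 50))
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)
  # no predictions: precision undefined -> 0 with flag
  r <- samplewise_prf(bs_events(0, 100), bs_events(), 1000)
  expect_equal(r$precision, 0)
  expect_false(r$precision_defined)
  expect_equal(r$recall, 0)
})

test_that("samplewise scoring equals per-sample rasterization on random layouts", {
  set.seed(1)
  n <- 50000
  for (i in 1:250) {
    truth <- random_events(sample(0:8, 1), n, tentative_prob = 0.2)
    pred <- random_events(sample(0:8, 1), n)
    r <- samplewise_prf(truth, pred, n)
    o <- oracle_prf(truth, pred, n)
    expect_equal(r$tp, o$tp)
    expect_equal(r$fp, o$fp)
    expect_equal(r$fn, o$fn)
  }
})

test_that("tentative regions can be excluded from scoring entirely", {
  truth <- bs_events(c(0, 1000), c(500, 1500), tentative = c(FALSE, TRUE))
  pred <- bs_events(c(0, 1000), c(500, 1500))
  strict <- samplewise_prf(truth, pred, 5000)
  expect_equal(strict$fp, 500)  # overlap with tentative counts as FP
  lenient <- samplewise_prf(truth, pred, 5000, tentative = "ignore")
  expect_equal(lenient$fp, 0)
  expect_equal(lenient$tp, 500)
})

test_that("segment error taxonomy classifies canonical fixtures", {
  n <- 160000
  # prediction overfills one event by 100 samples
  se <- segment_errors(bs_events(100, 200), bs_events(100, 300), n)
  expect_equal(se$overfill, 100 / 16000)
  expect_equal(se$insertion + se$merge + se$deletion +
                 se$fragmentation + se$underfill, 0)
  # prediction with no event nearby: insertion
  se <- segment_errors(bs_events(), bs_events(400, 500), n)
  expect_equal(se$insertion, 100 / 16000)
  # prediction bridging two events: the bridge is a merge
  se <- segment_errors(bs_events(c(0, 150), c(100, 250)), bs_events(0, 250), n)
  expect_equal(se$merge, 50 / 16000)
  # fully missed event: deletion
  se <- segment_errors(bs_events(1000, 2000), bs_events(), n)
  expect_equal(se$deletion, 1000 / 16000)
  # partially detected event: underfill at both edges
  se <- segment_errors(bs_events(1000, 2000), bs_events(1200, 1800), n)
  expect_equal(se$underfill, 400 / 16000)
  # gap inside one detected event: fragmentation
  se <- segment_errors(bs_events(1000, 2000),
                       bs_events(c(1000, 1600), c(1400, 2000)), n)
  expect_equal(se$fragmentation, 200 / 16000)
})

test_that("segment errors match the rasterized oracle and conserve FP/FN", {
  set.seed(2)
  n <- 50000
  for (i in 1:250) {
    truth <- random_events(sample(0:6, 1), n, tentative_prob = 0.1)
    pred <- random_events(sample(0:6, 1), n)
    se <- segment_errors(truth, pred, n)
    o <- oracle_segment_errors(truth, pred, n)
    for (k in names(o)) expect_equal(se[[k]], o[[k]], label = k)
    # conservation against samplewise counts
    sw <- samplewise_prf(truth, pred, n)
    expect_equal((se$insertion + se$merge + se$overfill) * 16000, sw$fp)
    expect_equal((se$deletion + se$fragmentation + se$underfill) * 16000, sw$fn)
  }
})

test_that("segment SNR matches closed-form amplitude ratios", {
  # equal RMS in and out of the event: 0 dB
  x <- numeric(160000)
  x[1:1000] <- 1     # event samples, RMS 1
  x[1001:160000] <- 1  # noise samples, RMS 1
  seg <- make_segment(x)
  expect_equal(segment_snr(seg, bs_events(0, 1000)), 0)
  # event RMS 10x noise RMS: 20 dB
  x[1:1000] <- 10
  expect_equal(segment_snr(make_segment(x), bs_events(0, 1000)), 20)
  # no event samples: NA (excluded from the analysis)
  expect_true(is.na(segment_snr(seg, bs_events())))
})

test_that("SNR-thresholded PR reduces to global PR at -Inf and is monotone", {
  spec <- corpus_spec(n_participants = 1, recording_duration = 120,
                      target_bs_ratio = 0.03, snr_range = c(-5, 12),
                      tentative_snr_floor = -100, seed = 40)
  set.seed(40)
  r <- generate_recording(spec)
  # predictions: the truth shifted by 30 ms (constant error rate)
  pred <- bs_events(r$events$onset + 480, r$events$offset + 480)
  st <- segment_table(r$recording, r$events, pred)
  tab <- pr_vs_snr(st, c(-Inf, -2, 2, 6))
  pooled <- st[!is.na(st$snr), ]
  p_global <- sum(pooled$tp) / (sum(pooled$tp) + sum(pooled$fp))
  expect_equal(tab$precision[tab$theta_s == -Inf], p_global)
  expect_true(all(diff(tab$n_segments) <= 0))
  expect_true(all(diff(tab$n_events) <= 0))
  expect_warning(pr_vs_snr(st, 1e6), "omitted")
})

test_that("duration thresholding filters truth and predictions symmetrically", {
  n <- 160000
  truth <- bs_events(c(0, 50000), c(32000, 52000))   # 2 s and 0.125 s
  pred <- bs_events(c(0, 17600, 50000), c(14400, 32000, 52000))
  # theta 0: same as unfiltered
  r0 <- pr_vs_duration(truth, pred, n, 0)
  rs <- samplewise_prf(truth, pred, n)
  expect_equal(r0$tp, rs$tp)
  expect_equal(r0$fp, rs$fp)
  # theta 1.5 s: the 2 s event stays but its 0.9 s fragments drop out,
  # so recall collapses; theta 0 recall is high
  r15 <- pr_vs_duration(truth, pred, n, 1.5)
  expect_gt(r0$recall, 0.9)
  expect_lt(r15$recall, r0$recall)
  expect_equal(r15$tp, 0)
  # threshold above every event: PR convention 0
  rbig <- pr_vs_duration(truth, pred, n, 10)
  expect_equal(rbig$precision, 0)
  expect_equal(rbig$recall, 0)
})

test_that("the imbalance sweep hits requested ratios and the analytic curve", {
  set.seed(3)
  n_frames <- 400000
  frame_truth <- runif(n_frames) < 0.05
  tpr <- 0.73; fpr <- 0.02
  frame_pred <- ifelse(frame_truth, runif(n_frames) < tpr,
                       runif(n_frames) < fpr)
  ratios <- c(0.001, 0.0089, 0.05, 0.15, 0.5)
  sw <- bs_ratio_sweep(frame_truth, frame_pred, ratios, seed = 4)
  expect_equal(sw$bs_ratio, ratios, tolerance = 0.02)
  expect_equal(sw$K / (sw$K + sw$J), sw$bs_ratio)
  closed <- ratios * tpr / (ratios * tpr + (1 - ratios) * fpr)
  expect_equal(sw$precision, closed, tolerance = 0.08)
  # precision rises with the BS ratio for a fixed-confusion predictor
  expect_true(all(diff(sw$precision) > 0))
  # recall stays at the TPR throughout
  expect_equal(sw$recall, rep(tpr, length(ratios)), tolerance = 0.05)
})

test_that("sweeping at the observed corpus ratio reproduces unsampled PR", {
  set.seed(5)
  n_frames <- 300000
  frame_truth <- runif(n_frames) < 0.01
  frame_pred <- ifelse(frame_truth, runif(n_frames) < 0.7,
                       runif(n_frames) < 0.005)
  obs_ratio <- mean(frame_truth)
  sw <- bs_ratio_sweep(frame_truth, frame_pred, obs_ratio, seed = 6)
  tp <- sum(frame_truth & frame_pred); fp <- sum(!frame_truth & frame_pred)
  expect_equal(sw$precision, tp / (tp + fp), tolerance = 0.05)
  # unreachable ratio warns and is skipped
  expect_warning(
    bs_ratio_sweep(logical(100), logical(100), 0.5, seed = 7), "unreachable")
})

test_that("ratio-to-event-rate conversion is linear through mean duration", {
  expect_equal(ratio_to_event_rate(0.0089, 0.383), 0.0089 * 3600 / 0.383)
  expect_equal(ratio_to_event_rate(0, 0.383), 0)
  expect_equal(ratio_to_event_rate(0.2, 0.5), 2 * ratio_to_event_rate(0.1, 0.5))
  expect_error(ratio_to_event_rate(0.1, 0), "positive")
})

test_that("median/IQR follows the midrange quartile convention", {
  r <- median_iqr(c(0, 10))
  expect_equal(r$median, 5)
  expect_equal(r$q1, 2.5)
  expect_equal(r$q3, 7.5)
  expect_equal(r$iqr, 5)
  expect_equal(median_iqr(rep(3, 5))$iqr, 0)
  r1 <- median_iqr(7)
  expect_equal(r1$median, 7)
  expect_equal(r1$iqr, 0)
  rs <- median_iqr(c(1, 2, 3, 4, 100), method = "standard")
  expect_equal(rs$median, 3)
  expect_equal(rs$iqr, unname(diff(stats::quantile(c(1, 2, 3, 4, 100),
                                                   c(0.25, 0.75)))))
  expect_error(median_iqr(numeric(0)), "empty")
})
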