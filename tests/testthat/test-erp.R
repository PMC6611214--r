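times_1k <- seq(-200, 3000, by = 10)  # 321 samples, 100 Hz

test_that("baseline correction subtracts the pre-stimulus mean exactly", {
  # constant epoch -> all zeros
  ep <- single_epoch(matrix(5, 1, length(times_1k)), times_1k)
  expect_true(all(baseline_correct(ep)$data == 0))
  # zero baseline, 3 uV after onset -> unchanged
  v <- matrix(ifelse(times_1k > 0, 3, 0), 1, length(times_1k), byrow = TRUE)
  ep2 <- single_epoch(v, times_1k)
  expect_equal(baseline_correct(ep2)$data, ep2$data)
  # linear ramp over the baseline with hand-computed mean
  ramp <- ifelse(times_1k <= 0, (times_1k + 200) / 200 * 2.5, 0)
  v3 <- matrix(ramp + ifelse(times_1k > 0, 4, 0), 1, length(times_1k))
  bc <- baseline_correct(single_epoch(v3, times_1k))
  expect_equal(bc$data[1, 1, 1, 1, times_1k == 1000], 4 - 1.25,
               ignore_attr = TRUE)
  # idempotence
  set.seed(1)
  rnd <- single_epoch(matrix(rnorm(2 * length(times_1k)), 2), times_1k)
  once <- baseline_correct(rnd)
  expect_equal(baseline_correct(once)$data, once$data, tolerance = 1e-12)
  # empty window errors
  expect_error(baseline_correct(rnd, c(-0.5, -0.4)), "no samples")
})

test_that("artifact rejection applies the range and step rules per channel", {
  t_s <- times_1k
  sine <- 10 * sin(2 * pi * t_s / 500)
  spike <- sine; spike[150] <- spike[150] + 200
  ramp <- approx(range(t_s), c(-70, 70), xout = t_s)$y       # range 140, tiny steps
  small_ramp <- ramp * 100 / 140                              # range 100 -> kept
  d <- array(0, dim = c(1, 1, 4, 1, length(t_s)))
  d[1, 1, 1, 1, ] <- sine
  d[1, 1, 2, 1, ] <- spike
  d[1, 1, 3, 1, ] <- ramp
  d[1, 1, 4, 1, ] <- small_ramp
  out <- reject_artifacts(make_epoch_set(d, t_s))
  expect_equal(as.vector(out$rejected[1, 1, ]), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(out$report$trials_rejected, 2)
  expect_equal(out$report$trials_kept, 2)
  # the slow ramp trips only the range rule: shrinking the range keeps it,
  # so the step rule never fired for it
  expect_lt(max(abs(diff(ramp))), 75)
})

test_that("minimum-trial enforcement is a strict at-least rule", {
  report <- data.frame(participant = rep(1:3, each = 2), item = rep(1:2, 3),
                       trials_total = 30,
                       trials_rejected = c(0, 15, 14, 0, 0, 0))
  report$trials_kept <- report$trials_total - report$trials_rejected
  # participant 1 has an item with 15 kept -> excluded; 16 kept -> retained
  expect_equal(enforce_min_trials(report), 1)
  report$trials_rejected <- c(0, 14, 14, 0, 0, 0)
  report$trials_kept <- report$trials_total - report$trials_rejected
  expect_equal(enforce_min_trials(report), integer(0))
  all_bad <- data.frame(participant = 1:2, item = 1, trials_total = 10,
                        trials_rejected = 10, trials_kept = 0)
  expect_error(enforce_min_trials(all_bad), "all 2 participants")
})

test_that("item averaging pools kept trials pointwise", {
  t_s <- seq(-100, 500, by = 10)
  v <- matrix(rnorm(2 * length(t_s)), 2)
  d <- array(0, dim = c(1, 1, 3, 2, length(t_s)))
  for (r in 1:3) d[1, 1, r, , ] <- v
  ep <- make_epoch_set(d, t_s)
  w <- average_item(ep, 1, 1)
  expect_equal(w$values, v, ignore_attr = TRUE)
  expect_equal(w$n_trials, 3)
  # opposite trials cancel
  d2 <- d; d2[1, 1, 1, , ] <- v; d2[1, 1, 2, , ] <- -v
  w2 <- average_item(make_epoch_set(d2, t_s), 1, 1, keep = c(TRUE, TRUE, FALSE))
  expect_true(all(abs(w2$values) < 1e-12))
  expect_error(average_item(ep, 1, 1, keep = rep(FALSE, 3)),
               "no kept trials")
})

test_that("averaging n noisy trials shrinks the error about 1/sqrt(n)", {
  set.seed(42)
  t_s <- seq(0, 1000, by = 2)
  template <- 5 * exp(-(t_s - 300)^2 / (2 * 60^2))
  n_tr <- 25
  d <- array(0, dim = c(1, 1, n_tr, 1, length(t_s)))
  for (r in 1:n_tr) d[1, 1, r, 1, ] <- template + rnorm(length(t_s), 0, 3)
  w <- average_item(make_epoch_set(d, t_s), 1, 1)
  rms_avg <- sqrt(mean((w$values[1, ] - template)^2))
  rms_single <- sqrt(mean((d[1, 1, 1, 1, ] - template)^2))
  expect_lt(rms_avg / rms_single, 0.35)   # approx 1/5 with sampling noise
  expect_gt(rms_avg / rms_single, 0.08)
})

test_that("group averaging weights items equally and obeys the LOO identity", {
  set.seed(7)
  ws <- random_item_waveforms(k = 6)
  plain <- average_group(ws)
  # exclusion of an absent item leaves the plain mean
  expect_equal(average_group(ws, exclude_item = 99)$values, plain$values)
  # leave-one-out identity: loo_i = (k * mean - w_i) / (k - 1)
  for (i in c(1, 4, 6)) {
    loo <- average_group(ws, exclude_item = i)
    expect_equal(loo$values, (6 * plain$values - ws[[i]]$values) / 5,
                 tolerance = 1e-12)
  }
  # linearity in the inputs
  scaled <- lapply(ws, function(w) { w$values <- 3 * w$values; w })
  expect_equal(average_group(scaled)$values, 3 * plain$values,
               tolerance = 1e-12)
  # identical items are unchanged by exclusion
  same <- lapply(1:6, function(i) { w <- ws[[1]]; w$condition <- i; w })
  expect_equal(average_group(same, exclude_item = 3)$values, ws[[1]]$values)
  expect_error(average_group(ws[1], exclude_item = 1), "empties the group")
})

test_that("ROI averaging is an unweighted channel mean", {
  t_s <- seq(0, 100, by = 10)
  w <- erp_waveform(matrix(c(1, 2, 3), 3, length(t_s)),
                    c("F3", "Fz", "F4"), t_s, n_trials = 1)
  expect_equal(roi_average(w, c("F3", "Fz", "F4")),
               rep(2, length(t_s)), ignore_attr = TRUE)
  expect_equal(roi_average(w, "Fz"), rep(2, length(t_s)), ignore_attr = TRUE)
  expect_error(roi_average(w, c("Fz", "Pz")), "Pz")
})

test_that("peak-to-peak N200 subtracts the P200 peak from the N200 trough", {
  t_s <- seq(-200, 600, by = 2)
  expect_equal(n200_peak_to_peak(rep(0, length(t_s)), t_s), 0)
  tr <- numeric(length(t_s))
  tr[t_s == 180] <- 5                    # P200 peak
  tr[t_s == 300] <- -3                   # N200 trough
  expect_equal(n200_peak_to_peak(tr, t_s), -8)
  # offset invariance
  expect_equal(n200_peak_to_peak(tr + 11.3, t_s),
               n200_peak_to_peak(tr, t_s), tolerance = 1e-12)
  # overlapping windows force a non-positive value on any trace
  set.seed(3)
  for (k in 1:25)
    expect_lte(n200_peak_to_peak(rnorm(length(t_s)), t_s), 0)
  expect_error(n200_peak_to_peak(rep(0, 5), seq(0, 40, 10)), "outside")
})

test_that("window means use half-open intervals that partition time", {
  t_s <- seq(-200, 3000, by = 4)
  expect_equal(window_mean(rep(2.51, length(t_s)), t_s, c(400, 800)), 2.51)
  # linear ramp 0 -> 4 over 400-800: mean 2 up to one-sample discretization
  ramp <- pmax(0, pmin(4, (t_s - 400) / 100))
  expect_equal(window_mean(ramp, t_s, c(400, 800)), 2, tolerance = 0.05)
  # boxcar on 800-3000 only
  box <- ifelse(t_s >= 800, 3, 0)
  expect_equal(window_mean(box, t_s, c(400, 800)), 0)
  expect_equal(window_mean(box, t_s, c(2000, 3000)), 3)
  # half-open: consecutive windows never share samples
  i1 <- which(t_s >= 400 & t_s < 800)
  i2 <- which(t_s >= 800 & t_s < 1200)
  expect_length(intersect(i1, i2), 0)
  expect_error(window_mean(ramp, t_s, c(2800, 3300)), "outside")
})

test_that("measure_trace dispatches window labels and rejects unknown ones", {
  t_s <- seq(-200, 3000, by = 10)
  tr <- rep(1.5, length(t_s))
  for (m in c("400-800", "800-1200", "1200-1600", "1600-2000", "2000-3000",
              "n200_mean_200_400", "n200_mean_228_344"))
    expect_equal(measure_trace(tr, t_s, m), 1.5)
  expect_equal(measure_trace(tr, t_s, "n200"), 0)
  expect_error(measure_trace(tr, t_s, "bogus"), "unknown measure")
})
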