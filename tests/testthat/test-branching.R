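test_that("bout binning matches hand-computed counts and conserves mass", {
  spikes <- data.frame(unit = 1L, time = c(0.001, 0.010, 0.020))
  ser <- bin_bout(spikes, c(0, 0.048), 0.016, min_bins = 0)
  expect_equal(ser$counts, c(2L, 1L, 0L))
  # an empty bout gives an all-zero series
  empty <- bin_bout(data.frame(unit = integer(0), time = numeric(0)),
                    c(0, 0.048), 0.016, min_bins = 0)
  expect_equal(empty$counts, c(0L, 0L, 0L))
  # 60 s at 16 ms = 3750 complete bins
  expect_equal(length(bin_bout(spikes, c(0, 60), 0.016)$counts), 3750L)
  # mass conservation: all spikes inside complete bins are counted
  set.seed(39)
  times <- sort(runif(500, 0, 10))
  ser2 <- bin_bout(data.frame(unit = 1L, time = times), c(0, 10), 0.016)
  n_bins <- length(ser2$counts)
  expect_equal(sum(ser2$counts), sum(times < n_bins * 0.016))
  expect_error(bin_bout(spikes, c(0, 0.5), 0.016), "too short")
})

test_that("lag slopes agree with an explicit per-lag regression oracle", {
  ser <- simulate_branching(0.9, 1, 2e4, seed = 40)
  est <- mr_estimate(ser, k_max = 5)
  x <- as.numeric(ser$counts)
  for (k in 1:5) {
    n <- length(x)
    slope <- unname(coef(lm(x[(k + 1):n] ~ x[1:(n - k)]))[2])
    expect_equal(est$lag_slopes[k], slope, tolerance = 0.01)
  }
})

test_that("multistep regression recovers sigma and resists subsampling", {
  ser <- simulate_branching(0.95, 0.5, 1e5, seed = 41)
  est_full <- mr_estimate(ser)
  expect_true(est_full$accepted)
  expect_equal(est_full$sigma, 0.95, tolerance = 0.015)
  # 10% binomial subsampling: the naive lag-1 slope collapses but the
  # exponential-fit sigma does not
  sub <- simulate_branching(0.95, 0.5, 1e5, subsample_prob = 0.1, seed = 41)
  est_sub <- mr_estimate(sub)
  expect_equal(est_sub$sigma, 0.95, tolerance = 0.02)
  expect_lt(est_sub$lag_slopes[1], 0.8)
  # 5% vs 100% observation changes sigma by less than 0.02
  sub5 <- simulate_branching(0.95, 0.5, 1e5, subsample_prob = 0.05, seed = 41)
  expect_lt(abs(mr_estimate(sub5)$sigma - est_full$sigma), 0.02)
})

test_that("independent Poisson noise is rejected as structureless", {
  set.seed(42)
  ser <- simulate_branching(0, 5, 2e4, seed = 42)  # iid Poisson(5)
  est <- mr_estimate(ser)
  expect_true(all(abs(est$lag_slopes) < 0.05))
  # either the fit rejects outright or the screen rejects the flat structure
  scr <- stationarity_screen(ser, est)
  expect_false(scr$accepted)
})

test_that("the stationarity screen accepts stationary series and rejects drift", {
  ok <- simulate_branching(0.9, 1, 2e4, seed = 43)
  expect_true(stationarity_screen(ok)$accepted)
  drift <- simulate_branching(0.9, 1, 2e4, seed = 43,
                              nonstationarity = list(type = "drift", factor = 3))
  scr <- stationarity_screen(drift)
  expect_false(scr$accepted)
  expect_match(scr$reason, "drift")
  # fast two-state switching makes the lag slopes oscillate, which the
  # exponential-fit quality criterion catches
  updown <- simulate_branching(0.6, 1, 2e4, seed = 44,
                               nonstationarity = list(type = "updown",
                                                      period = 20,
                                                      low = 0.5, high = 20))
  scr_ud <- stationarity_screen(updown)
  expect_false(scr_ud$accepted)
  expect_match(scr_ud$reason, "inconsistent")
  expect_error(stationarity_screen(simulate_branching(0.5, 1, 150, seed = 1)),
               "too short")
})

test_that("per-subject summaries average accepted bouts per epoch", {
  set.seed(45)
  bouts <- data.frame(start = c(0, 300, 86400, 86700),
                      end = c(200, 500, 86600, 86900),
                      epoch = c("baseline", "baseline", "post_cond", "post_cond"))
  spk <- list()
  for (i in seq_len(nrow(bouts))) {
    sig <- if (bouts$epoch[i] == "baseline") 0.99 else 0.94
    ser <- simulate_branching(sig, 0.3, floor(200 / 0.016),
                              subsample_prob = 0.3)
    spk[[i]] <- spikes_from_counts(ser, 10, t_start = bouts$start[i])
  }
  ds <- spike_dataset(do.call(rbind, spk), bouts, "test_mouse", "CFC")
  ss <- subject_sigma(ds)
  expect_equal(nrow(ss$bouts), 4L)
  # near-critical bouts may legitimately trip the drift screen; the epochs
  # must still be covered by accepted bouts
  expect_gte(sum(ss$bouts$accepted), 3L)
  ep <- ss$epochs
  expect_false(any(ep$missing))
  base <- ep$mean_sigma[ep$epoch == "baseline"]
  post <- ep$mean_sigma[ep$epoch == "post_cond"]
  expect_equal(base, 0.99, tolerance = 0.03)
  expect_lt(abs((post - base) - (-0.05)), 0.035)
  # epoch means are the means of the accepted bout estimates
  expect_equal(base, mean(ss$bouts$sigma[ss$bouts$accepted &
                                           ss$bouts$epoch == "baseline"]))
})

test_that("the learning score is a percentage-point difference", {
  expect_equal(learning_score(60, 10), 50)
  expect_equal(learning_score(10, 10), 0)
  expect_equal(learning_score(5, 20), -15)
  expect_error(learning_score(120, 10), "0, 100")
})

test_that("group summaries report per-condition changes without filtering", {
  subj <- data.frame(
    subject = sprintf("m%d", 1:8),
    condition = c(rep("CFC", 5), rep("Sham", 3)),
    sigma_baseline = rep(1, 8),
    sigma_post = c(rep(1, 5) - 0.04 + c(-0.01, 0.01, 0, 0.005, -0.005),
                   rep(1, 3) - 0.005))
  gs <- group_change_summary(subj)
  expect_equal(gs$n, c(5L, 3L))
  expect_lt(gs$mean_delta[gs$condition == "CFC"], -0.03)
  expect_lt(gs$p_value[gs$condition == "CFC"], 0.05)
  # all-zero deltas: mean zero, no location test possible
  null <- group_change_summary(data.frame(
    subject = 1:4, condition = "CFC", sigma_baseline = 1, sigma_post = 1))
  expect_equal(null$mean_delta, 0)
  expect_false(isTRUE(null$p_value < 0.1))
  # an outlier is reflected, not removed
  out <- group_change_summary(data.frame(
    subject = 1:3, condition = "CFC", sigma_baseline = 1,
    sigma_post = c(0.95, 0.96, 1.2)))
  expect_gt(out$mean_delta, 0)
})
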