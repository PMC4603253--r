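test_that("rate histogram equals brute-force counting and conserves spikes", {
  # 50 neurons firing one spike each inside one bin -> 10 spikes/(neuron s)
  rec <- synth_record(as.list(seq(5000, 5099, length.out = 50)),
                      n_neurons = 50, duration = 10000)
  tr <- rate_histogram(rec, bin = 100)
  expect_equal(as.numeric(tr$rate[51, 1]), 10)
  expect_equal(sum(tr$rate[-51, 1]), 0)

  # random spikes against a naive per-bin loop
  set.seed(11)
  times <- sort(runif(2000, 0, 20000))
  rec <- spinalcpg:::spike_record_from_times(times, n_neurons = 20,
                                             duration = 20000)
  tr <- rate_histogram(rec, bin = 250)
  naive <- vapply(seq_len(80), function(b)
    sum(times >= (b - 1) * 250 & times < b * 250) / (20 * 0.25), numeric(1))
  expect_equal(unname(tr$rate[, 1]), naive)

  # conservation: sum over bins x size x bin-seconds = total spike count
  expect_equal(sum(tr$rate[, 1]) * 20 * 0.25, length(times))

  # no spikes -> all-zero trace
  empty <- spinalcpg:::spike_record_from_times(numeric(0), 5, 1000)
  expect_true(all(rate_histogram(empty, 100)$rate == 0))
})

test_that("burst detection recovers square waves and ignores tonic traces", {
  tr <- synth_square(n_bins = 600, period_bins = 20, duty_bins = 10)
  b <- detect_bursts(tr)
  expect_gt(nrow(b), 25)
  expect_equal(unique(diff(b$onset)), 2000)        # 0.5 Hz
  expect_true(all(b$peak == 20))
  # onsets at rising edges (multiples of 2 s)
  expect_true(all(b$onset %% 2000 == 0))

  expect_equal(nrow(detect_bursts(synth_trace(rep(15, 400)))), 0)
  expect_equal(nrow(detect_bursts(synth_trace(rep(0, 400)))), 0)
})

test_that("burst detection recovers noisy synthetic ground truth", {
  set.seed(42)
  n_bins <- 1200
  onsets_true <- seq(20, n_bins - 20, by = 25)     # bins
  x <- rep(0, n_bins)
  for (o in onsets_true) x[o:(o + 7)] <- 20 * exp(-(0:7) / 4)
  x <- pmax(0, x + rnorm(n_bins, 0, 0.8))
  b <- detect_bursts(synth_trace(x))
  hits <- vapply(onsets_true * 100 - 100, function(t0)
    any(abs(b$onset - t0) <= 100), logical(1))
  expect_gte(mean(hits), 0.95)
  expect_lte(nrow(b), length(onsets_true) + 2)
})

test_that("regime classification distinguishes silence, bursting, tonic", {
  zero <- synth_trace(rep(0, 200))
  expect_identical(classify_regime(zero, detect_bursts(zero)), "silence")
  sq <- synth_square(400, 20, 8)
  expect_identical(classify_regime(sq, detect_bursts(sq)), "bursting")
  tonic <- synth_trace(rep(12, 200))
  expect_identical(classify_regime(tonic, detect_bursts(tonic)), "tonic")
  short <- synth_trace(rep(0, 50))
  expect_error(classify_regime(short, detect_bursts(short)), "short")
})

test_that("frequency and amplitude series follow periodic bursts", {
  b <- synth_bursts(onset = seq(0, 58000, by = 2000),
                    offset = seq(600, 58600, by = 2000),
                    peak = rep(30, 30), duration = 60000)
  fa <- frequency_amplitude_series(b, window = 10000, duration = 60000)
  expect_true(all(abs(fa$frequency - 0.5) < 1e-12))
  expect_true(all(fa$amplitude == 30))
  # a window with fewer than two onsets is undefined
  sparse <- synth_bursts(onset = c(1000, 15000), offset = c(1500, 15500),
                         duration = 20000)
  fa <- frequency_amplitude_series(sparse, window = 10000, duration = 20000)
  expect_true(all(is.na(fa$frequency)))
})

test_that("phase relation labels synchrony, alternation, uncoordinated", {
  on <- seq(0, 40000, by = 2000)
  ref <- synth_bursts(on, on + 600)
  # identical series -> synchrony at phase 0
  same <- phase_relation(ref, ref)
  expect_identical(same$label, "synchrony")
  expect_lt(min(same$phase, 1 - same$phase), 0.05)
  # half-period shift -> alternation at phase 0.5
  shifted <- synth_bursts(on + 1000, on + 1600)
  alt <- phase_relation(ref, shifted)
  expect_identical(alt$label, "alternation")
  expect_equal(alt$phase, 0.5, tolerance = 0.02)
  expect_gt(alt$R, 0.95)
  # uniform-random onsets -> low concentration
  set.seed(7)
  rnd <- synth_bursts(sort(runif(40, 0, 40000)), sort(runif(40, 0, 40000)) + 100)
  unc <- phase_relation(ref, rnd)
  expect_identical(unc$label, "uncoordinated")
  expect_lt(unc$R, 0.7)
  expect_error(phase_relation(ref, synth_bursts(5000, 5400)),
               "insufficient")
})

test_that("phase labels are invariant to time shift and rescale", {
  on <- seq(0, 40000, by = 2000)
  ref <- synth_bursts(on, on + 600)
  oth <- synth_bursts(on + 1000, on + 1500)
  base <- phase_relation(ref, oth)
  for (f in list(function(x) x + 12345, function(x) x * 3.7)) {
    r2 <- phase_relation(synth_bursts(f(on), f(on + 600)),
                         synth_bursts(f(on + 1000), f(on + 1500)))
    expect_identical(r2$label, base$label)
    expect_equal(r2$phase, base$phase, tolerance = 0.01)
  }
})

test_that("midpoint phasing is robust to unequal duty cycles", {
  # flexor: short bursts; extensor: long bursts filling the gap
  on <- seq(0, 40000, by = 2000)
  flexor <- synth_bursts(on, on + 400)
  extensor <- synth_bursts(on + 500, on + 1900)
  by_onset <- phase_relation(flexor, extensor)
  by_mid <- phase_relation(flexor, extensor, event = "midpoint")
  expect_identical(by_mid$label, "alternation")
  expect_equal(by_mid$phase, 0.5, tolerance = 0.12)
  expect_false(by_onset$label == "alternation")  # onset sits at phase 0.25
})

test_that("deletion classification flags missed bursts and their context", {
  period <- 1000
  on <- seq(0, 30000, by = period)
  # two consecutive bursts deleted at 15 s and 16 s; rhythm resumes on grid
  kept <- on[!(on %in% c(15000, 16000))]
  target <- synth_bursts(kept, kept + 300, duration = 31000)
  contra <- synth_bursts(on + 500, on + 800, duration = 31000)
  # antagonist: bursts in anti-phase normally, sustained during the deletion
  x <- rep(2, 310)
  for (o in kept) x[(o / 100 + 4):(o / 100 + 9)] <- 18
  x[150:170] <- 18
  atr <- synth_trace(x)
  rep_ <- classify_deletions(target, atr, "pop", contra, fit_end = 14500)
  expect_equal(nrow(rep_), 2)
  expect_equal(rep_$expected_onset, c(15000, 16000), tolerance = 1e-6)
  expect_true(all(rep_$antagonist == "sustained"))
  expect_true(all(rep_$contralateral_deviation < 0.05, na.rm = TRUE))
  expect_false(any(rep_$resetting))

  # resetting variant: post-deletion grid shifted by 0.4 cycle
  shifted <- c(on[on < 15000], seq(17400, 30400, by = period))
  target2 <- synth_bursts(shifted, shifted + 300, duration = 31000)
  rep2 <- classify_deletions(target2, atr, "pop", contra, fit_end = 14500)
  expect_gt(nrow(rep2), 0)
  expect_true(all(rep2$resetting))

  # unperturbed series -> no deletions
  clean <- synth_bursts(on, on + 300, duration = 31000)
  rep3 <- classify_deletions(clean, atr, "pop", contra, fit_end = 14500)
  expect_equal(nrow(rep3), 0)

  # unstable pre-perturbation rhythm is refused
  set.seed(3)
  jit <- cumsum(runif(20, 200, 1800))
  noisy <- synth_bursts(jit, jit + 100, duration = 31000)
  expect_error(classify_deletions(noisy, atr, "pop", contra,
                                  fit_end = max(jit) + 1), "CV")
})

test_that("phase-duration slopes separate flexor and extensor phases", {
  # constructed: flexor duration constant, extensor = period - constant
  set.seed(2)
  periods <- seq(1000, 2600, length.out = 20)
  on <- cumsum(c(0, periods))
  flexor <- synth_bursts(on, on + 400, duration = max(on) + 3000)
  fit <- phase_duration_slopes(flexor)
  expect_equal(fit$flexor_slope, 0, tolerance = 1e-9)
  expect_equal(fit$extensor_slope, 1, tolerance = 1e-9)
  expect_equal(fit$n_cycles, 20)

  # least squares agrees with explicit normal equations
  durs <- 400 + 0.2 * (periods - 1000) + rnorm(20, 0, 10)
  off <- on[seq_len(20)] + durs
  fx <- synth_bursts(on[seq_len(21)], c(off, on[21] + 400),
                     duration = max(on) + 3000)
  fit <- phase_duration_slopes(fx)
  X <- cbind(1, periods)
  beta <- solve(t(X) %*% X, t(X) %*% durs)
  expect_equal(fit$flexor_slope, beta[2], tolerance = 1e-9)

  expect_error(phase_duration_slopes(synth_bursts(on[1:5], on[1:5] + 400)),
               "cycles")
  const <- seq(0, 20000, by = 1000)
  expect_error(phase_duration_slopes(synth_bursts(const, const + 300)),
               "period range")
})

test_that("single interior peak detection is selective", {
  expect_true(single_interior_peak(c(1, 3, 6, 9, 7, 5, 4, 3, 2)))
  expect_false(single_interior_peak(c(9, 8, 7, 6, 5, 4, 3, 2, 1)))
  expect_false(single_interior_peak(c(1, 2, 3, 4, 5, 6, 7, 8, 9)))
})
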