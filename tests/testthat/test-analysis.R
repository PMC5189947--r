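test_that("firing rates rectify membrane potentials", {
  expect_equal(firing_rates(0.5), 0.5)
  expect_equal(firing_rates(-0.3), 0)
  m <- matrix(c(-1, 2, 0, -0.5), 2)
  expect_equal(firing_rates(m), matrix(c(0, 2, 0, 0), 2))
  # zero-mean symmetric ensemble: mean rate is half the mean absolute value
  set.seed(1)
  u <- rnorm(1e5)
  expect_equal(mean(firing_rates(u)), mean(abs(u)) / 2, tolerance = 0.02)
})

test_that("the LFP is the population-average membrane potential", {
  u <- matrix(rnorm(50), 10, 5)
  expect_equal(lfp(u), rowMeans(u))
  expect_equal(lfp(u[, 1, drop = FALSE]), u[, 1])
  expect_equal(lfp(u + 2), lfp(u) + 2)
})

test_that("autocorrelation matches closed forms on reference signals", {
  set.seed(2)
  white <- rnorm(2e4)
  a <- autocorrelation(white, 50)
  expect_equal(a$acf[1], 1)
  expect_lt(max(abs(a$acf[-1])), 0.05)
  # pure sinusoid: cosine autocorrelation at the same period, shrunk by the
  # (1 - lag/n) taper of the biased estimator
  t <- seq(0, 20, by = 0.01)
  s <- sin(2 * pi * t / 2.5)
  a <- autocorrelation(s, 500)
  cosine <- (1 - a$lags / length(s)) * cos(2 * pi * a$lags * 0.01 / 2.5)
  expect_lt(max(abs(a$acf - cosine)), 0.03)
  expect_error(autocorrelation(rep(1, 100), 10), "zero-variance")
})

test_that("the Welch spectrum locates a known tone", {
  set.seed(3)
  fs <- 2000
  t <- seq(0, 10, by = 1 / fs)
  y <- sin(2 * pi * 40 * t) + 0.2 * rnorm(length(t))
  ps <- power_spectrum(y, fs)
  expect_equal(ps$peak_freq, 40, tolerance = 0.06)
  expect_true(all(diff(ps$freqs) > 0))
  expect_error(power_spectrum(y[1:100], fs), "insufficient")
})

test_that("the Gaussian-window spectrogram tracks a frequency step", {
  fs <- 2000
  t1 <- seq(0, 2, by = 1 / fs)
  t2 <- seq(0, 2, by = 1 / fs)
  y <- c(sin(2 * pi * 30 * t1), sin(2 * pi * 80 * t2))
  sg <- spectrogram(y, fs, window_sd = 0.1)
  early <- colMeans(sg$power[sg$times < 1.5, ])
  late <- colMeans(sg$power[sg$times > 2.5, ])
  expect_equal(sg$freqs[which.max(early)], 30, tolerance = 0.1)
  expect_equal(sg$freqs[which.max(late)], 80, tolerance = 0.05)
})

test_that("unit normalised MSE is crossed where the curve says it is", {
  curve <- structure(
    list(times = c(0.01, 0.02, 0.03, 0.04), mse_mean = c(9, 3, 0.8, 0.4),
         mse_sem = rep(0.1, 4), n_reps = 10, mode = "hamiltonian",
         z_gen = 1),
    class = "convergence_curve")
  expect_equal(time_to_unit_mse(curve), 0.03)
  curve$mse_mean <- c(9, 7, 5, 4)
  expect_warning(expect_true(is.na(time_to_unit_mse(curve))), "not reached")
})

test_that("oscillatory sampling converges faster than gradient ascent", {
  net <- small_net()
  stim <- sample_stimulus(net$gsm, 1, seed = 40)
  ham <- convergence_curve(net, mode = "hamiltonian", n_reps = 12,
                           t_post = 1.5, t_pre = 0.5, seed = 1,
                           stimulus = stim)
  lan <- convergence_curve(net, mode = "langevin", n_reps = 12,
                           t_post = 1.5, t_pre = 0.5, seed = 1,
                           stimulus = stim)
  t_ham <- time_to_unit_mse(ham)
  t_lan <- time_to_unit_mse(lan)
  expect_false(is.na(t_ham))
  expect_false(is.na(t_lan))
  expect_lt(t_ham, t_lan)
  expect_true(all(ham$mse_sem >= 0))
})

test_that("the standard error band shrinks with the number of repetitions", {
  net <- small_net()
  stim <- sample_stimulus(net$gsm, 1, seed = 41)
  c8 <- convergence_curve(net, mode = "langevin", n_reps = 8, t_post = 0.4,
                          t_pre = 0.3, seed = 2, stimulus = stim)
  c32 <- convergence_curve(net, mode = "langevin", n_reps = 32, t_post = 0.4,
                           t_pre = 0.3, seed = 2, stimulus = stim)
  ratio <- mean(c8$mse_sem) / mean(c32$mse_sem)
  expect_gt(ratio, 1.3) # expected 2 with sampling noise
  expect_lt(ratio, 3.1)
})

test_that("oscillatory spectral mass separates the two samplers", {
  net <- small_net()
  stim <- sample_stimulus(net$gsm, 1, seed = 42)
  mass_above <- function(mode) {
    traj <- simulate(net, protocol = simulation_protocol(
      t_pre = 0.5, t_post = 3, z_gen = 1, mode = mode,
      z_fixed = if (mode == "langevin") 1 else NULL, seed = 3),
      stimulus = stim)
    y <- traj$u[traj$times > 0, 1]
    ps <- power_spectrum(y - mean(y), fs = traj$fs)
    sum(ps$power[ps$freqs > 20]) / sum(ps$power)
  }
  expect_gt(mass_above("hamiltonian"), 1.5 * mass_above("langevin"))
})

test_that("energy fluctuates only on the slow stochastic timescale", {
  # the u-trace oscillates in the gamma band; the joint log-density does not
  net <- small_net()
  traj <- simulate(net, protocol = simulation_protocol(
    t_pre = 0.5, t_post = 3, z_gen = 1, mode = "hamiltonian_fixed_z",
    seed = 4, thin = 10L))
  keep <- traj$times > 0
  u <- traj$u[keep, ]
  v <- traj$v[keep, ]
  x <- traj$stimulus$x
  energy <- vapply(seq_len(nrow(u)), function(i) {
    log_joint(net, u[i, ], v[i, ], 1, x)
  }, numeric(1))
  # an oscillatory series dips deeply negative within the first cycles; the
  # energy autocorrelation decays without ringing
  max_lag <- round(0.05 * traj$fs)
  expect_lt(min(autocorrelation(u[, 1], max_lag)$acf), -0.3)
  expect_gt(min(autocorrelation(energy, max_lag)$acf), -0.1)
})

test_that("balance metrics demand an inhibitory population", {
  net <- small_net()
  traj <- simulate(net, protocol = simulation_protocol(
    t_pre = 0.1, t_post = 0.2, z_gen = 1, mode = "langevin", seed = 5))
  expect_error(ei_balance(traj, net), "Langevin")
})

test_that("excitation and inhibition are balanced on average, imbalanced momentarily", {
  net <- default_net()
  bal <- ei_balance(balance_traj(), net)
  slope <- eisampler:::tls_slope(bal$trial_mean_pairs[, 1],
                                 bal$trial_mean_pairs[, 2])
  expect_gt(slope, 0.8)
  expect_lt(slope, 1.2)
  expect_gt(bal$peak_lag, 0) # inhibition lags excitation
  expect_lt(bal$peak_lag, 0.01)
  expect_gt(bal$peak_corr, 0.8)
  expect_gt(var(as.vector(bal$exc_current_t - bal$inh_current_t)), 0)
  expect_true(all(abs(bal$xcorr) <= 1 + 1e-12))
})

test_that("transient metrics quantify a constructed rate bump", {
  fs <- 1000
  pre <- rep(1, 500)
  t_post <- seq(1, 700) / fs
  steady <- 0.5
  bump <- steady + 1.5 * exp(-(t_post - 0.03)^2 / (2 * 0.01^2))
  tm <- transient_metrics(c(pre, bump), onset_index = 500, fs = fs)
  expect_true(tm$transient_present)
  expect_equal(tm$baseline_rate, 1, tolerance = 1e-2)
  expect_equal(tm$steady_rate, 0.5, tolerance = 0.01)
  expect_equal(tm$peak_rate, 2, tolerance = 0.02)
  expect_equal(tm$time_to_peak, 0.03, tolerance = 0.005)
  expect_equal(tm$excursion_duration, 0.03 + 0.0215, tolerance = 0.2)
  # monotone relaxation from a high baseline: no transient
  relax <- c(rep(2, 500), 0.5 + 1.5 * exp(-t_post / 0.05))
  tm2 <- transient_metrics(relax, onset_index = 500, fs = fs)
  expect_false(tm2$transient_present)
  expect_true(is.na(tm2$excursion_duration))
})
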