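#' Firing rates from membrane potentials
#'
#' Rectified-linear transform: rates equal membrane potentials where
#' positive and zero elsewhere.
#'
#' @param u Numeric vector or matrix of membrane potentials.
#' @return Object of the same shape.
#' @export
firing_rates <- function(u) {
  pmax(u, 0)
}

#' Local field potential of a trajectory
#'
#' The LFP proxy is the average excitatory membrane potential across cells at
#' each recorded time (averaging and summing differ only by a constant
#' factor).
#'
#' @param trajectory An \code{"ei_trajectory"}, or a time x cells matrix.
#' @return Numeric time series.
#' @export
lfp <- function(trajectory) {
  u <- if (inherits(trajectory, "ei_trajectory")) trajectory$u else
    as.matrix(trajectory)
  stopifnot(ncol(u) >= 1)
  rowMeans(u)
}

#' Empirical autocorrelation of a time series
#'
#' Mean-subtracted, variance-normalised autocorrelation with
#' \code{acf[lag 0] = 1}.
#'
#' @param series Numeric time series.
#' @param max_lag Maximum lag in samples; must be below the series length.
#' @return List with \code{lags} (samples) and \code{acf}.
#' @export
autocorrelation <- function(series, max_lag) {
  stopifnot(length(series) > max_lag, max_lag >= 1)
  if (stats::var(series) == 0) {
    stop("autocorrelation undefined for a zero-variance series")
  }
  a <- stats::acf(series, lag.max = max_lag, plot = FALSE,
                  demean = TRUE)$acf[, 1, 1]
  list(lags = 0:max_lag, acf = as.numeric(a))
}

#' Welch power spectrum of an LFP series
#'
#' Averaged periodogram over Hann-tapered, mean-subtracted segments
#' (500 ms, 50% overlap by default). Returns both the power spectral density
#' and power multiplied by frequency, the quantity plotted to compensate the
#' 1/f trend of scale-free background fluctuations; the peak frequency is the
#' argmax of power x frequency above a 5 Hz floor.
#'
#' @param series Numeric time series (a stationary post-onset segment).
#' @param fs Sampling rate (Hz).
#' @param segment Segment length (seconds).
#' @param overlap Fractional overlap between segments.
#' @param floor_hz Lower frequency bound for the peak search.
#' @return Object of class \code{"spectral_result"}: list with \code{freqs},
#'   \code{power}, \code{power_times_freq}, \code{peak_freq}, \code{fs}.
#' @export
power_spectrum <- function(series, fs, segment = 0.5, overlap = 0.5,
                           floor_hz = 5) {
  L <- round(segment * fs)
  if (length(series) < 2 * L * (1 - overlap) + L) {
    stop("insufficient data: need at least two spectral segments")
  }
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, L - 1) / (L - 1)) # Hann taper
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(series) - L + 1L, by = step)
  P <- numeric(L)
  for (s0 in starts) {
    seg <- series[s0:(s0 + L - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- P + abs(stats::fft(seg))^2
  }
  P <- P / (length(starts) * fs * sum(w^2))
  freqs <- (seq_len(L) - 1) * fs / L
  keep <- freqs <= fs / 2
  freqs <- freqs[keep]
  P <- P[keep]
  pxf <- P * freqs
  band <- freqs > floor_hz
  structure(
    list(
      freqs = freqs, power = P, power_times_freq = pxf,
      peak_freq = freqs[band][which.max(pxf[band])], fs = fs
    ),
    class = "spectral_result"
  )
}

#' @export
print.spectral_result <- function(x, ...) {
  cat(sprintf(
    "Welch spectrum: %d bins up to %.4g Hz, peak (power x f) at %.4g Hz\n",
    length(x$freqs), max(x$freqs), x$peak_freq
  ))
  invisible(x)
}

#' @export
plot.spectral_result <- function(x, xlim = c(0, 150), ...) {
  keep <- x$freqs >= xlim[1] & x$freqs <= xlim[2]
  graphics::plot(x$freqs[keep], x$power_times_freq[keep], type = "l",
                 xlab = "frequency (Hz)", ylab = "power x frequency", ...)
  graphics::abline(v = x$peak_freq, lty = 3)
  invisible(x)
}

#' Gaussian-window spectrogram
#'
#' Short-time Fourier transform with a Gaussian taper (standard deviation
#' \code{window_sd}, truncated at three standard deviations), hopped across
#' the series.
#'
#' @param series Numeric time series.
#' @param fs Sampling rate (Hz).
#' @param window_sd Gaussian window standard deviation (seconds).
#' @param hop Hop between window centres (seconds).
#' @return List with \code{times} (window centres, s), \code{freqs} (Hz) and
#'   \code{power} (time x frequency matrix).
#' @export
spectrogram <- function(series, fs, window_sd = 0.1, hop = 0.025) {
  half <- round(3 * window_sd * fs)
  L <- 2L * half + 1L
  if (length(series) < L) stop("insufficient data: series shorter than window")
  w <- exp(-((seq_len(L) - 1 - half) / (window_sd * fs))^2 / 2)
  centres <- seq(half + 1L, length(series) - half, by = max(1L, round(hop * fs)))
  freqs <- (seq_len(L) - 1) * fs / L
  keep <- freqs <= fs / 2
  P <- matrix(NA_real_, length(centres), sum(keep))
  for (i in seq_along(centres)) {
    seg <- series[(centres[i] - half):(centres[i] + half)]
    seg <- (seg - mean(seg)) * w
    P[i, ] <- (abs(stats::fft(seg))^2 / (fs * sum(w^2)))[keep]
  }
  list(times = (centres - 1) / fs, freqs = freqs[keep], power = P)
}

#' Trial-averaged LFP power spectrum of the full network
#'
#' Simulates several independent trials (fresh stimulus and fresh noise per
#' trial) at one generative contrast, computes the Welch spectrum of the
#' post-onset LFP in each, and averages the power across trials before
#' locating the peak. Averaging over stimulus draws matters: the inferred
#' contrast of a single trial tracks the realised strength of that
#' particular image patch, so single-trial peaks scatter around the
#' harmonic-law prediction at the generative contrast.
#'
#' @param net An [ei_network()].
#' @param z_gen Generative contrast.
#' @param n_trials Number of independent trials averaged. Single-trial peak
#'   estimates scatter widely (the gamma bump is weak relative to the slow
#'   stochastic component in some draws); eight trials keep the averaged peak
#'   stable to within a few hertz.
#' @param t_post Post-onset duration per trial (seconds).
#' @param seed Master seed; each trial derives its own stimulus and noise.
#' @param mode Sampler variant passed to the protocol.
#' @return A \code{"spectral_result"} (trial-averaged), with the per-trial
#'   peak frequencies attached as \code{$trial_peaks}.
#' @export
lfp_spectrum <- function(net, z_gen, n_trials = 8, t_post = 3, seed = 1L,
                         mode = "hamiltonian") {
  stopifnot(inherits(net, "ei_network"), n_trials >= 1)
  acc <- NULL
  trial_peaks <- numeric(n_trials)
  for (k in seq_len(n_trials)) {
    traj <- simulate(net, protocol = simulation_protocol(
      t_pre = 1, t_post = t_post, z_gen = z_gen, mode = mode,
      seed = derive_seed(seed, 600L + k)))
    ps <- power_spectrum(lfp(traj)[traj$times > 0], fs = traj$fs)
    trial_peaks[k] <- ps$peak_freq
    acc <- if (is.null(acc)) ps else {
      acc$power <- acc$power + ps$power
      acc
    }
  }
  acc$power <- acc$power / n_trials
  acc$power_times_freq <- acc$power * acc$freqs
  band <- acc$freqs > 5
  acc$peak_freq <- acc$freqs[band][which.max(acc$power_times_freq[band])]
  acc$trial_peaks <- trial_peaks
  acc
}

#' Sampling-efficiency convergence curve
#'
#' Measures how quickly the running time-average of the excitatory potentials
#' after stimulus onset approaches the posterior mean. For each repetition
#' the normalised mean square error at time t is the squared error of the
#' running mean, per dimension divided by the posterior variance at the
#' generative contrast, averaged over dimensions; one statistically fair
#' posterior sample scores 1 in this normalisation. Repetitions share the
#' stimulus and differ in their noise streams.
#'
#' The Hamiltonian mode runs the full network (contrast inferred jointly);
#' the Langevin mode runs the u-only gradient sampler at the generative
#' contrast, the control with matched noise and the recurrent weights
#' removed.
#'
#' @param net An [ei_network()].
#' @param z_gen Generative contrast of the stimulus.
#' @param mode \code{"hamiltonian"} or \code{"langevin"}.
#' @param n_reps Number of repetitions (at least 2).
#' @param t_post Post-onset duration covered by the curve (seconds).
#' @param t_pre Equilibration time (seconds).
#' @param dt Integration step (seconds).
#' @param seed Master seed.
#' @param stimulus Optional fixed [sample_stimulus()].
#' @return Object of class \code{"convergence_curve"}: list with
#'   \code{times}, \code{mse_mean}, \code{mse_sem}, \code{n_reps},
#'   \code{mode}, \code{z_gen}.
#' @export
convergence_curve <- function(net, z_gen = 1,
                              mode = c("hamiltonian", "langevin"),
                              n_reps = 100, t_post = 2, t_pre = 1,
                              dt = 5e-5, seed = 1L, stimulus = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "ei_network"), n_reps >= 2)
  protocol <- simulation_protocol(
    t_pre = t_pre, t_post = t_post, z_gen = z_gen, dt = dt, mode = mode,
    z_fixed = if (mode == "langevin") z_gen else NULL, seed = seed
  )
  if (is.null(stimulus)) {
    stimulus <- sample_stimulus(net$gsm, z_gen,
                                seed = derive_seed(protocol$seed, 2L))
  }
  post <- posterior_u(net$gsm, stimulus$x, z_gen)
  res <- run_engine(net, protocol, stimulus = stimulus, n_reps = n_reps,
                    record = "convergence", posterior = post)
  structure(
    list(
      times = res$times,
      mse_mean = rowMeans(res$mse),
      mse_sem = apply(res$mse, 1, stats::sd) / sqrt(n_reps),
      n_reps = n_reps, mode = mode, z_gen = z_gen
    ),
    class = "convergence_curve"
  )
}

#' @export
print.convergence_curve <- function(x, ...) {
  t1 <- time_to_unit_mse(x)
  cat(sprintf(
    "Convergence curve (%s, z_gen = %.3g, %d repetitions)\n",
    x$mode, x$z_gen, x$n_reps
  ))
  if (is.na(t1)) {
    cat(sprintf(
      "  single-fair-sample level not reached; final MSE %.3g at %.3g s\n",
      x$mse_mean[length(x$mse_mean)], x$times[length(x$times)]
    ))
  } else {
    cat(sprintf("  reaches the single-fair-sample level at %.1f ms\n",
                1000 * t1))
  }
  invisible(x)
}

#' @export
plot.convergence_curve <- function(x, ...) {
  graphics::plot(x$times, x$mse_mean, type = "l", log = "y",
                 xlab = "time from onset (s)", ylab = "normalised MSE", ...)
  graphics::lines(x$times, x$mse_mean + 2 * x$mse_sem, lty = 2)
  graphics::lines(x$times, pmax(x$mse_mean - 2 * x$mse_sem,
                                .Machine$double.eps), lty = 2)
  graphics::abline(h = 1, lty = 3)
  invisible(x)
}

#' Time for the mean convergence curve to reach the single-sample level
#'
#' First time at which the repetition-averaged normalised MSE drops to 1,
#' the error level of a single statistically fair posterior sample.
#'
#' @param curve A [convergence_curve()].
#' @return Time in seconds, or \code{NA} (with a warning reporting the final
#'   value) if the level is not reached within the simulated window.
#' @export
time_to_unit_mse <- function(curve) {
  stopifnot(inherits(curve, "convergence_curve"))
  i <- which(curve$mse_mean <= 1)[1]
  if (is.na(i)) {
    warning(sprintf(
      "unit normalised MSE not reached; final value %.3g at %.3g s",
      curve$mse_mean[length(curve$mse_mean)],
      curve$times[length(curve$times)]
    ))
    return(NA_real_)
  }
  curve$times[i]
}

#' Excitation-inhibition balance metrics
#'
#' Quantifies how the recurrent inhibitory current tracks the recurrent
#' excitatory current in a Hamiltonian-mode trajectory. Per excitatory cell
#' the recurrent excitatory current is \code{W_uu u} and the inhibitory
#' current \code{W_uv v}; their trial means form the per-cell balance
#' scatter. The cross-correlation between the population-average excitatory
#' and inhibitory membrane potentials locates the lag of inhibition: the
#' reported \code{peak_lag} is positive when inhibition lags excitation.
#'
#' @param trajectory An \code{"ei_trajectory"} from the Hamiltonian (or
#'   fixed-z Hamiltonian) mode.
#' @param net The [ei_network()] that generated it.
#' @param max_lag Maximum cross-correlation lag (seconds).
#' @param after_onset Use only the post-onset epoch (default \code{TRUE}).
#' @return Object of class \code{"ei_balance"}: list with
#'   \code{exc_current_t}, \code{inh_current_t}, \code{trial_mean_pairs}
#'   (cells x 2), \code{xcorr_lags} (s), \code{xcorr}, \code{peak_lag} (s),
#'   \code{peak_corr}.
#' @export
ei_balance <- function(trajectory, net, max_lag = 0.05, after_onset = TRUE) {
  stopifnot(inherits(trajectory, "ei_trajectory"), inherits(net, "ei_network"))
  if (trajectory$protocol$mode == "langevin") {
    stop("balance metrics need an inhibitory population; ",
         "Langevin-mode trajectories have none")
  }
  keep <- if (after_onset) trajectory$times > 0 else
    rep(TRUE, length(trajectory$times))
  u <- trajectory$u[keep, , drop = FALSE]
  v <- trajectory$v[keep, , drop = FALSE]
  exc <- u %*% t(net$W_uu)
  inh <- v %*% t(net$W_uv)
  ue <- rowMeans(u)
  vi <- rowMeans(v)
  lag_max <- round(max_lag * trajectory$fs)
  cc <- stats::ccf(ue, vi, lag.max = lag_max, plot = FALSE)
  lags <- -as.numeric(cc$lag) / trajectory$fs # positive: inhibition lags
  r <- as.numeric(cc$acf)
  ord <- order(lags)
  lags <- lags[ord]
  r <- r[ord]
  structure(
    list(
      exc_current_t = exc, inh_current_t = inh,
      trial_mean_pairs = cbind(E = colMeans(exc), I = colMeans(inh)),
      xcorr_lags = lags, xcorr = r,
      peak_lag = lags[which.max(r)], peak_corr = max(r)
    ),
    class = "ei_balance"
  )
}

#' @export
print.ei_balance <- function(x, ...) {
  cat("Excitation-inhibition balance\n")
  cat(sprintf(
    "  peak cross-correlation %.3f at lag %.2f ms (positive: inhibition lags)\n",
    x$peak_corr, 1000 * x$peak_lag
  ))
  fit <- tls_slope(x$trial_mean_pairs[, 1], x$trial_mean_pairs[, 2])
  cat(sprintf("  per-cell mean E vs I: total-least-squares slope %.3f\n", fit))
  invisible(x)
}

#' @export
plot.ei_balance <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$trial_mean_pairs, xlab = "mean excitatory current",
                 ylab = "mean inhibitory current", ...)
  graphics::abline(0, 1, lty = 3)
  graphics::plot(1000 * x$xcorr_lags, x$xcorr, type = "l",
                 xlab = "lag (ms), positive: inhibition lags",
                 ylab = "cross-correlation")
  graphics::abline(v = 1000 * x$peak_lag, lty = 3)
  invisible(x)
}

# Total-least-squares (orthogonal regression) slope through the centroid.
tls_slope <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  v <- eigen(stats::cov(cbind(xc, yc)), symmetric = TRUE)$vectors[, 1]
  v[2] / v[1]
}

#' Stimulus-onset transient metrics of a population rate curve
#'
#' Quantifies the firing-rate transient at stimulus onset. Baseline is the
#' mean rate over the second half of the pre-onset epoch; the steady-state
#' rate is the mean over the final quarter of the post-onset epoch; the peak
#' is the maximum of the (5 ms boxcar smoothed) rate within the first 150 ms
#' after onset. The transient overshoot is the peak in excess of both the
#' baseline and the steady state, so a rate that merely relaxes
#' monotonically from one level to the other shows no transient; the
#' transient-present flag additionally requires the overshoot to exceed 10%
#' of the larger of the steady and baseline rates, so that fluctuations of
#' the rate estimate are not reported as transients.
#' The excursion duration runs from onset until the smoothed rate first falls
#' back to within 10% of the overshoot above the steady state.
#'
#' @param rates Population-mean firing rate per time step (full epoch,
#'   pre and post onset).
#' @param onset_index Index of the last pre-onset sample.
#' @param fs Sampling rate of \code{rates} (Hz).
#' @param peak_window Window after onset searched for the peak (seconds).
#' @param smooth Boxcar width for smoothing (seconds).
#' @return Object of class \code{"transient_metrics"}: list with
#'   \code{baseline_rate}, \code{peak_rate}, \code{steady_rate},
#'   \code{overshoot}, \code{time_to_peak} (s), \code{excursion_duration}
#'   (s), \code{transient_present}.
#' @export
transient_metrics <- function(rates, onset_index, fs, peak_window = 0.150,
                              smooth = 0.005) {
  stopifnot(onset_index >= 2, onset_index < length(rates), fs > 0)
  k <- max(1L, round(smooth * fs))
  sm <- stats::filter(rates, rep(1 / k, k), sides = 2)
  sm[is.na(sm)] <- rates[is.na(sm)]
  sm <- as.numeric(sm)
  pre <- sm[ceiling(onset_index / 2):onset_index]
  post <- sm[(onset_index + 1L):length(sm)]
  baseline <- mean(pre)
  steady <- mean(post[floor(0.75 * length(post)):length(post)])
  win <- seq_len(min(length(post), round(peak_window * fs)))
  peak <- max(post[win])
  t_peak <- which.max(post[win]) / fs
  overshoot <- peak - max(baseline, steady)
  present <- overshoot > 0.1 * max(steady, baseline, .Machine$double.eps)
  if (present) {
    level <- steady + 0.1 * (peak - steady)
    below <- which(post < level & seq_along(post) / fs >= t_peak)[1]
    excursion <- if (is.na(below)) NA_real_ else below / fs
  } else {
    excursion <- NA_real_
  }
  structure(
    list(
      baseline_rate = baseline, peak_rate = peak, steady_rate = steady,
      overshoot = overshoot, time_to_peak = t_peak,
      excursion_duration = excursion, transient_present = present
    ),
    class = "transient_metrics"
  )
}

#' @export
print.transient_metrics <- function(x, ...) {
  cat("Stimulus-onset transient\n")
  cat(sprintf(
    "  baseline %.3g, peak %.3g, steady %.3g (rate units)\n",
    x$baseline_rate, x$peak_rate, x$steady_rate
  ))
  if (x$transient_present) {
    cat(sprintf(
      "  overshoot %.3g, peak at %.1f ms, excursion %.1f ms\n",
      x$overshoot, 1000 * x$time_to_peak,
      1000 * x$excursion_duration
    ))
  } else {
    cat("  no transient (rate relaxes monotonically between levels)\n")
  }
  invisible(x)
}

#' Repetition-averaged population rate around stimulus onset
#'
#' Runs \code{n_reps} noise-independent repetitions of a protocol (shared
#' stimulus) and returns the across-repetition average of the population-mean
#' firing rate at every integration step, the input expected by
#' [transient_metrics()].
#'
#' @param net An [ei_network()].
#' @param protocol A [simulation_protocol()].
#' @param n_reps Number of repetitions.
#' @param stimulus Optional fixed stimulus.
#' @return List with \code{times}, \code{rates} (averaged), \code{rate_sem},
#'   \code{z_mean}, \code{onset_index}, \code{fs}.
#' @export
population_rate_curve <- function(net, protocol, n_reps = 8, stimulus = NULL) {
  res <- run_engine(net, protocol, stimulus = stimulus, n_reps = n_reps,
                    record = "rates")
  list(
    times = res$times,
    rates = rowMeans(res$rates),
    rate_sem = apply(res$rates, 1, stats::sd) / sqrt(ncol(res$rates)),
    z_mean = res$z_mean,
    onset_index = res$onset_index,
    fs = res$fs
  )
}
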