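#' Run a figure-level experiment
#'
#' Orchestrates the standard simulation experiments end to end and writes
#' their metric tables (CSV), a machine-readable JSON summary, and optionally
#' PNG figures into \code{out_dir}. Every summary records the master seed and
#' the parameters used, and rerunning with the same configuration reproduces
#' all numbers bit-identically.
#'
#' Experiments:
#' \describe{
#'   \item{\code{efficiency}}{Convergence of the running-mean posterior
#'     estimate for the Hamiltonian network and the Langevin control;
#'     reports \code{time_to_unit_mse} per mode and their ratio.}
#'   \item{\code{oscillations}}{LFP spectra at the requested contrasts;
#'     reports the simulated peak frequencies against the harmonic
#'     prediction.}
#'   \item{\code{balance}}{Excitation-inhibition tracking: per-cell mean
#'     currents and the population cross-correlation lag.}
#'   \item{\code{transients}}{Repetition-averaged population-rate transients
#'     for the full, Langevin and fixed-contrast dynamics at each contrast.}
#'   \item{\code{rho_sweep}}{Robustness of the oscillation and transient
#'     signatures across the noise time constant tau_L.}
#' }
#'
#' @param experiment One of \code{"efficiency"}, \code{"oscillations"},
#'   \code{"balance"}, \code{"transients"}, \code{"rho_sweep"}.
#' @param out_dir Output directory (created if needed).
#' @param net An [ei_network()]; the default operating point if omitted.
#' @param z_gen_list Contrast levels for the contrast-resolved experiments.
#' @param n_reps Number of repetitions where repetitions apply.
#' @param t_post Post-onset duration per run (seconds).
#' @param seed Master seed.
#' @param tau_L_list tau_L values (seconds) for \code{rho_sweep}.
#' @param make_figures Also write PNG figures.
#' @return The summary list, invisibly; side effect: files in \code{out_dir}.
#' @export
run_experiment <- function(experiment = c("efficiency", "oscillations",
                                          "balance", "transients",
                                          "rho_sweep"),
                           out_dir = tempfile("eisampler-"),
                           net = NULL,
                           z_gen_list = c(0.5, 1, 2),
                           n_reps = NULL,
                           t_post = NULL,
                           seed = 1L,
                           tau_L_list = c(0.060, 0.150, 0.400),
                           make_figures = FALSE) {
  experiment <- match.arg(experiment)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(net)) net <- default_network()
  summary <- list(experiment = experiment, seed = seed,
                  tau_ms = 1000 * net$tau, tau_L_ms = 1000 * net$tau_L,
                  sigma_x_sq = net$gsm$sigma_x_sq)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage '%s': %s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILURE"))
      stop(sprintf("experiment '%s' failed at stage '%s': %s",
                   experiment, name, conditionMessage(e)), call. = FALSE)
    })
  }

  if (experiment == "efficiency") {
    if (is.null(n_reps)) n_reps <- 100
    if (is.null(t_post)) t_post <- 2
    curves <- stage("convergence", lapply(
      c("hamiltonian", "langevin"),
      function(m) convergence_curve(net, z_gen = 1, mode = m,
                                    n_reps = n_reps, t_post = t_post,
                                    seed = seed)
    ))
    names(curves) <- c("hamiltonian", "langevin")
    times <- vapply(curves, function(cv)
      suppressWarnings(time_to_unit_mse(cv)), numeric(1))
    tab <- do.call(rbind, lapply(names(curves), function(m) {
      data.frame(mode = m, time_s = curves[[m]]$times,
                 mse_mean = curves[[m]]$mse_mean,
                 mse_sem = curves[[m]]$mse_sem)
    }))
    utils::write.csv(tab, file.path(out_dir, "convergence_curves.csv"),
                     row.names = FALSE)
    summary$n_reps <- n_reps
    summary$time_to_unit_mse_ms <- as.list(1000 * times)
    summary$langevin_hamiltonian_ratio <-
      unname(times["langevin"] / times["hamiltonian"])
    if (make_figures) {
      grDevices::png(file.path(out_dir, "convergence.png"), 640, 480)
      plot(curves$hamiltonian, main = "normalised MSE of the running mean")
      graphics::lines(curves$langevin$times, curves$langevin$mse_mean,
                      col = "blue")
      grDevices::dev.off()
    }
  } else if (experiment == "oscillations") {
    if (is.null(t_post)) t_post <- 3
    if (is.null(n_reps)) n_reps <- 8
    rows <- stage("spectra", lapply(z_gen_list, function(zg) {
      ps <- lfp_spectrum(net, zg, n_trials = n_reps, t_post = t_post,
                         seed = seed)
      data.frame(z_gen = zg,
                 f_predicted = oscillation_frequency(zg, net$tau,
                                                     net$gsm$sigma_x_sq),
                 f_simulated = ps$peak_freq)
    }))
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "oscillation_frequencies.csv"),
                     row.names = FALSE)
    summary$peak_freqs_hz <- stats::setNames(
      as.list(tab$f_simulated), paste0("z_", tab$z_gen))
    summary$predicted_freqs_hz <- stats::setNames(
      as.list(tab$f_predicted), paste0("z_", tab$z_gen))
    summary$monotone_increasing <- all(diff(tab$f_simulated) > 0)
  } else if (experiment == "balance") {
    if (is.null(t_post)) t_post <- 3
    traj <- stage("simulate", simulate(net, protocol = simulation_protocol(
      t_pre = 1, t_post = t_post, z_gen = 1, seed = seed)))
    bal <- stage("balance", ei_balance(traj, net))
    utils::write.csv(
      data.frame(cell = seq_len(nrow(bal$trial_mean_pairs)),
                 mean_excitation = bal$trial_mean_pairs[, 1],
                 mean_inhibition = bal$trial_mean_pairs[, 2]),
      file.path(out_dir, "balance_means.csv"), row.names = FALSE)
    summary$peak_lag_ms <- 1000 * bal$peak_lag
    summary$peak_corr <- bal$peak_corr
    summary$tls_slope <- tls_slope(bal$trial_mean_pairs[, 1],
                                   bal$trial_mean_pairs[, 2])
    if (make_figures) {
      grDevices::png(file.path(out_dir, "balance.png"), 800, 400)
      plot(bal)
      grDevices::dev.off()
    }
  } else if (experiment == "transients") {
    if (is.null(n_reps)) n_reps <- 8
    if (is.null(t_post)) t_post <- 1
    grid <- expand.grid(mode = c("hamiltonian", "langevin",
                                 "hamiltonian_fixed_z"),
                        z_gen = z_gen_list, stringsAsFactors = FALSE)
    rows <- stage("transients", lapply(seq_len(nrow(grid)), function(i) {
      # the Langevin control is the u-only gradient sampler at z = z_gen
      pr <- simulation_protocol(t_pre = 1, t_post = t_post,
                                z_gen = grid$z_gen[i], mode = grid$mode[i],
                                z_fixed = if (grid$mode[i] == "langevin")
                                  grid$z_gen[i] else NULL,
                                seed = seed)
      rc <- population_rate_curve(net, pr, n_reps = n_reps)
      tm <- transient_metrics(rc$rates, rc$onset_index, rc$fs)
      data.frame(mode = grid$mode[i], z_gen = grid$z_gen[i],
                 baseline = tm$baseline_rate, peak = tm$peak_rate,
                 steady = tm$steady_rate, overshoot = tm$overshoot,
                 transient_present = tm$transient_present,
                 time_to_peak_ms = 1000 * tm$time_to_peak,
                 excursion_ms = 1000 * tm$excursion_duration)
    }))
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "transients.csv"),
                     row.names = FALSE)
    summary$n_reps <- n_reps
    summary$transients <- tab
  } else { # rho_sweep
    if (is.null(t_post)) t_post <- 2
    rows <- stage("sweep", lapply(tau_L_list, function(tl) {
      net_tl <- ei_network(net$gsm, tau = net$tau, tau_L = tl)
      traj <- simulate(net_tl, protocol = simulation_protocol(
        t_pre = 1, t_post = t_post, z_gen = 1, seed = seed))
      ps <- power_spectrum(lfp(traj)[traj$times > 0], fs = traj$fs)
      rc <- population_rate_curve(net_tl, simulation_protocol(
        t_pre = 1, t_post = t_post, z_gen = 2, seed = seed), n_reps = 6)
      tm <- transient_metrics(rc$rates, rc$onset_index, rc$fs)
      data.frame(tau_L_ms = 1000 * tl, peak_freq_hz = ps$peak_freq,
                 oscillatory = ps$peak_freq > 20,
                 transient_present = tm$transient_present)
    }))
    tab <- do.call(rbind, rows)
    utils::write.csv(tab, file.path(out_dir, "rho_sweep.csv"),
                     row.names = FALSE)
    summary$sweep <- tab
  }

  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}

#' Small-scale validation of the sampler's core guarantees
#'
#' Runs quick checks of the properties the construction is supposed to
#' guarantee and reports pass/fail per property (failures are report
#' entries, not errors):
#' \itemize{
#'   \item Dale's law: all recurrent weights nonnegative at the requested
#'     time constants (a run with \code{tau >= tau_L} is the designed
#'     failure, naming the offending matrix).
#'   \item Energy conservation: the drift of the joint log-density under the
#'     noise-free Hamiltonian component shrinks as the step size is halved.
#'   \item Harmonic frequency: a noise-free reduced fixed-z run oscillates at
#'     the predicted frequency.
#'   \item Stationary law: the empirical covariance of a short fixed-z run of
#'     a small network matches the posterior covariance loosely.
#' }
#'
#' @param tau,tau_L Time constants (seconds) for the weight check.
#' @param sigma_x_sq Observation noise variance for the frequency check.
#' @param seed Seed for the stochastic checks.
#' @return A data frame with columns \code{property}, \code{pass},
#'   \code{detail}.
#' @export
validate_suite <- function(tau = 0.010, tau_L = 0.150, sigma_x_sq = 0.1,
                           seed = 1L) {
  out <- list()
  note <- function(property, pass, detail) {
    out[[length(out) + 1]] <<- data.frame(
      property = property, pass = pass, detail = detail,
      stringsAsFactors = FALSE)
  }

  small <- ei_network(gsm_model(build_gabor_bank(
    gabor_bank_spec(image_side = 12, orientations = 0,
                    locations = rbind(c(.3, .3), c(.5, .5), c(.7, .7))),
    sigma_x_sq = sigma_x_sq), sigma_x_sq = sigma_x_sq))

  # Dale's law at requested time constants
  dale <- tryCatch({
    build_weights(small$M, small$B, tau, tau_L)
    list(TRUE, sprintf("all weights nonnegative at tau/tau_L = %.3g",
                       tau / tau_L))
  }, error = function(e) list(FALSE, conditionMessage(e)))
  note("dale_law", dale[[1]], dale[[2]])

  # Energy conservation of the noise-free Hamiltonian component
  stim <- sample_stimulus(small$gsm, 1, seed = seed)
  post <- posterior_u(small$gsm, stim$x, 1)
  drift_at <- function(dt) {
    st <- list(u = post$mean + 0.5, v = post$mean, z = 1)
    e0 <- log_joint(small, st$u, st$v, st$z, stim$x)
    for (i in seq_len(round(0.02 / dt))) {
      d <- drift_hamiltonian(st, small, stim$x, conservative = TRUE)
      st$u <- st$u + d$du * dt
      st$v <- st$v + d$dv * dt
    }
    abs(log_joint(small, st$u, st$v, st$z, stim$x) - e0)
  }
  d1 <- drift_at(2e-5)
  d2 <- drift_at(5e-6)
  note("energy_conservation", d2 < d1 / 2,
       sprintf("energy drift %.3g -> %.3g as dt halves twice", d1, d2))

  # Reduced-model frequency against the closed form
  rt <- simulate_reduced("fixed_z", u0 = 1.5, z = 1, duration = 0.1,
                         tau = 0.010, sigma_x_sq = sigma_x_sq, u_bar = 1)
  crossings <- which(diff(sign(rt$u - 1)) != 0)
  f_sim <- 1 / (2 * mean(diff(rt$times[crossings])))
  f_pred <- oscillation_frequency(1, 0.010, sigma_x_sq)
  note("harmonic_frequency", abs(f_sim - f_pred) / f_pred < 0.02,
       sprintf("simulated %.2f Hz vs predicted %.2f Hz", f_sim, f_pred))

  # Stationary covariance of a short fixed-z run (loose Monte Carlo check)
  traj <- simulate(small, protocol = simulation_protocol(
    t_pre = 1, t_post = 6, z_gen = 1, mode = "hamiltonian_fixed_z",
    seed = seed))
  emp <- stats::cov(traj$u[traj$times > 0, ])
  rel <- max(abs(emp - post$cov)) / max(abs(post$cov))
  note("stationary_covariance", rel < 0.35,
       sprintf("max relative covariance error %.3g", rel))

  do.call(rbind, out)
}
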