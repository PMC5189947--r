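#' Stimulus-onset simulation protocol
#'
#' Describes one run of the sampler: an equilibration epoch with a blank
#' stimulus (an image drawn at zero contrast), followed at onset by a
#' stimulus drawn at contrast \code{z_gen}. Time is measured in seconds with
#' onset at zero.
#'
#' Modes: \code{"hamiltonian"} is the full network (joint inference of the
#' feature intensities and the contrast), \code{"langevin"} removes the
#' recurrent weight matrices and the inhibitory population, leaving noisy
#' gradient ascent, and \code{"hamiltonian_fixed_z"} freezes the contrast at
#' \code{z_fixed} (default \code{z_gen}) while keeping the full
#' excitatory-inhibitory dynamics. Supplying \code{z_fixed} freezes the
#' contrast in any mode; in particular \code{"langevin"} with
#' \code{z_fixed = z_gen} is the u-only gradient sampler used as the
#' efficiency control.
#'
#' @param t_pre Equilibration time before onset (seconds). The default 1 s is
#'   about 6.7 Langevin time constants.
#' @param t_post Simulated time after onset (seconds).
#' @param z_gen Generative contrast of the stimulus.
#' @param dt Euler-Maruyama step (seconds). The default 0.05 ms keeps
#'   \code{dt * omega} well below one for the stiffest oscillatory mode at
#'   \code{z_gen = 2}.
#' @param mode Sampler variant; see Details.
#' @param z_fixed Optional contrast at which z is frozen.
#' @param seed Master seed; stimulus draws and every noise stream are derived
#'   from it, so a protocol reruns bit-identically.
#' @param thin Record every \code{thin}-th step in trajectories.
#' @return Object of class \code{"simulation_protocol"}.
#' @export
simulation_protocol <- function(t_pre = 1, t_post = 2, z_gen = 1,
                                dt = 5e-5,
                                mode = c("hamiltonian", "langevin",
                                         "hamiltonian_fixed_z"),
                                z_fixed = NULL, seed = 1L, thin = 1L) {
  mode <- match.arg(mode)
  stopifnot(t_pre > 0, t_post > 0, z_gen >= 0, dt > 0)
  if (mode == "hamiltonian_fixed_z" && is.null(z_fixed)) z_fixed <- z_gen
  if (!is.null(z_fixed)) stopifnot(z_fixed >= 0)
  structure(
    list(
      t_pre = t_pre, t_post = t_post, z_gen = z_gen, dt = dt,
      mode = mode, z_fixed = z_fixed, seed = as.integer(seed),
      thin = as.integer(thin)
    ),
    class = "simulation_protocol"
  )
}

#' @export
print.simulation_protocol <- function(x, ...) {
  cat(sprintf(
    "Simulation protocol: %s mode, z_gen = %.3g%s\n", x$mode, x$z_gen,
    if (!is.null(x$z_fixed)) sprintf(" (z frozen at %.3g)", x$z_fixed) else ""
  ))
  cat(sprintf(
    "  %.3g s pre + %.3g s post onset, dt = %.3g ms, seed %d\n",
    x$t_pre, x$t_post, 1000 * x$dt, x$seed
  ))
  invisible(x)
}

#' Drift of the Hamiltonian excitatory-inhibitory dynamics
#'
#' Deterministic part of the coupled membrane-potential equations:
#' \code{du/dt = (W_uu u - W_uv v) / tau + I_input / tau_L} and
#' \code{dv/dt = (W_vu u - W_vv v - I_input) / tau}, where \code{I_input} is
#' [input_current()] evaluated at the state's contrast. With
#' \code{conservative = TRUE} the Langevin (noise-balancing) terms are
#' dropped, leaving the energy-conserving Hamiltonian flow: recurrent weights
#' at \code{tau / tau_L = 0} and no input term in \code{du/dt}.
#'
#' @param state List with elements \code{u}, \code{v}, \code{z} (and
#'   optionally \code{v_z}).
#' @param net An [ei_network()].
#' @param x Image vector.
#' @param conservative Drop the Langevin terms (default \code{FALSE}).
#' @return List with \code{du} and \code{dv} (per-second rates of change).
#' @export
drift_hamiltonian <- function(state, net, x, conservative = FALSE) {
  stopifnot(inherits(net, "ei_network"),
            length(state$u) == net$n, length(state$v) == net$n)
  I_u <- input_current(net$gsm, state$u, state$z, x)
  if (conservative) {
    du <- drop(net$M %*% (state$u - state$v)) / net$tau
    dv <- (drop(net$M %*% (state$u - state$v)) - I_u) / net$tau
  } else {
    du <- drop(net$W_uu %*% state$u - net$W_uv %*% state$v) / net$tau +
      I_u / net$tau_L
    dv <- (drop(net$W_vu %*% state$u - net$W_vv %*% state$v) - I_u) / net$tau
  }
  list(du = du, dv = dv)
}

#' Drift of the contrast subsystem
#'
#' Scalar analogue of [drift_hamiltonian()] for the contrast variable and its
#' auxiliary partner, with unit coupling and unit mass, driven by
#' [z_input_current()].
#'
#' @inheritParams drift_hamiltonian
#' @return List with \code{dz} and \code{dv_z}.
#' @export
drift_z <- function(state, net, x) {
  stopifnot(inherits(net, "ei_network"))
  I_z <- z_input_current(net$gsm, state$u, state$z, x)
  w <- net$z_weights
  list(
    dz = (w["W_zz"] * state$z - w["W_zv"] * state$v_z) / net$tau +
      I_z / net$tau_L,
    dv_z = (w["W_vz"] * state$z - w["W_vv"] * state$v_z - I_z) / net$tau
  )
}

#' Drift of the Langevin control sampler
#'
#' Noisy gradient ascent on the log-posterior, obtained by deleting the
#' recurrent weight matrices: \code{du/dt = I_input / tau_L}. There is no
#' inhibitory population.
#'
#' @inheritParams drift_hamiltonian
#' @return Numeric vector \code{du}.
#' @export
drift_langevin <- function(state, net, x) {
  stopifnot(inherits(net, "ei_network"))
  input_current(net$gsm, state$u, state$z, x) / net$tau_L
}

#' Simulate the sampling network
#'
#' Integrates the stochastic membrane-potential dynamics with the
#' Euler-Maruyama scheme under a stimulus-onset protocol. The returned
#' trajectory carries the excitatory and inhibitory potentials, the inferred
#' contrast and its auxiliary variable at every recorded step, with onset at
#' time zero.
#'
#' The contrast variable is kept nonnegative by a reflecting boundary: a step
#' crossing zero reflects \code{z} and negates its auxiliary momentum.
#' Trajectories are reproducible: the protocol seed determines the stimulus
#' draws and all noise streams.
#'
#' @param object An [ei_network()].
#' @param nsim Number of repetitions (fresh noise, shared stimulus). With
#'   \code{nsim > 1} a list of trajectories is returned.
#' @param seed Optional override of the protocol seed.
#' @param protocol A [simulation_protocol()].
#' @param stimulus Optional [sample_stimulus()] result to use after onset in
#'   place of a stimulus drawn from the protocol seed.
#' @param ... Unused.
#' @return An object of class \code{"ei_trajectory"} (or a list of them):
#'   list with \code{times}, \code{u}, \code{v} (time x cells), \code{z},
#'   \code{v_z}, \code{onset_index}, \code{protocol}, \code{stimulus},
#'   \code{blank}, \code{fs} (recorded sampling rate, Hz).
#' @export
#' @examples
#' net <- ei_network(gsm_model(build_gabor_bank(
#'   gabor_bank_spec(image_side = 12, orientations = 0))))
#' traj <- simulate(net, protocol = simulation_protocol(
#'   t_pre = 0.1, t_post = 0.1, seed = 1))
#' traj
simulate.ei_network <- function(object, nsim = 1, seed = NULL,
                                protocol = simulation_protocol(),
                                stimulus = NULL, ...) {
  stopifnot(inherits(protocol, "simulation_protocol"))
  if (!is.null(seed)) protocol$seed <- as.integer(seed)
  if (nsim == 1) {
    return(run_engine(object, protocol, stimulus = stimulus,
                      n_reps = 1L, record = "trajectory"))
  }
  lapply(seq_len(nsim), function(k) {
    p <- protocol
    p$seed <- derive_seed(protocol$seed, 7000L + k)
    run_engine(object, p, stimulus = stimulus, n_reps = 1L,
               record = "trajectory", stimulus_seed_from = protocol$seed)
  })
}

#' @export
print.ei_trajectory <- function(x, ...) {
  cat(sprintf(
    "EI sampler trajectory (%s mode): %d cells, %d recorded steps\n",
    x$protocol$mode, ncol(x$u), nrow(x$u)
  ))
  cat(sprintf(
    "  t in [%.3g, %.3g] s, onset at 0; fs = %.4g Hz\n",
    x$times[1], x$times[length(x$times)], x$fs
  ))
  post <- x$z[x$times > 0]
  if (length(post)) {
    cat(sprintf("  mean inferred contrast after onset: %.3g\n", mean(post)))
  }
  invisible(x)
}

#' @export
plot.ei_trajectory <- function(x, cells = 1:min(3, ncol(x$u)), ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::matplot(x$times, x$u[, cells, drop = FALSE], type = "l", lty = 1,
                    xlab = "time from onset (s)",
                    ylab = "membrane potential u", ...)
  graphics::abline(v = 0, lty = 3)
  graphics::plot(x$times, x$z, type = "l", xlab = "time from onset (s)",
                 ylab = "inferred contrast z")
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

# ---------------------------------------------------------------------------
# Internal integration engine.
#
# Vectorised over repetitions: the state is carried as n x R matrices so one
# R-level loop over time steps serves any number of noise-independent
# repetitions. Depending on `record`, it returns a full trajectory (R = 1), a
# per-repetition population-rate matrix, or per-repetition running-mean
# normalised MSE curves against a fixed-z posterior.
run_engine <- function(net, protocol, stimulus = NULL, n_reps = 1L,
                       record = c("trajectory", "rates", "convergence"),
                       posterior = NULL, record_every = NULL,
                       stimulus_seed_from = NULL) {
  record <- match.arg(record)
  gsm <- net$gsm
  n <- net$n
  R <- as.integer(n_reps)
  dt <- protocol$dt
  s2 <- gsm$sigma_x_sq
  G <- gsm$gram
  C_inv <- gsm$C_inv
  tau <- net$tau
  tau_L <- net$tau_L
  sd_noise <- sqrt(2 / tau_L) * sqrt(dt)
  mode <- protocol$mode
  langevin <- mode == "langevin"
  z_fixed <- protocol$z_fixed
  zfree <- is.null(z_fixed)
  wz <- net$z_weights

  # Stimuli: the blank and the onset stimulus are drawn from seeds derived
  # from the master seed, so repetitions share them while noise differs.
  stim_seed_base <- if (is.null(stimulus_seed_from)) protocol$seed else
    stimulus_seed_from
  blank <- sample_stimulus(gsm, 0, seed = derive_seed(stim_seed_base, 1L))
  if (is.null(stimulus)) {
    stimulus <- sample_stimulus(gsm, protocol$z_gen,
                                seed = derive_seed(stim_seed_base, 2L))
  }
  stopifnot(inherits(stimulus, "gsm_stimulus"))

  # Work in zero-offset coordinates; the prior-mean offset is added back on
  # output (trajectories translate, the dynamics do not change).
  AtX0 <- drop(crossprod(gsm$A, blank$x))
  AtX1 <- drop(crossprod(gsm$A, stimulus$x))

  n_pre <- round(protocol$t_pre / dt)
  n_post <- round(protocol$t_post / dt)
  n_tot <- n_pre + n_post

  U <- matrix(0, n, R)
  V <- matrix(0, n, R)
  z <- rep(if (zfree) 1 else z_fixed, R)
  vz <- rep(1, R)

  thin <- if (record == "trajectory") protocol$thin else 1L
  if (record == "trajectory") {
    stopifnot(R == 1L)
    n_rec <- floor(n_tot / thin)
    u_t <- matrix(NA_real_, n_rec, n)
    v_t <- matrix(NA_real_, n_rec, n)
    z_t <- numeric(n_rec)
    vz_t <- numeric(n_rec)
    t_rec <- numeric(n_rec)
  } else if (record == "rates") {
    rate_t <- matrix(NA_real_, n_tot, R)
    z_mean_t <- numeric(n_tot)
  } else {
    stopifnot(!is.null(posterior))
    if (is.null(record_every)) record_every <- max(1L, round(0.001 / dt))
    u_bar <- posterior$mean - gsm$b
    s_diag <- diag(posterior$cov)
    n_rec <- floor(n_post / record_every)
    mse_t <- matrix(NA_real_, n_rec, R)
    t_rec <- numeric(n_rec)
    run_sum <- matrix(0, n, R)
    i_rec <- 0L
  }

  set.seed(derive_seed(protocol$seed, 3L))
  AtX <- AtX0
  k_rec <- 0L
  for (i in seq_len(n_tot)) {
    if (i == n_pre + 1L) AtX <- AtX1
    GU <- G %*% U
    if (zfree) {
      zr <- rep(z, each = n)
      I_u <- (zr / s2) * (AtX - zr * GU) - C_inv %*% U
      I_z <- (colSums(U * AtX) - z * colSums(U * GU)) / s2 - z
    } else {
      I_u <- (z[1] / s2) * (AtX - z[1] * GU) - C_inv %*% U
    }
    if (langevin) {
      U <- U + (I_u / tau_L) * dt + sd_noise * matrix(stats::rnorm(n * R), n, R)
      if (zfree) {
        z <- z + (I_z / tau_L) * dt + sd_noise * stats::rnorm(R)
        neg <- which(z < 0)
        if (length(neg)) z[neg] <- -z[neg]
      }
    } else {
      dU <- (net$W_uu %*% U - net$W_uv %*% V) / tau + I_u / tau_L
      dV <- (net$W_vu %*% U - net$W_vv %*% V - I_u) / tau
      U <- U + dU * dt + sd_noise * matrix(stats::rnorm(n * R), n, R)
      V <- V + dV * dt + sd_noise * matrix(stats::rnorm(n * R), n, R)
      if (zfree) {
        dz <- (wz["W_zz"] * z - wz["W_zv"] * vz) / tau + I_z / tau_L
        dvz <- (wz["W_vz"] * z - wz["W_vv"] * vz - I_z) / tau
        z <- z + dz * dt + sd_noise * stats::rnorm(R)
        vz <- vz + dvz * dt + sd_noise * stats::rnorm(R)
        neg <- which(z < 0)
        if (length(neg)) {
          z[neg] <- -z[neg]
          vz[neg] <- -vz[neg]
        }
      }
    }
    if (i %% 2000L == 0L && !(all(is.finite(U)) && all(is.finite(z)))) {
      stop(sprintf(
        "integration blew up (non-finite state) at t = %.4g s with dt = %.3g s",
        (i - n_pre) * dt, dt
      ))
    }
    if (record == "trajectory") {
      if (i %% thin == 0L) {
        k_rec <- k_rec + 1L
        u_t[k_rec, ] <- U[, 1]
        v_t[k_rec, ] <- V[, 1]
        z_t[k_rec] <- z[1]
        vz_t[k_rec] <- vz[1]
        t_rec[k_rec] <- (i - n_pre) * dt
      }
    } else if (record == "rates") {
      rate_t[i, ] <- colMeans(pmax(U + gsm$b, 0))
      z_mean_t[i] <- mean(z)
    } else if (i > n_pre) {
      run_sum <- run_sum + U
      j <- i - n_pre
      if (j %% record_every == 0L) {
        i_rec <- i_rec + 1L
        u_hat <- run_sum / j
        mse_t[i_rec, ] <- colMeans((u_hat - u_bar)^2 / s_diag)
        t_rec[i_rec] <- j * dt
      }
    }
  }
  if (!all(is.finite(U))) {
    stop(sprintf("integration blew up (non-finite state) with dt = %.3g s", dt))
  }

  if (record == "trajectory") {
    structure(
      list(
        times = t_rec,
        u = u_t + matrix(gsm$b, nrow(u_t), n, byrow = TRUE),
        v = v_t + matrix(gsm$b, nrow(v_t), n, byrow = TRUE),
        z = z_t, v_z = vz_t,
        onset_index = floor(n_pre / thin),
        protocol = protocol,
        stimulus = stimulus, blank = blank,
        fs = 1 / (dt * thin)
      ),
      class = "ei_trajectory"
    )
  } else if (record == "rates") {
    list(
      times = (seq_len(n_tot) - n_pre) * dt,
      rates = rate_t, z_mean = z_mean_t,
      onset_index = n_pre, fs = 1 / dt
    )
  } else {
    list(times = t_rec, mse = mse_t)
  }
}

# Deterministic 32-bit seed derivation (master seed + stream label).
# Carried out in doubles (exact below 2^53) to avoid integer overflow.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 2654435 + as.numeric(stream) * 40503) %%
               2147483647)
}
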