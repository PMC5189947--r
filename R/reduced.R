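#' Harmonic frequency of the reduced fixed-contrast dynamics
#'
#' Folding the inhibitory population into the excitatory equations (with the
#' ideal mass matrix) collapses the noise-free sampler, at fixed contrast,
#' to independent harmonic oscillators about the posterior mean with
#' frequency
#' \deqn{f(z) = \frac{1}{2\pi\tau}\sqrt{z^2/\sigma_x^2 + 1/(1-\sigma_x^2)},}
#' the square root of the per-dimension posterior precision divided by the
#' membrane time constant. The frequency is strictly increasing in contrast;
#' at the default operating point it spans the gamma band (30-100 Hz for z
#' between 0.5 and 2).
#'
#' @param z Contrast (vectorised).
#' @param tau Membrane time constant (seconds).
#' @param sigma_x_sq Observation noise variance.
#' @return Frequency in Hz.
#' @export
#' @examples
#' oscillation_frequency(c(0.5, 1, 2))  # about 30, 53, 102 Hz
oscillation_frequency <- function(z, tau = 0.010, sigma_x_sq = 0.1) {
  stopifnot(all(z >= 0), tau > 0, sigma_x_sq > 0, sigma_x_sq < 1)
  sqrt(z^2 / sigma_x_sq + 1 / (1 - sigma_x_sq)) / (2 * pi * tau)
}

#' Acceleration of the reduced dynamics at fixed contrast
#'
#' Second-order form of the collapsed noise-free sampler: each component
#' obeys \code{u'' = -(1/tau^2) (z^2/sigma_x_sq + 1/(1-sigma_x_sq))
#' (u - u_bar)}, a harmonic restoring force towards the posterior mean whose
#' stiffness is the posterior precision.
#'
#' @param u Current value(s) of the reduced coordinate.
#' @param u_bar Posterior mean.
#' @param z Fixed contrast.
#' @param tau Membrane time constant (seconds).
#' @param sigma_x_sq Observation noise variance.
#' @return Acceleration, s^-2.
#' @export
reduced_accel_fixed_z <- function(u, u_bar, z, tau = 0.010, sigma_x_sq = 0.1) {
  stopifnot(tau > 0, sigma_x_sq > 0, sigma_x_sq < 1, z >= 0)
  -(z^2 / sigma_x_sq + 1 / (1 - sigma_x_sq)) * (u - u_bar) / tau^2
}

#' Acceleration of the reduced dynamics with inferred contrast
#'
#' One-dimensional model of the joint inference of contrast and feature
#' intensity. Because contrast equilibrates much faster than the feature
#' intensity, it is slaved to \code{z = x / (A u)}, which makes the spring
#' stiffness state dependent:
#' \code{u'' = -(1/tau^2) (x^2/(sigma_x_sq A^2 u^2) + 1/(1-sigma_x_sq))
#' (u - u_bar)}. The stiffness is large at small \code{|u|} and small at
#' large \code{|u|}; started below the posterior mean the system therefore
#' accelerates hard, overshoots, and produces the onset transient.
#'
#' To guard the division, \code{|u|} is floored at \code{eps * u_bar}
#' (default 1e-3): below the floor the stiffness is held at its floor value.
#'
#' @param u Current value(s) of the reduced coordinate.
#' @param x One-dimensional stimulus value.
#' @param A One-dimensional basis weight.
#' @param u_bar Posterior mean (steady-state level).
#' @param tau Membrane time constant (seconds).
#' @param sigma_x_sq Observation noise variance.
#' @param eps Relative floor on \code{|u|}.
#' @return Acceleration, s^-2.
#' @export
reduced_accel_inferred_z <- function(u, x, A = 1, u_bar = 1, tau = 0.010,
                                     sigma_x_sq = 0.1, eps = 1e-3) {
  stopifnot(tau > 0, sigma_x_sq > 0, sigma_x_sq < 1, A != 0, eps > 0)
  u_eff <- pmax(abs(u), eps * abs(u_bar))
  -(x^2 / (sigma_x_sq * A^2 * u_eff^2) + 1 / (1 - sigma_x_sq)) *
    (u - u_bar) / tau^2
}

#' Integrate a reduced second-order model
#'
#' Deterministic velocity-Verlet integration of either reduced model. The
#' symplectic scheme preserves the oscillation amplitude of the fixed-z
#' (undamped harmonic) model over many cycles.
#'
#' @param model \code{"fixed_z"} or \code{"inferred_z"}.
#' @param u0,u_dot0 Initial coordinate and velocity.
#' @param duration Simulated time (seconds).
#' @param dt Integration step (seconds); default 0.01 ms.
#' @param z Fixed contrast (fixed_z model).
#' @param x,A One-dimensional stimulus and basis weight (inferred_z model).
#' @param u_bar Posterior mean.
#' @param tau Membrane time constant (seconds).
#' @param sigma_x_sq Observation noise variance.
#' @param eps Stiffness floor of the inferred-z model.
#' @return Object of class \code{"reduced_trajectory"}: list with
#'   \code{times}, \code{u}, \code{u_dot}, \code{model}, \code{u_bar} and the
#'   parameters.
#' @export
#' @examples
#' rt <- simulate_reduced("inferred_z", u0 = 0.1, u_dot0 = 0,
#'                        duration = 0.2, x = 1)
#' excursion_duration(rt)  # about 0.03 s
simulate_reduced <- function(model = c("fixed_z", "inferred_z"),
                             u0, u_dot0 = 0, duration = 0.2, dt = 1e-5,
                             z = 1, x = 1, A = 1, u_bar = 1,
                             tau = 0.010, sigma_x_sq = 0.1, eps = 1e-3) {
  model <- match.arg(model)
  stopifnot(duration > 0, dt > 0)
  accel <- if (model == "fixed_z") {
    function(u) reduced_accel_fixed_z(u, u_bar, z, tau, sigma_x_sq)
  } else {
    function(u) reduced_accel_inferred_z(u, x, A, u_bar, tau, sigma_x_sq, eps)
  }
  n <- round(duration / dt)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  u[1] <- u0
  v[1] <- u_dot0
  a <- accel(u0)
  for (i in seq_len(n)) {
    u[i + 1] <- u[i] + v[i] * dt + 0.5 * a * dt^2
    a_new <- accel(u[i + 1])
    v[i + 1] <- v[i] + 0.5 * (a + a_new) * dt
    a <- a_new
    if (!is.finite(u[i + 1])) {
      stop(sprintf("reduced integration blew up at t = %.4g s", i * dt))
    }
  }
  structure(
    list(
      times = (0:n) * dt, u = u, u_dot = v,
      model = model, u_bar = u_bar,
      params = list(z = z, x = x, A = A, tau = tau,
                    sigma_x_sq = sigma_x_sq, dt = dt)
    ),
    class = "reduced_trajectory"
  )
}

#' @export
print.reduced_trajectory <- function(x, ...) {
  cat(sprintf(
    "Reduced %s trajectory: %.3g s at dt = %.3g ms, u in [%.3g, %.3g]\n",
    x$model, x$times[length(x$times)], 1000 * x$params$dt,
    min(x$u), max(x$u)
  ))
  invisible(x)
}

#' @export
plot.reduced_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$u, type = "l", xlab = "time (s)", ylab = "u", ...)
  graphics::abline(h = x$u_bar, lty = 3)
  invisible(x)
}

#' Duration of the initial excursion of a reduced trajectory
#'
#' Measures the onset transient of a deterministic reduced run: the time from
#' the start until the trajectory first returns to the steady-state level
#' (the posterior mean) after its first peak. For the inferred-contrast model
#' started below the mean this is the duration of the large overshoot.
#'
#' @param rt A [simulate_reduced()] result.
#' @return Duration in seconds, or \code{NA} with a warning if the trajectory
#'   never returns within the simulated window.
#' @export
excursion_duration <- function(rt) {
  stopifnot(inherits(rt, "reduced_trajectory"))
  u <- rt$u
  peak <- which(diff(sign(diff(u))) < 0)[1] + 1L # first local maximum
  if (is.na(peak)) {
    warning("no peak found within the simulated window")
    return(NA_real_)
  }
  after <- seq(peak, length(u) - 1L)
  cross <- after[u[after] >= rt$u_bar & u[after + 1L] < rt$u_bar][1]
  if (is.na(cross)) {
    warning("trajectory does not return to the steady-state level")
    return(NA_real_)
  }
  # linear interpolation of the crossing time
  f <- (u[cross] - rt$u_bar) / (u[cross] - u[cross + 1L])
  rt$times[cross] + f * rt$params$dt
}
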