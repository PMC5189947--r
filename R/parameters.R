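#' Prior covariance of the feature intensities
#'
#' The retina/LGN pathway whitens visual input, so the prior covariance of
#' the feature intensities is taken proportional to the inverse Gram matrix
#' of the basis: \code{C = (1 - sigma_x_sq) * solve(t(A) %*% A)}. The
#' proportionality constant matches the covariance of the filter projections
#' of whitened images under the generative model (valid for complete and
#' undercomplete bases).
#'
#' @param A Basis matrix (pixels x features).
#' @param sigma_x_sq Observation noise variance, in (0, 1).
#' @return Symmetric positive-definite covariance matrix.
#' @export
#' @examples
#' build_prior_covariance(matrix(1), 0.1)  # 1-D case: 0.9
build_prior_covariance <- function(A, sigma_x_sq) {
  stopifnot(is.matrix(A), sigma_x_sq > 0, sigma_x_sq < 1)
  gram <- crossprod(A)
  C <- (1 - sigma_x_sq) * solve_spd(gram, "degenerate basis: t(A) %*% A")
  (C + t(C)) / 2
}

#' Mass matrix of the auxiliary (inhibitory) variables
#'
#' The ideal mass matrix equalising sampling speed across directions would be
#' \code{solve(t(A) %*% A)}, but Dale's law requires nonnegative synaptic
#' weights, so negative elements are clipped at zero:
#' \code{M_ij = max(0, solve(t(A) %*% A)_ij)}. Positive definiteness of the
#' clipped matrix is not guaranteed in general and is verified here; for the
#' default Gabor bank it holds comfortably.
#'
#' @inheritParams build_prior_covariance
#' @return Symmetric positive-definite mass matrix.
#' @export
build_mass_matrix <- function(A) {
  stopifnot(is.matrix(A))
  gram_inv <- solve_spd(crossprod(A), "degenerate basis: t(A) %*% A")
  M <- pmax(gram_inv, 0)
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= -1e-10 * max(ev)) {
    stop(sprintf(
      "clipped mass matrix is not positive definite (smallest eigenvalue %.3e)",
      min(ev)
    ))
  }
  M
}

#' Recurrent weight matrices of the sampler
#'
#' Builds the four synaptic weight matrices coupling the excitatory (u) and
#' inhibitory (v) populations from the mass matrix \code{M}, the auxiliary
#' coupling \code{B}, and the two time constants:
#' \deqn{W_{uu} = B'MB - (tau/tau_L) MB, \quad W_{uv} = B'M - (tau/tau_L) M,}
#' \deqn{W_{vu} = MB + (tau/tau_L) B'MB, \quad W_{vv} = M + (tau/tau_L) B'M.}
#' Every element of every matrix must be nonnegative (Dale's law); a negative
#' element aborts with the name of the offending matrix. The scalar
#' \code{B = M = 1} case yields the four weights of the contrast (z)
#' subsystem.
#'
#' @param M Mass matrix (symmetric positive definite), or the scalar 1.
#' @param B Auxiliary coupling matrix (identity by default), or the scalar 1.
#' @param tau Membrane/recurrent time constant (seconds).
#' @param tau_L Langevin noise-injection time constant (seconds); must exceed
#'   \code{tau}.
#' @return A list with elements \code{W_uu}, \code{W_uv}, \code{W_vu},
#'   \code{W_vv}.
#' @export
#' @examples
#' build_weights(1, 1, tau = 0.01, tau_L = 0.15)  # scalar z-subsystem weights
build_weights <- function(M, B = NULL, tau, tau_L) {
  M <- as.matrix(M)
  if (is.null(B)) B <- diag(nrow(M))
  B <- as.matrix(B)
  stopifnot(tau > 0, tau_L > 0)
  r <- tau / tau_L
  MB <- M %*% B
  BtM <- crossprod(B, M)
  BtMB <- crossprod(B, MB)
  W <- list(
    W_uu = BtMB - r * MB,
    W_uv = BtM - r * M,
    W_vu = MB + r * BtMB,
    W_vv = M + r * BtM
  )
  for (nm in names(W)) {
    if (min(W[[nm]]) < 0) {
      stop(sprintf(
        "Dale's law violated: %s has negative elements (min %.3e)",
        nm, min(W[[nm]])
      ))
    }
  }
  W
}

#' Observation noise from afferent spike-count statistics
#'
#' Models the feed-forward drive to a cortical cell as the spike count of
#' \code{N} retinal ganglion cells firing Poisson trains at rate \code{r}
#' within an integration window \code{dt}; the coefficient of variation of
#' that count gives the noise-to-signal ratio \code{sigma_x = 1 /
#' sqrt(N * r * dt)}.
#'
#' @param N Number of afferent cells.
#' @param r Mean firing rate (Hz).
#' @param dt Temporal integration window (seconds).
#' @return The scalar sigma_x (not its square).
#' @export
#' @examples
#' estimate_sigma_x(100, 1, 0.1)   # 1/sqrt(10)
#' estimate_sigma_x(1000, 1, 0.1)  # 0.1
estimate_sigma_x <- function(N, r, dt) {
  stopifnot(N > 0, r > 0, dt > 0)
  1 / sqrt(N * r * dt)
}

#' Langevin time constant from vesicle-release noise
#'
#' Equates the rate at which the sampler injects membrane-potential variance,
#' \code{2 * sigma^2 / tau_L}, with the variance injection rate of stochastic
#' vesicle release, \code{s * r * v}, giving \code{tau_L = 2 * sigma^2 /
#' (s * r * v)}.
#'
#' @param sigma Membrane potential scale (mV).
#' @param s Number of presynaptic cells.
#' @param r Presynaptic firing rate (Hz).
#' @param v Variance of a unitary EPSP (mV^2).
#' @return Point estimate of tau_L in seconds.
#' @export
estimate_tau_L <- function(sigma, s, r, v) {
  stopifnot(sigma > 0, s > 0, r > 0, v > 0)
  2 * sigma^2 / (s * r * v)
}

#' Log-normal description of an uncertain biophysical quantity
#'
#' Encodes an uncertain parameter by the range believed to contain roughly
#' 95% of its probability mass, treating the bounds as two standard
#' deviations from the mean in the log domain. The central value is the
#' geometric mean of the bounds.
#'
#' @param low,high Range bounds on the natural scale (\code{low < high}).
#' @return Object of class \code{"biophys_estimate"} with fields
#'   \code{central}, \code{low}, \code{high}, \code{log_mu},
#'   \code{log_sigma}.
#' @export
biophys_estimate <- function(low, high) {
  if (!(low > 0) || !(high > low)) {
    stop("need 0 < low < high for a log-normal range")
  }
  log_mu <- (log(low) + log(high)) / 2
  log_sigma <- (log(high) - log(low)) / 4
  structure(
    list(
      central = exp(log_mu), low = low, high = high,
      log_mu = log_mu, log_sigma = log_sigma
    ),
    class = "biophys_estimate"
  )
}

#' @export
print.biophys_estimate <- function(x, ...) {
  cat(sprintf(
    "log-normal estimate: central %.4g (95%% range %.4g-%.4g)\n",
    x$central, x$low, x$high
  ))
  invisible(x)
}

#' Propagate biophysical uncertainty to the Langevin time constant
#'
#' Combines log-normal uncertainties on the membrane potential scale
#' \code{sigma}, synapse count \code{s}, presynaptic rate \code{r} and
#' unitary EPSP variance \code{v} into the induced log-normal distribution of
#' \code{tau_L = 2 sigma^2 / (s r v)}. The propagation is exact in the log
#' domain: the log-parameters add (with \code{sigma} entering twice).
#'
#' The default ranges span the values reported across the physiology
#' literature: sigma 2.5-7.5 mV, 1000-10000 input cells, rates 0.5-10 Hz,
#' EPSP variance 0.05-0.1 mV^2.
#'
#' @param sigma,s,r,v [biophys_estimate()] objects (or \code{c(low, high)}
#'   ranges, which are converted).
#' @return A [biophys_estimate()] describing tau_L in seconds.
#' @export
#' @examples
#' propagate_tau_L()$central  # back-of-the-envelope tau_L, seconds
propagate_tau_L <- function(sigma = biophys_estimate(2.5, 7.5),
                            s = biophys_estimate(1000, 10000),
                            r = biophys_estimate(0.5, 10),
                            v = biophys_estimate(0.05, 0.1)) {
  as_est <- function(x) {
    if (inherits(x, "biophys_estimate")) x else biophys_estimate(x[1], x[2])
  }
  sigma <- as_est(sigma); s <- as_est(s); r <- as_est(r); v <- as_est(v)
  log_mu <- log(2) + 2 * sigma$log_mu - s$log_mu - r$log_mu - v$log_mu
  log_sd <- sqrt(4 * sigma$log_sigma^2 + s$log_sigma^2 +
                   r$log_sigma^2 + v$log_sigma^2)
  biophys_estimate(exp(log_mu - 2 * log_sd), exp(log_mu + 2 * log_sd))
}

# Invert a symmetric positive-definite matrix via Cholesky, with a
# domain-specific error message on failure.
solve_spd <- function(S, what = "matrix") {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch)) stop(sprintf("%s is singular or not positive definite", what))
  chol2inv(ch)
}
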