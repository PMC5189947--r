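#' Gaussian scale mixture model of image patches
#'
#' Constructs the generative model under which the sampler performs
#' inference. An image patch \code{x} (pixel grey levels) is generated by
#' scaling a Gaussian vector of feature intensities \code{u ~ N(b, C)} by a
#' nonnegative contrast variable \code{z} (half-normal prior, i.e. a standard
#' normal truncated at zero) and projecting through the basis:
#' \code{x ~ N(z * A %*% (u - b), sigma_x_sq * I)}. The prior covariance is
#' tied to the basis by [build_prior_covariance()] so that filter projections
#' of model images are white.
#'
#' The optional prior mean \code{b} shifts the feature intensities so that
#' membrane potentials stay positive; because the likelihood subtracts it
#' again, the distribution of images (and hence the sampling dynamics) is
#' unchanged. See [apply_offset()].
#'
#' @param A Basis matrix from [build_gabor_bank()], or any pixels x features
#'   matrix with invertible Gram matrix.
#' @param sigma_x_sq Observation noise variance, in (0, 1). The default 0.1
#'   places single-filter evidence about ten times above the prior precision
#'   at unit contrast.
#' @param b Optional prior mean (offset) of \code{u}; default zero.
#' @return Object of class \code{"gsm"} with elements \code{A}, \code{C},
#'   \code{C_inv}, \code{gram} (= \code{t(A) %*% A}), \code{sigma_x_sq},
#'   \code{K}, \code{b}, \code{n_pixels}, \code{n_features}.
#' @export
#' @examples
#' gsm <- gsm_model(build_gabor_bank(gabor_bank_spec()))
#' gsm
gsm_model <- function(A, sigma_x_sq = 0.1, b = NULL) {
  stopifnot(is.matrix(A), sigma_x_sq > 0, sigma_x_sq < 1)
  n <- ncol(A)
  if (is.null(b)) b <- rep(0, n)
  stopifnot(length(b) == n, all(is.finite(b)))
  gram <- crossprod(A)
  C <- build_prior_covariance(A, sigma_x_sq)
  structure(
    list(
      A = A,
      C = C,
      C_inv = solve_spd(C, "prior covariance"),
      gram = gram,
      sigma_x_sq = sigma_x_sq,
      K = 1 - sigma_x_sq,
      b = b,
      n_pixels = nrow(A),
      n_features = n
    ),
    class = "gsm"
  )
}

#' @export
print.gsm <- function(x, ...) {
  cat("Gaussian scale mixture image model\n")
  cat(sprintf(
    "  %d pixels, %d features; sigma_x^2 = %.3g, K = %.3g\n",
    x$n_pixels, x$n_features, x$sigma_x_sq, x$K
  ))
  ev <- eigen(x$gram, symmetric = TRUE, only.values = TRUE)$values
  cat(sprintf(
    "  eigenvalues of t(A) A in [%.3g, %.3g] (spread %.2f)\n",
    min(ev), max(ev), max(ev) / min(ev)
  ))
  if (any(x$b != 0)) cat("  prior mean offset in effect\n")
  invisible(x)
}

#' Shift the prior mean of the feature intensities
#'
#' Returns a model whose prior over \code{u} is centred on \code{b} while the
#' likelihood reads \code{A %*% (u - b)}, leaving the distribution of images
#' intact. Posterior means shift by exactly \code{b}; trajectories of the
#' sampler shift likewise, which keeps membrane potentials positive without
#' altering the represented posterior.
#'
#' @param gsm A [gsm_model()].
#' @param b Numeric offset vector (length \code{n_features}).
#' @return A shifted \code{"gsm"} object.
#' @export
apply_offset <- function(gsm, b) {
  stopifnot(inherits(gsm, "gsm"), length(b) == gsm$n_features, all(is.finite(b)))
  out <- gsm
  out$b <- gsm$b + b
  out
}

#' Draw a stimulus from the generative model
#'
#' Samples \code{u_gen ~ N(b, C)} and an image \code{x ~ N(z_gen * A %*%
#' (u_gen - b), sigma_x_sq * I)}. With \code{z_gen = 0} this produces the
#' blank ("no stimulus") input used before stimulus onset.
#'
#' @param gsm A [gsm_model()].
#' @param z_gen Generative contrast (nonnegative scalar).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class \code{"gsm_stimulus"}: list with \code{x},
#'   \code{u_gen}, \code{z_gen}, \code{seed}.
#' @export
#' @examples
#' gsm <- gsm_model(build_gabor_bank(gabor_bank_spec()))
#' stim <- sample_stimulus(gsm, z_gen = 1, seed = 7)
#' length(stim$x)
sample_stimulus <- function(gsm, z_gen, seed = NULL) {
  stopifnot(inherits(gsm, "gsm"), z_gen >= 0)
  if (!is.null(seed)) set.seed(seed)
  draw <- drop(rmvn_chol(1, gsm$C))
  u_gen <- gsm$b + draw
  x <- z_gen * drop(gsm$A %*% draw) +
    sqrt(gsm$sigma_x_sq) * stats::rnorm(gsm$n_pixels)
  structure(
    list(x = x, u_gen = u_gen, z_gen = z_gen, seed = seed),
    class = "gsm_stimulus"
  )
}

#' @export
print.gsm_stimulus <- function(x, ...) {
  cat(sprintf(
    "GSM stimulus: %d pixels, z_gen = %.3g, rms grey level %.3g\n",
    length(x$x), x$z_gen, sqrt(mean(x$x^2))
  ))
  invisible(x)
}

#' Exact conditional posterior of the feature intensities
#'
#' For a fixed contrast \code{z}, the posterior of \code{u} given an image
#' \code{x} is Gaussian with covariance
#' \code{Sigma(z) = solve(C_inv + (z^2 / sigma_x_sq) * gram)} and mean
#' \code{(z / sigma_x_sq) * Sigma(z) %*% t(A) %*% x} (plus the prior-mean
#' offset). The covariance shrinks monotonically (in the Loewner order) as
#' \code{z} grows: more contrast means more evidence.
#'
#' @param gsm A [gsm_model()].
#' @param x Image vector (pixels).
#' @param z Conditioning contrast (nonnegative scalar).
#' @return Object of class \code{"gsm_posterior"}: list with \code{mean},
#'   \code{cov}, \code{precision}, \code{z}.
#' @export
#' @examples
#' gsm <- gsm_model(matrix(1), sigma_x_sq = 0.1)  # 1-D model
#' post <- posterior_u(gsm, x = 1, z = 1)
#' c(post$mean, post$cov)  # 0.9, 0.09
posterior_u <- function(gsm, x, z) {
  stopifnot(inherits(gsm, "gsm"), z >= 0, length(x) == gsm$n_pixels)
  precision <- gsm$C_inv + (z^2 / gsm$sigma_x_sq) * gsm$gram
  precision <- (precision + t(precision)) / 2
  cov <- solve_spd(precision, "posterior precision")
  cov <- (cov + t(cov)) / 2
  mean <- gsm$b + drop((z / gsm$sigma_x_sq) * cov %*% crossprod(gsm$A, x))
  structure(
    list(mean = mean, cov = cov, precision = precision, z = z),
    class = "gsm_posterior"
  )
}

#' @export
print.gsm_posterior <- function(x, ...) {
  cat(sprintf(
    "GSM conditional posterior at z = %.3g: %d dimensions\n",
    x$z, length(x$mean)
  ))
  cat(sprintf(
    "  |mean| = %.3g, mean variance = %.3g\n",
    sqrt(sum(x$mean^2)), mean(diag(x$cov))
  ))
  invisible(x)
}

#' Input current to the excitatory population
#'
#' The gradient of the log-posterior of \code{u}, delivered to the network as
#' an external (prediction-error) current:
#' \code{(z / sigma_x_sq) * t(A) %*% (x - z * A %*% u) - C_inv %*% u}
#' (written here for the zero-offset model; the offset shifts \code{u}).
#' Algebraically this equals \code{precision %*% (mean - u)} of the
#' conditional posterior, so it vanishes exactly at the posterior mean.
#'
#' @param gsm A [gsm_model()].
#' @param u Feature-intensity (excitatory membrane potential) vector.
#' @param z Contrast at which the gradient is evaluated.
#' @param x Image vector.
#' @return Numeric vector of currents, one per excitatory cell.
#' @export
input_current <- function(gsm, u, z, x) {
  stopifnot(inherits(gsm, "gsm"), length(u) == gsm$n_features,
            length(x) == gsm$n_pixels)
  u0 <- u - gsm$b
  drop((z / gsm$sigma_x_sq) * crossprod(gsm$A, x - z * (gsm$A %*% u0)) -
         gsm$C_inv %*% u0)
}

#' Input current to the contrast subsystem
#'
#' Gradient of the joint log-density with respect to the contrast variable:
#' \code{(1 / sigma_x_sq) * sum((A %*% u) * (x - z * A %*% u)) - z}, where
#' the final \code{-z} is the half-normal prior pull (the truncation at zero
#' is enforced by the reflecting boundary of the dynamics, not here).
#'
#' @inheritParams input_current
#' @return Scalar current driving the contrast unit.
#' @export
z_input_current <- function(gsm, u, z, x) {
  stopifnot(inherits(gsm, "gsm"), length(u) == gsm$n_features,
            length(x) == gsm$n_pixels)
  Au <- drop(gsm$A %*% (u - gsm$b))
  sum(Au * (x - z * Au)) / gsm$sigma_x_sq - z
}

#' Joint log-density (negative energy) of the sampler state
#'
#' Returns \code{log P(u | x, z) + log N(v; B u, M^-1)} up to additive
#' constants (sufficient for energy-conservation and autocorrelation
#' diagnostics). The u-part is evaluated through the generative densities,
#' \code{-||x - z A u||^2 / (2 sigma_x_sq) - u' C_inv u / 2}, whose gradient
#' is exactly [input_current()].
#'
#' @param net An [ei_network()].
#' @param u,v Excitatory and inhibitory membrane potential vectors.
#' @param z Contrast at which the density is evaluated.
#' @param x Image vector.
#' @return Scalar log-density (up to an additive constant).
#' @export
log_joint <- function(net, u, v, z, x) {
  stopifnot(inherits(net, "ei_network"))
  gsm <- net$gsm
  u0 <- u - gsm$b
  resid <- x - z * drop(gsm$A %*% u0)
  vres <- v - drop(net$B %*% u)
  -sum(resid^2) / (2 * gsm$sigma_x_sq) -
    drop(crossprod(u0, gsm$C_inv %*% u0)) / 2 -
    drop(crossprod(vres, net$M %*% vres)) / 2
}

# Draw n rows from N(0, S) via the Cholesky factor.
rmvn_chol <- function(n, S) {
  d <- nrow(S)
  matrix(stats::rnorm(n * d), n, d) %*% chol(S)
}
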