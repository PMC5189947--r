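#' Excitatory-inhibitory sampling network
#'
#' Assembles the full parameter set of the stochastic sampler that draws from
#' the GSM posterior: the auxiliary coupling \code{B} (identity), the clipped
#' mass matrix \code{M}, the four recurrent weight matrices, the scalar
#' weights of the contrast subsystem (\code{B = M = 1}), and the noise level
#' \code{rho^2 = 2 / tau_L}. All weights are elementwise nonnegative (Dale's
#' law), which is verified on construction.
#'
#' @param gsm A [gsm_model()].
#' @param tau Membrane time constant in seconds (default 10 ms), governing
#'   the recurrent excitatory-inhibitory loop and hence the oscillation
#'   timescale.
#' @param tau_L Langevin time constant in seconds (default 150 ms), the rate
#'   at which noise is injected; equivalently \code{rho^2 = 2 / tau_L}.
#' @return Object of class \code{"ei_network"} bundling the model, the
#'   matrices and the time constants.
#' @export
#' @examples
#' net <- ei_network(gsm_model(build_gabor_bank(gabor_bank_spec())))
#' net
ei_network <- function(gsm, tau = 0.010, tau_L = 0.150) {
  stopifnot(inherits(gsm, "gsm"), tau > 0, tau_L > 0)
  if (tau >= tau_L) stop("tau must be smaller than tau_L")
  n <- gsm$n_features
  B <- diag(n)
  M <- build_mass_matrix(gsm$A)
  W <- build_weights(M, B, tau, tau_L)
  zW <- build_weights(1, 1, tau, tau_L)
  structure(
    list(
      gsm = gsm,
      tau = tau,
      tau_L = tau_L,
      rho_sq = 2 / tau_L,
      B = B,
      M = M,
      M_inv = solve_spd(M, "mass matrix"),
      W_uu = W$W_uu, W_uv = W$W_uv, W_vu = W$W_vu, W_vv = W$W_vv,
      z_weights = c(
        W_zz = zW$W_uu[1, 1], W_zv = zW$W_uv[1, 1],
        W_vz = zW$W_vu[1, 1], W_vv = zW$W_vv[1, 1]
      ),
      n = n
    ),
    class = "ei_network"
  )
}

#' @export
print.ei_network <- function(x, ...) {
  cat("Excitatory-inhibitory sampling network\n")
  cat(sprintf(
    "  %d excitatory + %d inhibitory cells + contrast subsystem\n", x$n, x$n
  ))
  cat(sprintf(
    "  tau = %.3g ms, tau_L = %.3g ms (rho^2 = %.3g /s)\n",
    1000 * x$tau, 1000 * x$tau_L, x$rho_sq
  ))
  cat(sprintf(
    "  weights nonnegative: %s; mass matrix PD: %s\n",
    all(x$W_uu >= 0, x$W_uv >= 0, x$W_vu >= 0, x$W_vv >= 0),
    min(eigen(x$M, symmetric = TRUE, only.values = TRUE)$values) > 0
  ))
  invisible(x)
}

#' @export
summary.ei_network <- function(object, ...) {
  ev_gram <- eigen(object$gsm$gram, symmetric = TRUE, only.values = TRUE)$values
  ev_M <- eigen(object$M, symmetric = TRUE, only.values = TRUE)$values
  out <- list(
    n = object$n,
    tau = object$tau,
    tau_L = object$tau_L,
    rho_sq = object$rho_sq,
    sigma_x_sq = object$gsm$sigma_x_sq,
    gram_eigen_range = range(ev_gram),
    gram_eigen_spread = max(ev_gram) / min(ev_gram),
    mass_eigen_range = range(ev_M),
    predicted_freq = vapply(
      c(0.5, 1, 2),
      function(z) oscillation_frequency(z, object$tau, object$gsm$sigma_x_sq),
      numeric(1)
    )
  )
  class(out) <- "summary.ei_network"
  out
}

#' @export
print.summary.ei_network <- function(x, ...) {
  cat("EI sampling network summary\n")
  cat(sprintf("  cells per population     : %d\n", x$n))
  cat(sprintf("  tau / tau_L              : %.3g ms / %.3g ms (ratio %.3g)\n",
              1000 * x$tau, 1000 * x$tau_L, x$tau_L / x$tau))
  cat(sprintf("  rho^2                    : %.3g /s\n", x$rho_sq))
  cat(sprintf("  sigma_x^2                : %.3g\n", x$sigma_x_sq))
  cat(sprintf("  eigenvalues of t(A) A    : [%.3g, %.3g] (spread %.2f)\n",
              x$gram_eigen_range[1], x$gram_eigen_range[2],
              x$gram_eigen_spread))
  cat(sprintf("  predicted LFP peaks (Hz) : %s at z = 0.5, 1, 2\n",
              paste(sprintf("%.1f", x$predicted_freq), collapse = ", ")))
  invisible(x)
}

#' Default sampling network
#'
#' Convenience constructor wiring together the default 15-filter Gabor bank,
#' the GSM model and the EI network at the standard operating point
#' (tau = 10 ms, tau_L = 150 ms, sigma_x^2 = 0.1).
#'
#' @param image_side Pixels per image side for the Gabor raster.
#' @param sigma_x_sq Observation noise variance.
#' @param tau,tau_L Time constants in seconds.
#' @return An [ei_network()].
#' @export
default_network <- function(image_side = 24, sigma_x_sq = 0.1,
                            tau = 0.010, tau_L = 0.150) {
  spec <- gabor_bank_spec(image_side = image_side)
  A <- build_gabor_bank(spec, sigma_x_sq = sigma_x_sq)
  ei_network(gsm_model(A, sigma_x_sq = sigma_x_sq), tau = tau, tau_L = tau_L)
}

#' Write or read a network configuration
#'
#' Serialises the scalar configuration of a network (time constants in
#' milliseconds, noise variance, image geometry) as a flat YAML mapping; all
#' matrices are rebuilt deterministically from these scalars on read, so a
#' round trip reproduces the network exactly.
#'
#' @param net An [ei_network()] built by [default_network()] (i.e. whose
#'   basis carries its [gabor_bank_spec()]).
#' @param path File path for the YAML configuration.
#' @return \code{write_network_config} returns \code{path} invisibly;
#'   \code{read_network_config} returns the reconstructed [ei_network()].
#' @export
write_network_config <- function(net, path) {
  stopifnot(inherits(net, "ei_network"))
  spec <- attr(net$gsm$A, "spec")
  if (is.null(spec)) {
    stop("network basis carries no Gabor spec; cannot serialise to config")
  }
  cfg <- list(
    image_side = spec$image_side,
    n_orientations = length(spec$orientations),
    n_locations = nrow(spec$locations),
    minor_axis_sd = spec$minor_axis_sd,
    major_axis_min = min(spec$major_axis_sds),
    major_axis_max = max(spec$major_axis_sds),
    wavelength = spec$wavelength,
    sigma_x_sq = net$gsm$sigma_x_sq,
    tau_ms = 1000 * net$tau,
    tau_L_ms = 1000 * net$tau_L
  )
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_network_config
#' @export
read_network_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  default_network(
    image_side = cfg$image_side,
    sigma_x_sq = cfg$sigma_x_sq,
    tau = cfg$tau_ms / 1000,
    tau_L = cfg$tau_L_ms / 1000
  )
}

#' Export a network matrix as CSV
#'
#' @param net An [ei_network()].
#' @param which One of \code{"A"}, \code{"C"}, \code{"M"}, \code{"W_uu"},
#'   \code{"W_uv"}, \code{"W_vu"}, \code{"W_vv"}.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
export_matrix <- function(net, which, path) {
  stopifnot(inherits(net, "ei_network"))
  mats <- list(
    A = net$gsm$A, C = net$gsm$C, M = net$M,
    W_uu = net$W_uu, W_uv = net$W_uv, W_vu = net$W_vu, W_vv = net$W_vv
  )
  which <- match.arg(which, names(mats))
  utils::write.csv(mats[[which]], path, row.names = FALSE)
  invisible(path)
}
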