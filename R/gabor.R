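#' Specify a bank of Gabor filters
#'
#' Describes the geometry of an undercomplete Gabor filter bank used as the
#' feature basis \code{A} of the Gaussian scale mixture image model. The
#' default bank has 15 filters: three orientations (0, pi/3, 2pi/3) at each of
#' five locations (the image centre and the four points 1/6 of an image width
#' in from the corners). All geometric quantities are expressed in units of
#' the image width, with the image occupying the unit square.
#'
#' The Gaussian envelope of every filter has a minor-axis standard deviation
#' of 0.1 image widths; the major-axis standard deviations span 0.1 to 0.5
#' image widths. By default they are assigned as a deterministic, evenly
#' spaced sequence over that interval (one value per filter), which keeps the
#' construction fully reproducible; \code{major_axis = "random"} instead draws
#' them uniformly (seeded). The carrier sinusoid has wavelength 0.13 image
#' widths and, by default, even (cosine) phase. The envelope's major axis lies
#' along the wave front, perpendicular to the wave vector.
#'
#' @param image_side Number of pixels along one side of the square image
#'   raster.
#' @param orientations Filter orientations in radians.
#' @param locations Two-column matrix of envelope centres in image-width
#'   units; rows must lie inside the unit square.
#' @param minor_axis_sd Envelope standard deviation along the wave vector
#'   (image widths).
#' @param major_axis_range Range spanned by the envelope standard deviations
#'   along the wave front (image widths).
#' @param wavelength Carrier wavelength (image widths).
#' @param phase Carrier phase in radians; 0 gives even-symmetric filters.
#' @param major_axis Either \code{"even"} (deterministic evenly spaced
#'   sequence, the default) or \code{"random"} (seeded uniform draws).
#' @param seed Seed used when \code{major_axis = "random"}.
#'
#' @return An object of class \code{"gabor_bank_spec"}.
#' @seealso [build_gabor_bank()]
#' @export
#' @examples
#' spec <- gabor_bank_spec()
#' spec$n_filters
gabor_bank_spec <- function(image_side = 24,
                            orientations = c(0, pi / 3, 2 * pi / 3),
                            locations = rbind(
                              centre = c(1 / 2, 1 / 2),
                              sw = c(1 / 6, 1 / 6),
                              nw = c(1 / 6, 5 / 6),
                              se = c(5 / 6, 1 / 6),
                              ne = c(5 / 6, 5 / 6)
                            ),
                            minor_axis_sd = 0.1,
                            major_axis_range = c(0.1, 0.5),
                            wavelength = 0.13,
                            phase = 0,
                            major_axis = c("even", "random"),
                            seed = 1L) {
  major_axis <- match.arg(major_axis)
  locations <- as.matrix(locations)
  stopifnot(
    image_side >= 2, ncol(locations) == 2,
    all(locations >= 0 & locations <= 1),
    minor_axis_sd > 0, wavelength > 0,
    length(major_axis_range) == 2, all(major_axis_range > 0),
    major_axis_range[1] <= major_axis_range[2]
  )
  n_filters <- nrow(locations) * length(orientations)
  major_axis_sds <- if (major_axis == "even") {
    seq(major_axis_range[1], major_axis_range[2], length.out = n_filters)
  } else {
    set.seed(seed)
    stats::runif(n_filters, major_axis_range[1], major_axis_range[2])
  }
  structure(
    list(
      image_side = as.integer(image_side),
      orientations = orientations,
      locations = locations,
      minor_axis_sd = minor_axis_sd,
      major_axis_sds = major_axis_sds,
      wavelength = wavelength,
      phase = phase,
      n_filters = n_filters
    ),
    class = "gabor_bank_spec"
  )
}

#' @export
print.gabor_bank_spec <- function(x, ...) {
  cat("Gabor filter bank specification\n")
  cat(sprintf("  image raster : %d x %d pixels\n", x$image_side, x$image_side))
  cat(sprintf(
    "  filters      : %d (%d locations x %d orientations)\n",
    x$n_filters, nrow(x$locations), length(x$orientations)
  ))
  cat(sprintf(
    "  envelope sd  : minor %.3g, major %.3g-%.3g image widths\n",
    x$minor_axis_sd, min(x$major_axis_sds), max(x$major_axis_sds)
  ))
  cat(sprintf("  wavelength   : %.3g image widths\n", x$wavelength))
  invisible(x)
}

#' Build the Gabor basis matrix
#'
#' Samples every filter of a [gabor_bank_spec()] on the pixel grid (pixel
#' centres, coordinates in image-width units) and assembles them as the
#' columns of the basis matrix \code{A}, ordered location-major and
#' orientation-minor. The construction is deterministic: the same spec always
#' yields a bit-identical matrix.
#'
#' Individual filters are not normalised (their norms vary with the envelope
#' area), but a single global scale factor calibrates the basis so that the
#' slowest mode of the unit-contrast posterior has unit precision
#' (\code{lambda_min(Sigma(1)^-1) = 1}, see
#' \code{vignette("hamiltonian-sampling")}). With noise injected at rate
#' 2/tau_L on every membrane potential, this makes the slowest stochastic
#' component of the sampler relax with time constant \code{tau_L}, the regime
#' in which the recurrent oscillations run roughly an order of magnitude
#' faster than the shared stochastic component. \code{normalize = "none"}
#' returns the raw filters.
#'
#' @param spec A [gabor_bank_spec()].
#' @param sigma_x_sq Observation noise variance used by the calibration (the
#'   posterior precision depends on it).
#' @param normalize \code{"slowest_mode"} (default) or \code{"none"}.
#' @return A \code{pixels x n_filters} numeric matrix with the spec attached
#'   as attribute \code{"spec"}.
#' @export
#' @examples
#' A <- build_gabor_bank(gabor_bank_spec())
#' dim(A)  # 576 x 15
build_gabor_bank <- function(spec, sigma_x_sq = 0.1,
                             normalize = c("slowest_mode", "none")) {
  stopifnot(inherits(spec, "gabor_bank_spec"), sigma_x_sq > 0, sigma_x_sq < 1)
  normalize <- match.arg(normalize)
  side <- spec$image_side
  px <- (seq_len(side) - 0.5) / side
  grid <- expand.grid(x = px, y = px)
  n <- spec$n_filters
  A <- matrix(0, side * side, n)
  k <- 0L
  for (li in seq_len(nrow(spec$locations))) {
    for (oi in seq_along(spec$orientations)) {
      k <- k + 1L
      theta <- spec$orientations[oi]
      dx <- grid$x - spec$locations[li, 1]
      dy <- grid$y - spec$locations[li, 2]
      along <- cos(theta) * dx + sin(theta) * dy # wave-vector direction
      front <- -sin(theta) * dx + cos(theta) * dy # wave-front direction
      A[, k] <- exp(
        -along^2 / (2 * spec$minor_axis_sd^2) -
          front^2 / (2 * spec$major_axis_sds[k]^2)
      ) * cos(2 * pi * along / spec$wavelength + spec$phase)
    }
  }
  gram <- crossprod(A)
  ev <- eigen(gram, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= .Machine$double.eps * max(ev) * nrow(A)) {
    stop("degenerate basis: t(A) %*% A is numerically singular")
  }
  if (normalize == "slowest_mode") {
    K <- 1 - sigma_x_sq
    target <- 1 / (1 / K + 1 / sigma_x_sq) # lambda_min(G) giving unit precision
    A <- A * sqrt(target / min(ev))
  }
  attr(A, "spec") <- spec
  A
}
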