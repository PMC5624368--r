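#' Six-parameter gamut generator settings
#'
#' Locations and widths of the independent normal opponent deviates
#' (lambda, theta, xi) that drive [sample_gamut()]. A fitted
#' [gamut_signature()] can be passed anywhere a `gamut_params` is expected.
#'
#' @param mu_lambda,mu_theta,mu_xi channel locations.
#' @param sigma_lambda,sigma_theta,sigma_xi channel widths (>= 0).
#' @export
gamut_params <- function(mu_lambda = 0, mu_theta = 0, mu_xi = 0,
                         sigma_lambda = 1, sigma_theta = 0.5, sigma_xi = 0.1) {
  sig <- c(sigma_lambda, sigma_theta, sigma_xi)
  if (any(sig < 0)) stop("sigmas must be non-negative", call. = FALSE)
  structure(list(mu_lambda = mu_lambda, mu_theta = mu_theta, mu_xi = mu_xi,
                 sigma_lambda = sigma_lambda, sigma_theta = sigma_theta,
                 sigma_xi = sigma_xi),
            class = "gamut_params")
}

#' Generate random RGB gamut samples
#'
#' Two-tiered generator: draw independent normal deviates (lambda, theta,
#' xi) in the opponent frame, rotate to physical-domain channel triples with
#' the inverse opponent transform, and squash each channel through the
#' logistic map. All output values are strictly inside (0, 1).
#'
#' @param params a [gamut_params()] or [gamut_signature()].
#' @param n number of samples.
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return n x 3 matrix of RGB values in (0, 1).
#' @examples
#' rgb <- sample_gamut(sublunar_preset(), 1000, seed = 1)
#' gamut_signature(rgb)
#' @export
sample_gamut <- function(params, n, seed = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  local_seed(seed)
  opp <- cbind(stats::rnorm(n, params$mu_lambda, params$sigma_lambda),
               stats::rnorm(n, params$mu_theta, params$sigma_theta),
               stats::rnorm(n, params$mu_xi, params$sigma_xi))
  rgb <- omega(opponent_inverse(opp))
  colnames(rgb) <- c("r", "g", "b")
  rgb
}

#' Preset gamut parameters: typical terrestrial and "alien" gamuts
#'
#' `sublunar_preset()` uses the median opponent spreads observed across
#' natural-image corpora, `(sigma_lambda, sigma_theta, sigma_xi) =
#' (1.07, 0.47, 0.13)`, all locations zero (cameras white-balance the
#' locations away). It produces the typical terrestrial gamut: highly
#' correlated RGB channels, mostly grays with red-blue and slight
#' green-purple variation.
#'
#' `alien_preset()` uses roughly equal spreads `(pi/6, pi sqrt(6)/12,
#' pi sqrt(2)/8)`, approximately (0.524, 0.641, 0.555). These are the unique
#' widths for which the physical-domain channels come out exactly
#' independent with equal variance (the inverse opponent transform is not
#' orthogonal, so naively equal opponent widths would leave an 18% red-blue
#' correlation), and that common variance equals `pi^2/12`, the variance of
#' the logistic distribution of scale 1/2 underlying [omega()]. The
#' push-forward of each channel is then approximately uniform: RGB
#' histograms are nearly flat, the covariance is essentially proportional
#' to the identity, and the samples look garish and unnatural - saturated
#' greens and purples included.
#'
#' @return A [gamut_params()].
#' @export
sublunar_preset <- function() {
  gamut_params(sigma_lambda = 1.07, sigma_theta = 0.47, sigma_xi = 0.13)
}

#' @rdname sublunar_preset
#' @export
alien_preset <- function() {
  s <- pi / 6  # physical channels iid N(0, pi^2/12): see the roxygen note
  gamut_params(sigma_lambda = s, sigma_theta = s * sqrt(3 / 2),
               sigma_xi = s * 3 / (2 * sqrt(2)))
}

#' Render gamut samples as a swatch image
#'
#' Fills a grid of square cells row-major with the given colors and returns
#' an 8-bit image array. Quantization follows the package byte convention
#' `v -> round(256 v - 0.5)` clipped to 0..255, the inverse of the
#' [read_image()] mapping, so a render/ingest round trip moves each channel
#' by at most 1/256.
#'
#' @param samples n x 3 RGB values in (0, 1).
#' @param ncol,nrow grid dimensions in cells (`ncol * nrow <= n`).
#' @param cell cell side in pixels.
#' @param path optional PNG output path.
#' @return Invisibly, the image as an H x W x 3 array of bytes stored as
#'   integers 0..255.
#' @export
render_swatch <- function(samples, ncol, nrow, cell = 8L, path = NULL) {
  samples <- as.matrix(samples)
  if (nrow(samples) < ncol * nrow)
    stop(sprintf("need %d samples to fill a %d x %d grid, got %d",
                 ncol * nrow, nrow, ncol, nrow(samples)), call. = FALSE)
  bytes <- pmin(pmax(round(256 * samples - 0.5), 0), 255)
  img <- array(0L, dim = c(nrow * cell, ncol * cell, 3L))
  k <- 1L
  for (i in seq_len(nrow)) {
    for (j in seq_len(ncol)) {
      rows <- ((i - 1L) * cell + 1L):(i * cell)
      cols <- ((j - 1L) * cell + 1L):(j * cell)
      for (ch in 1:3) img[rows, cols, ch] <- bytes[k, ch]
      k <- k + 1L
    }
  }
  if (!is.null(path)) png::writePNG((img + 0.0) / 255, target = path)
  invisible(img)
}

#' Robustness of the covariance structure under display distortions
#'
#' Simulates what uncalibrated display or web processing does to channel
#' statistics. "True" RGB samples are produced by squashing Gaussian
#' physical-domain triples with the given mean and covariance through the
#' logistic map. Each distortion draw applies an independent per-channel
#' gain A and gamma exponent, `v -> (A v)^gamma`, clips to the clamp range,
#' and records the Pearson correlation between distorted and true values in
#' each channel. The correlations are pooled over channels (three per draw)
#' and summarized by their median and quartiles.
#'
#' @param cov_physical 3x3 positive-semidefinite physical-domain covariance.
#' @param means length-3 physical-domain means.
#' @param gamma_range,gain_range uniform sampling intervals for the
#'   per-channel gamma and gain.
#' @param n_draws number of distortion draws.
#' @param n_samples number of RGB samples.
#' @param seed optional integer seed.
#' @param delta clip margin after distortion (the ingestion clamp).
#' @return A list with `median`, `q1`, `q3` and the pooled `correlations`
#'   (length `3 * n_draws`).
#' @export
distortion_experiment <- function(cov_physical, means = c(0, 0, 0),
                                  gamma_range = c(0.5, 1.5),
                                  gain_range = c(0.5, 1.5),
                                  n_draws = 1000L, n_samples = 10000L,
                                  seed = NULL, delta = 1 / 512) {
  C <- as.matrix(cov_physical)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev))))
    stop("cov_physical must be positive semidefinite", call. = FALSE)
  if (any(gamma_range <= 0) || any(gain_range <= 0))
    stop("gamma and gain ranges must be positive", call. = FALSE)
  local_seed(seed)
  L <- chol(C + diag(1e-12, 3))
  phys <- sweep(matrix(stats::rnorm(3 * n_samples), ncol = 3) %*% L, 2, means, "+")
  true <- omega(phys)
  cors <- matrix(NA_real_, 3L, n_draws)
  for (d in seq_len(n_draws)) {
    gam <- stats::runif(3, gamma_range[1], gamma_range[2])
    amp <- stats::runif(3, gain_range[1], gain_range[2])
    for (ch in 1:3) {
      v <- clamp_observation((amp[ch] * true[, ch])^gam[ch], delta)
      cors[ch, d] <- stats::cor(v, true[, ch])
    }
  }
  q <- stats::quantile(cors, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], correlations = as.numeric(cors))
}
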