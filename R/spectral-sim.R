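#' Settings of the toy reflectance-spectrum model
#'
#' Random reflectance spectra are modelled as a stationary Gaussian
#' articulation process with a Lorentzian (1/f^2) power spectrum, squashed
#' into (0, 1) by the logistic map: `R(l) = omega(shift + scale * g(l))`.
#'
#' @param tau correlation length of the articulation, in units of the
#'   visible-range width (1 = the whole window; the three RGB bins each
#'   have width 1/3).
#' @param shift location of the articulation (0 = mid-gray spectra).
#' @param scale articulation amplitude (>= 0); large values drive the
#'   spectra towards binary, telegraph-wave-like profiles.
#' @param n_wavelengths grid size, divisible by 3 (default 96).
#' @param seed optional integer seed used by the sampling operations.
#' @export
spectral_params <- function(tau = 1 / 3, shift = 0, scale = 1,
                            n_wavelengths = 96L, seed = NULL) {
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (scale < 0) stop("scale must be non-negative", call. = FALSE)
  n_wavelengths <- as.integer(n_wavelengths)
  if (n_wavelengths < 6L || n_wavelengths %% 3L != 0L)
    stop("n_wavelengths must be a multiple of 3 (and at least 6)", call. = FALSE)
  structure(list(tau = tau, shift = shift, scale = scale,
                 n_wavelengths = n_wavelengths, seed = seed),
            class = "spectral_params")
}

# Spectral synthesis of the articulation process: random phases with a
# Lorentzian amplitude filter S(f) = 1/(f^2 + fc^2), fc = 1/(2 pi tau), on a
# periodic domain `pad` times longer than the visible window (so the window
# is a proper excerpt of a stationary process, not forced to one period),
# inverse FFT, crop, and divide by the theoretical standard deviation.
synthesize_articulation <- function(tau, n, m, pad = 8L) {
  N <- n * pad
  f <- (0:(N / 2)) / pad           # cycles per visible-range width
  fc <- 1 / (2 * pi * tau)
  S <- 1 / (f^2 + fc^2)
  S[1] <- 0                        # zero-mean process
  sd_theory <- sqrt(2 * sum(S[2:(N / 2)]) + S[N / 2 + 1])
  out <- matrix(NA_real_, m, n)
  done <- 0L
  while (done < m) {               # chunked so z stays modest in memory
    mc <- min(512L, m - done)
    a <- matrix(stats::rnorm((N / 2 + 1) * mc), N / 2 + 1, mc)
    b <- matrix(stats::rnorm((N / 2 + 1) * mc), N / 2 + 1, mc)
    z <- complex(real = a, imaginary = b) * sqrt(S / 2)
    dim(z) <- dim(a)
    z[1, ] <- 0
    z[N / 2 + 1, ] <- complex(real = a[N / 2 + 1, ]) * sqrt(S[N / 2 + 1])
    full <- rbind(z, Conj(z[(N / 2):2, , drop = FALSE]))
    g <- Re(stats::mvfft(full, inverse = TRUE))
    out[done + seq_len(mc), ] <- t(g[seq_len(n), , drop = FALSE])
    done <- done + mc
  }
  out / sd_theory
}

#' Sample the standardized articulation process
#'
#' Returns raw Gaussian articulation samples (before shift, scale and the
#' sigmoid), one spectrum per row, standardized to zero mean and unit
#' variance. Exposed mainly so the process statistics (autocorrelation,
#' spectral slope) can be examined directly.
#'
#' @param params a [spectral_params()].
#' @param n number of spectra.
#' @param seed optional seed (defaults to `params$seed`).
#' @return n x n_wavelengths matrix.
#' @export
sample_articulation <- function(params, n = 1L, seed = params$seed) {
  local_seed(seed)
  synthesize_articulation(params$tau, params$n_wavelengths, n)
}

#' Sample random reflectance spectra
#'
#' @inheritParams sample_articulation
#' @return `sample_spectra`: n x n_wavelengths matrix of reflectances in
#'   (0, 1); `sample_spectrum`: a single spectrum as a vector.
#' @export
sample_spectra <- function(params, n = 1L, seed = params$seed) {
  g <- sample_articulation(params, n, seed)
  omega(params$shift + params$scale * g)
}

#' @rdname sample_spectra
#' @export
sample_spectrum <- function(params, seed = params$seed) {
  drop(sample_spectra(params, 1L, seed))
}

#' Bin spectra into RGB triples
#'
#' Hyperspectral imaging with three bins: the mean reflectance over each
#' third of the wavelength grid (equal-width stand-ins for the
#' parts-of-daylight bands). The first third is reported as the first
#' channel.
#'
#' @param spectrum a spectrum vector or an n x m matrix of spectra
#'   (m divisible by 3).
#' @return A length-3 vector, or an n x 3 matrix.
#' @export
bin_rgb <- function(spectrum) {
  m <- if (is.matrix(spectrum)) ncol(spectrum) else length(spectrum)
  if (m %% 3L != 0L) stop("grid size must be divisible by 3", call. = FALSE)
  k <- m / 3L
  if (!is.matrix(spectrum)) spectrum <- matrix(spectrum, nrow = 1L)
  out <- cbind(rowMeans(spectrum[, 1:k, drop = FALSE]),
               rowMeans(spectrum[, (k + 1L):(2L * k), drop = FALSE]),
               rowMeans(spectrum[, (2L * k + 1L):m, drop = FALSE]))
  colnames(out) <- c("r", "g", "b")
  if (nrow(out) == 1L) drop(out) else out
}

#' Ensemble statistics of the toy spectral model
#'
#' Draws `n` spectra, bins them to RGB, and summarizes the physical-domain
#' covariance. For tau of the order of the bin width this reproduces the
#' expected channel covariance structure: nearest-bin correlations nearly
#' equal, the widest separation least correlated, the dominant eigenvector
#' achromatic and Z well above 1.
#'
#' @inheritParams sample_articulation
#' @param n number of spectra (>= 100).
#' @return A list with the `rgb` samples, the physical-domain `summary`
#'   (a `cov_summary`) and `eps = c(eps1, eps2, eps3)` from the
#'   physical-domain correlation matrix.
#' @export
model_ensemble <- function(params, n, seed = params$seed) {
  if (n < 100L) stop("n must be at least 100", call. = FALSE)
  rgb <- bin_rgb(sample_spectra(params, n, seed))
  phys <- to_physical(rgb)
  s <- summarize_triples(phys)
  cr <- stats::cov2cor(s$cov)
  list(rgb = rgb, summary = s,
       eps = c(eps1 = 1 - cr[1, 2], eps2 = 1 - cr[1, 3], eps3 = 1 - cr[2, 3]))
}

# the 12 edges of the RGB cube, as corner-index pairs; the first six are the
# boundary-color ("Goethe") edges reachable by a spectrum with a single
# light-dark transition: black-red, red-yellow, yellow-white, white-cyan,
# cyan-blue, blue-black.  The other six all involve green or magenta.
cube_corners <- rbind(black = c(0, 0, 0), red = c(1, 0, 0),
                      yellow = c(1, 1, 0), white = c(1, 1, 1),
                      cyan = c(0, 1, 1), blue = c(0, 0, 1),
                      green = c(0, 1, 0), magenta = c(1, 0, 1))
cube_edges <- list(goethe = list(c("black", "red"), c("red", "yellow"),
                                 c("yellow", "white"), c("white", "cyan"),
                                 c("cyan", "blue"), c("blue", "black")),
                   other = list(c("green", "yellow"), c("green", "cyan"),
                                c("green", "black"), c("magenta", "red"),
                                c("magenta", "blue"), c("magenta", "white")))

# distance from each row of pts to the segment a-b
dist_to_edge <- function(pts, a, b) {
  ab <- b - a
  t <- pmin(pmax((sweep(pts, 2, a) %*% ab) / sum(ab^2), 0), 1)
  foot <- sweep(t %*% t(ab), 2, a, "+")
  sqrt(rowSums((pts - foot)^2))
}

#' Telegraph-wave limit: Goethe's edge colors
#'
#' In the large-amplitude limit the model's spectra degenerate to random
#' telegraph waves: binary profiles switching between the two saturated
#' reflectance levels. This check simulates that limit directly as a
#' two-state Markov (telegraph) process with Poisson switching at rate
#' `1/(2 tau)` -- which has exactly the model's Lorentzian 1/f^2 power
#' spectrum -- bins the spectra to RGB, and classifies each sample by its
#' distance to the twelve edges of the RGB cube. Spectra whose transitions
#' all fall in one wavelength bin land on one of the six boundary-color
#' (Goethe) edges; no spectrum with a single transition can reach the six
#' green/magenta edges. With `tau = 1` the expected number of transitions
#' per window is 1/2, so about nine in ten samples lie on a Goethe edge.
#'
#' @param params a [spectral_params()] with `scale >= 5` (the near-binary
#'   regime; the saturated levels are `omega(shift +- scale)`).
#' @param n number of spectra.
#' @param edge_tol distance tolerance to count a sample as "on" an edge.
#' @param seed optional seed.
#' @return A list with `fraction_goethe`, `fraction_other` (samples within
#'   tolerance of a green/magenta edge but not of a Goethe edge),
#'   `edge_counts` (named, all twelve edges) and the `rgb` samples.
#' @export
telegraph_limit_check <- function(params, n, edge_tol = 0.05,
                                  seed = params$seed) {
  if (params$scale < 5)
    stop("telegraph limit needs scale >= 5 (near-binary spectra)", call. = FALSE)
  local_seed(seed)
  m <- params$n_wavelengths
  lo <- omega(params$shift - params$scale)
  hi <- omega(params$shift + params$scale)
  p_flip <- 1 - exp(-(1 / m) / (2 * params$tau))
  spectra <- matrix(NA_real_, n, m)
  for (i in seq_len(n)) {
    flips <- stats::runif(m - 1L) < p_flip
    state <- cumsum(c(sample(c(0L, 1L), 1L), flips)) %% 2L
    spectra[i, ] <- ifelse(state == 1L, hi, lo)
  }
  rgb <- bin_rgb(spectra)
  lab <- vapply(c(cube_edges$goethe, cube_edges$other),
                function(e) paste(e, collapse = "-"), character(1))
  d <- vapply(c(cube_edges$goethe, cube_edges$other), function(e)
    dist_to_edge(rgb, cube_corners[e[1], ], cube_corners[e[2], ]),
    numeric(n))
  near <- d < edge_tol
  near_goethe <- rowSums(near[, 1:6, drop = FALSE]) > 0
  near_other <- rowSums(near[, 7:12, drop = FALSE]) > 0 & !near_goethe
  # per-edge counts assign each in-tolerance sample to its nearest edge
  # (corner samples touch several edges; ties resolve to the Goethe list)
  nearest <- apply(d, 1, which.min)
  within <- d[cbind(seq_len(n), nearest)] < edge_tol
  counts <- tabulate(nearest[within], nbins = 12L)
  names(counts) <- lab
  list(fraction_goethe = mean(near_goethe),
       fraction_other = mean(near_other),
       edge_counts = counts,
       rgb = rgb)
}
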