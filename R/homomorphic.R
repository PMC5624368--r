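#' Logistic map between the physical domain and the observation domain
#'
#' `omega()` maps the real line (the "physical domain", where multiplicative
#' physical parameters live on a logarithmic scale) onto the open unit
#' interval (observer channel intensities); `omega_inv()` is its inverse.
#' The pair is `(1 + tanh(x))/2` and `atanh(2y - 1)`: any sigmoid would do in
#' principle, this one is fast and self-inverse to high accuracy.
#'
#' @param x real values.
#' @param y values strictly inside (0, 1); the endpoints are rejected, since
#'   they map to infinity — observation values must be clamped on ingestion
#'   (see [clamp_observation()]).
#' @return `omega`: values in (0, 1); `omega_inv`: real values.
#' @examples
#' omega(0)          # 0.5
#' omega_inv(omega(1.3))
#' @export
omega <- function(x) (1 + tanh(x)) / 2

#' @rdname omega
#' @export
omega_inv <- function(y) {
  if (any(y <= 0 | y >= 1))
    stop("omega_inv needs values strictly inside (0, 1); clamp observations first",
         call. = FALSE)
  atanh(2 * y - 1)
}

#' Clamp observation-domain values away from 0 and 1
#'
#' Ingested intensities are clamped to `[delta, 1 - delta]` so that the
#' inverse logistic map never produces infinities. 8-bit pixels read through
#' [read_image()] can never hit the endpoints by construction; the clamp
#' protects synthetic or distorted data.
#'
#' @param x numeric vector/matrix/array of intensities.
#' @param delta clamp margin, default 1/512 (half of an 8-bit quantization step).
#' @export
clamp_observation <- function(x, delta = 1 / 512) {
  pmin(pmax(x, delta), 1 - delta)
}

#' Transform RGB fields between observation and physical domains
#'
#' Elementwise [omega_inv()] / [omega()]; an instance of homomorphic
#' filtering: statistics are collected in the observation domain but studied
#' in the physical domain, where the generative physics is near-linear and
#' channel marginals are near-normal.
#'
#' @param field numeric matrix (n x 3) or array (H x W x 3) of channel values.
#' @param clamp apply [clamp_observation()] before inverting (default TRUE).
#' @param delta clamp margin.
#' @export
to_physical <- function(field, clamp = TRUE, delta = 1 / 512) {
  if (clamp) field <- clamp_observation(field, delta)
  omega_inv(field)
}

#' @rdname to_physical
#' @export
to_observation <- function(field) omega(field)

#' The opponent-channel transform
#'
#' `opponent_T()` returns the constant matrix taking physical-domain channel
#' triples (rho, chi, beta) to opponent coordinates: Lambda (white-black, the
#' channel mean), Theta (red-blue, the first difference) and Xi
#' (green-purple, the second difference). `opponent_T_inv()` is its exact
#' matrix inverse.
#'
#' @return A 3x3 numeric matrix.
#' @export
opponent_T <- function() {
  matrix(c(4, 4, 4,
           6, 0, -6,
           -3, 6, -3) / 12,
         nrow = 3, byrow = TRUE,
         dimnames = list(c("Lambda", "Theta", "Xi"), c("rho", "chi", "beta")))
}

#' @rdname opponent_T
#' @export
opponent_T_inv <- function() {
  matrix(c(3, 3, -2,
           3, 0, 4,
           3, -3, -2) / 3,
         nrow = 3, byrow = TRUE,
         dimnames = list(c("rho", "chi", "beta"), c("Lambda", "Theta", "Xi")))
}

#' Map physical-domain triples to opponent channels and back
#'
#' Row-wise matrix multiplication by [opponent_T()] (forward) or
#' [opponent_T_inv()] (inverse). Accepts an n x 3 matrix or an H x W x 3
#' array; the shape is preserved.
#'
#' @param field physical-domain (forward) or opponent-domain (inverse) values.
#' @export
opponent_forward <- function(field) apply_matrix3(field, opponent_T())

#' @rdname opponent_forward
#' @export
opponent_inverse <- function(field) apply_matrix3(field, opponent_T_inv())

# multiply the 3-channel last dimension of a matrix/array by M
apply_matrix3 <- function(field, M) {
  d <- dim(field)
  if (is.null(d) && length(field) == 3L) return(drop(M %*% field))
  if (length(d) == 2L && d[2] == 3L) {
    out <- field %*% t(M)
    colnames(out) <- rownames(M)
    return(out)
  }
  if (length(d) == 3L && d[3] == 3L) {
    flat <- matrix(field, ncol = 3L) %*% t(M)
    return(array(flat, dim = d))
  }
  stop("expected a length-3 vector, n x 3 matrix, or H x W x 3 array",
       call. = FALSE)
}

#' Kubelka-Munk reflectance of an infinitely thick turbid layer
#'
#' For a layer with specific absorption K and scattering S, the diffuse
#' reflectance of the infinitely thick layer satisfies
#' `(1 - R)^2 / (2 R) = xi` with `xi = K/S`. `km_reflectance()` returns the
#' root in (0, 1], `R = 1 + xi - sqrt(xi^2 + 2 xi)`, and `km_xi()` is the
#' exact inverse. The map is monotone decreasing from R(0) = 1 towards 0.
#'
#' @param xi non-negative absorption/scattering ratio K/S.
#' @param R reflectance in (0, 1].
#' @export
km_reflectance <- function(xi) {
  if (any(xi < 0)) stop("xi = K/S must be non-negative", call. = FALSE)
  1 + xi - sqrt(xi^2 + 2 * xi)
}

#' @rdname km_reflectance
#' @export
km_xi <- function(R) {
  if (any(R <= 0 | R > 1)) stop("reflectance must lie in (0, 1]", call. = FALSE)
  (1 - R)^2 / (2 * R)
}

#' Push a log-normal physical prior through the sigmoid
#'
#' Draws `n` log-domain values from Normal(mu, sigma) and maps them through
#' [omega()], the schematic sigmoid of the generalized physics. Depending on
#' (mu, sigma) the resulting reflectance histogram is unimodal, skewed
#' towards 0 or 1, or bimodal with peaks at both ends -- the shapes seen in
#' empirical reflectance data.
#'
#' @param mu,sigma location and width of the physical-domain normal
#'   (sigma > 0).
#' @param n number of draws.
#' @param seed optional integer seed (restores the RNG state on exit).
#' @param bins number of equal-width histogram bins on (0, 1).
#' @return A list with `breaks`, `counts` (summing to `n`) and the raw
#'   `values`.
#' @export
km_histogram <- function(mu, sigma, n, seed = NULL, bins = 50L) {
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  local_seed(seed)
  v <- omega(stats::rnorm(n, mu, sigma))
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE), nbins = bins)
  list(breaks = breaks, counts = counts, values = v)
}

# Seed an operation locally: set the RNG from `seed` and restore the caller's
# RNG state when the calling function exits.  NULL leaves the RNG alone.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  restore <- function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }
  do.call(on.exit,
          list(substitute(f(), list(f = restore)), add = TRUE),
          envir = env)
  set.seed(seed)
  invisible()
}
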