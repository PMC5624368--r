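#' Covariance and eigenstructure summary of channel triples
#'
#' Computes the mean, unbiased covariance, sorted eigendecomposition and the
#' Z statistic (dominant eigenvalue over the sum of the other two) of a
#' sample of channel triples. Eigenvectors are sign-normalized so that their
#' largest-magnitude component is positive; `cov_normalized` rescales the
#' covariance so its largest-magnitude entry equals `normalize_to`, the
#' convention used when quoting such matrices.
#'
#' @param samples n x 3 matrix (or H x W x 3 array) of triples, n >= 4.
#' @param normalize_to 100 or 1000; scale of the quoted covariance.
#' @return An object of class `cov_summary` with fields `mean`, `cov`,
#'   `cov_normalized`, `normalize_to`, `eigenvalues` (descending),
#'   `eigenvectors` (matching columns), `Z` and `n`.
#' @export
summarize_triples <- function(samples, normalize_to = 100) {
  if (length(dim(samples)) == 3L) samples <- matrix(samples, ncol = 3L)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("samples must have 3 columns", call. = FALSE)
  n <- nrow(samples)
  if (n < 4L) stop("need at least 4 triples", call. = FALSE)
  if (!normalize_to %in% c(100, 1000))
    stop("normalize_to must be 100 or 1000", call. = FALSE)
  C <- stats::cov(samples)
  if (max(abs(C)) == 0 || any(!is.finite(C)))
    stop("degenerate input: zero or non-finite variance", call. = FALSE)
  e <- eigen(C, symmetric = TRUE)
  if (e$values[1] <= 0)
    stop("degenerate input: no variance along any direction", call. = FALSE)
  vecs <- e$vectors
  for (j in 1:3) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  Z <- e$values[1] / sum(e$values[2:3])
  structure(list(mean = colMeans(samples),
                 cov = C,
                 cov_normalized = C * normalize_to / max(abs(C)),
                 normalize_to = normalize_to,
                 eigenvalues = e$values,
                 eigenvectors = vecs,
                 Z = Z,
                 n = n),
            class = "cov_summary")
}

#' @export
print.cov_summary <- function(x, ...) {
  cat(sprintf("<cov_summary: n = %d, Z = %.3g>\n", x$n, x$Z))
  cat(sprintf("covariance (scaled to %g):\n", x$normalize_to))
  print(round(x$cov_normalized, 1))
  invisible(x)
}

#' Model covariance of spectrally adjacent channels
#'
#' The covariance structure expected for three spectral bins of a
#' translation-invariant articulation process: unit diagonal, off-diagonal
#' correlations `1 - eps` falling off monotonically with spectral
#' separation. `eps1` couples bands 1-2, `eps2` bands 1-3 (the widest
#' separation, hence typically the largest), `eps3` bands 2-3.
#'
#' @param eps1,eps2,eps3 values in (0, 1).
#' @return A symmetric 3x3 matrix.
#' @export
model_covariance <- function(eps1, eps2, eps3) {
  e <- c(eps1, eps2, eps3)
  if (any(e <= 0 | e >= 1)) stop("all eps must lie in (0, 1)", call. = FALSE)
  matrix(c(1, 1 - eps1, 1 - eps2,
           1 - eps1, 1, 1 - eps3,
           1 - eps2, 1 - eps3, 1), nrow = 3, byrow = TRUE)
}

#' Eigenstructure of the symmetric model covariance
#'
#' For the symmetric special case `eps1 = eps3 = eps`, `eps2 = 2 eps`, the
#' model covariance has `(1, 0, -1)/sqrt(2)` as an exact eigenvector with
#' eigenvalue exactly `2 eps`; as eps -> 0 the normalized eigenvalues tend
#' to (1, 2 eps / 3, 2 eps / 9), so the second and third eigenvalues sit in
#' the fixed ratio 3 and the Z statistic tends to `9 / (8 eps)`.
#'
#' @param eps value in (0, 0.1).
#' @return A list with `cov`, sorted `eigenvalues`, sign-normalized
#'   `eigenvectors` and `Z`.
#' @export
model_eigen <- function(eps) {
  if (eps <= 0 || eps >= 0.1) stop("eps must lie in (0, 0.1)", call. = FALSE)
  C <- model_covariance(eps, 2 * eps, eps)
  e <- eigen(C, symmetric = TRUE)
  vecs <- e$vectors
  for (j in 1:3) {
    k <- which.max(abs(vecs[, j]))
    if (vecs[k, j] < 0) vecs[, j] <- -vecs[, j]
  }
  list(cov = C, eigenvalues = e$values, eigenvectors = vecs,
       Z = e$values[1] / sum(e$values[2:3]))
}

#' Stereographic projection of eigendirections from the white point
#'
#' Projects the three eigendirections of a covariance summary onto the plane
#' orthogonal to the achromatic pole `(1,1,1)/sqrt(3)`, stereographically
#' from the pole's antipode: the pole itself lands at the origin and
#' directions orthogonal to the pole land on the unit circle. Coordinates
#' are expressed in the fiducial opponent axes `(1,0,-1)/sqrt(2)` (x) and
#' `(-1,2,-1)/sqrt(6)` (y), so a red-blue opponent eigenvector plots at
#' (1, 0) and a green-purple one at (0, 1). Eigendirections are axes
#' (sign-ambiguous); each is first flipped into the hemisphere facing the
#' pole, and near-equatorial directions are flipped to a non-negative first
#' coordinate.
#'
#' @param summary a `cov_summary` (or any list with an `eigenvectors`
#'   matrix of unit-norm columns).
#' @return 3 x 2 matrix of projected points (rows follow eigen order).
#' @export
stereographic_frame <- function(summary) {
  V <- summary$eigenvectors
  if (is.null(V) || any(!is.finite(V)) || any(colSums(V^2) < 1e-12))
    stop("invalid eigenvectors", call. = FALSE)
  pole <- c(1, 1, 1) / sqrt(3)
  ax <- c(1, 0, -1) / sqrt(2)
  ay <- c(-1, 2, -1) / sqrt(6)
  out <- matrix(NA_real_, 3, 2, dimnames = list(NULL, c("x", "y")))
  for (j in 1:3) {
    u <- V[, j] / sqrt(sum(V[, j]^2))
    dp <- sum(u * pole)
    if (abs(dp) > 0.5) {
      # polar-ish direction: into the hemisphere facing the pole
      if (dp < 0) u <- -u
    } else {
      # near-equatorial: lexicographically non-negative in the (x, y) axes
      px <- sum(u * ax)
      if (px < -1e-9 || (abs(px) <= 1e-9 && sum(u * ay) < 0)) u <- -u
    }
    dp <- sum(u * pole)
    proj <- (u - dp * pole) / (1 + dp)
    out[j, ] <- c(sum(proj * ax), sum(proj * ay))
  }
  out
}

#' Six-parameter gamut signature of an RGB field
#'
#' Runs the analysis pipeline: clamp, transform to the physical domain,
#' rotate to opponent channels, then take per-channel means and standard
#' deviations. The resulting six numbers are the gamut signature
#' (and the parameter set of [sample_gamut()]).
#'
#' @param field RGB values in (0,1): n x 3 matrix or H x W x 3 array.
#' @param delta ingestion clamp margin.
#' @return An object of class `gamut_signature`: a named list with
#'   `mu_lambda`, `mu_theta`, `mu_xi`, `sigma_lambda`, `sigma_theta`,
#'   `sigma_xi` and `n`.
#' @export
gamut_signature <- function(field, delta = 1 / 512) {
  if (length(dim(field)) == 3L) field <- matrix(field, ncol = 3L)
  opp <- opponent_forward(to_physical(field, delta = delta))
  structure(list(mu_lambda = mean(opp[, 1]),
                 mu_theta = mean(opp[, 2]),
                 mu_xi = mean(opp[, 3]),
                 sigma_lambda = stats::sd(opp[, 1]),
                 sigma_theta = stats::sd(opp[, 2]),
                 sigma_xi = stats::sd(opp[, 3]),
                 n = nrow(opp)),
            class = "gamut_signature")
}

#' @export
print.gamut_signature <- function(x, ...) {
  cat(sprintf(paste0("<gamut_signature: Lambda %.3f+-%.3f, Theta %.3f+-%.3f, ",
                     "Xi %.3f+-%.3f (n = %d)>\n"),
              x$mu_lambda, x$sigma_lambda, x$mu_theta, x$sigma_theta,
              x$mu_xi, x$sigma_xi, x$n))
  invisible(x)
}

#' Power-law fit linking the opponent spreads of many gamuts
#'
#' Across image corpora the green-purple spread tracks the red-blue spread
#' as `sigma_xi = psi * sigma_theta^power` with power close to one. Fitted by
#' ordinary least squares of `log(sigma_xi)` on `log(sigma_theta)`:
#' `power` is the slope and `psi` is `exp(intercept)`. Because the
#' proportionality constant is ambiguous when the power is not exactly one,
#' the slope of the through-origin linear fit of `sigma_xi` on
#' `sigma_theta` is also reported as `psi_linear`.
#'
#' @param signatures list of [gamut_signature()]s (at least 3) with positive
#'   `sigma_theta`, `sigma_xi`.
#' @return An object of class `psi_fit`: list with `psi`, `power`, `r2`,
#'   `psi_linear` and `n`.
#' @export
psi_regression <- function(signatures) {
  if (length(signatures) < 3L)
    stop("need at least 3 signatures", call. = FALSE)
  st <- vapply(signatures, function(s) s$sigma_theta, numeric(1))
  sx <- vapply(signatures, function(s) s$sigma_xi, numeric(1))
  if (any(st <= 0) || any(sx <= 0))
    stop("all signatures need positive sigma_theta and sigma_xi", call. = FALSE)
  if (stats::var(log(st)) == 0)
    stop("degenerate fit: all sigma_theta equal", call. = FALSE)
  fit <- stats::lm(log(sx) ~ log(st))
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((log(sx) - mean(log(sx)))^2)
  structure(list(psi = unname(exp(stats::coef(fit)[1])),
                 power = unname(stats::coef(fit)[2]),
                 r2 = r2,
                 psi_linear = unname(stats::coef(stats::lm(sx ~ st + 0))[1]),
                 n = length(signatures)),
            class = "psi_fit")
}

#' @export
print.psi_fit <- function(x, ...) {
  cat(sprintf("<psi_fit: sigma_xi = %.4f * sigma_theta^%.3f (R2 = %.3f, n = %d)>\n",
              x$psi, x$power, x$r2, x$n))
  invisible(x)
}
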