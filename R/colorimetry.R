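#' Two spectral cuts splitting the visible range into three bands
#'
#' @param cut_low,cut_high cut wavelengths in nm; the three bands are
#'   (range start, `cut_low`), (`cut_low`, `cut_high`), (`cut_high`,
#'   range end).
#' @param range wavelength range being partitioned (checked against cuts).
#' @return An object of class `band_partition`.
#' @export
band_partition <- function(cut_low, cut_high, range = c(380, 700)) {
  if (!(range[1] < cut_low && cut_low < cut_high && cut_high < range[2]))
    stop("need range_min < cut_low < cut_high < range_max", call. = FALSE)
  structure(list(cut_low = cut_low, cut_high = cut_high, range = range),
            class = "band_partition")
}

#' @export
print.band_partition <- function(x, ...) {
  cat(sprintf("<band_partition: cuts %.2f, %.2f nm in (%g, %g)>\n",
              x$cut_low, x$cut_high, x$range[1], x$range[2]))
  invisible(x)
}

# Product integrand illuminant(l) * cmf(l) per column, with its cumulative
# trapezoidal integral; the workhorse shared by band_tristimulus and the cut
# search.  cum(x) evaluates the cumulative integral at arbitrary (fractional)
# wavelengths by splitting the straddling grid interval, which keeps sub-nm
# cut positions exact for the piecewise-linear integrand.
band_integrand <- function(illuminant, cmf) {
  stopifnot(inherits(illuminant, "spectral_table"), inherits(cmf, "spectral_table"))
  if (illuminant$kind != "illuminant" || cmf$kind != "cmf")
    stop("arguments must be an illuminant table and a cmf table", call. = FALSE)
  if (length(illuminant$wavelength) != length(cmf$wavelength) ||
      any(illuminant$wavelength != cmf$wavelength))
    stop("illuminant and cmf must share the same wavelength grid", call. = FALSE)
  wl <- illuminant$wavelength
  w <- illuminant$values[, 1] * cmf$values
  dl <- diff(wl)
  ctz <- apply(w, 2, function(y) {
    cumsum(c(0, dl * (y[-1] + y[-length(y)]) / 2))
  })
  cum <- function(x) {
    i <- findInterval(x, wl, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(wl) - 1L)
    f <- x - wl[i]
    h <- dl[i]
    out <- vapply(1:3, function(j) {
      y0 <- w[i, j]
      slope <- (w[i + 1L, j] - w[i, j]) / h
      ctz[i, j] + f * y0 + f^2 * slope / 2
    }, numeric(length(x)))
    if (length(x) == 1L) matrix(out, nrow = 1L) else out
  }
  list(wavelength = wl, w = w, cum = cum, total = ctz[length(wl), ])
}

#' Band tristimulus vectors of a partitioned illuminant
#'
#' Integrates illuminant times colour-matching functions over each of the
#' three bands of a partition (trapezoid rule on the working grid; cuts
#' falling between grid points split the straddling interval linearly).
#' The columns of the result are the tristimulus vectors of the three
#' spectral bands, and they always sum to the full-range tristimulus
#' of the illuminant.
#'
#' @param illuminant,cmf [spectral_table()]s on a common grid.
#' @param partition a [band_partition()].
#' @return A 3x3 matrix of class `rgb_basis`; columns are the band
#'   tristimulus vectors in band order (short, middle, long wavelengths).
#' @export
band_tristimulus <- function(illuminant, cmf, partition) {
  bi <- band_integrand(illuminant, cmf)
  rng <- range(bi$wavelength)
  if (partition$cut_low <= rng[1] || partition$cut_high >= rng[2])
    stop("cuts fall outside the wavelength grid", call. = FALSE)
  A <- bi$cum(c(partition$cut_low, partition$cut_high))
  m <- cbind(A[1, ], A[2, ] - A[1, ], bi$total - A[2, ])
  rownames(m) <- c("X", "Y", "Z")
  colnames(m) <- c("band1", "band2", "band3")
  structure(m, class = c("rgb_basis", class(m)))
}

#' Per-wavelength generators of the object-color solid
#'
#' The set of tristimulus values of all 0-1 spectral attenuations of an
#' illuminant is a zonotope: the Minkowski sum of the per-interval
#' tristimulus increments of the illuminant. This returns those generators
#' (one per grid interval, trapezoid increments, so they sum to the
#' full-spectrum tristimulus).
#'
#' @inheritParams band_tristimulus
#' @param coarsen integer stride >= 1; a value k > 1 merges runs of k
#'   consecutive intervals into single generators, which changes nothing in
#'   the solid's outline at the resolution of interest but cuts the O(n^3)
#'   volume cost.
#' @return n x 3 matrix of generator vectors.
#' @export
color_solid_generators <- function(illuminant, cmf, coarsen = 1L) {
  bi <- band_integrand(illuminant, cmf)
  g <- apply(bi$w, 2, function(y) {
    dl <- diff(bi$wavelength)
    dl * (y[-1] + y[-length(y)]) / 2
  })
  coarsen <- as.integer(coarsen)
  if (coarsen > 1L) {
    grp <- (seq_len(nrow(g)) - 1L) %/% coarsen
    g <- apply(g, 2, function(col) as.numeric(tapply(col, grp, sum)))
  }
  g
}

#' Volume of a three-dimensional zonotope
#'
#' Standard zonotope volume: the sum of `|det|` over all triples of
#' generators. O(n^3) in the number of generators.
#'
#' @param generators n x 3 matrix, n >= 3.
#' @return The volume (non-negative scalar).
#' @export
zonotope_volume <- function(generators) {
  g <- as.matrix(generators)
  n <- nrow(g)
  if (n < 3L) stop("need at least 3 generators", call. = FALSE)
  idx <- utils::combn(n, 2L)
  # cross products of all pairs, then dot with every third generator k > j
  cx <- cbind(g[idx[1, ], 2] * g[idx[2, ], 3] - g[idx[1, ], 3] * g[idx[2, ], 2],
              g[idx[1, ], 3] * g[idx[2, ], 1] - g[idx[1, ], 1] * g[idx[2, ], 3],
              g[idx[1, ], 1] * g[idx[2, ], 2] - g[idx[1, ], 2] * g[idx[2, ], 1])
  total <- 0
  for (k in 3:n) {
    sel <- idx[2, ] < k
    total <- total + sum(abs(cx[sel, , drop = FALSE] %*% g[k, ]))
  }
  total
}

#' Fraction of the color solid claimed by a band parallelepiped
#'
#' Ratio of the volume of the parallelepiped spanned by the three band
#' tristimulus vectors to the volume of the full object-color solid.
#' Volume ratios are invariant under any nonsingular linear recoding of
#' color space, which is what makes the cut optimization well posed.
#'
#' @inheritParams band_tristimulus
#' @inheritParams color_solid_generators
#' @return Scalar in (0, 1].
#' @export
volume_fraction <- function(illuminant, cmf, partition, coarsen = 1L) {
  b <- band_tristimulus(illuminant, cmf, partition)
  abs(det(unclass(b))) / zonotope_volume(color_solid_generators(illuminant, cmf, coarsen))
}

#' Optimal cuts: the parts-of-daylight RGB basis
#'
#' Finds the two cut wavelengths for which the parallelepiped spanned by the
#' three band tristimulus vectors has maximal volume, i.e. claims the largest
#' volume fraction of the object-color solid. Exhaustive search over all cut
#' pairs on a coarse grid, followed by deterministic coordinate-wise
#' golden-section refinement. For the D65 illuminant and the CIE 1964
#' observer the optimum is near 482.7 and 565.4 nm.
#'
#' @inheritParams band_tristimulus
#' @param coarse_step coarse search step in nm.
#' @param refine_tol golden-section bracket width at which refinement stops, nm.
#' @return A list with the optimal `partition`, the achieved `det`
#'   (absolute determinant of the band basis), and `objective`, the
#'   function used internally (for diagnostics).
#' @export
optimize_cuts <- function(illuminant, cmf, coarse_step = 1, refine_tol = 0.01) {
  bi <- band_integrand(illuminant, cmf)
  rng <- range(bi$wavelength)
  obj <- function(c1, c2) {
    A <- bi$cum(c(c1, c2))
    abs(det(cbind(A[1, ], A[2, ] - A[1, ], bi$total - A[2, ])))
  }
  cand <- seq(rng[1] + coarse_step, rng[2] - coarse_step, by = coarse_step)
  best <- c(NA_real_, NA_real_)
  best_v <- -Inf
  for (c1 in cand) {
    for (c2 in cand[cand > c1]) {
      v <- obj(c1, c2)
      if (v > best_v) {  # strict: ties keep the lexicographically smallest pair
        best_v <- v
        best <- c(c1, c2)
      }
    }
  }
  if (!is.finite(best_v) || best_v <= 0)
    stop("degenerate illuminant: no partition with nonzero volume", call. = FALSE)
  golden <- function(f, lo, hi) {
    gr <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    while (b - a > refine_tol) {
      c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
      if (f(c1) > f(d1)) b <- d1 else a <- c1
    }
    (a + b) / 2
  }
  c1 <- best[1]; c2 <- best[2]
  for (it in 1:30) {
    prev <- c(c1, c2)
    c1 <- golden(function(x) obj(x, c2),
                 max(rng[1] + refine_tol, c1 - 2 * coarse_step),
                 min(c2 - refine_tol, c1 + 2 * coarse_step))
    c2 <- golden(function(x) obj(c1, x),
                 max(c1 + refine_tol, c2 - 2 * coarse_step),
                 min(rng[2] - refine_tol, c2 + 2 * coarse_step))
    if (max(abs(c(c1, c2) - prev)) < refine_tol / 2) break
  }
  list(partition = band_partition(c1, c2, rng), det = obj(c1, c2))
}

#' Colour-matching functions re-expressed in a band RGB basis
#'
#' Applies the inverse of a band basis to the colour-matching function triple
#' at each wavelength. For the optimal partition, integrating illuminant
#' times the new functions over each band gives the identity matrix, and the
#' new functions are predominantly non-negative.
#'
#' @param cmf a [spectral_table()] of kind `"cmf"`.
#' @param basis an `rgb_basis` (3x3, nonsingular).
#' @return A [spectral_table()] of kind `"cmf"` holding the three new
#'   matching functions.
#' @export
rgb_matching_functions <- function(cmf, basis) {
  b <- unclass(basis)
  if (abs(det(b)) < .Machine$double.eps * max(abs(b))^3)
    stop("band basis is singular", call. = FALSE)
  vals <- t(solve(b, t(cmf$values)))
  out <- cmf
  out$values <- vals
  out
}
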