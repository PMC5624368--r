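# Shared fixture builders for the test suite.  Everything is generated in
# code; nothing binary is stored.

# flat (unit) illuminant on a 1-nm grid
flat_illuminant <- function(grid = 380:680) {
  spectral_table(grid, rep(1, length(grid)), "illuminant")
}

# three disjoint piecewise-linear boxcar "colour-matching functions" on
# [380, 680]: each is 1 on its band interior with 1-nm ramps that reach zero
# exactly at the band boundaries (480 and 580), so the band integrals are
# exactly diagonal for cuts at the boundaries.
boxcar_cmf <- function(grid = 380:680) {
  ramp <- function(lo, hi) {
    v <- numeric(length(grid))
    v[grid > lo & grid < hi] <- 1
    v[grid == lo | grid == hi] <- 0
    # 1-nm ramps at the ends of the support
    v[grid == lo + 1] <- 1
    v[grid == hi - 1] <- 1
    v
  }
  f1 <- ramp(379, 480); f1[grid == 380] <- 1   # left end open at the boundary
  f2 <- ramp(480, 580)
  f3 <- ramp(580, 681); f3[grid == 680] <- 1
  spectral_table(grid, cbind(f1, f2, f3), "cmf")
}

# n samples with population covariance equal to the symmetric band model
# (eps, 2 eps, eps), built by a linear map of white noise
eq2_samples <- function(eps, n, seed = 1) {
  C <- model_covariance(eps, 2 * eps, eps)
  set.seed(seed)
  matrix(rnorm(3 * n), n, 3) %*% chol(C)
}

# write an RGB byte array (H x W x 3, integers 0..255) to a temp PNG
write_byte_png <- function(bytes) {
  path <- tempfile(fileext = ".png")
  png::writePNG(bytes / 255, target = path)
  path
}

angle_deg <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  acos(pmin(1, abs(sum(u * v)))) * 180 / pi
}

opp_e2 <- c(1, 0, -1) / sqrt(2)
opp_e3 <- c(-1, 2, -1) / sqrt(6)
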