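test_that("covariance summaries behave for white and band-structured input", {
  set.seed(10)
  white <- matrix(rnorm(3e5), ncol = 3)
  s <- summarize_triples(white)
  expect_equal(s$Z, 0.5, tolerance = 0.02)   # lambda1/(lambda2+lambda3)
  expect_equal(max(abs(s$cov_normalized)), 100)
  expect_equal(crossprod(s$eigenvectors), diag(3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(s$eigenvalues) <= 0))

  x <- eq2_samples(0.01, 1e6, seed = 11)
  expect_equal(summarize_triples(x)$Z, 9 / (8 * 0.01), tolerance = 0.1)

  expect_error(summarize_triples(matrix(1, 10, 3)), "degenerate")
  expect_error(summarize_triples(white[1:3, ]), "at least 4")
})

test_that("summaries are permutation invariant and Z is scale invariant", {
  set.seed(12)
  x <- eq2_samples(0.05, 5000, seed = 12)
  s1 <- summarize_triples(x)
  s2 <- summarize_triples(x[sample(nrow(x)), ])
  expect_equal(s1$cov, s2$cov)
  expect_equal(s1$Z, s2$Z)
  s3 <- summarize_triples(17.3 * x)
  expect_equal(s3$Z, s1$Z, tolerance = 1e-12)
  expect_equal(s3$eigenvectors, s1$eigenvectors, tolerance = 1e-8)
})

test_that("the band model covariance has the prescribed entries", {
  expect_equal(model_covariance(0.1, 0.2, 0.1),
               matrix(c(1, .9, .8, .9, 1, .9, .8, .9, 1), 3, 3))
  M <- model_covariance(0.05, 0.2, 0.1)
  expect_equal(M, t(M))
  expect_error(model_covariance(0, 0.1, 0.1), "0, 1")
  expect_error(model_covariance(0.1, 1, 0.1), "0, 1")
})

test_that("model eigenstructure: exact red-blue eigenvector and limits", {
  for (eps in c(1e-6, 1e-4, 1e-2)) {
    C <- model_covariance(eps, 2 * eps, eps)
    # (1,0,-1)/sqrt(2) is an exact eigenvector with eigenvalue 2 eps
    expect_lt(max(abs(drop(C %*% opp_e2) - 2 * eps * opp_e2)), 1e-12)
    me <- model_eigen(eps)
    expect_lt(abs(me$eigenvalues[2] - 2 * eps), 1e-12)
  }
  expect_equal(model_eigen(1e-6)$eigenvalues[2] /
                 model_eigen(1e-6)$eigenvalues[3], 3, tolerance = 1e-6)
  me <- model_eigen(1e-4)
  expect_equal(me$Z * 8 * 1e-4 / 9, 1, tolerance = 1e-3)
  expect_equal(angle_deg(me$eigenvectors[, 2], opp_e2), 0, tolerance = 1e-8)
  expect_error(model_eigen(0.5), "0, 0.1")
})

test_that("stereographic frame maps pole to origin and opponent axes to unit points", {
  frame_of <- function(v1, v2, v3)
    stereographic_frame(list(eigenvectors = cbind(v1, v2, v3)))
  f <- frame_of(c(1, 1, 1) / sqrt(3), opp_e2, opp_e3)
  expect_equal(f[1, ], c(0, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(f[2, ], c(1, 0), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(f[3, ], c(0, 1), tolerance = 1e-12, ignore_attr = TRUE)
  # equatorial directions land on the unit circle, sign-independently
  expect_equal(sqrt(sum(frame_of(opp_e2, -opp_e2, opp_e3)[2, ]^2)), 1,
               tolerance = 1e-12)
  # model frames converge to the reference points as eps -> 0
  offs <- vapply(c(0.05, 0.01, 0.001), function(eps) {
    f <- stereographic_frame(model_eigen(eps))
    max(abs(f - rbind(c(0, 0), c(1, 0), c(0, 1))))
  }, numeric(1))
  expect_lt(offs[2], 1e-2)
  expect_lt(offs[3], 1e-3)
  expect_true(all(diff(offs) < 0))
  # the exact eigenvector projects exactly
  expect_equal(stereographic_frame(model_eigen(0.01))[2, ], c(1, 0),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(stereographic_frame(list(eigenvectors = matrix(0, 3, 3))),
               "invalid")
})

test_that("gamut signatures recover generator parameters", {
  expect_sig <- function(sig, mu, sigma, n) {
    se_mu <- sigma / sqrt(n)
    se_sd <- sigma / sqrt(2 * n)
    expect_lt(abs(sig$mu_lambda - mu[1]), 3 * se_mu[1] + 1e-12)
    expect_lt(abs(sig$mu_theta - mu[2]), 3 * se_mu[2] + 1e-12)
    expect_lt(abs(sig$mu_xi - mu[3]), 3 * se_mu[3] + 1e-12)
    expect_lt(abs(sig$sigma_lambda - sigma[1]), 3 * se_sd[1] + 1e-12)
    expect_lt(abs(sig$sigma_theta - sigma[2]), 3 * se_sd[2] + 1e-12)
    expect_lt(abs(sig$sigma_xi - sigma[3]), 3 * se_sd[3] + 1e-12)
  }
  const <- gamut_signature(matrix(0.5, 100, 3))
  expect_equal(c(const$mu_lambda, const$mu_theta, const$mu_xi), c(0, 0, 0))
  expect_equal(c(const$sigma_lambda, const$sigma_theta, const$sigma_xi),
               c(0, 0, 0))

  p <- gamut_params(0.2, -0.1, 0.05, 1.07, 0.47, 0.13)
  sig <- gamut_signature(sample_gamut(p, 1e5, seed = 21), delta = 1e-9)
  expect_sig(sig, c(0.2, -0.1, 0.05), c(1.07, 0.47, 0.13), 1e5)
})

test_that("eigenvectors of band-structured samples align with the opponent axes", {
  angles <- vapply(c(0.1, 0.01, 0.001), function(eps) {
    s <- summarize_triples(eq2_samples(eps, 1e5, seed = 13))
    max(angle_deg(s$eigenvectors[, 2], opp_e2),
        angle_deg(s$eigenvectors[, 3], opp_e3))
  }, numeric(1))
  expect_true(all(diff(angles) < 0))
  expect_lt(angles[3], 1)
})

test_that("psi regression recovers exact and noisy power laws", {
  st <- seq(0.2, 0.8, length.out = 7)
  sigs <- lapply(st, function(s) list(sigma_theta = s, sigma_xi = 0.114 * s))
  f <- psi_regression(sigs)
  expect_equal(f$power, 1, tolerance = 1e-10)
  expect_equal(f$psi, 0.114, tolerance = 1e-10)
  expect_equal(f$psi_linear, 0.114, tolerance = 1e-10)
  expect_equal(f$r2, 1, tolerance = 1e-10)

  set.seed(14)
  fits <- t(replicate(100, {
    st <- seq(0.2, 0.8, length.out = 16)
    sx <- 0.114 * st * exp(rnorm(16, 0, 0.1))
    ss <- lapply(seq_along(st),
                 function(i) list(sigma_theta = st[i], sigma_xi = sx[i]))
    ft <- psi_regression(ss)
    c(ft$power, ft$psi)
  }))
  expect_gte(mean(abs(fits[, 1] - 1) < 0.15 &
                    abs(fits[, 2] / 0.114 - 1) < 0.2), 0.9)
  expect_lt(abs(median(fits[, 1]) - 1), 0.05)
  expect_lt(abs(median(fits[, 2]) / 0.114 - 1), 0.1)

  expect_error(psi_regression(sigs[1:2]), "at least 3")
  same <- lapply(1:5, function(i) list(sigma_theta = 0.5, sigma_xi = 0.1))
  expect_error(psi_regression(same), "degenerate")
  neg <- c(sigs[1:3], list(list(sigma_theta = 0, sigma_xi = 0.1)))
  expect_error(psi_regression(neg), "positive")
})
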