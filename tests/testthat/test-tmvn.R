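test_that("mvn_cdf matches closed-form symmetry and orthant cases", {
  expect_equal(mvn_cdf(0, mean = 0, sigma = matrix(1)), 0.5)
  expect_equal(mvn_cdf(c(0, 0), sigma = diag(2)), 0.25, tolerance = 1e-8)
  # orthant probability with correlation 1/2: 1/4 + asin(1/2)/(2 pi) = 1/3
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  expect_equal(mvn_cdf(c(0, 0), sigma = S), 1 / 3, tolerance = 1e-8)
  # unbounded coordinates integrate out
  expect_equal(mvn_cdf(c(0, Inf), sigma = S), 0.5, tolerance = 1e-10)
  expect_equal(mvn_cdf(c(Inf, Inf), sigma = S), 1)
  expect_equal(mvn_cdf(c(0, -Inf), sigma = S), 0)
})

test_that("mvn_cdf rejects non-positive-definite covariances", {
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_error(mvn_cdf(c(0, 0), sigma = bad), "positive definite")
})

test_that("bivariate routine agrees with mvtnorm across the rho range", {
  set.seed(42)
  for (i in 1:60) {
    h <- runif(1, -4, 4); k <- runif(1, -4, 4)
    r <- runif(1, -0.999, 0.999)
    ref <- mvtnorm::pmvnorm(upper = c(h, k),
                            corr = matrix(c(1, r, r, 1), 2),
                            algorithm = mvtnorm::Miwa(steps = 512))
    expect_lt(abs(censmix:::pbvn(h, k, r) - as.numeric(ref)), 1e-9)
  }
})

test_that("univariate truncated-normal moments match the closed form", {
  m <- tmvn_moments(0, mean = 0, sigma = matrix(1))
  expect_equal(m$mean, -dnorm(0) / pnorm(0), tolerance = 1e-10)
  expect_equal(m$mean, -0.7979, tolerance = 1e-4)
  expect_equal(m$cov[1, 1], 1 - (dnorm(0) / pnorm(0))^2, tolerance = 1e-10)
  expect_equal(m$cov[1, 1], 0.3634, tolerance = 1e-4)
  expect_equal(m$log_mass, log(0.5), tolerance = 1e-12)
})

test_that("unbounded limits return the untruncated moments unchanged", {
  S <- matrix(c(2, 0.6, 0.6, 1), 2)
  m <- tmvn_moments(c(Inf, Inf), mean = c(1, -1), sigma = S)
  expect_identical(m$mean, c(1, -1))
  expect_identical(m$cov, S)
  expect_identical(m$log_mass, 0)
})

test_that("truncated moments agree with a rejection-sampling oracle", {
  set.seed(7)
  S <- matrix(c(1, 0.5, 0.5, 1), 2)
  u <- c(0, 0)
  m <- tmvn_moments(u, mean = c(0, 0), sigma = S)
  mc <- mc_trunc_oracle(u, c(0, 0), S, n_draws = 4e5)
  expect_true(all(abs(m$mean - mc$mean) < 3 * mc$mean_se))
  expect_lt(max(abs(m$cov - mc$cov)), 0.01)
  # mixed bounded/unbounded, d = 3
  S3 <- matrix(c(1, 0.3, 0.2, 0.3, 1, 0.4, 0.2, 0.4, 1), 3)
  u3 <- c(0.5, Inf, -0.2)
  m3 <- tmvn_moments(u3, mean = rep(0, 3), sigma = S3)
  mc3 <- mc_trunc_oracle(u3, rep(0, 3), S3, n_draws = 4e5)
  expect_true(all(abs(m3$mean - mc3$mean) < 3.5 * mc3$mean_se))
  expect_lt(max(abs(m3$cov - mc3$cov)), 0.015)
})

test_that("log_mass equals the log rectangle probability", {
  set.seed(11)
  for (i in 1:10) {
    d <- sample(1:4, 1)
    A <- matrix(rnorm(d * d), d)
    S <- crossprod(A) + diag(0.5, d)
    u <- rnorm(d, 0.5, 1)
    m <- tmvn_moments(u, mean = rep(0, d), sigma = S)
    expect_equal(m$log_mass, log(mvn_cdf(u, rep(0, d), S)),
                 tolerance = 1e-10)
  }
})

test_that("truncation from above pulls every mean down under positive
          correlation, and reduces the univariate variance", {
  set.seed(13)
  for (i in 1:20) {
    d <- sample(2:4, 1)
    # random PSD with nonnegative off-diagonals
    A <- matrix(abs(rnorm(d * d)), d)
    S <- crossprod(A) + diag(0.5, d)
    u <- rnorm(d, 0.8, 0.8)
    m <- tmvn_moments(u, mean = rep(0, d), sigma = S)
    expect_true(all(m$mean <= 1e-10))
  }
  for (u in c(-1, 0, 1.5)) {
    m <- tmvn_moments(u, 0, matrix(1))
    expect_lt(m$cov[1, 1], 1)
  }
})

test_that("moments are continuous in the truncation point", {
  S <- matrix(c(1, 0.4, 0.4, 1), 2)
  u <- c(0.3, -0.2)
  m1 <- tmvn_moments(u, c(0, 0), S)
  m2 <- tmvn_moments(u + 1e-6, c(0, 0), S)
  expect_lt(max(abs(m1$mean - m2$mean)), 1e-4)
  expect_lt(max(abs(m1$cov - m2$cov)), 1e-4)
})

test_that("a negligible-mass region raises the degenerate-region error", {
  expect_error(tmvn_moments(-40, 0, matrix(1)),
               class = "censmix_low_mass")
})

test_that("conditioning then truncating matches marginal truncation when
          blocks are independent, and the univariate reduction", {
  S <- diag(c(1, 2, 0.5))
  m1 <- cond_trunc_moments(q_obs = 0.7, limits = c(0.1, -0.3),
                           mean = rep(0, 3), sigma = S,
                           obs_idx = 1L, cens_idx = c(2L, 3L))
  m2 <- tmvn_moments(c(0.1, -0.3), c(0, 0), diag(c(2, 0.5)))
  expect_equal(m1$mean, m2$mean, tolerance = 1e-12)
  expect_equal(m1$cov, m2$cov, tolerance = 1e-12)
  # single censored coordinate: univariate truncated-normal closed form
  S2 <- matrix(c(1, 0.6, 0.6, 2), 2)
  ct <- cond_trunc_moments(q_obs = 0.5, limits = -0.2, mean = c(0, 1),
                           sigma = S2, obs_idx = 1L, cens_idx = 2L)
  cmu <- 1 + 0.6 * 0.5
  cvv <- 2 - 0.6^2
  z <- (-0.2 - cmu) / sqrt(cvv)
  h <- dnorm(z) / pnorm(z)
  expect_equal(ct$mean, cmu - sqrt(cvv) * h, tolerance = 1e-10)
  expect_equal(ct$cov[1, 1], cvv * (1 - z * h - h^2), tolerance = 1e-10)
})

test_that("conditional truncated moments match a conditional
          rejection-sampling oracle in three dimensions", {
  set.seed(21)
  S3 <- matrix(c(1, 0.3, 0.2, 0.3, 1, 0.4, 0.2, 0.4, 1), 3)
  ct <- cond_trunc_moments(q_obs = 0.3, limits = c(-0.1, 0.2),
                           mean = rep(0, 3), sigma = S3,
                           obs_idx = 2L, cens_idx = c(1L, 3L))
  # sample the exact conditional law given the observed coordinate,
  # then reject draws above the limits
  cm <- S3[c(1, 3), 2] * 0.3
  cv <- S3[c(1, 3), c(1, 3)] - tcrossprod(S3[c(1, 3), 2])
  mc <- mc_trunc_oracle(c(-0.1, 0.2), cm, cv, n_draws = 4e5)
  expect_true(all(abs(ct$mean - mc$mean) < 3.5 * mc$mean_se))
  expect_lt(max(abs(ct$cov - mc$cov)), 0.015)
})

test_that("compound-symmetry specialisations agree with the general
          routines", {
  set.seed(31)
  for (i in 1:8) {
    d <- sample(2:6, 1)
    s2 <- runif(1, 0.2, 1)
    psi <- runif(1, 0, 0.8)
    u <- runif(d, -1, 1.5)
    m <- runif(d, -0.5, 0.5)
    V <- matrix(psi, d, d) + diag(s2, d)
    a <- censmix:::cs_trunc_moments(u, m, s2, psi)
    b <- tmvn_moments(u, m, V)
    # agreement is limited by the general path's quasi-Monte-Carlo
    # precision (~1e-6), not by the Gauss-Hermite rule
    expect_lt(max(abs(a$mean - b$mean)), 1e-4)
    expect_lt(max(abs(a$cov - b$cov)), 1e-4)
    expect_lt(abs(a$log_mass - b$log_mass), 1e-4)
    expect_equal(censmix:::cs_logcdf(u, m, s2, psi),
                 log(mvn_cdf(u, m, V)), tolerance = 1e-5)
    expect_equal(censmix:::cs_ldnorm(u, m, s2, psi),
                 mvtnorm::dmvnorm(u, m, V, log = TRUE), tolerance = 1e-8)
  }
})

test_that("the compiled compound-symmetry kernel matches the R reference
          implementation exactly", {
  set.seed(41)
  for (i in 1:10) {
    d <- sample(1:7, 1)
    s2 <- runif(1, 0.2, 1)
    psi <- runif(1, 0, 0.8)
    u <- runif(d, -1, 1.5)
    m <- runif(d, -0.5, 0.5)
    a <- censmix:::cs_trunc_moments(u, m, s2, psi)
    b <- censmix:::cs_trunc_moments_r(u, m, s2, psi)
    expect_equal(a$mean, b$mean, tolerance = 1e-12)
    expect_equal(a$cov, b$cov, tolerance = 1e-12)
    expect_equal(a$log_mass, b$log_mass, tolerance = 1e-12)
    expect_equal(censmix:::cs_logcdf(u, m, s2, psi),
                 censmix:::cs_logcdf_r(u, m, s2, psi), tolerance = 1e-12)
  }
})
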