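test_that("the generator respects its design: censoring flags, noiseless
          limit, reproducibility", {
  d0 <- example_design(N = 20)
  d0$limit <- NA
  sim <- censmix_simulate(d0, seed = 1)
  expect_true(all(sim$data$cens == 0))
  expect_equal(sim$data$y,
               unlist(sim$truth$y_latent), tolerance = 1e-12)

  # noiseless limit: responses collapse onto the mean curve
  dn <- censmix_design(pi = 1, alpha = matrix(c(4, -2), 2),
                       sigma2 = 1e-12, psi = NULL, df = 1,
                       times = c(0, 1, 2), N = 5, limit = NA)
  simn <- censmix_simulate(dn, seed = 2)
  mu <- mean_curve(dn$spline, c(4, -2), c(0, 1, 2))
  expect_equal(simn$data$y, rep(mu, 5), tolerance = 1e-5)

  # identical seeds give byte-identical output
  s1 <- censmix_simulate(example_design(N = 15), seed = 9)
  s2 <- censmix_simulate(example_design(N = 15), seed = 9)
  expect_identical(s1$data, s2$data)
  expect_identical(s1$truth$assignment, s2$truth$assignment)
})

test_that("the empirical censoring fraction matches the analytic normal
          prediction", {
  # constant mean mu, limit at mu: half the observations censored
  dn <- censmix_design(pi = 1, alpha = matrix(c(3, 0), 2), sigma2 = 1,
                       psi = NULL, df = 1,
                       times = seq(0, 1, length.out = 10),
                       N = 1000, limit = 3)
  sim <- censmix_simulate(dn, seed = 5)
  n <- nrow(sim$data)
  expect_lt(abs(mean(sim$data$cens) - 0.5), 3 * sqrt(0.25 / n))
  expect_equal(expected_censoring(dn), 0.5, tolerance = 1e-12)
  # and the default two-group design sits near its analytic prediction
  d <- example_design(N = 400)
  expect_equal(expected_censoring(d), 0.2, tolerance = 0.005)
  simd <- censmix_simulate(d, seed = 6)
  p <- expected_censoring(d)
  expect_lt(abs(mean(simd$data$cens) - p),
            4 * sqrt(p * (1 - p) / nrow(simd$data)))
})

test_that("component matching is the optimal assignment", {
  expect_equal(as.integer(match_components(c(1, 1, 2, 2), c(1, 1, 2, 2))),
               1:2)
  expect_equal(as.integer(match_components(c(2, 2, 1, 1), c(1, 1, 2, 2))),
               2:1)
  # brute force over all permutations for random 3- and 4-component labels
  set.seed(101)
  for (G in 3:4) {
    for (rep in 1:20) {
      est <- sample.int(G, 40, replace = TRUE)
      ref <- sample.int(G, 40, replace = TRUE)
      perm <- match_components(est, ref, G = G)
      agree <- attr(perm, "agreement")
      perms <- censmix:::permutations(G)
      best <- max(vapply(seq_len(nrow(perms)), function(k)
        sum(perms[k, ][est] == ref), 0L))
      expect_equal(agree, best)
      expect_equal(sum(perm[est] == ref), best)
    }
  }
})

test_that("the adjusted Rand index follows the pair-counting formula", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # label invariance
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  a <- sample.int(3, 30, replace = TRUE)
  b <- sample.int(3, 30, replace = TRUE)
  expect_equal(adjusted_rand(a, b), adjusted_rand(a, 4 - b))
  # both single-cluster partitions: perfect agreement by convention
  expect_equal(adjusted_rand(rep(1, 5), rep(2, 5)), 1)
  expect_error(adjusted_rand(integer(0), integer(0)), "nonempty")
  # independent cross-check against an established implementation
  skip_if_not_installed("mclust")
  set.seed(5)
  for (rep in 1:10) {
    a <- sample.int(4, 50, replace = TRUE)
    b <- sample.int(3, 50, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("the parametric bootstrap recovers weights and clusters on a
          well-separated design and is deterministic", {
  d <- example_design(N = 120)
  bt <- censmix_bootstrap(d, B = 2,
                          control = censmix_control(n_starts = 2,
                                                    max_iter = 200,
                                                    seed = 3))
  expect_equal(nrow(bt$replicates), 2L)
  expect_true(all(bt$replicates$weight_err < 0.15))
  expect_true(all(bt$replicates$ari > 0.8))
  bt2 <- censmix_bootstrap(d, B = 2,
                           control = censmix_control(n_starts = 2,
                                                     max_iter = 200,
                                                     seed = 3))
  expect_identical(bt$replicates, bt2$replicates)

  # degenerate single-component design: ARI defined as 1
  d1 <- censmix_design(pi = 1, alpha = matrix(c(4, -1), 2), sigma2 = 0.2,
                       psi = c(0.1), df = 1, times = c(0, 1, 2, 3),
                       N = 25, limit = 2.8)
  b1 <- censmix_bootstrap(d1, B = 1,
                          control = censmix_control(n_starts = 1,
                                                    max_iter = 200,
                                                    seed = 4))
  expect_equal(b1$replicates$ari, 1)
})

test_that("simulate-then-fit errors shrink as the sample grows", {
  err_at <- function(N, seeds) {
    vapply(seeds, function(s) {
      sim <- censmix_simulate(example_design(N = N), seed = s)
      fit <- censmix_fit(sim$data, G = 2, df = 2,
                         control = censmix_control(n_starts = 2,
                                                   max_iter = 200,
                                                   seed = s))
      map <- apply(fit$tau, 1, which.max)
      perm <- match_components(map, sim$truth$assignment, G = 2)
      tt <- seq(0, 28, length.out = 15)
      sqrt(mean(vapply(1:2, function(g) {
        est <- mean_curve(fit$spline, fit$params$alpha[, g], tt)
        tru <- mean_curve(example_design(N = N)$spline,
                          example_design(N = N)$alpha[, perm[g]], tt)
        mean((est - tru)^2)
      }, 0)))
    }, 0)
  }
  e_small <- err_at(40, 1:3)
  e_large <- err_at(160, 1:3)
  expect_lt(mean(e_large), mean(e_small))
})
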