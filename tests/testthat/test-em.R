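test_that("E-step reduces to posterior weights = pi for identical
          components, and to the BLUP without censoring", {
  sim <- toy_dataset(N = 10, seed = 11)   # no censoring
  spec <- censmix_spec(2, df = 1)
  ds <- censmix:::build_dataset(sim$data, spec)
  alpha <- cbind(c(4, -2), c(4, -2))
  p <- censmix_params(c(0.3, 0.7), alpha, c(0.3, 0.3),
                      list(matrix(0.2), matrix(0.2)))
  es <- censmix:::e_step(ds, p)
  expect_equal(es$tau, matrix(rep(c(0.3, 0.7), each = 10), 10),
               tolerance = 1e-12)
  # G = 1: tau = 1, yhat = q, bhat = Psi Z' V^{-1} (q - X alpha)
  p1 <- censmix_params(1, alpha[, 1, drop = FALSE], 0.3, list(matrix(0.2)))
  ds1 <- censmix:::build_dataset(sim$data, censmix_spec(1, df = 1))
  es1 <- censmix:::e_step(ds1, p1)
  expect_equal(es1$tau, matrix(1, 10, 1))
  ind <- ds1$individuals[[1]]
  rec <- es1$comp[[1]][[1]]
  expect_equal(rec$yhat, ind$q)
  expect_equal(rec$trOmega, 0)
  V <- matrix(0.2, ind$n, ind$n) + diag(0.3, ind$n)
  blup <- drop(0.2 * matrix(1, 1, ind$n) %*%
                 solve(V, ind$q - drop(ind$X %*% alpha[, 1])))
  expect_equal(rec$bhat, blup, tolerance = 1e-10)
})

test_that("E-step conditional moments match a joint rejection-sampling
          oracle with one censored coordinate", {
  # one individual, n = 2, random intercept, second coordinate censored
  limit <- -0.1
  dat <- tibble::tibble(id = 1, time = c(0, 1), y = c(0.9, limit),
                        cens = c(0, 1))
  spec <- censmix_spec(1, df = 1)
  ds <- censmix:::build_dataset(dat, spec)
  alpha <- matrix(c(0.5, 0), 2)
  psi <- 0.4; s2 <- 0.7
  p <- censmix_params(1, alpha, s2, list(matrix(psi)))
  es <- censmix:::e_step(ds, p)
  rec <- es$comp[[1]][[1]]

  # simulate (beta, e), keep draws consistent with the observed coordinate
  # (narrow window) and the censoring event
  set.seed(99)
  n_mc <- 4e6
  b <- rnorm(n_mc, 0, sqrt(psi))
  y1 <- 0.5 + b + rnorm(n_mc, 0, sqrt(s2))
  y2 <- 0.5 + b + rnorm(n_mc, 0, sqrt(s2))
  keep <- abs(y1 - 0.9) < 0.01 & y2 <= limit
  nk <- sum(keep)
  expect_gt(nk, 2000)
  se_y2 <- sd(y2[keep]) / sqrt(nk)
  se_b <- sd(b[keep]) / sqrt(nk)
  expect_lt(abs(rec$yhat[2] - mean(y2[keep])), 4 * se_y2)
  expect_lt(abs(rec$bhat - mean(b[keep])), 4 * se_b)
  expect_lt(abs(rec$Bcov[1, 1] - var(b[keep])), 6 * var(b[keep]) / sqrt(nk))
  expect_lt(abs(rec$trOmega - var(y2[keep])),
            6 * var(y2[keep]) / sqrt(nk))
})

test_that("M-step with hard assignments and no censoring is group-wise
          least squares", {
  sim <- toy_dataset(N = 12, psi = c(0, 0), seed = 13)
  spec <- censmix_spec(2, df = 1, random_intercept = FALSE)
  ds <- censmix:::build_dataset(sim$data, spec)
  grp <- rep(1:2, each = 6)
  tau <- matrix(0, 12, 2); tau[cbind(1:12, grp)] <- 1
  es <- list(tau = tau, comp = lapply(1:2, function(g)
    lapply(ds$individuals, function(ind)
      list(yhat = ind$q, trOmega = 0))))
  p <- censmix:::m_step(ds, es, spec)
  for (g in 1:2) {
    ids <- which(grp == g)
    rows <- unlist(lapply(ds$individuals[ids], `[[`, "rows"))
    fit <- lm.fit(ds$Xall[rows, ], sim$data$y[rows])
    expect_equal(p$alpha[, g], unname(fit$coefficients), tolerance = 1e-10)
    expect_equal(p$sigma2[g], sum(fit$residuals^2) / length(rows),
                 tolerance = 1e-10)
  }
  expect_equal(p$pi, c(0.5, 0.5))
  # pooled residual variance equals the weighted combination
  spec_eq <- censmix_spec(2, df = 1, random_intercept = FALSE,
                          equal_sigma = TRUE)
  peq <- censmix:::m_step(ds, es, spec_eq)
  expect_equal(peq$sigma2[1], peq$sigma2[2])
  ntot <- sum(vapply(ds$individuals, `[[`, 0L, "n"))
  expect_equal(peq$sigma2[1],
               sum(p$sigma2 * ntot / 2) / ntot, tolerance = 1e-10)
})

test_that("the M-step maximises the expected complete log-likelihood
          locally", {
  sim <- toy_dataset(N = 10, limit = 3.2, seed = 17)
  spec <- censmix_spec(2, df = 1)
  ds <- censmix:::build_dataset(sim$data, spec)
  p0 <- censmix_params(c(0.5, 0.5), cbind(c(4, -2), c(4, 1)), c(0.3, 0.4),
                       list(matrix(0.2), matrix(0.3)))
  es <- censmix:::e_step(ds, p0)
  p1 <- censmix:::m_step(ds, es, spec)

  qfun <- function(p) {
    # expected complete log-likelihood under the E-step distribution
    total <- 0
    for (i in seq_len(ds$N)) {
      ind <- ds$individuals[[i]]
      for (g in 1:2) {
        rec <- es$comp[[g]][[i]]
        mu <- drop(ind$X %*% p$alpha[, g])
        resid <- rec$yhat - mu - rec$bhat
        ess <- sum(resid^2) + rec$trOmega + rec$trZBZ - 2 * rec$crossZY
        psi <- p$Psi[[g]][1, 1]
        total <- total + es$tau[i, g] *
          (log(p$pi[g]) -
             0.5 * (ind$n * log(2 * pi * p$sigma2[g]) +
                      ess / p$sigma2[g]) -
             0.5 * (log(2 * pi * psi) +
                      (rec$bhat^2 + rec$Bcov[1, 1]) / psi))
      }
    }
    total
  }
  q1 <- qfun(p1)
  set.seed(1)
  for (rep in 1:40) {
    pp <- p1
    pert <- function(x) x * (1 + rnorm(length(x), 0, 1e-3))
    w <- pmax(pert(p1$pi), 1e-6); pp$pi <- w / sum(w)
    pp$alpha <- pert(p1$alpha)
    pp$sigma2 <- pert(p1$sigma2)
    pp$Psi <- lapply(p1$Psi, function(P) matrix(pert(P[1, 1])))
    expect_lte(qfun(pp), q1 + 1e-10)
  }
})

test_that("every EM iteration increases the observed log-likelihood", {
  sim <- toy_dataset(N = 15, limit = 3.2, seed = 19)
  fit <- censmix_fit(sim$data, G = 2, df = 1, control = fast_ctl(seed = 3))
  expect_true(all(diff(fit$trace) > -1e-8))
  # and the reported log-likelihood is consistent with the general path
  ds <- censmix:::build_dataset(sim$data, fit$spec)
  expect_equal(fit$loglik, censmix:::observed_loglik(ds, fit$params),
               tolerance = 1e-6)
})

test_that("one further EM cycle barely moves a tightly converged fit", {
  sim <- toy_dataset(N = 20, limit = 3.2, seed = 23)
  fit <- censmix_fit(sim$data, G = 2, df = 1,
                     control = fast_ctl(seed = 2, tol = 1e-9,
                                        max_iter = 2000))
  ds <- censmix:::build_dataset(sim$data, fit$spec)
  es <- censmix:::e_step(ds, fit$params)
  p2 <- censmix:::m_step(ds, es, fit$spec)
  relch <- function(a, b) max(abs(a - b) / pmax(abs(a), 1e-4))
  expect_lt(relch(fit$params$pi, p2$pi), 1e-4)
  expect_lt(relch(fit$params$alpha, p2$alpha), 1e-4)
  expect_lt(relch(fit$params$sigma2, p2$sigma2), 1e-4)
})

test_that("relabelling components permutes parameters but not the
          likelihood", {
  sim <- toy_dataset(N = 12, limit = 3.2, seed = 29)
  fit <- censmix_fit(sim$data, G = 2, df = 1, control = fast_ctl(seed = 5))
  ds <- censmix:::build_dataset(sim$data, fit$spec)
  p <- fit$params
  pr <- censmix_params(p$pi[2:1], p$alpha[, 2:1], p$sigma2[2:1],
                       p$Psi[2:1])
  expect_equal(censmix:::observed_loglik(ds, pr),
               censmix:::observed_loglik(ds, p), tolerance = 1e-10)
})

test_that("initialisation is deterministic given the seed and keeps all
          groups populated", {
  sim <- toy_dataset(N = 30, seed = 31)
  spec <- censmix_spec(3, df = 1)
  ds <- censmix:::build_dataset(sim$data, spec)
  set.seed(7); p1 <- censmix:::initialize_params(ds, spec)
  set.seed(7); p2 <- censmix:::initialize_params(ds, spec)
  expect_identical(p1, p2)
  for (s in 1:200) {
    set.seed(s)
    grp <- NULL
    p <- censmix:::initialize_params(ds, spec)
    expect_true(all(p$pi > 0))
  }
  # G = 1 initialisation is the OLS fit with censored values at limits
  spec1 <- censmix_spec(1, df = 1, random_intercept = FALSE)
  ds1 <- censmix:::build_dataset(sim$data, spec1)
  pp <- censmix:::initialize_params(ds1, spec1)
  ols <- lm.fit(ds1$Xall, unlist(lapply(ds1$individuals, `[[`, "q")))
  expect_equal(pp$alpha[, 1], unname(ols$coefficients), tolerance = 1e-10)
})

test_that("with one component and no censoring the fit matches a
          reference mixed-model ML fit", {
  skip_if_not_installed("lme4")
  sim <- toy_dataset(N = 25, times = c(0, 1, 2, 3, 4), seed = 37)
  fit <- censmix_fit(sim$data, G = 1, df = 1,
                     control = censmix_control(tol = 1e-10,
                                               max_iter = 5000,
                                               n_starts = 1, seed = 1))
  d <- as.data.frame(sim$data)
  X <- censmix:::build_dataset(sim$data, fit$spec)$Xall
  d$x1 <- X[, 2]
  ref <- lme4::lmer(y ~ x1 + (1 | id), data = d, REML = FALSE)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-4)
  expect_equal(unname(fit$params$alpha[, 1]),
               unname(lme4::fixef(ref)), tolerance = 1e-3)
})

test_that("without censoring or random effects the fit matches a naive
          mixture-of-regressions EM run from the same start", {
  sim <- toy_dataset(N = 24, psi = c(0, 0), seed = 41)
  spec <- censmix_spec(2, df = 1, random_intercept = FALSE)
  ds <- censmix:::build_dataset(sim$data, spec)
  grp <- rep(1:2, 12)
  tau0 <- matrix(0, 24, 2); tau0[cbind(1:24, grp)] <- 1
  fit <- censmix_fit(sim$data, G = 2, df = 1, random_intercept = FALSE,
                     control = censmix_control(tol = 1e-8, max_iter = 2000,
                                               n_starts = 1, seed = 1),
                     init_tau = tau0)
  y <- unlist(lapply(ds$individuals, `[[`, "q"))
  idv <- rep(seq_len(ds$N), vapply(ds$individuals, `[[`, 0L, "n"))
  ref <- naive_mixreg_em(y, ds$Xall, idv, G = 2, tau0 = tau0, tol = 1e-8,
                         max_iter = 2000)
  expect_equal(fit$loglik, ref$loglik, tolerance = 1e-6)
})

test_that("component starvation aborts the chain with a diagnostic", {
  sim <- toy_dataset(N = 8, seed = 43)
  spec <- censmix_spec(2, df = 1)
  ds <- censmix:::build_dataset(sim$data, spec)
  p <- censmix_params(c(1 - 1e-12, 1e-12), cbind(c(4, -2), c(100, 0)),
                      c(0.3, 0.3), list(matrix(0.2), matrix(0.2)))
  expect_error(censmix:::e_step(ds, p, starve_floor = 1e-3),
               class = "censmix_starved")
})
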