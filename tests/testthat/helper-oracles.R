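# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: brute-force integration, rejection
# sampling, textbook recursions and a naive EM, each written directly from
# first principles.

# rejection-sampling moments of X ~ N(mean, sigma) | X <= upper
mc_trunc_oracle <- function(upper, mean, sigma, n_draws = 1e6) {
  X <- mvtnorm::rmvnorm(n_draws, mean = mean, sigma = as.matrix(sigma))
  keep <- rep(TRUE, n_draws)
  for (j in seq_along(upper)) {
    if (is.finite(upper[j])) keep <- keep & X[, j] <= upper[j]
  }
  Xk <- X[keep, , drop = FALSE]
  list(
    mean = colMeans(Xk),
    cov = stats::cov(Xk),
    mass = mean(keep),
    n_kept = nrow(Xk),
    mean_se = apply(Xk, 2, stats::sd) / sqrt(nrow(Xk))
  )
}

# de Boor's recursion for the B-spline basis B_{j,k}(x) on knot vector t
deboor_basis <- function(x, degree, knots, boundary) {
  tful <- c(rep(boundary[1], degree + 1), knots, rep(boundary[2], degree + 1))
  nb <- length(tful) - degree - 1
  B <- matrix(0, length(x), nb)
  for (m in seq_along(x)) {
    xx <- min(max(x[m], boundary[1]), boundary[2])
    # order 1 (degree 0)
    b <- numeric(length(tful) - 1)
    for (j in seq_along(b)) {
      if (xx >= tful[j] && xx < tful[j + 1]) b[j] <- 1
    }
    if (xx >= boundary[2]) b[max(which(tful < boundary[2]))] <- 1
    for (k in seq_len(degree)) {
      bn <- numeric(length(b) - 1)
      for (j in seq_along(bn)) {
        d1 <- tful[j + k] - tful[j]
        d2 <- tful[j + k + 1] - tful[j + 1]
        a1 <- if (d1 > 0) (xx - tful[j]) / d1 * b[j] else 0
        a2 <- if (d2 > 0) (tful[j + k + 1] - xx) / d2 * b[j + 1] else 0
        bn[j] <- a1 + a2
      }
      b <- bn
    }
    B[m, ] <- b[seq_len(nb)]
  }
  B
}

# direct (no log-sum-exp) mixture likelihood for small censored problems
naive_mixture_loglik <- function(data, pi, alpha, sigma2, psi = NULL) {
  ids <- unique(data$id)
  G <- length(pi)
  total <- 0
  for (id in ids) {
    d <- data[data$id == id, ]
    d <- d[order(d$time), ]
    lik <- 0
    for (g in seq_len(G)) {
      lik <- lik + pi[g] * exp(naive_component_loglik(d, alpha[, g],
                                                      sigma2[g],
                                                      if (is.null(psi)) 0
                                                      else psi[g]))
    }
    total <- total + log(lik)
  }
  total
}

# component likelihood by conditioning + mvtnorm CDF, straightforwardly
naive_component_loglik <- function(d, a, s2, psi) {
  X <- attr(d, "X")
  mu <- drop(X %*% a)
  n <- nrow(d)
  V <- diag(s2, n) + psi
  cz <- d$cens == 1
  if (!any(cz)) {
    return(mvtnorm::dmvnorm(d$y, mu, V, log = TRUE))
  }
  o <- which(!cz); cc <- which(cz)
  ll <- 0
  if (length(o)) {
    ll <- mvtnorm::dmvnorm(d$y[o], mu[o], V[o, o, drop = FALSE],
                           log = TRUE)
    cm <- mu[cc] + V[cc, o, drop = FALSE] %*%
      solve(V[o, o, drop = FALSE], d$y[o] - mu[o])
    cv <- V[cc, cc, drop = FALSE] - V[cc, o, drop = FALSE] %*%
      solve(V[o, o, drop = FALSE], V[o, cc, drop = FALSE])
  } else {
    cm <- mu[cc]; cv <- V
  }
  p <- mvtnorm::pmvnorm(upper = d$y[cc], mean = drop(cm),
                        sigma = (cv + t(cv)) / 2,
                        algorithm = mvtnorm::Miwa(steps = 128))
  ll + log(max(as.numeric(p), 1e-300))
}

# textbook EM for a mixture of linear regressions (no censoring, no random
# effects), run from supplied hard assignments; independent of the package
naive_mixreg_em <- function(y, X, id, G, tau0, tol = 1e-6,
                            max_iter = 500) {
  ids <- unique(id)
  N <- length(ids)
  idx <- split(seq_along(y), match(id, ids))
  tau <- tau0
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    # M-step
    pi_g <- colMeans(tau)
    alpha <- matrix(0, ncol(X), G)
    sigma2 <- numeric(G)
    for (g in seq_len(G)) {
      w <- unlist(lapply(seq_len(N), function(i)
        rep(tau[i, g], length(idx[[i]]))))
      fitw <- stats::lm.wfit(X, y, w)
      alpha[, g] <- fitw$coefficients
      sigma2[g] <- sum(w * fitw$residuals^2) / sum(w)
    }
    # E-step + loglik
    lmat <- matrix(0, N, G)
    for (g in seq_len(G)) {
      mu <- drop(X %*% alpha[, g])
      for (i in seq_len(N)) {
        lmat[i, g] <- log(pi_g[g]) +
          sum(stats::dnorm(y[idx[[i]]], mu[idx[[i]]], sqrt(sigma2[g]),
                           log = TRUE))
      }
    }
    m <- apply(lmat, 1, max)
    ll <- sum(m + log(rowSums(exp(lmat - m))))
    tau <- exp(lmat - (m + log(rowSums(exp(lmat - m)))))
    if (abs(ll - ll_old) / max(abs(ll_old), 1e-10) < tol && it > 1) break
    ll_old <- ll
  }
  list(loglik = ll, pi = pi_g, alpha = alpha, sigma2 = sigma2, tau = tau)
}

# attach the fitting design matrix to a long data frame, matching the
# package's basis construction
with_design <- function(d, sspec) {
  d <- d[order(d$time), ]
  attr(d, "X") <- spline_basis(d$time, sspec)
  d
}

# small long-format dataset with explicit design matrices already built;
# returns both the tibble and per-id design rows for oracle use
toy_dataset <- function(N = 6, times = c(0, 1, 2, 4), df = 1,
                        alpha = cbind(c(4, -2), c(4, 1)),
                        pi = c(0.5, 0.5), sigma2 = c(0.3, 0.3),
                        psi = c(0.2, 0.2), limit = NA, seed = 1) {
  design <- censmix_design(pi = pi, alpha = alpha, sigma2 = sigma2,
                           psi = psi, df = df, times = times, N = N,
                           limit = limit)
  censmix_simulate(design, seed = seed)
}

fast_ctl <- function(seed = 1, n_starts = 2, max_iter = 200, tol = 1e-6) {
  censmix_control(tol = tol, max_iter = max_iter, n_starts = n_starts,
                  seed = seed)
}
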