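# Compound-symmetry (random-intercept) specializations.
#
# With a random intercept the marginal covariance of every response vector
# is sigma2*I + psi*J (J = all ones). This family is closed under both
# Gaussian conditioning and the Tallis moment recursion: conditioning
# CS(sigma2, psi) on one coordinate gives CS(sigma2, psi*sigma2/(sigma2+psi))
# plus an equal mean shift on the remaining coordinates. The rectangle
# probability of a CS Gaussian is a one-dimensional integral over the shared
# factor,
#   P(X <= u) = E_z[ prod_j Phi((u_j - m_j - sqrt(psi) z) / sigma) ],
#   z ~ N(0,1),
# evaluated here with a fixed 48-point Gauss-Hermite rule, so the whole
# E-step is deterministic and needs no general MVN CDF.

# probabilists' Gauss-Hermite rule via Golub-Welsch (weights sum to 1)
gauss_hermite <- function(K) {
  i <- seq_len(K - 1L)
  J <- matrix(0, K, K)
  J[cbind(i, i + 1L)] <- sqrt(i)
  J[cbind(i + 1L, i)] <- sqrt(i)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = e$vectors[1L, ]^2)
}

.gh <- local({
  g <- gauss_hermite(48L)
  g$logw <- log(g$weights)
  g
})

# log P(X <= upper) for X ~ N(mean, sigma2*I + psi*J); Inf limits dropped.
# Dispatches to the compiled kernel; the R implementation below is kept as
# the readable reference and exercised against the compiled one in tests.
cs_logcdf <- function(upper, mean, sigma2, psi) {
  fin <- is.finite(upper)
  if (!any(fin)) return(0)
  if (any(upper == -Inf)) return(-Inf)
  .cs_logcdf_cpp(upper[fin], rep_len(mean, length(upper))[fin],
                 sigma2, psi, .gh$nodes, .gh$logw)
}

cs_logcdf_r <- function(upper, mean, sigma2, psi) {
  fin <- is.finite(upper)
  if (!any(fin)) return(0)
  if (any(upper == -Inf)) return(-Inf)
  u <- upper[fin]
  m <- mean[fin]
  s <- sqrt(sigma2)
  if (psi <= 0) {
    return(sum(stats::pnorm(u, m, s, log.p = TRUE)))
  }
  sd_m <- sqrt(sigma2 + psi)
  if (length(u) == 1L) {
    return(stats::pnorm(u, m, sd_m, log.p = TRUE))
  }
  if (length(u) == 2L) {
    return(log(pbvn((u[1L] - m[1L]) / sd_m, (u[2L] - m[2L]) / sd_m,
                    psi / (sigma2 + psi))))
  }
  z <- .gh$nodes
  K <- length(z)
  # K x d matrix of log Phi terms
  args <- (matrix(u - m, K, length(u), byrow = TRUE) -
             (sqrt(psi) * z)) / s
  lp <- stats::pnorm(args, log.p = TRUE)
  lt <- .gh$logw + rowSums(lp)
  mx <- max(lt)
  mx + log(sum(exp(lt - mx)))
}

# Truncated moments of X ~ N(mean, sigma2*I + psi*J) restricted to
# {X <= upper}. Same Tallis reduction as tmvn_moments(), with every lower-
# dimensional CDF evaluated on the (still CS) conditional laws. The
# compiled kernel handles the all-finite case; unbounded coordinates fall
# back to the R reference implementation below.
cs_trunc_moments <- function(upper, mean, sigma2, psi,
                             mass_floor = 1e-12) {
  mean <- rep_len(mean, length(upper))
  if (all(is.finite(upper))) {
    res <- .cs_trunc_moments_cpp(upper, mean, sigma2, psi, mass_floor,
                                 .gh$nodes, .gh$logw)
    if (!isTRUE(res$ok)) {
      stop(structure(
        class = c("censmix_low_mass", "error", "condition"),
        list(message = paste0(
          "truncation region mass below floor (log mass ",
          format(res$log_mass, digits = 4), ")"), call = NULL)
      ))
    }
    return(list(mean = as.numeric(res$mean), cov = res$cov,
                log_mass = res$log_mass))
  }
  cs_trunc_moments_r(upper, mean, sigma2, psi, mass_floor)
}

cs_trunc_moments_r <- function(upper, mean, sigma2, psi,
                               mass_floor = 1e-12) {
  d <- length(upper)
  fin <- is.finite(upper)
  sig_d <- sigma2 + psi                     # marginal variance
  if (!any(fin)) {
    V <- matrix(psi, d, d); diag(V) <- sig_d
    return(list(mean = mean, cov = V, log_mass = 0))
  }
  log_alpha <- cs_logcdf_r(upper, mean, sigma2, psi)
  if (log_alpha < log(mass_floor)) {
    stop(structure(
      class = c("censmix_low_mass", "error", "condition"),
      list(message = paste0("truncation region mass below floor (log mass ",
                            format(log_alpha, digits = 4), ")"),
           call = NULL)
    ))
  }
  alpha <- exp(log_alpha)
  if (d == 1L) {
    s <- sqrt(sig_d)
    z <- (upper - mean) / s
    h <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
    mu_t <- mean - s * h
    var_t <- sig_d * (1 - z * h - h * h)
    return(list(mean = mu_t, cov = matrix(max(var_t, 0)),
                log_mass = log_alpha))
  }

  u <- upper - mean
  # conditional CS parameters after one / two conditionings
  c1 <- psi / sig_d                  # regression weight on the conditioned u
  psi1 <- psi * sigma2 / sig_d
  sig_d1 <- sigma2 + psi1
  c2 <- psi1 / sig_d1

  # F_k = phi(u_k; sig_d) * P(rest <= limits | X_k = u_k)
  idx_fin <- which(fin)
  Fk <- numeric(d)
  fk_dens <- stats::dnorm(u, 0, sqrt(sig_d))
  if (d - 1L <= 2L || psi1 <= 0) {
    for (k in idx_fin) {
      if (fk_dens[k] > 0) {
        rest <- seq_len(d)[-k]
        Fk[k] <- fk_dens[k] *
          exp(cs_logcdf_r(u[rest], rep(c1 * u[k], d - 1L), sigma2, psi1))
      }
    }
  } else {
    # one batched Gauss-Hermite evaluation across all conditioning
    # coordinates: args[z, j, k] = (u_j - c1 u_k - sqrt(psi1) z) / sigma
    K <- length(.gh$nodes)
    s <- sqrt(sigma2)
    M1 <- outer(u, c1 * u, "-") / s          # (j, k)
    zs <- sqrt(psi1) * .gh$nodes / s
    lp <- stats::pnorm(
      rep(M1, each = K) - zs, log.p = TRUE    # (z, j, k)
    )
    dim(lp) <- c(K, d, d)
    for (k in idx_fin) lp[, k, k] <- 0        # exclude j = k
    Ssum <- colSums(aperm(lp, c(2L, 1L, 3L))) # (z, k), summed over j
    lt <- .gh$logw + Ssum
    mx <- apply(lt, 2L, max)
    Fk[idx_fin] <- (fk_dens *
                      exp(mx + log(colSums(exp(sweep(lt, 2L, mx))))))[idx_fin]
  }

  # F_kq = phi2(u_k, u_q) * P(rest | X_k = u_k, X_q = u_q)
  F2 <- matrix(0, d, d)
  if (length(idx_fin) >= 2L) {
    S2 <- matrix(c(sig_d, psi, psi, sig_d), 2L)
    psi2 <- psi1 * sigma2 / sig_d1
    for (ai in seq_len(length(idx_fin) - 1L)) {
      for (bi in (ai + 1L):length(idx_fin)) {
        k <- idx_fin[ai]; q <- idx_fin[bi]
        f2 <- dmvnorm2(u[c(k, q)], S2)
        if (f2 > 0) {
          rest <- seq_len(d)[-c(k, q)]
          if (length(rest) == 0L) {
            F2[k, q] <- f2
          } else {
            shift <- c1 * u[k] + c2 * (u[q] - c1 * u[k])
            F2[k, q] <- f2 * exp(cs_logcdf_r(
              u[rest], rep(shift, length(rest)), sigma2, psi2
            ))
          }
          F2[q, k] <- F2[k, q]
        }
      }
    }
  }

  sigma <- matrix(psi, d, d); diag(sigma) <- sig_d
  sdiag <- rep(sig_d, d)
  mu_c <- -drop(sigma %*% Fk) / alpha
  ukFk <- ifelse(fin, u * Fk, 0)
  T1 <- -(sigma %*% (ukFk / sdiag * t(sigma))) / alpha
  A <- sigma %*% F2
  ck <- rowSums(sigma * F2)
  Vmat <- A - sweep(sigma, 2L, ck / sdiag, "*")
  T2 <- sigma %*% t(Vmat) / alpha
  M <- sigma + T1 + T2
  covt <- M - tcrossprod(mu_c)
  covt <- (covt + t(covt)) / 2
  list(mean = mean + mu_c, cov = covt, log_mass = log_alpha)
}

# log-density of y ~ N(mu, sigma2*I + psi*J) in closed form
cs_ldnorm <- function(y, mu, sigma2, psi) {
  n <- length(y)
  e <- y - mu
  se <- sum(e)
  ldet <- (n - 1) * log(sigma2) + log(sigma2 + n * psi)
  quad <- (sum(e * e) - psi * se * se / (sigma2 + n * psi)) / sigma2
  -0.5 * (n * log(2 * pi) + ldet + quad)
}
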