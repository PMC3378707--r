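#' Multivariate normal rectangle probability P(X <= upper)
#'
#' Evaluates the multivariate normal distribution function over the
#' lower-open rectangle \{x : x <= upper componentwise\}. Coordinates with an
#' upper limit of `+Inf` impose no restriction and are integrated out; any
#' `-Inf` limit gives probability zero. Dimensions one and two use exact
#' closed-form routines (`pnorm` and a Gauss--Legendre bivariate algorithm of
#' the Drezner--Wesolowsky/Genz type); dimension three uses the
#' deterministic trivariate TVPACK routine of [mvtnorm::pmvnorm()]; higher
#' dimensions use the Genz--Bretz quasi-Monte-Carlo algorithm run under a
#' fixed internal seed (the caller's RNG state is saved and restored), so
#' every evaluation path is reproducible bit-for-bit and accurate at any
#' correlation strength.
#'
#' @param upper Numeric vector of upper integration limits (may contain
#'   `Inf`).
#' @param mean Numeric mean vector, recycled scalar allowed. Default 0.
#' @param sigma Symmetric positive-definite covariance matrix.
#' @return A single probability in \[0, 1\].
#' @examples
#' mvn_cdf(c(0, 0), sigma = diag(2))                     # 0.25
#' mvn_cdf(0, mean = 0, sigma = matrix(1))               # 0.5
#' @export
mvn_cdf <- function(upper, mean = 0, sigma) {
  sigma <- as.matrix(sigma)
  d <- length(upper)
  if (d < 1L) stop("`upper` must have length >= 1")
  mean <- rep_len(mean, d)
  if (!all(is.finite(mean)) || !all(is.finite(sigma))) {
    stop("non-finite `mean` or `sigma`")
  }
  if (nrow(sigma) != d || ncol(sigma) != d) {
    stop("`sigma` must be ", d, "x", d)
  }
  check_pd(sigma)
  mvn_cdf_core(upper, mean, sigma)
}

# Internal CDF dispatch without validation (hot path).
mvn_cdf_core <- function(upper, mean, sigma) {
  if (any(upper == -Inf)) return(0)
  keep <- is.finite(upper)
  if (!any(keep)) return(1)
  if (!all(keep)) {
    upper <- upper[keep]
    mean <- mean[keep]
    sigma <- sigma[keep, keep, drop = FALSE]
  }
  d <- length(upper)
  if (d == 1L) {
    return(stats::pnorm(upper, mean, sqrt(sigma[1L])))
  }
  if (d == 2L) {
    s1 <- sqrt(sigma[1L, 1L]); s2 <- sqrt(sigma[2L, 2L])
    rho <- sigma[1L, 2L] / (s1 * s2)
    return(pbvn((upper[1L] - mean[1L]) / s1,
                (upper[2L] - mean[2L]) / s2, rho))
  }
  p <- if (d == 3L) {
    mvtnorm::pmvnorm(
      upper = upper, mean = mean, sigma = sigma,
      algorithm = mvtnorm::TVPACK(1e-12)
    )
  } else {
    # Genz-Bretz quasi-Monte-Carlo under a fixed seed: accurate at any
    # correlation (unlike grid quadrature) and reproducible
    with_fixed_rng(
      mvtnorm::pmvnorm(
        upper = upper, mean = mean, sigma = sigma,
        algorithm = mvtnorm::GenzBretz(abseps = 1e-9, maxpts = 100000L)
      )
    )
  }
  min(max(as.numeric(p), 0), 1)
}

# Gauss-Legendre nodes/weights used by the bivariate routine (3/6/10-point
# rules selected by |rho|), as in Genz's TVPACK.
.bvn_w <- list(
  c(0.1713244923791705, 0.3607615730481384, 0.4679139345726904),
  c(0.04717533638651177, 0.1069393259953183, 0.1600783285433464,
    0.2031674267230659, 0.2334925365383547, 0.2491470458134029),
  c(0.01761400713915212, 0.04060142980038694, 0.06267204833410906,
    0.08327674157670475, 0.1019301198172404, 0.1181945319615184,
    0.1316886384491766, 0.1420961093183821, 0.1491729864726037,
    0.1527533871307259)
)
.bvn_x <- list(
  c(-0.9324695142031522, -0.6612093864662647, -0.2386191860831970),
  c(-0.9815606342467191, -0.9041172563704750, -0.7699026741943050,
    -0.5873179542866171, -0.3678314989981802, -0.1252334085114692),
  c(-0.9931285991850949, -0.9639719272779138, -0.9122344282513259,
    -0.8391169718222188, -0.7463319064601508, -0.6360536807265150,
    -0.5108670019508271, -0.3737060887154196, -0.2277858511416451,
    -0.07652652113349733)
)

# Standard bivariate normal P(X <= h, Y <= k) with correlation rho.
# Deterministic Gauss-Legendre evaluation (Drezner-Wesolowsky for
# |rho| < 0.925, Genz's tail-stable transformation otherwise); absolute
# accuracy ~1e-15.
pbvn <- function(h, k, rho) {
  if (is.na(rho) || abs(rho) > 1 + 1e-12) stop("invalid correlation")
  rho <- max(-1, min(1, rho))
  ng <- if (abs(rho) < 0.3) 1L else if (abs(rho) < 0.75) 2L else 3L
  w <- .bvn_w[[ng]]; x <- .bvn_x[[ng]]
  twopi <- 2 * pi
  # work in the survival form bvnd(a, b) = P(X > a, Y > b)
  a <- -h; b <- -k
  hk <- a * b
  bvn <- 0
  if (abs(rho) < 0.925) {
    if (abs(rho) > 0) {
      hs <- (a * a + b * b) / 2
      asr <- asin(rho)
      sn <- sin(asr * (c(x, -x) + 1) / 2)
      bvn <- sum(c(w, w) * exp((sn * hk - hs) / (1 - sn * sn)))
      bvn <- bvn * asr / (2 * twopi)
    }
    bvn <- bvn + stats::pnorm(-a) * stats::pnorm(-b)
  } else {
    if (rho < 0) {
      b <- -b
      hk <- -hk
    }
    if (abs(rho) < 1) {
      as1 <- (1 - rho) * (1 + rho)
      aa <- sqrt(as1)
      bs <- (a - b)^2
      cc <- (4 - hk) / 8
      dd <- (12 - hk) / 16
      asr <- -(bs / as1 + hk) / 2
      if (asr > -100) {
        bvn <- aa * exp(asr) *
          (1 - cc * (bs - as1) * (1 - dd * bs / 5) / 3 +
             cc * dd * as1 * as1 / 5)
      }
      if (-hk < 100) {
        bb <- sqrt(bs)
        bvn <- bvn - exp(-hk / 2) * sqrt(twopi) * stats::pnorm(-bb / aa) *
          bb * (1 - cc * bs * (1 - dd * bs / 5) / 3)
      }
      aa <- aa / 2
      xs <- (aa * (c(x, -x) + 1))^2
      rs <- sqrt(1 - xs)
      asr <- -(bs / xs + hk) / 2
      ok <- asr > -100
      if (any(ok)) {
        bvn <- bvn + sum(aa * c(w, w)[ok] * exp(asr[ok]) *
          (exp(-hk * (1 - rs[ok]) / (2 * (1 + rs[ok]))) / rs[ok] -
             (1 + cc * xs[ok] * (1 + dd * xs[ok]))))
      }
      bvn <- -bvn / twopi
    }
    if (rho > 0) {
      bvn <- bvn + stats::pnorm(-max(a, b))
    } else {
      bvn <- -bvn
      if (b > a) bvn <- bvn + stats::pnorm(b) - stats::pnorm(a)
    }
  }
  min(max(bvn, 0), 1)
}

# Run `expr` under a fixed RNG state and restore the caller's state after.
with_fixed_rng <- function(expr, seed = 190561L) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

check_pd <- function(sigma, label = "sigma") {
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop(
      "covariance matrix `", label, "` is not positive definite ",
      "(condition number ", format(kappa(sigma), digits = 4), ")",
      call. = FALSE
    )
  }
  invisible(ch)
}

# CDF tolerant of the (numerically) singular conditional covariances that
# arise inside the moment recursion; adds a tiny ridge when needed.
mvn_cdf_psd <- function(upper, mean, sigma) {
  d <- length(upper)
  if (d >= 3L) {
    sigma <- as.matrix(sigma)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) {
      sigma <- sigma + diag(1e-10 * max(diag(sigma), 1), d)
    }
  }
  mvn_cdf_core(upper, mean, sigma)
}

#' Moments of an upper-truncated multivariate normal distribution
#'
#' Closed-form mean and covariance of `X | X <= upper` for
#' `X ~ N(mean, sigma)`, via the Tallis-type reduction: the first moment
#' needs, for each truncated coordinate, its marginal density at the limit
#' times a (d-1)-dimensional normal probability, and the second moment
#' additionally needs bivariate densities at pairs of limits times
#' (d-2)-dimensional probabilities. `Inf` entries in `upper` mark
#' coordinates that are not truncated; with every limit infinite the
#' untruncated moments are returned and the log region mass is 0.
#'
#' This is the computational core of the EM algorithm's E-step for
#' left-censored responses: a left-censored block of a response vector is
#' the restriction of a Gaussian to an upper rectangle at the detection
#' limits.
#'
#' @inheritParams mvn_cdf
#' @param mass_floor Smallest admissible probability of the truncation
#'   region; below it the region is declared degenerate and an error of
#'   class `"censmix_low_mass"` is thrown (callers may fall back to
#'   imputing the limits).
#' @return A list of class `"censmix_tmvn"` with elements `mean` (vector),
#'   `cov` (symmetric matrix) and `log_mass` (log probability of the
#'   region).
#' @examples
#' m <- tmvn_moments(0, mean = 0, sigma = matrix(1))
#' m$mean   # -dnorm(0)/pnorm(0) = -0.7979
#' @export
tmvn_moments <- function(upper, mean = 0, sigma, mass_floor = 1e-12) {
  sigma <- as.matrix(sigma)
  d <- length(upper)
  mean <- rep_len(mean, d)
  if (d < 1L) stop("`upper` must have length >= 1")
  if (nrow(sigma) != d) stop("`sigma` must be ", d, "x", d)
  fin <- is.finite(upper)
  if (!any(fin)) {
    return(structure(
      list(mean = mean, cov = sigma, log_mass = 0),
      class = "censmix_tmvn"
    ))
  }
  if (any(upper == -Inf)) {
    stop("upper limit of -Inf gives an empty truncation region")
  }
  alpha <- mvn_cdf_core(upper, mean, sigma)
  if (alpha < mass_floor) {
    stop(structure(
      class = c("censmix_low_mass", "error", "condition"),
      list(
        message = paste0(
          "truncation region mass ", format(alpha, digits = 4),
          " below floor ", format(mass_floor, digits = 4)
        ),
        call = NULL
      )
    ))
  }
  if (d == 1L) {
    s <- sqrt(sigma[1L, 1L])
    z <- (upper - mean) / s
    h <- exp(stats::dnorm(z, log = TRUE) - stats::pnorm(z, log.p = TRUE))
    mu_t <- mean - s * h
    var_t <- sigma[1L, 1L] * (1 - z * h - h * h)
    return(structure(
      list(mean = mu_t, cov = matrix(max(var_t, 0)), log_mass = log(alpha)),
      class = "censmix_tmvn"
    ))
  }

  u <- upper - mean   # centred limits
  sdiag <- diag(sigma)
  idx_fin <- which(fin)

  # F_k = phi(u_k) * P(remaining coords <= limits | X_k = u_k)
  Fk <- numeric(d)
  for (k in idx_fin) {
    fk <- stats::dnorm(u[k], 0, sqrt(sdiag[k]))
    if (fk > 0) {
      rest <- seq_len(d)[-k]
      cm <- sigma[rest, k] * (u[k] / sdiag[k])
      cv <- sigma[rest, rest, drop = FALSE] -
        tcrossprod(sigma[rest, k]) / sdiag[k]
      Fk[k] <- fk * mvn_cdf_psd(u[rest], cm, cv)
    }
  }

  # F_kq = phi2(u_k, u_q) * P(remaining <= limits | X_k = u_k, X_q = u_q)
  F2 <- matrix(0, d, d)
  if (length(idx_fin) >= 2L) {
    for (ai in seq_len(length(idx_fin) - 1L)) {
      for (bi in (ai + 1L):length(idx_fin)) {
        k <- idx_fin[ai]; q <- idx_fin[bi]
        S2 <- sigma[c(k, q), c(k, q)]
        f2 <- dmvnorm2(u[c(k, q)], S2)
        if (f2 > 0) {
          rest <- seq_len(d)[-c(k, q)]
          if (length(rest) == 0L) {
            F2[k, q] <- f2
          } else {
            B <- sigma[rest, c(k, q), drop = FALSE]
            w2 <- solve(S2, u[c(k, q)])
            cm <- drop(B %*% w2)
            cv <- sigma[rest, rest, drop = FALSE] - B %*% solve(S2, t(B))
            F2[k, q] <- f2 * mvn_cdf_psd(u[rest], cm, cv)
          }
          F2[q, k] <- F2[k, q]
        }
      }
    }
  }

  mu_c <- -drop(sigma %*% Fk) / alpha       # centred truncated mean
  ukFk <- ifelse(fin, u * Fk, 0)

  # second-moment matrix (vectorised Tallis second-order terms)
  T1 <- -(sigma %*% (ukFk / sdiag * t(sigma))) / alpha
  A <- sigma %*% F2                          # A[j,k] = sum_q s_jq F2[kq]
  ck <- rowSums(sigma * F2)                  # c_k = sum_q s_kq F2[kq]
  Vmat <- A - sweep(sigma, 2L, ck / sdiag, "*")
  T2 <- sigma %*% t(Vmat) / alpha
  M <- sigma + T1 + T2

  covt <- M - tcrossprod(mu_c)
  covt <- (covt + t(covt)) / 2
  structure(
    list(mean = mean + mu_c, cov = covt, log_mass = log(alpha)),
    class = "censmix_tmvn"
  )
}

# Bivariate normal density at a point, zero mean, covariance S (2x2).
dmvnorm2 <- function(x, S) {
  det2 <- S[1L, 1L] * S[2L, 2L] - S[1L, 2L]^2
  if (det2 <= 0) return(0)
  qf <- (x[1L]^2 * S[2L, 2L] - 2 * x[1L] * x[2L] * S[1L, 2L] +
           x[2L]^2 * S[1L, 1L]) / det2
  exp(-0.5 * qf) / (2 * pi * sqrt(det2))
}

#' Moments of a censored block after conditioning on observed coordinates
#'
#' Splits a Gaussian vector into observed and censored coordinates, applies
#' the Gaussian conditioning formula given the observed values, and
#' truncates the conditional law of the censored block at the detection
#' limits. The returned `log_mass` is the log probability that the censored
#' block lies below its limits given the observed block, i.e. the censored
#' factor of the observed-data likelihood.
#'
#' @param q_obs Observed values (length = `length(obs_idx)`).
#' @param limits Upper limits for the censored coordinates
#'   (length = `length(cens_idx)`).
#' @param mean,sigma Moments of the full d-dimensional Gaussian.
#' @param obs_idx,cens_idx Integer index sets partitioning `1:d`;
#'   `cens_idx` must be nonempty.
#' @inheritParams tmvn_moments
#' @return A `"censmix_tmvn"` list for the censored block.
#' @export
cond_trunc_moments <- function(q_obs, limits, mean, sigma,
                               obs_idx, cens_idx, mass_floor = 1e-12) {
  sigma <- as.matrix(sigma)
  d <- nrow(sigma)
  mean <- rep_len(mean, d)
  if (length(cens_idx) == 0L) stop("`cens_idx` must be nonempty")
  if (!setequal(c(obs_idx, cens_idx), seq_len(d)) ||
      length(obs_idx) + length(cens_idx) != d) {
    stop("`obs_idx` and `cens_idx` must partition 1:", d)
  }
  if (length(obs_idx) == 0L) {
    return(tmvn_moments(limits, mean, sigma, mass_floor))
  }
  Voo <- sigma[obs_idx, obs_idx, drop = FALSE]
  ch <- tryCatch(chol(Voo), error = function(e) NULL)
  if (is.null(ch)) stop("observed-block covariance is singular")
  Vco <- sigma[cens_idx, obs_idx, drop = FALSE]
  w <- backsolve(ch, forwardsolve(t(ch), q_obs - mean[obs_idx]))
  cm <- mean[cens_idx] + drop(Vco %*% w)
  K <- backsolve(ch, forwardsolve(t(ch), t(Vco)))
  cv <- sigma[cens_idx, cens_idx, drop = FALSE] - Vco %*% K
  cv <- (cv + t(cv)) / 2
  tmvn_moments(limits, cm, cv, mass_floor)
}
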