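#' Control settings for the EM algorithm
#'
#' @param tol Convergence threshold on the relative change of the observed
#'   log-likelihood between successive iterations.
#' @param max_iter Iteration cap per EM chain. Convergence of this EM is
#'   slow by construction (three kinds of missing data: memberships, random
#'   effects, censored values), so the cap is generous.
#' @param n_starts Number of random initializations; the chain with the
#'   highest observed log-likelihood wins.
#' @param seed Master seed; every source of randomness in a fit (partition
#'   starts, any quasi-random CDF fallback) derives from it.
#' @param starve_floor A component whose total responsibility falls below
#'   `starve_floor * N` aborts its chain (prevents singular updates).
#' @param verbose Print per-chain progress.
#' @return A list of class `"censmix_control"`.
#' @export
censmix_control <- function(tol = 1e-6, max_iter = 500L, n_starts = 5L,
                            seed = NULL, starve_floor = 1e-6,
                            verbose = FALSE) {
  if (tol <= 0) stop("`tol` must be > 0")
  structure(
    list(tol = tol, max_iter = as.integer(max_iter),
         n_starts = as.integer(n_starts),
         seed = if (is.null(seed)) NULL else as.integer(seed),
         starve_floor = starve_floor, verbose = isTRUE(verbose)),
    class = "censmix_control"
  )
}

# ---- E-step ---------------------------------------------------------------

# Posterior component probabilities and the conditional moments of the
# censored responses and random effects, per individual and component.
# Uses the iterated expectation: condition the marginal law of Y_i on the
# observed coordinates, truncate the censored block at its limits, then
# propagate to the random effects through the Gaussian linear identities
#   E[b | Y]   = Psi Z' V^{-1} (Y - mu)
#   Cov[b | q] = Psi - Psi Z' V^{-1} Z Psi + W' Omega W,  W = V^{-1} Z Psi
#   Cov[Y, b | q] = Omega W.
e_step <- function(dataset, params, starve_floor = 0) {
  G <- length(params$pi)
  N <- dataset$N
  r <- dataset$r
  ll <- matrix(NA_real_, N, G)
  comp <- vector("list", G)
  for (g in seq_len(G)) comp[[g]] <- vector("list", N)

  for (g in seq_len(G)) {
    s2 <- params$sigma2[g]
    psi <- if (r > 0L) params$Psi[[g]][1L, 1L] else 0
    mu_all <- drop(dataset$Xall %*% params$alpha[, g])
    for (i in seq_len(N)) {
      ind <- dataset$individuals[[i]]
      cz <- ind$cens == 1L
      n <- ind$n
      mu <- mu_all[ind$rows]
      if (!any(cz)) {
        yhat <- ind$q
        sOmega <- trOmega <- 0
        ll[i, g] <- cs_ldnorm(ind$q, mu, s2, psi)
      } else {
        cm <- censored_moments(ind, mu, s2, psi, cz)
        yhat <- cm$yhat
        trOmega <- sum(diag(cm$cov_c))
        sOmega <- sum(cm$cov_c)
        ll[i, g] <- cm$loglik
      }
      rec <- list(yhat = yhat, trOmega = trOmega)
      if (r > 0L) {
        # random-intercept identities: V^{-1} 1 = 1 / (s2 + n psi)
        w0 <- psi / (s2 + n * psi)
        rec$bhat <- w0 * sum(yhat - mu)
        Bcov <- psi * s2 / (s2 + n * psi) + w0 * w0 * sOmega
        rec$Bcov <- matrix(Bcov)
        rec$trZBZ <- n * Bcov
        rec$crossZY <- w0 * sOmega
      }
      comp[[g]][[i]] <- rec
    }
  }

  lw <- sweep(ll, 2L, log(params$pi), "+")
  m <- apply(lw, 1L, max)
  lse <- m + log(rowSums(exp(lw - m)))
  tau <- exp(lw - lse)
  tau <- tau / rowSums(tau)
  loglik <- sum(lse)

  if (any(colSums(tau) < starve_floor * N)) {
    stop(structure(
      class = c("censmix_starved", "error", "condition"),
      list(message = paste0(
        "component starvation: responsibilities ",
        paste(format(colSums(tau), digits = 3), collapse = ", ")
      ), call = NULL)
    ))
  }

  list(tau = tau, loglik = loglik, ll = ll, comp = comp)
}

# Conditional moments of one individual's response given the observed
# coordinates and the censoring event, under the compound-symmetric
# marginal V = s2*I + psi*J. Returns the conditional mean of the full
# response vector, the conditional covariance of the censored block, and
# the observed-data log-likelihood contribution.
censored_moments <- function(ind, mu, s2, psi, cz = ind$cens == 1L) {
  tm <- tryCatch({
    if (all(cz)) {
      cs_trunc_moments(ind$q, mu, s2, psi)
    } else {
      o <- !cz
      no <- sum(o)
      # conditioning CS(s2, psi) on the observed block shifts the censored
      # means equally and keeps compound symmetry
      w_o <- psi / (s2 + no * psi)
      shift <- w_o * sum(ind$q[o] - mu[o])
      psi_t <- psi * s2 / (s2 + no * psi)
      tm <- cs_trunc_moments(ind$q[cz], mu[cz] + shift, s2, psi_t)
      tm$log_mass <- tm$log_mass + cs_ldnorm(ind$q[o], mu[o], s2, psi)
      tm
    }
  }, censmix_low_mass = function(e) NULL)
  if (is.null(tm)) {
    # degenerate truncation region: impute the limits
    censmix_log_event("mass_floor_fallback")
    nc <- sum(cz)
    tm <- list(mean = ind$q[cz], cov = matrix(0, nc, nc),
               log_mass = log(1e-300) +
                 if (all(cz)) 0 else cs_ldnorm(ind$q[!cz], mu[!cz],
                                               s2, psi))
  }
  yhat <- ind$q
  yhat[cz] <- tm$mean
  list(yhat = yhat, cov_c = tm$cov, cz = cz, loglik = tm$log_mass)
}

# ---- M-step ---------------------------------------------------------------

# Closed-form updates. alpha_g is a responsibility-weighted least-squares
# fit of yhat - Z bhat on X; sigma2_g uses the expected residual sum of
# squares at the *updated* alpha (still an exact joint maximiser, since the
# alpha update does not depend on sigma2); Psi_g averages bhat bhat' + Bcov.
# Under equality constraints the numerators and denominators pool over g.
m_step <- function(dataset, es, spec) {
  G <- spec$G
  N <- dataset$N
  tau <- es$tau
  Sg <- colSums(tau)
  p <- dataset$p
  r <- dataset$r

  alpha <- matrix(0, p, G)
  num_s <- den_s <- numeric(G)
  Psi_acc <- if (r > 0L) lapply(seq_len(G), function(g) matrix(0, r, r))

  for (g in seq_len(G)) {
    A <- matrix(0, p, p)
    cvec <- numeric(p)
    for (i in seq_len(N)) {
      ind <- dataset$individuals[[i]]
      rec <- es$comp[[g]][[i]]
      w <- tau[i, g]
      resp <- rec$yhat
      if (r > 0L) resp <- resp - rec$bhat
      A <- A + w * ind$XtX
      cvec <- cvec + w * drop(crossprod(ind$X, resp))
    }
    a_g <- tryCatch(solve(A, cvec), error = function(e) {
      stop("singular weighted design (rank deficiency) in component ", g,
           call. = FALSE)
    })
    alpha[, g] <- a_g
    mu_all <- drop(dataset$Xall %*% a_g)
    for (i in seq_len(N)) {
      ind <- dataset$individuals[[i]]
      rec <- es$comp[[g]][[i]]
      w <- tau[i, g]
      resid <- rec$yhat - mu_all[ind$rows]
      ess <- rec$trOmega
      if (r > 0L) {
        resid <- resid - rec$bhat
        ess <- ess + rec$trZBZ - 2 * rec$crossZY
        Psi_acc[[g]] <- Psi_acc[[g]] + w * (tcrossprod(rec$bhat) + rec$Bcov)
      }
      num_s[g] <- num_s[g] + w * (sum(resid^2) + ess)
      den_s[g] <- den_s[g] + w * ind$n
    }
  }

  sigma2 <- if (spec$equal_sigma) {
    rep(sum(num_s) / sum(den_s), G)
  } else {
    num_s / den_s
  }
  sigma2 <- pmax(sigma2, 1e-10)

  Psi <- NULL
  if (r > 0L) {
    Psi <- if (spec$equal_psi) {
      P <- Reduce(`+`, Psi_acc) / N
      rep(list(psd_clip(P)), G)
    } else {
      lapply(seq_len(G), function(g) psd_clip(Psi_acc[[g]] / Sg[g]))
    }
  }

  censmix_params(pi = Sg / N, alpha = alpha, sigma2 = sigma2, Psi = Psi)
}

psd_clip <- function(P) {
  P <- (P + t(P)) / 2
  e <- eigen(P, symmetric = TRUE)
  if (min(e$values) < 0) {
    censmix_log_event("psi_psd_clip")
    P <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    P <- (P + t(P)) / 2
  }
  P
}

# ---- initialization -------------------------------------------------------

# Random uniform partition of the individuals into G groups (each of size
# >= 2, redrawn up to 100 times), censored values held at their limits and
# random effects at zero, followed by an M-step on the hard assignments.
# A zero random-effect start would make Psi = 0 an absorbing state, so the
# random-intercept variance is instead seeded from the between-individual
# variance of mean residuals within each initial group.
initialize_params <- function(dataset, spec) {
  G <- spec$G
  N <- dataset$N
  if (G == 1L) {
    tau <- matrix(1, N, 1L)
  } else {
    for (try in seq_len(100L)) {
      grp <- sample.int(G, N, replace = TRUE)
      if (min(tabulate(grp, G)) >= 2L) break
      if (try == 100L) stop("could not draw a partition with >= 2 ",
                            "individuals per group")
    }
    tau <- matrix(0, N, G)
    tau[cbind(seq_len(N), grp)] <- 1
  }
  init_from_tau(dataset, spec, tau)
}

# Hard or soft responsibilities -> starting parameters via a pseudo M-step
# with yhat = q (limits imputed), bhat = 0, Omega = Bcov = 0.
init_from_tau <- function(dataset, spec, tau) {
  N <- dataset$N
  r <- dataset$r
  comp <- vector("list", spec$G)
  for (g in seq_len(spec$G)) {
    comp[[g]] <- lapply(dataset$individuals, function(ind) {
      rec <- list(yhat = ind$q, trOmega = 0)
      if (r > 0L) {
        rec$bhat <- numeric(r)
        rec$Bcov <- matrix(0, r, r)
        rec$trZBZ <- 0
        rec$crossZY <- 0
      }
      rec
    })
  }
  es <- list(tau = tau, comp = comp)
  spec0 <- spec
  spec0$equal_psi <- FALSE           # Psi rebuilt below anyway
  params <- m_step(dataset, es, spec0)
  if (r > 0L) {
    Psi <- vector("list", spec$G)
    for (g in seq_len(spec$G)) {
      mres <- w <- numeric(N)
      for (i in seq_len(N)) {
        ind <- dataset$individuals[[i]]
        mres[i] <- mean(ind$q - drop(ind$X %*% params$alpha[, g]))
        w[i] <- tau[i, g]
      }
      wsum <- sum(w)
      mbar <- sum(w * mres) / wsum
      v <- sum(w * (mres - mbar)^2) / max(wsum - 1, 1)
      v <- max(v, 0.1 * params$sigma2[g])
      Psi[[g]] <- diag(v, r)
    }
    if (spec$equal_psi) {
      P <- Reduce(`+`, Psi) / spec$G
      Psi <- rep(list(P), spec$G)
    }
    params <- censmix_params(params$pi, params$alpha, params$sigma2, Psi)
  }
  params
}

# ---- EM driver ------------------------------------------------------------

run_em_chain <- function(dataset, spec, control, params) {
  trace <- numeric(0)
  converged <- FALSE
  es <- NULL
  ll_old <- NA_real_
  for (it in seq_len(control$max_iter)) {
    es <- e_step(dataset, params, starve_floor = control$starve_floor)
    trace[it] <- es$loglik
    if (it > 1L &&
        abs(es$loglik - ll_old) / max(abs(ll_old), 1e-10) < control$tol) {
      converged <- TRUE
      break
    }
    ll_old <- es$loglik
    params <- m_step(dataset, es, spec)
  }
  list(params = params, loglik = es$loglik, trace = trace, tau = es$tau,
       niter = length(trace), converged = converged)
}

#' Fit a finite mixture of linear mixed models to left-censored data
#'
#' The workhorse of the package: fits a `G`-component mixture of Gaussian
#' linear (mixed) models with B-spline mean trajectories to long-format
#' longitudinal data with left-censored responses, by an EM algorithm whose
#' E-step evaluates posterior component probabilities together with
#' closed-form conditional moments of the censored responses (truncated
#' multivariate normal) and of the random effects, and whose M-step is in
#' closed form. The best of `n_starts` randomly initialized chains is
#' returned.
#'
#' @param data A data frame with columns `id`, `time`, `y`, `cens`
#'   (0 = observed, 1 = left-censored; for censored rows `y` records the
#'   detection limit) and optionally `limit` (per-row detection limit
#'   overriding `y` on censored rows). The response scale is taken as
#'   supplied (e.g. log10 copies/ml); no transformation is applied.
#' @param G Number of mixture components.
#' @param df B-spline degrees of freedom of the mean trajectories (1--5).
#' @param random_intercept Include a Gaussian random intercept per
#'   individual.
#' @param equal_sigma,equal_psi Constrain residual / random-intercept
#'   variances to be equal across components.
#' @param control A [censmix_control()] list.
#' @param init_tau Optional `N x G` matrix of starting responsibilities
#'   (rows in first-appearance order of `id`); replaces the random starts —
#'   used e.g. to warm-start constrained fits from an unconstrained one.
#' @param ignore_censoring If `TRUE` the censoring indicators are ignored
#'   and recorded limits treated as observed values (the naive fit the
#'   censoring-aware model is compared against).
#' @return An object of class `"censmix_fit"`; see [tidy.censmix_fit()],
#'   [glance.censmix_fit()], [augment.censmix_fit()],
#'   [autoplot.censmix_fit()].
#' @examples
#' sim <- censmix_simulate(example_design(N = 40), seed = 1)
#' fit <- censmix_fit(sim$data, G = 2, df = 2,
#'                    control = censmix_control(n_starts = 2, seed = 1,
#'                                              max_iter = 100))
#' glance(fit)
#' @export
censmix_fit <- function(data, G, df = 2L, random_intercept = TRUE,
                        equal_sigma = FALSE, equal_psi = FALSE,
                        control = censmix_control(), init_tau = NULL,
                        ignore_censoring = FALSE) {
  spec <- censmix_spec(G, df, random_intercept, equal_sigma, equal_psi)
  data <- as.data.frame(data)
  if (ignore_censoring) {
    if (!is.null(data$limit)) {
      cz <- data$cens == 1
      ok <- is.finite(data$limit[cz])
      data$y[cz][ok] <- data$limit[cz][ok]
    }
    data$cens <- 0
  }
  dataset <- build_dataset(data, spec)
  seed <- if (is.null(control$seed)) {
    sample.int(.Machine$integer.max, 1L)
  } else {
    control$seed
  }

  chains <- vector("list", 0L)
  best <- NULL
  # warm starts and G = 1 initialisation are deterministic: one chain
  n_starts <- if (!is.null(init_tau) || G == 1L) 1L else control$n_starts
  for (s in seq_len(n_starts)) {
    set.seed(derive_seed(seed, s, 7919))
    res <- tryCatch({
      params0 <- if (is.null(init_tau)) {
        initialize_params(dataset, spec)
      } else {
        init_from_tau(dataset, spec, init_tau)
      }
      run_em_chain(dataset, spec, control, params0)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      chains[[s]] <- list(ok = FALSE, message = conditionMessage(res))
      next
    }
    chains[[s]] <- list(ok = TRUE, loglik = res$loglik, niter = res$niter,
                        converged = res$converged)
    if (control$verbose) {
      message(sprintf("chain %d: loglik %.4f after %d iterations",
                      s, res$loglik, res$niter))
    }
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (is.null(best)) {
    stop("all EM chains failed: ",
         paste(vapply(chains, function(ch) ch$message %||% "",
                      character(1L)), collapse = "; "))
  }

  k <- count_parameters(spec, dataset$p, dataset$r)
  nobs <- sum(vapply(dataset$individuals, `[[`, 0L, "n"))
  structure(
    list(
      params = best$params, loglik = best$loglik, trace = best$trace,
      tau = best$tau, niter = best$niter, converged = best$converged,
      seed = seed, spec = spec, spline = dataset$spline,
      k = k, N = dataset$N, nobs = nobs,
      AIC = -2 * best$loglik + 2 * k,
      BIC = -2 * best$loglik + k * log(dataset$N),
      ids = dataset$ids, data = data, dataset = dataset,
      chains = chains, control = control
    ),
    class = "censmix_fit"
  )
}

#' @export
print.censmix_fit <- function(x, ...) {
  cat(sprintf(
    "censmix fit: G = %d, df = %d, %s%s%s\n",
    x$spec$G, x$spec$df,
    if (x$spec$random_intercept) "random intercept" else "no random effects",
    if (x$spec$equal_sigma) ", equal sigma2" else "",
    if (x$spec$equal_psi) ", equal Psi" else ""
  ))
  cat(sprintf("  N = %d individuals, %d observations, k = %d\n",
              x$N, x$nobs, x$k))
  cat(sprintf("  logLik %.4f, AIC %.2f, BIC %.2f (%d iterations%s)\n",
              x$loglik, x$AIC, x$BIC, x$niter,
              if (x$converged) "" else ", NOT converged"))
  cat("  weights:", paste(format(x$params$pi, digits = 3),
                          collapse = " "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive a child seed from a master seed and an index, safely inside the
# 32-bit integer range
derive_seed <- function(seed, index, mult) {
  as.integer((as.numeric(seed) + as.numeric(mult) * as.numeric(index)) %%
               2147483647)
}
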