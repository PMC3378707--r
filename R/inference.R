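# Score-based inference: per-individual gradients of the observed-data
# log-likelihood, the empirical information matrix built from their outer
# products, and pointwise confidence bands for the component mean curves.
#
# The component scores use Fisher's identity: the gradient of the censored
# observed-data log-likelihood of component g equals the conditional
# expectation, given the observed data, of the gradient of the complete
# Gaussian log-density. With r = yhat - mu and Omega the conditional
# covariance of the response (nonzero only on the censored block),
#   d/d alpha:  X' V^{-1} r
#   d/d theta (theta any variance parameter, D = dV/d theta):
#     -tr(V^{-1} D)/2 + [ r' V^{-1} D V^{-1} r + tr(V^{-1} D V^{-1} Omega) ]/2
# and the mixture score weights component scores by the posterior
# probabilities tau_ig; the weights themselves contribute
# tau_ig/pi_g - tau_iG/pi_G on the (G-1)-dimensional free chart.

# name and index the free parameters of a fitted model
param_index <- function(fit) {
  spec <- fit$spec
  G <- spec$G
  p <- nrow(fit$params$alpha)
  terms <- rownames(fit$params$alpha) %||% colnames(fit$dataset$Xall) %||%
    paste0("x", seq_len(p))
  out <- list()
  if (G > 1L) {
    out[[length(out) + 1L]] <- tibble::tibble(
      block = "pi", component = seq_len(G - 1L),
      term = paste0("pi", seq_len(G - 1L))
    )
  }
  for (g in seq_len(G)) {
    out[[length(out) + 1L]] <- tibble::tibble(
      block = "alpha", component = g, term = terms
    )
  }
  if (spec$equal_sigma) {
    out[[length(out) + 1L]] <- tibble::tibble(
      block = "sigma2", component = NA_integer_, term = "sigma2"
    )
  } else {
    out[[length(out) + 1L]] <- tibble::tibble(
      block = "sigma2", component = seq_len(G),
      term = paste0("sigma2_", seq_len(G))
    )
  }
  if (spec$random_intercept) {
    if (spec$equal_psi) {
      out[[length(out) + 1L]] <- tibble::tibble(
        block = "psi", component = NA_integer_, term = "psi"
      )
    } else {
      out[[length(out) + 1L]] <- tibble::tibble(
        block = "psi", component = seq_len(G),
        term = paste0("psi_", seq_len(G))
      )
    }
  }
  idx <- dplyr::bind_rows(out)
  idx$index <- seq_len(nrow(idx))
  idx
}

#' Per-individual score vectors of the observed-data log-likelihood
#'
#' Analytic gradients of each individual's log mixture likelihood with
#' respect to the free parameters (component weights on the (G-1)-chart,
#' fixed effects, residual variances, random-intercept variances), with the
#' censored coordinates handled through the conditional truncated-normal
#' moments. Equality-constrained variance blocks are collapsed by summing
#' the component-wise scores.
#'
#' @param fit A converged [censmix_fit()] object.
#' @return An `N x k` matrix; rows sum to the total gradient, which is
#'   approximately zero at the MLE.
#' @export
score_vectors <- function(fit) {
  params <- fit$params
  spec <- fit$spec
  dataset <- fit$dataset
  G <- spec$G
  N <- dataset$N
  p <- nrow(params$alpha)
  r <- dataset$r
  idx <- param_index(fit)
  k <- nrow(idx)
  S <- matrix(0, N, k, dimnames = list(dataset$ids, idx$term))

  # posterior responsibilities at the supplied parameters
  es <- e_step(dataset, params)
  tau <- es$tau

  col_pi <- which(idx$block == "pi")
  col_alpha <- function(g) which(idx$block == "alpha" & idx$component == g)
  col_sigma <- function(g) {
    if (spec$equal_sigma) which(idx$block == "sigma2") else
      which(idx$block == "sigma2" & idx$component == g)
  }
  col_psi <- function(g) {
    if (spec$equal_psi) which(idx$block == "psi") else
      which(idx$block == "psi" & idx$component == g)
  }

  for (i in seq_len(N)) {
    ind <- dataset$individuals[[i]]
    cz <- ind$cens == 1L
    n <- ind$n
    if (G > 1L) {
      S[i, col_pi] <- tau[i, seq_len(G - 1L)] / params$pi[seq_len(G - 1L)] -
        tau[i, G] / params$pi[G]
    }
    for (g in seq_len(G)) {
      s2 <- params$sigma2[g]
      psi <- if (r > 0L) params$Psi[[g]][1L, 1L] else 0
      mu <- drop(ind$X %*% params$alpha[, g])
      V <- diag(s2, n)
      if (psi > 0) V <- V + psi
      Vinv <- solve(V)
      if (any(cz)) {
        cmom <- censored_moments(ind, mu, s2, psi, cz)
        yhat <- cmom$yhat
        Omega <- matrix(0, n, n)
        Omega[cz, cz] <- cmom$cov_c
      } else {
        yhat <- ind$q
        Omega <- NULL
      }
      resid <- yhat - mu
      w <- tau[i, g]
      if (!is.finite(w)) stop("non-finite responsibility for individual ",
                              ind$id)

      # alpha block
      Vr <- drop(Vinv %*% resid)
      S[i, col_alpha(g)] <- w * drop(crossprod(ind$X, Vr))

      # sigma2 block: D = I
      s_sig <- -0.5 * sum(diag(Vinv)) + 0.5 * sum(Vr * Vr)
      if (!is.null(Omega)) {
        s_sig <- s_sig + 0.5 * sum(Vinv * (Omega %*% Vinv))
      }
      S[i, col_sigma(g)] <- S[i, col_sigma(g)] + w * s_sig

      # psi block: D = J (all-ones), so tr(V^{-1} D) = sum(V^{-1}),
      # r'V^{-1} D V^{-1} r = (1'V^{-1}r)^2, and the Omega term is
      # v' Omega v with v = V^{-1} 1
      if (r > 0L) {
        v1 <- rowSums(Vinv)
        s_psi <- -0.5 * sum(v1) + 0.5 * sum(v1 * resid)^2
        if (!is.null(Omega)) {
          s_psi <- s_psi + 0.5 * drop(crossprod(v1, Omega %*% v1))
        }
        S[i, col_psi(g)] <- S[i, col_psi(g)] + w * s_psi
      }
    }
  }
  if (!all(is.finite(S))) {
    bad <- which(!is.finite(S), arr.ind = TRUE)[1L, ]
    stop("non-finite score for individual ", dataset$ids[bad[1L]],
         " in block ", idx$block[bad[2L]])
  }
  S
}

#' Empirical-information standard errors for a fitted model
#'
#' Approximates the information matrix by the sum of outer products of the
#' per-individual score vectors (no second derivatives needed for
#' independent individuals) and returns standard errors from its inverse.
#' A numerically singular information matrix falls back to the
#' Moore--Penrose pseudo-inverse with a warning and flags the affected
#' coordinates.
#'
#' @param fit A converged [censmix_fit()] object.
#' @return An object of class `"censmix_info"`: list with `scores` (N x k),
#'   `info` (k x k), `cov` (its inverse), `se`, `param_index` (tibble
#'   mapping coordinates to named parameters) and `pseudo` (logical flag).
#' @export
censmix_se <- function(fit) {
  if (!isTRUE(fit$converged)) {
    warning("fit has not converged; standard errors may be unreliable")
  }
  S <- score_vectors(fit)
  info <- crossprod(S)
  info <- (info + t(info)) / 2
  k <- ncol(info)
  e <- eigen(info, symmetric = TRUE)
  tol <- max(e$values) * 1e-12
  pseudo <- any(e$values < tol)
  if (pseudo) {
    warning("empirical information is numerically singular; ",
            "using pseudo-inverse")
    inv_vals <- ifelse(e$values > tol, 1 / e$values, 0)
  } else {
    inv_vals <- 1 / e$values
  }
  cov <- e$vectors %*% (inv_vals * t(e$vectors))
  cov <- (cov + t(cov)) / 2
  idx <- param_index(fit)
  se <- sqrt(pmax(diag(cov), 0))
  if (pseudo) {
    flagged <- e$values < tol
    idx$flagged <- colSums((e$vectors[, flagged, drop = FALSE])^2) > 1e-6
  } else {
    idx$flagged <- FALSE
  }
  structure(
    list(scores = S, info = info, cov = cov, se = se, param_index = idx,
         pseudo = pseudo),
    class = "censmix_info"
  )
}

#' Pointwise confidence band for a component mean curve
#'
#' The fitted mean of component `g` at each time is `b(t)' alpha_g` with
#' `b(t)` the spline basis row; its pointwise variance is
#' `b(t)' Cov(alpha_g) b(t)` with the coefficient covariance taken from the
#' inverse empirical information, giving the usual normal-quantile band.
#'
#' @param fit A [censmix_fit()] object.
#' @param info A [censmix_se()] result for `fit` (computed if omitted).
#' @param component Component index.
#' @param times Evaluation times (within the spline boundary).
#' @param level Coverage level of the pointwise band.
#' @return A tibble with columns `time`, `estimate`, `lower`, `upper`,
#'   `component`.
#' @export
censmix_band <- function(fit, info = NULL, component = 1L,
                         times = NULL, level = 0.95) {
  if (is.null(info)) info <- censmix_se(fit)
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  g <- as.integer(component)
  if (g < 1L || g > fit$spec$G) stop("no such component")
  if (is.null(times)) {
    times <- seq(fit$spline$boundary[1L], fit$spline$boundary[2L],
                 length.out = 50L)
  }
  B <- spline_basis(times, fit$spline)
  est <- drop(B %*% fit$params$alpha[, g])
  cols <- which(info$param_index$block == "alpha" &
                  info$param_index$component == g)
  Ca <- info$cov[cols, cols, drop = FALSE]
  sdv <- sqrt(pmax(rowSums((B %*% Ca) * B), 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  tibble::tibble(
    time = times, estimate = est,
    lower = est - z * sdv, upper = est + z * sdv,
    component = g
  )
}
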