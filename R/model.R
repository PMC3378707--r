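#' Model structure of a censored-mixture fit
#'
#' Bundles the structural choices of one model in the class: the number of
#' mixture components `G`, the spline flexibility `df` of the shared
#' fixed-effects basis, whether individuals carry a random intercept, and
#' whether the residual variances and/or random-effect variances are
#' constrained to be equal across components.
#'
#' @param G Number of components (>= 1).
#' @param df Spline degrees of freedom (1--5), see [spline_spec()].
#' @param random_intercept Logical; `FALSE` fits the mixture of ordinary
#'   regressions variant (no between-individual heterogeneity beyond the
#'   mixture itself).
#' @param equal_sigma Logical; pool the residual variance across components.
#' @param equal_psi Logical; pool the random-intercept variance across
#'   components (ignored when `random_intercept = FALSE`).
#' @return An object of class `"censmix_spec"`.
#' @export
censmix_spec <- function(G, df = 2L, random_intercept = TRUE,
                         equal_sigma = FALSE, equal_psi = FALSE) {
  G <- as.integer(G)
  if (G < 1L) stop("`G` must be >= 1")
  structure(
    list(
      G = G, df = as.integer(df),
      random_intercept = isTRUE(random_intercept),
      equal_sigma = isTRUE(equal_sigma),
      equal_psi = isTRUE(random_intercept) && isTRUE(equal_psi)
    ),
    class = "censmix_spec"
  )
}

#' Parameter set of a G-component censored mixture of mixed models
#'
#' @param pi Component weights, strictly positive, summing to one.
#' @param alpha `p x G` matrix of fixed-effect coefficient vectors.
#' @param sigma2 Length-`G` vector of residual variances (> 0).
#' @param Psi `NULL` (no random effects) or a list of `G` symmetric
#'   positive-semidefinite `r x r` random-effect covariance matrices.
#' @return An object of class `"censmix_params"`.
#' @export
censmix_params <- function(pi, alpha, sigma2, Psi = NULL) {
  alpha <- as.matrix(alpha)
  G <- length(pi)
  if (any(pi <= 0)) stop("component weights must be strictly positive")
  if (abs(sum(pi) - 1) > 1e-10) stop("component weights must sum to 1")
  if (ncol(alpha) != G) stop("`alpha` must have G = ", G, " columns")
  if (length(sigma2) != G || any(sigma2 <= 0)) {
    stop("`sigma2` must be ", G, " positive values")
  }
  if (!is.null(Psi)) {
    if (length(Psi) != G) stop("`Psi` must be a list of ", G, " matrices")
    Psi <- lapply(Psi, function(P) {
      P <- as.matrix(P)
      if (max(abs(P - t(P))) > 1e-8) stop("`Psi` must be symmetric")
      P <- (P + t(P)) / 2
      if (min(eigen(P, symmetric = TRUE, only.values = TRUE)$values) <
          -1e-8) {
        stop("`Psi` must be positive semi-definite")
      }
      P
    })
  }
  structure(
    list(pi = as.numeric(pi), alpha = alpha, sigma2 = as.numeric(sigma2),
         Psi = Psi),
    class = "censmix_params"
  )
}

#' Number of free parameters of a model structure
#'
#' `(G - 1)` free weights, `G * p` fixed effects, one residual variance per
#' component (or one shared), and `r (r + 1) / 2` random-effect covariance
#' parameters per component (or one shared block; none without random
#' effects). Used by the AIC/BIC penalties.
#'
#' @param spec A [censmix_spec()] object.
#' @param p Number of fixed-effect coefficients per component.
#' @param r Random-effects dimension (0 without random effects).
#' @return Integer count.
#' @export
count_parameters <- function(spec, p, r = as.integer(spec$random_intercept)) {
  if (p < 1L) stop("`p` must be >= 1")
  G <- spec$G
  k <- (G - 1L) + G * p
  k <- k + if (spec$equal_sigma) 1L else G
  if (r > 0L) {
    blk <- r * (r + 1L) / 2L
    k <- k + if (spec$equal_psi) blk else G * blk
  }
  as.integer(k)
}

# ---- internal dataset representation -------------------------------------

# Validate a long-format data frame and return it ordered by individual and
# time. Columns: id, time, y, cens (0/1), optional limit.
validate_long <- function(data) {
  need <- c("id", "time", "y", "cens")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  }
  bad <- which(!(data$cens %in% c(0, 1)))
  if (length(bad)) {
    stop("`cens` must be 0 or 1; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (anyNA(data$time) || !all(is.finite(data$time))) {
    stop("`time` must be finite")
  }
  if (anyNA(data$y) || !all(is.finite(data$y))) {
    stop("`y` must be finite (record the detection limit for censored rows)")
  }
  key <- paste(data$id, data$time, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (id, time) pair(s); offending row(s): ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "))
  }
  ord <- order(match(data$id, unique(data$id)), data$time)
  data[ord, , drop = FALSE]
}

# Build the per-individual structure (q, c, X, Z) for a given model spec.
# `q` holds the observed response, overridden by `limit` on censored rows
# when a limit column is present.
build_dataset <- function(data, spec, sspec = NULL) {
  data <- validate_long(as.data.frame(data))
  if (is.null(sspec)) sspec <- spline_spec(data$time, spec$df)
  q <- data$y
  if (!is.null(data$limit)) {
    cz <- data$cens == 1
    ok <- is.finite(data$limit[cz])
    q[cz][ok] <- data$limit[cz][ok]
  }
  X <- spline_basis(data$time, sspec)
  ids <- unique(data$id)
  idx <- split(seq_len(nrow(data)), match(data$id, ids))
  individuals <- lapply(seq_along(ids), function(i) {
    rows <- idx[[i]]
    n <- length(rows)
    list(
      id = ids[i],
      q = q[rows],
      cens = as.integer(data$cens[rows]),
      time = data$time[rows],
      X = X[rows, , drop = FALSE],
      Z = if (spec$random_intercept) matrix(1, n, 1L) else NULL,
      n = n,
      rows = rows,
      XtX = crossprod(X[rows, , drop = FALSE])
    )
  })
  structure(
    list(individuals = individuals, N = length(ids), ids = ids,
         spline = sspec, p = sspec$df + 1L,
         r = as.integer(spec$random_intercept), spec = spec,
         Xall = X),
    class = "censmix_data"
  )
}

# ---- marginal moments and likelihood -------------------------------------

# mu = X alpha_g, V = Z Psi_g Z' + sigma2_g I (V = sigma2_g I without
# random effects).
marginal_moments <- function(ind, params, g) {
  p <- nrow(params$alpha)
  if (ncol(ind$X) != p) {
    stop("design/parameter dimension mismatch for individual ", ind$id)
  }
  mu <- drop(ind$X %*% params$alpha[, g])
  V <- diag(params$sigma2[g], ind$n)
  if (!is.null(ind$Z) && !is.null(params$Psi)) {
    if (ncol(ind$Z) != nrow(params$Psi[[g]])) {
      stop("random design dimension mismatch for individual ", ind$id)
    }
    V <- V + ind$Z %*% params$Psi[[g]] %*% t(ind$Z)
  }
  list(mu = mu, V = V)
}

# Log-density of the uncensored block times the conditional normal
# probability of the censored block at its limits. `mom` may be passed to
# reuse precomputed marginal moments.
component_loglik <- function(ind, params, g, mom = NULL,
                             cdf_floor = 1e-300) {
  if (is.null(mom)) mom <- marginal_moments(ind, params, g)
  if (!all(is.finite(ind$q))) stop("non-finite response for individual ",
                                   ind$id)
  cz <- ind$cens == 1L
  if (!any(cz)) {
    return(ldmvnorm_chol(ind$q, mom$mu, mom$V))
  }
  if (all(cz)) {
    p <- mvn_cdf(ind$q, mom$mu, mom$V)
    if (p < cdf_floor) {
      censmix_log_event("cdf_floor")
      p <- cdf_floor
    }
    return(log(p))
  }
  o <- which(!cz); cc <- which(cz)
  Voo <- mom$V[o, o, drop = FALSE]
  ch <- chol(Voo)
  ll_obs <- ldmvnorm_chol(ind$q[o], mom$mu[o], Voo, ch = ch)
  Vco <- mom$V[cc, o, drop = FALSE]
  w <- backsolve(ch, forwardsolve(t(ch), ind$q[o] - mom$mu[o]))
  cm <- mom$mu[cc] + drop(Vco %*% w)
  K <- backsolve(ch, forwardsolve(t(ch), t(Vco)))
  cv <- mom$V[cc, cc, drop = FALSE] - Vco %*% K
  cv <- (cv + t(cv)) / 2
  pc <- mvn_cdf(ind$q[cc], cm, cv)
  if (pc < cdf_floor) {
    censmix_log_event("cdf_floor")
    pc <- cdf_floor
  }
  ll_obs + log(pc)
}

# Gaussian log-density via a Cholesky factor (reusable).
ldmvnorm_chol <- function(x, mu, V, ch = chol(V)) {
  z <- forwardsolve(t(ch), x - mu)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(z * z)
}

# N x G matrix of per-individual, per-component log-likelihood
# contributions log L_ig.
component_loglik_matrix <- function(dataset, params) {
  G <- length(params$pi)
  out <- matrix(NA_real_, dataset$N, G)
  for (i in seq_len(dataset$N)) {
    ind <- dataset$individuals[[i]]
    for (g in seq_len(G)) {
      out[i, g] <- component_loglik(ind, params, g)
    }
  }
  out
}

# Observed-data log-likelihood: sum_i log sum_g pi_g L_ig, stabilised by
# log-sum-exp.
observed_loglik <- function(dataset, params, ll_mat = NULL) {
  if (dataset$N < 1L) stop("empty dataset")
  if (is.null(ll_mat)) ll_mat <- component_loglik_matrix(dataset, params)
  lw <- sweep(ll_mat, 2L, log(params$pi), "+")
  m <- apply(lw, 1L, max)
  sum(m + log(rowSums(exp(lw - m))))
}

# ---- lightweight event log ------------------------------------------------

censmix_env <- new.env(parent = emptyenv())
censmix_env$events <- list()

censmix_log_event <- function(type) {
  n <- censmix_env$events[[type]]
  censmix_env$events[[type]] <- if (is.null(n)) 1L else n + 1L
  invisible(NULL)
}

censmix_reset_events <- function() {
  censmix_env$events <- list()
  invisible(NULL)
}

censmix_events <- function() censmix_env$events
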