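#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy the parameters of a censored-mixture fit
#'
#' @param x A [censmix_fit()] object.
#' @param se Add empirical-information standard errors (refits the score
#'   vectors; see [censmix_se()]).
#' @param info Optionally a precomputed [censmix_se()] result.
#' @param ... Unused.
#' @return A tibble with one row per free parameter: `block`, `component`,
#'   `term`, `estimate` and, with `se = TRUE`, `std.error`.
#' @method tidy censmix_fit
#' @export
tidy.censmix_fit <- function(x, se = FALSE, info = NULL, ...) {
  idx <- param_index(x)
  est <- numeric(nrow(idx))
  G <- x$spec$G
  for (j in seq_len(nrow(idx))) {
    g <- idx$component[j]
    est[j] <- switch(
      idx$block[j],
      pi = x$params$pi[g],
      alpha = x$params$alpha[match(idx$term[j],
                                   rownames(x$params$alpha) %||%
                                     colnames(x$dataset$Xall)), g],
      sigma2 = x$params$sigma2[if (is.na(g)) 1L else g],
      psi = x$params$Psi[[if (is.na(g)) 1L else g]][1L, 1L]
    )
  }
  out <- tibble::tibble(
    block = idx$block, component = idx$component, term = idx$term,
    estimate = est
  )
  if (se) {
    if (is.null(info)) info <- censmix_se(x)
    out$std.error <- info$se
  }
  out
}

#' One-row summary of a censored-mixture fit
#'
#' @param x A [censmix_fit()] object.
#' @param ... Unused.
#' @return A tibble with `logLik`, `AIC`, `BIC`, `k`, `N`, `nobs`,
#'   `niter`, `converged`.
#' @method glance censmix_fit
#' @export
glance.censmix_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, AIC = x$AIC, BIC = x$BIC, k = x$k,
    N = x$N, nobs = x$nobs, niter = x$niter, converged = x$converged
  )
}

#' Per-individual posterior summary of a censored-mixture fit
#'
#' @param x A [censmix_fit()] object.
#' @param ... Unused.
#' @return A tibble with one row per individual: `id`, the posterior
#'   probabilities `.tau1` ... `.tauG`, the maximum-a-posteriori component
#'   `.component` and its probability `.map_prob`.
#' @method augment censmix_fit
#' @export
augment.censmix_fit <- function(x, ...) {
  tau <- x$tau
  colnames(tau) <- paste0(".tau", seq_len(ncol(tau)))
  out <- tibble::tibble(id = x$ids)
  out <- dplyr::bind_cols(out, tibble::as_tibble(tau))
  out$.component <- apply(x$tau, 1L, which.max)
  out$.map_prob <- apply(x$tau, 1L, max)
  out
}

#' Tidy a model-selection table
#'
#' @param x A [censmix_select()] object.
#' @param ... Unused.
#' @return The selection tibble (one row per fitted grid cell).
#' @method tidy censmix_select
#' @export
tidy.censmix_select <- function(x, ...) x$table

#' @rdname tidy.censmix_select
#' @method glance censmix_select
#' @export
glance.censmix_select <- function(x, ...) {
  best <- x$table[x$table$cell == x$best_bic, ]
  tibble::tibble(
    n_models = nrow(x$table), n_converged = sum(x$table$converged),
    best_G = best$G, best_df = best$df,
    best_equal_sigma = best$equal_sigma, best_equal_psi = best$equal_psi,
    best_BIC = best$BIC
  )
}
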