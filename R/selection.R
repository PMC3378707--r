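#' Fit a grid of censored-mixture models and rank them by BIC/AIC
#'
#' Fits every combination of number of components, spline flexibility,
#' random-intercept presence and variance constraints with a shared EM
#' control, and tabulates log-likelihood, parameter count and information
#' criteria. `AIC = -2 l + 2 k`; `BIC = -2 l + k log(N)` with `N` the
#' number of individuals (the independent units of the mixture). Cells
#' whose EM fails are recorded with `NA` and excluded from the winners, as
#' are non-converged fits.
#'
#' @inheritParams censmix_fit
#' @param G_values,df_values Integer vectors of candidate component counts
#'   and spline degrees of freedom.
#' @param random_intercept Logical vector: models with and/or without a
#'   random intercept.
#' @param equal_sigma,equal_psi Logical vectors of variance-constraint
#'   settings to cross (`equal_psi` is dropped for cells without random
#'   effects).
#' @param control Shared [censmix_control()]; per-cell seeds derive
#'   deterministically from `control$seed` and the cell index.
#' @param keep_fits Keep the fitted objects (memory permitting).
#' @return An object of class `"censmix_select"`: a list with `table`
#'   (tibble, sorted by BIC), `best_bic` / `best_aic` (row indices into the
#'   unsorted grid), and `fits` (list, possibly of `NULL`s).
#' @examples
#' sim <- censmix_simulate(example_design(N = 40), seed = 1)
#' sel <- censmix_select(sim$data, G_values = 1:2, df_values = 2,
#'                       control = censmix_control(n_starts = 2, seed = 1,
#'                                                 max_iter = 100))
#' sel$table
#' @export
censmix_select <- function(data, G_values = 1:5, df_values = 1:5,
                           random_intercept = TRUE,
                           equal_sigma = c(FALSE, TRUE),
                           equal_psi = c(FALSE, TRUE),
                           control = censmix_control(),
                           keep_fits = TRUE) {
  grid <- expand.grid(
    G = as.integer(G_values), df = as.integer(df_values),
    random_intercept = as.logical(random_intercept),
    equal_sigma = as.logical(equal_sigma),
    equal_psi = as.logical(equal_psi),
    KEEP.OUT.ATTRS = FALSE
  )
  # without random effects the Psi constraint is vacuous
  grid$equal_psi[!grid$random_intercept] <- FALSE
  grid <- unique(grid)
  if (nrow(grid) == 0L) stop("empty model grid")
  seed <- control$seed %||% 1L

  N <- length(unique(data$id))
  rows <- vector("list", nrow(grid))
  fits <- vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    g <- grid[cell, ]
    ctl <- control
    ctl$seed <- derive_seed(seed, cell, 15485863)
    fit <- tryCatch(
      censmix_fit(data, G = g$G, df = g$df,
                  random_intercept = g$random_intercept,
                  equal_sigma = g$equal_sigma, equal_psi = g$equal_psi,
                  control = ctl),
      error = function(e) e
    )
    failed <- inherits(fit, "error")
    rows[[cell]] <- tibble::tibble(
      cell = cell, G = g$G, df = g$df,
      random_intercept = g$random_intercept,
      equal_sigma = g$equal_sigma, equal_psi = g$equal_psi,
      loglik = if (failed) NA_real_ else fit$loglik,
      k = if (failed) NA_integer_ else fit$k,
      AIC = if (failed) NA_real_ else fit$AIC,
      BIC = if (failed) NA_real_ else fit$BIC,
      converged = if (failed) FALSE else fit$converged,
      error = if (failed) conditionMessage(fit) else NA_character_
    )
    if (keep_fits && !failed) fits[[cell]] <- fit
  }
  table <- dplyr::bind_rows(rows)
  eligible <- table$converged & !is.na(table$BIC)
  if (!any(eligible)) stop("no model in the grid converged")
  best_bic <- table$cell[eligible][which.min(table$BIC[eligible])]
  best_aic <- table$cell[eligible][which.min(table$AIC[eligible])]
  structure(
    list(
      table = dplyr::arrange(table, .data$BIC),
      best_bic = best_bic, best_aic = best_aic,
      fits = fits, N = N, seed = seed
    ),
    class = "censmix_select"
  )
}

#' Two-stage model selection over variance constraints
#'
#' Stage one selects, by BIC, the best combination of number of components
#' and spline flexibility among the models with unrestricted (component-
#' specific) variances. Stage two fixes that combination and fits the
#' constrained variants (equal residual variances and/or equal
#' random-intercept variances), warm-starting each constrained EM from the
#' stage-one posterior probabilities; the winner among all stage-two
#' candidates (including the unrestricted stage-one model) is reported.
#'
#' @inheritParams censmix_select
#' @param criterion `"bic"` or `"aic"` for the stage-two choice (stage one
#'   always uses the BIC).
#' @return A list of class `"censmix_two_stage"`: `stage1` (a
#'   `censmix_select`), `table` (stage-annotated tibble over both stages),
#'   `best` (the winning fit), `best_row` (its row).
#' @export
censmix_two_stage <- function(data, G_values = 1:5, df_values = 1:5,
                              random_intercept = TRUE,
                              criterion = c("bic", "aic"),
                              control = censmix_control()) {
  criterion <- match.arg(criterion)
  stage1 <- censmix_select(
    data, G_values = G_values, df_values = df_values,
    random_intercept = random_intercept,
    equal_sigma = FALSE, equal_psi = FALSE,
    control = control, keep_fits = TRUE
  )
  best1 <- stage1$fits[[stage1$best_bic]]
  if (is.null(best1)) stop("stage-1 winner has no stored fit")
  spec1 <- best1$spec

  combos <- expand.grid(equal_sigma = c(FALSE, TRUE),
                        equal_psi = c(FALSE, TRUE))
  if (!spec1$random_intercept) combos <- unique(transform(
    combos, equal_psi = FALSE))
  rows <- list()
  fits <- list()
  for (j in seq_len(nrow(combos))) {
    es <- combos$equal_sigma[j]
    ep <- combos$equal_psi[j]
    if (!es && !ep) {
      fit <- best1
    } else {
      ctl <- control
      ctl$seed <- derive_seed(stage1$seed, j, 7717)
      fit <- tryCatch(
        censmix_fit(data, G = spec1$G, df = spec1$df,
                    random_intercept = spec1$random_intercept,
                    equal_sigma = es, equal_psi = ep,
                    control = ctl, init_tau = best1$tau),
        error = function(e) NULL
      )
    }
    fits[[j]] <- fit
    rows[[j]] <- tibble::tibble(
      stage = if (!es && !ep) "stage1" else "stage2",
      G = spec1$G, df = spec1$df,
      equal_sigma = es, equal_psi = ep,
      loglik = if (is.null(fit)) NA_real_ else fit$loglik,
      k = if (is.null(fit)) NA_integer_ else fit$k,
      AIC = if (is.null(fit)) NA_real_ else fit$AIC,
      BIC = if (is.null(fit)) NA_real_ else fit$BIC,
      converged = if (is.null(fit)) FALSE else fit$converged,
      niter = if (is.null(fit)) NA_integer_ else fit$niter
    )
  }
  table <- dplyr::bind_rows(rows)
  crit <- if (criterion == "bic") table$BIC else table$AIC
  eligible <- which(table$converged & !is.na(crit))
  if (!length(eligible)) stop("no stage-2 candidate converged")
  win <- eligible[which.min(crit[eligible])]
  structure(
    list(stage1 = stage1, table = table, best = fits[[win]],
         best_row = table[win, ]),
    class = "censmix_two_stage"
  )
}

#' @export
print.censmix_select <- function(x, ...) {
  cat("censmix model grid:", nrow(x$table), "cells, N =", x$N, "\n")
  print(utils::head(as.data.frame(x$table), 8L))
  invisible(x)
}

#' @export
print.censmix_two_stage <- function(x, ...) {
  cat("censmix two-stage selection\n")
  print(as.data.frame(x$table))
  invisible(x)
}
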