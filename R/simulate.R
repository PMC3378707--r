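#' Describe a generating model for simulation
#'
#' Bundles everything needed to draw datasets from the model class: the
#' mixture parameters, the spline basis the fixed effects refer to, the
#' measurement schedule, the number of individuals and the detection limit.
#'
#' @param pi Component weights.
#' @param alpha `p x G` coefficient matrix (`p = df + 1`, intercept first).
#' @param sigma2 Residual variances, length `G`.
#' @param psi Random-intercept variances, length `G`, or `NULL` for the
#'   no-random-effects variant.
#' @param df Spline degrees of freedom of the mean curves.
#' @param times Measurement schedule: a numeric vector shared by all
#'   individuals, or a list of length `N` of per-individual schedules.
#' @param N Number of individuals.
#' @param limit Left-censoring limit on the response scale, or `NA` for no
#'   censoring.
#' @return An object of class `"censmix_design"`.
#' @export
censmix_design <- function(pi, alpha, sigma2, psi = NULL, df, times, N,
                           limit = NA) {
  alpha <- as.matrix(alpha)
  G <- length(pi)
  stopifnot(ncol(alpha) == G, length(sigma2) == G,
            is.null(psi) || length(psi) == G, N >= 1)
  if (!is.list(times)) times <- rep(list(as.numeric(times)), N)
  if (length(times) != N) stop("`times` must have length N")
  if (any(lengths(times) < 1L)) stop("each individual needs >= 1 time")
  all_t <- unlist(times)
  sspec <- spline_spec(all_t, df)
  if (nrow(alpha) != sspec$df + 1L) {
    stop("`alpha` must have df + 1 = ", sspec$df + 1L, " rows")
  }
  structure(
    list(pi = pi / sum(pi), alpha = alpha, sigma2 = as.numeric(sigma2),
         psi = if (is.null(psi)) NULL else as.numeric(psi),
         df = as.integer(df), times = times, N = as.integer(N),
         limit = limit, spline = sspec),
    class = "censmix_design"
  )
}

#' A small well-separated two-component example design
#'
#' A convenience generating model used in examples and tests: two
#' trajectory groups on a front-loaded measurement schedule over one
#' observation period — one group declines and stays low (dipping under the
#' detection limit late), the other declines and rebounds — with a random
#' intercept per individual. Means and variances are in units of a
#' log10-scaled assay response.
#'
#' @param N Number of individuals.
#' @param limit Detection limit; the default yields 20% censored
#'   observations in expectation under the design (computed with
#'   [expected_censoring()]).
#' @param psi Random-intercept variance (shared by both components).
#' @param sigma2 Residual variances for the two components.
#' @return A [censmix_design()] object with `G = 2`, `df = 2`, 8 occasions.
#' @export
example_design <- function(N = 200L, limit = 2.53, psi = 0.16,
                           sigma2 = c(0.16, 0.16)) {
  times <- c(0, 1, 2, 4, 8, 12, 20, 28)
  # df = 2 basis over these times: intercept + two quadratic B-splines
  alpha <- cbind(c(5.0, -4.8, -3.0),   # decline, stays low
                 c(5.0, -2.4, 0.5))    # decline then rebound
  censmix_design(
    pi = c(0.55, 0.45), alpha = alpha, sigma2 = sigma2,
    psi = c(psi, psi), df = 2L, times = times, N = N, limit = limit
  )
}

#' Draw one dataset from a generating design
#'
#' For each individual a component is drawn from the weights, a random
#' intercept from `N(0, psi_g)`, residuals from `N(0, sigma2_g)`, and the
#' response is left-censored at the design's limit: rows with
#' `y <= limit` are flagged `cens = 1` and record the limit in `y`. The
#' latent truth (assignments, random effects, uncensored responses) is
#' returned out-of-band and never enters the data the fitting functions see.
#'
#' @param design A [censmix_design()] object.
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @return A list of class `"censmix_sim"` with `data` (tibble: `id`,
#'   `time`, `y`, `cens`, `limit`) and `truth` (list: `assignment`, `beta`,
#'   `y_latent`, `design`).
#' @export
censmix_simulate <- function(design, seed = NULL) {
  stopifnot(inherits(design, "censmix_design"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  G <- length(design$pi)
  r <- if (is.null(design$psi)) 0L else 1L
  rows <- vector("list", design$N)
  assignment <- integer(design$N)
  beta <- numeric(design$N)
  y_latent <- vector("list", design$N)
  for (i in seq_len(design$N)) {
    tt <- design$times[[i]]
    g <- sample.int(G, 1L, prob = design$pi)
    assignment[i] <- g
    X <- spline_basis(tt, design$spline)
    mu <- drop(X %*% design$alpha[, g])
    b <- if (r > 0L) stats::rnorm(1L, 0, sqrt(design$psi[g])) else 0
    beta[i] <- b
    y <- mu + b + stats::rnorm(length(tt), 0, sqrt(design$sigma2[g]))
    y_latent[[i]] <- y
    cens <- if (is.na(design$limit)) rep(0L, length(tt)) else
      as.integer(y <= design$limit)
    yq <- y
    yq[cens == 1L] <- design$limit
    rows[[i]] <- tibble::tibble(
      id = i, time = tt, y = yq, cens = cens,
      limit = if (is.na(design$limit)) NA_real_ else design$limit
    )
  }
  structure(
    list(
      data = dplyr::bind_rows(rows),
      truth = list(assignment = assignment, beta = beta,
                   y_latent = y_latent, design = design)
    ),
    class = "censmix_sim"
  )
}

#' Expected censoring fraction of a design
#'
#' Analytic probability that an observation falls at or below the limit,
#' averaged over components, occasions and (Gaussian) random effects:
#' `P(Y_ij <= L) = Phi((L - mu_g(t_j)) / sqrt(psi_g + sigma2_g))`.
#'
#' @param design A [censmix_design()] object.
#' @return Expected fraction of censored observations.
#' @export
expected_censoring <- function(design) {
  if (is.na(design$limit)) return(0)
  G <- length(design$pi)
  tot <- 0
  wt <- 0
  for (i in seq_len(design$N)) {
    tt <- design$times[[i]]
    X <- spline_basis(tt, design$spline)
    for (g in seq_len(G)) {
      mu <- drop(X %*% design$alpha[, g])
      s <- sqrt(design$sigma2[g] + if (is.null(design$psi)) 0 else
        design$psi[g])
      tot <- tot + design$pi[g] * sum(stats::pnorm(design$limit, mu, s))
      wt <- wt + design$pi[g] * length(tt)
    }
  }
  tot / wt
}

#' Match estimated components to reference labels
#'
#' Finds the permutation of the estimated component labels that maximizes
#' agreement with a reference assignment (or with a reference fit's MAP
#' assignment), by exhaustive optimal assignment over the `G x G` confusion
#' matrix. Ties break to the lexicographically smallest permutation.
#'
#' @param est Integer vector of estimated labels in `1:G`.
#' @param ref Integer vector of reference labels in `1:G`, same length.
#' @param G Number of components (defaults to the larger max label).
#' @return Integer permutation `perm` such that `perm[est]` best matches
#'   `ref`; `attr(,"agreement")` holds the matched agreement count.
#' @export
match_components <- function(est, ref, G = max(est, ref)) {
  if (length(est) != length(ref)) stop("partitions must have equal length")
  if (max(est) > G || max(ref) > G) stop("labels exceed G")
  conf <- matrix(0L, G, G)
  for (i in seq_along(est)) {
    conf[est[i], ref[i]] <- conf[est[i], ref[i]] + 1L
  }
  perms <- permutations(G)
  best <- NULL
  best_agree <- -1L
  for (k in seq_len(nrow(perms))) {
    pm <- perms[k, ]
    agree <- sum(conf[cbind(seq_len(G), pm)])
    if (agree > best_agree) {
      best <- pm
      best_agree <- agree
    }
  }
  structure(best, agreement = best_agree)
}

# all permutations of 1:n (n <= 6 in practice), in lexicographic order
permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (j in seq_len(nrow(sub))) {
      out[row, ] <- c(first, rest[sub[j, ]])
      row <- row + 1L
    }
  }
  out
}

#' Adjusted Rand index of two partitions
#'
#' Pair-counting agreement between two partitions of the same items,
#' corrected so that its expectation under independent random partitions
#' with the same margins is zero (Hubert--Arabie form). Two single-cluster
#' partitions agree perfectly and return 1.
#'
#' @param a,b Label vectors of equal positive length (any label type).
#' @return The adjusted Rand index, at most 1.
#' @examples
#' adjusted_rand(c(1, 1, 2, 2), c(1, 2, 1, 2))   # -0.5
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) == 0L || length(a) != length(b)) {
    stop("partitions must be nonempty and of equal length")
  }
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  tot <- choose(n, 2)
  expected <- sum_a * sum_b / tot
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)   # e.g. both single-cluster partitions
  (sum_ij - expected) / (maxi - expected)
}

#' Parametric-bootstrap evaluation of estimation and selection
#'
#' Draws `B` datasets from a generating design (or from a fitted model's
#' parameters), refits each one — either with the generating structure
#' fixed, or selecting the number of components over a grid by AIC/BIC —
#' matches the estimated components to the generating assignment, and
#' reports per-replicate parameter errors and the adjusted Rand index of
#' the maximum-a-posteriori clustering against the truth.
#'
#' @param design A [censmix_design()], or a `censmix_fit` (its parameters
#'   and the observed schedule are reused as the generating design).
#' @param B Number of bootstrap replicates.
#' @param G_values Candidate numbers of components; with more than one
#'   value each replicate is refitted for every candidate and the BIC/AIC
#'   winners recorded.
#' @param control A [censmix_control()]; the master `seed` drives every
#'   replicate deterministically.
#' @return A list of class `"censmix_boot"` with a per-replicate tibble
#'   `replicates` and a `summary` list (selection frequencies, ARI
#'   mean/sd/min/max, mean absolute weight error).
#' @export
censmix_bootstrap <- function(design, B = 20L,
                              G_values = NULL,
                              control = censmix_control(n_starts = 2L)) {
  if (inherits(design, "censmix_fit")) design <- design_from_fit(design)
  stopifnot(inherits(design, "censmix_design"))
  if (B < 1L) stop("`B` must be >= 1")
  G_true <- length(design$pi)
  if (is.null(G_values)) G_values <- G_true
  seed <- control$seed %||% 1L
  has_re <- !is.null(design$psi)

  reps <- vector("list", B)
  for (b in seq_len(B)) {
    rep_seed <- derive_seed(seed, b, 104729)
    sim <- censmix_simulate(design, seed = rep_seed)
    fits <- list()
    ok <- TRUE
    for (G in G_values) {
      f <- tryCatch(
        censmix_fit(
          sim$data, G = G, df = design$df,
          random_intercept = has_re,
          control = censmix_control(
            tol = control$tol, max_iter = control$max_iter,
            n_starts = control$n_starts, seed = rep_seed + G,
            starve_floor = control$starve_floor
          )
        ),
        error = function(e) NULL
      )
      fits[[as.character(G)]] <- f
      if (is.null(f) && G == G_true) ok <- FALSE
    }
    conv <- !vapply(fits, is.null, logical(1L))
    bics <- vapply(fits, function(f) if (is.null(f)) Inf else f$BIC, 0)
    aics <- vapply(fits, function(f) if (is.null(f)) Inf else f$AIC, 0)
    G_bic <- if (any(conv)) G_values[which.min(bics)] else NA_integer_
    G_aic <- if (any(conv)) G_values[which.min(aics)] else NA_integer_

    ari <- werr <- NA_real_
    if (ok && !is.null(fits[[as.character(G_true)]])) {
      ft <- fits[[as.character(G_true)]]
      map <- apply(ft$tau, 1L, which.max)
      if (G_true == 1L) {
        ari <- 1
        werr <- 0
      } else {
        perm <- match_components(map, sim$truth$assignment, G = G_true)
        ari <- adjusted_rand(map, sim$truth$assignment)
        # estimated component g corresponds to generating component perm[g]
        werr <- max(abs(ft$params$pi - design$pi[perm]))
      }
    }
    reps[[b]] <- tibble::tibble(
      replicate = b, seed = rep_seed, G_bic = G_bic, G_aic = G_aic,
      ari = ari, weight_err = werr,
      loglik = if (ok) fits[[as.character(G_true)]]$loglik else NA_real_
    )
  }
  replicates <- dplyr::bind_rows(reps)
  ari_ok <- replicates$ari[!is.na(replicates$ari)]
  structure(
    list(
      replicates = replicates,
      summary = list(
        B = B,
        bic_freq = table(factor(replicates$G_bic, levels = G_values)),
        aic_freq = table(factor(replicates$G_aic, levels = G_values)),
        ari_mean = mean(ari_ok), ari_sd = stats::sd(ari_ok),
        ari_min = suppressWarnings(min(ari_ok)),
        ari_max = suppressWarnings(max(ari_ok)),
        weight_err_mean = mean(replicates$weight_err, na.rm = TRUE)
      ),
      design = design, seed = seed
    ),
    class = "censmix_boot"
  )
}

# Reuse a fitted model as a generating design (parametric bootstrap off a
# fit): parameters from the fit, schedules from the fitted data.
design_from_fit <- function(fit) {
  times <- lapply(fit$dataset$individuals, `[[`, "time")
  limit <- if (!is.null(fit$data$limit) && any(is.finite(fit$data$limit))) {
    stats::median(fit$data$limit[is.finite(fit$data$limit)])
  } else if (any(fit$data$cens == 1)) {
    stats::median(fit$data$y[fit$data$cens == 1])
  } else {
    NA
  }
  censmix_design(
    pi = fit$params$pi, alpha = fit$params$alpha,
    sigma2 = fit$params$sigma2,
    psi = if (is.null(fit$params$Psi)) NULL else
      vapply(fit$params$Psi, function(P) P[1L, 1L], 0),
    df = fit$spec$df, times = times, N = fit$N, limit = limit
  )
}

#' @export
print.censmix_boot <- function(x, ...) {
  s <- x$summary
  cat(sprintf("censmix parametric bootstrap: B = %d replicates\n", s$B))
  cat("  BIC selection frequencies:\n")
  print(s$bic_freq)
  cat(sprintf("  ARI: mean %.3f (sd %.3f), range [%.3f, %.3f]\n",
              s$ari_mean, s$ari_sd, s$ari_min, s$ari_max))
  invisible(x)
}
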