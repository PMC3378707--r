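#' Read long-format censored longitudinal data from CSV
#'
#' Expects a comma-separated UTF-8 file with a header row and columns
#' `id`, `time`, `y`, `cens` (0 = observed, 1 = left-censored at the
#' recorded value) and optionally `limit` (per-observation detection
#' limit overriding `y` on censored rows). Validation failures (missing
#' columns, non-binary censoring indicators, duplicate `(id, time)` pairs)
#' are reported with row numbers.
#'
#' @param path Path to the CSV file.
#' @return A tibble ordered by individual (first appearance) and time.
#' @export
censmix_read <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  tibble::as_tibble(validate_long(as.data.frame(data)))
}

#' Write long-format data to CSV
#'
#' @param data A data frame with the long-format columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
censmix_write <- function(data, path) {
  readr::write_csv(tibble::as_tibble(data), path, progress = FALSE)
  invisible(path)
}

.censmix_schema_version <- "1.0"

#' Serialize a fitted model to JSON
#'
#' Writes the model structure, the parameters (random-effect covariances
#' half-vectorized), the log-likelihood and its trace, the spline
#' specification, the master seed and the package version, in full double
#' precision, so fitted models are self-describing and reloadable.
#'
#' @param fit A [censmix_fit()] object.
#' @param path Output path for the JSON file.
#' @return `path`, invisibly.
#' @export
censmix_write_fit <- function(fit, path) {
  obj <- list(
    schema_version = .censmix_schema_version,
    package_version = as.character(utils::packageVersion("censmix")),
    seed = fit$seed,
    spec = fit$spec[c("G", "df", "random_intercept", "equal_sigma",
                      "equal_psi")],
    spline = fit$spline[c("df", "degree", "knots", "boundary")],
    params = list(
      pi = fit$params$pi,
      alpha = fit$params$alpha,
      sigma2 = fit$params$sigma2,
      psi_vech = if (is.null(fit$params$Psi)) NULL else
        lapply(fit$params$Psi, vech)
    ),
    loglik = fit$loglik, k = fit$k, N = fit$N, nobs = fit$nobs,
    AIC = fit$AIC, BIC = fit$BIC,
    niter = fit$niter, converged = fit$converged,
    trace = fit$trace,
    tau = fit$tau,
    ids = as.character(fit$ids)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Reload a serialized fit
#'
#' Restores the structure, parameters and fit summaries written by
#' [censmix_write_fit()]. The result carries no data; pass it as warm
#' start or use its parameters directly.
#'
#' @param path Path to a fit JSON file.
#' @return A list with `spec` ([censmix_spec()]), `spline`
#'   ([spline_spec()] shape), `params` ([censmix_params()]), `loglik`,
#'   `trace`, `tau`, `seed` and the stored criteria.
#' @export
censmix_read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version)) stop("not a censmix fit file")
  spec <- censmix_spec(obj$spec$G, obj$spec$df, obj$spec$random_intercept,
                       obj$spec$equal_sigma, obj$spec$equal_psi)
  sspec <- structure(
    list(df = as.integer(obj$spline$df),
         degree = as.integer(obj$spline$degree),
         knots = as.numeric(obj$spline$knots),
         boundary = as.numeric(obj$spline$boundary)),
    class = "censmix_spline"
  )
  Psi <- NULL
  if (!is.null(obj$params$psi_vech)) {
    pv <- obj$params$psi_vech
    if (is.matrix(pv)) pv <- split(pv, col(pv))   # jsonlite simplification
    if (!is.list(pv)) pv <- as.list(pv)
    Psi <- lapply(pv, unvech)
  }
  params <- censmix_params(
    pi = obj$params$pi,
    alpha = matrix(unlist(obj$params$alpha), ncol = length(obj$params$pi)),
    sigma2 = obj$params$sigma2, Psi = Psi
  )
  list(
    spec = spec, spline = sspec, params = params,
    loglik = obj$loglik, trace = obj$trace, tau = obj$tau,
    seed = obj$seed, AIC = obj$AIC, BIC = obj$BIC, k = obj$k, N = obj$N,
    converged = obj$converged, schema_version = obj$schema_version
  )
}

# half-vectorization (lower triangle including diagonal) and its inverse
vech <- function(M) M[lower.tri(M, diag = TRUE)]

unvech <- function(v) {
  v <- as.numeric(v)
  r <- (sqrt(8 * length(v) + 1) - 1) / 2
  if (abs(r - round(r)) > 1e-8) stop("invalid vech length")
  r <- as.integer(round(r))
  M <- matrix(0, r, r)
  M[lower.tri(M, diag = TRUE)] <- v
  M <- M + t(M) - diag(diag(M), r)
  M
}
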