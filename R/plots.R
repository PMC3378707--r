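#' Plot a fitted censored mixture of mixed models
#'
#' Spaghetti plot of the observed trajectories coloured by
#' maximum-a-posteriori component, overlaid with the fitted component mean
#' curves and, optionally, pointwise confidence bands. Censored
#' observations are drawn as open triangles at the detection limit.
#'
#' @param object A [censmix_fit()] object.
#' @param band Add pointwise confidence bands (computes [censmix_se()]).
#' @param level Band coverage level.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot censmix_fit
#' @export
autoplot.censmix_fit <- function(object, band = FALSE, level = 0.95, ...) {
  data <- tibble::as_tibble(object$data)
  map <- tibble::tibble(
    id = object$ids,
    component = factor(apply(object$tau, 1L, which.max))
  )
  data <- dplyr::left_join(data, map, by = "id")
  tt <- seq(object$spline$boundary[1L], object$spline$boundary[2L],
            length.out = 80L)
  curves <- purrr::map_dfr(seq_len(object$spec$G), function(g) {
    tibble::tibble(
      time = tt,
      estimate = mean_curve(object$spline, object$params$alpha[, g], tt),
      component = factor(g)
    )
  })
  p <- ggplot2::ggplot(data, ggplot2::aes(x = .data$time, y = .data$y)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$id,
                                    colour = .data$component),
                       alpha = 0.25) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$component,
                                     shape = factor(.data$cens)),
                        size = 1, alpha = 0.5) +
    ggplot2::scale_shape_manual(values = c(`0` = 16, `1` = 2),
                                labels = c("observed", "censored"),
                                name = NULL)
  if (band) {
    info <- censmix_se(object)
    bands <- purrr::map_dfr(seq_len(object$spec$G), function(g) {
      b <- censmix_band(object, info, g, times = tt, level = level)
      b$component <- factor(b$component)
      b
    })
    p <- p + ggplot2::geom_ribbon(
      data = bands,
      ggplot2::aes(x = .data$time, ymin = .data$lower, ymax = .data$upper,
                   fill = .data$component),
      alpha = 0.2, inherit.aes = FALSE
    )
  }
  p +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$time, y = .data$estimate,
                                    colour = .data$component),
                       linewidth = 1) +
    ggplot2::labs(x = "time", y = "response", colour = "component",
                  fill = "component")
}

#' Plot an information-criterion profile over the model grid
#'
#' @param object A [censmix_select()] object.
#' @param criterion `"BIC"` or `"AIC"`.
#' @param ... Unused.
#' @return A ggplot object: criterion against number of components, one
#'   line per (df, constraint) combination.
#' @method autoplot censmix_select
#' @export
autoplot.censmix_select <- function(object, criterion = c("BIC", "AIC"),
                                    ...) {
  criterion <- match.arg(criterion)
  tab <- object$table
  tab$value <- tab[[criterion]]
  tab$variant <- interaction(
    paste0("df", tab$df),
    ifelse(tab$equal_sigma, "eq.s2", "un.s2"),
    ifelse(tab$equal_psi, "eq.psi", "un.psi"),
    ifelse(tab$random_intercept, "RI", "noRI"),
    drop = TRUE
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$G, y = .data$value,
                                    colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of components", y = criterion,
                  colour = "model variant")
}
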