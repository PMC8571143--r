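#' Plot Kaplan-Meier curves with Greenwood confidence bands
#'
#' @param object A `div_km` object from [km_curves()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.div_km <- function(object, ...) {
  df <- tidy(object)
  # prepend time 0 at survival 1 for each group
  t0 <- df |>
    dplyr::distinct(.data$group) |>
    dplyr::mutate(time = 0, n_risk = NA_integer_, n_event = 0L,
                  estimate = 1, conf_low = 1, conf_high = 1)
  df <- dplyr::bind_rows(t0, df) |> dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   colour = .data$group, fill = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
                         stat = StatStepribbon, alpha = 0.2, colour = NA) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = sprintf("%s time (months)", toupper(object$endpoint)),
                  y = "Survival probability",
                  subtitle = sprintf("log-rank p = %.3g", object$logrank_p)) +
    ggplot2::theme_minimal()
}

# step-ribbon stat so Greenwood bands follow the KM steps
StatStepribbon <- ggplot2::ggproto(
  "StatStepribbon", ggplot2::Stat,
  compute_group = function(data, scales, ...) {
    data <- data[order(data$x), ]
    n <- nrow(data)
    if (n < 2) return(data)
    xs <- rep(data$x, each = 2)[-1]
    ix <- rep(seq_len(n), each = 2)[-2 * n]
    out <- data[ix, ]
    out$x <- xs
    out
  },
  required_aes = c("x", "ymin", "ymax")
)

#' Plot the cutpoint scan of a maximally selected log-rank statistic
#'
#' Standardised absolute log-rank score against each candidate cut, with
#' the selected cut marked.
#'
#' @param object A `div_cutpoint` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.div_cutpoint <- function(object, ...) {
  ggplot2::ggplot(object$candidates,
                  ggplot2::aes(x = .data$cut, y = .data$std_score)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$cut_value, linetype = 2) +
    ggplot2::labs(x = "candidate cut", y = "standardised |log-rank score|",
                  subtitle = sprintf("q = %.3f, adjusted p = %.3g",
                                     object$q_statistic, object$p_adjusted)) +
    ggplot2::theme_minimal()
}

#' Bar plot of a phenotype distribution
#'
#' @param dist A [phenotype_distribution()] tibble.
#' @param top Show only the `top` most abundant phenotypes.
#' @return A ggplot.
#' @export
plot_phenotype_distribution <- function(dist, top = 15) {
  df <- dist |>
    dplyr::arrange(dplyr::desc(.data$p)) |>
    utils::head(top)
  df$phenotype <- factor(df$phenotype, levels = rev(df$phenotype))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p, y = .data$phenotype)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "proportion of included cells", y = NULL) +
    ggplot2::theme_minimal()
}

#' Map of cell positions coloured by phenotype
#'
#' @param cells Phenotyped cell tibble for one core.
#' @param top Colour the `top` most abundant labels; others grey.
#' @return A ggplot.
#' @export
plot_core_map <- function(cells, top = 8) {
  tab <- sort(table(cells$phenotype), decreasing = TRUE)
  keep <- names(tab)[seq_len(min(top, length(tab)))]
  cells$label <- ifelse(cells$phenotype %in% keep, cells$phenotype, "other")
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x_um, y = .data$y_um,
                                      colour = .data$label)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = "phenotype") +
    ggplot2::theme_minimal()
}
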