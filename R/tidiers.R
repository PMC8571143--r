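#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a per-feature Cox fit
#'
#' @param x A `div_cox` object from [cox_fit()].
#' @param ... Unused.
#' @return Tibble with one row per model term: `feature`, `term`, `beta`,
#'   `hr`, `ci_low`, `ci_high`, `p`, `n`, `n_events`.
#' @export
tidy.div_cox <- function(x, ...) x$table

#' @rdname tidy.div_cox
#' @export
glance.div_cox <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint,
    adjust_flipi = x$adjust_flipi,
    n_features = length(x$fits)
  )
}

#' Tidy Kaplan-Meier curves
#'
#' @param x A `div_km` object from [km_curves()].
#' @param ... Unused.
#' @return Tibble of the per-group step function: `group`, `time`,
#'   `n_risk`, `n_event`, `estimate`, `conf_low`, `conf_high`.
#' @export
tidy.div_km <- function(x, ...) {
  s <- summary(x$fit, censored = TRUE)
  grp <- if (is.null(s$strata)) factor(rep("all", length(s$time))) else s$strata
  tibble::tibble(
    group = sub("^\\.group=", "", as.character(grp)),
    time = s$time,
    n_risk = s$n.risk,
    n_event = s$n.event,
    estimate = s$surv,
    conf_low = s$lower,
    conf_high = s$upper
  )
}

#' @rdname tidy.div_km
#' @export
glance.div_km <- function(x, ...) {
  tibble::tibble(
    endpoint = x$endpoint,
    n = nrow(x$data),
    n_events = sum(x$data$.event),
    n_groups = nlevels(x$data$.group),
    logrank_p = x$logrank_p
  )
}

#' Tidy a cutpoint scan
#'
#' @param x A `div_cutpoint` object from [contal_oquigley_cutpoint()].
#' @param ... Unused.
#' @return `tidy()`: the candidate-cut tibble (`cut`, `n_high`, `score`,
#'   `std_score`, `p_logrank`); `glance()`: a one-row summary.
#' @export
tidy.div_cutpoint <- function(x, ...) x$candidates

#' @rdname tidy.div_cutpoint
#' @export
glance.div_cutpoint <- function(x, ...) {
  tibble::tibble(
    cut_value = x$cut_value,
    q_statistic = x$q_statistic,
    p_logrank = x$p_logrank,
    p_adjusted = x$p_adjusted,
    group_fraction_high = x$group_fraction_high,
    n = x$n,
    n_events = x$n_events
  )
}
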