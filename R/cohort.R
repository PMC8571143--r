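#' Aggregate per-core features to the patient level
#'
#' Cores are sampled in triplicate per patient; the patient's feature value
#' is the median over their available cores (missing core values dropped,
#' mean-of-middle convention for even counts). Invariant to core order.
#'
#' @param profiles Per-core feature tibble with `patient_id` (see
#'   [profile_cores()]).
#' @param features Character vector of feature columns to aggregate;
#'   defaults to every numeric column except identifiers/counts.
#' @return A tibble with one row per patient: `patient_id`, `n_cores`, and
#'   the median of each feature.
#' @export
aggregate_patients <- function(profiles, features = NULL) {
  if (!nrow(profiles)) abort_data("no cores to aggregate")
  if (!"patient_id" %in% names(profiles)) {
    abort_data("profiles must carry a patient_id column")
  }
  if (is.null(features)) {
    num <- vapply(profiles, is.numeric, logical(1))
    features <- setdiff(names(profiles)[num],
                        c("n_cells", "n_cells_included", "n_pairs"))
  }
  missing <- setdiff(features, names(profiles))
  if (length(missing)) {
    abort_data(sprintf("unknown feature column(s): %s", paste(missing, collapse = ", ")))
  }
  profiles |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_cores = dplyr::n(),
      dplyr::across(dplyr::all_of(features), ~ stats::median(.x, na.rm = TRUE)),
      .groups = "drop"
    )
}

#' Intra-patient coefficient of variation across replicate cores
#'
#' For each patient with at least two cores and a positive mean, the CoV is
#' `100 * sd / mean` (sample standard deviation, n - 1 denominator) of the
#' feature over the patient's cores; it measures how reproducible a feature
#' is across triplicate cores from the same biopsy. Patients with fewer
#' than two cores or a non-positive mean are skipped with a notice. The
#' cohort summary is the median CoV across contributing patients, stored in
#' the `cohort_median_cov` attribute.
#'
#' @param profiles Per-core feature tibble with `patient_id`.
#' @param feature Feature column name.
#' @return Tibble `patient_id`, `n_cores`, `mean`, `sd`, `cov_pct`, with
#'   attribute `cohort_median_cov`.
#' @export
intra_patient_cov <- function(profiles, feature) {
  if (!feature %in% names(profiles)) {
    abort_data(sprintf("unknown feature column: %s", feature))
  }
  per <- profiles |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      n_cores = sum(!is.na(.data[[feature]])),
      mean = mean(.data[[feature]], na.rm = TRUE),
      sd = stats::sd(.data[[feature]], na.rm = TRUE),
      .groups = "drop"
    )
  skip <- per$n_cores < 2L | !(per$mean > 0)
  if (any(skip)) {
    message(sprintf("intra_patient_cov(%s): skipping %d patient(s) with <2 cores or non-positive mean",
                    feature, sum(skip)))
  }
  out <- per[!skip, , drop = FALSE]
  out$cov_pct <- 100 * out$sd / out$mean
  attr(out, "cohort_median_cov") <- if (nrow(out)) stats::median(out$cov_pct) else NA_real_
  attr(out, "feature") <- feature
  out
}

endpoint_cols <- function(data, endpoint) {
  tc <- paste0(endpoint, "_months"); ec <- paste0(endpoint, "_event")
  missing <- setdiff(c(tc, ec), names(data))
  if (length(missing)) {
    abort_data(sprintf("missing endpoint column(s): %s", paste(missing, collapse = ", ")))
  }
  list(time = tc, event = ec)
}

#' Cox proportional-hazards models per feature
#'
#' Fits one Cox model per feature, with the feature as a continuous
#' covariate (hazard ratio per unit), optionally adjusted for the ordinal
#' FLIPI score (0-5). Ties are handled with the Efron approximation.
#' Patients missing the endpoint, the feature, or (when adjusting) FLIPI
#' are dropped listwise and the retained counts reported per model.
#'
#' @param data Patient-level tibble: endpoint columns
#'   `<endpoint>_months`/`<endpoint>_event`, feature columns, and `flipi`
#'   when `adjust_flipi = TRUE`.
#' @param endpoint `"os"` or `"pfs"` (any prefix matching the column pair).
#' @param features Character vector of feature column names.
#' @param adjust_flipi Add FLIPI as an ordinal covariate.
#' @return Object of class `div_cox`; [generics::tidy()] gives one row per
#'   model term with `hr`, `ci_low`, `ci_high`, `p`, `n`, `n_events`.
#' @export
cox_fit <- function(data, endpoint = "os", features, adjust_flipi = FALSE) {
  cols <- endpoint_cols(data, endpoint)
  if (adjust_flipi && !"flipi" %in% names(data)) {
    abort_data("adjust_flipi = TRUE requires a 'flipi' column")
  }
  fits <- list(); rows <- list()
  for (f in features) {
    if (!f %in% names(data)) abort_data(sprintf("unknown feature column: %s", f))
    keep_cols <- c(cols$time, cols$event, f, if (adjust_flipi) "flipi")
    df <- data[stats::complete.cases(data[keep_cols]), keep_cols, drop = FALSE]
    names(df)[1:3] <- c(".time", ".event", ".feature")
    n <- nrow(df); n_events <- sum(df$.event)
    if (n_events < 1) {
      abort_data(sprintf("no events for endpoint '%s' (feature %s)", endpoint, f),
                 class = "entrotme_fit_error")
    }
    if (stats::var(df$.feature) == 0) {
      abort_data(sprintf("feature %s is constant; hazard ratio undefined", f),
                 class = "entrotme_fit_error")
    }
    if (adjust_flipi && n < nrow(data)) {
      message(sprintf("cox_fit(%s, %s): %d of %d patients retained after listwise deletion",
                      endpoint, f, n, nrow(data)))
    }
    fml <- if (adjust_flipi) {
      stats::as.formula("survival::Surv(.time, .event) ~ .feature + flipi")
    } else {
      stats::as.formula("survival::Surv(.time, .event) ~ .feature")
    }
    fit <- tryCatch(
      survival::coxph(fml, data = df, ties = "efron"),
      error = function(e) abort_data(
        sprintf("Cox model failed for feature %s: %s", f, conditionMessage(e)),
        class = "entrotme_fit_error")
    )
    sm <- summary(fit)
    terms <- rownames(sm$coefficients)
    term_lab <- ifelse(terms == ".feature", f, terms)
    rows[[f]] <- tibble::tibble(
      feature = f,
      term = term_lab,
      beta = sm$coefficients[, "coef"],
      hr = sm$coefficients[, "exp(coef)"],
      se = sm$coefficients[, "se(coef)"],
      ci_low = sm$conf.int[, "lower .95"],
      ci_high = sm$conf.int[, "upper .95"],
      p = sm$coefficients[, "Pr(>|z|)"],
      n = n,
      n_events = n_events
    )
    fits[[f]] <- fit
  }
  structure(
    list(table = dplyr::bind_rows(rows), fits = fits,
         endpoint = endpoint, adjust_flipi = adjust_flipi),
    class = "div_cox"
  )
}

#' @export
print.div_cox <- function(x, ...) {
  cat(sprintf("<div_cox> Cox PH, endpoint %s%s\n", x$endpoint,
              if (x$adjust_flipi) " (FLIPI-adjusted)" else ""))
  print(x$table)
  invisible(x)
}

#' Kaplan-Meier curves with Greenwood confidence intervals
#'
#' Product-limit survival estimate per group with 95% confidence intervals
#' from Greenwood's variance formula, plus the log-rank test across groups.
#'
#' @param data Patient-level tibble with endpoint columns.
#' @param endpoint `"os"` or `"pfs"`.
#' @param group Name of a grouping column in `data` (each level non-empty).
#' @return Object of class `div_km` wrapping the [survival::survfit()] fit;
#'   `tidy()` returns the per-group step function, `autoplot()` draws it.
#' @export
km_curves <- function(data, endpoint = "os", group) {
  cols <- endpoint_cols(data, endpoint)
  if (!group %in% names(data)) abort_data(sprintf("unknown group column: %s", group))
  df <- data[stats::complete.cases(data[c(cols$time, cols$event, group)]),
             c(cols$time, cols$event, group)]
  names(df) <- c(".time", ".event", ".group")
  df$.group <- as.factor(df$.group)
  if (any(table(df$.group) == 0) || nlevels(df$.group) == 0 || nrow(df) == 0) {
    abort_data("every group must contain at least one subject")
  }
  fit <- survival::survfit(survival::Surv(.time, .event) ~ .group, data = df,
                           conf.type = "log", conf.int = 0.95)
  logrank_p <- if (nlevels(df$.group) > 1) {
    sd <- survival::survdiff(survival::Surv(.time, .event) ~ .group, data = df)
    stats::pchisq(sd$chisq, df = nlevels(df$.group) - 1, lower.tail = FALSE)
  } else NA_real_
  structure(
    list(fit = fit, data = df, endpoint = endpoint, group = group,
         logrank_p = logrank_p),
    class = "div_km"
  )
}

#' @export
print.div_km <- function(x, ...) {
  cat(sprintf("<div_km> Kaplan-Meier, endpoint %s by %s; log-rank p = %.4g\n",
              x$endpoint, x$group, x$logrank_p))
  print(x$fit)
  invisible(x)
}

#' Dichotomise a feature at a cutpoint
#'
#' Labels subjects `"high"` when the feature is strictly above the cut and
#' `"low"` otherwise (ties at the cut go to `"low"`, consistent with
#' candidate cuts being observed values).
#'
#' @param values Numeric feature vector.
#' @param cut Cut value (e.g. from [contal_oquigley_cutpoint()]).
#' @return Factor with levels `low`, `high`.
#' @export
split_at_cutpoint <- function(values, cut) {
  factor(ifelse(values > cut, "high", "low"), levels = c("low", "high"))
}

#' POD24 association tests per feature
#'
#' Compares each feature between patients with and without progression of
#' disease within 24 months (POD24): a two-sided Mann-Whitney U test
#' (exact where possible, normal approximation with ties), and logistic
#' regression odds ratios per unit feature, univariable and FLIPI-adjusted.
#' Only patients with a defined POD24 flag (at least 24 months of follow-up
#' or an earlier progression event) enter.
#'
#' @param data Patient-level tibble with logical/0-1 `pod24`, feature
#'   columns, and `flipi` for the adjusted model.
#' @param features Character vector of feature column names.
#' @param adjust_flipi Also fit FLIPI-adjusted models.
#' @return Tibble with one row per feature and model (`univariable`,
#'   `flipi_adjusted`): `or`, `ci_low`, `ci_high`, `p`, and `mw_p` (on
#'   univariable rows) from the Mann-Whitney test.
#' @export
pod24_tests <- function(data, features, adjust_flipi = TRUE) {
  if (!"pod24" %in% names(data)) abort_data("missing pod24 column")
  rows <- list()
  for (f in features) {
    if (!f %in% names(data)) abort_data(sprintf("unknown feature column: %s", f))
    df <- data[!is.na(data$pod24) & !is.na(data[[f]]), , drop = FALSE]
    y <- as.integer(as.logical(df$pod24))
    if (length(unique(y)) < 2L) {
      abort_data("POD24 outcome has a single class; tests undefined")
    }
    mw <- suppressWarnings(stats::wilcox.test(df[[f]] ~ y, exact = NULL))
    fitrow <- function(model, dsub, fml) {
      g <- stats::glm(fml, data = dsub, family = stats::binomial())
      est <- stats::coef(g)[".feature"]
      se <- sqrt(diag(stats::vcov(g)))[".feature"]
      tibble::tibble(
        feature = f, model = model, n = nrow(dsub), n_events = sum(dsub$.y),
        or = exp(est), ci_low = exp(est - 1.96 * se), ci_high = exp(est + 1.96 * se),
        p = summary(g)$coefficients[".feature", "Pr(>|z|)"],
        mw_p = if (model == "univariable") mw$p.value else NA_real_
      )
    }
    dsub <- tibble::tibble(.y = y, .feature = df[[f]],
                           flipi = if ("flipi" %in% names(df)) df$flipi else NA_real_)
    rows[[paste0(f, "_uni")]] <- fitrow("univariable", dsub, .y ~ .feature)
    if (adjust_flipi) {
      dadj <- dsub[!is.na(dsub$flipi), , drop = FALSE]
      if (nrow(dadj) && length(unique(dadj$.y)) == 2L) {
        rows[[paste0(f, "_adj")]] <- fitrow("flipi_adjusted", dadj, .y ~ .feature + flipi)
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Bonferroni multiple-testing correction
#'
#' For a family of `k` tests at family-wise level `alpha`, the per-test
#' significance threshold is `alpha / k`; a p-value exactly at the
#' threshold is flagged significant (closed rule). With the package's
#' default family of 10 features at `alpha = 0.05` the threshold is 0.005.
#'
#' @param p Numeric vector of p-values (the test family).
#' @param alpha Family-wise significance level in (0, 1).
#' @return Tibble `p`, `threshold`, `significant`.
#' @export
bonferroni_adjust <- function(p, alpha = 0.05) {
  if (!length(p)) abort_data("empty p-value family")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort_config("alpha must be in (0, 1)")
  }
  thr <- alpha / length(p)
  tibble::tibble(p = p, threshold = thr, significant = p <= thr)
}
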