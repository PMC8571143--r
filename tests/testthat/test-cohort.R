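make_profiles <- function(values, patients) {
  tibble::tibble(patient_id = patients, core_id = seq_along(values),
                 phenotype_entropy = values)
}

test_that("patient aggregation takes the median over cores", {
  prof <- make_profiles(c(1, 2, 4, 3.7, 1, 3), c("a", "a", "a", "b", "c", "c"))
  agg <- aggregate_patients(prof, "phenotype_entropy")
  expect_equal(agg$phenotype_entropy[agg$patient_id == "a"], 2)   # odd count
  expect_equal(agg$phenotype_entropy[agg$patient_id == "b"], 3.7) # single core
  expect_equal(agg$phenotype_entropy[agg$patient_id == "c"], 2)   # mean of middle
  # invariant to core order
  shuf <- prof[c(4, 2, 6, 1, 5, 3), ]
  expect_equal(aggregate_patients(shuf, "phenotype_entropy"),
               agg[order(agg$patient_id), ])
  expect_error(aggregate_patients(prof[0, ], "phenotype_entropy"), "no cores")
})

test_that("intra-patient CoV uses the n-1 sd over replicate cores", {
  prof <- make_profiles(c(2, 2, 2, 1, 2, 3, 5), c("a", "a", "a", "b", "b", "b", "d"))
  cc <- suppressMessages(intra_patient_cov(prof, "phenotype_entropy"))
  expect_equal(cc$cov_pct[cc$patient_id == "a"], 0)
  expect_equal(cc$cov_pct[cc$patient_id == "b"], 50)  # sd 1, mean 2
  expect_false("d" %in% cc$patient_id)                # single core skipped
  expect_equal(attr(cc, "cohort_median_cov"), 25)
  # non-positive mean skipped with a notice
  prof2 <- make_profiles(c(-1, -2, 1, 2), c("e", "e", "f", "f"))
  expect_message(cc2 <- intra_patient_cov(prof2, "phenotype_entropy"), "skipping")
  expect_equal(cc2$patient_id, "f")
})

sim_surv_data <- function(n, beta, seed, feature = NULL) {
  withr::with_seed(seed, {
    f <- feature %||% stats::rnorm(n)
    t <- rexp(n, rate = exp(beta * f))
    cens <- stats::runif(n, 0, 3)
    tibble::tibble(
      patient_id = as.character(seq_len(n)), f = f,
      os_months = pmin(t, cens), os_event = as.integer(t <= cens),
      flipi = sample(0:5, n, replace = TRUE)
    )
  })
}

test_that("Cox fits recover per-unit hazard ratios and rescale consistently", {
  d <- sim_surv_data(400, beta = 0.7, seed = 5)
  fit <- cox_fit(d, "os", "f")
  row <- tidy(fit)
  expect_equal(row$beta, 0.7, tolerance = 0.15)
  expect_true(row$ci_low < row$hr && row$hr < row$ci_high)
  # scaling the feature by c rescales beta by 1/c
  d$f10 <- d$f * 10
  fit10 <- cox_fit(d, "os", "f10")
  expect_equal(tidy(fit10)$beta, row$beta / 10, tolerance = 1e-8)
  # FLIPI-adjusted model reports both terms
  fit_adj <- cox_fit(d, "os", "f", adjust_flipi = TRUE)
  expect_setequal(tidy(fit_adj)$term, c("f", "flipi"))
})

test_that("degenerate Cox inputs raise fit errors", {
  d <- sim_surv_data(50, beta = 0, seed = 6)
  d$constant <- 1
  expect_error(cox_fit(d, "os", "constant"), class = "entrotme_fit_error")
  d2 <- d; d2$os_event <- 0
  expect_error(cox_fit(d2, "os", "f"), class = "entrotme_fit_error")
})

test_that("null Cox confidence intervals cover HR = 1 near the nominal rate", {
  covered <- vapply(1:60, function(s) {
    d <- sim_surv_data(120, beta = 0, seed = 100 + s)
    row <- tidy(cox_fit(d, "os", "f"))
    row$ci_low <= 1 && 1 <= row$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.85)  # 95% nominal, binomial noise at 60 reps
})

test_that("Kaplan-Meier estimates match the hand product-limit computation", {
  d <- tibble::tibble(patient_id = as.character(1:5),
                      os_months = 1:5, os_event = c(1, 1, 0, 1, 0),
                      grp = "all")
  km <- km_curves(d, "os", "grp")
  td <- tidy(km)
  # S(1) = 4/5; S(2) = 4/5 * 3/4 = 3/5; S(3) censored -> 3/5; S(4) = 3/5 * 1/2
  expect_equal(td$estimate[td$time == 1], 0.8)
  expect_equal(td$estimate[td$time == 2], 0.6)
  expect_equal(td$estimate[td$time == 3], 0.6)
  expect_equal(td$estimate[td$time == 4], 0.3)
  expect_equal(td$estimate[td$time == 5], 0.3)
  expect_true(is.na(km$logrank_p))  # single group
})

test_that("KM with no censoring equals the empirical survival function", {
  withr::with_seed(8, {
    t <- sample(1:20, 30, replace = TRUE)
    d <- tibble::tibble(patient_id = as.character(1:30), os_months = t,
                        os_event = 1, grp = "all")
    td <- tidy(km_curves(d, "os", "grp"))
    ev <- td[td$n_event > 0, ]
    expect_equal(ev$estimate, vapply(ev$time, function(u) mean(t > u), numeric(1)))
  })
  # all censored -> flat at 1
  d2 <- tibble::tibble(patient_id = as.character(1:4), os_months = c(2, 4, 6, 8),
                       os_event = 0, grp = "all")
  expect_true(all(tidy(km_curves(d2, "os", "grp"))$estimate == 1))
})

test_that("KM groups split at a cutpoint and produce a log-rank p", {
  d <- sim_surv_data(80, beta = 1, seed = 9)
  d$grp <- split_at_cutpoint(d$f, stats::median(d$f))
  expect_equal(levels(d$grp), c("low", "high"))
  expect_equal(sum(d$f == stats::median(d$f) & d$grp == "high"), 0)  # ties go low
  km <- km_curves(d, "os", "grp")
  expect_lt(km$logrank_p, 0.05)
  expect_error(km_curves(d[0, ], "os", "grp"), "at least one")
})

test_that("POD24 tests flag an informative feature and guard degenerate input", {
  withr::with_seed(10, {
    n <- 60
    pod <- rep(c(TRUE, FALSE), c(20, 40))
    d <- tibble::tibble(
      patient_id = as.character(1:n), pod24 = pod,
      f = as.numeric(pod) + stats::rnorm(n, sd = 0.6),
      flipi = sample(0:5, n, replace = TRUE)
    )
    res <- pod24_tests(d, "f")
    uni <- res[res$model == "univariable", ]
    expect_gt(uni$or, 1)
    expect_lt(uni$p, 0.01)
    expect_lt(uni$mw_p, 0.01)
    expect_true("flipi_adjusted" %in% res$model)
    d$pod24 <- FALSE
    expect_error(pod24_tests(d, "f"), "single class")
  })
})

test_that("Mann-Whitney p-values are roughly uniform under the null", {
  ps <- vapply(1:200, function(s) {
    withr::with_seed(3000 + s, {
      d <- tibble::tibble(patient_id = as.character(1:40),
                          pod24 = rep(c(TRUE, FALSE), 20),
                          f = stats::rnorm(40))
      pod24_tests(d, "f", adjust_flipi = FALSE)$mw_p[1]
    })
  }, numeric(1))
  # exact MW p-values are discrete at n = 40, hence tied; the KS check is
  # still informative as an approximate uniformity screen
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("Bonferroni thresholds follow alpha / k with a closed boundary", {
  fam <- bonferroni_adjust(c(0.004, 0.005, 0.0051, 0.2, rep(0.5, 6)), alpha = 0.05)
  expect_equal(fam$threshold[1], 0.005)
  expect_equal(fam$significant[1:3], c(TRUE, TRUE, FALSE))
  expect_equal(bonferroni_adjust(0.03, 0.05)$threshold, 0.05)  # k = 1
  expect_error(bonferroni_adjust(numeric(0)), "empty")
  expect_error(bonferroni_adjust(0.5, alpha = 1.2), "alpha")
})
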