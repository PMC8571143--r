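test_that("phenotype distribution applies the reserved-class exclusions", {
  cells <- cells_from_labels(c("DAPI_ONLY", "DAPI_ONLY", "CD21_ONLY",
                               "CD4+CD8-CD68-FOXP3-PD-1-"))
  pd <- phenotype_distribution(cells)
  expect_equal(attr(pd, "n_cells"), 1L)
  expect_equal(pd$phenotype, "CD4+CD8-CD68-FOXP3-PD-1-")
  expect_equal(pd$p, 1)
  # single-label sample
  pd2 <- phenotype_distribution(rep("CD4-CD8+CD68-FOXP3-PD-1-", 10))
  expect_equal(pd2$p, 1)
  # empty distribution is valid
  pd3 <- phenotype_distribution(c("DAPI_ONLY", "CD21_ONLY"))
  expect_equal(attr(pd3, "n_cells"), 0L)
  expect_equal(shannon_entropy(pd3), 0)
})

test_that("proportions equal multiset frequencies on a random label multiset", {
  withr::with_seed(11, {
    codes <- phenotype_levels(include_reserved = FALSE)
    labs <- sample(codes[1:7], 100, replace = TRUE,
                   prob = c(.3, .25, .15, .1, .1, .05, .05))
    pd <- phenotype_distribution(labs)
    want <- table(labs) / 100
    expect_equal(stats::setNames(pd$p, pd$phenotype),
                 stats::setNames(as.numeric(want), names(want)))
  })
})

test_that("Shannon entropy matches hand-evaluated cases", {
  expect_equal(shannon_entropy(rep(1 / 32, 32)), log(32), tolerance = 1e-12)
  expect_equal(shannon_entropy(c(1)), 0)
  # -(0.5 ln 0.5 + 2 * 0.25 ln 0.25) = 1.5 ln 2
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5 * log(2), tolerance = 1e-12)
  expect_equal(round(shannon_entropy(c(0.5, 0.25, 0.25)), 4), 1.0397)
  # counts and proportions agree; zero classes are inert
  expect_equal(shannon_entropy(c(2, 1, 1, 0)), shannon_entropy(c(0.5, 0.25, 0.25)))
})

test_that("entropy is bounded by log of the number of included labels", {
  withr::with_seed(21, {
    for (i in 1:20) {
      k <- sample(2:32, 1)
      p <- stats::rgamma(k, 1); p <- p / sum(p)
      h <- shannon_entropy(p)
      expect_gte(h, 0)
      expect_lte(h, log(k) + 1e-12)
      expect_lte(h, log(32) + 1e-12)
    }
  })
})

test_that("merging phenotype classes never increases entropy", {
  withr::with_seed(31, {
    for (i in 1:25) {
      k <- sample(3:12, 1)
      p <- stats::rgamma(k, 0.7); p <- p / sum(p)
      h <- shannon_entropy(p)
      merged <- c(p[1] + p[2], p[-(1:2)])
      expect_lte(shannon_entropy(merged), h + 1e-12)
    }
  })
})

test_that("entropy depends only on proportions (duplication invariance)", {
  cells <- cells_from_labels(rep(c("CD4+CD8-CD68-FOXP3-PD-1-",
                                   "CD4-CD8+CD68-FOXP3-PD-1-",
                                   "CD4-CD8-CD68+FOXP3-PD-1-"), c(5, 3, 2)))
  h1 <- shannon_entropy(phenotype_distribution(cells))
  doubled <- dplyr::bind_rows(cells, dplyr::mutate(cells, x_um = x_um + 0.5))
  expect_equal(shannon_entropy(phenotype_distribution(doubled)), h1)
})

test_that("cell density divides subset counts by tissue area", {
  cells <- cells_from_labels(rep("CD4-CD8+CD68-FOXP3-PD-1-", 100))
  expect_equal(cell_density(cells, "CD8+", 0.5), 200)
  expect_error(cell_density(cells, "CD8+", 0), "positive")
  # compound predicate excludes double-positives
  cells2 <- cells_from_labels(c("CD4+CD8-CD68-FOXP3-PD-1-",
                                "CD4+CD8-CD68+FOXP3-PD-1-",
                                "CD4-CD8-CD68+FOXP3-PD-1-"))
  expect_equal(cell_density(cells2, "CD4+CD68-", 1), 1)
  expect_equal(cell_density(cells2, "CD4+", 1), 2)   # regardless of other markers
  expect_equal(cell_density(cells2, "CD68+", 1), 2)
})

test_that("marker-level densities match an independent filter-then-count oracle", {
  core <- random_core(300, seed = 41,
                      labels = phenotype_levels(include_reserved = TRUE))
  for (sub in c("CD68+", "CD8+", "CD4+FOXP3+", "CD8+PD-1+")) {
    req <- gregexpr("(CD68|CD4|CD8|FOXP3|PD-1)[+-]", sub)
    toks <- regmatches(sub, req)[[1]]
    keep <- rep(TRUE, nrow(core))
    for (tk in toks) {
      m <- substr(tk, 1, nchar(tk) - 1)
      sgn <- substr(tk, nchar(tk), nchar(tk)) == "+"
      keep <- keep & (grepl(paste0(m, "+"), core$phenotype, fixed = TRUE) == sgn)
    }
    expect_equal(cell_density(core, sub, 2), sum(keep) / 2)
  }
})

test_that("densities and ratio are homogeneous under doubling", {
  cells <- cells_from_labels(rep(c("CD4+CD8-CD68-FOXP3-PD-1-", "DAPI_ONLY"), c(6, 9)))
  doubled <- dplyr::bind_rows(cells, cells)
  expect_equal(cell_density(doubled, "CD4+", 1), 2 * cell_density(cells, "CD4+", 1))
  expect_equal(immune_ratio(doubled), immune_ratio(cells))
})

test_that("immune ratio counts immune vs DAPI-only cells, CD21-only in neither", {
  cells <- cells_from_labels(rep(c("CD4+CD8-CD68-FOXP3-PD-1-", "DAPI_ONLY"), c(50, 100)))
  expect_equal(immune_ratio(cells), 0.5)
  none <- cells_from_labels(rep("DAPI_ONLY", 10))
  expect_equal(immune_ratio(none), 0)
  mixed <- cells_from_labels(c(rep("CD4+CD8-CD68-FOXP3-PD-1-", 3),
                               rep("CD4-CD8+CD68-FOXP3-PD-1+", 2),
                               rep("CD21_ONLY", 4),
                               rep("DAPI_ONLY", 10)))
  expect_equal(immune_ratio(mixed), 5 / 10)
  no_dapi <- cells_from_labels(rep("CD4+CD8-CD68-FOXP3-PD-1-", 5))
  expect_error(immune_ratio(no_dapi), class = "entrotme_ratio_error")
})
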