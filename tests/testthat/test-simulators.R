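test_that("genotypes follow Hardy-Weinberg frequencies and are seed-reproducible", {
  g <- simulate_genotypes(20000, 3, maf = 0.5, seed = 1)
  freq <- tabulate(g[, 1] + 1L, 3) / 20000
  expect_equal(freq, c(0.25, 0.5, 0.25), tolerance = 0.03)
  g2 <- simulate_genotypes(20000, 3, maf = 0.5, seed = 1)
  expect_identical(g, g2)
  g_low <- simulate_genotypes(500, 2, maf = 1e-6, seed = 2)
  expect_true(all(g_low == 0))
  expect_error(simulate_genotypes(10, 2, maf = 0.6), "maf")
  expect_error(simulate_genotypes(10, 2, maf = 0), "maf")
})

test_that("odds-ratio conversion yields row-stochastic penetrances with the right limits", {
  v <- c(0.3, 0.4, 0.3)
  flat <- penetrance_from_odds(v, matrix(1, 9, 3), mafs = c(0.5, 0.5))
  expect_equal(unname(flat$table), matrix(v, 9, 3, byrow = TRUE))
  expect_equal(flat$achieved_prevalence, v)

  pen <- penetrance_from_odds(v, odds_pattern_cyclic(4), mafs = c(0.5, 0.5))
  expect_equal(rowSums(pen$table), rep(1, 9), ignore_attr = TRUE)
  expect_true(all(pen$table >= 0 & pen$table <= 1))

  # a huge odds ratio concentrates its cell on that class
  or <- matrix(1, 9, 3); or[5, 2] <- 1e9
  conc <- penetrance_from_odds(v, or)
  expect_equal(unname(conc$table[5, ]), c(0, 1, 0), tolerance = 1e-6)

  fitted <- penetrance_from_odds(v, odds_pattern_cyclic(4), mafs = c(0.5, 0.5),
                                 match_prevalence = TRUE)
  expect_lt(max(abs(fitted$achieved_prevalence - v)), 1e-6)
  expect_error(penetrance_from_odds(c(0.5, 0.5), matrix(-1, 3, 2)), "positive")
})

test_that("categorical phenotype draws classes from the genotype cell's penetrance row", {
  g <- simulate_genotypes(200, 4, 0.4, seed = 3)
  deg <- matrix(rep(c(1, 0, 0), each = 9), 9, 3)
  expect_true(all(simulate_categorical_phenotype(g, c(1, 2), deg, seed = 1) == 1L))

  # class frequencies converge to the genotype-weighted penetrance marginals
  pen <- penetrance_from_odds(c(0.3, 0.4, 0.3), odds_pattern_cyclic(4),
                              mafs = c(0.3, 0.3))
  gg <- simulate_genotypes(1e5, 2, 0.3, seed = 4)
  cls <- simulate_categorical_phenotype(gg, c(1, 2), pen, seed = 5)
  obs <- tabulate(cls, 3)
  gof <- stats::chisq.test(obs, p = pen$achieved_prevalence)
  expect_gt(gof$p.value, 0.01)
  expect_identical(cls, simulate_categorical_phenotype(gg, c(1, 2), pen, seed = 5))
})

test_that("mixture trait matches its closed-form cell means and variances", {
  model <- quant_penetrance_model(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3),
                                  sigma_L = 0.8, sigma_H = 1.0, alpha = 0.4,
                                  mafs = c(0.4, 0.4))
  g <- simulate_genotypes(2e5, 2, 0.4, seed = 6)
  y <- simulate_quantitative_phenotype(g, c(1, 2), model, seed = 7)
  cell <- interaction(g[, 1], g[, 2])
  f <- model$f[cbind(g[, 1] + 1, g[, 2] + 1)]
  for (cl in levels(cell)) {
    idx <- cell == cl
    fij <- f[idx][1]
    expect_equal(mean(y[idx]), fij, tolerance = 0.05)
    expected_var <- if (fij < model$fbar) 0.8^2 else 1.0^2 + 0.4^2
    expect_equal(stats::var(y[idx]), expected_var, tolerance = 0.06)
  }
  # flat mean table with alpha = 0: pure N(f, sigma_H^2), genotype-independent
  flat <- quant_penetrance_model(matrix(2, 3, 3), sigma_H = 1, alpha = 0,
                                 mafs = c(0.4, 0.4))
  y0 <- simulate_quantitative_phenotype(g[1:5e4, ], c(1, 2), flat, seed = 8)
  expect_equal(mean(y0), 2, tolerance = 0.05)
  expect_equal(stats::var(y0), 1, tolerance = 0.05)
})

test_that("heritability-targeted models hit the requested variance fraction", {
  for (h2 in c(0.05, 0.1, 0.2, 0.4)) {
    m <- quant_model_from_heritability(h2, mafs = c(0.2, 0.2))
    expect_equal(m$heritability, h2, tolerance = 1e-10)
  }
  expect_error(quant_model_from_heritability(0.1, pattern = matrix(1, 3, 3)),
               "no genotype variance")
})

test_that("trait categorization applies mean/sd thresholds with ties to the upper class", {
  # c(-1, 0, 1) has sample mean 0 and sd 1 exactly
  expect_equal(categorize_trait(c(-1, 0, 1), J = 3), c(1L, 2L, 3L))
  expect_equal(categorize_trait(c(-1, 0, 1), J = 4), c(1L, 3L, 4L))
  y <- c(-2, -1, 0, 1, 2)  # mean 0; below-mean -> class 1, above -> class 2
  expect_equal(categorize_trait(y, J = 2), c(1L, 1L, 2L, 2L, 2L))
  expect_error(categorize_trait(rep(1, 5), J = 2), "degenerate")
  expect_error(categorize_trait(c(-1, 0, 1), J = 5), "2, 3 or 4")

  # class proportions on a large normal sample match the normal areas
  set.seed(9)
  yn <- rnorm(1e5)
  p3 <- tabulate(categorize_trait(yn, 3), 3) / 1e5
  expect_equal(p3, c(pnorm(-0.43), pnorm(0.43) - pnorm(-0.43), pnorm(-0.43)),
               tolerance = 0.02)
  p4 <- tabulate(categorize_trait(yn, 4), 4) / 1e5
  expect_equal(p4, diff(pnorm(c(-Inf, -0.67, 0, 0.67, Inf))), tolerance = 0.02)
})

test_that("null datasets are phenotype-independent of genotype and reproducible", {
  ds <- simulate_null_dataset(5000, 3, 0.3, trait = "categorical",
                              prevalence = c(0.3, 0.4, 0.3), seed = 10)
  expect_equal(tabulate(ds$phenotype, 3) / 5000, c(0.3, 0.4, 0.3),
               tolerance = 0.03)
  ds2 <- simulate_null_dataset(5000, 3, 0.3, trait = "categorical",
                               prevalence = c(0.3, 0.4, 0.3), seed = 10)
  expect_identical(ds$phenotype, ds2$phenotype)
  expect_identical(ds$genotypes, ds2$genotypes)

  dq <- simulate_null_dataset(400, 20, 0.2, trait = "quantitative", seed = 11)
  cls <- categorize_trait(dq$phenotype, 3)
  s <- scan_order(dq$genotypes, cls, 2)
  expect_lt(s$gids[1], 0.5)  # far from perfect separation under the null
})

test_that("blood-pressure classification reproduces the nine-class composite table", {
  # one representative (SBP, DBP) per band combination, in class order 1..9
  sbp <- c(115, 115, 115, 130, 130, 130, 145, 145, 145)
  dbp <- c(75, 85, 95, 75, 85, 95, 75, 85, 95)
  res <- classify_blood_pressure(sbp, dbp)
  expect_equal(res$class, 1:9)
  expect_equal(res$label,
               c("normal", "prehypertension", "hypertension",
                 "prehypertension", "prehypertension", "hypertension",
                 "hypertension", "hypertension", "hypertension"))
  # boundary values belong to the upper band
  expect_equal(classify_blood_pressure(c(120, 140), c(80, 90))$class, c(5L, 9L))
  expect_error(classify_blood_pressure(NA, 80), "finite")
  expect_error(classify_blood_pressure(Inf, 80), "finite")
})

test_that("composite phenotypes index the Cartesian product row-major", {
  # components exhibiting 3 classes each: (2, 1) -> (2-1)*3 + (1-1) + 1 = 4
  a <- c(1, 2, 3, 2); b <- c(1, 1, 3, 2)
  expect_equal(compose_phenotypes(list(a, b)), c(1L, 4L, 9L, 5L))
  expect_equal(compose_phenotypes(list(a)), c(1L, 2L, 3L, 2L))
  expect_error(compose_phenotypes(list()), "non-empty")
  expect_error(compose_phenotypes(list(1:3, 1:4)), "equal length")
  # two 3-class traits span up to nine composite states
  full <- expand.grid(1:3, 1:3)
  expect_equal(sort(unique(compose_phenotypes(list(full[, 1], full[, 2])))), 1:9)
})
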