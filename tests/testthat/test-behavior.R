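# Exact tests and the behavioural summaries: binomial tails against base R's
# binom.test and rational arithmetic, Fisher's exact test against exhaustive
# enumeration and fisher.test, siring-asymmetry grouping, complementarity
# tables, harvest rate, and the seasonal phallus regression.

test_that("one-sided binomial tails reproduce the exact rational values", {
  expect_equal(binomial_tail(18, 22), sum(choose(22, 18:22)) / 2^22,
               tolerance = 1e-12)
  expect_equal(binomial_tail(10, 11), 12 / 2048)
  expect_equal(binomial_tail(11, 13), 92 / 8192)
  expect_equal(binomial_tail(0, 5), 1)
  expect_equal(binomial_tail(5, 5), 0.5^5)
  expect_error(binomial_tail(6, 5), "k must")
  expect_error(binomial_tail(0, 0), "n must")
})

test_that("binomial tails agree with binom.test and complement exactly", {
  for (i in 1:25) {
    withr::with_seed(i, { n <- sample(1:25, 1); k <- sample(0:n, 1) })
    expect_equal(binomial_tail(k, n),
                 binom.test(k, n, alternative = "greater")$p.value,
                 tolerance = 1e-12)
    # P(X >= k) + P(X <= k - 1) = 1
    lower <- if (k == 0) 0 else pbinom(k - 1, n, 0.5)
    expect_equal(binomial_tail(k, n) + lower, 1, tolerance = 1e-12)
  }
  expect_equal(binomial_tail(9, 10, sided = "two"),
               min(1, 2 * binomial_tail(9, 10)))
  expect_equal(binomial_tail(5, 10, sided = "two"), 1)
})

test_that("Fisher's exact test matches enumeration and fisher.test", {
  expect_equal(fisher_exact_2x2(matrix(c(28, 14, 2, 5), 2)), 0.0926458,
               tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  for (i in 1:40) {
    withr::with_seed(i, tab <- matrix(sample(1:20, 4, TRUE), 2))
    expect_equal(fisher_exact_2x2(tab), fisher_enum_oracle(tab),
                 tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("siring summaries group by asymmetry and pool exact tests", {
  df <- data.frame(pair = c("A x B", "C x D", "E x F"),
                   n_f1 = c(10L, 4L, 6L),
                   asymmetry_mm = c(60, 39.9, 45),
                   sire_longer = c(9L, 1L, 5L),
                   sire_shorter = c(1L, 3L, 1L))
  res <- summarize_sire_tests(df)
  expect_equal(res$pairs$group, c("large", "small", "large"))  # 39.9 -> small
  pooled <- res$pooled[res$pooled$group == "large", ]
  expect_equal(pooled$n_f1, 16)
  expect_equal(pooled$sire_longer, 14)
  expect_equal(pooled$binomial_p, binomial_tail(14, 16))
  expect_equal(pooled$percent_longer, 100 * 14 / 16)
  # an explicit published sectioning overrides the threshold
  df$section <- c("large", "large", "small")
  res2 <- summarize_sire_tests(df)
  expect_equal(res2$pairs$group, df$section)
  # inconsistent counts are rejected
  bad <- df; bad$sire_longer[1] <- 99L
  expect_error(summarize_sire_tests(bad), "must equal")
})

test_that("pair records derive from individual F1s and morphology, leaving gaps unscored", {
  morph <- data.frame(
    species = c("longduck", "shortduck", "midduck", "noduck"),
    winter_phallus_mm = c(100, 30, NA, NA),
    summer_phallus_mm = c(120, 35, 80, NA),
    male_mass_g = c(1000, 700, 850, 600),
    female_mass_g = c(900, 650, 800, 550))
  f1s <- data.frame(
    specimen_id = sprintf("h%d", 1:6),
    species_a = c("longduck", "longduck", "longduck", "midduck", "longduck", "noduck"),
    species_b = c("shortduck", "shortduck", "shortduck", "shortduck", "midduck", "midduck"),
    sire = c("longduck", "longduck", "shortduck", "midduck", "longduck", "noduck"),
    dam = c("shortduck", "shortduck", "longduck", "shortduck", "midduck", "midduck"))
  res <- group_by_asymmetry(f1s, morph)
  ld <- res$pairs[res$pairs$pair == "longduck x shortduck", ]
  expect_equal(ld$n_f1, 3L)
  expect_equal(ld$asymmetry_mm, 70)
  expect_equal(ld$sire_longer, 2L)
  expect_false(ld$asymmetry_estimated)
  # midduck's winter mean is estimated from its summer mean by the regression
  md <- res$pairs[res$pairs$pair == "midduck x shortduck", ]
  expect_equal(md$asymmetry_mm, abs(predict_winter_phallus(80) - 30),
               tolerance = 1e-9)
  expect_true(md$asymmetry_estimated)
  # noduck has no seasonal mean at all: its pair is unscored, not guessed
  expect_true("midduck x noduck" %in% res$unscored$pair)
  expect_false("midduck x noduck" %in% res$pairs$pair)
})

test_that("complementarity tables conserve F1 counts and support variants", {
  morph <- data.frame(
    species = c("big", "small"),
    winter_phallus_mm = c(90, 20),
    male_mass_g = c(1200, 500),
    female_mass_g = c(1100, 450))
  f1s <- data.frame(
    specimen_id = sprintf("h%d", 1:5),
    species_a = "big", species_b = "small",
    sire = c("big", "big", "big", "small", "small"),
    dam = c("small", "small", "small", "big", "big"))
  res <- build_complementarity(f1s, morph)
  expect_equal(sum(res$table), 5)
  expect_equal(res$table["sire_heavier", "sire_longer"], 3L)
  expect_equal(res$table["dam_heavier", "sire_shorter"], 2L)
  # dropping the pair empties the table and the test
  res_b <- build_complementarity(f1s, morph, drop_pairs = "big x small")
  expect_equal(sum(res_b$table), 0)
  expect_true(is.na(res_b$fisher_p))
  # zero differences are excluded with a warning
  morph0 <- morph; morph0$male_mass_g[1] <- morph0$female_mass_g[2]
  expect_warning(res0 <- build_complementarity(f1s[1, ], morph0), "excluded")
  expect_equal(res0$n_excluded, 1L)
})

test_that("harvest rate scales to per-10,000 parentals", {
  expect_equal(harvest_rate(62431, 326586889), 1.91162, tolerance = 1e-5)
  expect_lt(harvest_rate(62431, 326586889), 2)
  expect_equal(harvest_rate(1, 10000), 1)
  expect_equal(harvest_rate(0, 5000), 0)
  expect_error(harvest_rate(5, 0), "parental")
})

test_that("the seasonal phallus regression fits and predicts on the log10 scale", {
  # noise-free log-linear data: exact coefficient recovery
  summer <- c(20, 40, 60, 90, 120)
  winter <- 10^(0.7836 * log10(summer) + 0.3195)
  fit <- suppressWarnings(fit_winter_phallus(summer, winter))
  expect_equal(fit$slope, 0.7836, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.3195, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  # apply-mode plug-in on the fixed published coefficients
  expect_equal(predict_winter_phallus(100), 10^1.8867, tolerance = 1e-4)
  expect_equal(predict_winter_phallus(100), 77.04, tolerance = 1e-3)
  # noisy data around the same relation recovers the slope
  withr::with_seed(81, {
    s <- 10^runif(20, 1, 2.2)
    w <- 10^(0.7836 * log10(s) + 0.3195 + rnorm(20, 0, 0.05))
  })
  fit_n <- fit_winter_phallus(s, w)
  expect_lt(abs(fit_n$slope - 0.7836), 0.1)
  expect_error(fit_winter_phallus(c(1, 2), c(1, 2)), ">= 3 species")
  expect_error(fit_winter_phallus(c(-1, 2, 3), c(1, 2, 3)), "positive")
  expect_error(predict_winter_phallus(0), "positive")
})

test_that("flock-association test is the one-sided binomial on the larger category", {
  expect_equal(association_test(11, 2), 92 / 8192)
  expect_equal(association_test(1, 1), 0.75)          # P(X >= 1 | n = 2)
  for (k in 1:6) {
    expect_equal(association_test(k, 0), binomial_tail(k, k))
  }
  expect_error(association_test(0, 0), "total")
  expect_error(association_test(-1, 2), "non-negative")
})

test_that("bundled published tables load with consistent internal counts", {
  tab <- siring_asymmetry_table()
  expect_equal(sum(tab$n_f1), 80)
  expect_true(all(tab$sire_longer + tab$sire_shorter == tab$n_f1))
  comp <- complementarity_tables()
  expect_equal(sum(comp$all), 59)
  expect_equal(sum(comp$reduced), 49)
  flock <- flock_association_table()
  expect_equal(sum(flock$father_flock) + sum(flock$mother_flock), 13)
})
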