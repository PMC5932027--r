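test_that("normality transforms follow the published conventions", {
  t1 <- apply_transforms(data.frame(fe3 = 10, magnetite = 0))
  expect_equal(t1$fe3, 1)
  expect_equal(t1$magnetite, 2)       # log10(0 + 100)
  t2 <- apply_transforms(data.frame(magnetite = 900))
  expect_equal(t2$magnetite, 3)       # log10(1000)
  expect_error(apply_transforms(data.frame(fe3 = c(3, 0))), "positive")
  # other columns untouched
  t3 <- apply_transforms(data.frame(fe3 = 1, r2star = 0.03))
  expect_equal(t3$r2star, 0.03)
})

test_that("the dispersion screen flags gross outliers and spares clean data", {
  r <- screen_outliers(c(1, 2, 3, 100))
  expect_identical(r$flagged, c(FALSE, FALSE, FALSE, TRUE))
  expect_lt(r$p_values[1], 0.01)
  same <- screen_outliers(rep(5, 10))
  expect_false(any(same$flagged))
  expect_error(screen_outliers(c(1, 2, 3)), "at least 4")
  # type-I control: clean normal samples flagged in < 5% of draws
  set.seed(81)
  hits <- replicate(1000, any(screen_outliers(rnorm(20))$flagged))
  expect_gte(mean(!hits), 0.95 - 0.02)
  # iteration: two gross outliers removed, not more
  r2 <- screen_outliers(c(rnorm(20), 50, 80))
  expect_equal(sum(r2$flagged), 2)
})

test_that("group tests report t, Brown-Forsythe and demographics", {
  tab <- data.frame(group = rep(c("AD", "control"), each = 6),
                    ferrihydrite = rep(c(1, 2, 3, 4, 5, 6), 2),
                    age = rep(c(70, 75, 80, 85, 90, 95), 2),
                    sex = rep(c("m", "f"), 6))
  res <- group_tests(tab, variables = "ferrihydrite")
  tt <- res[res$test == "student_t", ]
  expect_equal(tt$statistic, 0)
  expect_equal(tt$p, 1)
  expect_true(all(c("mann_whitney", "chi_square") %in% res$test))
  expect_equal(res$p[res$variable == "age"], 1, tolerance = 1e-6)

  # zero-variance guard
  tabz <- data.frame(group = rep(c("AD", "control"), each = 4),
                     fe3 = c(rep(2, 4), 1:4))
  expect_warning(rz <- group_tests(tabz, variables = "fe3"), "variance")
  expect_true(all(is.na(rz$p[rz$variable == "fe3"])))
})

test_that("mean test detects the published ferrihydrite separation", {
  # groups drawn at 5x the study sizes from the published moments
  set.seed(91)
  hits <- replicate(200, {
    x <- c(rnorm(110, 381.12, 178.97), rnorm(70, 240.84, 98.02))
    tab <- data.frame(group = rep(c("AD", "control"), c(110, 70)),
                      ferrihydrite = pmax(x, 1))
    res <- group_tests(tab, variables = "ferrihydrite")
    res$p[res$test == "student_t"] < 0.05
  })
  expect_gt(mean(hits), 0.95)
})

test_that("the Brown-Forsythe test matches the reference implementation", {
  set.seed(92)
  x <- c(rnorm(20, 0, 1), rnorm(25, 0, 2.5))
  g <- factor(rep(c("a", "b"), c(20, 25)))
  ours <- levene_bf(x, g)
  ref <- car::leveneTest(x, g, center = median)
  expect_equal(ours$statistic, ref[1, "F value"], tolerance = 1e-10)
  expect_equal(ours$p_value, ref[1, "Pr(>F)"], tolerance = 1e-10)
})

test_that("the correlogram recovers monotone, null and targeted structure", {
  # perfectly monotone pair
  tab <- data.frame(group = "AD", fe3 = 1:12, flr = (1:12)^3)
  cg <- correlogram(tab, variables = c("fe3", "flr"))
  expect_equal(cg$rho["fe3", "flr"], 1)
  # independent columns at large n
  set.seed(93)
  tab2 <- data.frame(fe3 = rexp(5000), flr = rnorm(5000))
  cg2 <- correlogram(tab2, variables = c("fe3", "flr"))
  expect_lt(abs(cg2$rho["fe3", "flr"]), 0.05)
  # constant column -> NA
  tab3 <- data.frame(fe3 = rep(1, 8), flr = 1:8)
  cg3 <- correlogram(tab3, variables = c("fe3", "flr"))
  expect_true(is.na(cg3$rho["fe3", "flr"]))
  # synthetic AD cohort targeted at rho(fe3, flr) = 0.825
  coh <- generate_cohort(cohort_spec(n_ad = 2000, n_control = 3, seed = 5))
  cg4 <- correlogram(coh, "AD", variables = c("fe3", "flr"))
  expect_lt(abs(cg4$rho["fe3", "flr"] - 0.825), 0.05)
})

test_that("Spearman estimates are invariant under monotone transforms", {
  set.seed(94)
  x <- rlnorm(60); y <- x + rnorm(60)
  r0 <- cor(x, y, method = "spearman")
  tab <- data.frame(a = log(x), b = y^3 + 5)
  cg <- correlogram(tab, variables = c("a", "b"))
  expect_equal(cg$rho["a", "b"], r0, tolerance = 1e-12)
})

test_that("small-sample Spearman p-values come from exact enumeration", {
  set.seed(95)
  x <- rnorm(7); y <- rnorm(7)
  cg <- correlogram(data.frame(a = x, b = y), variables = c("a", "b"))
  # oracle: exact p from the null permutation distribution via cor.test
  ref <- cor.test(x, y, method = "spearman", exact = TRUE)
  expect_equal(cg$p["a", "b"], ref$p.value, tolerance = 1e-10)
})

test_that("Fisher-z comparison reproduces its closed form and symmetry", {
  cc <- compare_correlations(-0.629, 18, -0.908, 11)
  expect_equal(cc$zr1, atanh(-0.629))
  expect_lt(abs(cc$p_value - 0.076), 0.001)
  cc2 <- compare_correlations(-0.729, 18, -0.935, 11)
  expect_lt(abs(cc2$p_value - 0.079), 0.001)
  # identical coefficients: no difference
  eq <- compare_correlations(0.5, 20, 0.5, 20)
  expect_equal(eq$z_diff, 0)
  expect_equal(eq$p_value, 1)
  # antisymmetry: swapping groups negates z, preserves p
  a <- compare_correlations(0.3, 15, 0.7, 25)
  b <- compare_correlations(0.7, 25, 0.3, 15)
  expect_equal(a$z_diff, -b$z_diff)
  expect_equal(a$p_value, b$p_value)
  expect_error(compare_correlations(1, 10, 0.5, 10), "Fisher")
  expect_error(compare_correlations(0.2, 3, 0.5, 10), "at least 4")
})

test_that("partial correlation reduces to the plain correlation and errors on collinearity", {
  set.seed(96)
  n <- 4000
  x <- rnorm(n); y <- 0.6 * x + rnorm(n); z <- rnorm(n)  # z independent
  tab <- data.frame(x = x, y = y, z = z)
  pc <- partial_correlation(tab, "x", "y", "z")
  plain <- cor(x, y, method = "spearman")
  expect_lt(abs(pc$estimate - plain), 0.03)
  expect_lt(pc$p_value, 1e-10)
  # y identical to z: denominator degenerates
  tab2 <- data.frame(x = rnorm(10), y = 1:10, z = 1:10)
  expect_error(partial_correlation(tab2, "x", "y", "z"), "collinear")
  expect_error(partial_correlation(tab2[1:4, ], "x", "y", "z"), "5 complete")
})

test_that("pooled partial correlations reproduce the published sign pattern", {
  # positive Fe(III)~FLR, negative ferrihydrite~FLR, near-zero
  # Fe(III)~ferrihydrite once FLR is controlled
  set.seed(97)
  ok <- replicate(20, {
    coh <- generate_cohort(cohort_spec(n_ad = 250, n_control = 250,
                                       seed = sample.int(1e6, 1)))
    p1 <- partial_correlation(coh, "fe3", "flr", "ferrihydrite")$estimate
    p2 <- partial_correlation(coh, "ferrihydrite", "flr", "fe3")$estimate
    p3 <- partial_correlation(coh, "fe3", "ferrihydrite", "flr")$estimate
    p1 > 0 && p2 < 0 && abs(p3) < 0.35
  })
  expect_gte(mean(ok), 0.9)
})

test_that("Braak stratification pools controls at stage <= 3", {
  tab <- data.frame(group = c(rep("control", 3), rep("AD", 6)),
                    braak = c(0, 2, 3, 4, 4, 5, 5, 6, 6),
                    ferrihydrite = c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  s <- braak_stratify(tab, variables = "ferrihydrite")
  expect_identical(unique(s$stratum), c("<=3", "4", "5", "6"))
  expect_equal(s$mean[s$stratum == "<=3"], 2)
  expect_equal(s$n[s$stratum == "4"], 2)
  # empty stratum omitted
  tab2 <- tab[tab$braak != 5, ]
  s2 <- braak_stratify(tab2, variables = "ferrihydrite")
  expect_false("5" %in% s2$stratum)
  expect_error(braak_stratify(transform(tab, braak = c(7, braak[-1]))),
               "0-6")
  expect_error(braak_stratify(transform(tab, braak = rep(2, 9))), "Braak")
})
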