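test_that("cohort generation is seed-deterministic and validates its spec", {
  s1 <- cohort_spec(n_ad = 20, n_control = 15, seed = 11)
  expect_identical(generate_cohort(s1), generate_cohort(s1))
  s2 <- cohort_spec(n_ad = 20, n_control = 15, seed = 12)
  expect_false(identical(generate_cohort(s1), generate_cohort(s2)))

  expect_error(cohort_spec(n_ad = 2), "at least 3")
  expect_error(cohort_spec(alpha = 0.7), "alpha")
  bad <- default_marginals()
  bad$AD$fe3$sd <- -1
  expect_error(marginal_spec("lognormal", 5, -1), "non-negative")
})

test_that("panel invariants hold: positivity, loading range, Braak rules", {
  coh <- generate_cohort(cohort_spec(n_ad = 200, n_control = 200, seed = 4))
  expect_true(all(coh$fe3 > 0))
  expect_true(all(coh$ferrihydrite >= 0))
  expect_true(all(coh$magnetite >= 0))
  expect_true(all(coh$r2star >= 0))
  expect_true(all(coh$lf >= 0 & coh$lf <= 4500))
  expect_true(all(coh$braak[coh$group == "control"] <= 3))
  expect_true(all(coh$braak[coh$group == "AD"] >= 4))
  # Braak assignment by severity rank: per-stage means of the assignment
  # variable are monotone within each diagnostic group by construction
  for (g in c("AD", "control")) {
    d <- coh[coh$group == g, ]
    m <- tapply(d$ferrihydrite, d$braak, mean)
    expect_true(all(diff(m) > 0))
  }
})

test_that("marginal moments converge to the specified group values", {
  coh <- generate_cohort(cohort_spec(n_ad = 10000, n_control = 10000,
                                     seed = 2))
  ad <- coh[coh$group == "AD", ]
  ct <- coh[coh$group == "control", ]
  expect_lt(abs(mean(ad$ferrihydrite) / 381.12 - 1), 0.02)
  expect_lt(abs(mean(ct$ferrihydrite) / 240.84 - 1), 0.02)
  expect_lt(abs(mean(ad$fe3) / 6.74 - 1), 0.02)
  expect_lt(abs(mean(ad$magnetite) / 118.83 - 1), 0.02)
  expect_lt(abs(mean(ad$r2star) / 0.033 - 1), 0.02)
})

test_that("copula reproduces target Spearman structure, including the null", {
  # independence: all targets zero
  marg <- default_marginals()
  vars <- names(marg$AD)
  zero <- diag(length(vars))
  dimnames(zero) <- list(vars, vars)
  spec0 <- cohort_spec(n_ad = 10000, n_control = 3,
                       spearman = list(AD = zero, control = zero), seed = 9)
  ad0 <- generate_cohort(spec0)
  ad0 <- ad0[ad0$group == "AD", vars]
  rho0 <- cor(ad0, method = "spearman")
  expect_lt(max(abs(rho0[upper.tri(rho0)])), 0.05)

  # headline target: Fe(III) ~ loading ratio at rho = 0.825
  coh <- generate_cohort(cohort_spec(n_ad = 10000, n_control = 10000,
                                     seed = 2))
  ad <- coh[coh$group == "AD", ]
  expect_lt(abs(cor(ad$fe3, ad$flr, method = "spearman") - 0.825), 0.03)
  expect_lt(abs(cor(ad$fe3, ad$ferrihydrite, method = "spearman") + 0.629),
            0.03)
})

test_that("PSD repair fixes mild violations and rejects severe ones", {
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(nearest_psd(R, tol = 0.05), "positive semidefinite")
  expect_silent(Rp <- nearest_psd(R, tol = 1))
  expect_gte(min(eigen(Rp)$values), 0)
  expect_equal(diag(Rp), rep(1, 3))
  # a PSD matrix passes through unchanged
  ok <- diag(3); ok[1, 2] <- ok[2, 1] <- 0.5
  expect_identical(nearest_psd(ok), ok)
  expect_error(nearest_psd(matrix(c(1, 2, 2, 1), 2)), "\\[-1, 1\\]")
})

test_that("synthesized echo stacks follow the mono-exponential law", {
  p <- toy_panel(r2star = 0.033)
  st <- synthesize_echo_stack(p$r2star, shape = c(3, 3), A = 1000)
  expect_equal(st$data[1, 1, 1], 1000 * exp(-0.4125))
  expect_equal(st$data[2, 3, 4], 1000 * exp(-44.6 * 0.033))
  flat <- synthesize_echo_stack(0, shape = c(2, 2), A = 700)
  expect_true(all(flat$data == 700))
  expect_error(synthesize_echo_stack(0.03, noise_frac = -1), "non-negative")
  expect_error(synthesize_echo_stack(0.03, te_ms = c(30, 20)), "increasing")
})

test_that("synthesized IRM curves follow the Langevin model exactly", {
  p <- toy_panel()
  # f = 0: flat at the background
  p0 <- toy_panel(magnetite = 0)
  c0 <- synthesize_irm(p0, 100, b_offset = 3e-6)
  expect_true(all(abs(c0$moment_emu_g - 3e-6) < 1e-18))
  # asymptote: Ms f + B as H -> infinity
  big <- synthesize_irm(p, 100, fields_G = c(10, 1e9), b_offset = 1e-6)
  expect_equal(big$moment_emu_g[2], 84 * p$magnetite * 1e-9 + 1e-6,
               tolerance = 1e-6)
  # x = 1 point: Ms f (coth 1 - 1) + B
  cst <- iron_constants()
  H1 <- 100 / (p$magnetite_moment * cst$x_coef)  # field where x = 1 at 100 K
  c1 <- synthesize_irm(p, 100, fields_G = c(H1 / 2, H1, 2 * H1),
                       b_offset = 0)
  expect_equal(c1$moment_emu_g[2],
               84 * p$magnetite * 1e-9 * (1 / tanh(1) - 1), tolerance = 1e-10)
  expect_error(synthesize_irm(p, 77), "temperature")
})

test_that("synthesized EPR spectra scale with Fe(III) content", {
  tm <- small_template()
  p1 <- toy_panel(fe3 = 5)
  p2 <- toy_panel(fe3 = 10)
  s1 <- synthesize_epr_spectrum(p1, tm)
  s2 <- synthesize_epr_spectrum(p2, tm)
  expect_equal(double_integral(s2), 2 * double_integral(s1))
  s0 <- synthesize_epr_spectrum(toy_panel(fe3 = 0), tm)
  expect_true(all(s0$amplitude == 0))
  # noiseless quantification round-trip
  ref <- synthetic_epr_reference()
  amp <- fit_epr_amplitude(s1, tm)
  fe3 <- quantify_fe3(amp$scale, double_integral(tm), ref, s1$sample_mass_g)
  expect_equal(fe3, 5, tolerance = 1e-8)
})
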