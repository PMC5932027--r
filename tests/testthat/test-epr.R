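test_that("spin matrices satisfy angular momentum algebra and the ZFS term is traceless", {
  ops <- spin_matrices(2.5)
  comm <- ops$Sx %*% ops$Sy - ops$Sy %*% ops$Sx
  expect_equal(comm, 1i * ops$Sz, tolerance = 1e-12)
  S2 <- ops$Sx %*% ops$Sx + ops$Sy %*% ops$Sy + ops$Sz %*% ops$Sz
  expect_equal(S2, (2.5 * 3.5) * diag(6) + 0i, tolerance = 1e-12)
  # zero-field splitting: eigen-shifts sum to zero at B = 0
  sys <- spin_system()
  ev <- eigen(ironforms:::.zfs_term(sys), symmetric = TRUE,
              only.values = TRUE)$values
  expect_equal(sum(ev), 0, tolerance = 1e-9)
})

test_that("production resonance search matches the dense eigen-scan oracle", {
  sys <- spin_system()
  freq <- 9.4859
  dirs <- ironforms:::fibonacci_octant(10)
  for (k in seq_len(nrow(dirs))) {
    prod <- resonance_fields(sys, freq, dirs[k, ], b_range = c(50, 350))
    oracle <- dense_scan_resonances(sys, freq, dirs[k, ],
                                    b_range = c(50, 350), step = 0.05)
    expect_equal(nrow(prod), nrow(oracle))
    for (r in seq_len(nrow(prod))) {
      o <- oracle[oracle[, "i"] == prod$lower[r] &
                  oracle[, "j"] == prod$upper[r], , drop = FALSE]
      expect_lt(min(abs(o[, "b"] - prod$b_res[r])), 0.1)
    }
  }
})

test_that("stick positions along z match a dense field scan at zero strain", {
  sys <- spin_system(gstrain = c(0, 0, 0))
  prod <- resonance_fields(sys, 9.4859, c(0, 0, 1), b_range = c(5, 400))
  oracle <- dense_scan_resonances(sys, 9.4859, c(0, 0, 1),
                                  b_range = c(5, 400), step = 0.02)
  expect_equal(nrow(prod), nrow(oracle))
  expect_equal(sort(prod$b_res), sort(oracle[, "b"]), tolerance = 0.05)
})

test_that("powder spectrum peaks at the g' = 4.3 resonance and converges", {
  tm <- small_template()
  absb <- as.numeric(pracma::cumtrapz(tm$field_mT, tm$amplitude))
  peak <- tm$field_mT[which.max(absb)]
  g43 <- 9.4859 / (4.3 * iron_constants()$ghz_per_mt)
  expect_lt(abs(peak - g43), 5)
  # orientation-grid convergence: doubling changes the double integral < 1%
  tm2 <- simulate_epr_spectrum(spin_system(),
                               field_mT = seq(50, 350, by = 1),
                               n_orient = 120)
  expect_lt(abs(double_integral(tm2) / double_integral(tm) - 1), 0.01)
})

test_that("axial and rhombic systems differ qualitatively near g' = 4.3", {
  field <- seq(50, 350, by = 2)
  rh <- simulate_epr_spectrum(spin_system(gstrain = c(0.05, 0.05, 0.05)),
                              field_mT = field, n_orient = 60)
  ax <- simulate_epr_spectrum(spin_system(EoverD = 0,
                                          gstrain = c(0.05, 0.05, 0.05)),
                              field_mT = field, n_orient = 60)
  win <- field > 140 & field < 175
  # rhombic concentrates absorption near 157 mT; axial does not
  frac <- function(s) {
    a <- abs(as.numeric(pracma::cumtrapz(s$field_mT, s$amplitude)))
    sum(a[win]) / sum(a)
  }
  expect_gt(frac(rh), 2 * frac(ax))
})

test_that("simulation guards warn on degenerate requests", {
  expect_warning(simulate_epr_spectrum(spin_system(D = 0),
                                       field_mT = seq(50, 350, by = 5),
                                       n_orient = 50), "4.3")
  expect_warning(simulate_epr_spectrum(spin_system(),
                                       field_mT = seq(400, 600, by = 5),
                                       n_orient = 50), "cover")
  expect_error(spin_system(EoverD = 0.5), "E/D")
  expect_error(spin_system(g = c(-1, 2, 2)), "positive")
  expect_error(spin_system(S = 1.5), "5/2")
})

test_that("amplitude + baseline fitting is exact for linear models", {
  tm <- small_template()
  m1 <- epr_spectrum(tm$field_mT, 3.7 * tm$amplitude, tm$frequency_GHz)
  f1 <- fit_epr_amplitude(m1, tm)
  expect_equal(f1$scale, 3.7, tolerance = 1e-10)
  expect_equal(unname(f1$baseline), c(0, 0), tolerance = 1e-8)

  m2 <- epr_spectrum(tm$field_mT,
                     tm$amplitude + 0.1 + 0.01 * tm$field_mT,
                     tm$frequency_GHz)
  f2 <- fit_epr_amplitude(m2, tm)
  expect_equal(f2$scale, 1, tolerance = 1e-8)
  expect_equal(unname(f2$baseline), c(0.1, 0.01), tolerance = 1e-8)

  zero_tmpl <- epr_spectrum(tm$field_mT, rep(0, length(tm$field_mT)),
                            tm$frequency_GHz)
  expect_error(fit_epr_amplitude(m1, zero_tmpl), "degenerate")
})

test_that("amplitude recovery stays within 2% under 1% peak noise", {
  tm <- small_template()
  peak <- max(abs(tm$amplitude))
  set.seed(61)
  errs <- replicate(100, {
    noisy <- epr_spectrum(tm$field_mT,
                          2.5 * tm$amplitude +
                            rnorm(length(tm$amplitude), 0, 0.01 * peak),
                          tm$frequency_GHz)
    abs(fit_epr_amplitude(noisy, tm)$scale / 2.5 - 1)
  })
  expect_lt(median(errs), 0.02)
})

test_that("double integration is exact on analytic signals", {
  b <- seq(-8, 8, by = 0.01)
  gauss_deriv <- -b / sqrt(2 * pi) * exp(-b^2 / 2)   # d/dB of unit Gaussian
  s <- epr_spectrum(b + 200, gauss_deriv, 9.4859)
  expect_lt(abs(double_integral(s) - 1), 1e-3)
  z <- epr_spectrum(b + 200, rep(0, length(b)), 9.4859)
  expect_equal(double_integral(z), 0)
  # axis reversal: constructor canonicalizes, result unchanged
  srev <- epr_spectrum(rev(b + 200), rev(gauss_deriv), 9.4859)
  expect_equal(double_integral(srev), double_integral(s))
  # gauss input units convert 10:1
  sg <- epr_spectrum((b + 200) * 10, gauss_deriv, 9.4859, field_unit = "G")
  expect_equal(sg$field_mT, s$field_mT)
})

test_that("quantification is linear, mass-normalized and matches the reference", {
  ref <- epr_reference(10, 0.02, 5)
  c1 <- quantify_fe3(1, 2, ref, 0.02)
  c2 <- quantify_fe3(2, 2, ref, 0.02)
  expect_equal(c2, 2 * c1)
  # equal integral and mass -> reference concentration
  expect_equal(quantify_fe3(1, 5, ref, 0.02), 10)
  # homogeneous sample: concentration independent of aliquot mass
  # (signal integral scales with mass)
  big <- quantify_fe3(1, 5 * 2, ref, 0.04)
  expect_equal(big, quantify_fe3(1, 5, ref, 0.02))
  expect_warning(quantify_fe3(1, 5, ref, 0.02, sample_temperature_K = 20),
                 "Curie")
  expect_error(epr_reference(-1, 1, 1), "positive")
})

test_that("a subject generated at the AD-mean Fe(III) is recovered noiselessly", {
  tm <- small_template()
  p <- toy_panel(fe3 = 6.74)
  s <- synthesize_epr_spectrum(p, tm)
  ref <- synthetic_epr_reference()
  amp <- fit_epr_amplitude(s, tm)
  fe3 <- quantify_fe3(amp$scale, double_integral(tm), ref, s$sample_mass_g)
  expect_lt(abs(fe3 / 6.74 - 1), 0.02)
})

test_that("EPR spectra round-trip through CSV + sidecar", {
  tm <- small_template()
  s <- epr_spectrum(tm$field_mT, tm$amplitude, 9.4859, sample_mass_g = 0.015)
  path <- file.path(tempdir(), "spec.csv")
  write_epr_csv(s, path)
  back <- read_epr_csv(path)
  expect_equal(back$amplitude, s$amplitude)
  expect_equal(back$frequency_GHz, 9.4859)
  expect_equal(back$sample_mass_g, 0.015)
  unlink(c(path, sub("csv$", "json", path)))
})
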