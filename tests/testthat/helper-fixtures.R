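# Shared fixtures, built once per test run.

# Small powder template: enough orientations for a stable g' = 4.3 line,
# coarse enough to keep the suite fast.
small_template <- function() {
  if (is.null(.fixture_env$template))
    .fixture_env$template <- simulate_epr_spectrum(
      spin_system(), field_mT = seq(50, 350, by = 1), n_orient = 60)
  .fixture_env$template
}

.fixture_env <- new.env(parent = emptyenv())

# A one-row panel with round ground-truth values for signal-synthesis tests.
toy_panel <- function(fe3 = 6.74, ferrihydrite = 381.12, magnetite = 118.83,
                      magnetite_moment = 5e4, ferritin_moment = 260,
                      r2star = 0.033) {
  data.frame(subject_id = "S001", group = "AD", braak = 4,
             r2star = r2star, fe3 = fe3, ferrihydrite = ferrihydrite,
             magnetite = magnetite, magnetite_moment = magnetite_moment,
             ferritin_moment = ferritin_moment,
             lf = (ferritin_moment / 5.92)^2,
             flr = 100 * (ferritin_moment / 5.92)^2 / 4500,
             stringsAsFactors = FALSE)
}

# Dense-grid eigenvalue-scan oracle for EPR resonance fields: scans the
# 6x6 Hamiltonian on a fine field grid and locates each sign change of
# (E_j - E_i - nu) by linear interpolation.  Independent of the bisection
# search used in production.
dense_scan_resonances <- function(sys, freq, n, b_range = c(1, 400),
                                  step = 0.02) {
  grid <- seq(b_range[1], b_range[2], by = step)
  ev <- vapply(grid, function(b) {
    sort(eigen(ironforms:::.hamiltonian(sys, b, n), symmetric = TRUE,
               only.values = TRUE)$values)
  }, numeric(6))
  out <- NULL
  for (i in 1:5) for (j in (i + 1):6) {
    f <- ev[j, ] - ev[i, ] - freq
    cr <- which(sign(f[-1]) * sign(f[-length(f)]) < 0)
    for (c0 in cr) {
      b0 <- grid[c0] - f[c0] * step / (f[c0 + 1] - f[c0])
      out <- rbind(out, c(b = b0, i = i, j = j))
    }
  }
  out
}
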