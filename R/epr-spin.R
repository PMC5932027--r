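## S = 5/2 spin-Hamiltonian machinery for cw-EPR powder simulation.
## Energies are kept in GHz and fields in mT throughout this file.

#' Spin operator matrices
#'
#' Matrices of Sx, Sy, Sz in the |S, m> basis (m descending), for
#' half-integer or integer spin.
#'
#' @param S Spin quantum number (default 5/2).
#' @return List of complex matrices \code{Sx}, \code{Sy}, \code{Sz} of
#'   dimension \code{2S+1}.
#' @export
spin_matrices <- function(S = 2.5) {
  m <- seq(S, -S, by = -1)
  n <- length(m)
  sp <- matrix(0, n, n)  # S+ in this basis: <m+1|S+|m>
  if (n > 1)
    for (k in 2:n) sp[k - 1, k] <- sqrt(S * (S + 1) - m[k] * (m[k] + 1))
  Sx <- (sp + t(sp)) / 2 + 0i
  Sy <- (sp - t(sp)) / (2i)
  Sz <- diag(m) + 0i
  list(Sx = Sx, Sy = Sy, Sz = Sz)
}

#' Define an S = 5/2 zero-field-splitting spin system
#'
#' Parameters of the high-spin Fe(III) Hamiltonian
#' \deqn{H = \mu_B B \sum_k g_k n_k S_k + D(S_z^2 - S(S+1)/3)
#'       + E(S_x^2 - S_y^2)}
#' with principal g values, Gaussian g-strain widths, axial ZFS \code{D}
#' and rhombicity \code{E/D}.  Defaults are the fixed rhombic-Fe(III)
#' parameter set used for tissue spectra: near-maximal rhombicity
#' (\code{E/D = 0.3324}) whose middle Kramers doublet produces the
#' effective g' = 4.3 resonance.
#'
#' @param S Spin (fixed at 5/2).
#' @param g Principal g values (length 3, positive).
#' @param gstrain Gaussian strain width of each principal g value
#'   (length 3, non-negative).
#' @param D Axial zero-field splitting, GHz.
#' @param EoverD Rhombicity E/D, in \[0, 1/3\].
#' @param temperature_K Measurement temperature (Boltzmann populations).
#' @return An object of class \code{spin_system}.
#' @export
spin_system <- function(S = 2.5, g = c(1.83, 1.998, 2.0151),
                        gstrain = c(0.574, 0.129, 0.0197),
                        D = 20.96, EoverD = 0.3324,
                        temperature_K = 12) {
  if (S != 2.5) stop("only S = 5/2 is supported")
  if (length(g) != 3 || any(g <= 0)) stop("g must be 3 positive values")
  if (length(gstrain) != 3 || any(gstrain < 0))
    stop("gstrain must be 3 non-negative widths")
  if (EoverD < 0 || EoverD > 1 / 3)
    stop("E/D must lie in [0, 1/3]")
  if (temperature_K <= 0) stop("temperature must be positive")
  structure(list(S = S, g = g, gstrain = gstrain, D = D, E = D * EoverD,
                 EoverD = EoverD, temperature_K = temperature_K,
                 ops = spin_matrices(S)),
            class = "spin_system")
}

# Full Hamiltonian (GHz) at field B_mT along unit vector n (molecular frame)
.hamiltonian <- function(sys, B_mT, n) {
  ghz <- iron_constants()$ghz_per_mt
  ops <- sys$ops
  Hz <- ghz * B_mT * (sys$g[1] * n[1] * ops$Sx +
                      sys$g[2] * n[2] * ops$Sy +
                      sys$g[3] * n[3] * ops$Sz)
  Hz + .zfs_term(sys)
}

.zfs_term <- function(sys) {
  ops <- sys$ops
  S <- sys$S
  Id <- diag(nrow(ops$Sz)) + 0i
  sys$D * (ops$Sz %*% ops$Sz - S * (S + 1) / 3 * Id) +
    sys$E * (ops$Sx %*% ops$Sx - ops$Sy %*% ops$Sy)
}

.eigvals <- function(sys, B_mT, n) {
  sort(eigen(.hamiltonian(sys, B_mT, n), symmetric = TRUE,
             only.values = TRUE)$values)
}

#' Resonance fields for one orientation
#'
#' Locates all fields in \code{b_range} at which an eigenvalue difference
#' of the spin Hamiltonian equals the microwave quantum \code{h nu}:
#' the eigenvalues are scanned on a coarse field grid and each sign change
#' of \code{E_j - E_i - nu} is refined by bisection.  For each resonance
#' the transition intensity (squared perpendicular spin matrix element,
#' averaged over the two microwave polarizations, weighted by the
#' Boltzmann population difference and the frequency-to-field conversion
#' factor \code{1/|d(dE)/dB|}) and the first-order g-strain field widths
#' (Hellmann-Feynman derivatives \code{dB_res/dg_k}) are returned.
#'
#' @param sys A [spin_system()].
#' @param freq_GHz Microwave frequency, GHz.
#' @param n Unit field direction in the molecular frame.
#' @param b_range Field search window, mT.
#' @param coarse_step Coarse scan step, mT.
#' @param tol Bisection tolerance on the resonance field, mT.
#' @return data.frame with columns \code{b_res}, \code{lower},
#'   \code{upper} (level indices), \code{weight} (net intensity) and
#'   \code{sigma_g} (strain-induced Gaussian field width, mT).
#' @export
resonance_fields <- function(sys, freq_GHz, n, b_range = c(1, 400),
                             coarse_step = 1, tol = 1e-4) {
  grid <- seq(b_range[1], b_range[2], by = coarse_step)
  ev <- vapply(grid, function(b) .eigvals(sys, b, n), numeric(6))
  pairs <- utils::combn(6, 2)
  out <- list()
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    fvals <- ev[j, ] - ev[i, ] - freq_GHz
    sgn <- sign(fvals)
    cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    for (c0 in cross) {
      lo <- grid[c0]; hi <- grid[c0 + 1]
      flo <- fvals[c0]
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        e <- .eigvals(sys, mid, n)
        fm <- e[j] - e[i] - freq_GHz
        if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
      }
      out[[length(out) + 1]] <- c(b = (lo + hi) / 2, i = i, j = j)
    }
  }
  if (!length(out))
    return(data.frame(b_res = numeric(0), lower = integer(0),
                      upper = integer(0), weight = numeric(0),
                      sigma_g = numeric(0)))
  res <- do.call(rbind, out)
  ann <- t(apply(res, 1, function(r) {
    .annotate_resonance(sys, freq_GHz, n, r[["b"]], r[["i"]], r[["j"]])
  }))
  data.frame(b_res = res[, "b"], lower = as.integer(res[, "i"]),
             upper = as.integer(res[, "j"]),
             weight = ann[, 1], sigma_g = ann[, 2])
}

# intensity weight and strain width at one resonance
.annotate_resonance <- function(sys, freq_GHz, n, b, i, j) {
  cst <- iron_constants()
  H <- .hamiltonian(sys, b, n)
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  vals <- e$values[ord]; vecs <- e$vectors[, ord, drop = FALSE]
  vi <- vecs[, i]; vj <- vecs[, j]
  ops <- sys$ops
  # two unit vectors perpendicular to n
  ref <- if (abs(n[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  u <- ref - sum(ref * n) * n; u <- u / sqrt(sum(u^2))
  v <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  gop <- function(d) {
    sys$g[1] * d[1] * ops$Sx + sys$g[2] * d[2] * ops$Sy +
      sys$g[3] * d[3] * ops$Sz
  }
  amp <- (Mod(sum(Conj(vi) * (gop(u) %*% vj)))^2 +
          Mod(sum(Conj(vi) * (gop(v) %*% vj)))^2) / 2
  # Boltzmann population difference at the measurement temperature
  en_K <- vals * cst$kelvin_per_ghz
  pop <- exp(-(en_K - min(en_K)) / sys$temperature_K)
  pop <- pop / sum(pop)
  dpop <- pop[i] - pop[j]
  # Hellmann-Feynman: d(dE)/dB and d(dE)/dg_k
  sk <- function(op) Re(sum(Conj(vj) * (op %*% vj)) - sum(Conj(vi) * (op %*% vi)))
  dS <- c(sk(ops$Sx), sk(ops$Sy), sk(ops$Sz))
  ghz <- cst$ghz_per_mt
  dDE_dB <- ghz * sum(sys$g * n * dS)
  if (abs(dDE_dB) < 1e-12) dDE_dB <- sign(dDE_dB + 1e-300) * 1e-12
  dB_dg <- -ghz * b * n * dS / dDE_dB
  sigma_g <- sqrt(sum((dB_dg * sys$gstrain)^2))
  c(amp * dpop / abs(dDE_dB), sigma_g)
}

# deterministic low-discrepancy grid of unit vectors on the positive octant
# (the Hamiltonian is invariant under sign flips of any field component)
fibonacci_octant <- function(n) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  golden <- (sqrt(5) - 1) / 2
  phi <- ((i * golden) %% 1) * (pi / 2)
  st <- sqrt(1 - z^2)
  cbind(st * cos(phi), st * sin(phi), z)
}

#' Simulate a powder first-derivative cw-EPR spectrum
#'
#' Powder-averages the resonance fields of a [spin_system()] over a
#' deterministic spherical Fibonacci grid restricted to one octant (the
#' Hamiltonian is invariant under sign flips of the field components) and
#' accumulates, for every resonance, the analytic first derivative of a
#' Gaussian absorption line centred at the resonance field.  The Gaussian
#' width combines the first-order g-strain mapping
#' \code{|dB_res/dg_k| sigma_gk} (in quadrature over the three principal
#' axes) with an intrinsic residual linewidth.  Modulation-amplitude
#' broadening is not convolved (6 G peak-to-peak is small against the
#' strain-dominated linewidths here).
#'
#' @param sys A [spin_system()].
#' @param freq_GHz Microwave frequency, GHz.
#' @param field_mT Ascending field axis, mT; should cover the g' = 4.3
#'   region (about \code{hv/(4.3 mu_B)}) for the default system.
#' @param n_orient Number of powder orientations (>= 50).
#' @param lw_mT Intrinsic residual Gaussian linewidth (standard deviation),
#'   mT.
#' @param sample_mass_g Optional wet mass of the sample, g (metadata).
#' @return An object of class \code{epr_spectrum}: \code{field_mT},
#'   first-derivative \code{amplitude} (arbitrary units),
#'   \code{frequency_GHz}, \code{temperature_K}, \code{modulation_Gpp},
#'   \code{sample_mass_g}.
#' @export
simulate_epr_spectrum <- function(sys, freq_GHz = 9.4859,
                                  field_mT = seq(50, 350, by = 0.5),
                                  n_orient = 400, lw_mT = 1.5,
                                  sample_mass_g = NA_real_) {
  stopifnot(inherits(sys, "spin_system"))
  if (is.unsorted(field_mT, strictly = TRUE))
    stop("field axis must be strictly increasing")
  if (n_orient < 50) stop("at least 50 orientations are required")
  g43_pos <- freq_GHz / (4.3 * iron_constants()$ghz_per_mt)
  if (sys$D == 0)
    warning("D = 0: no g' = 4.3 feature will be present")
  else if (g43_pos < min(field_mT) || g43_pos > max(field_mT))
    warning("field axis does not cover the g' = 4.3 resonance near ",
            round(g43_pos, 1), " mT")
  margin <- 0.2 * diff(range(field_mT))
  b_range <- c(max(min(field_mT) - margin, 0.5), max(field_mT) + margin)
  dirs <- fibonacci_octant(n_orient)
  deriv <- numeric(length(field_mT))
  for (k in seq_len(n_orient)) {
    res <- resonance_fields(sys, freq_GHz, dirs[k, ], b_range = b_range)
    if (!nrow(res)) next
    for (r in seq_len(nrow(res))) {
      sg <- sqrt(res$sigma_g[r]^2 + lw_mT^2)
      db <- field_mT - res$b_res[r]
      # d/dB of a unit-area Gaussian absorption
      deriv <- deriv - res$weight[r] * db / (sg^3 * sqrt(2 * pi)) *
        exp(-db^2 / (2 * sg^2))
    }
  }
  epr_spectrum(field_mT, deriv / n_orient, freq_GHz,
               temperature_K = sys$temperature_K,
               sample_mass_g = sample_mass_g)
}

#' Construct an EPR spectrum object
#'
#' A measured or simulated first-derivative cw-EPR spectrum with its
#' acquisition metadata.  Fields in gauss are accepted and converted
#' (1 mT = 10 G); a descending axis is canonically reordered.
#'
#' @param field_mT Field axis, mT, strictly monotone.
#' @param amplitude First-derivative amplitude (arbitrary units).
#' @param frequency_GHz Microwave frequency, GHz (positive).
#' @param temperature_K Temperature, K.
#' @param modulation_Gpp Modulation amplitude, gauss peak-to-peak.
#' @param sample_mass_g Wet mass of the measured tissue, g.
#' @param field_unit \code{"mT"} or \code{"G"}.
#' @return Object of class \code{epr_spectrum}.
#' @export
epr_spectrum <- function(field_mT, amplitude, frequency_GHz,
                         temperature_K = 12, modulation_Gpp = 6,
                         sample_mass_g = NA_real_, field_unit = c("mT", "G")) {
  field_unit <- match.arg(field_unit)
  if (field_unit == "G") field_mT <- field_mT / 10
  if (length(field_mT) != length(amplitude))
    stop("field and amplitude must have the same length")
  if (frequency_GHz <= 0) stop("frequency must be positive")
  if (is.unsorted(field_mT, strictly = TRUE)) {
    if (is.unsorted(rev(field_mT), strictly = TRUE))
      stop("field axis must be strictly monotone")
    field_mT <- rev(field_mT); amplitude <- rev(amplitude)
  }
  structure(list(field_mT = field_mT, amplitude = amplitude,
                 frequency_GHz = frequency_GHz,
                 temperature_K = temperature_K,
                 modulation_Gpp = modulation_Gpp,
                 sample_mass_g = sample_mass_g),
            class = "epr_spectrum")
}

#' @export
print.epr_spectrum <- function(x, ...) {
  cat(sprintf(
    "EPR spectrum: %d points, %.1f-%.1f mT, %.4f GHz, %g K\n",
    length(x$field_mT), min(x$field_mT), max(x$field_mT),
    x$frequency_GHz, x$temperature_K))
  invisible(x)
}
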