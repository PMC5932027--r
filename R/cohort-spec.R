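#' Convert a target Spearman correlation to the latent Pearson correlation
#'
#' For a Gaussian copula, a latent (normal-scores) Pearson correlation of
#' \code{2 sin(pi rho / 6)} yields population Spearman correlation
#' \code{rho} for any continuous marginals.
#'
#' @param rho Spearman correlation(s) in \[-1, 1\].
#' @return Latent Pearson correlation(s).
#' @export
spearman_to_pearson <- function(rho) {
  if (any(abs(rho) > 1)) stop("Spearman rho must lie in [-1, 1]")
  2 * sin(pi * rho / 6)
}

#' Repair a correlation matrix to the nearest positive semidefinite matrix
#'
#' Eigenvalue clipping: negative eigenvalues are raised to a small floor,
#' the matrix is reconstructed and rescaled to unit diagonal.  If the
#' repaired matrix differs from the input by more than \code{tol} in any
#' entry the input is considered irreparable and an error is raised.
#'
#' @param R Symmetric matrix with unit diagonal, entries in \[-1, 1\].
#' @param tol Maximum tolerated absolute entry change introduced by repair.
#' @param eig_floor Eigenvalue floor used for clipping.
#' @return A positive semidefinite correlation matrix.
#' @export
nearest_psd <- function(R, tol = 0.05, eig_floor = 1e-8) {
  if (!isSymmetric(unname(R), tol = 1e-10))
    stop("correlation matrix must be symmetric")
  if (any(abs(diag(R) - 1) > 1e-12))
    stop("correlation matrix must have unit diagonal")
  if (any(abs(R) > 1 + 1e-12))
    stop("correlation entries must lie in [-1, 1]")
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= eig_floor) return(R)
  v <- pmax(e$values, eig_floor)
  Rp <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(Rp))
  Rp <- Rp / outer(d, d)
  diag(Rp) <- 1
  if (max(abs(Rp - R)) > tol)
    stop("correlation matrix is too far from positive semidefinite; ",
         "repair would change an entry by ", signif(max(abs(Rp - R)), 3))
  Rp
}

## Marginal specification helpers --------------------------------------------
## A marginal is a list(family, mean, sd) with mean/sd on the natural
## (reported) scale.  Supported families:
##   lognormal   - moment-matched lognormal (strictly positive)
##   truncnorm0  - normal truncated at 0; the underlying normal parameters
##                 are solved numerically so the *truncated* variable has
##                 exactly the requested mean/sd
##   clamplognormal - max(Y - offset, 0) with Y lognormal; the lognormal
##                 parameters are solved numerically so the *clamped*
##                 variable has exactly the requested mean/sd.  This is the
##                 back-transform of a normal on the log10(x + offset) scale
##                 with an atom at zero (samples below the detection limit).

marginal_spec <- function(family, mean, sd, offset = 100) {
  if (sd < 0) stop("marginal sd must be non-negative")
  if (!family %in% c("lognormal", "truncnorm0", "clamplognormal"))
    stop("unknown marginal family: ", family)
  list(family = family, mean = mean, sd = sd, offset = offset)
}

# moments of max(Y - off, 0), Y ~ lognormal(mu, sig)
.clamp_lnorm_moments <- function(mu, sig, off) {
  m1 <- exp(mu + sig^2 / 2)
  p_above <- stats::pnorm((mu - log(off)) / sig)
  ey_above <- m1 * stats::pnorm((mu + sig^2 - log(off)) / sig)
  ey2_above <- exp(2 * mu + 2 * sig^2) *
    stats::pnorm((mu + 2 * sig^2 - log(off)) / sig)
  ex <- ey_above - off * p_above
  ex2 <- ey2_above - 2 * off * ey_above + off^2 * p_above
  c(mean = ex, sd = sqrt(max(ex2 - ex^2, 0)))
}

# mean/sd of a normal(mu, sig) truncated at 0
.truncnorm_moments <- function(mu, sig) {
  a <- -mu / sig
  Z <- stats::pnorm(a, lower.tail = FALSE)
  h <- stats::dnorm(a) / Z
  m1 <- mu + sig * h
  v <- sig^2 * (1 + a * h - h^2)
  c(mean = m1, sd = sqrt(max(v, 0)))
}

# underlying normal parameters whose 0-truncation has the target moments
.truncnorm_params <- function(m, s) {
  if (m <= 0) stop("truncated-normal marginal requires positive mean")
  # if truncation is numerically irrelevant, skip the solve
  if (m / s > 8) return(c(m, s))
  obj <- function(p) {
    mm <- .truncnorm_moments(p[1], exp(p[2]))
    sum((mm - c(m, s))^2 / c(m, s)^2)
  }
  fit <- stats::optim(c(m, log(s)), obj,
                      control = list(reltol = 1e-15, maxit = 5000))
  c(fit$par[1], exp(fit$par[2]))
}

# quantile function for one marginal, given uniforms
.marginal_quantile <- function(ms, u) {
  m <- ms$mean; s <- ms$sd
  switch(ms$family,
    lognormal = {
      if (m <= 0) stop("lognormal marginal requires positive mean")
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      stats::qlnorm(u, meanlog, sdlog)
    },
    truncnorm0 = {
      par <- .truncnorm_params(m, s)
      p0 <- stats::pnorm(0, par[1], par[2])
      stats::qnorm(p0 + u * (1 - p0), par[1], par[2])
    },
    clamplognormal = {
      off <- ms$offset
      obj <- function(p) {
        mm <- .clamp_lnorm_moments(p[1], exp(p[2]), off)
        sum((mm - c(m, s))^2)
      }
      start_sdlog <- sqrt(log(1 + (s / (m + off))^2))
      start <- c(log(m + off) - start_sdlog^2 / 2, log(start_sdlog))
      fit <- stats::optim(start, obj, control = list(reltol = 1e-14,
                                                     maxit = 5000))
      pmax(stats::qlnorm(u, fit$par[1], exp(fit$par[2])) - off, 0)
    })
}

#' Specify a synthetic two-group cohort
#'
#' Defines group sizes, per-variable marginal distributions (on the reported
#' scale) and per-group target Spearman correlation matrices for the
#' Gaussian-copula cohort generator.  The defaults encode the study
#' conditions of a post-mortem temporal-cortex iron cohort: 22 AD patients
#' and 14 controls, the published group means/SDs of median R2*, EPR
#' Fe(III), magnetite/maghemite and ferrihydrite concentration, and the
#' published significant Spearman correlations among iron forms, all other
#' pairs set to zero.  The ferritin particle moment marginals (which, with
#' \code{alpha}, set the loading factor) and the magnetite particle moment
#' marginals are not tabulated in that form and are chosen to reproduce the
#' reported qualitative structure: mean loading near 1600 atoms (~36% of
#' capacity) in controls and near 1960 (~44%) in AD, and magnetite moments
#' well above 1000 Bohr magnetons with a markedly larger AD mean.
#'
#' Variables: \code{r2star} (ms^-1), \code{fe3} (ug/g wet weight),
#' \code{ferrihydrite} (ug/g dry weight), \code{magnetite} (ng/g dry
#' weight), \code{magnetite_moment} and \code{ferritin_moment} (Bohr
#' magnetons).
#'
#' @param n_ad,n_control Group sizes (each at least 3).
#' @param marginals Named list (per group) of named lists of
#'   \code{marginal_spec}-style entries; defaults as described.
#' @param spearman Named list (per group) of target Spearman matrices over
#'   the six variables.
#' @param braak_by Variable whose within-group rank drives Braak-stage
#'   assignment (controls get stages 0-3, AD 4-6, by rank quantile, so
#'   stratum means of this variable are monotone in stage by construction).
#' @param alpha Exponent of the loading-factor relation used to derive the
#'   ground-truth LF from the ferritin moment (in \[0.5, 0.6\]).
#' @param seed Integer seed; generation is fully reproducible.
#' @param psd_tol Tolerance forwarded to [nearest_psd()].
#' @return An object of class \code{cohort_spec}.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_ad = 22L, n_control = 14L,
                        marginals = default_marginals(),
                        spearman = default_spearman(),
                        braak_by = "ferrihydrite",
                        alpha = 0.5,
                        seed = 1L,
                        psd_tol = 0.05) {
  if (n_ad < 3 || n_control < 3) stop("group sizes must be at least 3")
  vars <- names(marginals$AD)
  for (g in c("AD", "control")) {
    if (!identical(names(marginals[[g]]), vars))
      stop("marginal variable sets must agree across groups")
    R <- spearman[[g]]
    if (!identical(dim(R), c(length(vars), length(vars))))
      stop("Spearman matrix has wrong dimension for group ", g)
    nearest_psd(spearman_to_pearson(R), tol = psd_tol)  # validity check
  }
  if (!braak_by %in% vars) stop("braak_by must name a cohort variable")
  if (alpha < 0.5 || alpha > 0.6) stop("alpha must lie in [0.5, 0.6]")
  structure(list(n_ad = as.integer(n_ad), n_control = as.integer(n_control),
                 variables = vars, marginals = marginals,
                 spearman = spearman, braak_by = braak_by,
                 alpha = alpha, seed = as.integer(seed),
                 psd_tol = psd_tol),
            class = "cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_marginals <- function() {
  list(
    AD = list(
      r2star = marginal_spec("truncnorm0", 0.033, 0.005),
      fe3 = marginal_spec("lognormal", 6.74, 3.48),
      ferrihydrite = marginal_spec("truncnorm0", 381.12, 178.97),
      magnetite = marginal_spec("clamplognormal", 118.83, 125.87),
      magnetite_moment = marginal_spec("lognormal", 5e4, 2e4),
      ferritin_moment = marginal_spec("lognormal", 262, 40)
    ),
    control = list(
      r2star = marginal_spec("truncnorm0", 0.028, 0.004),
      fe3 = marginal_spec("lognormal", 5.29, 3.66),
      ferrihydrite = marginal_spec("truncnorm0", 240.84, 98.02),
      magnetite = marginal_spec("clamplognormal", 121.03, 123.11),
      magnetite_moment = marginal_spec("lognormal", 2.5e4, 1e4),
      ferritin_moment = marginal_spec("lognormal", 237, 25)
    )
  )
}

#' @rdname cohort_spec
#' @export
default_spearman <- function() {
  vars <- c("r2star", "fe3", "ferrihydrite", "magnetite",
            "magnetite_moment", "ferritin_moment")
  mk <- function(entries) {
    R <- diag(length(vars))
    dimnames(R) <- list(vars, vars)
    for (e in entries) {
      R[e[[1]], e[[2]]] <- R[e[[2]], e[[1]]] <- e[[3]]
    }
    R
  }
  list(
    AD = mk(list(list("fe3", "ferritin_moment", 0.825),
                 list("fe3", "ferrihydrite", -0.629),
                 list("ferrihydrite", "ferritin_moment", -0.729),
                 list("ferrihydrite", "magnetite", 0.474))),
    control = mk(list(list("fe3", "ferritin_moment", 0.865),
                      list("fe3", "ferrihydrite", -0.908),
                      list("ferrihydrite", "ferritin_moment", -0.935)))
  )
}
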