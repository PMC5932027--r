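#' Default pipeline run configuration
#'
#' All tunables of a full simulate-fit-stats run, each with a default.
#' Noise levels are expressed per modality: Rician channel noise as a
#' fraction of the MRI prefactor (0.05 = SNR 20), SQUID and EPR noise as
#' fractions of the respective signal amplitudes.  The configuration
#' round-trips losslessly through YAML.
#'
#' @param seed Integer seed governing every random draw of the run.
#' @param n_ad,n_control Cohort sizes.
#' @param noise List of per-modality noise fractions (\code{mri},
#'   \code{squid}, \code{epr}); zero means noiseless.
#' @param alpha Loading-factor exponent, in \[0.5, 0.6\].
#' @param ms_magnetite,ms_ferrihydrite Fixed saturation magnetizations,
#'   emu/g.
#' @param snr_threshold Discard threshold for the 100 K IRM screen.
#' @param welch Use Welch instead of pooled-variance t-tests.
#' @param mri_shape Voxel grid synthesized per subject.
#' @param epr_orientations Powder orientations for the template.
#' @param write_raw Also write per-subject raw signal files.
#' @return A list of class \code{run_config}.
#' @export
run_config <- function(seed = 1L, n_ad = 22L, n_control = 14L,
                       noise = list(mri = 0.05, squid = 0.01, epr = 0.01),
                       alpha = 0.5, ms_magnetite = 84,
                       ms_ferrihydrite = 0.62, snr_threshold = 4,
                       welch = FALSE, mri_shape = c(12L, 12L),
                       epr_orientations = 200L, write_raw = FALSE) {
  structure(list(seed = as.integer(seed), n_ad = as.integer(n_ad),
                 n_control = as.integer(n_control), noise = noise,
                 alpha = alpha, ms_magnetite = ms_magnetite,
                 ms_ferrihydrite = ms_ferrihydrite,
                 snr_threshold = snr_threshold, welch = welch,
                 mri_shape = as.integer(mri_shape),
                 epr_orientations = as.integer(epr_orientations),
                 write_raw = isTRUE(write_raw)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' Measure one subject's panel from synthesized raw signals
#'
#' Runs the three modality fits (relaxometry, EPR quantification, 100 K
#' and 5 K Langevin fits) on raw signals synthesized from one ground-truth
#' panel row, applying the SNR discard rule to the 100 K curve.
#'
#' @param panel One-row data.frame from [generate_cohort()].
#' @param template EPR template from [simulate_epr_spectrum()].
#' @param config A [run_config()].
#' @return One-row data.frame of measured quantities (columns as the
#'   ground-truth panel, plus \code{magnetite_usable}).
#' @export
measure_subject <- function(panel, template, config = run_config()) {
  ## MRI
  stack <- synthesize_echo_stack(panel$r2star,
                                 noise_frac = config$noise$mri,
                                 shape = config$mri_shape)
  roi <- array(TRUE, config$mri_shape)
  # log-linear is exact at zero noise; under noise the nonlinear refinement
  # avoids the log-transform bias of magnitude data
  mri_method <- if (config$noise$mri > 0) "nonlinear" else "loglinear"
  r2 <- roi_median(fit_r2star(stack, mri_method), roi)$median_r2star
  ## EPR
  peak <- max(abs(template$amplitude)) *
    panel$fe3 * 0.015 / double_integral(template)
  spec <- synthesize_epr_spectrum(panel, template,
                                  noise_sd = config$noise$epr * abs(peak))
  ref <- synthetic_epr_reference()
  amp <- fit_epr_amplitude(spec, template)
  fe3 <- quantify_fe3(amp$scale, double_integral(template), ref,
                      spec$sample_mass_g)
  ## SQUID 100 K (magnetite/maghemite)
  p100 <- irm_true_parameters(panel, 100)
  c100 <- synthesize_irm(panel, 100,
                         noise_sd = config$noise$squid * p100$Ms * p100$f)
  if (check_snr(c100, config$snr_threshold)) {
    f100 <- fit_irm(c100, config$ms_magnetite)
    magnetite <- concentration_from_fraction(f100$f, "magnetite_100K")
    magnetite_moment <- f100$mu_p
    usable <- TRUE
  } else {
    magnetite <- 0
    magnetite_moment <- NA_real_
    usable <- FALSE
  }
  ## SQUID 5 K (ferrihydrite / ferritin)
  p5 <- irm_true_parameters(panel, 5)
  c5 <- synthesize_irm(panel, 5,
                       noise_sd = config$noise$squid * p5$Ms * p5$f)
  f5 <- fit_irm(c5, config$ms_ferrihydrite)
  ferrihydrite <- concentration_from_fraction(f5$f, "ferrihydrite_5K")
  load <- loading_factor(f5$mu_p, config$alpha)
  data.frame(subject_id = panel$subject_id, group = panel$group,
             braak = panel$braak, r2star = r2, fe3 = fe3,
             ferrihydrite = ferrihydrite, magnetite = magnetite,
             magnetite_moment = magnetite_moment,
             ferritin_moment = f5$mu_p, lf = load$lf, flr = load$flr,
             magnetite_usable = usable, stringsAsFactors = FALSE)
}

#' Run the full simulate-fit-stats pipeline
#'
#' Generates a seeded ground-truth cohort, synthesizes and fits raw
#' signals per subject, applies the discard rule, runs the statistics
#' layer, and writes all stage outputs plus a manifest (seed, package
#' version, file checksums) under \code{outdir}.  A rerun with the same
#' configuration reproduces identical output files.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with \code{truth}, \code{measured},
#'   \code{stats} and \code{manifest}.
#' @export
run_pipeline <- function(config = run_config(), outdir = tempfile("ironrun")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  ## stage 1: cohort ground truth
  spec <- cohort_spec(n_ad = config$n_ad, n_control = config$n_control,
                      alpha = config$alpha, seed = config$seed)
  truth <- generate_cohort(spec)
  utils::write.csv(truth, file.path(outdir, "cohort_truth.csv"),
                   row.names = FALSE)
  ## stage 2: per-subject raw synthesis + modality fits
  set.seed(config$seed + 1L)
  template <- epr_template(n_orient = config$epr_orientations)
  measured <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
    measure_subject(truth[i, ], template, config)
  }))
  utils::write.csv(measured, file.path(outdir, "cohort_measured.csv"),
                   row.names = FALSE)
  ## stage 3: statistics
  stats_out <- cohort_statistics(measured, welch = config$welch)
  utils::write.csv(stats_out$tests, file.path(outdir, "group_tests.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(stats_out$correlogram_ad$rho),
                   file.path(outdir, "correlogram_AD.csv"))
  utils::write.csv(as.data.frame(stats_out$correlogram_control$rho),
                   file.path(outdir, "correlogram_control.csv"))
  jsonlite::write_json(stats_out$report,
                       file.path(outdir, "stats_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ## manifest
  files <- c("cohort_truth.csv", "cohort_measured.csv", "group_tests.csv",
             "correlogram_AD.csv", "correlogram_control.csv",
             "stats_report.json")
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ironforms")),
    config = unclass(config),
    outputs = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, measured = measured, stats = stats_out,
                 manifest = manifest))
}

#' Statistics layer of the pipeline
#'
#' Group tests, per-group correlograms, the Fisher-z comparison for every
#' pair significant in either group, and the pooled rank-based partial
#' correlations among Fe(III), ferrihydrite and the loading ratio.
#'
#' @param measured Measured cohort table (see [measure_subject()]).
#' @param welch Welch t-tests instead of pooled.
#' @return List with \code{tests}, \code{correlogram_ad},
#'   \code{correlogram_control}, \code{comparisons}, \code{partial},
#'   \code{braak}, and a JSON-ready \code{report}.
#' @export
cohort_statistics <- function(measured, welch = FALSE) {
  tests <- group_tests(measured, welch = welch)
  cg_ad <- correlogram(measured, "AD")
  cg_ct <- correlogram(measured, "control")
  vars <- rownames(cg_ad$rho)
  comparisons <- list()
  for (a in seq_along(vars)) for (b in seq_along(vars)) {
    if (b <= a) next
    pa <- cg_ad$p[a, b]; pc <- cg_ct$p[a, b]
    if (is.na(pa) || is.na(pc)) next
    if (pa < 0.05 || pc < 0.05) {
      cc <- compare_correlations(cg_ad$rho[a, b], cg_ad$n[a, b],
                                 cg_ct$rho[a, b], cg_ct$n[a, b])
      comparisons[[paste(vars[a], vars[b], sep = "~")]] <- cc
    }
  }
  partial <- list(
    fe3_flr_given_ferrihydrite =
      partial_correlation(measured, "fe3", "flr", "ferrihydrite"),
    ferrihydrite_flr_given_fe3 =
      partial_correlation(measured, "ferrihydrite", "flr", "fe3"),
    fe3_ferrihydrite_given_flr =
      partial_correlation(measured, "fe3", "ferrihydrite", "flr"))
  braak <- braak_stratify(measured)
  report <- list(
    group_tests = tests,
    spearman_AD = cg_ad$rho, spearman_control = cg_ct$rho,
    fisher_z = lapply(comparisons, unclass),
    partial_correlation = partial,
    braak_strata = braak)
  list(tests = tests, correlogram_ad = cg_ad, correlogram_control = cg_ct,
       comparisons = comparisons, partial = partial, braak = braak,
       report = report)
}

## cached unit-amplitude EPR template (deterministic; depends only on the
## orientation count, axis and linewidth)
.template_cache <- new.env(parent = emptyenv())

#' Cached default EPR template
#'
#' The powder template with the fixed rhombic-Fe(III) parameter set, at
#' the default frequency and field axis; cached per orientation count for
#' the session (the simulation is deterministic).
#'
#' @param n_orient Number of powder orientations.
#' @return An [epr_spectrum()].
#' @export
epr_template <- function(n_orient = 200) {
  key <- as.character(n_orient)
  if (is.null(.template_cache[[key]]))
    .template_cache[[key]] <-
      simulate_epr_spectrum(spin_system(), n_orient = n_orient)
  .template_cache[[key]]
}
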