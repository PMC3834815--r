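# End-to-end pipeline: simulate -> fit -> cd -> report.  Every stage
# reads its inputs from the output directory, so stages can be run
# separately (e.g. `fit` on measured files dropped into decays/).  All
# randomness flows from the master seed through substream_seed(), and
# writers format deterministically, so a repeated run is byte-identical.

pipeline_log <- function(verbose, stage, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  invisible(NULL)
}

decay_dir <- function(cfg) file.path(cfg$outdir, "decays")
cd_dir <- function(cfg) file.path(cfg$outdir, "cd")
fit_dir <- function(cfg) file.path(cfg$outdir, "fits")

pipeline_irf <- function(cfg) {
  grid <- make_time_grid(cfg$channels, cfg$window_ns)
  make_irf(irf_spec(cfg$irf$fwhm_ps, cfg$irf$t0_ns), grid)
}

stage_simulate <- function(cfg, verbose) {
  dir.create(decay_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  dir.create(cd_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  irf <- pipeline_irf(cfg)
  write_decay_file(irf, file.path(decay_dir(cfg), "irf.tsv"))
  artifacts <- character(0)
  conc_2ap <- cfg$dna_conc_M * cfg$residues_2ap
  for (cond in cfg$conditions) {
    comp <- get_preset(cond$preset)
    set <- simulate_global_set(comp, irf, cfg$wavelengths,
                               peak_counts = cfg$peak_counts,
                               background = cfg$background,
                               seed = substream_seed(cfg$seed, cond$name))
    for (j in seq_along(set)) {
      set[[j]]$metadata$condition <- cond$name
      set[[j]]$metadata$preset <- cond$preset
      f <- file.path(decay_dir(cfg),
                     sprintf("%s_%gnm.tsv", cond$name, cfg$wavelengths[j]))
      write_decay_file(set[[j]], f)
      artifacts <- c(artifacts, f)
    }
    # CD: n_scans noisy sample scans + matched blanks (baseline only),
    # emitted in raw mdeg as an instrument would
    spec <- cd_couplet_spec(unpaired_fraction = cond$unpaired_fraction,
                            noise_sd = cfg$cd$noise_sd,
                            baseline_coeffs = cfg$cd$baseline_coeffs)
    blank_spec <- cd_couplet_spec(unpaired_fraction = 1,
                                  noise_sd = cfg$cd$noise_sd,
                                  baseline_coeffs = cfg$cd$baseline_coeffs)
    for (s in seq_len(cfg$cd$n_scans)) {
      samp <- simulate_cd_spectrum(
        spec, seed = substream_seed(cfg$seed, paste0("cd_", cond$name, "_", s)),
        metadata = list(condition = cond$name, scan = s))
      blank <- simulate_cd_spectrum(
        blank_spec,
        seed = substream_seed(cfg$seed, paste0("cdblank_", cond$name, "_", s)),
        metadata = list(condition = cond$name, scan = s))
      fs <- file.path(cd_dir(cfg), sprintf("%s_scan%d.tsv", cond$name, s))
      fb <- file.path(cd_dir(cfg), sprintf("%s_blank%d.tsv", cond$name, s))
      write_cd_file(to_millidegrees(samp, conc_2ap, cfg$pathlength_cm), fs)
      write_cd_file(to_millidegrees(blank, conc_2ap, cfg$pathlength_cm), fb)
      artifacts <- c(artifacts, fs, fb)
    }
    pipeline_log(verbose, "simulate",
                 "condition %s (preset %s): %d decays, %d CD scans",
                 cond$name, cond$preset, length(set), cfg$cd$n_scans)
  }
  artifacts
}

stage_fit <- function(cfg, verbose) {
  irf_path <- file.path(decay_dir(cfg), "irf.tsv")
  if (!file.exists(irf_path))
    abort_config("fit stage: no IRF found; run 'simulate' first or supply decays/irf.tsv")
  irf <- read_decay_file(irf_path)
  dir.create(fit_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  fits <- list()
  artifacts <- character(0)
  for (cond in cfg$conditions) {
    files <- file.path(decay_dir(cfg),
                       sprintf("%s_%gnm.tsv", cond$name, cfg$wavelengths))
    missing <- !file.exists(files)
    if (any(missing))
      abort_config(sprintf("fit stage: missing decay file(s): %s",
                           paste(files[missing], collapse = ", ")))
    curves <- lapply(files, read_decay_file)
    fit <- fit_global(curves, irf, cfg$n_components)
    if (!fit$converged)
      abort_fit(sprintf("global fit did not converge for condition '%s'",
                        cond$name))
    unc <- NULL
    if (cfg$n_boot > 0)
      unc <- estimate_uncertainties(fit, curves, irf, n_boot = cfg$n_boot,
                                    seed = substream_seed(cfg$seed,
                                                          paste0("boot_", cond$name)))
    A <- a_factors(fit)
    As <- a_factors(fit, per_sample = TRUE)
    tab <- data.frame(component = seq_len(fit$model$n_components),
                      tau_ns = fit$model$lifetimes)
    for (j in seq_along(cfg$wavelengths))
      tab[[sprintf("A_%gnm", cfg$wavelengths[j])]] <- A[, j]
    tab$A_sample <- As
    if (!is.null(unc)) {
      tab$tau_rel_sd <- unc$tau_rel_sd
      tab$A_rel_sd <- unc$afactor_rel_sd
    }
    f <- file.path(fit_dir(cfg), sprintf("%s_fit.tsv", cond$name))
    write_tsv_table(tab, f)
    diag <- data.frame(wavelength_nm = cfg$wavelengths,
                       chisq_reduced = fit$chisq_reduced$per_curve,
                       runs_test_p = fit$residual_randomness)
    fd <- file.path(fit_dir(cfg), sprintf("%s_diagnostics.tsv", cond$name))
    write_tsv_table(diag, fd)
    pipeline_log(verbose, "fit", "%s: chi2_r = %.4g (%d iterations)",
                 cond$name, fit$chisq_reduced$global, fit$n_iterations)
    fits[[cond$name]] <- fit
    artifacts <- c(artifacts, f, fd)
  }
  list(fits = fits, artifacts = artifacts)
}

stage_cd <- function(cfg, verbose) {
  conc_2ap <- cfg$dna_conc_M * cfg$residues_2ap
  metrics <- list()
  for (cond in cfg$conditions) {
    sfiles <- file.path(cd_dir(cfg),
                        sprintf("%s_scan%d.tsv", cond$name,
                                seq_len(cfg$cd$n_scans)))
    bfiles <- file.path(cd_dir(cfg),
                        sprintf("%s_blank%d.tsv", cond$name,
                                seq_len(cfg$cd$n_scans)))
    missing <- !file.exists(c(sfiles, bfiles))
    if (any(missing))
      abort_config(sprintf("cd stage: missing CD scan files for '%s'",
                           cond$name))
    samp <- average_scans(lapply(sfiles, read_cd_file))
    blank <- average_scans(lapply(bfiles, read_cd_file))
    proc <- to_delta_epsilon(
      smooth_means_movement(baseline_subtract(samp, blank),
                            cfg$smoothing_width),
      conc_2ap, cfg$pathlength_cm)
    metrics[[cond$name]] <- exciton_metrics(proc)
  }
  mt <- data.frame(
    condition = names(metrics),
    amplitude_330 = vapply(metrics, `[[`, numeric(1), "amplitude_330"),
    band_mean_320_330 = vapply(metrics, `[[`, numeric(1), "band_mean_320_330"),
    peak_wavelength = vapply(metrics, `[[`, numeric(1), "peak_wavelength"))
  f1 <- file.path(cfg$outdir, "cd_metrics.tsv")
  write_tsv_table(mt, f1)
  ref <- metrics[[cfg$reference]]
  others <- setdiff(names(metrics), cfg$reference)
  ch <- data.frame(
    condition = others,
    reference = rep(cfg$reference, length(others)),
    signal_change_pct = vapply(others, function(nm)
      percent_signal_change(metrics[[nm]], ref), numeric(1)),
    band_mean_change_pct = vapply(others, function(nm)
      percent_signal_change(metrics[[nm]], ref, "band_mean_320_330"),
      numeric(1)))
  f2 <- file.path(cfg$outdir, "cd_changes.tsv")
  write_tsv_table(ch, f2)
  pipeline_log(verbose, "cd", "metrics for %d condition(s) written",
               length(metrics))
  list(metrics = metrics, artifacts = c(f1, f2))
}

stage_report <- function(cfg, fits, verbose) {
  irf <- pipeline_irf(cfg)
  ref_fit <- fits[[cfg$reference]]
  rows <- list()
  report_lines <- character(0)
  # noiseless reference states for the two-state mixture estimate
  ds_comp <- get_preset(cfg$mixture_refs$ds)
  ss_comp <- get_preset(cfg$mixture_refs$ss)
  ds_ref <- fit_global(
    decay_curve(irf$times,
                decay_expectation(ds_comp, irf, cfg$peak_counts)),
    irf, length(ds_comp$lifetimes), fit_shift = FALSE)
  ss_ref <- fit_global(
    decay_curve(irf$times,
                decay_expectation(ss_comp, irf, cfg$peak_counts)),
    irf, length(ss_comp$lifetimes), fit_shift = FALSE)
  artifacts <- character(0)
  for (cond in cfg$conditions) {
    fit <- fits[[cond$name]]
    st <- classify_components(fit)
    files <- file.path(decay_dir(cfg),
                       sprintf("%s_%gnm.tsv", cond$name, cfg$wavelengths))
    curves <- lapply(files, read_decay_file)
    mix <- estimate_mixture_fraction(curves, ds_ref, ss_ref, irf)
    rows[[cond$name]] <- data.frame(
      condition = cond$name,
      stacked = st$populations[["stacked"]],
      partially_stacked_fast = st$populations[["partially_stacked_fast"]],
      partially_stacked_slow = st$populations[["partially_stacked_slow"]],
      extrahelical = st$populations[["extrahelical"]],
      unpaired_mixture_fraction = mix$fraction,
      mixture_residual = mix$residual_distance)
    report_lines <- c(report_lines,
      sprintf("condition %s (preset %s):", cond$name, cond$preset),
      sprintf("  lifetimes (ns): %s",
              paste(sprintf("%.4g", st$lifetimes), collapse = ", ")),
      sprintf("  A factors:      %s",
              paste(sprintf("%.3f", st$afactors), collapse = ", ")),
      sprintf("  classes:        %s",
              paste(st$component_class, collapse = ", ")),
      sprintf("  unpaired mixture fraction: %.3f (residual %.4f)",
              mix$fraction, mix$residual_distance))
    if (cond$name != cfg$reference) {
      pc <- percent_param_change(fit, ref_fit)
      fpc <- file.path(cfg$outdir,
                       sprintf("param_change_%s_vs_%s.tsv",
                               cond$name, cfg$reference))
      write_tsv_table(pc, fpc)
      artifacts <- c(artifacts, fpc)
      report_lines <- c(report_lines,
        sprintf("  vs %s: delta-tau%% = %s; delta-A%% = %s",
                cfg$reference,
                paste(sprintf("%+.1f", pc$delta_tau_pct), collapse = ", "),
                paste(sprintf("%+.1f", pc$delta_a_pct), collapse = ", ")))
    }
  }
  tab <- do.call(rbind, rows)
  f1 <- file.path(cfg$outdir, "state_report.tsv")
  write_tsv_table(tab, f1)
  f2 <- file.path(cfg$outdir, "state_report.txt")
  writeLines(report_lines, f2)
  pipeline_log(verbose, "report", "state report for %d condition(s) written",
               nrow(tab))
  c(artifacts, f1, f2)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages on a [run_config()]: `simulate` writes
#' decay and CD files, `fit` globally fits each condition's decays,
#' `cd` processes the CD scans to exciton metrics and percent changes,
#' `report` produces conformational populations, parameter-change tables
#' and mixture fractions, and `all` chains every stage.  A repeated run
#' with the same config and seed reproduces every numeric output
#' byte-identically.
#'
#' @param config a [run_config()] (or path to a JSON config).
#' @param mode one of `"simulate"`, `"fit"`, `"cd"`, `"report"`, `"all"`.
#' @param verbose print per-stage log lines.
#' @return invisibly, a manifest: list of written artifact paths by
#'   stage.  A manifest TSV is also written to the output directory.
#' @export
run_pipeline <- function(config, mode = c("all", "simulate", "fit", "cd",
                                          "report"),
                         verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "run_config"))
    abort_config("config must be a run_config or a path to one")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  if (mode %in% c("simulate", "all"))
    manifest$simulate <- stage_simulate(config, verbose)
  fits <- NULL
  if (mode %in% c("fit", "report", "all")) {
    fr <- stage_fit(config, verbose)
    fits <- fr$fits
    manifest$fit <- fr$artifacts
  }
  if (mode %in% c("cd", "all"))
    manifest$cd <- stage_cd(config, verbose)$artifacts
  if (mode %in% c("report", "all"))
    manifest$report <- stage_report(config, fits, verbose)
  rel <- function(p) sub(paste0("^", config$outdir, "/?"), "", p)
  mf <- data.frame(
    stage = rep(names(manifest), lengths(manifest)),
    artifact = rel(unlist(manifest, use.names = FALSE)))
  write_tsv_table(mf, file.path(config$outdir, "manifest.tsv"))
  invisible(manifest)
}
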