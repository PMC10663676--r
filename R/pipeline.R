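# Orchestration: simulate -> quantify (CGE) -> model (assembly, CDMS) ->
# density/vbar/banding -> assays -> report.

#' Construct a pipeline run configuration
#'
#' @param scenarios Character vector of default scenario names (subset of
#'   `names(default_scenarios())`) or a named list of [scenario_spec()]s.
#'   Must be non-empty.
#' @param outdir Output directory for simulated inputs and reports; `NULL`
#'   keeps everything in memory.
#' @param seed Integer seed; every stochastic stage derives its seed from it.
#' @param n_ions CDMS ions per scenario.
#' @param cal_distortion CDMS m/z distortion to inject and recalibrate.
#' @param mois Potency MOI levels.
#' @param correlation_moi MOI at which the stoichiometry-potency
#'   correlation is computed.
#' @param rpm_first,rpm_second The two ultracentrifugation speeds compared.
#' @param bulk_label Reference scenario for potency normalization.
#' @return Object of class `run_config`.
#' @export
pipeline_config <- function(scenarios = names(default_scenarios()),
                            outdir = NULL, seed = 1, n_ions = 3000,
                            cal_distortion = 1.0,
                            mois = c(1e2, 5e2, 1e3, 2.5e3, 5e3),
                            correlation_moi = 1e2,
                            rpm_first = 34000, rpm_second = 24000,
                            bulk_label = "bulk_wt") {
  if (length(scenarios) == 0) {
    stop("`scenarios` must not be empty", call. = FALSE)
  }
  if (is.character(scenarios)) {
    all_specs <- default_scenarios()
    unknown <- setdiff(scenarios, names(all_specs))
    if (length(unknown) > 0) {
      stop("unknown scenario name(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    scenarios <- all_specs[scenarios]
  }
  stopifnot(is.list(scenarios),
            all(vapply(scenarios, inherits, logical(1), "scenario_spec")))
  names(scenarios) <- vapply(scenarios, `[[`, character(1), "name")
  structure(list(scenarios = scenarios, outdir = outdir,
                 seed = as.integer(seed), n_ions = n_ions,
                 cal_distortion = cal_distortion, mois = mois,
                 correlation_moi = correlation_moi,
                 rpm_first = rpm_first, rpm_second = rpm_second,
                 bulk_label = bulk_label),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' For every configured scenario: simulates the instrument data, quantifies
#' VP stoichiometry from the CGE trace, recalibrates and histograms the
#' CDMS events (mode mass, FWHM, percent/ppm gap to the stoichiometry-based
#' theoretical mass), converts measured densities to vbar and predicts band
#' position/width at both rotor speeds, extracts Tm, and — across scenarios
#' — normalizes potency to the bulk reference and correlates the
#' stoichiometry metrics with relative potency.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A `pipeline_report` list; when `config$outdir` is set, simulated
#'   inputs, `report.json` and `report.txt` are written beneath it.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  say("pipeline: seed %d, %d scenario(s): %s", config$seed,
      length(config$scenarios), paste(names(config$scenarios),
                                      collapse = ", "))
  mig <- cge_migration_defaults()
  model_ref <- gradient_model(config$rpm_first)
  per_scenario <- list()
  metric_rows <- list()
  for (spec in config$scenarios) {
    sseed <- (config$seed * 131L + match(spec$name,
                                         names(config$scenarios))) %%
      .Machine$integer.max
    if (!is.null(config$outdir)) {
      simulate_scenario(spec, file.path(config$outdir, spec$name),
                        seed = sseed, n_ions = config$n_ions,
                        cal_distortion = config$cal_distortion)
    }
    say("  [%s] CGE quantification", spec$name)
    prot <- make_cge_trace(spec, "protein", seed = sseed * 7L + 1L)
    corr <- baseline_correct(prot)
    peaks <- detect_and_integrate(corr, windows = mig$windows)
    areas <- peak_areas(peaks)
    eps <- attr(prot, "truth")$epsilons
    stoich <- stoichiometry_from_areas(areas, eps[names(areas)])

    say("  [%s] CDMS histogram", spec$name)
    cdms <- make_cdms_events(spec, n_ions = config$n_ions,
                             seed = sseed * 7L + 3L,
                             cal_distortion = config$cal_distortion)
    cal <- calibration_factor(cdms$gdh$observed_mz, cdms$gdh$theoretical_mz)
    masses <- ion_mass(cdms$events$mz, cdms$events$charge, cal)
    masses <- filter_mass_window(masses, 3e6, 5e6, cap = config$n_ions)
    hist <- mass_histogram(masses)
    theo_mass <- scenario_mass_moments(spec)$mean
    say("  [%s] density / banding", spec$name)
    dens <- make_density_readouts(spec, seed = sseed * 7L + 4L)
    dens_mean <- stats::aggregate(buoyant_density ~ band, dens, mean)
    bands <- list()
    for (rpm in c(config$rpm_first, config$rpm_second)) {
      gm <- gradient_model(rpm, model_ref$r_top, model_ref$r_bottom,
                           model_ref$loading_density,
                           model_ref$temperature, model_ref$beta0)
      profile <- suppressWarnings(equilibrium_gradient(gm))
      for (bi in seq_len(nrow(dens_mean))) {
        pos <- band_position(profile, dens_mean$buoyant_density[bi])
        sig <- if (pos$in_column) {
          band_width(gm, pos$r_band, theo_mass,
                     vbar_from_density(dens_mean$buoyant_density[bi]))
        } else NA_real_
        bands[[length(bands) + 1]] <- data.frame(
          rpm = rpm, band = dens_mean$band[bi],
          buoyant_density = dens_mean$buoyant_density[bi],
          r_band = pos$r_band, sigma_r = sig, in_column = pos$in_column)
      }
    }
    therm <- make_thermal_scan(spec, seed = sseed * 7L + 5L)
    ratios <- stoich$ratios
    vp3t <- sum(ratios[intersect(c("VP3", "VP3clip"), names(ratios))])
    metric_rows[[spec$name]] <- data.frame(
      sample = spec$name,
      vp1_only = ratios[["VP1"]] / (ratios[["VP2"]] + vp3t),
      vp2_only = ratios[["VP2"]] / (ratios[["VP1"]] + vp3t),
      vp12_combined = stoich$vp12_over_vp3total)
    per_scenario[[spec$name]] <- list(
      name = spec$name,
      stoichiometry = list(
        ratios = as.list(round_away(ratios, 1)),
        vp12_over_vp3total = round_away(stoich$vp12_over_vp3total, 2),
        vp12_over_vp3total_full = stoich$vp12_over_vp3total),
      mass = list(
        theoretical_mda = signif(theo_mass / 1e6, 3),
        cdms_mode_mda = signif(hist$mode_mass / 1e6, 3),
        fwhm_mda = round(hist$fwhm / 1e6, 3),
        gap_percent = 100 * (hist$mode_mass - theo_mass) / theo_mass,
        gap_ppm = mass_ppm_error(hist$mode_mass, theo_mass),
        n_ions = hist$n_ions),
      density = list(
        bands = dens_mean$buoyant_density,
        vbar_isopycnic = round_away(
          vbar_from_density(dens_mean$buoyant_density), 4),
        vbar_composition_water = round_away(
          sum(vapply(spec$components, function(cm)
            cm$weight * composition_vbar(cm$ensemble), numeric(1))), 4)),
      banding = do.call(rbind, bands),
      tm_c = round(tm_from_bcm(therm), 1))
  }
  say("  potency normalization and correlation")
  pot <- make_potency_table(config$scenarios, mois = config$mois,
                            seed = config$seed * 977L)
  rel <- relative_potency(pot, bulk_label = config$bulk_label)
  metrics <- do.call(rbind, metric_rows)
  pot_at <- rel[rel$moi == config$correlation_moi, ]
  correlation <- if (nrow(metrics) >= 3) {
    stoich_potency_correlation(metrics, pot_at)
  } else {
    data.frame(metric = character(0), r = numeric(0),
               intercept = numeric(0), slope = numeric(0),
               degenerate = logical(0))
  }
  resolution <- list(
    rpm = c(config$rpm_first, config$rpm_second),
    comparison = lapply(c(config$rpm_first, config$rpm_second), function(r)
      two_speed_comparison(model_ref, r, 1.352, 1.361,
                           particle_mass = 4.6e6)))
  report <- structure(list(
    seed = config$seed,
    version = as.character(utils::packageVersion("vpstoich")),
    scenarios = per_scenario,
    relative_potency = rel,
    correlation = correlation,
    two_speed = resolution), class = "pipeline_report")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      report_to_json(report), file.path(config$outdir, "report.json"),
      auto_unbox = TRUE, digits = NA)
    writeLines(format_report(report), file.path(config$outdir, "report.txt"))
    utils::write.csv(pot, file.path(config$outdir, "potency_records.csv"),
                     row.names = FALSE)
  }
  report
}

# plain-list view of the report for stable JSON serialization
report_to_json <- function(report) {
  list(seed = report$seed, version = report$version,
       scenarios = lapply(report$scenarios, function(s) {
         s$banding <- lapply(seq_len(nrow(s$banding)), function(i)
           as.list(s$banding[i, ]))
         s
       }),
       relative_potency = lapply(seq_len(nrow(report$relative_potency)),
         function(i) as.list(report$relative_potency[i, ])),
       correlation = lapply(seq_len(nrow(report$correlation)),
         function(i) as.list(report$correlation[i, ])),
       two_speed = report$two_speed)
}

format_report <- function(report) {
  out <- c(sprintf("vpstoich pipeline report (seed %d, version %s)",
                   report$seed, report$version), "")
  for (s in report$scenarios) {
    out <- c(out, sprintf("== %s ==", s$name),
      sprintf("  (VP1+VP2)/VP3_total = %.2f",
              s$stoichiometry$vp12_over_vp3total),
      sprintf("  mass: theoretical %.3g MDa, CDMS mode %.3g MDa (gap %.2f%%), FWHM %.3f MDa",
              s$mass$theoretical_mda, s$mass$cdms_mode_mda,
              s$mass$gap_percent, s$mass$fwhm_mda),
      sprintf("  density band(s): %s g/cm3; isopycnic vbar: %s cm3/g; water vbar (composition): %.4f",
              paste(sprintf("%.3f", s$density$bands), collapse = ", "),
              paste(sprintf("%.4f", s$density$vbar_isopycnic), collapse = ", "),
              s$density$vbar_composition_water),
      sprintf("  Tm = %.1f C", s$tm_c), "")
  }
  r <- report$correlation
  if (nrow(r) > 0) {
    out <- c(out, "== stoichiometry-potency correlation ==",
             vapply(seq_len(nrow(r)), function(i)
               sprintf("  %-14s r = %.3f", r$metric[i], r$r[i]),
               character(1)))
  }
  cmp <- report$two_speed$comparison
  out <- c(out, "", "== two-speed banding comparison (F1.1 vs F2.2 densities) ==",
    vapply(seq_along(cmp), function(i)
      sprintf("  %d rpm: delta_r = %.3f cm, sigma_r = %.4f cm, resolution = %.2f",
              report$two_speed$rpm[i], cmp[[i]]$delta_r, cmp[[i]]$sigma_r,
              cmp[[i]]$resolution), character(1)))
  out
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
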