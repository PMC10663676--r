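# Seeded synthetic-data generators. The five default scenarios encode the
# stated characteristics of bulk wild-type rAAV2, the two-cycle CsCl
# fractions (low-density F1.1-like, high-density F2.2-like) and the two
# translation-start variants (M203V-like, M211V-like): molar VP ratios,
# buoyant densities, mass-histogram widths, per-MOI potency effects and
# melting temperatures. Every generator returns its ground truth alongside
# the simulated data so recovery tests are self-contained.

VP_OFFSETS <- c(VP1 = 0L, VP2 = 137L, VP3 = 202L, VP3clip = 210L)

#' Deterministic synthetic VP sequences
#'
#' Generates a SYNTHETIC stand-in for the rAAV2 capsid protein isoforms
#' (no real cap sequence is bundled): a 735-residue VP1 with AAV-like
#' residue composition, from which VP2 (598 aa), VP3 (533 aa) and VP3clip
#' (525 aa, eight residues shorter than VP3) are derived as N-terminally
#' truncated forms sharing the C-terminal common region, exactly as the
#' real isoforms do. The sequences are fixed (internal seed) and do not
#' depend on the caller's RNG.
#'
#' @return Named character vector `VP1, VP2, VP3, VP3clip`.
#' @export
make_vp_sequences <- function() {
  # composition roughly matching globular viral structural proteins
  aa <- names(.residue_avg_mass)
  w <- c(G = 8.0, A = 7.5, S = 7.0, P = 5.5, V = 6.5, T = 6.5, C = 1.0,
         L = 8.0, I = 4.5, N = 5.5, D = 5.5, Q = 4.5, K = 5.0, E = 5.5,
         M = 1.5, H = 2.0, F = 4.0, R = 4.5, Y = 3.5, W = 1.5)
  vp1 <- with_seed(20230101L, {
    s <- sample(aa, 735, replace = TRUE, prob = w[aa])
    s[1] <- "M"
    # methionines at the internal translation starts, as in the real cap ORF
    s[VP_OFFSETS["VP2"] + 1] <- "T"   # VP2 starts at a non-canonical ACG (Thr)
    s[VP_OFFSETS["VP3"] + 1] <- "M"
    s[VP_OFFSETS["VP3clip"] + 1] <- "M"
    paste(s, collapse = "")
  })
  c(VP1 = vp1,
    VP2 = substring(vp1, VP_OFFSETS["VP2"] + 1),
    VP3 = substring(vp1, VP_OFFSETS["VP3"] + 1),
    VP3clip = substring(vp1, VP_OFFSETS["VP3clip"] + 1))
}

#' Write VP sequences as a FASTA file
#'
#' @param sequences Named character vector (default [make_vp_sequences()]).
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_vp_fasta <- function(sequences = make_vp_sequences(), path,
                           width = 60) {
  lines <- unlist(lapply(names(sequences), function(nm) {
    s <- sequences[[nm]]
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", nm, " synthetic rAAV2-like capsid protein"),
      substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Shared CGE migration configuration
#'
#' Peak positions (minutes), Gaussian peak width and per-species assignment
#' windows used by both the trace generator and the default analysis.
#' Migration order VP3clip < VP3 < VP2 < VP1; absolute times are
#' instrument-specific and configurable.
#'
#' @return List `positions`, `sigma`, `windows`.
#' @export
cge_migration_defaults <- function() {
  list(positions = c(VP3clip = 19.8, VP3 = 20.6, VP2 = 24.0, VP1 = 26.5),
       sigma = 0.08,
       windows = list(VP3clip = c(19.4, 20.19), VP3 = c(20.2, 21.3),
                      VP2 = c(23.4, 24.6), VP1 = c(25.9, 27.1)))
}

#' Construct a scenario specification
#'
#' A scenario bundles the capsid ensemble(s) it contains (a mixture for the
#' bulk state), its buoyant density band(s), per-MOI potency multipliers
#' versus the bulk reference, a melting temperature, and per-channel noise
#' parameters.
#'
#' @param name Scenario label.
#' @param components List of `list(ensemble = capsid_ensemble, weight = w)`.
#' @param buoyant_density One density per band, g/cm^3.
#' @param potency_effects data.frame `moi, multiplier`; effects between the
#'   listed MOIs are interpolated linearly in log(MOI) and held flat
#'   outside.
#' @param tm Melting temperature, deg C.
#' @param genome_nt Genome length, nucleotides (mass uses 309 Da/nt).
#' @param noise List of per-channel noise parameters: `cge_frac` (Gaussian
#'   trace noise as fraction of max peak height), `mass_sd` (CDMS
#'   instrument mass SD, Da, added to the compositional spread),
#'   `density_sd` (g/cm^3), `potency_cv` (per-well CV), `bcm_sd` (nm).
#' @param charge_model List `a, exponent, cv, low_fraction, low_scale` for
#'   the CDMS charge generator `z = a * mass^exponent * (1 + noise)`.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, components, buoyant_density,
                          potency_effects, tm, genome_nt = 2900,
                          noise = list(), charge_model = list()) {
  stopifnot(is.list(components), length(components) >= 1)
  w <- vapply(components, `[[`, numeric(1), "weight")
  stopifnot(all(w > 0))
  for (cm in components) stopifnot(inherits(cm$ensemble, "capsid_ensemble"))
  total_w <- sum(w)
  components <- lapply(components, function(cm) {
    cm$weight <- cm$weight / total_w
    cm
  })
  noise_defaults <- list(cge_frac = 0.002, mass_sd = 0, density_sd = 0.001,
                         potency_cv = 0.05, bcm_sd = 0.05)
  noise <- utils::modifyList(noise_defaults, noise)
  charge_defaults <- list(a = 0.00552, exponent = 2 / 3, cv = 0.03,
                          low_fraction = 0.1, low_scale = 0.6)
  charge_model <- utils::modifyList(charge_defaults, charge_model)
  stopifnot(is.data.frame(potency_effects),
            all(c("moi", "multiplier") %in% names(potency_effects)))
  structure(list(name = name, components = components,
                 buoyant_density = buoyant_density,
                 potency_effects = potency_effects, tm = tm,
                 genome_nt = genome_nt, noise = noise,
                 charge_model = charge_model),
            class = "scenario_spec")
}

#' Mass moments of a scenario's particle population
#'
#' Mixture moments over the scenario's components: each component
#' contributes its multinomial compositional mean/variance
#' ([assembly_mass_moments()]); between-component mean differences add
#' mixture variance. Instrument noise is not included.
#'
#' @param spec A [scenario_spec()].
#' @return List `mean`, `sd`, `fwhm` (Da).
#' @export
scenario_mass_moments <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  w <- vapply(spec$components, `[[`, numeric(1), "weight")
  mom <- lapply(spec$components, function(cm) assembly_mass_moments(cm$ensemble))
  means <- vapply(mom, `[[`, numeric(1), "mean")
  vars <- vapply(mom, `[[`, numeric(1), "sd")^2
  m <- sum(w * means)
  v <- sum(w * (vars + means^2)) - m^2
  list(mean = m, sd = sqrt(v), fwhm = .fwhm_factor * sqrt(v))
}

# per-MOI potency multiplier, log-MOI linear interpolation, flat outside
effect_at <- function(spec, moi) {
  tab <- spec$potency_effects
  if (nrow(tab) == 1) return(rep(tab$multiplier, length(moi)))
  stats::approx(log(tab$moi), tab$multiplier, xout = log(moi),
                rule = 2)$y
}

#' Default scenario set
#'
#' The five stated ensembles. Molar VP1:VP2:VP3:VP3clip ratios — F1.1-like
#' 1.0:1.3:6.9:0.4, F2.2-like 1.0:1.4:8.6:0.4, M203V-like 1.0:1.4:2.0:4.9
#' (clip-dominant, (VP1+VP2)/VP3_total = 0.35), M211V-like 1.0:1.4:7.5:0
#' (no clip, 0.32); bulk WT is a 50:50 mixture of the F1.1/F2.2 ensembles.
#' Densities 1.352 / 1.361 (bulk: both bands) / 1.359 / 1.359 g/cm^3;
#' melting temperatures 67.1 / 68.2 / 67.7 deg C; per-MOI potency effects
#' at the stated endpoints (+8.9% at MOI 5e2; -17.8% at 1e3; +24.7% at 1e2
#' and +21.9% at 5e2; +11.9% at 1e3 and +8.2% at 2.5e3). Each scenario's
#' CDMS instrument mass noise defaults to the value that makes the total
#' mass-histogram width match the stated FWHM (0.18 / 0.13 / 0.16 MDa;
#' fraction scenarios reuse the bulk instrument noise since their FWHMs are
#' not stated) given the multinomial compositional spread.
#'
#' @param genome_nt Genome length in nucleotides.
#' @return Named list of [scenario_spec()]s:
#'   `bulk_wt, f1_1, f2_2, m203v, m211v`.
#' @export
default_scenarios <- function(genome_nt = 2900) {
  seqs <- make_vp_sequences()
  species <- lapply(names(seqs), function(nm) vp_species(nm, seqs[[nm]]))
  names(species) <- names(seqs)
  genome_mass <- genome_nt * .dna_residue_mass
  ens <- function(ratios) {
    capsid_ensemble(species[names(ratios)], ratios / sum(ratios), genome_mass)
  }
  e_f11 <- ens(c(VP1 = 1, VP2 = 1.3, VP3 = 6.9, VP3clip = 0.4))
  e_f22 <- ens(c(VP1 = 1, VP2 = 1.4, VP3 = 8.6, VP3clip = 0.4))
  e_m203v <- ens(c(VP1 = 1, VP2 = 1.4, VP3 = 2.0, VP3clip = 4.9))
  e_m211v <- ens(c(VP1 = 1, VP2 = 1.4, VP3 = 7.5, VP3clip = 0))

  one <- function(e) list(list(ensemble = e, weight = 1))
  eff <- function(moi, mult) data.frame(moi = moi, multiplier = mult)

  # instrument mass noise calibrated to the stated FWHMs
  inst_sd <- function(components, fwhm_target) {
    v_comp <- scenario_mass_moments(
      structure(list(components = components), class = "scenario_spec"))$sd^2
    sqrt(max(0, (fwhm_target / .fwhm_factor)^2 - v_comp))
  }
  comp_bulk <- list(list(ensemble = e_f11, weight = 0.5),
                    list(ensemble = e_f22, weight = 0.5))
  sd_bulk <- inst_sd(comp_bulk, 0.18e6)
  sd_m203v <- inst_sd(one(e_m203v), 0.13e6)
  sd_m211v <- inst_sd(one(e_m211v), 0.16e6)

  list(
    bulk_wt = scenario_spec("bulk_wt", comp_bulk,
                            buoyant_density = c(1.352, 1.361),
                            potency_effects = eff(1e3, 1.0), tm = 67.1,
                            genome_nt = genome_nt,
                            noise = list(mass_sd = sd_bulk)),
    f1_1 = scenario_spec("f1_1", one(e_f11), buoyant_density = 1.352,
                         potency_effects = eff(5e2, 1.089), tm = 67.1,
                         genome_nt = genome_nt,
                         noise = list(mass_sd = sd_bulk)),
    f2_2 = scenario_spec("f2_2", one(e_f22), buoyant_density = 1.361,
                         potency_effects = eff(1e3, 0.822), tm = 67.1,
                         genome_nt = genome_nt,
                         noise = list(mass_sd = sd_bulk)),
    m203v = scenario_spec("m203v", one(e_m203v), buoyant_density = 1.359,
                          potency_effects = eff(c(1e2, 5e2), c(1.247, 1.219)),
                          tm = 68.2, genome_nt = genome_nt,
                          noise = list(mass_sd = sd_m203v)),
    m211v = scenario_spec("m211v", one(e_m211v), buoyant_density = 1.359,
                          potency_effects = eff(c(1e3, 2.5e3), c(1.119, 1.082)),
                          tm = 67.7, genome_nt = genome_nt,
                          noise = list(mass_sd = sd_m211v))
  )
}

# aggregate molar amounts per species over mixture components
scenario_molar_amounts <- function(spec) {
  out <- NULL
  for (cm in spec$components) {
    n <- stats::setNames(cm$weight * cm$ensemble$fractions,
                         species_names(cm$ensemble))
    if (is.null(out)) out <- n else {
      for (nm in names(n)) {
        out[nm] <- (if (nm %in% names(out)) out[nm] else 0) + n[nm]
      }
    }
  }
  out
}

scenario_species <- function(spec) spec$components[[1]]$ensemble$species

#' Simulate a CGE trace for a scenario
#'
#' Protein channel: one Gaussian peak per VP species at the configured
#' migration position with area proportional to `n_i * epsilon214_i`, on a
#' slowly drifting baseline with additive Gaussian noise. ssDNA channel: a
#' single genome peak whose position depends only on genome length, so
#' scenarios with the same genome share the apex.
#'
#' @param spec A [scenario_spec()].
#' @param channel `"protein"` or `"ssdna"`.
#' @param seed RNG seed.
#' @param noise_frac Noise SD as a fraction of the maximum peak height
#'   (default from the scenario; 0 gives a clean trace).
#' @param migration Migration configuration ([cge_migration_defaults()]).
#' @return An [electropherogram()] with attribute `truth` (injected areas,
#'   molar amounts, epsilons and the true `(VP1+VP2)/VP3_total`).
#' @export
make_cge_trace <- function(spec, channel = c("protein", "ssdna"),
                           seed = NULL, noise_frac = spec$noise$cge_frac,
                           migration = cge_migration_defaults()) {
  channel <- match.arg(channel)
  if (channel == "protein") {
    time <- seq(16, 30, by = 0.005)
    n <- scenario_molar_amounts(spec)
    eps <- vapply(scenario_species(spec), function(s) s$epsilon214,
                  numeric(1))
    names(eps) <- vapply(scenario_species(spec), function(s) s$name,
                         character(1))
    areas <- n * eps[names(n)]
    areas <- areas / max(areas)          # arbitrary absorbance units
    sig <- migration$sigma
    y <- numeric(length(time))
    for (nm in names(areas)) {
      y <- y + areas[nm] / (sig * sqrt(2 * pi)) *
        exp(-(time - migration$positions[nm])^2 / (2 * sig^2))
    }
    peak_max <- max(y)
    drift <- 0.02 * peak_max * (1 + (time - min(time)) / diff(range(time)))
    noise <- with_seed(seed,
      stats::rnorm(length(time), 0, noise_frac * peak_max))
    tr <- electropherogram(time, y + drift + noise, channel = "protein")
    vp12 <- sum(n[intersect(c("VP1", "VP2"), names(n))])
    vp3t <- sum(n[intersect(c("VP3", "VP3clip"), names(n))])
    attr(tr, "truth") <- list(areas = areas, molar_amounts = n,
                              epsilons = eps,
                              vp12_over_vp3total = vp12 / vp3t)
    tr
  } else {
    time <- seq(10, 20, by = 0.005)
    apex <- spec$genome_nt / 2900 * 14.5
    sig <- 0.15
    y <- 1 / (sig * sqrt(2 * pi)) * exp(-(time - apex)^2 / (2 * sig^2))
    noise <- with_seed(seed,
      stats::rnorm(length(time), 0, noise_frac * max(y)))
    tr <- electropherogram(time, y + noise, channel = "ssdna")
    attr(tr, "truth") <- list(apex = apex, genome_nt = spec$genome_nt)
    tr
  }
}

#' Simulate CDMS ion events for a scenario
#'
#' Per ion: a mixture component is chosen by weight, the 60-mer composition
#' is drawn from the component's multinomial, mass = subunits + genome +
#' Gaussian instrument noise, charge follows the compact-ion surface
#' scaling `z = a * mass^(2/3) * (1 + noise)` with an optional low-charge
#' subpopulation, and the observed m/z is distorted by a multiplicative
#' calibration error. A set of reference (GDH-like) calibrant peaks carrying
#' the same distortion is returned for recalibration.
#'
#' @param spec A [scenario_spec()].
#' @param n_ions Number of ions.
#' @param seed RNG seed.
#' @param cal_distortion Multiplicative m/z distortion (1 = perfectly
#'   calibrated instrument).
#' @param gdh_mass,gdh_charges Calibrant oligomer mass (Da) and charge
#'   states used for the reference peaks.
#' @return List `events` (data.frame `mz, charge`), `gdh` (data.frame
#'   `observed_mz, theoretical_mz`), `truth` (mean mass, compositional +
#'   instrument SD, low-charge fraction, distortion).
#' @export
make_cdms_events <- function(spec, n_ions = 3000, seed = NULL,
                             cal_distortion = 1.0,
                             gdh_mass = 336000, gdh_charges = 30:39) {
  stopifnot(inherits(spec, "scenario_spec"), n_ions >= 1)
  cmod <- spec$charge_model
  genome_mass <- spec$genome_nt * .dna_residue_mass
  with_seed(seed, {
    w <- vapply(spec$components, `[[`, numeric(1), "weight")
    comp_idx <- sample.int(length(w), n_ions, replace = TRUE, prob = w)
    mass <- numeric(n_ions)
    for (ci in seq_along(w)) {
      sel <- comp_idx == ci
      if (!any(sel)) next
      e <- spec$components[[ci]]$ensemble
      counts <- stats::rmultinom(sum(sel), e$n_subunits, e$fractions)
      mass[sel] <- as.numeric(crossprod(counts, species_masses(e))) +
        genome_mass
    }
    mass <- mass + stats::rnorm(n_ions, 0, spec$noise$mass_sd)
    charge <- cmod$a * mass^cmod$exponent *
      (1 + stats::rnorm(n_ions, 0, cmod$cv))
    low <- stats::runif(n_ions) < cmod$low_fraction
    charge[low] <- charge[low] * cmod$low_scale
    mz_true <- (mass + charge * .proton_mass) / charge
    events <- data.frame(mz = cal_distortion * mz_true, charge = charge)
    gdh_theory <- (gdh_mass + gdh_charges * .proton_mass) / gdh_charges
    gdh <- data.frame(observed_mz = cal_distortion * gdh_theory,
                      theoretical_mz = gdh_theory)
    mom <- scenario_mass_moments(spec)
    list(events = events, gdh = gdh,
         truth = list(mean_mass = mom$mean,
                      total_sd = sqrt(mom$sd^2 + spec$noise$mass_sd^2),
                      low_charge_fraction = cmod$low_fraction,
                      cal_distortion = cal_distortion))
  })
}

#' Simulate buoyant-density readouts
#'
#' One noisy density per band per replicate; a mixture scenario with two
#' bands (bulk WT) emits both densities.
#'
#' @param spec A [scenario_spec()].
#' @param n_replicates Replicates per band.
#' @param seed RNG seed.
#' @param sd Measurement SD, g/cm^3 (default from the scenario).
#' @return data.frame `sample, band, replicate, buoyant_density`.
#' @export
make_density_readouts <- function(spec, n_replicates = 3, seed = NULL,
                                  sd = spec$noise$density_sd) {
  grid <- expand.grid(band = seq_along(spec$buoyant_density),
                      replicate = seq_len(n_replicates))
  noise <- with_seed(seed, stats::rnorm(nrow(grid), 0, sd))
  data.frame(sample = spec$name, band = grid$band,
             replicate = grid$replicate,
             buoyant_density = spec$buoyant_density[grid$band] + noise)
}

#' Simulate a flow-cytometry potency table
#'
#' The bulk reference follows a saturating dose-response in MOI
#' (`Emax * moi / (K + moi)`); every other scenario's expectation is the
#' bulk value times its per-MOI effect multiplier. Per-well multiplicative
#' Gaussian noise (CV) is applied and values are clipped to `[0, 1]`.
#'
#' @param specs List of [scenario_spec()]s (must include the bulk
#'   reference).
#' @param mois MOI levels.
#' @param n_wells Replicate wells per sample x MOI.
#' @param seed RNG seed.
#' @param emax,k Bulk dose-response parameters.
#' @return data.frame `sample, moi, replicate, gfp_positive` with attribute
#'   `truth` (expected relative potency per sample x MOI).
#' @export
make_potency_table <- function(specs, mois = c(1e2, 5e2, 1e3, 2.5e3, 5e3),
                               n_wells = 3, seed = NULL,
                               emax = 0.9, k = 1e3) {
  bulk_mean <- emax * mois / (k + mois)
  rows <- list()
  truth <- list()
  for (spec in specs) {
    mult <- effect_at(spec, mois)
    truth[[spec$name]] <- data.frame(sample = spec$name, moi = mois,
                                     expected_relative = mult)
    for (j in seq_along(mois)) {
      rows[[length(rows) + 1]] <- data.frame(
        sample = spec$name, moi = mois[j], replicate = seq_len(n_wells),
        expectation = bulk_mean[j] * mult[j], cv = spec$noise$potency_cv)
    }
  }
  tab <- do.call(rbind, rows)
  noise <- with_seed(seed, stats::rnorm(nrow(tab), 0, tab$cv))
  tab$gfp_positive <- pmin(1, pmax(0, tab$expectation * (1 + noise)))
  tab$expectation <- NULL
  tab$cv <- NULL
  attr(tab, "truth") <- do.call(rbind, truth)
  tab
}

#' Simulate a DSF thermal scan
#'
#' Logistic barycentric-mean redshift from 330 to 345 nm centred at the
#' scenario's melting temperature, with Gaussian noise.
#'
#' @param spec A [scenario_spec()].
#' @param seed RNG seed.
#' @param temperatures Scan temperatures, deg C.
#' @param slope Transition width parameter, deg C.
#' @param noise_sd BCM noise, nm (default from the scenario).
#' @return data.frame `temperature, bcm` with attribute `truth` (the
#'   injected Tm).
#' @export
make_thermal_scan <- function(spec, seed = NULL,
                              temperatures = seq(40, 90, by = 0.5),
                              slope = 2, noise_sd = spec$noise$bcm_sd) {
  bcm <- 330 + 15 * stats::plogis((temperatures - spec$tm) / slope)
  noise <- with_seed(seed, stats::rnorm(length(temperatures), 0, noise_sd))
  out <- data.frame(temperature = temperatures, bcm = bcm + noise)
  attr(out, "truth") <- list(tm = spec$tm)
  out
}

#' Write all simulated inputs for a scenario to a directory
#'
#' Emits the plain-text files the analysis stages consume — VP FASTA, CGE
#' traces (protein and ssDNA), CDMS events and calibrant peaks, density
#' readouts, thermal scan — plus a `truth.json` sidecar with every
#' generator's ground truth. (The potency table spans scenarios and is
#' written by the pipeline, not per scenario.)
#'
#' @param spec A [scenario_spec()].
#' @param outdir Output directory (created if needed).
#' @param seed RNG seed; sub-seeds are derived per channel.
#' @param n_ions CDMS ion count.
#' @param cal_distortion CDMS m/z distortion.
#' @return Invisibly, the list of written file paths.
#' @export
simulate_scenario <- function(spec, outdir, seed = 1, n_ions = 3000,
                              cal_distortion = 1.0) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  seed <- as.integer(seed) %% 100000L
  prot <- make_cge_trace(spec, "protein", seed = seed * 7L + 1L)
  ssdna <- make_cge_trace(spec, "ssdna", seed = seed * 7L + 2L)
  cdms <- make_cdms_events(spec, n_ions = n_ions, seed = seed * 7L + 3L,
                           cal_distortion = cal_distortion)
  dens <- make_density_readouts(spec, seed = seed * 7L + 4L)
  therm <- make_thermal_scan(spec, seed = seed * 7L + 5L)
  write_vp_fasta(path = p("vp_synthetic.fasta"))
  utils::write.csv(data.frame(minutes = prot$time, signal = prot$signal),
                   p("cge_protein.csv"), row.names = FALSE)
  utils::write.csv(data.frame(minutes = ssdna$time, signal = ssdna$signal),
                   p("cge_ssdna.csv"), row.names = FALSE)
  utils::write.csv(cdms$events, p("cdms_events.csv"), row.names = FALSE)
  utils::write.csv(cdms$gdh, p("cdms_gdh_calibration.csv"),
                   row.names = FALSE)
  utils::write.csv(dens, p("densities.csv"), row.names = FALSE)
  utils::write.csv(therm, p("thermal_scan.csv"), row.names = FALSE)
  truth <- list(scenario = spec$name,
                cge = attr(prot, "truth"), ssdna = attr(ssdna, "truth"),
                cdms = cdms$truth,
                buoyant_density = spec$buoyant_density, tm = spec$tm)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(vapply(c("vp_synthetic.fasta", "cge_protein.csv",
                     "cge_ssdna.csv", "cdms_events.csv",
                     "cdms_gdh_calibration.csv", "densities.csv",
                     "thermal_scan.csv", "truth.json"), p, character(1)))
}
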