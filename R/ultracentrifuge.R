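# Isopycnic CsCl density-gradient physics: vbar <-> buoyant density,
# composition-based theoretical vbar, the equilibrium gradient of a spinning
# CsCl column, band position/width, the two-speed resolution comparison
# that rationalizes a slower second spin, and a Svedberg smooth-sphere
# s <-> M consistency check.

#' Partial specific volume at the isopycnic point
#'
#' At its banding position a particle's buoyant density equals the local
#' solution density, so the effective vbar is the reciprocal of the banding
#' density.
#'
#' @param rho Buoyant density, g/cm^3 (> 0); vectorized.
#' @return vbar in cm^3/g.
#' @examples
#' vbar_from_density(1.352)  # 0.7396
#' @export
vbar_from_density <- function(rho) {
  if (any(rho <= 0)) stop("density must be > 0", call. = FALSE)
  1 / rho
}

#' Theoretical particle vbar from VP composition
#'
#' Protein vbar is the mass-weighted average of residue partial specific
#' volumes (Cohn-Edsall style) over the ensemble's expected 60-mer
#' composition; the particle vbar combines protein and ssDNA contributions
#' weighted by mass.
#'
#' @param spec A [capsid_ensemble()] whose species carry sequences.
#' @param residue_vbar Named residue vbar table, cm^3/g
#'   (default [residue_partial_specific_volumes()]).
#' @param dna_vbar Partial specific volume of the packaged ssDNA, cm^3/g.
#' @return Particle vbar, cm^3/g (in water; no CsCl preferential-solvation
#'   correction).
#' @export
composition_vbar <- function(spec, residue_vbar = residue_partial_specific_volumes(),
                             dna_vbar = 0.55) {
  stopifnot(inherits(spec, "capsid_ensemble"))
  per_species <- lapply(spec$species, function(s) {
    if (is.null(s$sequence)) {
      stop(sprintf("species %s has no sequence; composition vbar needs one",
                   s$name), call. = FALSE)
    }
    res <- strsplit(toupper(s$sequence), "")[[1]]
    if (!all(res %in% names(residue_vbar))) {
      stop("residue without a vbar table entry in ", s$name, call. = FALSE)
    }
    w <- .residue_avg_mass[res]
    list(mass = s$monomer_mass, vbar = sum(w * residue_vbar[res]) / sum(w))
  })
  m <- vapply(per_species, `[[`, numeric(1), "mass")
  v <- vapply(per_species, `[[`, numeric(1), "vbar")
  p <- spec$fractions
  m_protein <- spec$n_subunits * sum(p * m)
  vbar_protein <- sum(p * m * v) / sum(p * m)
  (m_protein * vbar_protein + spec$genome_mass * dna_vbar) /
    (m_protein + spec$genome_mass)
}

#' Construct an equilibrium gradient model
#'
#' Rotor and solution parameters defining a CsCl equilibrium density
#' gradient. Defaults approximate a swinging-bucket run (SW41-class rotor,
#' sector-shaped geometry assumed for salt conservation) loaded with 2.5 M
#' CsCl.
#'
#' @param rpm Rotor speed, revolutions per minute.
#' @param r_top,r_bottom Column radial limits, cm (`r_top < r_bottom`).
#' @param loading_density Initial uniform solution density, g/cm^3.
#' @param temperature Kelvin.
#' @param beta0 CsCl gradient coefficient, cm^5/(g s^2); a single
#'   representative literature value is used by default.
#' @return Object of class `gradient_model` (adds `omega`, rad/s).
#' @export
gradient_model <- function(rpm, r_top = 6.74, r_bottom = 15.31,
                           loading_density = 1.33, temperature = 293.15,
                           beta0 = .cscl_beta0) {
  if (rpm < 0) stop("rpm must be >= 0", call. = FALSE)
  if (r_top >= r_bottom) stop("`r_top` must be < `r_bottom`", call. = FALSE)
  if (loading_density < 1.0 || loading_density > 1.9) {
    stop("loading density outside the CsCl solubility range", call. = FALSE)
  }
  structure(list(rpm = rpm, omega = rpm * 2 * pi / 60,
                 r_top = r_top, r_bottom = r_bottom,
                 loading_density = loading_density,
                 temperature = temperature, beta0 = beta0),
            class = "gradient_model")
}

# isoconcentration radius of a sector-shaped (weight ~ r) column
r_isoconcentration <- function(model) {
  sqrt((model$r_top^2 + model$r_bottom^2) / 2)
}

#' Equilibrium CsCl density profile
#'
#' At sedimentation-diffusion equilibrium the density obeys
#' `rho(r) = rho_iso + (omega^2 / beta0) * (r^2 - r_iso^2) / 2`, where the
#' isoconcentration radius `r_iso` is fixed by salt conservation: the
#' volume-weighted (sector-shaped, weight proportional to r) mean density
#' equals the loading density, giving `r_iso^2 = (r_top^2 + r_bottom^2)/2`.
#'
#' @param model A [gradient_model()].
#' @param n Number of radial sample points for the returned profile table.
#' @return Object of class `density_profile`: a list with the vectorized
#'   functions `rho(r)` and `drho_dr(r)`, `r_iso`, the source `model`, a
#'   `profile` data.frame (`r`, `rho`) and `subisodense` (TRUE when the
#'   gradient is so steep that rho < 1 g/cm^3 somewhere in the column).
#' @export
equilibrium_gradient <- function(model, n = 201) {
  stopifnot(inherits(model, "gradient_model"))
  r_iso <- r_isoconcentration(model)
  slope_coef <- model$omega^2 / model$beta0
  rho <- function(r) model$loading_density + slope_coef * (r^2 - r_iso^2) / 2
  drho_dr <- function(r) slope_coef * r
  r <- seq(model$r_top, model$r_bottom, length.out = n)
  prof <- data.frame(r = r, rho = rho(r))
  sub <- any(prof$rho < 1.0)
  if (sub) {
    warning("gradient steep enough that rho < 1 g/cm^3 within the column",
            call. = FALSE)
  }
  structure(list(rho = rho, drho_dr = drho_dr, r_iso = r_iso, model = model,
                 profile = prof, subisodense = sub),
            class = "density_profile")
}

#' Radial banding position of a particle
#'
#' Root-finds the radius where the local solution density equals the
#' particle's buoyant density. Outside the column the prediction is flagged
#' rather than an error.
#'
#' @param profile A `density_profile` from [equilibrium_gradient()].
#' @param particle_density Buoyant density, g/cm^3.
#' @param tol Root-finder tolerance on r, cm.
#' @return List `r_band` (cm, NA when out of column), `in_column` (logical).
#' @export
band_position <- function(profile, particle_density, tol = 1e-9) {
  stopifnot(inherits(profile, "density_profile"))
  m <- profile$model
  if (m$omega == 0) {
    # uniform column: the particle bands anywhere / nowhere; treat the
    # matching-density case as banding at the isoconcentration radius
    if (abs(particle_density - m$loading_density) < 1e-12) {
      return(list(r_band = profile$r_iso, in_column = TRUE))
    }
    return(list(r_band = NA_real_, in_column = FALSE))
  }
  f <- function(r) profile$rho(r) - particle_density
  if (f(m$r_top) > 0 || f(m$r_bottom) < 0) {
    return(list(r_band = NA_real_, in_column = FALSE))
  }
  root <- stats::uniroot(f, c(m$r_top, m$r_bottom), tol = tol)$root
  list(r_band = root, in_column = TRUE)
}

#' Equilibrium band width (Meselson-style)
#'
#' Gaussian band standard deviation
#' `sigma_r = sqrt(R T / (M vbar (drho/dr) omega^2 r_band))` with `M` the
#' particle molar mass — diffusion broadening balanced against the
#' restoring buoyant force in the local gradient.
#'
#' @param model A [gradient_model()] (omega > 0).
#' @param r_band Banding radius, cm.
#' @param particle_mass Particle mass, Da (g/mol).
#' @param vbar Particle partial specific volume, cm^3/g.
#' @return sigma_r in cm.
#' @export
band_width <- function(model, r_band, particle_mass, vbar) {
  stopifnot(inherits(model, "gradient_model"))
  if (model$omega == 0) {
    stop("no banding at omega = 0: gradient slope is zero", call. = FALSE)
  }
  stop_if_not_number(particle_mass, "particle_mass", positive = TRUE)
  stop_if_not_number(vbar, "vbar", positive = TRUE)
  slope <- model$omega^2 * r_band / model$beta0
  sqrt(.R_erg * model$temperature /
         (particle_mass * vbar * slope * model$omega^2 * r_band))
}

#' Two-speed band separation and resolution comparison
#'
#' First-order (linearized about the isoconcentration radius) band theory
#' for comparing rotor speeds: the separation between two particle
#' densities is `Delta_r = beta0 (rho2 - rho1) / (omega^2 r_iso)` and the
#' band width is evaluated at `r_iso`, so both scale exactly as `omega^-2`
#' and their ratio (the resolution) is speed-invariant. A slower second
#' spin therefore widens the physical gap between bands (easier
#' fractionation) without changing Delta_r/sigma.
#'
#' @param model A [gradient_model()] providing geometry, temperature and
#'   loading density (its rpm field is ignored).
#' @param rpm Rotor speed to evaluate.
#' @param rho1,rho2 The two particle buoyant densities, g/cm^3.
#' @param particle_mass Particle mass, Da.
#' @param vbar Particle vbar, cm^3/g.
#' @return List `delta_r` (cm), `sigma_r` (cm, at r_iso), `resolution`
#'   (`delta_r / sigma_r`).
#' @export
two_speed_comparison <- function(model, rpm, rho1, rho2, particle_mass,
                                 vbar = vbar_from_density((rho1 + rho2) / 2)) {
  stopifnot(inherits(model, "gradient_model"))
  m <- gradient_model(rpm, model$r_top, model$r_bottom,
                      model$loading_density, model$temperature, model$beta0)
  r_iso <- r_isoconcentration(m)
  delta_r <- m$beta0 * abs(rho2 - rho1) / (m$omega^2 * r_iso)
  sigma_r <- band_width(m, r_iso, particle_mass, vbar)
  list(delta_r = delta_r, sigma_r = sigma_r, resolution = delta_r / sigma_r)
}

#' Sphere-model mass from a sedimentation coefficient
#'
#' Inverts the Svedberg relation for an anhydrous smooth sphere
#' (`s = M (1 - vbar rho) / (N_A 6 pi eta R_s)` with
#' `R_s = (3 M vbar / (4 pi N_A))^(1/3)`), giving `M` proportional to
#' `s^(3/2)`. A consistency-check tool, not a mass determination: hydration
#' and shape (frictional ratio > 1) are ignored.
#'
#' @param s_value Sedimentation coefficient in Svedberg (1e-13 s).
#' @param vbar Particle partial specific volume, cm^3/g.
#' @param solvent_density g/cm^3.
#' @param solvent_viscosity poise.
#' @return Particle mass in Da.
#' @export
svedberg_sphere_mass <- function(s_value, vbar, solvent_density = 1.005,
                                 solvent_viscosity = 0.01002) {
  buoy <- 1 - vbar * solvent_density
  if (any(buoy <= 0)) {
    stop("1 - vbar*rho <= 0: particle floats, sphere model undefined",
         call. = FALSE)
  }
  s_sec <- s_value * 1e-13
  geo <- (3 * vbar / (4 * pi * .avogadro))^(1 / 3)
  (s_sec * .avogadro * 6 * pi * solvent_viscosity * geo / buoy)^(3 / 2)
}

#' Write a density profile and band table as CSV
#'
#' @param profile A `density_profile`.
#' @param band_table data.frame (`sample`, `particle_density`); band
#'   positions are computed and appended.
#' @param profile_path,bands_path Output CSV paths (either may be NULL).
#' @return The augmented band table, invisibly.
#' @export
write_gradient_csv <- function(profile, band_table = NULL,
                               profile_path = NULL, bands_path = NULL) {
  if (!is.null(profile_path)) {
    utils::write.csv(profile$profile, profile_path, row.names = FALSE)
  }
  if (!is.null(band_table)) {
    pos <- lapply(band_table$particle_density,
                  function(d) band_position(profile, d))
    band_table$r_band <- vapply(pos, `[[`, numeric(1), "r_band")
    band_table$in_column <- vapply(pos, `[[`, logical(1), "in_column")
    if (!is.null(bands_path)) {
      utils::write.csv(band_table, bands_path, row.names = FALSE)
    }
  }
  invisible(band_table)
}
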