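# Capsid composition model: sequence-derived extinction coefficients and
# masses, molar stoichiometry from CGE peak areas, and the 60-subunit
# random-incorporation (multinomial) assembly/mass model.

N_SUBUNITS <- 60L

#' Molar extinction coefficient at 214 nm from sequence
#'
#' Predicts the molar absorptivity of a denatured polypeptide at 214 nm as
#' the sum of one peptide-bond term per bond plus per-residue side-chain
#' contributions (Kuipers-Gruppen scheme; see
#' [epsilon214_coefficients()]). Proline engaged in a peptide bond uses the
#' bond-aware proline coefficient; a proline at the N-terminus contributes
#' only its free N-terminal value. N-terminal acetylation is assumed to add
#' no absorbance.
#'
#' @param sequence Amino-acid sequence, standard one-letter codes.
#' @return Molar absorptivity in 1/(M cm); `0` for an empty sequence.
#' @examples
#' molar_extinction_214("GG")   # one bond + two glycines
#' @export
molar_extinction_214 <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) return(0)
  res <- strsplit(sequence, "")[[1]]
  unknown <- which(!res %in% names(.eps214_side))
  if (length(unknown) > 0) {
    stop(sprintf("unknown residue code '%s' at position %d",
                 res[unknown[1]], unknown[1]), call. = FALSE)
  }
  side <- .eps214_side[res]
  # prolines only carry the peptide-bonded coefficient when their imino
  # nitrogen is in a bond, i.e. anywhere but position 1
  if (res[1] == "P") side[1] <- .eps214_pro_nterm
  (length(res) - 1) * .eps214_bond + sum(side)
}

#' Average molecular mass of a polypeptide from sequence
#'
#' Sum of average residue masses plus one water; no N-terminal Met
#' processing or post-translational modifications are applied.
#'
#' @param sequence One-letter amino-acid string.
#' @return Mass in Da.
#' @export
sequence_average_mass <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) return(0)
  res <- strsplit(sequence, "")[[1]]
  unknown <- which(!res %in% names(.residue_avg_mass))
  if (length(unknown) > 0) {
    stop(sprintf("unknown residue code '%s' at position %d",
                 res[unknown[1]], unknown[1]), call. = FALSE)
  }
  sum(.residue_avg_mass[res]) + .water_mass
}

#' Construct a capsid protein species
#'
#' One viral protein (VP) isoform: its sequence (optional), monomer mass and
#' 214 nm molar extinction coefficient. When a sequence is supplied, missing
#' mass/epsilon values are computed from it; a user-supplied monomer mass
#' (e.g. an LC-MS deconvoluted mass carrying modifications) is checked
#' against the sequence mass and a warning is raised beyond 25 ppm, but the
#' supplied value always wins.
#'
#' @param name Species label, e.g. `"VP1"`, `"VP2"`, `"VP3"`, `"VP3clip"`.
#' @param sequence Optional amino-acid sequence.
#' @param monomer_mass Optional monomer mass, Da.
#' @param epsilon214 Optional molar absorptivity at 214 nm, 1/(M cm).
#' @param ppm_warn Agreement threshold for the sequence-mass check (ppm).
#' @return An object of class `vp_species`.
#' @export
vp_species <- function(name, sequence = NULL, monomer_mass = NULL,
                       epsilon214 = NULL, ppm_warn = 25) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (is.null(sequence) && (is.null(monomer_mass) || is.null(epsilon214))) {
    stop("without a sequence, both `monomer_mass` and `epsilon214` are required",
         call. = FALSE)
  }
  seq_mass <- if (!is.null(sequence)) sequence_average_mass(sequence) else NULL
  if (is.null(monomer_mass)) {
    monomer_mass <- seq_mass
  } else if (!is.null(seq_mass) && seq_mass > 0) {
    ppm <- mass_ppm_error(monomer_mass, seq_mass)
    if (ppm > ppm_warn) {
      warning(sprintf(
        "%s: supplied monomer mass deviates from sequence mass by %.0f ppm",
        name, ppm), call. = FALSE)
    }
  }
  if (is.null(epsilon214)) epsilon214 <- molar_extinction_214(sequence)
  stop_if_not_number(monomer_mass, "monomer_mass", positive = TRUE)
  if (!is.null(sequence) && nchar(sequence) >= 2 && epsilon214 <= 0) {
    stop("epsilon214 must be > 0 for a sequence of length >= 2", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence,
                 monomer_mass = monomer_mass, epsilon214 = epsilon214),
            class = "vp_species")
}

#' @export
print.vp_species <- function(x, ...) {
  cat(sprintf("<vp_species> %s: %.1f Da, eps214 = %.0f /(M cm)%s\n",
              x$name, x$monomer_mass, x$epsilon214,
              if (is.null(x$sequence)) "" else
                sprintf(", %d aa", nchar(x$sequence))))
  invisible(x)
}

#' Construct a capsid ensemble specification
#'
#' Describes a population of 60-subunit icosahedral capsids by the molar
#' fractions of its VP species plus the mass of the packaged genome. This is
#' both the ground truth of the synthetic generators and the target of
#' inference from CGE/CDMS data.
#'
#' @param species List of [vp_species()] objects.
#' @param fractions Molar fractions per species (normalized internally).
#' @param genome_mass Packaged genome mass in Da (0 for empty particles).
#' @return Object of class `capsid_ensemble` with fixed `n_subunits = 60`.
#' @export
capsid_ensemble <- function(species, fractions, genome_mass = 0) {
  stopifnot(is.list(species), length(species) >= 1,
            all(vapply(species, inherits, logical(1), "vp_species")))
  stopifnot(is.numeric(fractions), length(fractions) == length(species),
            all(is.finite(fractions)))
  if (any(fractions < 0)) stop("fractions must be non-negative", call. = FALSE)
  s <- sum(fractions)
  if (s <= 0) stop("fractions must not all be zero", call. = FALSE)
  stop_if_not_number(genome_mass, "genome_mass")
  if (genome_mass < 0) stop("genome_mass must be >= 0", call. = FALSE)
  structure(list(species = species, fractions = fractions / s,
                 genome_mass = genome_mass, n_subunits = N_SUBUNITS),
            class = "capsid_ensemble")
}

species_masses <- function(spec) {
  vapply(spec$species, function(s) s$monomer_mass, numeric(1))
}

species_names <- function(spec) {
  vapply(spec$species, function(s) s$name, character(1))
}

#' Molar stoichiometry from CGE peak areas
#'
#' Converts per-species 214 nm peak areas into molar amounts via
#' `n_i = A_i / epsilon_i`, then reports ratios normalized to VP1 = 1, molar
#' fractions, expected copies per 60-mer, and the summary metric
#' `(VP1 + VP2) / VP3_total` with `VP3_total = VP3 + VP3clip`.
#'
#' @param areas Named numeric vector of peak areas (>= 0); must contain `VP1`.
#' @param epsilons Named numeric vector of 214 nm molar absorptivities
#'   (> 0), same names as `areas`.
#' @return Object of class `stoichiometry_result` with fields `ratios`,
#'   `fractions`, `expected_counts_60`, `vp12_over_vp3total`.
#' @examples
#' eps <- c(VP1 = 1, VP2 = 1, VP3 = 1, VP3clip = 1)
#' stoichiometry_from_areas(c(VP1 = 1, VP2 = 1.3, VP3 = 6.9, VP3clip = 0.4), eps)
#' @export
stoichiometry_from_areas <- function(areas, epsilons) {
  stopifnot(is.numeric(areas), is.numeric(epsilons))
  if (is.null(names(areas)) || is.null(names(epsilons))) {
    stop("`areas` and `epsilons` must be named by VP species", call. = FALSE)
  }
  epsilons <- epsilons[names(areas)]
  if (anyNA(epsilons)) stop("`epsilons` missing for some species", call. = FALSE)
  if (any(areas < 0)) stop("peak areas must be >= 0", call. = FALSE)
  if (any(epsilons <= 0)) stop("epsilon214 values must be > 0", call. = FALSE)
  n <- areas / epsilons
  if (!"VP1" %in% names(n)) stop("a `VP1` entry is required", call. = FALSE)
  if (n[["VP1"]] <= 0) {
    stop("VP1 molar amount is zero; cannot normalize ratios to VP1",
         call. = FALSE)
  }
  ratios <- n / n[["VP1"]]
  fractions <- n / sum(n)
  counts60 <- expected_counts_60(fractions)
  vp3_names <- intersect(c("VP3", "VP3clip"), names(n))
  vp12_names <- intersect(c("VP1", "VP2"), names(n))
  vp3_total <- sum(n[vp3_names])
  if (length(vp3_names) == 0 || vp3_total <= 0) {
    stop("VP3_total is zero; (VP1+VP2)/VP3_total is undefined", call. = FALSE)
  }
  structure(list(ratios = ratios, fractions = fractions,
                 expected_counts_60 = counts60,
                 vp12_over_vp3total = sum(n[vp12_names]) / vp3_total),
            class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, digits = 2, ...) {
  cat("<stoichiometry_result>\n")
  cat("  ratios (VP1 = 1): ",
      paste(sprintf("%s %.1f", names(x$ratios), x$ratios), collapse = ", "), "\n")
  cat(sprintf("  (VP1+VP2)/VP3_total = %.2f  [%.4f]\n",
              round_away(x$vp12_over_vp3total, digits), x$vp12_over_vp3total))
  invisible(x)
}

#' Expected VP copies in a 60-mer
#'
#' @param fractions Molar fractions (non-negative, summing to 1 after
#'   normalization).
#' @return `60 * fractions`, summing to 60.
#' @export
expected_counts_60 <- function(fractions) {
  stopifnot(is.numeric(fractions), all(is.finite(fractions)))
  if (any(fractions < 0)) stop("fractions must be non-negative", call. = FALSE)
  s <- sum(fractions)
  if (abs(s - 1) > 1e-6) stop("fractions must sum to 1", call. = FALSE)
  N_SUBUNITS * fractions / s
}

#' Theoretical mean particle mass of an ensemble
#'
#' `60 * sum(p_i * m_i) + genome_mass`: the expected mass of a full particle
#' under random subunit incorporation, i.e. the CGE-derived stoichiometry
#' converted to a 60-mer plus the packaged genome.
#'
#' @param spec A [capsid_ensemble()].
#' @return Mass in Da.
#' @export
theoretical_particle_mass <- function(spec) {
  stopifnot(inherits(spec, "capsid_ensemble"))
  N_SUBUNITS * sum(spec$fractions * species_masses(spec)) + spec$genome_mass
}

#' Closed-form mass moments of the multinomial assembly model
#'
#' Under independent random incorporation of subunits (multinomial with 60
#' trials over the molar fractions), particle mass has mean
#' `60 * E[m] + genome`, variance `60 * (E[m^2] - E[m]^2)` and, in the
#' Gaussian approximation, FWHM `2 sqrt(2 ln 2) * sd`.
#'
#' @param spec A [capsid_ensemble()].
#' @return List with `mean`, `sd`, `fwhm` (Da).
#' @export
assembly_mass_moments <- function(spec) {
  stopifnot(inherits(spec, "capsid_ensemble"))
  m <- species_masses(spec)
  p <- spec$fractions
  mbar <- sum(p * m)
  v <- N_SUBUNITS * (sum(p * m^2) - mbar^2)
  sd <- sqrt(max(v, 0))
  list(mean = N_SUBUNITS * mbar + spec$genome_mass,
       sd = sd, fwhm = .fwhm_factor * sd)
}

#' Sample particle compositions from the assembly model
#'
#' Draws per-particle VP copy numbers from a multinomial with 60 trials over
#' the ensemble's molar fractions and fills in the particle mass
#' (subunits + genome).
#'
#' @param spec A [capsid_ensemble()].
#' @param n_particles Number of particles to draw (>= 1).
#' @param seed Optional RNG seed for reproducibility.
#' @return data.frame with one count column per species plus `mass` (Da).
#' @export
sample_assembly <- function(spec, n_particles, seed = NULL) {
  stopifnot(inherits(spec, "capsid_ensemble"))
  stop_if_not_number(n_particles, "n_particles", positive = TRUE)
  counts <- with_seed(seed,
    stats::rmultinom(n_particles, N_SUBUNITS, spec$fractions))
  m <- species_masses(spec)
  out <- as.data.frame(t(counts))
  names(out) <- species_names(spec)
  out$mass <- as.numeric(crossprod(counts, m)) + spec$genome_mass
  out
}

#' Enumerate integer compositions compatible with a particle mass
#'
#' Exhaustively enumerates all non-negative integer VP count vectors summing
#' to 60 whose particle mass (counts x monomer masses + genome) lies within
#' `tolerance` of `target_mass`. Intended for interpreting a CDMS-determined
#' particle mass as candidate VP1/VP2/VP3(/VP3clip) combinations.
#'
#' @param target_mass Target particle mass, Da.
#' @param tolerance Half-width of the accepted mass window, Da (>= 0;
#'   `Inf` returns every composition).
#' @param spec A [capsid_ensemble()] providing species masses and genome mass.
#' @return data.frame with one count column per species plus `mass` and
#'   `deviation` (Da, signed `mass - target`), sorted by `abs(deviation)`
#'   then lexicographically by counts. Zero rows is a valid result.
#' @export
compositions_for_mass <- function(target_mass, tolerance, spec) {
  stopifnot(inherits(spec, "capsid_ensemble"))
  stop_if_not_number(target_mass, "target_mass")
  if (!is.numeric(tolerance) || length(tolerance) != 1 || is.na(tolerance) ||
      tolerance < 0) {
    stop("`tolerance` must be a single number >= 0", call. = FALSE)
  }
  m <- species_masses(spec)
  k <- length(m)
  grids <- compositions_of(N_SUBUNITS, k)   # k columns, rows sum to 60
  mass <- as.numeric(grids %*% m) + spec$genome_mass
  dev <- mass - target_mass
  keep <- which(abs(dev) <= tolerance)
  out <- as.data.frame(grids[keep, , drop = FALSE])
  names(out) <- species_names(spec)
  out$mass <- mass[keep]
  out$deviation <- dev[keep]
  ord <- do.call(order, c(list(abs(out$deviation)),
                          unname(as.list(out[species_names(spec)]))))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# All weak compositions of n into k parts, as a matrix with k columns.
# k <= 4 at n = 60 gives at most choose(63, 3) = 39711 rows.
compositions_of <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  parts <- lapply(0:n, function(first) {
    rest <- compositions_of(n - first, k - 1)
    cbind(first, rest, deparse.level = 0)
  })
  do.call(rbind, parts)
}

#' Relative mass error in parts per million
#'
#' @param observed Observed mass, Da.
#' @param theoretical Theoretical mass, Da (> 0).
#' @return `1e6 * abs(observed - theoretical) / theoretical`.
#' @export
mass_ppm_error <- function(observed, theoretical) {
  stopifnot(is.numeric(observed), is.numeric(theoretical))
  if (any(theoretical <= 0)) stop("`theoretical` must be > 0", call. = FALSE)
  1e6 * abs(observed - theoretical) / theoretical
}

#' Read VP species from a FASTA file
#'
#' Parses a plain-text protein FASTA file; the first word of each
#' description line is taken as the species name. Masses and 214 nm
#' extinction coefficients are computed from the sequences.
#'
#' @param path FASTA file path.
#' @return Named list of [vp_species()].
#' @export
read_vp_fasta <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  idx <- grep("^>", lines)
  if (length(idx) == 0) stop("no FASTA records in ", path, call. = FALSE)
  ends <- c(idx[-1] - 1, length(lines))
  out <- lapply(seq_along(idx), function(i) {
    name <- strsplit(sub("^>", "", lines[idx[i]]), "\\s+")[[1]][1]
    seqs <- if (ends[i] > idx[i]) {
      paste(lines[(idx[i] + 1):ends[i]], collapse = "")
    } else ""
    vp_species(name, sequence = gsub("\\s", "", seqs))
  })
  names(out) <- vapply(out, function(s) s$name, character(1))
  out
}

#' Write a stoichiometry result as CSV
#'
#' One row per species with columns `species, ratio_vs_vp1, fraction,
#' expected_count_60`, plus the `(VP1+VP2)/VP3_total` summary in an attribute
#' comment row is avoided: the summary is returned invisibly.
#'
#' @param x A `stoichiometry_result`.
#' @param path Output CSV path.
#' @return Invisibly, the summary metric.
#' @export
write_stoichiometry_csv <- function(x, path) {
  stopifnot(inherits(x, "stoichiometry_result"))
  df <- data.frame(species = names(x$ratios),
                   ratio_vs_vp1 = as.numeric(x$ratios),
                   fraction = as.numeric(x$fractions),
                   expected_count_60 = as.numeric(x$expected_counts_60))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(x$vp12_over_vp3total)
}
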