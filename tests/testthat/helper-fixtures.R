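# Shared fixtures and independent oracles, built in code.

# two- and three-species toy ensembles with round masses
toy_species <- function(masses, names = paste0("S", seq_along(masses))) {
  Map(function(m, nm) vp_species(nm, monomer_mass = m, epsilon214 = 1000),
      masses, names)
}

toy_ensemble <- function(masses, fractions, genome_mass = 0,
                         names = paste0("S", seq_along(masses))) {
  capsid_ensemble(toy_species(masses, names), fractions, genome_mass)
}

# default four-species scenario set built once per test file
scenarios <- default_scenarios()

# the printed molar ratio worked examples
ratio_f11 <- c(VP1 = 1.0, VP2 = 1.3, VP3 = 6.9, VP3clip = 0.4)
ratio_f22 <- c(VP1 = 1.0, VP2 = 1.4, VP3 = 8.6, VP3clip = 0.4)

# round half away from zero, independent of the package helper
round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# independent recursive enumeration oracle for compositions_for_mass
enumerate_compositions_oracle <- function(n, masses, genome, target, tol) {
  out <- list()
  recurse <- function(prefix, remaining, depth) {
    if (depth == length(masses)) {
      counts <- c(prefix, remaining)
      mass <- sum(counts * masses) + genome
      if (abs(mass - target) <= tol) {
        out[[length(out) + 1]] <<- c(counts, mass)
      }
      return(invisible())
    }
    for (k in 0:remaining) recurse(c(prefix, k), remaining - k, depth + 1)
  }
  recurse(integer(0), n, 1)
  if (length(out) == 0) {
    return(matrix(numeric(0), ncol = length(masses) + 1))
  }
  do.call(rbind, out)
}

# synthetic Gaussian electropherogram builder
gaussian_trace <- function(positions, areas, sigma = 0.08, offset = 0,
                           from = min(positions) - 3, to = max(positions) + 3,
                           by = 0.005, noise_sd = 0, seed = NULL,
                           channel = "protein") {
  x <- seq(from, to, by = by)
  y <- rep(offset, length(x))
  for (i in seq_along(positions)) {
    y <- y + areas[i] / (sigma * sqrt(2 * pi)) *
      exp(-(x - positions[i])^2 / (2 * sigma^2))
  }
  if (noise_sd > 0) {
    y <- y + vpstoich:::with_seed(seed, rnorm(length(x), 0, noise_sd))
  }
  electropherogram(x, y, channel = channel)
}
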