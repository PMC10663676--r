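# capsid composition model: extinction coefficients, stoichiometry
# arithmetic, 60-mer assembly/mass model

test_that("molar_extinction_214 sums bond and side-chain terms", {
  tab <- epsilon214_coefficients()
  expect_identical(molar_extinction_214(""), 0)
  # hand sum: one bond + two glycines
  expect_equal(molar_extinction_214("GG"),
               tab$peptide_bond + 2 * tab$side_chain[["G"]])
  # single residue: no bond
  expect_equal(molar_extinction_214("W"), tab$side_chain[["W"]])
  # N-terminal proline uses the free value, internal proline the bonded one
  expect_equal(molar_extinction_214("PG"),
               tab$peptide_bond + tab$proline_n_terminal +
                 tab$side_chain[["G"]])
  expect_equal(molar_extinction_214("GP"),
               tab$peptide_bond + tab$side_chain[["G"]] +
                 tab$side_chain[["P"]])
  expect_error(molar_extinction_214("GAXZG"), "'X' at position 3")
})

test_that("molar_extinction_214 matches a residue-by-residue oracle on VP3", {
  vp3 <- make_vp_sequences()[["VP3"]]
  tab <- epsilon214_coefficients()
  res <- strsplit(vp3, "")[[1]]
  oracle <- (length(res) - 1) * tab$peptide_bond +
    sum(vapply(seq_along(res), function(i) {
      if (res[i] == "P" && i == 1) tab$proline_n_terminal
      else tab$side_chain[[res[i]]]
    }, numeric(1)))
  expect_equal(molar_extinction_214(vp3), oracle, tolerance = 1e-6)
})

test_that("stoichiometry_from_areas reproduces the printed worked examples", {
  eps <- c(VP1 = 1.4e6, VP2 = 1.1e6, VP3 = 9.7e5, VP3clip = 9.5e5)
  for (cs in list(list(r = ratio_f11, want = 0.32),
                  list(r = ratio_f22, want = 0.27))) {
    areas <- cs$r * eps[names(cs$r)]
    st <- stoichiometry_from_areas(areas, eps)
    expect_s3_class(st, "stoichiometry_result")
    expect_equal(round_half_up(st$vp12_over_vp3total, 2), cs$want)
    expect_equal(unname(st$ratios), unname(cs$r / cs$r[["VP1"]]))
    expect_equal(sum(st$fractions), 1, tolerance = 1e-12)
    expect_equal(sum(st$expected_counts_60), 60, tolerance = 1e-9)
  }
})

test_that("stoichiometry is scale invariant and symmetric for equal input", {
  eps <- c(VP1 = 2, VP2 = 2, VP3 = 2, VP3clip = 2)
  st <- stoichiometry_from_areas(c(VP1 = 5, VP2 = 5, VP3 = 5, VP3clip = 5),
                                 eps)
  expect_equal(unname(st$ratios), rep(1, 4))
  expect_equal(st$vp12_over_vp3total, 1.0)
  # multiplying all areas by any constant changes nothing
  a0 <- ratio_f11 * c(3, 1, 2, 5)
  base <- stoichiometry_from_areas(a0, c(VP1 = 3, VP2 = 1, VP3 = 2,
                                         VP3clip = 5))
  for (k in c(1e-6, 0.37, 1e8)) {
    sk <- stoichiometry_from_areas(a0 * k, c(VP1 = 3, VP2 = 1, VP3 = 2,
                                             VP3clip = 5))
    expect_equal(sk$ratios, base$ratios)
    expect_equal(sk$vp12_over_vp3total, base$vp12_over_vp3total)
  }
})

test_that("stoichiometry_from_areas error paths", {
  eps <- c(VP1 = 1, VP2 = 1, VP3 = 1, VP3clip = 1)
  expect_error(
    stoichiometry_from_areas(c(VP1 = 0, VP2 = 1, VP3 = 1, VP3clip = 1), eps),
    "VP1")
  expect_error(
    stoichiometry_from_areas(c(VP1 = 1, VP2 = 1), c(VP1 = 1, VP2 = 1)),
    "VP3_total")
  expect_error(
    stoichiometry_from_areas(c(VP1 = 1, VP3 = -0.1), c(VP1 = 1, VP3 = 1)),
    ">= 0")
  expect_error(
    stoichiometry_from_areas(c(VP1 = 1, VP3 = 1), c(VP1 = 1, VP3 = 0)),
    "> 0")
})

test_that("expected_counts_60 converts fractions to copies", {
  expect_equal(unname(expected_counts_60(c(1, 1, 10) / 12)), c(5, 5, 50))
  expect_equal(unname(expected_counts_60(c(1, 0, 0, 0))), c(60, 0, 0, 0))
  fr <- ratio_f11 / sum(ratio_f11)
  counts <- expected_counts_60(fr)
  expect_equal(sum(counts), 60)
  expect_equal(counts[["VP3"]], 60 * 6.9 / sum(ratio_f11))
  expect_error(expected_counts_60(c(0.5, 0.6, -0.1)), "non-negative")
})

test_that("theoretical_particle_mass is the 60-mer mean plus genome", {
  expect_equal(theoretical_particle_mass(toy_ensemble(80000, 1)), 4.8e6)
  expect_equal(
    theoretical_particle_mass(toy_ensemble(c(60000, 80000), c(0.5, 0.5),
                                           genome_mass = 700000)),
    60 * 70000 + 700000)
  # identity at a degenerate fraction vector
  e <- toy_ensemble(c(123, 456, 789), c(1, 0, 0), genome_mass = 55)
  expect_equal(theoretical_particle_mass(e), 60 * 123 + 55)
})

test_that("assembly_mass_moments matches the exact binomial variance", {
  expect_equal(assembly_mass_moments(toy_ensemble(80000, 1))$sd, 0)
  expect_equal(assembly_mass_moments(toy_ensemble(80000, 1))$fwhm, 0)
  m <- assembly_mass_moments(toy_ensemble(c(1, 2), c(0.5, 0.5)))
  expect_equal(m$sd, sqrt(15))   # binomial: 60 * 0.25 * (2-1)^2
  expect_equal(m$fwhm, 2 * sqrt(2 * log(2)) * sqrt(15))
})

test_that("Monte-Carlo assembly converges to the closed-form moments", {
  spec <- scenarios$f1_1$components[[1]]$ensemble
  mom <- assembly_mass_moments(spec)
  draws <- sample_assembly(spec, 1e5, seed = 71)
  expect_equal(mean(draws$mass), mom$mean, tolerance = 1e-3)
  expect_equal(sd(draws$mass), mom$sd, tolerance = 0.02)
})

test_that("sample_assembly is deterministic and respects degenerate input", {
  e <- toy_ensemble(c(10, 20, 30, 40), c(1, 0, 0, 0))
  draws <- sample_assembly(e, 50, seed = 3)
  expect_true(all(draws$S1 == 60))
  expect_true(all(draws$mass == 600))
  expect_identical(sample_assembly(e, 100, seed = 9),
                   sample_assembly(e, 100, seed = 9))
})

test_that("concentrating fractions onto the dominant species never raises sd", {
  set.seed(404)
  for (rep in 1:25) {
    m <- sort(runif(4, 5e4, 9e4))
    p <- runif(4)
    d <- sample.int(4, 1)
    p[d] <- p[d] + sum(p)          # make species d dominant (> 1/2)
    p <- p / sum(p)
    e0 <- toy_ensemble(m, p)
    sds <- vapply(seq(0, 1, by = 0.1), function(t) {
      pt <- (1 - t) * p
      pt[d] <- pt[d] + t
      assembly_mass_moments(toy_ensemble(m, pt))$sd
    }, numeric(1))
    expect_true(all(diff(sds) <= 1e-9))
  }
})

test_that("mass ordering follows the combined VP1+VP2 metric", {
  e_f11 <- scenarios$f1_1$components[[1]]$ensemble
  e_f22 <- scenarios$f2_2$components[[1]]$ensemble
  expect_identical(e_f11$genome_mass, e_f22$genome_mass)
  expect_gt(theoretical_particle_mass(e_f11),
            theoretical_particle_mass(e_f22))
})

test_that("compositions_for_mass equals exhaustive enumeration", {
  e <- toy_ensemble(c(10, 20, 30), c(1, 1, 1) / 3)
  hit <- compositions_for_mass(1800, 0, e)
  expect_equal(nrow(hit), 1)
  expect_equal(unname(unlist(hit[1, c("S1", "S2", "S3")])), c(0, 0, 60))
  # all weak compositions of 60 into 3 parts
  expect_equal(nrow(compositions_for_mass(0, Inf, e)), choose(62, 2))
  # self-consistency for a generic 4-species instance
  e4 <- toy_ensemble(c(81261, 65623, 58275, 57472), rep(0.25, 4),
                     genome_mass = 896100)
  target <- sum(c(5, 5, 50, 0) * c(81261, 65623, 58275, 57472)) + 896100
  hits <- compositions_for_mass(target, 0, e4)
  key <- apply(hits[, 1:4], 1, paste, collapse = ",")
  expect_true("5,5,50,0" %in% key)
  # against the independent recursive oracle, several tolerance regimes
  for (tol in c(0, 500, 5000)) {
    mine <- compositions_for_mass(4.5e6, tol, e4)
    oracle <- enumerate_compositions_oracle(60, c(81261, 65623, 58275, 57472),
                                            896100, 4.5e6, tol)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(mine) > 0) {
      expect_setequal(apply(mine[, 1:4], 1, paste, collapse = ","),
                      apply(oracle[, 1:4, drop = FALSE], 1, paste,
                            collapse = ","))
    }
  }
  # sorted by absolute deviation
  near <- compositions_for_mass(4.5e6, 5e4, e4)
  expect_true(all(diff(abs(near$deviation)) >= -1e-9))
})

test_that("mass_ppm_error behaves as a relative error in ppm", {
  expect_equal(mass_ppm_error(59750.5, 59750.0), 1e6 * 0.5 / 59750)
  expect_equal(mass_ppm_error(59750.5, 59750.0), 8.4, tolerance = 0.01)
  expect_equal(mass_ppm_error(1234.5, 1234.5), 0)
  expect_equal(mass_ppm_error(4.70e6, 4.58e6), 26200, tolerance = 0.01)
  expect_error(mass_ppm_error(1, 0), "> 0")
})

test_that("vp_species computes and checks sequence-derived values", {
  s <- vp_species("VP3", sequence = "GGAAW")
  expect_equal(s$monomer_mass, sequence_average_mass("GGAAW"))
  expect_equal(s$epsilon214, molar_extinction_214("GGAAW"))
  # supplied mass out of tolerance raises a warning but is kept
  expect_warning(
    sx <- vp_species("VP3", sequence = "GGAAW",
                     monomer_mass = sequence_average_mass("GGAAW") * 1.001,
                     epsilon214 = 1),
    "ppm")
  expect_equal(sx$monomer_mass, sequence_average_mass("GGAAW") * 1.001)
  # within 25 ppm: silent
  expect_silent(vp_species("VP3", sequence = "GGAAW",
                           monomer_mass = sequence_average_mass("GGAAW") *
                             (1 + 1e-5), epsilon214 = 1))
  expect_error(vp_species("X"), "monomer_mass")
})

test_that("FASTA round trip preserves names and sequence-derived masses", {
  path <- withr::local_tempfile(fileext = ".fasta")
  write_vp_fasta(path = path)
  back <- read_vp_fasta(path)
  seqs <- make_vp_sequences()
  expect_named(back, names(seqs))
  for (nm in names(seqs)) {
    expect_equal(back[[nm]]$sequence, unname(seqs[[nm]]))
    expect_equal(back[[nm]]$monomer_mass, sequence_average_mass(seqs[[nm]]))
  }
})
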