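# isopycnic density physics, band theory, Svedberg sphere model

test_that("vbar_from_density reproduces the printed isopycnic vbars", {
  expect_equal(round(vbar_from_density(1.352), 4), 0.7396)
  expect_equal(round(vbar_from_density(1.352) - vbar_from_density(1.361), 4),
               0.0049)
  expect_equal(vbar_from_density(1.0), 1.0)
  expect_equal(1.361 - 1.352, 0.009)
  expect_error(vbar_from_density(0), "> 0")
  # reciprocal round trip
  expect_equal(vbar_from_density(vbar_from_density(1.2345)), 1.2345)
})

test_that("composition_vbar: identities and the F1.1/F2.2 direction", {
  tab <- residue_partial_specific_volumes()
  gly <- capsid_ensemble(
    list(vp_species("G60", sequence = strrep("G", 60))), 1, genome_mass = 0)
  expect_equal(composition_vbar(gly), unname(tab["G"]))
  # protein mass = dna mass -> midpoint of protein vbar and dna vbar
  ala <- vp_species("A50", sequence = strrep("A", 50))
  e <- capsid_ensemble(list(ala), 1, genome_mass = 60 * ala$monomer_mass)
  expect_equal(composition_vbar(e, dna_vbar = 0.55),
               (tab[["A"]] + 0.55) / 2)
  v11 <- composition_vbar(scenarios$f1_1$components[[1]]$ensemble)
  v22 <- composition_vbar(scenarios$f2_2$components[[1]]$ensemble)
  expect_gt(v11, v22)
  expect_lt(v11 - v22, 0.001)
  noseq <- capsid_ensemble(list(vp_species("X", monomer_mass = 5e4,
                                           epsilon214 = 1)), 1)
  expect_error(composition_vbar(noseq), "sequence")
})

test_that("equilibrium gradient conserves salt and scales with omega^2", {
  gm0 <- gradient_model(0)
  prof0 <- equilibrium_gradient(gm0)
  expect_true(all(prof0$profile$rho == gm0$loading_density))

  gm <- gradient_model(20000)
  prof <- equilibrium_gradient(gm)
  # volume-weighted (sector: weight ~ r) mean equals loading density;
  # adaptive quadrature as the independent integration oracle
  mean_rho <- integrate(function(r) prof$rho(r) * r, gm$r_top, gm$r_bottom,
                        rel.tol = 1e-12)$value /
    integrate(function(r) r, gm$r_top, gm$r_bottom, rel.tol = 1e-12)$value
  expect_equal(mean_rho, gm$loading_density, tolerance = 1e-9)
  expect_true(all(diff(prof$profile$rho) >= 0))

  gm2 <- gradient_model(40000)
  prof2 <- suppressWarnings(equilibrium_gradient(gm2))
  span1 <- prof$rho(gm$r_bottom) - prof$rho(gm$r_top)
  span2 <- prof2$rho(gm2$r_bottom) - prof2$rho(gm2$r_top)
  expect_equal(span2 / span1, 4, tolerance = 1e-12)
  # steep gradient flags sub-unit density
  expect_warning(equilibrium_gradient(gradient_model(34000)), "rho < 1")
  expect_true(suppressWarnings(
    equilibrium_gradient(gradient_model(34000)))$subisodense)
})

test_that("salt conservation holds across random models (property)", {
  set.seed(99)
  for (i in 1:20) {
    gm <- gradient_model(runif(1, 5000, 30000),
                         r_top = runif(1, 4, 8), r_bottom = runif(1, 10, 16),
                         loading_density = runif(1, 1.2, 1.5))
    prof <- suppressWarnings(equilibrium_gradient(gm))
    mean_rho <- integrate(function(r) prof$rho(r) * r, gm$r_top,
                          gm$r_bottom, rel.tol = 1e-12)$value /
      integrate(function(r) r, gm$r_top, gm$r_bottom,
                rel.tol = 1e-12)$value
    expect_equal(mean_rho, gm$loading_density, tolerance = 1e-9)
    expect_true(all(diff(prof$profile$rho) >= 0))
  }
})

test_that("band_position finds the isopycnic radius", {
  gm <- gradient_model(20000)
  prof <- equilibrium_gradient(gm)
  # particle at loading density bands at the isoconcentration radius
  pos <- band_position(prof, gm$loading_density)
  expect_true(pos$in_column)
  expect_equal(pos$r_band, prof$r_iso, tolerance = 1e-7)
  # self-consistency: zero net buoyant force at the band
  pos2 <- band_position(prof, 1.352)
  expect_equal(prof$rho(pos2$r_band), 1.352, tolerance = 1e-9)
  # out of column
  too_dense <- band_position(prof, prof$rho(gm$r_bottom) + 0.1)
  expect_false(too_dense$in_column)
  expect_true(is.na(too_dense$r_band))
})

test_that("band_position on a hand-built linear profile (algebra oracle)", {
  gm <- gradient_model(10000, r_top = 5, r_bottom = 12,
                       loading_density = 1.33)
  lin <- structure(list(rho = function(r) 1.30 + 0.01 * (r - 5),
                        drho_dr = function(r) rep(0.01, length(r)),
                        r_iso = 8.5, model = gm,
                        profile = data.frame(r = c(5, 12),
                                             rho = c(1.30, 1.37)),
                        subisodense = FALSE),
                   class = "density_profile")
  pos <- band_position(lin, 1.352)
  expect_equal(pos$r_band, 5 + 5.2, tolerance = 1e-7)
})

test_that("band_width scaling laws", {
  gm <- gradient_model(24000)
  s1 <- band_width(gm, 11, 4.6e6, 0.74)
  expect_equal(band_width(gm, 11, 4 * 4.6e6, 0.74), s1 / 2)
  # with drho/dr ~ omega^2, sigma ~ omega^-2 at fixed radius
  gm2 <- gradient_model(48000)
  expect_equal(band_width(gm2, 11, 4.6e6, 0.74), s1 / 4, tolerance = 1e-12)
  expect_error(band_width(gradient_model(0), 11, 4.6e6, 0.74), "omega = 0")
})

test_that("two-speed comparison: separation grows as omega^-2, resolution fixed", {
  gm <- gradient_model(34000)
  c34 <- two_speed_comparison(gm, 34000, 1.352, 1.361, 4.6e6)
  c24 <- two_speed_comparison(gm, 24000, 1.352, 1.361, 4.6e6)
  expect_equal(c24$delta_r / c34$delta_r, (34 / 24)^2, tolerance = 1e-6)
  expect_equal(c24$sigma_r / c34$sigma_r, (34 / 24)^2, tolerance = 1e-6)
  expect_equal(c24$resolution, c34$resolution, tolerance = 1e-6)
  expect_gt(c24$delta_r, c34$delta_r)
})

test_that("svedberg_sphere_mass: scaling, direction, root-finder oracle", {
  m1 <- svedberg_sphere_mass(50, 0.74)
  expect_equal(svedberg_sphere_mass(100, 0.74) / m1, 2^1.5,
               tolerance = 1e-12)
  # the printed s-values imply ~3.6% higher mass for F1.1
  ratio <- svedberg_sphere_mass(99.5, 0.74) / svedberg_sphere_mass(97.2, 0.74)
  expect_gt(ratio, 1)
  expect_equal(ratio, (99.5 / 97.2)^1.5, tolerance = 1e-12)
  # independent numeric inversion of the forward sphere model
  vbar <- 0.74; rho <- 1.005; eta <- 0.01002
  forward_s <- function(M) {
    Rs <- (3 * M * vbar / (4 * pi * 6.02214076e23))^(1 / 3)
    M * (1 - vbar * rho) / (6.02214076e23 * 6 * pi * eta * Rs) / 1e-13
  }
  M_closed <- svedberg_sphere_mass(100, vbar, rho, eta)
  M_root <- uniroot(function(M) forward_s(M) - 100, c(1e5, 1e9),
                    tol = 1e-3)$root
  expect_equal(M_closed, M_root, tolerance = 1e-6)
  expect_error(svedberg_sphere_mass(100, 0.8, solvent_density = 1.3),
               "floats")
})

test_that("gradient CSV writer computes band positions", {
  gm <- gradient_model(24000)
  prof <- equilibrium_gradient(gm)
  tab <- write_gradient_csv(prof,
                            data.frame(sample = c("f1_1", "f2_2"),
                                       particle_density = c(1.352, 1.361)))
  expect_true(all(tab$in_column))
  expect_lt(tab$r_band[1], tab$r_band[2])
})
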