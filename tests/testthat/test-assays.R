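# potency normalization, stoichiometry-potency correlation, DSF Tm

make_records <- function(means, mois = c(1e2, 1e3), n = 3, noise = 0) {
  rows <- list()
  for (s in names(means)) {
    for (j in seq_along(mois)) {
      v <- means[[s]][j]
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, moi = mois[j], replicate = seq_len(n),
        gfp_positive = pmin(1, pmax(0, v + noise * (seq_len(n) - 2))))
    }
  }
  do.call(rbind, rows)
}

test_that("relative_potency normalizes to the bulk reference", {
  rec <- make_records(list(bulk_wt = c(0.1, 0.4), a = c(0.12, 0.36)))
  rel <- relative_potency(rec, "bulk_wt")
  expect_equal(rel$value[rel$sample == "bulk_wt"], c(1, 1))
  expect_equal(rel$value[rel$sample == "a" & rel$moi == 1e2], 1.2)
  expect_equal(rel$value[rel$sample == "a" & rel$moi == 1e3], 0.9)
  # missing bulk at one MOI names the MOI
  bad <- rec[!(rec$sample == "bulk_wt" & rec$moi == 1e3), ]
  expect_error(relative_potency(bad, "bulk_wt"), "1000")
  expect_error(relative_potency(transform(rec, gfp_positive = 2),
                                "bulk_wt"), "0, 1")
})

test_that("relative_potency propagates replicate SD to first order", {
  rec <- make_records(list(bulk_wt = c(0.2, 0.2), a = c(0.3, 0.3)),
                      noise = 0.01)
  rel <- relative_potency(rec, "bulk_wt")
  row <- rel[rel$sample == "a" & rel$moi == 1e2, ]
  expect_equal(row$value, 0.3 / 0.2)
  expect_equal(row$sd, row$value * sqrt((0.01 / 0.3)^2 + (0.01 / 0.2)^2))
  # normalization idempotence: renormalizing already-relative values
  # (bulk identically 1) returns them unchanged
  rec2 <- make_records(list(bulk_wt = c(1, 1), a = c(0.9, 0.4)))
  rel2 <- relative_potency(rec2, "bulk_wt")
  expect_equal(rel2$value[rel2$sample == "a"], c(0.9, 0.4))
})

test_that("correlation: exact linearity, degeneracy, affine invariance", {
  met <- data.frame(sample = letters[1:5], m1 = c(1, 2, 3, 4, 5),
                    m2 = c(2, 2, 2, 2, 2))
  pot <- data.frame(sample = letters[1:5], value = 0.5 + 0.1 * (1:5))
  co <- stoich_potency_correlation(met, pot)
  expect_equal(co$r[co$metric == "m1"], 1.0)
  expect_true(co$degenerate[co$metric == "m2"])
  expect_true(is.na(co$r[co$metric == "m2"]))
  expect_equal(co$intercept[co$metric == "m1"], 0.5)
  expect_equal(co$slope[co$metric == "m1"], 0.1)
  # affine rescaling of the metric leaves |r| unchanged
  met2 <- transform(met, m1 = 7 - 3 * m1)
  co2 <- stoich_potency_correlation(met2, pot)
  expect_equal(abs(co2$r[co2$metric == "m1"]), 1.0)
  expect_error(stoich_potency_correlation(met[1:2, ], pot), "3 samples")
})

test_that("potency generated from the combined metric favours it (95/100)", {
  # five ensembles whose VP1:VP2 split varies at fixed or crossing
  # (VP1+VP2)/VP3_total, so the single-VP metrics are not collinear with
  # the combined one; potency is generated from the combined metric
  ratios <- list(a = c(1, 1, 8, 0), b = c(1, 2, 8, 0), c = c(2, 1, 8, 0),
                 d = c(1.5, 1.5, 7, 0), e = c(0.8, 0.8, 9, 0.2))
  met <- do.call(rbind, lapply(names(ratios), function(nm) {
    x <- ratios[[nm]]
    v3 <- x[3] + x[4]
    data.frame(sample = nm, vp1_only = x[1] / (x[2] + v3),
               vp2_only = x[2] / (x[1] + v3),
               combined = (x[1] + x[2]) / v3)
  }))
  wins <- vapply(1:100, function(s) {
    pot <- data.frame(sample = met$sample,
                      value = vpstoich:::with_seed(s,
                        0.2 + 2.5 * met$combined + rnorm(5, 0, 0.02)))
    co <- stoich_potency_correlation(met, pot)
    r <- setNames(co$r, co$metric)
    r[["combined"]] > r[["vp1_only"]] && r[["combined"]] > r[["vp2_only"]]
  }, logical(1))
  expect_gte(sum(wins), 95)
})

test_that("tm_from_bcm finds the sigmoid midpoint and rejects flat scans", {
  temps <- seq(40, 90, by = 0.5)
  mk <- function(tm, noise = 0, seed = 1) {
    bcm <- 330 + 15 * plogis((temps - tm) / 2)
    if (noise > 0) {
      bcm <- bcm + vpstoich:::with_seed(seed, rnorm(length(temps), 0, noise))
    }
    data.frame(temperature = temps, bcm = bcm)
  }
  expect_equal(tm_from_bcm(mk(67.1)), 67.1, tolerance = 0.002)
  expect_equal(tm_from_bcm(mk(67.1, noise = 0.05, seed = 4)), 67.1,
               tolerance = 0.004)
  # linear ramp has no interior derivative peak
  expect_error(tm_from_bcm(data.frame(temperature = temps,
                                      bcm = 330 + 0.2 * temps)),
               "transition|peak")
  expect_error(tm_from_bcm(data.frame(temperature = temps, bcm = 330)),
               "transition")
  expect_error(tm_from_bcm(mk(67.1)[1:10, ]), "20")
  expect_error(tm_from_bcm(data.frame(temperature = rev(temps),
                                      bcm = mk(67.1)$bcm)), "increasing")
})

test_that("Tm is invariant to BCM offset and shifts with temperature", {
  temps <- seq(40, 90, by = 0.5)
  scan <- data.frame(temperature = temps,
                     bcm = 330 + 15 * plogis((temps - 68.2) / 2))
  t0 <- tm_from_bcm(scan)
  expect_equal(tm_from_bcm(transform(scan, bcm = bcm + 12.3)), t0)
  shifted <- data.frame(temperature = temps + 3, bcm = scan$bcm)
  expect_equal(tm_from_bcm(shifted), t0 + 3, tolerance = 1e-9)
})

test_that("variant melting temperatures recover within 0.2 C, ordered", {
  t203 <- tm_from_bcm(make_thermal_scan(scenarios$m203v, seed = 5))
  t211 <- tm_from_bcm(make_thermal_scan(scenarios$m211v, seed = 6))
  twt <- tm_from_bcm(make_thermal_scan(scenarios$bulk_wt, seed = 7))
  expect_equal(t203, 68.2, tolerance = 0.2 / 68.2)
  expect_equal(t211, 67.7, tolerance = 0.2 / 67.7)
  expect_true(t203 > t211 && t211 > twt)
})
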