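test_that("charge spacing is contour length over charge count", {
  expect_equal(charge_spacing(polyelectrolyte_chain(1, 4)), 0.25)
  expect_equal(charge_spacing(polyelectrolyte_chain(10, 10)), 1.0)
  expect_equal(charge_spacing(polyelectrolyte_chain(100, 400)), 0.25)
  expect_error(polyelectrolyte_chain(-1, 4), "positive")
  expect_error(polyelectrolyte_chain(1, 0), ">= 1")
})

test_that("Bjerrum length in water at 25 C is ~0.714 nm and scales inversely", {
  w <- solvent_conditions()
  lb <- bjerrum_length(w)
  expect_equal(lb, 0.7139609, tolerance = 1e-6)
  expect_equal(bjerrum_length(solvent_conditions(dielectric_constant = 157)),
               lb / 2, tolerance = 1e-12)
  expect_equal(bjerrum_length(solvent_conditions(temperature = 2 * 298.15)),
               lb / 2, tolerance = 1e-12)
  expect_equal(solvent_conditions(temperature_C = 25)$temperature, 298.15)
})

test_that("line charge density of heparan sulphate reaches the condensed regime", {
  st <- line_charge_density(0.25)
  expect_equal(signif(st$xi, 2), 2.9)
  expect_true(st$is_condensed)
  expect_equal(st$condensed_fraction + st$effective_charge_fraction, 1)
  # renormalization to the critical density: effective fraction * xi = 1
  expect_equal(st$effective_charge_fraction * st$xi, 1)
  # xi = 1 exactly when b equals the Bjerrum length
  expect_equal(line_charge_density(bjerrum_length(solvent_conditions()))$xi, 1)
  # inverse proportionality in b, to machine tolerance
  expect_equal(line_charge_density(0.125)$xi, 2 * st$xi, tolerance = 1e-12)
  expect_error(line_charge_density(0), "positive")
})

test_that("condensed-charge fraction follows the Manning closure", {
  expect_equal(condensation_fraction(1), 0)
  expect_equal(condensation_fraction(0.5), 0)
  expect_equal(condensation_fraction(2.9), 1 - 1 / 2.9)
  expect_error(condensation_fraction(0), "positive")
  # monotone non-decreasing, in [0, 1), -> 1 as xi grows
  xi <- c(0.2, 0.7, 1, 1.3, 2, 5, 50, 1e6)
  fr <- condensation_fraction(xi)
  expect_true(all(diff(fr) >= 0))
  expect_true(all(fr >= 0 & fr < 1))
  expect_equal(fr[length(fr)], 1, tolerance = 1e-5)
  # below and at the threshold there is no condensation
  expect_true(all(condensation_fraction(seq(0.05, 1, by = 0.05)) == 0))
})
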