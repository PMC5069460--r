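test_that("residue and term masses agree with the elemental oracle", {
  # residue masses = dehydrated monosaccharides
  expect_equal(composition_mass(hmo_composition(hex = 1)),
               elemental_mass(C = 6, H = 12, O = 6), tolerance = 1e-8)
  expect_equal(composition_mass(hmo_composition(hexnac = 1)),
               elemental_mass(C = 8, H = 15, N = 1, O = 6), tolerance = 1e-8)
  expect_equal(composition_mass(hmo_composition(fuc = 1)),
               elemental_mass(C = 6, H = 12, O = 5), tolerance = 1e-8)
  expect_equal(composition_mass(hmo_composition(neu5ac = 1)),
               elemental_mass(C = 11, H = 19, N = 1, O = 9), tolerance = 1e-8)
  # lactose C12H22O11 and the 2'FL alditol C18H34O15
  expect_equal(composition_mass(hmo_composition(hex = 2)),
               elemental_mass(C = 12, H = 22, O = 11), tolerance = 1e-6)
  expect_equal(composition_mass(hmo_composition(hex = 2)), 342.1162,
               tolerance = 1e-4)
  expect_equal(
    composition_mass(hmo_composition(hex = 2, fuc = 1, reduced = TRUE)),
    elemental_mass(C = 18, H = 34, O = 15), tolerance = 1e-6)
  expect_equal(
    composition_mass(hmo_composition(hex = 2, fuc = 1, reduced = TRUE)),
    490.1898, tolerance = 1e-4)
})

test_that("alditol increment, monotonicity and condensation additivity hold", {
  set.seed(7)
  for (i in 1:25) {
    a <- hmo_composition(sample(0:4, 1), sample(0:3, 1), sample(0:3, 1),
                         sample(0:2, 1) + 1)
    expect_equal(
      composition_mass(dplyr::mutate(a, reduced = TRUE)) -
        composition_mass(a),
      2.015650, tolerance = 1e-9)
    # strictly increasing in every residue count
    for (col in c("hex", "hexnac", "fuc", "neu5ac")) {
      b <- a
      b[[col]] <- b[[col]] + 1L
      expect_gt(composition_mass(b), composition_mass(a))
    }
    # glycosidic condensation: mass(a + b) = mass(a) + mass(b) - water
    b <- hmo_composition(sample(0:3, 1) + 1, sample(0:2, 1))
    ab <- hmo_composition(a$hex + b$hex, a$hexnac + b$hexnac,
                          a$fuc + b$fuc, a$neu5ac + b$neu5ac)
    expect_equal(composition_mass(ab),
                 composition_mass(a) + composition_mass(b) -
                   elemental_mass(H = 2, O = 1),
                 tolerance = 1e-9)
  }
  expect_error(composition_mass(tibble::tibble(hex = 0, hexnac = 0,
                                               fuc = 0, neu5ac = 0)),
               "at least one residue")
  expect_error(hmo_composition(hex = -1), "non-negative")
})

test_that("m/z arithmetic is a protonation and its exact inverse", {
  expect_equal(mz_from_mass(488.1741, 1L), 489.1814, tolerance = 1e-4)
  expect_equal(mz_from_mass(488.1741, 2L), 245.0943, tolerance = 1e-4)
  set.seed(11)
  mass <- runif(50, 300, 2000)
  z <- sample(1:3, 50, replace = TRUE)
  expect_equal(mass_from_mz(mz_from_mass(mass, z), z), mass,
               tolerance = 1e-9)
  expect_error(mz_from_mass(500, 0), "positive integer")
  expect_error(mz_from_mass(-1, 1), "positive")
})

test_that("ppm error is signed, antisymmetric to first order, and guarded", {
  expect_identical(ppm_error(489.1814, 489.1814), 0)
  expect_equal(ppm_error(489.1912, 489.1814), 20.0, tolerance = 0.05)
  a <- 500.123; b <- 500.131
  expect_equal(ppm_error(a, b), -ppm_error(b, a), tolerance = 1e-3)
  expect_error(ppm_error(500, 0), "positive")
})

test_that("glycan classes partition compositions by decoration", {
  expect_identical(glycan_class(hmo_composition(hex = 2, fuc = 1)),
                   "fucosylated")
  expect_identical(glycan_class(hmo_composition(hex = 3, hexnac = 1)),
                   "neutral")
  expect_identical(glycan_class(hmo_composition(hex = 2, neu5ac = 1)),
                   "sialylated")
  expect_identical(glycan_class(hmo_composition(hex = 2, fuc = 1,
                                                neu5ac = 1)),
                   "fucosylated_sialylated")
  # every composition maps to exactly one class
  grid <- tidyr::crossing(hex = 1:3, hexnac = 0:2, fuc = 0:2, neu5ac = 0:2)
  cls <- glycan_class(grid)
  expect_true(all(cls %in% glycan_classes()))
  expect_length(cls, nrow(grid))
})

test_that("the packaged library is valid and library invariants are enforced", {
  lib <- hmo_library()
  expect_gte(nrow(lib), 25)
  expect_true(all(lib$reduced))
  expect_setequal(unique(lib$class),
                  c("neutral", "fucosylated", "sialylated"))
  # same-composition entries (true isomers) share their group label
  expect_identical(lib$isomer_group[lib$name == "LNT"],
                   lib$isomer_group[lib$name == "LNnT"])
  dup <- dplyr::bind_rows(lib, lib[1, ])
  expect_error(validate_hmo_library(dup), "unique")
  bad <- lib
  bad$isomer_group[bad$name == "LNnT"] <- "other"
  expect_error(validate_hmo_library(bad), "isomer_group")
  bad_rt <- lib
  bad_rt$rt_ref_min[1] <- -1
  expect_error(validate_hmo_library(bad_rt), "rt_ref_min")
})
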