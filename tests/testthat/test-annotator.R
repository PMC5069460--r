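test_that("decompose_mass matches the brute-force oracle on known masses", {
  cfg <- tolerance_config()
  # 2'FL alditol: the window holds exactly one composition
  got <- decompose_mass(490.1898, cfg, reduced = TRUE)
  expect_identical(as_comp_set(got),
                   data.frame(hex = 2L, hexnac = 0L, fuc = 1L,
                              neu5ac = 0L, row.names = 1L))
  # LNT/LNnT alditol: contains Hex3 HexNAc1; full set fixed by the oracle
  got <- decompose_mass(709.2641, cfg, reduced = TRUE)
  expect_true(any(got$hex == 3 & got$hexnac == 1 & got$fuc == 0 &
                    got$neu5ac == 0))
  expect_equal(as_comp_set(got), brute_force_decompose(709.2641),
               ignore_attr = TRUE)
  # below the smallest admissible mass
  expect_identical(nrow(decompose_mass(100.0, cfg)), 0L)
})

test_that("decompose_mass equals the oracle on random masses and is ordered", {
  cfg <- tolerance_config()
  set.seed(3)
  for (m in runif(30, 300, 2000)) {
    got <- decompose_mass(m, cfg, reduced = TRUE)
    expect_equal(as_comp_set(got), brute_force_decompose(m),
                 ignore_attr = TRUE, label = sprintf("mass %.4f", m))
    expect_true(all(abs(got$ppm) <= cfg$ppm_tol))
    expect_false(is.unsorted(abs(got$ppm)))
  }
})

test_that("enlarging the ppm window or DP bounds never removes a candidate", {
  set.seed(4)
  for (m in runif(10, 300, 1500)) {
    narrow <- as_comp_set(decompose_mass(m, tolerance_config(ppm_tol = 10)))
    wide <- as_comp_set(decompose_mass(m, tolerance_config(ppm_tol = 30)))
    expect_true(nrow(dplyr::anti_join(narrow, wide,
                                      by = names(narrow))) == 0L)
    tight_dp <- as_comp_set(decompose_mass(
      m, tolerance_config(dp_bounds = c(3L, 8L))))
    loose_dp <- as_comp_set(decompose_mass(
      m, tolerance_config(dp_bounds = c(2L, 32L))))
    expect_true(nrow(dplyr::anti_join(tight_dp, loose_dp,
                                      by = names(tight_dp))) == 0L)
  }
})

test_that("structure assignment is gated by RT and falls back gracefully", {
  lib <- hmo_library()
  cfg <- tolerance_config()
  rt_2fl <- lib$rt_ref_min[lib$name == "2'FL"]
  mass_2fl <- composition_mass(lib[lib$name == "2'FL", ])
  feats <- tibble::tibble(
    sample_id = "s1",
    mz = mz_from_mass(mass_2fl, 1L),
    charge = 1L,
    rt_min = c(rt_2fl + 0.1, rt_2fl + 20),  # far from every Hex2Fuc1 reference
    abundance = c(1000, 900)
  )
  ann <- annotate_features(feats, lib, cfg)
  expect_identical(ann$structure[1], "2'FL")
  expect_identical(ann$status[1], "assigned")
  expect_identical(ann$status[2], "composition-only")
  expect_true(is.na(ann$structure[2]))
  # empty library: never assigned, composition still determined
  ann0 <- annotate_features(feats, empty_library(), cfg)
  expect_true(all(ann0$status == "composition-only"))
  # a decoy-like mass yields no composition at all
  dec <- annotate_features(make_features("s1", 400.123, 5, 10),
                           lib, cfg)
  expect_identical(dec$status, "unassigned")
})

test_that("an exact RT tie between same-composition entries reports the group", {
  lib <- hmo_library()
  cfg <- tolerance_config(rt_tol = 2)
  rts <- lib$rt_ref_min[lib$name %in% c("LNT", "LNnT")]
  mid <- mean(rts)  # equidistant from both references
  feats <- make_features("s1", composition_mass(lib[lib$name == "LNT", ]),
                         mid, 1000)
  ann <- annotate_features(feats, lib, cfg)
  expect_identical(ann$structure, "LNT")  # the shared isomer-group label
  expect_identical(ann$isomer_group, "LNT")
})

test_that("annotation is invariant to input feature order", {
  lib <- hmo_library()
  set.seed(9)
  feats <- make_features(
    "s1", composition_mass(lib[1:10, ]),
    lib$rt_ref_min[1:10] + rnorm(10, 0, 0.05),
    runif(10, 1e3, 1e6))
  a <- annotate_features(feats, lib)
  perm <- sample(nrow(feats))
  b <- annotate_features(feats[perm, ], lib)
  b <- b[order(match(b$rt, a$rt)), ]
  expect_equal(b$structure, a$structure)
  expect_equal(b$abundance, a$abundance)
})

test_that("co-eluting same-composition peaks merge with abundance conserved", {
  lib <- hmo_library()
  cfg <- tolerance_config()
  m_fl <- composition_mass(hmo_composition(hex = 2, fuc = 1,
                                           reduced = TRUE))
  # two peaks 0.1 min apart sum; 2.4 min apart stay separate
  ann <- annotate_features(
    make_features("s1", rep(m_fl, 4), c(10.1, 10.2, 12.5, 30.0),
                  c(1000, 500, 800, 300)),
    empty_library(), cfg)
  g <- group_isomers(ann, cfg)
  expect_identical(nrow(g), 3L)
  expect_equal(sum(g$abundance), sum(ann$abundance))
  merged <- g[g$n_merged == 2L, ]
  expect_equal(merged$abundance, 1500)
  expect_equal(merged$rt, stats::weighted.mean(c(10.1, 10.2), c(1000, 500)))
  # transitive chaining: three peaks linked pairwise form one group
  chain <- group_isomers(
    annotate_features(
      make_features("s1", rep(m_fl, 3), c(10.0, 10.2, 10.4),
                    c(100, 200, 300)),
      empty_library(), cfg),
    cfg)
  expect_identical(nrow(chain), 1L)
  expect_equal(chain$abundance, 600)
  expect_identical(chain$n_merged, 3L)
})

test_that("a merged group of two assigned isomers takes the group label", {
  lib <- hmo_library()
  cfg <- tolerance_config(rt_tol = 0.5, coelution_tol = 3)
  m_lnt <- composition_mass(lib[lib$name == "LNT", ])
  rts <- lib$rt_ref_min[match(c("LNT", "LNnT"), lib$name)]
  ann <- annotate_features(
    make_features("s1", rep(m_lnt, 2), rts, c(700, 300)), lib, cfg)
  expect_setequal(ann$structure, c("LNT", "LNnT"))
  g <- group_isomers(ann, cfg)
  expect_identical(nrow(g), 1L)
  expect_identical(g$structure, "LNT")  # isomer-group label
  expect_equal(g$abundance, 1000)
})
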