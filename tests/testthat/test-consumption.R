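test_that("the label-free normalization evaluates its defining examples", {
  m <- make_matrix(control = c(A = 1000, B = 1000),
                   s = c(A = 500, B = 1000))
  tot <- total_consumption(m, "s", "control")
  expect_equal(tot$pct, 25)
  expect_identical(tot$n_structures, 2L)
  expect_false(tot$clamped)
  expect_equal(structure_consumption(m, "s", "control", "A")$pct, 50)
  expect_equal(structure_consumption(m, "s", "control", "B")$pct, 0)
  # identity, full depletion, overshoot clamping
  expect_equal(total_consumption(m, "control", "control")$pct, 0)
  zero <- make_matrix(control = c(A = 10, B = 20), s = c(A = 0, B = 0))
  expect_equal(total_consumption(zero, "s", "control")$pct, 100)
  dbl <- make_matrix(control = c(A = 10), s = c(A = 20))
  res <- total_consumption(dbl, "s", "control")
  expect_equal(res$pct, 0)
  expect_equal(res$raw, -100)
  expect_true(res$clamped)
  # degenerate control
  allz <- make_matrix(control = c(A = 0), s = c(A = 5))
  expect_error(total_consumption(allz, "s", "control"), "control")
})

test_that("a structure absent from the control is excluded with a warning", {
  m <- make_matrix(control = c(A = 100, B = 0), s = c(A = 50, B = 10))
  expect_warning(res <- structure_consumption(m, "s", "control", "B"),
                 "no control abundance")
  expect_true(is.na(res$pct))
})

test_that("total raw consumption is the control-weighted mean of structures", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    ctrl <- runif(n, 1, 1e6)
    smp <- runif(n, 0, 2e6)
    m <- make_matrix(control = stats::setNames(ctrl, paste0("g", 1:n)),
                     s = stats::setNames(smp, paste0("g", 1:n)))
    tot_raw <- total_consumption(m, "s", "control")$raw
    cons_raw <- (1 - smp / ctrl) * 100
    w <- ctrl / sum(ctrl)
    expect_equal(tot_raw, sum(w * cons_raw), tolerance = 1e-9)
    # scale invariance under joint rescaling
    k <- runif(1, 0.01, 100)
    expect_equal(total_consumption(m * k, "s", "control")$raw, tot_raw,
                 tolerance = 1e-9)
  }
})

test_that("decreasing any sample abundance never decreases total consumption", {
  set.seed(32)
  ctrl <- stats::setNames(runif(10, 10, 1000), paste0("g", 1:10))
  smp <- stats::setNames(runif(10, 0, 1000), paste0("g", 1:10))
  base <- total_consumption(make_matrix(control = ctrl, s = smp),
                            "s", "control")$raw
  for (i in 1:10) {
    smp2 <- smp
    smp2[i] <- smp2[i] * runif(1, 0, 0.9)
    after <- total_consumption(make_matrix(control = ctrl, s = smp2),
                               "s", "control")$raw
    expect_gte(after, base)
  }
})

test_that("class consumption restricts the sums and handles empty classes", {
  lib <- hmo_library()
  cfg <- tolerance_config()
  ann <- lapply(c(control = "control", s = "s"), function(id) {
    ab <- if (id == "control") rep(1000, 6) else
      c(0, 0, 0, 1000, 1000, 1000)  # fucosylated depleted, neutral intact
    sel <- lib[lib$name %in% c("2'FL", "3FL", "LDFT",
                               "LNT", "LNnT", "LNH"), ]
    group_isomers(annotate_features(
      make_features(id, composition_mass(sel), sel$rt_ref_min, ab),
      lib, cfg), cfg)
  })
  mat <- align_runs(dplyr::bind_rows(ann), cfg, reference = "control")
  expect_equal(class_consumption(mat, "s", "control", "fucosylated")$pct,
               100)
  expect_equal(class_consumption(mat, "s", "control", "neutral")$pct, 0)
  sial <- class_consumption(mat, "s", "control", "sialylated")
  expect_true(is.na(sial$pct))
  # a single-structure class equals that structure's consumption
  one <- make_matrix(control = c(A = 200), s = c(A = 50))
  expect_equal(total_consumption(one, "s", "control")$pct,
               structure_consumption(one, "s", "control", "A")$pct)
})

test_that("digestion percentages mirror the consumption rules", {
  m <- make_matrix(control = c(`2FL` = 100, LNT = 200),
                   dig = c(`2FL` = 0, LNT = 200))
  tab <- digestion_percent(m, "dig", "control")
  expect_equal(tab$pct[tab$structure == "2FL"], 100)  # fully removed
  expect_equal(tab$pct[tab$structure == "LNT"], 0)    # untouched
})

test_that("temporal profiles order depletion events and summarize replicates", {
  lib <- hmo_library()
  tps <- paste0("t", 1:4)
  prog <- tidyr::crossing(structure = lib$name, time_point = tps)
  prog$fraction <- 0.1
  prog$fraction[prog$structure == "2'FL" &
                  prog$time_point %in% c("t2", "t3", "t4")] <- 1
  prog$fraction[prog$structure == "LNT" & prog$time_point == "t4"] <- 1
  sim <- simulate_fermentation(simulation_spec(
    seed = 2, library = lib, consumption_program = prog, time_points = tps,
    n_decoys = 0L, replicates = 2L))
  res <- suppressMessages(
    run_pipeline(sim$features, sim$manifest, lib))
  prof <- res$profile
  first_dep <- function(label) {
    as.integer(min(which(
      prof$mean_pct[prof$label == label] >= 95)))
  }
  expect_lt(first_dep("2'FL"), first_dep("LNT"))
  expect_true(all(prof$n_replicates == 2L))
  expect_true(all(is.finite(prof$sd_pct)))
  # single replicate: sd is absent
  sim1 <- simulate_fermentation(simulation_spec(
    seed = 2, library = lib, consumption_program = prog, time_points = tps,
    n_decoys = 0L, replicates = 1L))
  res1 <- suppressMessages(run_pipeline(sim1$features, sim1$manifest, lib))
  expect_true(all(is.na(res1$profile$sd_pct)))
  # a zero-consumption program stays flat near 0 within noise
  prog0 <- dplyr::mutate(prog, fraction = 0)
  sim0 <- simulate_fermentation(simulation_spec(
    seed = 3, library = lib, consumption_program = prog0,
    time_points = tps, n_decoys = 0L))
  res0 <- suppressMessages(run_pipeline(sim0$features, sim0$manifest, lib))
  tot0 <- res0$consumption[res0$consumption$level == "total", ]
  expect_true(all(abs(tot0$raw) < 10))
})
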