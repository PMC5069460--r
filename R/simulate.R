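# Seeded generators for every input the pipeline consumes. The statistical
# model mirrors what the analysis assumes about the measurement process:
# ion-count abundances spanning orders of magnitude (log-normal across
# structures), multiplicative log-normal intensity noise within a run,
# Gaussian ppm mass error truncated at the annotation window, Gaussian RT
# jitter, and decoy features placed >= 25 ppm from every library mass so
# annotator precision is exactly scorable.

rtrunc_norm <- function(n, sd, max_abs) {
  if (sd == 0) return(rep(0, n))
  x <- stats::rnorm(n, 0, sd)
  while (any(bad <- abs(x) > max_abs)) {
    x[bad] <- stats::rnorm(sum(bad), 0, sd)
  }
  x
}

lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))  # mean-1 multiplicative noise
}

#' Default HMO consumption program
#'
#' Consumption fractions per structure and time point emulating preferential
#' fucosylated-HMO utilization: fucosylated structures are depleted early
#' and nearly completely, neutral core structures mostly late, sialylated
#' structures partially.
#'
#' @param library A validated structure library.
#' @param time_points Ordered time-point labels (defaults to the four
#'   exponential-phase sampling points at OD600 0.2, 0.4, 0.6, 0.75).
#' @return A tibble with `structure`, `time_point`, `fraction`.
#' @export
default_consumption_program <- function(
    library = hmo_library(),
    time_points = c("od0.2", "od0.4", "od0.6", "od0.75")) {
  library <- validate_hmo_library(library)
  ramp <- list(
    fucosylated            = c(0.55, 0.85, 0.95, 0.97),
    fucosylated_sialylated = c(0.55, 0.85, 0.95, 0.97),
    neutral                = c(0.05, 0.15, 0.45, 0.80),
    sialylated             = c(0.02, 0.10, 0.20, 0.40)
  )
  idx <- round(seq(1, 4, length.out = length(time_points)))
  tidyr::crossing(structure = library$name,
                  time_point = factor(time_points, levels = time_points)) |>
    dplyr::mutate(
      class = library$class[match(.data$structure, library$name)],
      fraction = vapply(seq_along(.data$structure), function(i) {
        ramp[[.data$class[i]]][idx[match(.data$time_point[i], time_points)]]
      }, numeric(1)),
      time_point = as.character(.data$time_point)
    ) |>
    dplyr::select("structure", "time_point", "fraction")
}

#' Specification of a simulated fermentation experiment
#'
#' Bundles every knob of the generator. Defaults reproduce the design of the
#' profiled fermentations: triplicate sampling at four exponential-phase
#' time points, 5 ppm mass-error sd truncated at the 20 ppm annotation
#' window, small RT jitter, 5% multiplicative intensity noise, and a decoy
#' contingent of unannotatable features.
#'
#' @param seed Integer seed; identical seed and spec give identical output.
#' @param library A structure library tibble.
#' @param control_median Median control-pool abundance, ion counts.
#' @param control_cv Coefficient of variation of the log-normal abundance
#'   spread across structures (2 spans roughly an order of magnitude).
#' @param consumption_program Tibble `structure`, `time_point`, `fraction`
#'   of true consumed fraction in \[0, 1\].
#' @param time_points Ordered time-point labels.
#' @param noise_cv Multiplicative intensity noise CV per measurement.
#' @param mass_error_ppm_sd Gaussian sd of the ppm mass error.
#' @param mass_error_ppm_max Truncation bound of the mass error, ppm.
#' @param rt_jitter_sd Gaussian sd of retention-time jitter, minutes.
#' @param n_decoys Decoy features per sample.
#' @param decoy_min_ppm Minimum ppm distance of decoys from any library mass.
#' @param replicates Replicates per time point.
#' @param charge Charge state of the simulated protonated ions.
#' @return A list of class `simulation_spec`.
#' @export
simulation_spec <- function(seed = 1L, library = hmo_library(),
                            control_median = 1e6, control_cv = 2,
                            consumption_program = NULL,
                            time_points = c("od0.2", "od0.4",
                                            "od0.6", "od0.75"),
                            noise_cv = 0.05, mass_error_ppm_sd = 5,
                            mass_error_ppm_max = 20, rt_jitter_sd = 0.1,
                            n_decoys = 10L, decoy_min_ppm = 25,
                            replicates = 3L, charge = 1L) {
  library <- validate_hmo_library(library)
  if (is.null(consumption_program)) {
    consumption_program <- default_consumption_program(library, time_points)
  }
  stopifnot(all(consumption_program$fraction >= 0),
            all(consumption_program$fraction <= 1),
            noise_cv >= 0, mass_error_ppm_sd >= 0, rt_jitter_sd >= 0,
            control_median > 0, replicates >= 1, n_decoys >= 0,
            decoy_min_ppm > 0)
  structure(
    list(seed = as.integer(seed), library = library,
         control_median = control_median, control_cv = control_cv,
         consumption_program = consumption_program,
         time_points = time_points, noise_cv = noise_cv,
         mass_error_ppm_sd = mass_error_ppm_sd,
         mass_error_ppm_max = mass_error_ppm_max,
         rt_jitter_sd = rt_jitter_sd, n_decoys = as.integer(n_decoys),
         decoy_min_ppm = decoy_min_ppm, replicates = as.integer(replicates),
         charge = as.integer(charge)),
    class = "simulation_spec"
  )
}

observe_features <- function(spec, sample_id, abundance) {
  lib <- spec$library
  mass_th <- composition_mass(lib)
  eps <- rtrunc_norm(nrow(lib), spec$mass_error_ppm_sd,
                     spec$mass_error_ppm_max)
  tibble::tibble(
    sample_id = sample_id,
    mz = mz_from_mass(mass_th * (1 + eps * 1e-6), spec$charge),
    charge = spec$charge,
    rt_min = lib$rt_ref_min + stats::rnorm(nrow(lib), 0, spec$rt_jitter_sd),
    abundance = abundance,
    source = lib$name
  )
}

decoy_features <- function(spec, sample_id) {
  if (spec$n_decoys == 0L) return(NULL)
  lib_mass <- composition_mass(spec$library)
  draw_one <- function() {
    repeat {
      m <- stats::runif(1, 350, 1800)
      if (min(abs(ppm_error(m, lib_mass))) >= spec$decoy_min_ppm) return(m)
    }
  }
  masses <- vapply(seq_len(spec$n_decoys), function(i) draw_one(), numeric(1))
  tibble::tibble(
    sample_id = sample_id,
    mz = mz_from_mass(masses, spec$charge),
    charge = spec$charge,
    rt_min = stats::runif(spec$n_decoys, 2, 45),
    abundance = spec$control_median / 10 * lognoise(spec$n_decoys, 1),
    source = "decoy"
  )
}

#' Simulate a fermentation glycoprofiling experiment
#'
#' Draws a control pool (abundances log-normal across structures), then for
#' every time point and replicate generates a sample whose structure
#' abundances are `control * (1 - programmed fraction) * noise`, observed
#' with ppm mass error, RT jitter and added decoys. The programmed truth
#' table is returned alongside, sufficient to score every downstream output.
#'
#' @param spec A [simulation_spec()].
#' @return A list of class `hmo_simulation` with `features` (one validated
#'   feature tibble covering the control and all samples; the `source`
#'   column carries the generating structure or `"decoy"`), `manifest`,
#'   `truth` and `spec`.
#' @export
simulate_fermentation <- function(spec = simulation_spec()) {
  set.seed(spec$seed)
  lib <- spec$library
  base <- spec$control_median *
    exp(stats::rnorm(nrow(lib), 0, sqrt(log(1 + spec$control_cv^2))))
  tabs <- list(dplyr::bind_rows(observe_features(spec, "control", base),
                                decoy_features(spec, "control")))
  rows <- list()
  for (tp in spec$time_points) {
    frac <- spec$consumption_program$fraction[
      match(paste(lib$name, tp),
            paste(spec$consumption_program$structure,
                  spec$consumption_program$time_point))]
    if (any(is.na(frac))) {
      stop("consumption program misses structures at time point ", tp,
           call. = FALSE)
    }
    for (r in seq_len(spec$replicates)) {
      id <- paste0(tp, "_r", r)
      ab <- base * (1 - frac) * lognoise(nrow(lib), spec$noise_cv)
      tabs[[length(tabs) + 1L]] <-
        dplyr::bind_rows(observe_features(spec, id, ab),
                         decoy_features(spec, id))
      rows[[length(rows) + 1L]] <-
        tibble::tibble(sample_id = id, role = "fermentation",
                       time_point = tp, replicate = r)
    }
  }
  manifest <- validate_manifest(list(control_id = "control",
                                     samples = dplyr::bind_rows(rows)))
  features <- validate_features(dplyr::bind_rows(tabs),
                                context = "simulated features")
  truth <- dplyr::mutate(
    spec$consumption_program,
    class = lib$class[match(.data$structure, lib$name)]
  )
  structure(list(features = features, manifest = manifest, truth = truth,
                 spec = spec),
            class = "hmo_simulation")
}

#' Simulate an enzyme-digestion experiment
#'
#' One undigested reference pool plus replicate digested pools in which each
#' structure is removed by its programmed digestion fraction, observed with
#' the same noise model as [simulate_fermentation()].
#'
#' @param spec A [simulation_spec()]; `replicates` sets the number of
#'   digested runs.
#' @param fractions Named numeric vector (names = structure names) or tibble
#'   with `structure` and `fraction`: true digested fraction in \[0, 1\].
#'   Structures not named are undigested.
#' @return A list of class `hmo_simulation` with `features`, `manifest`,
#'   `truth`, `spec`.
#' @export
simulate_digestion <- function(spec = simulation_spec(), fractions) {
  if (is.data.frame(fractions)) {
    fractions <- stats::setNames(fractions$fraction, fractions$structure)
  }
  lib <- spec$library
  unknown <- setdiff(names(fractions), lib$name)
  if (length(unknown)) {
    stop("unknown structures in digestion fractions: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  frac <- stats::setNames(rep(0, nrow(lib)), lib$name)
  frac[names(fractions)] <- fractions
  stopifnot(all(frac >= 0), all(frac <= 1))
  set.seed(spec$seed)
  base <- spec$control_median *
    exp(stats::rnorm(nrow(lib), 0, sqrt(log(1 + spec$control_cv^2))))
  tabs <- list(dplyr::bind_rows(observe_features(spec, "undigested", base),
                                decoy_features(spec, "undigested")))
  rows <- list()
  for (r in seq_len(spec$replicates)) {
    id <- paste0("digested_r", r)
    ab <- base * (1 - frac) * lognoise(nrow(lib), spec$noise_cv)
    tabs[[length(tabs) + 1L]] <-
      dplyr::bind_rows(observe_features(spec, id, ab),
                       decoy_features(spec, id))
    rows[[length(rows) + 1L]] <-
      tibble::tibble(sample_id = id, role = "digestion",
                     time_point = "digested", replicate = r)
  }
  manifest <- validate_manifest(list(control_id = "undigested",
                                     samples = dplyr::bind_rows(rows)))
  features <- validate_features(dplyr::bind_rows(tabs),
                                context = "simulated digestion")
  truth <- tibble::tibble(structure = lib$name, fraction = unname(frac),
                          class = lib$class)
  structure(list(features = features, manifest = manifest, truth = truth,
                 spec = spec),
            class = "hmo_simulation")
}

#' Write a simulation to disk
#'
#' Writes `features.csv`, `manifest.yaml` and `truth.tsv` in the dialects
#' the package readers accept.
#'
#' @param sim An `hmo_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_features(sim$features, file.path(dir, "features.csv"))
  write_manifest(sim$manifest, file.path(dir, "manifest.yaml"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}

#' Simulate microplate growth curves
#'
#' Logistic growth toward a programmed plateau on top of a constant blank,
#' with Gaussian read noise, plus blank rows per substrate and a no-sugar
#' control per strain.
#'
#' @param truth Tibble with `strain`, `substrate`, `plateau_od`.
#' @param seed Integer seed.
#' @param blank_od Constant medium blank OD600.
#' @param no_sugar_plateau Plateau of the inoculated no-sugar control.
#' @param rate Logistic growth rate, per hour.
#' @param n0 Inoculum OD600.
#' @param t_max,dt Time range and reading interval, hours.
#' @param noise_sd Gaussian read noise sd, OD units.
#' @return A readings tibble in the [read_growth()] layout, with a `role`
#'   column.
#' @export
simulate_growth <- function(truth, seed = 1L, blank_od = 0.05,
                            no_sugar_plateau = 0.05, rate = 0.4, n0 = 0.01,
                            t_max = 48, dt = 0.5, noise_sd = 0.005) {
  set.seed(seed)
  times <- seq(0, t_max, by = dt)
  logistic <- function(k) {
    k * n0 * exp(rate * times) / (k + n0 * (exp(rate * times) - 1))
  }
  curve_rows <- function(strain, substrate, role, k) {
    tibble::tibble(
      strain = strain, substrate = substrate, role = role, time_h = times,
      od600 = blank_od + (if (is.na(k)) 0 else logistic(k)) +
        stats::rnorm(length(times), 0, noise_sd)
    )
  }
  out <- lapply(seq_len(nrow(truth)), function(i) {
    curve_rows(truth$strain[i], truth$substrate[i], "sample",
               truth$plateau_od[i])
  })
  for (sub in unique(truth$substrate)) {
    out[[length(out) + 1L]] <- curve_rows("blank", sub, "blank", NA)
  }
  for (st in unique(truth$strain)) {
    out[[length(out) + 1L]] <-
      curve_rows(st, "no_sugar", "no_sugar", no_sugar_plateau)
  }
  dplyr::bind_rows(out)
}

#' Simulate a glycan-array replicate table
#'
#' Six replicates per glycan around a programmed true RFU with
#' multiplicative noise; optionally one injected outlier per replicate set
#' (a single replicate inflated or deflated by `outlier_factor`), which the
#' six-replicate trimmed mean is designed to absorb.
#'
#' @param truth Tibble with `glycan_string`, `rfu` and optionally `sbp`.
#' @param seed Integer seed.
#' @param noise_cv Multiplicative replicate noise CV.
#' @param outlier Inject one outlier per replicate set?
#' @param outlier_factor Magnitude of the outlier (one replicate is
#'   multiplied by this factor or divided by it, at random).
#' @return A tibble in the [read_glycan_array()] layout.
#' @export
simulate_array <- function(truth, seed = 1L, noise_cv = 0.05,
                           outlier = TRUE, outlier_factor = 10) {
  set.seed(seed)
  if (!"sbp" %in% names(truth)) truth$sbp <- "protein"
  reps <- t(vapply(seq_len(nrow(truth)), function(i) {
    r <- truth$rfu[i] * lognoise(6L, noise_cv)
    if (outlier) {
      j <- sample.int(6L, 1L)
      r[j] <- r[j] * outlier_factor^(sample(c(-1, 1), 1L))
    }
    r
  }, numeric(6)))
  colnames(reps) <- paste0("rfu_", 1:6)
  dplyr::bind_cols(truth[, c("sbp", "glycan_string")],
                   tibble::as_tibble(reps))
}

#' @export
print.hmo_simulation <- function(x, ...) {
  cat("<hmo_simulation>", nrow(x$features), "features |",
      nrow(x$manifest$samples), "samples + control | seed",
      x$spec$seed, "\n")
  invisible(x)
}
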