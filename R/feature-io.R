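#' Matching and classification tolerances
#'
#' Every matching decision in the pipeline reads from one tolerance
#' configuration: the accurate-mass window (ppm), the retention-time window
#' for library assignment, the tighter co-elution window for isomer grouping,
#' the acquisition m/z range, the admissible degree-of-polymerization range
#' for composition decomposition, and the interval convention used at growth
#' classification boundaries.
#'
#' @param ppm_tol Accurate-mass tolerance, ppm (default 20, the standard
#'   annotation window for TOF glycan profiling).
#' @param rt_tol Retention-time tolerance for library assignment, minutes.
#' @param coelution_tol Maximum RT gap for two same-composition peaks to be
#'   summed as unresolved co-eluting isomers, minutes.
#' @param mz_window Acquisition m/z range, length-2 numeric.
#' @param dp_bounds Admissible degree of polymerization (residue count),
#'   length-2 integer.
#' @param growth_breaks OD600 cut points for the -, +, ++, +++ growth
#'   classes.
#' @param growth_boundary `"left-closed"` (default) places a boundary value
#'   in the upper class (half-open `[lo, hi)` intervals, so OD 0.5 is "++");
#'   `"right-closed"` places it in the lower class.
#' @return A list of class `tolerance_config`.
#' @export
tolerance_config <- function(ppm_tol = 20, rt_tol = 0.5, coelution_tol = 0.25,
                             mz_window = c(300, 2000), dp_bounds = c(2L, 32L),
                             growth_breaks = c(0.2, 0.5, 0.8),
                             growth_boundary = c("left-closed",
                                                 "right-closed")) {
  growth_boundary <- match.arg(growth_boundary)
  stopifnot(ppm_tol > 0, rt_tol > 0, coelution_tol > 0,
            length(mz_window) == 2, mz_window[1] < mz_window[2],
            length(dp_bounds) == 2, dp_bounds[1] >= 1,
            dp_bounds[1] <= dp_bounds[2],
            length(growth_breaks) == 3, !is.unsorted(growth_breaks))
  structure(
    list(ppm_tol = ppm_tol, rt_tol = rt_tol, coelution_tol = coelution_tol,
         mz_window = as.numeric(mz_window),
         dp_bounds = as.integer(dp_bounds),
         growth_breaks = as.numeric(growth_breaks),
         growth_boundary = growth_boundary),
    class = "tolerance_config"
  )
}

#' @export
print.tolerance_config <- function(x, ...) {
  cat("<tolerance_config>\n",
      sprintf("  ppm_tol: %g ppm | rt_tol: %g min | coelution_tol: %g min\n",
              x$ppm_tol, x$rt_tol, x$coelution_tol),
      sprintf("  mz_window: [%g, %g] | dp_bounds: [%d, %d]\n",
              x$mz_window[1], x$mz_window[2], x$dp_bounds[1], x$dp_bounds[2]),
      sprintf("  growth breaks: %s (%s)\n",
              paste(x$growth_breaks, collapse = ", "), x$growth_boundary),
      sep = "")
  invisible(x)
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read an LC-MS feature table
#'
#' A feature table holds one row per detected peak in one or more samples:
#' `sample_id`, either `mz` + `charge` or `neutral_mass` (exactly one mass
#' convention per table, declared by the header), `rt_min` and `abundance`
#' (absolute peak intensity, API, in ion counts). The delimiter (comma or
#' tab) is sniffed from the header line. Rows are validated, never silently
#' dropped: any invariant violation is a row-addressed error.
#'
#' @param path Path to a CSV/TSV feature table.
#' @param cfg A [tolerance_config()]; `mz` values are checked against its
#'   acquisition window.
#' @return A tibble of features in file order, with attribute
#'   `mass_convention` set to `"mz"` or `"neutral_mass"`.
#' @export
read_features <- function(path, cfg = tolerance_config()) {
  if (!file.exists(path)) stop("feature table not found: ", path,
                               call. = FALSE)
  feats <- readr::read_delim(path, delim = sniff_delim(path),
                             show_col_types = FALSE, progress = FALSE)
  validate_features(feats, cfg, context = path)
}

#' Validate an in-memory feature table
#'
#' @inheritParams read_features
#' @param feats A feature tibble.
#' @param context Label used in error messages (e.g. the file path).
#' @return The validated tibble with a `mass_convention` attribute.
#' @export
validate_features <- function(feats, cfg = tolerance_config(),
                              context = "feature table") {
  has_mz <- "mz" %in% names(feats)
  has_nm <- "neutral_mass" %in% names(feats)
  if (has_mz && has_nm) {
    stop(context, ": mixed mass conventions; declare either mz or ",
         "neutral_mass, not both", call. = FALSE)
  }
  if (!has_mz && !has_nm) {
    stop(context, ": missing mass column (mz or neutral_mass)", call. = FALSE)
  }
  need <- c("sample_id", "rt_min", "abundance", if (has_mz) "charge")
  miss <- setdiff(need, names(feats))
  if (length(miss)) {
    stop(context, ": missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_row <- function(ok, what) {
    if (any(!ok)) {
      stop(context, ": ", what, " at row ", which(!ok)[1], call. = FALSE)
    }
  }
  bad_row(is.finite(feats$abundance) & feats$abundance >= 0,
          "negative or missing abundance")
  bad_row(is.finite(feats$rt_min) & feats$rt_min > 0,
          "non-positive retention time")
  if (has_mz) {
    bad_row(is.finite(feats$charge) & feats$charge >= 1 &
              feats$charge == as.integer(feats$charge), "invalid charge")
    bad_row(feats$mz >= cfg$mz_window[1] & feats$mz <= cfg$mz_window[2],
            "m/z outside the declared acquisition window")
  } else {
    bad_row(is.finite(feats$neutral_mass) & feats$neutral_mass > 0,
            "non-positive neutral mass")
  }
  attr(feats, "mass_convention") <- if (has_mz) "mz" else "neutral_mass"
  feats
}

#' Write an LC-MS feature table
#'
#' Inverse of [read_features()]: writing then reading preserves values to the
#' declared precision.
#'
#' @param feats A feature tibble.
#' @param path Output path; extension `.tsv` selects tab, otherwise comma.
#' @return `path`, invisibly.
#' @export
write_features <- function(feats, path) {
  if (grepl("\\.tsv$", path)) {
    readr::write_tsv(feats, path, progress = FALSE)
  } else {
    readr::write_csv(feats, path, progress = FALSE)
  }
  invisible(path)
}

#' Read a sample manifest
#'
#' The manifest is a YAML file binding sample identifiers to the experiment
#' design: `control_id` names the uninoculated pool run as external standard,
#' and `samples` lists `{sample_id, role, time_point, replicate}` entries
#' with role `"fermentation"` or `"digestion"`. Time points keep their
#' manifest order (the sampling order along the growth curve, e.g. OD600
#' 0.2, 0.4, 0.6, 0.75).
#'
#' @param path Path to the YAML manifest.
#' @return A list of class `sample_manifest` with elements `control_id`,
#'   `samples` (a tibble) and `time_points` (ordered unique labels).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  samples <- dplyr::bind_rows(lapply(raw$samples, tibble::as_tibble))
  validate_manifest(list(control_id = raw$control_id, samples = samples))
}

#' Validate a sample manifest
#'
#' @param manifest A list with `control_id` and a `samples` tibble
#'   (`sample_id`, `role`, `time_point`, `replicate`).
#' @return A validated `sample_manifest` object.
#' @export
validate_manifest <- function(manifest) {
  if (is.null(manifest$control_id) || !nzchar(manifest$control_id)) {
    stop("manifest must name a control_id (the uninoculated pool)",
         call. = FALSE)
  }
  s <- manifest$samples
  need <- c("sample_id", "role", "time_point", "replicate")
  miss <- setdiff(need, names(s))
  if (length(miss)) {
    stop("manifest samples are missing fields: ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(s$role %in% c("fermentation", "digestion"))) {
    stop("sample role must be 'fermentation' or 'digestion'", call. = FALSE)
  }
  if (anyDuplicated(s$sample_id)) {
    stop("duplicate sample_id in manifest", call. = FALSE)
  }
  key <- paste(s$role, s$time_point, s$replicate)
  if (anyDuplicated(key)) {
    stop("duplicate (time_point, replicate) pair within a role: ",
         key[duplicated(key)][1], call. = FALSE)
  }
  structure(
    list(control_id = manifest$control_id, samples = tibble::as_tibble(s),
         time_points = unique(s$time_point)),
    class = "sample_manifest"
  )
}

#' Write a sample manifest
#'
#' @param manifest A `sample_manifest` (see [read_manifest()]).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(
    list(control_id = manifest$control_id,
         samples = lapply(seq_len(nrow(manifest$samples)), function(i) {
           as.list(manifest$samples[i, ])
         })),
    path
  )
  invisible(path)
}

#' @export
print.sample_manifest <- function(x, ...) {
  cat("<sample_manifest> control:", x$control_id, "|",
      nrow(x$samples), "samples |", "time points:",
      paste(x$time_points, collapse = ", "), "\n")
  invisible(x)
}
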