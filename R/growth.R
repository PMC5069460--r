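#' Classify growth from maximum OD600
#'
#' Four-level classification used for strain-by-substrate growth grids:
#' `-` negative (max OD600 < 0.2), `+` low (0.2 to 0.5), `++` moderate
#' (0.5 to 0.8), `+++` high (> 0.8). The printed intervals share endpoints,
#' so the boundary convention is made explicit: the default half-open
#' `[lo, hi)` convention places OD 0.5 in `++`; `"right-closed"` places it
#' in `+`.
#'
#' @param max_od Numeric vector of maximum blank-corrected OD600 values.
#' @param cfg A [tolerance_config()] supplying `growth_breaks` and
#'   `growth_boundary`.
#' @return Character vector in `c("-", "+", "++", "+++")`.
#' @examples
#' classify_growth(c(0.15, 0.5, 0.9))
#' @export
classify_growth <- function(max_od, cfg = tolerance_config()) {
  stopifnot(all(is.finite(max_od)))
  idx <- findInterval(max_od, cfg$growth_breaks,
                      left.open = cfg$growth_boundary == "right-closed")
  c("-", "+", "++", "+++")[idx + 1L]
}

interp_onto <- function(curve, times, what) {
  if (min(curve$time_h) > min(times) || max(curve$time_h) < max(times)) {
    stop(what, " curve does not cover the sample time range", call. = FALSE)
  }
  stats::approx(curve$time_h, curve$od600, xout = times, ties = mean)$y
}

#' Summarize one growth curve
#'
#' Subtracts the blank (un-inoculated medium with substrate, interpolated
#' onto the sample's time grid), takes the maximum corrected OD600, compares
#' it with the no-sugar control's maximum (the same blank is applied to
#' both), and classifies growth from the maximum OD per the footnote
#' thresholds.
#'
#' @param curve A tibble with `time_h` (strictly increasing) and `od600`.
#' @param blank Optional blank curve on an overlapping time range; `NULL`
#'   means readings are already blank-corrected.
#' @param no_sugar Optional no-sugar control curve (raw, same blank
#'   treatment); `NULL` leaves `delta_od` as `NA`.
#' @param cfg A [tolerance_config()].
#' @return A one-row tibble with `max_od`, `delta_od`, `growth_class`.
#' @export
summarize_growth <- function(curve, blank = NULL, no_sugar = NULL,
                             cfg = tolerance_config()) {
  stopifnot(all(c("time_h", "od600") %in% names(curve)))
  if (is.unsorted(curve$time_h, strictly = TRUE)) {
    stop("curve times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(curve$od600))) {
    stop("curve OD values must be finite", call. = FALSE)
  }
  corrected <- curve$od600
  if (!is.null(blank)) {
    corrected <- corrected - interp_onto(blank, curve$time_h, "blank")
  }
  max_od <- max(corrected)
  delta_od <- NA_real_
  if (!is.null(no_sugar)) {
    ns <- no_sugar$od600
    if (!is.null(blank)) {
      ns <- ns - interp_onto(blank, no_sugar$time_h, "blank")
    }
    delta_od <- max_od - max(ns)
  }
  tibble::tibble(max_od = max_od, delta_od = delta_od,
                 growth_class = classify_growth(max_od, cfg))
}

#' Read microplate growth curves
#'
#' Expects a CSV/TSV with columns `strain`, `substrate`, `time_h`, `od600`
#' and optionally `role` (`"sample"`, `"blank"` for un-inoculated medium
#' with substrate, `"no_sugar"` for the inoculated no-sugar control;
#' missing roles default to `"sample"`).
#'
#' @param path Path to the file.
#' @return A tibble of readings.
#' @export
read_growth <- function(path) {
  if (!file.exists(path)) stop("growth file not found: ", path,
                               call. = FALSE)
  g <- readr::read_delim(path, delim = sniff_delim(path),
                         show_col_types = FALSE, progress = FALSE)
  need <- c("strain", "substrate", "time_h", "od600")
  miss <- setdiff(need, names(g))
  if (length(miss)) {
    stop("growth table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"role" %in% names(g)) g$role <- "sample"
  g$role[is.na(g$role)] <- "sample"
  g
}

#' Strain-by-substrate growth summary grid
#'
#' Applies [summarize_growth()] to every (strain, substrate) sample curve in
#' a readings table, using that substrate's blank row set and the strain's
#' no-sugar control, and returns a reconstructed growth grid (one row per
#' strain and substrate with `max_od`, `delta_od` and the symbol class).
#'
#' @param readings A tibble from [read_growth()].
#' @param cfg A [tolerance_config()].
#' @return A tibble with `strain`, `substrate`, `max_od`, `delta_od`,
#'   `growth_class`.
#' @export
growth_table <- function(readings, cfg = tolerance_config()) {
  samples <- readings[readings$role == "sample", ]
  keys <- unique(samples[, c("strain", "substrate")])
  dplyr::bind_rows(lapply(seq_len(nrow(keys)), function(i) {
    strain <- keys$strain[i]; substrate <- keys$substrate[i]
    curve <- samples[samples$strain == strain &
                       samples$substrate == substrate, ]
    blank <- readings[readings$role == "blank" &
                        readings$substrate == substrate, ]
    ns <- readings[readings$role == "no_sugar" &
                     readings$strain == strain, ]
    res <- summarize_growth(
      curve,
      blank = if (nrow(blank)) blank else NULL,
      no_sugar = if (nrow(ns)) ns else NULL,
      cfg = cfg
    )
    dplyr::bind_cols(tibble::tibble(strain = strain, substrate = substrate),
                     res)
  }))
}
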