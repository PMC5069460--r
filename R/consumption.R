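# Eq.-style label-free normalization: raw percent consumption of a sample
# column against the external-standard (control) column,
#   raw = (1 - sum(API_sample) / sum(API_control)) * 100,
# over the n identified structures with control API > 0. Negative raw values
# (sample > control, possible under noise) are clamped to 0 and flagged;
# abundances are non-negative so raw never exceeds 100.

clamp_pct <- function(raw) {
  raw <- unname(raw)
  tibble::tibble(pct = pmin(pmax(raw, 0), 100), raw = raw,
                 clamped = raw < 0)
}

api_columns <- function(mat, sample_id, control_id, assigned_only = TRUE) {
  m <- if (inherits(mat, "abundance_matrix")) mat$abundance else mat
  for (id in c(sample_id, control_id)) {
    if (!id %in% colnames(m)) {
      stop("sample '", id, "' is not a column of the abundance matrix",
           call. = FALSE)
    }
  }
  keep <- rep(TRUE, nrow(m))
  cls <- rep(NA_character_, nrow(m))
  if (inherits(mat, "abundance_matrix")) {
    cls <- mat$structures$class
    if (assigned_only) {
      keep <- mat$structures$assigned
      excluded <- sum(m[!keep, sample_id]) + sum(m[!keep, control_id])
      total <- sum(m[, sample_id]) + sum(m[, control_id])
      if (excluded > 0 && total > 0) {
        message(sprintf(
          "excluding %d non-library rows (%.1f%% of summed abundance) from consumption sums",
          sum(!keep), 100 * excluded / total))
      }
    }
  }
  tibble::tibble(label = rownames(m)[keep], class = cls[keep],
                 sample = m[keep, sample_id], control = m[keep, control_id])
}

#' Total percent HMO consumption of one sample
#'
#' Normalizes the summed abundance of all identified structures in the
#' sample to that of the uninoculated control pool:
#' `(1 - sum(API_sample) / sum(API_control)) * 100`, over the n structures
#' with positive control abundance. Only library-assigned rows (including
#' grouped isomers) enter the sums; composition-only rows are excluded with
#' a logged note.
#'
#' @param mat An `abundance_matrix` (see [align_runs()]) or a plain numeric
#'   matrix with sample columns.
#' @param sample_id,control_id Column names of the sample and of the
#'   uninoculated control pool.
#' @return A one-row tibble with `pct` (clamped to \[0, 100\]), `raw`,
#'   `clamped` and `n_structures`.
#' @export
total_consumption <- function(mat, sample_id, control_id) {
  cols <- api_columns(mat, sample_id, control_id)
  cols <- cols[cols$control > 0, ]
  if (nrow(cols) == 0L || sum(cols$control) <= 0) {
    stop("control column has no structure with positive abundance",
         call. = FALSE)
  }
  raw <- (1 - sum(cols$sample) / sum(cols$control)) * 100
  dplyr::mutate(clamp_pct(raw), n_structures = nrow(cols))
}

#' Percent consumption of a single structure
#'
#' Same normalization as [total_consumption()] restricted to one structure:
#' a structure absent from the sample column counts as fully consumed (100%);
#' a structure absent from the control pool cannot be normalized and is
#' reported as `NA` with a warning.
#'
#' @inheritParams total_consumption
#' @param structure Row label of the structure or isomer group.
#' @return A one-row tibble with `structure`, `pct`, `raw`, `clamped`.
#' @export
structure_consumption <- function(mat, sample_id, control_id, structure) {
  cols <- api_columns(mat, sample_id, control_id, assigned_only = FALSE)
  i <- match(structure, cols$label)
  if (is.na(i)) {
    stop("structure '", structure, "' is not a row of the matrix",
         call. = FALSE)
  }
  if (cols$control[i] <= 0) {
    warning("structure '", structure,
            "' has no control abundance; consumption undefined",
            call. = FALSE)
    return(tibble::tibble(structure = structure, pct = NA_real_,
                          raw = NA_real_, clamped = NA))
  }
  raw <- (1 - cols$sample[i] / cols$control[i]) * 100
  dplyr::bind_cols(tibble::tibble(structure = structure), clamp_pct(raw))
}

#' Percent consumption of a glycan class
#'
#' The total-consumption normalization restricted to assigned structures of
#' one glycan class (neutral, fucosylated, sialylated or
#' fucosylated_sialylated).
#'
#' @inheritParams total_consumption
#' @param cls A glycan class label (see [glycan_classes()]).
#' @return A one-row tibble with `class`, `pct`, `raw`, `clamped`,
#'   `n_structures`; `pct` is `NA` when the class is empty in the control.
#' @export
class_consumption <- function(mat, sample_id, control_id, cls) {
  stopifnot(cls %in% glycan_classes())
  cols <- api_columns(mat, sample_id, control_id)
  cols <- cols[!is.na(cols$class) & cols$class == cls & cols$control > 0, ]
  if (nrow(cols) == 0L) {
    return(tibble::tibble(class = cls, pct = NA_real_, raw = NA_real_,
                          clamped = NA, n_structures = 0L))
  }
  raw <- (1 - sum(cols$sample) / sum(cols$control)) * 100
  dplyr::bind_cols(tibble::tibble(class = cls),
                   dplyr::mutate(clamp_pct(raw), n_structures = nrow(cols)))
}

#' Full consumption summary of one sample
#'
#' Per-structure, per-class and total percent consumption of one sample
#' against the control pool, in one long tibble.
#'
#' @inheritParams total_consumption
#' @return A tibble with columns `sample_id`, `level` (`"total"`, `"class"`
#'   or `"structure"`), `label`, `pct`, `raw`, `clamped`, `n_structures`.
#' @export
consumption_summary <- function(mat, sample_id, control_id) {
  cols <- api_columns(mat, sample_id, control_id)
  cols <- cols[cols$control > 0, ]
  if (nrow(cols) == 0L) {
    stop("control column has no structure with positive abundance",
         call. = FALSE)
  }
  eq1 <- function(sub) (1 - sum(sub$sample) / sum(sub$control)) * 100
  tot <- dplyr::mutate(clamp_pct(eq1(cols)), n_structures = nrow(cols),
                       level = "total", label = "total")
  cls_levels <- intersect(glycan_classes(), unique(cols$class))
  cls <- dplyr::bind_rows(lapply(cls_levels, function(k) {
    sub <- cols[!is.na(cols$class) & cols$class == k, ]
    dplyr::mutate(clamp_pct(eq1(sub)), n_structures = nrow(sub),
                  level = "class", label = k)
  }))
  str_raw <- (1 - cols$sample / cols$control) * 100
  str <- dplyr::mutate(clamp_pct(str_raw), label = cols$label,
                       level = "structure", n_structures = 1L)
  out <- dplyr::bind_rows(tot, cls, str)
  dplyr::select(dplyr::mutate(out, sample_id = sample_id),
                "sample_id", "level", "label", "pct", "raw", "clamped",
                "n_structures")
}

#' Per-structure enzymatic digestion percentages
#'
#' Applies the same label-free normalization with the undigested pool as the
#' reference: percent digestion of every assigned structure, heat-map-ready
#' (long format).
#'
#' @param mat An `abundance_matrix` holding the undigested and digested
#'   pools as columns.
#' @param digested_id,undigested_id Column names of the digested sample and
#'   the undigested reference pool.
#' @return A long tibble with `structure`, `class`, `pct`, `raw`, `clamped`.
#' @export
digestion_percent <- function(mat, digested_id, undigested_id) {
  cols <- api_columns(mat, digested_id, undigested_id)
  skipped <- cols$label[cols$control <= 0]
  if (length(skipped)) {
    warning("no undigested-pool abundance for: ",
            paste(skipped, collapse = ", "), "; excluded", call. = FALSE)
  }
  cols <- cols[cols$control > 0, ]
  raw <- (1 - cols$sample / cols$control) * 100
  dplyr::bind_cols(tibble::tibble(structure = cols$label,
                                  class = cols$class),
                   clamp_pct(raw))
}

#' Consumption trajectories across fermentation time points
#'
#' Computes consumption per replicate at every time point, then summarizes
#' each (time point, label) as mean and standard deviation across
#' replicates. Replicates are aggregated on the raw (unclamped) per-replicate
#' percentages — averaging after clamping would bias low-consumption
#' structures upward — and the reported mean is then clamped to \[0, 100\].
#'
#' @param mat An `abundance_matrix` containing the control and all
#'   fermentation sample columns.
#' @param manifest A `sample_manifest` (see [read_manifest()]); time points
#'   keep their manifest order.
#' @param level `"total"`, `"class"` or `"structure"`.
#' @param control_id Control column; defaults to the manifest's.
#' @param role Manifest role to profile (default `"fermentation"`).
#' @return A tibble with `time_point` (ordered factor), `level`, `label`,
#'   `mean_pct` (clamped), `sd_pct` (`NA` with fewer than 2 replicates),
#'   `n_replicates`, `clamped`.
#' @export
temporal_profile <- function(mat, manifest,
                             level = c("total", "class", "structure"),
                             control_id = manifest$control_id,
                             role = "fermentation") {
  level <- match.arg(level)
  samples <- manifest$samples[manifest$samples$role == role, ]
  if (length(unique(samples$time_point)) < 2L) {
    stop("temporal profile needs at least two time points", call. = FALSE)
  }
  m <- if (inherits(mat, "abundance_matrix")) mat$abundance else mat
  present <- samples$sample_id %in% colnames(m)
  if (any(!present)) {
    message("missing sample columns skipped: ",
            paste(samples$sample_id[!present], collapse = ", "))
    samples <- samples[present, ]
  }
  per_rep <- dplyr::bind_rows(lapply(seq_len(nrow(samples)), function(i) {
    res <- consumption_summary(mat, samples$sample_id[i], control_id)
    res <- res[res$level == level, ]
    res$time_point <- samples$time_point[i]
    res$replicate <- samples$replicate[i]
    res
  }))
  out <- dplyr::summarise(
    dplyr::group_by(per_rep, .data$time_point, .data$level, .data$label),
    mean_raw = mean(.data$raw),
    sd_pct = if (dplyr::n() >= 2L) stats::sd(.data$raw) else NA_real_,
    n_replicates = dplyr::n(),
    .groups = "drop"
  )
  out$mean_pct <- pmin(pmax(out$mean_raw, 0), 100)
  out$clamped <- out$mean_raw < 0
  out$time_point <- factor(out$time_point, levels = manifest$time_points)
  dplyr::select(
    dplyr::arrange(out, .data$time_point, .data$label),
    "time_point", "level", "label", "mean_pct", "sd_pct",
    "n_replicates", "clamped", "mean_raw"
  )
}
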