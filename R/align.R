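#' Align annotated runs into a structure-by-sample abundance matrix
#'
#' Replaces vendor "in-house" peak alignment with an explicit, deterministic
#' rule set centred on the external-standard run: structure-assigned entries
#' align by name; composition-only entries align by greedy nearest-RT
#' clustering within each composition, seeded from the reference run (the
#' uninoculated control, the natural anchor since consumption is normalized
#' to it); entries with no composition cluster by mass (within `ppm_tol`) and
#' RT (within `rt_tol`) the same way. Every input entry contributes to
#' exactly one row, so column sums equal per-sample abundance totals.
#'
#' @param annotations A grouped annotation tibble covering all samples
#'   (rows from [group_isomers()], bound together), or a list of such
#'   tibbles.
#' @param cfg A [tolerance_config()].
#' @param reference Sample id used to seed composition-only clusters;
#'   defaults to the first sample present.
#' @return An object of class `abundance_matrix`: a list with `abundance`
#'   (numeric matrix, rows = structures/groups/clusters, columns = samples,
#'   0 where absent), `structures` (row metadata: label, composition, glycan
#'   class, `assigned` flag) and `provenance` (long tibble tracing every
#'   nonzero cell to its source feature ids).
#' @export
align_runs <- function(annotations, cfg = tolerance_config(),
                       reference = NULL) {
  if (is.list(annotations) && !is.data.frame(annotations)) {
    annotations <- dplyr::bind_rows(annotations)
  }
  sample_ids <- unique(annotations$sample_id)
  if (is.null(reference)) reference <- sample_ids[1]
  if (!reference %in% sample_ids) {
    stop("reference sample '", reference, "' has no annotations",
         call. = FALSE)
  }
  sample_ids <- c(reference, setdiff(sample_ids, reference))

  ann <- annotations
  ann$row_label <- NA_character_

  # 1. assigned structures align by name; duplicates within a sample are a
  #    conflict the grouping stage should have resolved.
  is_asg <- ann$status == "assigned"
  dup <- ann[is_asg, c("sample_id", "structure")]
  if (anyDuplicated(dup)) {
    d <- dup[duplicated(dup), ][1, ]
    stop("conflicting duplicate assignment of '", d$structure,
         "' in sample '", d$sample_id, "'", call. = FALSE)
  }
  ann$row_label[is_asg] <- ann$structure[is_asg]

  # 2. composition-only: greedy nearest-RT clustering per composition,
  #    reference clusters first, then samples in order, features by RT.
  is_co <- ann$status == "composition-only"
  for (comp in unique(ann$composition[is_co])) {
    sel <- which(is_co & ann$composition == comp)
    ann$row_label[sel] <- cluster_labels(
      ann$sample_id[sel], ann$rt[sel], sample_ids,
      prefix = comp, rt_tol = cfg$rt_tol
    )
  }

  # 3. no composition at all: cluster by (mass, RT) with a ppm gate.
  is_un <- ann$status == "unassigned"
  if (any(is_un)) {
    sel <- which(is_un)
    ann$row_label[sel] <- cluster_labels(
      ann$sample_id[sel], ann$rt[sel], sample_ids,
      prefix = "feature", rt_tol = cfg$rt_tol,
      mass = ann$neutral_mass[sel], ppm_tol = cfg$ppm_tol
    )
  }

  cells <- dplyr::summarise(
    dplyr::group_by(ann, .data$row_label, .data$sample_id),
    abundance = sum(.data$abundance),
    feature_ids = paste(.data$feature_id, collapse = "+"),
    .groups = "drop"
  )
  labels <- sort(unique(ann$row_label))
  mat <- matrix(0, nrow = length(labels), ncol = length(sample_ids),
                dimnames = list(labels, sample_ids))
  mat[cbind(match(cells$row_label, labels),
            match(cells$sample_id, sample_ids))] <- cells$abundance

  meta <- dplyr::summarise(
    dplyr::group_by(ann, .data$row_label),
    hex = .data$hex[1], hexnac = .data$hexnac[1], fuc = .data$fuc[1],
    neu5ac = .data$neu5ac[1], reduced = .data$reduced[1],
    composition = .data$composition[1],
    assigned = .data$status[1] == "assigned",
    .groups = "drop"
  )
  meta <- meta[match(labels, meta$row_label), ]
  meta$class <- NA_character_
  has_comp <- !is.na(meta$hex)
  if (any(has_comp)) {
    meta$class[has_comp] <-
      glycan_class(meta[has_comp, c("hex", "hexnac", "fuc", "neu5ac")])
  }
  names(meta)[names(meta) == "row_label"] <- "label"

  structure(
    list(abundance = mat, structures = meta,
         provenance = dplyr::rename(cells, label = "row_label"),
         reference = reference),
    class = "abundance_matrix"
  )
}

# Greedy nearest-RT (optionally mass-gated) cluster assignment. Clusters are
# seeded from the reference sample's entries; later entries join the nearest
# compatible cluster or found a new one. Deterministic given input order.
cluster_labels <- function(sample_id, rt, sample_order, prefix, rt_tol,
                           mass = NULL, ppm_tol = NULL) {
  n <- length(rt)
  labels <- character(n)
  centers_rt <- numeric(0)
  centers_mass <- numeric(0)
  centers_lab <- character(0)
  ord <- order(match(sample_id, sample_order), rt)
  for (i in ord) {
    ok <- abs(centers_rt - rt[i]) <= rt_tol
    if (!is.null(mass)) {
      ok <- ok & abs(ppm_error(mass[i], pmax(centers_mass, 1e-9))) <= ppm_tol
    }
    if (any(ok)) {
      j <- which(ok)[which.min(abs(centers_rt[ok] - rt[i]))]
      labels[i] <- centers_lab[j]
    } else {
      lab <- sprintf("%s@%.2fmin", prefix, rt[i])
      while (lab %in% centers_lab) lab <- paste0(lab, "'")
      centers_rt <- c(centers_rt, rt[i])
      centers_mass <- c(centers_mass, if (is.null(mass)) 0 else mass[i])
      centers_lab <- c(centers_lab, lab)
      labels[i] <- lab
    }
  }
  labels
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat("<abundance_matrix>", nrow(x$abundance), "structures x",
      ncol(x$abundance), "samples | reference:", x$reference, "\n")
  cat("  assigned rows:", sum(x$structures$assigned), "| other rows:",
      sum(!x$structures$assigned), "\n")
  invisible(x)
}

#' Write an abundance matrix and its provenance
#'
#' @param mat An `abundance_matrix`.
#' @param path Output TSV path for the wide matrix; provenance goes to
#'   `<path>.provenance.tsv`.
#' @return `path`, invisibly.
#' @export
write_abundance_matrix <- function(mat, path) {
  wide <- tibble::as_tibble(mat$abundance, rownames = "label")
  readr::write_tsv(wide, path, progress = FALSE)
  readr::write_tsv(mat$provenance, paste0(path, ".provenance.tsv"),
                   progress = FALSE)
  invisible(path)
}
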