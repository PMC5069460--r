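# Cache of enumerated composition tables, keyed by (max mass, dp bounds,
# reduced). Enumeration is cheap (~1e4 rows) but runs once per config.
.comp_cache <- new.env(parent = emptyenv())

composition_table <- function(max_mass, cfg, reduced = TRUE) {
  key <- paste(format(max_mass), cfg$dp_bounds[1], cfg$dp_bounds[2], reduced)
  if (!is.null(.comp_cache[[key]])) return(.comp_cache[[key]])
  avail <- max_mass - .mass_water
  cap <- function(res) {
    max(0L, min(cfg$dp_bounds[2], floor(avail / .residue_mass[[res]])))
  }
  grid <- expand.grid(hex = 0:cap("hex"), hexnac = 0:cap("hexnac"),
                      fuc = 0:cap("fuc"), neu5ac = 0:cap("neu5ac"),
                      KEEP.OUT.ATTRS = FALSE)
  dp <- rowSums(grid)
  grid <- grid[dp >= cfg$dp_bounds[1] & dp <= cfg$dp_bounds[2], , drop = FALSE]
  grid$reduced <- reduced
  grid$mass <- composition_mass(grid)
  grid <- grid[grid$mass <= max_mass + 1, , drop = FALSE]
  grid <- grid[order(grid$mass), , drop = FALSE]
  out <- tibble::as_tibble(grid)
  .comp_cache[[key]] <- out
  out
}

#' Monosaccharide compositions consistent with a neutral mass
#'
#' Enumerates every Hex/HexNAc/Fuc/Neu5Ac composition whose theoretical
#' neutral mass lies within the configured ppm window of the observed mass
#' and whose degree of polymerization respects the configured bounds. The
#' enumeration is exhaustive within those bounds; the result is ordered by
#' increasing absolute ppm error, ties broken lexicographically on the
#' residue counts.
#'
#' @param neutral_mass Observed neutral monoisotopic mass, Da (> 0).
#' @param cfg A [tolerance_config()].
#' @param reduced Logical; decompose as an alditol (default `TRUE`, matching
#'   borohydride-reduced pools).
#' @return A tibble of candidate compositions with columns `hex`, `hexnac`,
#'   `fuc`, `neu5ac`, `reduced`, `mass`, `ppm`; zero rows when no composition
#'   fits.
#' @examples
#' decompose_mass(490.1898)  # 2'FL alditol -> Hex2 Fuc1
#' @export
decompose_mass <- function(neutral_mass, cfg = tolerance_config(),
                           reduced = TRUE) {
  stopifnot(length(neutral_mass) == 1, neutral_mass > 0)
  tab <- composition_table(max(neutral_mass, cfg$mz_window[2]), cfg, reduced)
  # |obs - m| <= ppm_tol * 1e-6 * m  <=>  m in [obs/(1+tol), obs/(1-tol)]
  tol <- cfg$ppm_tol * 1e-6
  lo <- neutral_mass / (1 + tol)
  hi <- neutral_mass / (1 - tol)
  hit <- tab[tab$mass >= lo & tab$mass <= hi, , drop = FALSE]
  hit$ppm <- ppm_error(neutral_mass, hit$mass)
  hit[order(abs(hit$ppm), hit$hex, hit$hexnac, hit$fuc, hit$neu5ac), ]
}

neutral_mass_of <- function(feats) {
  if ("neutral_mass" %in% names(feats)) {
    feats$neutral_mass
  } else {
    mass_from_mz(feats$mz, feats$charge)
  }
}

#' Annotate LC-MS features against an HMO structure library
#'
#' Each feature receives its candidate compositions from [decompose_mass()]
#' (ppm window on the neutral mass, after charge/proton removal). A library
#' structure is assigned when it shares a candidate composition and its
#' reference retention time lies within `rt_tol` of the observed RT; among
#' competing entries the nearest RT wins, then the smallest absolute ppm
#' error, and an exact RT tie is reported as the isomer-group label rather
#' than either name. Features with a composition but no RT match are
#' `"composition-only"`; features with no admissible composition are
#' `"unassigned"`.
#'
#' @param feats A validated feature tibble (see [read_features()]).
#' @param library A validated structure library (see [read_hmo_library()]).
#' @param cfg A [tolerance_config()].
#' @param reduced Logical; treat observed masses as alditols (default `TRUE`).
#' @return An annotation tibble, one row per feature, with the feature
#'   fields plus `composition`, residue counts, `ppm`, `n_candidates`,
#'   `structure`, `isomer_group`, `status` and `n_merged` (always 1 here;
#'   see [group_isomers()]).
#' @export
annotate_features <- function(feats, library = hmo_library(),
                              cfg = tolerance_config(), reduced = TRUE) {
  library <- validate_hmo_library(library)
  lib_key <- composition_label(library)
  nm <- neutral_mass_of(feats)
  n <- nrow(feats)
  out <- tibble::tibble(
    sample_id = feats$sample_id,
    feature_id = paste0(feats$sample_id, "#", seq_len(n)),
    neutral_mass = nm,
    rt = feats$rt_min,
    abundance = feats$abundance,
    hex = NA_integer_, hexnac = NA_integer_, fuc = NA_integer_,
    neu5ac = NA_integer_, reduced = reduced,
    composition = NA_character_, ppm = NA_real_, n_candidates = 0L,
    structure = NA_character_, isomer_group = NA_character_,
    status = "unassigned", n_merged = 1L
  )
  for (i in seq_len(n)) {
    cands <- decompose_mass(nm[i], cfg, reduced)
    out$n_candidates[i] <- nrow(cands)
    if (nrow(cands) == 0L) next
    cand_key <- composition_label(cands)
    # library entries whose composition matches any candidate, RT-gated
    hits <- which(library$reduced == reduced & lib_key %in% cand_key &
                    abs(library$rt_ref_min - out$rt[i]) <= cfg$rt_tol)
    best <- cands[1L, ]  # smallest |ppm| candidate
    if (length(hits)) {
      drt <- abs(library$rt_ref_min[hits] - out$rt[i])
      cand_ppm <- abs(cands$ppm[match(lib_key[hits], cand_key)])
      ord <- order(drt, cand_ppm)
      hits <- hits[ord]; drt <- drt[ord]
      tie <- hits[drt == drt[1]]
      chosen <- hits[1]
      out$structure[i] <- if (length(tie) > 1L) {
        library$isomer_group[chosen]
      } else {
        library$name[chosen]
      }
      out$isomer_group[i] <- library$isomer_group[chosen]
      out$status[i] <- "assigned"
      best <- cands[match(lib_key[chosen], cand_key), ]
    } else {
      out$status[i] <- "composition-only"
    }
    out$hex[i] <- best$hex; out$hexnac[i] <- best$hexnac
    out$fuc[i] <- best$fuc; out$neu5ac[i] <- best$neu5ac
    out$composition[i] <- composition_label(best)
    out$ppm[i] <- best$ppm
  }
  out
}

#' Group co-eluting same-composition isomers
#'
#' Within one sample, peaks of identical monosaccharide composition whose
#' retention times cannot be resolved (successive gaps no larger than
#' `coelution_tol`, applied transitively along the RT axis) are merged into a
#' single entry whose abundance is the sum of the members and whose RT is the
#' abundance-weighted mean. A merged group spanning two different assigned
#' structures is reported under their shared isomer-group label. Total
#' abundance is conserved exactly.
#'
#' @param annotations An annotation tibble for a single sample
#'   (see [annotate_features()]).
#' @param cfg A [tolerance_config()].
#' @return The grouped annotation tibble; `n_merged` counts members.
#' @export
group_isomers <- function(annotations, cfg = tolerance_config()) {
  if (length(unique(annotations$sample_id)) > 1L) {
    stop("group_isomers expects annotations from one sample", call. = FALSE)
  }
  no_comp <- is.na(annotations$composition)
  keep <- annotations[no_comp, , drop = FALSE]
  if (all(no_comp)) return(dplyr::arrange(keep, .data$rt))
  grouped <- annotations[!no_comp, , drop = FALSE] |>
    dplyr::arrange(.data$composition, .data$rt) |>
    dplyr::group_by(.data$composition) |>
    dplyr::mutate(
      cluster = cumsum(c(0, diff(.data$rt) > cfg$coelution_tol))
    ) |>
    dplyr::group_by(.data$composition, .data$cluster) |>
    dplyr::summarise(
      sample_id = .data$sample_id[1],
      feature_id = paste(.data$feature_id, collapse = "+"),
      neutral_mass = stats::weighted.mean(
        .data$neutral_mass, pmax(.data$abundance, 1e-12)),
      rt = stats::weighted.mean(.data$rt, pmax(.data$abundance, 1e-12)),
      abundance = sum(.data$abundance),
      hex = .data$hex[1], hexnac = .data$hexnac[1], fuc = .data$fuc[1],
      neu5ac = .data$neu5ac[1], reduced = .data$reduced[1],
      ppm = .data$ppm[which.min(abs(.data$ppm))],
      n_candidates = max(.data$n_candidates),
      structure = merge_structure_label(.data$structure, .data$isomer_group),
      isomer_group = if (all(is.na(.data$isomer_group))) NA_character_ else
        .data$isomer_group[!is.na(.data$isomer_group)][1],
      status = if (any(.data$status == "assigned")) "assigned" else
        "composition-only",
      n_merged = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(-"cluster") |>
    dplyr::select(dplyr::all_of(names(annotations)))
  dplyr::arrange(dplyr::bind_rows(grouped, keep), .data$rt)
}

merge_structure_label <- function(structures, groups) {
  s <- unique(structures[!is.na(structures)])
  if (length(s) == 0L) return(NA_character_)
  if (length(s) == 1L) return(s)
  # co-eluting distinct assignments share a composition, hence one group
  unique(groups[!is.na(groups)])[1]
}
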