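# Monoisotopic residue masses (Da) for the five HMO building blocks, derived
# once from atomic monoisotopic masses (C 12, H 1.00782503, N 14.00307401,
# O 15.99491462). Hex = C6H10O5, HexNAc = C8H13NO5, Fuc (deoxyhexose) =
# C6H10O4, Neu5Ac = C11H17NO8. Glc/Gal and GlcNAc/GalNAc are mass-degenerate
# and collapse onto Hex/HexNAc; identity beyond composition is carried only
# by the retention-time library.
.residue_mass <- c(
  hex    = 162.052824,
  hexnac = 203.079373,
  fuc    = 146.057909,
  neu5ac = 291.095417
)
.mass_water  <- 18.010565  # H2O, condensation/terminus
.mass_2h     <- 2.015650   # 2H alditol increment (borohydride-reduced end)
.mass_proton <- 1.007276   # for [M+nH]n+ ions

.residue_cols <- c("hex", "hexnac", "fuc", "neu5ac")

#' Monosaccharide compositions
#'
#' An HMO monosaccharide composition counts hexose (Glc/Gal), N-acetyl-
#' hexosamine (GlcNAc/GalNAc), deoxyhexose (Fuc) and N-acetylneuraminic acid
#' residues, plus a flag marking the reducing end as an alditol (open-chain
#' reduced form, +2H). Mass-degenerate residues are collapsed: composition is
#' the unit of accurate-mass annotation, not of structural identity.
#'
#' @param hex,hexnac,fuc,neu5ac Non-negative integer residue counts
#'   (vectorised; recycled to a common length).
#' @param reduced Logical; `TRUE` when the reducing end is an alditol.
#' @return A tibble with columns `hex`, `hexnac`, `fuc`, `neu5ac`, `reduced`,
#'   one row per composition.
#' @examples
#' hmo_composition(hex = 2, fuc = 1, reduced = TRUE)  # 2'FL / 3FL alditol
#' @export
hmo_composition <- function(hex = 0, hexnac = 0, fuc = 0, neu5ac = 0,
                            reduced = FALSE) {
  comp <- tibble::tibble(
    hex = as.integer(hex), hexnac = as.integer(hexnac),
    fuc = as.integer(fuc), neu5ac = as.integer(neu5ac),
    reduced = as.logical(reduced)
  )
  validate_composition(comp)
  comp
}

validate_composition <- function(comp) {
  stopifnot(all(.residue_cols %in% names(comp)))
  counts <- as.matrix(comp[.residue_cols])
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("residue counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) < 1)) {
    stop("composition must contain at least one residue (DP >= 1)",
         call. = FALSE)
  }
  invisible(comp)
}

#' Degree of polymerization of a composition
#'
#' @param comp A composition tibble (see [hmo_composition()]).
#' @return Integer vector of residue counts per row.
#' @export
composition_dp <- function(comp) {
  as.integer(rowSums(as.matrix(comp[.residue_cols])))
}

#' Compact text label for a composition, e.g. `"Hex2Fuc1"`
#'
#' Zero counts are omitted; the label is independent of the reduced flag and
#' is used as a row key for composition-only features.
#'
#' @param comp A composition tibble.
#' @return Character vector of labels.
#' @export
composition_label <- function(comp) {
  pretty <- c(hex = "Hex", hexnac = "HexNAc", fuc = "Fuc", neu5ac = "Neu5Ac")
  apply(as.matrix(comp[.residue_cols]), 1L, function(x) {
    nz <- x > 0
    paste0(pretty[.residue_cols][nz], x[nz], collapse = "")
  })
}

#' Neutral monoisotopic mass of a composition
#'
#' Sums fixed residue monoisotopic masses plus one water (terminal H/OH) and,
#' for alditols, the 2H reduction increment.
#'
#' @param comp A composition tibble with columns `hex`, `hexnac`, `fuc`,
#'   `neu5ac` and optionally `reduced` (default `FALSE`).
#' @return Numeric vector of neutral masses in Da.
#' @examples
#' composition_mass(hmo_composition(hex = 2))                  # lactose
#' composition_mass(hmo_composition(hex = 2, fuc = 1, reduced = TRUE))
#' @export
composition_mass <- function(comp) {
  validate_composition(comp)
  reduced <- if ("reduced" %in% names(comp)) comp$reduced else FALSE
  as.vector(
    as.matrix(comp[.residue_cols]) %*% .residue_mass[.residue_cols] +
      .mass_water + ifelse(reduced, .mass_2h, 0)
  )
}

#' m/z of a protonated positive-mode ion
#'
#' Only \eqn{[M+nH]^{n+}} adducts are supported (the profiling method runs in
#' positive ion mode); sodium/potassium adducts are out of scope.
#'
#' @param mass Neutral monoisotopic mass, Da (> 0).
#' @param charge Positive integer charge state.
#' @return m/z in Thomson.
#' @seealso [mass_from_mz()] for the exact inverse.
#' @export
mz_from_mass <- function(mass, charge = 1L) {
  if (any(mass <= 0)) stop("mass must be positive", call. = FALSE)
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (mass + charge * .mass_proton) / charge
}

#' Neutral mass from an observed m/z and charge
#'
#' @param mz Observed m/z (Thomson).
#' @param charge Positive integer charge state.
#' @return Neutral mass, Da.
#' @export
mass_from_mz <- function(mz, charge = 1L) {
  if (any(charge < 1) || any(charge != as.integer(charge))) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  mz * charge - charge * .mass_proton
}

#' Signed parts-per-million mass error
#'
#' @param observed Observed mass or m/z.
#' @param theoretical Theoretical value on the same scale (> 0).
#' @return Signed ppm error, `(observed - theoretical) / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical mass must be positive", call. = FALSE)
  }
  (observed - theoretical) / theoretical * 1e6
}

#' Glycan class of a composition
#'
#' Classes partition compositions by decoration: any Fuc makes a glycan
#' fucosylated, any Neu5Ac sialylated, both together fucosylated_sialylated,
#' neither neutral. Class-level consumption summaries aggregate over these.
#'
#' @param comp A composition tibble.
#' @return Character vector, one of `"neutral"`, `"fucosylated"`,
#'   `"sialylated"`, `"fucosylated_sialylated"`.
#' @export
glycan_class <- function(comp) {
  validate_composition(comp)
  dplyr::case_when(
    comp$fuc > 0 & comp$neu5ac > 0 ~ "fucosylated_sialylated",
    comp$fuc > 0                   ~ "fucosylated",
    comp$neu5ac > 0                ~ "sialylated",
    TRUE                           ~ "neutral"
  )
}

#' Ordered glycan class levels
#' @return Character vector of the four class labels.
#' @export
glycan_classes <- function() {
  c("neutral", "fucosylated", "sialylated", "fucosylated_sialylated")
}

#' Read an HMO structure library
#'
#' A library is a TSV with columns `name`, `hex`, `hexnac`, `fuc`, `neu5ac`,
#' `reduced`, `rt_ref_min`, `isomer_group`: one named structure per row with
#' its monosaccharide composition, reference retention time (minutes) and the
#' isomer-group label shared by structures of identical composition that may
#' co-elute (e.g. LNT and LNnT).
#'
#' @param path Path to the TSV file.
#' @return A validated tibble with a `class` column added.
#' @export
read_hmo_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path, call. = FALSE)
  lib <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  validate_hmo_library(lib)
}

#' Validate an HMO structure library
#'
#' Checks column presence, composition invariants, unique names, positive
#' reference retention times, and that entries sharing a composition carry a
#' common isomer-group label.
#'
#' @param lib A library tibble (see [read_hmo_library()]).
#' @return The library, invisibly augmented with a `class` column.
#' @export
validate_hmo_library <- function(lib) {
  need <- c("name", .residue_cols, "reduced", "rt_ref_min", "isomer_group")
  miss <- setdiff(need, names(lib))
  if (length(miss)) {
    stop("library is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  validate_composition(lib)
  if (anyDuplicated(lib$name)) {
    stop("library names must be unique: ",
         paste(unique(lib$name[duplicated(lib$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(lib$rt_ref_min)) || any(lib$rt_ref_min <= 0)) {
    stop("rt_ref_min must be positive and finite", call. = FALSE)
  }
  key <- composition_label(lib)
  grp <- tapply(lib$isomer_group, key, function(g) length(unique(g)))
  if (any(grp > 1)) {
    stop("structures sharing a composition must share one isomer_group",
         call. = FALSE)
  }
  lib$class <- glycan_class(lib)
  lib
}

#' Packaged HMO structure library
#'
#' Loads the library shipped with the package: the structures commonly
#' annotated in pooled human-milk oligosaccharide profiling (2'FL, 3FL, LNT,
#' LNnT, the LNFP and LNH series, sialyllactoses, ...). Compositions are
#' literature values; the reference retention times are synthetic placeholders
#' laid out on a plausible porous-graphitized-carbon elution axis, suitable
#' for simulation and testing but not for annotating real chromatograms.
#'
#' @return A validated library tibble.
#' @export
hmo_library <- function() {
  read_hmo_library(system.file("extdata", "hmo_library.tsv",
                               package = "hmoglyco", mustWork = TRUE))
}
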