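#' Trimmed mean of a six-replicate glycan-array set
#'
#' Glycan-array screens report six replicate RFU values per glycan; the
#' highest and the lowest single observation are removed and the remaining
#' four are averaged. With duplicated extremes exactly one occurrence of
#' each is dropped.
#'
#' @param replicates Numeric vector of exactly 6 RFU values.
#' @return The arithmetic mean of the middle four values.
#' @examples
#' trimmed_mean_rfu(c(1, 2, 3, 4, 5, 100))  # 3.5
#' @export
trimmed_mean_rfu <- function(replicates) {
  if (length(replicates) != 6L || any(!is.finite(replicates))) {
    stop("exactly 6 finite replicate RFU values are required", call. = FALSE)
  }
  s <- sort(replicates)
  mean(s[2:5])
}

# Residue vocabulary for the IUPAC-condensed dialect used on mammalian
# glycan arrays; matched longest-first. "GlcNA" appears verbatim in some
# published tables and is accepted as its own token.
.glycan_residues <- c(
  "Neu5Gc", "Neu5Ac", "GlcNAc", "GalNAc", "ManNAc", "GlcNA", "GalNA",
  "GlcA", "IdoA", "GlcN", "GalN", "KDN", "Gal", "Glc", "Man", "Fuc",
  "Xyl", "Rha", "Ara", "Neu"
)
.anomer_chars <- c("a", "b", "α", "β")

match_paren <- function(s, open) {
  depth <- 0L
  for (i in open:nchar(s)) {
    ch <- substr(s, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth == 0L) return(i)
    }
  }
  stop("unbalanced parentheses at position ", open, call. = FALSE)
}

parse_chain <- function(s, offset = 0L) {
  units <- list()
  pending <- list()
  pos <- 1L
  n <- nchar(s)
  while (pos <= n) {
    ch <- substr(s, pos, pos)
    if (ch == "(") {
      close <- match_paren(s, pos)
      content <- substr(s, pos + 1L, close - 1L)
      pending[[length(pending) + 1L]] <-
        if (grepl("^[0-9]+S$", content)) {
          list(type = "modifier", text = content)
        } else {
          list(type = "branch", chain = parse_chain(content, offset + pos))
        }
      pos <- close + 1L
      next
    }
    rest <- substr(s, pos, n)
    res <- NA_character_
    for (r in .glycan_residues) {
      if (startsWith(rest, r)) { res <- r; break }
    }
    if (is.na(res)) {
      stop("unknown residue token at position ", offset + pos, ": '",
           substr(rest, 1, 8), "'", call. = FALSE)
    }
    pos <- pos + nchar(res)
    anomer <- ""
    if (pos <= n && substr(s, pos, pos) %in% .anomer_chars) {
      anomer <- substr(s, pos, pos)
      pos <- pos + 1L
    }
    linkage <- ""
    m <- regmatches(substr(s, pos, n),
                    regexpr("^[0-9]+-[0-9]+", substr(s, pos, n)))
    if (length(m)) {
      linkage <- m
      pos <- pos + nchar(m)
    }
    units[[length(units) + 1L]] <- list(residue = res, anomer = anomer,
                                        linkage = linkage, groups = pending)
    pending <- list()
  }
  if (length(pending)) {
    stop("dangling parenthesized group with no attached residue",
         call. = FALSE)
  }
  units
}

serialize_unit <- function(u) {
  grp <- vapply(u$groups, function(g) {
    inner <- if (g$type == "modifier") g$text else serialize_chain(g$chain)
    paste0("(", inner, ")")
  }, character(1))
  paste0(paste(grp, collapse = ""), u$residue, u$anomer, u$linkage)
}

serialize_chain <- function(units) {
  paste(vapply(units, serialize_unit, character(1)), collapse = "")
}

#' Parse an IUPAC-condensed glycan string
#'
#' Parses the dialect used on mammalian glycan arrays: residues written from
#' the non-reducing end, anomeric configuration as `a`/`b` or Greek
#' alpha/beta, linkages as digit pairs (`1-4`), branches and sulfation
#' modifiers (`(6S)`) in parentheses preceding the residue they decorate,
#' and a trailing spacer suffix (`-Sp0` .. `-Sp25`) naming the linker to the
#' slide. Parsing is lossless: [serialize_glycan()] reproduces the input.
#'
#' @param glycan_string The glycan text, e.g. `"Fuca1-2Galβ-Sp8"`.
#' @return An object of class `glycan_structure`: a list with `chain` (the
#'   main-chain token list, each unit holding `residue`, `anomer`,
#'   `linkage` and parenthesized `groups`) and `spacer` (possibly empty).
#' @export
parse_glycan <- function(glycan_string) {
  stopifnot(is.character(glycan_string), length(glycan_string) == 1L)
  s <- glycan_string
  spacer <- ""
  m <- regmatches(s, regexpr("-Sp[0-9]+$", s))
  if (length(m)) {
    spacer <- sub("^-", "", m)
    sp_n <- as.integer(sub("Sp", "", spacer))
    if (sp_n > 25L) stop("spacer out of range: ", spacer, call. = FALSE)
    s <- sub("-Sp[0-9]+$", "", s)
  }
  structure(list(chain = parse_chain(s), spacer = spacer,
                 source = glycan_string),
            class = "glycan_structure")
}

#' Serialize a parsed glycan back to its string form
#'
#' @param glycan A `glycan_structure` from [parse_glycan()].
#' @param spacer Include the spacer suffix (default `TRUE`).
#' @return The glycan string.
#' @export
serialize_glycan <- function(glycan, spacer = TRUE) {
  stopifnot(inherits(glycan, "glycan_structure"))
  out <- serialize_chain(glycan$chain)
  if (spacer && nzchar(glycan$spacer)) {
    out <- paste0(out, "-", glycan$spacer)
  }
  out
}

#' @export
print.glycan_structure <- function(x, ...) {
  cat("<glycan_structure>", serialize_glycan(x), "\n")
  invisible(x)
}

unit_eq <- function(a, b) {
  a$residue == b$residue && a$anomer == b$anomer &&
    a$linkage == b$linkage &&
    identical(vapply(a$groups, function(g)
      if (g$type == "modifier") g$text else serialize_chain(g$chain),
      character(1)),
      vapply(b$groups, function(g)
        if (g$type == "modifier") g$text else serialize_chain(g$chain),
        character(1)))
}

#' Longest shared non-reducing-terminal motif
#'
#' Walks the main chains of a set of glycans from the non-reducing terminus
#' and returns the longest shared token prefix: units match fully when
#' residue, anomeric configuration, linkage and any parenthesized groups
#' agree; at the first unit where only the residue name is shared, the bare
#' residue is appended and the walk stops. Branches therefore participate
#' only when the branch point itself is shared. Spacers never count.
#'
#' @param glycans A list of glycan strings or `glycan_structure` objects
#'   (length >= 1).
#' @return The shared motif as a string; `""` when nothing is shared.
#' @examples
#' shared_motif(list("Fuca1-2Galβ-Sp8", "Fuca1-2Galβ1-4Glcβ-Sp0"))
#' @export
shared_motif <- function(glycans) {
  stopifnot(length(glycans) >= 1L)
  parsed <- lapply(glycans, function(g) {
    if (inherits(g, "glycan_structure")) g else parse_glycan(g)
  })
  chains <- lapply(parsed, `[[`, "chain")
  depth <- min(vapply(chains, length, integer(1)))
  motif <- character(0)
  for (i in seq_len(depth)) {
    units <- lapply(chains, `[[`, i)
    ref <- units[[1]]
    full <- all(vapply(units[-1], unit_eq, logical(1), a = ref))
    if (full) {
      motif <- c(motif, serialize_unit(ref))
      next
    }
    same_residue <- all(vapply(units, function(u) u$residue == ref$residue,
                               logical(1)))
    if (same_residue) motif <- c(motif, ref$residue)
    break
  }
  paste(motif, collapse = "")
}

#' Read a glycan-array replicate table
#'
#' Expects a TSV with columns `glycan_string`, `rfu_1` .. `rfu_6` and
#' optionally `sbp` (the solute-binding protein screened).
#'
#' @param path Path to the TSV.
#' @return A tibble, one row per glycan per protein.
#' @export
read_glycan_array <- function(path) {
  if (!file.exists(path)) stop("array file not found: ", path, call. = FALSE)
  arr <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("glycan_string", paste0("rfu_", 1:6))
  miss <- setdiff(need, names(arr))
  if (length(miss)) {
    stop("array table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"sbp" %in% names(arr)) arr$sbp <- "protein"
  arr
}

#' Summarize a glycan-array screen
#'
#' Applies the six-replicate trimmed mean per glycan, ranks glycans within
#' each protein by descending summarized RFU, and flags binders above the
#' RFU threshold.
#'
#' @param array A tibble from [read_glycan_array()].
#' @param threshold Binder-calling RFU threshold (default 100; screens
#'   publish no canonical cutoff, so this is an explicit analysis choice).
#' @return The input with `trimmed_mean`, `rank` and `binder` columns,
#'   replicate columns pivoted away.
#' @export
summarize_array <- function(array, threshold = 100) {
  long <- tidyr::pivot_longer(array, dplyr::all_of(paste0("rfu_", 1:6)),
                              names_to = "replicate", values_to = "rfu")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$sbp, .data$glycan_string),
    trimmed_mean = trimmed_mean_rfu(.data$rfu),
    .groups = "drop_last"
  )
  out <- dplyr::mutate(
    out,
    rank = rank(-.data$trimmed_mean, ties.method = "first"),
    binder = .data$trimmed_mean > threshold
  )
  dplyr::arrange(dplyr::ungroup(out), .data$sbp, .data$rank)
}

#' Shared motifs recognized by each array-screened protein
#'
#' For every protein, extracts the longest non-reducing-terminal motif
#' shared by all of its binder glycans.
#'
#' @inheritParams summarize_array
#' @return A tibble with `sbp`, `n_binders`, `motif`.
#' @export
array_motif_report <- function(array, threshold = 100) {
  summ <- summarize_array(array, threshold)
  binders <- summ[summ$binder, ]
  dplyr::summarise(
    dplyr::group_by(binders, .data$sbp),
    n_binders = dplyr::n(),
    motif = shared_motif(as.list(.data$glycan_string)),
    .groups = "drop"
  )
}
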