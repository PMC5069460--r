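# Independent oracles used across the suite. Constants are restated here on
# purpose (not read from the package) so the oracles check the
# implementation rather than echo it.

# Elemental monoisotopic mass from atomic monoisotopic masses.
elemental_mass <- function(C = 0, H = 0, N = 0, O = 0) {
  C * 12 + H * 1.00782503 + N * 14.00307401 + O * 15.99491462
}

# Exhaustive brute-force composition enumeration: nested loops over residue
# counts with mass pruning, ppm window applied to the theoretical mass.
# Returns a data.frame sorted lexicographically (a set, for comparison).
brute_force_decompose <- function(m, ppm_tol = 20, dp = c(2L, 32L),
                                  reduced = TRUE) {
  M_hex <- elemental_mass(C = 6, H = 10, O = 5)
  M_hexnac <- elemental_mass(C = 8, H = 13, N = 1, O = 5)
  M_fuc <- elemental_mass(C = 6, H = 10, O = 4)
  M_neu <- elemental_mass(C = 11, H = 17, N = 1, O = 8)
  base <- elemental_mass(H = 2, O = 1) + if (reduced) 2 * 1.00782503 else 0
  lim <- m * (1 + ppm_tol * 1e-6)
  out <- list()
  for (h in 0:dp[2]) {
    mh <- base + h * M_hex
    if (mh > lim) break
    for (x in 0:(dp[2] - h)) {
      mx <- mh + x * M_hexnac
      if (mx > lim) break
      for (f in 0:(dp[2] - h - x)) {
        mf <- mx + f * M_fuc
        if (mf > lim) break
        s_max <- dp[2] - h - x - f
        s <- 0:s_max
        mass <- mf + s * M_neu
        dpn <- h + x + f + s
        ok <- dpn >= dp[1] & dpn <= dp[2] &
          abs((m - mass) / mass * 1e6) <= ppm_tol
        for (si in s[ok]) {
          out[[length(out) + 1L]] <- c(hex = h, hexnac = x, fuc = f,
                                       neu5ac = si)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(hex = integer(), hexnac = integer(),
                      fuc = integer(), neu5ac = integer()))
  }
  df <- as.data.frame(do.call(rbind, out))
  df[order(df$hex, df$hexnac, df$fuc, df$neu5ac), , drop = FALSE]
}

# Composition set from a decompose_mass() result, in oracle ordering.
as_comp_set <- function(cands) {
  df <- as.data.frame(cands[, c("hex", "hexnac", "fuc", "neu5ac")])
  df <- df[order(df$hex, df$hexnac, df$fuc, df$neu5ac), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# All permutations of a vector (for order-invariance checks; n <= 7).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# An empty but schema-valid structure library.
empty_library <- function() {
  tibble::tibble(name = character(), hex = integer(), hexnac = integer(),
                 fuc = integer(), neu5ac = integer(), reduced = logical(),
                 rt_ref_min = numeric(), isomer_group = character())
}

# Minimal feature tibble builder (neutral-mass convention).
make_features <- function(sample_id, neutral_mass, rt_min, abundance) {
  validate_features(
    tibble::tibble(sample_id = sample_id, neutral_mass = neutral_mass,
                   rt_min = rt_min, abundance = abundance),
    context = "test features")
}

# A small abundance matrix from named control/sample vectors.
make_matrix <- function(control, ...) {
  cols <- c(list(control = control), list(...))
  m <- do.call(cbind, cols)
  rownames(m) <- names(control)
  m
}
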