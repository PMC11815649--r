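#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Monoisotopic masses (Da). C13/N15 are counted as distinct species so that
# heavy-substituted label atoms contribute a fixed mass and no isotopic
# variability.
.element_masses <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  C13 = 13.00335483780,
  N15 = 15.00010889840
)

.mass_proton <- 1.007276466
.mass_electron <- 0.000548580
.mass_C13_shift <- 13.00335483780 - 12.0        # 1.0033548
.mass_N15_shift <- 15.00010889840 - 14.0030740048 # 0.9970349

# Natural isotope patterns per element: probability at integer nominal-mass
# offsets starting at 0. Heavy species (C13/N15) are monoisotopic by
# construction.
.isotope_patterns <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99632, 0.00368),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9493, 0.0076, 0.0429, 0.0000, 0.0002),
  C13 = 1.0,
  N15 = 1.0
)

# Residue (amino-acid minus water) elemental compositions, standard 20.
.residue_table <- list(
  G = c(C = 2, H = 3, N = 1, O = 1, S = 0),
  A = c(C = 3, H = 5, N = 1, O = 1, S = 0),
  S = c(C = 3, H = 5, N = 1, O = 2, S = 0),
  P = c(C = 5, H = 7, N = 1, O = 1, S = 0),
  V = c(C = 5, H = 9, N = 1, O = 1, S = 0),
  T = c(C = 4, H = 7, N = 1, O = 2, S = 0),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  L = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  I = c(C = 6, H = 11, N = 1, O = 1, S = 0),
  N = c(C = 4, H = 6, N = 2, O = 2, S = 0),
  D = c(C = 4, H = 5, N = 1, O = 3, S = 0),
  Q = c(C = 5, H = 8, N = 2, O = 2, S = 0),
  K = c(C = 6, H = 12, N = 2, O = 1, S = 0),
  E = c(C = 5, H = 7, N = 1, O = 3, S = 0),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  H = c(C = 6, H = 7, N = 3, O = 1, S = 0),
  F = c(C = 9, H = 9, N = 1, O = 1, S = 0),
  R = c(C = 6, H = 12, N = 4, O = 1, S = 0),
  Y = c(C = 9, H = 9, N = 1, O = 2, S = 0),
  W = c(C = 11, H = 10, N = 2, O = 1, S = 0)
)

.comp_elements <- names(.element_masses)

#' Build an elemental composition
#'
#' An elemental composition is a named integer vector over the species
#' C, H, N, O, S, C13 and N15 (the two heavy species representing fixed
#' isotopic substitutions in TMTpro labels, which carry no further natural
#' variability).
#'
#' @param ... Named counts, e.g. `elemental_composition(C = 6, H = 12, O = 6)`.
#' @return An object of class `elem_comp`: a named numeric vector of
#'   non-negative integer counts over all seven species.
#' @examples
#' water <- elemental_composition(H = 2, O = 1)
#' monoisotopic_mass(water)
#' @export
elemental_composition <- function(...) {
  counts <- c(...)
  if (is.null(counts)) counts <- stats::setNames(numeric(0), character(0))
  bad <- setdiff(names(counts), .comp_elements)
  if (length(bad) > 0) {
    abort(paste0("Unknown element species: ", paste(bad, collapse = ", ")))
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("Element counts must be non-negative integers.")
  }
  out <- stats::setNames(numeric(length(.comp_elements)), .comp_elements)
  out[names(counts)] <- counts
  structure(out, class = "elem_comp")
}

.as_comp <- function(x) {
  if (inherits(x, "elem_comp")) return(x)
  do.call(elemental_composition, as.list(x))
}

#' @export
"+.elem_comp" <- function(e1, e2) {
  structure(unclass(e1) + unclass(e2), class = "elem_comp")
}

#' @export
print.elem_comp <- function(x, ...) {
  nz <- x[x > 0]
  cat("<elemental composition> ",
      paste0(names(nz), ifelse(nz > 1, nz, ""), collapse = " "),
      "  (", format(monoisotopic_mass(x), nsmall = 4), " Da)\n", sep = "")
  invisible(x)
}

#' Monoisotopic mass of a composition
#'
#' Sum of the lightest-isotope atomic masses, with C13/N15 species counted at
#' their heavy-isotope masses.
#'
#' @param comp An [elemental_composition()].
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(comp) {
  comp <- .as_comp(comp)
  sum(unclass(comp) * .element_masses[names(comp)])
}

#' Elemental composition of a labeled peptide
#'
#' Sums residue compositions plus one water, then applies the standard
#' TMTpro-experiment modification scheme: one TMTpro label on the N terminus
#' and one per lysine, N-ethylmaleimide (NEM) on every cysteine, and up to two
#' variable methionine oxidations.
#'
#' @param sequence Amino-acid string using the 20 standard one-letter codes.
#' @param n_oxidation Number of variable methionine oxidations (0, 1 or 2; at
#'   most the number of methionines).
#' @param label Label chemistry applied to N terminus and lysines. `"tmtpro"`
#'   (default) adds the canonical TMTpro composition per site; `"none"` leaves
#'   the peptide unlabeled.
#' @param nem_cysteine Apply NEM to cysteines (default `TRUE`).
#' @return An `elem_comp`. The attribute `n_labels` records the label count
#'   (1 for the N terminus + one per K when labeled).
#' @examples
#' composition_of_peptide("PEPTIDEK")
#' @export
composition_of_peptide <- function(sequence, n_oxidation = 0,
                                   label = c("tmtpro", "none"),
                                   nem_cysteine = TRUE) {
  label <- match.arg(label)
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) < 1) {
    abort("`sequence` must be a single non-empty string.")
  }
  res <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(res, names(.residue_table))
  if (length(unknown) > 0) {
    abort(paste0("Unknown residue letter(s): ", paste(unique(unknown), collapse = ", ")))
  }
  if (n_oxidation > 2) {
    abort("At most 2 variable modifications (methionine oxidations) are allowed.")
  }
  if (n_oxidation > sum(res == "M")) {
    abort("More oxidations requested than methionines present.")
  }
  counts <- Reduce(`+`, .residue_table[res])
  comp <- do.call(elemental_composition, as.list(counts)) +
    elemental_composition(H = 2, O = 1)
  n_labels <- 0L
  if (label == "tmtpro") {
    n_labels <- 1L + sum(res == "K")
    for (i in seq_len(n_labels)) comp <- comp + tmtpro_composition()
  }
  if (nem_cysteine) {
    n_cys <- sum(res == "C")
    if (n_cys > 0) {
      nem <- elemental_composition(C = 6, H = 7, N = 1, O = 2)
      for (i in seq_len(n_cys)) comp <- comp + nem
    }
  }
  if (n_oxidation > 0) comp <- comp + elemental_composition(O = n_oxidation)
  attr(comp, "n_labels") <- n_labels
  comp
}

# Truncated polynomial product: nonneg coefficient vectors indexed from
# offset 0; result truncated to `len` bins (exact for retained bins).
.poly_mult <- function(a, b, len) {
  out <- numeric(len)
  for (i in seq_along(a)) {
    if (a[i] == 0) next
    jmax <- min(length(b), len - i + 1)
    if (jmax < 1) break
    idx <- i:(i + jmax - 1)
    out[idx] <- out[idx] + a[i] * b[seq_len(jmax)]
  }
  out
}

# p(x)^n by squaring, truncated to `len` bins.
.poly_pow <- function(p, n, len) {
  result <- c(1, numeric(len - 1))
  base <- c(p, numeric(max(0, len - length(p))))[seq_len(len)]
  while (n > 0) {
    if (n %% 2 == 1) result <- .poly_mult(result, base, len)
    n <- n %/% 2
    if (n > 0) base <- .poly_mult(base, base, len)
  }
  result
}

#' Aggregated isotope envelope of a composition
#'
#' Computes the unit-mass-binned (aggregated) isotope distribution by
#' convolving per-element isotope patterns. Heavy-substituted species
#' (C13/N15 in TMTpro labels) contribute no variability. The distribution is
#' truncated at `n_offsets` bins; retained bins are exact (truncation only
#' discards probability mass beyond the last bin), so entries sum to at most 1.
#'
#' @param comp An `elem_comp`.
#' @param n_offsets Number of retained nominal-mass offsets (>= 1); bin 1 is
#'   the monoisotopic peak (offset 0).
#' @return Numeric vector of length `n_offsets` with probabilities at offsets
#'   `0:(n_offsets - 1)`.
#' @examples
#' isotope_envelope(elemental_composition(C = 1), 2)
#' @export
isotope_envelope <- function(comp, n_offsets = 6) {
  comp <- .as_comp(comp)
  if (n_offsets < 1) abort("`n_offsets` must be >= 1.")
  env <- c(1, numeric(n_offsets - 1))
  for (el in names(comp)) {
    n <- unclass(comp)[[el]]
    if (n == 0) next
    pat <- .isotope_patterns[[el]]
    if (length(pat) == 1) next
    env <- .poly_mult(env, .poly_pow(pat, n, n_offsets), n_offsets)
  }
  env
}

# Envelope with enough bins to retain >= 99.9% of the isotopologue mass
# (S/Cys-rich peptides need more than small ones).
.envelope_auto <- function(comp, start = 10, max_bins = 24) {
  n <- start
  repeat {
    env <- isotope_envelope(comp, n)
    if (sum(env) >= 0.9995 || n >= max_bins) return(env)
    n <- n + 4
  }
}
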