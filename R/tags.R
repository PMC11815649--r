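#' @importFrom dplyr mutate filter arrange select group_by ungroup summarise
#'   left_join bind_rows across n row_number pull rename
NULL

# Printed modification masses used throughout the standard search scheme.
#' Modification masses
#'
#' Canonical monoisotopic mass shifts of the static/variable modifications of
#' the standard TMTpro workflow: the TMTpro label (+304.2071 Da, N terminus
#' and lysines), N-ethylmaleimide (+125.047679 Da, cysteines), and methionine
#' oxidation (+15.99492 Da, variable).
#'
#' @return Named numeric vector with entries `tmtpro`, `nem`, `met_ox`.
#' @export
modification_masses <- function() {
  c(
    tmtpro = monoisotopic_mass(tmtpro_composition()),
    nem = monoisotopic_mass(elemental_composition(C = 6, H = 7, N = 1, O = 2)),
    met_ox = monoisotopic_mass(elemental_composition(O = 1))
  )
}

#' Canonical TMTpro label composition
#'
#' The nominal elemental composition of one TMTpro label as attached to an
#' amine: C8 (13C)7 H25 N (15N)2 O3, monoisotopic mass 304.2071 Da. Individual
#' tags redistribute the nine heavy atoms between reporter and balancer
#' regions (see [tmtpro_tags()]); their totals are isobaric within 0.02 Da.
#'
#' @return An `elem_comp`.
#' @export
tmtpro_composition <- function() {
  elemental_composition(C = 8, H = 25, N = 1, O = 3, C13 = 7, N15 = 2)
}

# Light reporter cation C8H16N+ (m/z of the TMT(pro) 126 reporter).
.reporter_base_mz <- function() {
  monoisotopic_mass(elemental_composition(C = 8, H = 16, N = 1)) - .mass_electron
}

.mass_CO <- function() monoisotopic_mass(elemental_composition(C = 1, O = 1))

#' The 18 TMTpro tag isotopologues
#'
#' Heavy-atom placement for each of the 18 TMTpro labels. Each tag carries
#' nine heavy substitutions (13C/15N) distributed between the reporter region
#' (capacity 8 C + 1 N), the balancer carbonyl that departs with the reporter
#' as CO, and the remaining complement region retained on the peptide
#' (capacity 6 C + 2 N). Reporter cation m/z reproduce the published
#' 126.127726..135.151600 series; complement nominal offsets span 0..8 with
#' two tags per offset whose exact masses differ by at most one 13C/15N swap
#' (6.32 mDa), which is why the 18 tags collapse into 9 complement channels
#' at practical Orbitrap resolving powers.
#'
#' @return A tibble with one row per tag: `tag`, heavy counts
#'   (`reporter_n13`, `reporter_n15`, `co_n13`, `comp_n13`, `comp_n15`),
#'   `reporter_mz` (cation m/z), `comp_nominal` (complement nominal offset),
#'   `comp_shift` (complement exact mass offset, Da) and `total_heavy_mass`
#'   (total heavy-substitution mass of the tag, Da).
#' @export
tmtpro_tags <- function() {
  tab <- tibble::tribble(
    ~tag,    ~reporter_n13, ~reporter_n15, ~co_n13, ~comp_n13, ~comp_n15,
    "126",   0L, 0L, 1L, 6L, 2L,
    "127N",  0L, 1L, 0L, 6L, 2L,
    "127C",  1L, 0L, 1L, 5L, 2L,
    "128N",  1L, 1L, 0L, 6L, 1L,
    "128C",  2L, 0L, 1L, 4L, 2L,
    "129N",  2L, 1L, 0L, 5L, 1L,
    "129C",  3L, 0L, 1L, 3L, 2L,
    "130N",  3L, 1L, 0L, 4L, 1L,
    "130C",  4L, 0L, 1L, 2L, 2L,
    "131N",  4L, 1L, 0L, 3L, 1L,
    "131C",  5L, 0L, 1L, 1L, 2L,
    "132N",  5L, 1L, 0L, 2L, 1L,
    "132C",  6L, 0L, 1L, 0L, 2L,
    "133N",  6L, 1L, 0L, 1L, 1L,
    "133C",  7L, 0L, 1L, 0L, 1L,
    "134N",  7L, 1L, 0L, 1L, 0L,
    "134C",  8L, 0L, 1L, 0L, 0L,
    "135N",  8L, 1L, 0L, 0L, 0L
  )
  tab |>
    mutate(
      reporter_mz = .reporter_base_mz() +
        .data$reporter_n13 * .mass_C13_shift + .data$reporter_n15 * .mass_N15_shift,
      comp_nominal = .data$comp_n13 + .data$comp_n15,
      comp_shift = .data$comp_n13 * .mass_C13_shift + .data$comp_n15 * .mass_N15_shift,
      total_heavy_mass =
        (.data$reporter_n13 + .data$co_n13 + .data$comp_n13) * .mass_C13_shift +
        (.data$reporter_n15 + .data$comp_n15) * .mass_N15_shift
    )
}

#' Read or fetch a tag impurity table
#'
#' Isotopic impurity fractions of each tag at nominal offsets -2..+2,
#' separately for the reporter and complement regions. The bundled default
#' table (`system.file("extdata", "tmtpro_impurities.tsv", package =
#' "tmtproc")`) carries realistic magnitudes (0-3% at +/-1 offsets) and is
#' used symmetrically by the simulator and the deconvolution, so correctness
#' is testable without vendor lot sheets. A user-measured table with columns
#' `tag_name`, `region` (`reporter`|`complement`), `offset` (-2..2),
#' `fraction` can be supplied instead.
#'
#' @param path Path to a TSV impurity table; `NULL` (default) loads the
#'   bundled table.
#' @return Tibble with columns `tag_name`, `region`, `offset`, `fraction`.
#'   Fractions sum to 1 within each (tag, region).
#' @export
read_impurity_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tmtpro_impurities.tsv", package = "tmtproc")
  }
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  required <- c("tag_name", "region", "offset", "fraction")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("Impurity table is missing column(s): ", paste(missing, collapse = ", ")))
  }
  sums <- tab |>
    group_by(.data$tag_name, .data$region) |>
    summarise(s = sum(.data$fraction), .groups = "drop")
  if (any(abs(sums$s - 1) > 1e-6)) {
    abort("Impurity fractions must sum to 1 within each (tag, region).")
  }
  tab
}

#' Identity (impurity-free) tag impurity table
#'
#' All probability at offset 0 for every tag and region. With this table the
#' deconvolution design matrix reduces to the shifted peptide envelope and the
#' pipeline reads channel peaks directly.
#'
#' @return Tibble in the [read_impurity_table()] layout.
#' @export
identity_impurities <- function() {
  tags <- tmtpro_tags()$tag
  tidyr::expand_grid(
    tag_name = tags,
    region = c("reporter", "complement"),
    offset = -2:2
  ) |>
    mutate(fraction = as.numeric(.data$offset == 0))
}

#' Collapse the 18 tags into complement channels
#'
#' Groups tags whose complement exact masses are unresolvable at practical
#' Orbitrap transient lengths. Tags are sorted by complement exact mass and
#' merged single-linkage wherever the gap to the next tag is below
#' `resolvable_dm`; with the full 18-plex and the default 0.02 Da threshold
#' this merges the 6.32 mDa 13C/15N pairs and yields 9 channels on a 1 Da
#' grid.
#'
#' @param tags Tag table as from [tmtpro_tags()] (any subset of rows).
#' @param resolvable_dm Smallest resolvable complement mass difference in Da
#'   (> 0). Values large enough to merge tags of distinct nominal offset are
#'   rejected, since they would break the 1 Da cluster grid.
#' @return A channel-model tibble, one row per channel ordered by increasing
#'   complement mass: `channel` ("c1".."cN"), `index`, `nominal_offset`
#'   (integer Da above the lightest channel), `exact_shift` (mean complement
#'   heavy mass of member tags, Da), `reporter_mz` (designated member tag's
#'   reporter, the lighter one), and `tags` (list column of member tag names).
#' @examples
#' build_channel_model(tmtpro_tags())
#' @export
build_channel_model <- function(tags = tmtpro_tags(), resolvable_dm = 0.02) {
  if (nrow(tags) == 0) abort("`tags` must contain at least one tag.")
  if (resolvable_dm <= 0) abort("`resolvable_dm` must be > 0.")
  ord <- tags |> arrange(.data$comp_shift, .data$tag)
  gaps <- diff(ord$comp_shift)
  grp <- cumsum(c(1, as.integer(gaps >= resolvable_dm)))
  ord$.grp <- grp
  model <- ord |>
    group_by(.data$.grp) |>
    summarise(
      nominal_offset = .data$comp_nominal[1],
      n_nominal = dplyr::n_distinct(.data$comp_nominal),
      exact_shift = mean(.data$comp_shift),
      reporter_mz = min(.data$reporter_mz),
      tags = list(.data$tag),
      .groups = "drop"
    )
  if (any(model$n_nominal > 1)) {
    abort("`resolvable_dm` merges tags with distinct nominal complement mass; this would break the 1 Da cluster grid.")
  }
  model |>
    arrange(.data$exact_shift) |>
    mutate(
      index = row_number(),
      channel = paste0("c", .data$index),
      nominal_offset = .data$nominal_offset - .data$nominal_offset[1],
      exact_shift = .data$exact_shift - .data$exact_shift[1]
    ) |>
    select("channel", "index", "nominal_offset", "exact_shift", "reporter_mz", "tags")
}

# Mean complement-region impurity vector (offsets -2..2) per channel, averaging
# member tags: within a channel the member abundances are indistinguishable by
# construction.
.channel_impurities <- function(channels, impurities) {
  comp <- impurities |> filter(.data$region == "complement")
  purrr::map(seq_len(nrow(channels)), function(i) {
    members <- channels$tags[[i]]
    vecs <- comp |>
      filter(.data$tag_name %in% members) |>
      group_by(.data$offset) |>
      summarise(fraction = mean(.data$fraction), .groups = "drop") |>
      arrange(.data$offset)
    stats::setNames(vecs$fraction, vecs$offset)
  })
}
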