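#' Complement-ion loss model
#'
#' TMTpro complementary ions arise when the reporter region leaves the
#' precursor during HCD fragmentation. The default model has the reporter
#' depart as a singly charged cation together with the balancer carbonyl as
#' neutral CO, so the complement retains `z - 1` charges; the alternative
#' treats the reporter loss as neutral (complement keeps all `z` charges).
#' The simulator and the quantifier must share one loss model; all
#' quantitative results are loss-model-invariant as long as they do.
#'
#' @param mode `"charged_reporter"` (default, `z_c = z - 1`) or
#'   `"neutral_loss"` (`z_c = z`).
#' @param reporter_mz Reference m/z of the departing reporter cation. Default
#'   is the heaviest-reporter member of the lowest complement channel
#'   (134.154565), which makes the lowest channel the base of the cluster
#'   grid.
#' @param co_loss Whether the balancer carbonyl departs as neutral CO with
#'   the reporter (default `TRUE`). With the paper-stated precursor windows
#'   (500-1074 at 2+, 350-1381 at 3+) the CO loss keeps every cluster peak
#'   below a 2000 m/z normal-range scan ceiling.
#' @return A list of class `loss_model`.
#' @export
loss_model <- function(mode = c("charged_reporter", "neutral_loss"),
                       reporter_mz = NULL, co_loss = TRUE) {
  mode <- match.arg(mode)
  if (is.null(reporter_mz)) {
    reporter_mz <- max(tmtpro_tags()$reporter_mz) # 134C, lowest complement channel
  }
  structure(list(mode = mode, reporter_mz = reporter_mz, co_loss = co_loss),
            class = "loss_model")
}

# Mass removed from the total precursor cation mass (z protons included) and
# the resulting complement charge.
.loss_arithmetic <- function(z, lm) {
  loss <- lm$reporter_mz + if (lm$co_loss) .mass_CO() else 0
  if (lm$mode == "charged_reporter") {
    list(loss = loss, z_c = z - 1L)
  } else {
    list(loss = loss - .mass_proton, z_c = z)
  }
}

#' Precursor eligibility windows for complement quantification
#'
#' Only 2+ and 3+ precursors inside m/z windows that keep the complement
#' cluster inside a normal-range Orbitrap MS2 scan are analyzed:
#' 500-1074 Th at z = 2 and 350-1381 Th at z = 3, bounds inclusive.
#'
#' @param z Precursor charge(s).
#' @param mz Precursor m/z value(s) (Th).
#' @return Logical vector.
#' @examples
#' precursor_eligible(c(2, 2, 4), c(600, 1200, 700))
#' @export
precursor_eligible <- function(z, mz) {
  if (any(z < 1) || any(mz <= 0)) abort("`z` must be >= 1 and `mz` > 0.")
  (z == 2 & mz >= 500 & mz <= 1074) | (z == 3 & mz >= 350 & mz <= 1381)
}

#' Theoretical precursor m/z of a labeled peptide
#'
#' @param comp Peptide composition (from [composition_of_peptide()]).
#' @param z Precursor charge.
#' @return m/z in Th.
#' @export
precursor_mz <- function(comp, z) {
  (monoisotopic_mass(comp) + z * .mass_proton) / z
}

#' Predict the complement-cluster m/z grid for a precursor
#'
#' The cluster template is channel-independent: its base peak sits at the
#' lowest complement channel and one expected peak follows per channel
#' nominal offset, spaced by one 13C mass difference per charge, plus
#' `extra_isotopes` trailing peptide-envelope peaks so the deconvolution
#' system is overdetermined.
#'
#' @param mz Precursor m/z (Th).
#' @param z Precursor charge (2 or 3 for triggered species).
#' @param channels Channel model from [build_channel_model()].
#' @param lm Loss model from [loss_model()].
#' @param extra_isotopes Trailing isotope peaks beyond the last channel
#'   (default 2).
#' @return A template tibble: `position` (0-based nominal offset), `channel`
#'   (channel name or `NA` for trailing isotope peaks), `mz` (expected peak
#'   m/z, strictly increasing, spaced by 1.0033548/z_c), and attributes
#'   `z_c` and `base_mz`.
#' @examples
#' ch <- build_channel_model(tmtpro_tags())
#' complement_grid(650.4, 2, ch)
#' @export
complement_grid <- function(mz, z, channels, lm = loss_model(),
                            extra_isotopes = 2) {
  la <- .loss_arithmetic(z, lm)
  if (la$z_c < 1) abort("Loss model yields complement charge < 1.")
  base <- (z * mz - la$loss) / la$z_c
  max_off <- max(channels$nominal_offset)
  positions <- 0:(max_off + extra_isotopes)
  tpl <- tibble(
    position = positions,
    channel = channels$channel[match(positions, channels$nominal_offset)],
    mz = base + positions * .mass_C13_shift / la$z_c
  )
  attr(tpl, "z_c") <- la$z_c
  attr(tpl, "base_mz") <- base
  tpl
}

#' Extract observed cluster intensities from a centroided spectrum
#'
#' For each expected template peak the most intense spectrum peak within
#' `tol_ppm` is recorded. If one spectrum peak is claimed by two expected
#' positions, the closer expected peak wins and the other is left unmatched.
#' Unmatched positions get intensity 0 and the spectrum noise floor.
#'
#' @param spectrum Peak tibble with columns `mz`, `intensity` and optionally
#'   `noise` (per-peak FT noise), sorted by `mz`.
#' @param template Template from [complement_grid()].
#' @param tol_ppm Matching tolerance in ppm (default 10).
#' @param noise_floor Noise assigned to unmatched positions (and to all
#'   positions when the spectrum has no noise array); default: smallest
#'   positive noise in the spectrum, else 1.
#' @param resolution Optional resolving power (at m/z 200) of the scan. When
#'   given, the matching window is widened to at least the local FT peak
#'   FWHM: a centroid is the merged envelope of everything inside the peak
#'   width, so a peak containing the expected signal can sit up to one width
#'   away from the expected position. `NULL` (default) uses the pure ppm
#'   window.
#' @return The template with columns `mz_observed`, `intensity`, `noise`,
#'   `matched` appended; expected `mz` is kept.
#' @export
extract_cluster <- function(spectrum, template, tol_ppm = 10,
                            noise_floor = NULL, resolution = NULL) {
  if (tol_ppm <= 0) abort("`tol_ppm` must be > 0.")
  if (is.unsorted(spectrum$mz)) abort("`spectrum` must be sorted by m/z.")
  has_noise <- "noise" %in% names(spectrum)
  if (is.null(noise_floor)) {
    noise_floor <- if (has_noise && any(spectrum$noise > 0)) {
      min(spectrum$noise[spectrum$noise > 0])
    } else 1
  }
  n <- nrow(template)
  cand <- integer(n)   # index of best spectrum peak per template row, 0 = none
  for (i in seq_len(n)) {
    tol <- template$mz[i] * tol_ppm * 1e-6
    if (!is.null(resolution)) {
      tol <- max(tol, .peak_fwhm(template$mz[i], resolution))
    }
    hits <- which(abs(spectrum$mz - template$mz[i]) <= tol)
    cand[i] <- if (length(hits) == 0) 0L else hits[which.max(spectrum$intensity[hits])]
  }
  # Resolve duplicate claims: closer expected peak wins.
  dup <- unique(cand[duplicated(cand) & cand > 0])
  for (pk in dup) {
    claimants <- which(cand == pk)
    d <- abs(template$mz[claimants] - spectrum$mz[pk])
    losers <- claimants[-which.min(d)]
    cand[losers] <- 0L
    warn(sprintf("Template positions %s lost peak contention at m/z %.4f.",
                 paste(template$position[losers], collapse = ","),
                 spectrum$mz[pk]))
  }
  matched <- cand > 0
  template |>
    mutate(
      mz_observed = ifelse(matched, spectrum$mz[pmax(cand, 1L)], NA_real_),
      intensity = ifelse(matched, spectrum$intensity[pmax(cand, 1L)], 0),
      noise = ifelse(matched & has_noise,
                     if (has_noise) spectrum$noise[pmax(cand, 1L)] else noise_floor,
                     noise_floor),
      matched = matched
    )
}
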