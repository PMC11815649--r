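#' Quantify complement clusters for a set of PSMs
#'
#' The end-to-end per-PSM pipeline: check precursor eligibility, predict the
#' complement cluster grid, extract observed intensities from the matched
#' MS2 scan, build the impurity design matrix from the peptide's isotope
#' envelope, solve the overdetermined system by QR least squares, and apply
#' the total signal-to-noise quantification filter.
#'
#' @param spectra Scan tibble as returned by [simulate_interference_sample()]
#'   or [read_spectra()]: columns `scan`, `precursor_mz`, `precursor_charge`
#'   and a `peaks` list column.
#' @param psms PSM tibble with columns `scan`, `peptide`, `charge`,
#'   `precursor_mz`, `protein` (and optionally `psm_id`, `n_oxidation`).
#' @param channels Channel model (default: full 18-tag model).
#' @param impurities Tag impurity table; must be the one that describes the
#'   labels actually used (the simulator and quantifier share the bundled
#'   default).
#' @param lm Loss model shared with acquisition/simulation.
#' @param tol_ppm Peak-matching tolerance (default 10 ppm).
#' @param extra_isotopes Trailing envelope peaks on the grid (default 2, so
#'   the system has more rows than channels).
#' @param nonneg Negative-abundance policy passed to [solve_channels()].
#' @param n_labeled_channels Number of labeled channels for the
#'   quantification filter (default 9).
#' @param resolution Resolving power (at m/z 200) of the quantification
#'   scans, used to widen peak matching to the local FT peak width (see
#'   [extract_cluster()]); default 45000. Set `NULL` for pure ppm matching.
#' @return A tibble with one row per eligible PSM: identifiers, one
#'   abundance column per channel (`c1..c9`), `total_sn`, `residual`,
#'   `n_matched` and the `quantified` flag. Ineligible PSMs are dropped with
#'   a message.
#' @examples
#' sim <- simulate_interference_sample(sim_config(
#'   n_peptides = c(yeast = 3, human = 0), poisson = FALSE, noise_floor = 0,
#'   seed = 1))
#' quantify_psms(sim$spectra, sim$psms)
#' @export
quantify_psms <- function(spectra, psms,
                          channels = build_channel_model(tmtpro_tags()),
                          impurities = read_impurity_table(),
                          lm = loss_model(), tol_ppm = 10,
                          extra_isotopes = 2,
                          nonneg = c("clip", "nnls", "none"),
                          n_labeled_channels = 9, resolution = 45000) {
  nonneg <- match.arg(nonneg)
  imp_comp <- .channel_impurities(channels, impurities)
  if (!"psm_id" %in% names(psms)) {
    psms$psm_id <- sprintf("psm_%05d", seq_len(nrow(psms)))
  }
  if (!"n_oxidation" %in% names(psms)) psms$n_oxidation <- 0L
  eligible <- precursor_eligible(psms$charge, psms$precursor_mz)
  if (any(!eligible)) {
    message(sum(!eligible), " PSM(s) outside the precursor eligibility windows were dropped.")
  }
  psms <- psms[eligible, , drop = FALSE]
  rows <- purrr::map(seq_len(nrow(psms)), function(i) {
    p <- psms[i, ]
    pk <- spectra$peaks[[match(p$scan, spectra$scan)]]
    comp <- composition_of_peptide(p$peptide, n_oxidation = p$n_oxidation)
    env <- .envelope_auto(comp)
    tpl <- complement_grid(p$precursor_mz, p$charge, channels, lm,
                           extra_isotopes = extra_isotopes)
    A <- .design_from_vectors(env, channels, imp_comp, n_rows = nrow(tpl),
                              row_start = 0)
    B <- extract_cluster(pk, tpl, tol_ppm = tol_ppm, resolution = resolution)
    fit <- solve_channels(A, B, nonneg = nonneg)
    out <- tibble(
      psm_id = p$psm_id, scan = p$scan, peptide = p$peptide,
      protein = p$protein, charge = p$charge
    )
    for (ch in names(fit$abundances)) out[[ch]] <- fit$abundances[[ch]]
    out$total_sn <- fit$total_sn
    out$residual <- fit$residual
    out$n_matched <- fit$n_matched
    out$quantified <- passes_quant_filter(fit, n_labeled_channels)
    out
  })
  bind_rows(rows)
}
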