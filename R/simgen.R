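#' Simulation configuration
#'
#' Defines the study conditions for the two-proteome interference experiment:
#' a yeast-like proteome labeled across the nine complement channels at
#' design ratios 0:1:5:10:1:10:5:1:0 and a human-like proteome at 1:1,
#' mixed 1 part yeast to 10 parts human, with coisolation interference,
#' Poisson ion statistics and an Orbitrap-style FT noise floor.
#'
#' @param design_ratios Named list of per-proteome design ratio vectors
#'   (length 9, one level per channel c1..c9).
#' @param mix_weights Named per-proteome mixing weights (relative total
#'   amounts loaded; default yeast 1, human 10).
#' @param n_peptides Named number of simulated target peptides per proteome.
#' @param coisolation_prob Probability that a scan contains a coisolated
#'   interferent (default 0).
#' @param interferent_fraction Interferent total cluster intensity as a
#'   fraction of the target's (default 0.5).
#' @param ion_scale Expected total complement-cluster ion count for a
#'   yeast-proteome target (default 5000); other proteomes scale with their
#'   mixing weight relative to yeast.
#' @param reporter_yield Reporter-region ion count relative to the complement
#'   cluster (default 1).
#' @param poisson Apply Poisson ion-counting noise (default `TRUE`).
#' @param noise_floor FT noise floor in ion units, added as zero-mean
#'   Gaussian scatter and reported as the per-peak noise estimate (default
#'   10; 0 disables).
#' @param resolution Orbitrap resolving power at m/z 200 used by the peak
#'   coalescence rule (default 45000).
#' @param isolation_width Precursor isolation window (Th, default 0.7).
#' @param lm Loss model shared by simulator and quantifier.
#' @param extra_isotopes Trailing envelope peaks on the observation grid.
#' @param impurities Tag impurity table (default bundled table).
#' @param seed Random seed (`NULL` leaves the RNG state alone).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(design_ratios = list(yeast = c(0, 1, 5, 10, 1, 10, 5, 1, 0),
                                            human = rep(1, 9)),
                       mix_weights = c(yeast = 1, human = 10),
                       n_peptides = c(yeast = 100, human = 0),
                       coisolation_prob = 0,
                       interferent_fraction = 0.5,
                       ion_scale = 5000,
                       reporter_yield = 1,
                       poisson = TRUE,
                       noise_floor = 10,
                       resolution = 45000,
                       isolation_width = 0.7,
                       lm = loss_model(),
                       extra_isotopes = 2,
                       impurities = read_impurity_table(),
                       seed = NULL) {
  design_ratios <- lapply(design_ratios, as.numeric)
  mix_weights <- unlist(mix_weights)
  n_peptides <- unlist(n_peptides)
  if (any(unlist(design_ratios) < 0)) abort("Design ratios must be >= 0.")
  if (any(mix_weights <= 0)) abort("Mixing weights must be > 0.")
  if (coisolation_prob < 0 || coisolation_prob > 1) {
    abort("`coisolation_prob` must be in [0, 1].")
  }
  if (ion_scale < 0) abort("`ion_scale` must be >= 0.")
  structure(as.list(environment()), class = "sim_config")
}

#' Random tryptic-like peptides
#'
#' Uniform-composition sequences of length 8-20 ending in K or R; only the
#' isotope envelope of the composition matters downstream.
#'
#' @param n Number of peptides.
#' @param min_len,max_len Length bounds.
#' @return Character vector.
#' @export
random_tryptic_peptides <- function(n, min_len = 8, max_len = 20) {
  aa <- setdiff(names(.residue_table), c("I"))  # I/L isobaric; keep L
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste0(paste(sample(aa, len - 1, replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }, character(1))
}

# FWHM of an FT analyzer at m/z m for resolving power R200 at m/z 200:
# resolution scales with 1/sqrt(m), so width scales with m^1.5.
.peak_fwhm <- function(mz, r200) mz^1.5 / (r200 * sqrt(200))

# Greedy centroid coalescence of a sorted peak table: peaks closer than the
# local FWHM are merged into one intensity-weighted centroid.
.coalesce_peaks <- function(peaks, r200) {
  if (nrow(peaks) < 2) return(peaks)
  peaks <- peaks |> arrange(.data$mz)
  grp <- integer(nrow(peaks))
  g <- 1L
  grp[1] <- g
  wsum <- peaks$mz[1] * peaks$intensity[1]
  isum <- peaks$intensity[1]
  for (i in 2:nrow(peaks)) {
    c_mz <- if (isum > 0) wsum / isum else peaks$mz[i - 1]
    if (peaks$mz[i] - c_mz < .peak_fwhm(c_mz, r200)) {
      grp[i] <- g
      wsum <- wsum + peaks$mz[i] * peaks$intensity[i]
      isum <- isum + peaks$intensity[i]
    } else {
      g <- g + 1L
      grp[i] <- g
      wsum <- peaks$mz[i] * peaks$intensity[i]
      isum <- peaks$intensity[i]
    }
  }
  peaks$.grp <- grp
  peaks |>
    group_by(.data$.grp) |>
    summarise(
      mz = sum(.data$mz * .data$intensity) / sum(.data$intensity),
      intensity = sum(.data$intensity),
      noise = max(.data$noise),
      .groups = "drop"
    ) |>
    select("mz", "intensity", "noise")
}

# Noiseless peak table (complement cluster + reporter region) for one
# peptide at given channel ion counts. Each 1 Da cluster bin aggregates
# contributions whose mass-defect spread (< 13 mDa) is unresolvable at the
# modeled transient lengths, so bins sit on the uniform 13C-spaced grid --
# the same grid the cluster template predicts.
.peptide_peak_table <- function(sequence, z, mz_prec, x_ions, config, channels,
                                imp_comp, rep_tpl) {
  comp <- composition_of_peptide(sequence)
  env <- .envelope_auto(comp)
  la <- .loss_arithmetic(z, config$lm)
  base <- (z * mz_prec - la$loss) / la$z_c
  max_off <- max(channels$nominal_offset)
  n_rows <- max_off + length(env) + 4
  A <- .design_from_vectors(env, channels, imp_comp,
                            n_rows = n_rows, row_start = -2)
  expected <- as.numeric(A %*% x_ions)
  pos <- attr(A, "row_positions")
  # Reporter region: one designated reporter per channel, spread by that
  # tag's reporter impurity vector (deliberately uncorrected downstream).
  rep_int <- config$reporter_yield * as.numeric(rep_tpl$frac %*% diag(x_ions))
  out <- tibble(
    mz = c(as.numeric(rep_tpl$mz), base + pos * .mass_C13_shift / la$z_c),
    intensity = c(rep_int, expected),
    region = rep(c("reporter", "complement"), c(length(rep_int), length(pos)))
  )
  out[out$intensity > 0, ]
}

# Per-channel designated-reporter m/z and impurity-fraction matrices
# (offsets -2..2 in rows), precomputed once per simulated run.
.reporter_template <- function(channels, impurities) {
  tagtab <- tmtpro_tags()
  rep_imp <- impurities |> filter(.data$region == "reporter")
  mzs <- matrix(0, 5, nrow(channels))
  frac <- matrix(0, 5, nrow(channels))
  for (i in seq_len(nrow(channels))) {
    desig <- channels$tags[[i]][which.min(
      tagtab$reporter_mz[match(channels$tags[[i]], tagtab$tag)])]
    vec <- rep_imp |> filter(.data$tag_name == desig) |> arrange(.data$offset)
    mzs[, i] <- channels$reporter_mz[i] + vec$offset * .mass_C13_shift
    frac[, i] <- vec$fraction
  }
  list(mz = mzs, frac = frac)
}

#' Simulate a two-proteome interference sample
#'
#' Generates one centroided MS2 scan per target peptide: the target's
#' complement cluster (channel intensities proportional to its proteome's
#' design ratios, distorted by the tag impurity table and Poisson ion
#' sampling) plus, with probability `coisolation_prob`, a coisolated
#' interferent's complement cluster, and both species' reporter-region
#' peaks. Peaks closer than the resolution-dependent width are coalesced
#' into one intensity-weighted centroid.
#'
#' @param config A [sim_config()].
#' @return A list with class `tmt_sim`: `spectra` (scan tibble with a
#'   `peaks` list column of mz/intensity/noise tibbles), `psms` (PSM table),
#'   and `truth` (ledger: one row per emitted scan with the channel truth
#'   vector `truth_c1..c9` in ion units, interferent identity/fraction, and
#'   the noiseless peak table as a list column).
#' @export
simulate_interference_sample <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  channels <- build_channel_model(tmtpro_tags())
  imp_comp <- .channel_impurities(channels, config$impurities)
  rep_tpl <- .reporter_template(channels, config$impurities)
  proteomes <- names(config$n_peptides)[config$n_peptides > 0]
  ref_w <- config$mix_weights[[1]]

  scans <- list(); psms <- list(); truths <- list()
  scan_id <- 0L
  for (prot in proteomes) {
    n <- config$n_peptides[[prot]]
    design <- config$design_ratios[[prot]]
    peps <- character(0)
    while (length(peps) < n) {
      cand <- random_tryptic_peptides(n)
      keep <- vapply(cand, function(s) {
        cmp <- composition_of_peptide(s)
        any(precursor_eligible(2:3, precursor_mz(cmp, 2:3)))
      }, logical(1))
      peps <- c(peps, cand[keep])
    }
    peps <- peps[seq_len(n)]
    for (j in seq_along(peps)) {
      scan_id <- scan_id + 1L
      seq_j <- peps[j]
      cmp <- composition_of_peptide(seq_j)
      zs <- c(2L, 3L)[precursor_eligible(2:3, precursor_mz(cmp, 2:3))]
      z <- if (length(zs) == 1) zs else sample(zs, 1)
      mz_prec <- precursor_mz(cmp, z)
      scale_j <- config$ion_scale * config$mix_weights[[prot]] / ref_w
      x_truth <- if (sum(design) > 0) design / sum(design) * scale_j else design * 0
      pk <- .peptide_peak_table(seq_j, z, mz_prec, x_truth, config, channels,
                                imp_comp, rep_tpl)

      interfered <- config$coisolation_prob > 0 &&
        stats::runif(1) < config$coisolation_prob
      int_pep <- NA_character_; int_scale <- NA_real_; int_prot <- NA_character_
      if (interfered) {
        w <- config$mix_weights / sum(config$mix_weights)
        int_prot <- sample(names(w), 1, prob = w)
        int_pep <- random_tryptic_peptides(1)
        int_z <- sample(2:3, 1)
        int_mz <- mz_prec + stats::runif(1, -config$isolation_width / 2,
                                         config$isolation_width / 2)
        int_design <- config$design_ratios[[int_prot]]
        int_total <- config$interferent_fraction * sum(x_truth)
        int_x <- int_design / sum(int_design) * int_total
        int_scale <- int_total / max(sum(x_truth), 1e-300)
        pk <- bind_rows(pk,
          .peptide_peak_table(int_pep, int_z, int_mz, int_x, config, channels,
                              imp_comp, rep_tpl))
      }

      noiseless <- pk |> arrange(.data$mz)
      obs <- noiseless
      if (config$poisson) obs$intensity <- stats::rpois(nrow(obs), obs$intensity)
      if (config$noise_floor > 0) {
        obs$intensity <- pmax(0, obs$intensity +
                                stats::rnorm(nrow(obs), 0, config$noise_floor))
      }
      obs$noise <- max(config$noise_floor, 1)
      obs <- obs |> filter(.data$intensity > 0) |> select("mz", "intensity", "noise")
      obs <- .coalesce_peaks(obs, config$resolution)

      scans[[scan_id]] <- tibble(
        scan = scan_id, ms_level = 2L,
        precursor_mz = mz_prec, precursor_charge = z,
        peaks = list(obs)
      )
      psms[[scan_id]] <- tibble(
        psm_id = sprintf("psm_%05d", scan_id), scan = scan_id,
        peptide = seq_j, modifications = "", charge = z,
        precursor_mz = mz_prec,
        protein = sprintf("%s_%04d", toupper(substr(prot, 1, 3)), j),
        xcorr = 1.5 + stats::rexp(1, 1), delta_cn = stats::runif(1, 0.2, 0.6),
        ppm_dev = stats::rnorm(1, 0, 2)
      )
      tr <- tibble(
        psm_id = sprintf("psm_%05d", scan_id), scan = scan_id,
        peptide = seq_j, proteome = prot, charge = z, precursor_mz = mz_prec,
        interfered = interfered, interferent_peptide = int_pep,
        interferent_proteome = int_prot, interferent_scale = int_scale,
        empty = nrow(obs) == 0,
        noiseless_peaks = list(noiseless)
      )
      for (k in seq_len(nrow(channels))) tr[[paste0("truth_c", k)]] <- x_truth[k]
      truths[[scan_id]] <- tr
    }
  }
  structure(list(
    spectra = bind_rows(scans),
    psms = bind_rows(psms),
    truth = bind_rows(truths),
    config = config,
    channels = channels
  ), class = "tmt_sim")
}

#' Reporter-ion baseline quantification
#'
#' Sums reporter-region intensity at each channel's designated reporter m/z.
#' Coisolated species share reporter m/z, so interference is included by
#' construction -- this is the interference-prone baseline the complement
#' method avoids. No impurity correction is applied.
#'
#' @param spectrum Peak tibble (`mz`, `intensity`).
#' @param channels Channel model.
#' @param tol_ppm Matching tolerance (default 10 ppm).
#' @return Named numeric vector of per-channel reporter intensities.
#' @export
quantify_reporters <- function(spectrum, channels, tol_ppm = 10) {
  out <- vapply(seq_len(nrow(channels)), function(i) {
    tol <- channels$reporter_mz[i] * tol_ppm * 1e-6
    sum(spectrum$intensity[abs(spectrum$mz - channels$reporter_mz[i]) <= tol])
  }, numeric(1))
  stats::setNames(out, channels$channel)
}

#' Real-time-search acceptance filter
#'
#' Emulates the on-instrument PSM filter: cross-correlation strictly greater
#' than 1.4, delta cross-correlation at least 0.2, absolute precursor mass
#' deviation at most 10 ppm, and membership of the target protein list
#' (exclusion-tag emulation of the semitargeted mode).
#'
#' @param xcorr Cross-correlation score(s).
#' @param delta_cn Delta cross-correlation score(s).
#' @param ppm_dev Precursor deviation(s) in ppm.
#' @param on_target_list Logical: PSM maps to a target-list protein.
#' @return Logical vector.
#' @examples
#' rts_accept(1.5, 0.25, 5, TRUE)
#' rts_accept(1.4, 0.25, 5, TRUE)  # strict threshold
#' @export
rts_accept <- function(xcorr, delta_cn, ppm_dev, on_target_list = TRUE) {
  if (any(!is.finite(xcorr)) || any(!is.finite(delta_cn)) || any(!is.finite(ppm_dev))) {
    abort("Scores must be finite.")
  }
  xcorr > 1.4 & delta_cn >= 0.2 & abs(ppm_dev) <= 10 & on_target_list
}

#' Simulate a developmental time-course quantification matrix
#'
#' Proteins are drawn from trajectory archetypes (constant, increasing,
#' decreasing, peaked) over developmental stages; each peptide observes its
#' protein's archetype under multiplicative lognormal noise. A configurable
#' fraction of constant proteins are flagged as anchors (the mitochondrial
#' stand-in used for normalization). An optional per-stage acquisition
#' efficiency emulates drift that anchor normalization must remove.
#'
#' @param n_proteins Number of proteins.
#' @param n_stages Number of stages (>= 2).
#' @param peptides_per_protein Peptides observed per protein.
#' @param archetypes Named list of trajectory functions of stage fraction
#'   `t` in \[0, 1\]; must include `constant`.
#' @param archetype_scale Multiplier on the non-constant archetype dynamic
#'   range (separation knob for recovery experiments).
#' @param anchor_fraction Fraction of proteins that are anchors (always
#'   constant).
#' @param noise_sd Lognormal sigma of peptide-level noise.
#' @param stage_efficiency Per-stage multiplicative acquisition efficiency
#'   (length `n_stages`; default all 1).
#' @param seed Random seed.
#' @return List: `quant` (peptide tibble: `peptide`, `protein`, `anchor`,
#'   stage columns `s1..sN`) and `proteins` (protein, archetype, anchor).
#' @export
simulate_timecourse <- function(n_proteins = 200, n_stages = 9,
                                peptides_per_protein = 3,
                                archetypes = NULL, archetype_scale = 1,
                                anchor_fraction = 0.15, noise_sd = 0.2,
                                stage_efficiency = NULL, seed = NULL) {
  if (n_stages < 2) abort("`n_stages` must be >= 2.")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(archetypes)) {
    archetypes <- list(
      constant = function(t) rep(1, length(t)),
      increasing = function(t) 1 + 2 * archetype_scale * t,
      decreasing = function(t) 1 + 2 * archetype_scale * (1 - t),
      peaked = function(t) 1 + 3 * archetype_scale * exp(-((t - 0.5) / 0.18)^2)
    )
  }
  if (!"constant" %in% names(archetypes)) {
    abort("`archetypes` must include a constant class (the anchor stand-in).")
  }
  if (is.null(stage_efficiency)) stage_efficiency <- rep(1, n_stages)
  if (length(stage_efficiency) != n_stages) {
    abort("`stage_efficiency` must have length `n_stages`.")
  }
  tfrac <- seq(0, 1, length.out = n_stages)
  n_anchor <- round(anchor_fraction * n_proteins)
  arch_names <- c(rep("constant", n_anchor),
                  sample(names(archetypes), n_proteins - n_anchor, replace = TRUE))
  proteins <- tibble(
    protein = sprintf("P%04d", seq_len(n_proteins)),
    archetype = arch_names,
    anchor = seq_len(n_proteins) <= n_anchor
  )
  quant <- purrr::map_dfr(seq_len(n_proteins), function(i) {
    traj <- archetypes[[proteins$archetype[i]]](tfrac)
    purrr::map_dfr(seq_len(peptides_per_protein), function(p) {
      noise <- if (noise_sd > 0) exp(stats::rnorm(n_stages, 0, noise_sd)) else rep(1, n_stages)
      vals <- traj * noise * stage_efficiency
      out <- tibble(peptide = sprintf("%s_pep%02d", proteins$protein[i], p),
                    protein = proteins$protein[i],
                    anchor = proteins$anchor[i])
      for (s in seq_len(n_stages)) out[[paste0("s", s)]] <- vals[s]
      out
    })
  })
  list(quant = quant, proteins = proteins)
}
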