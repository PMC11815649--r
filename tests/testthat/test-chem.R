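# Standalone residue monoisotopic masses (standard table) for oracle sums.
.residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

test_that("peptide compositions follow the static labeling scheme", {
  gk <- composition_of_peptide("GK")
  # one label on the N terminus plus one on the lysine
  expect_equal(attr(gk, "n_labels"), 2L)
  expect_equal(unclass(gk)[["C13"]], 14)
  expect_equal(unclass(gk)[["N15"]], 4)

  # NEM on cysteine shifts the residue by the printed +125.047679
  with_nem <- composition_of_peptide("CAR", label = "none")
  without <- composition_of_peptide("CAR", label = "none", nem_cysteine = FALSE)
  expect_equal(monoisotopic_mass(with_nem) - monoisotopic_mass(without),
               125.047679, tolerance = 1e-8)

  # residue-table summation oracle
  oracle <- sum(.residue_masses[strsplit("PEPTIDE", "")[[1]]]) + 18.010565
  expect_equal(monoisotopic_mass(composition_of_peptide("PEPTIDE", label = "none",
                                                        nem_cysteine = FALSE)),
               oracle, tolerance = 1e-4)

  # methionine oxidation is the printed +15.99492
  ox <- composition_of_peptide("AMK", n_oxidation = 1)
  noox <- composition_of_peptide("AMK")
  expect_equal(monoisotopic_mass(ox) - monoisotopic_mass(noox),
               15.99492, tolerance = 1e-5)

  expect_error(composition_of_peptide("AXZ"), "Unknown residue")
  expect_error(composition_of_peptide("AMMK", n_oxidation = 3), "At most 2")
})

test_that("monoisotopic masses match reference values", {
  expect_equal(monoisotopic_mass(tmtpro_composition()), 304.2071,
               tolerance = 0.0005 / 304)
  expect_equal(monoisotopic_mass(elemental_composition()), 0)
  expect_equal(monoisotopic_mass(elemental_composition(H = 2, O = 1)),
               18.010565, tolerance = 1e-4 / 18)
})

test_that("aggregated isotope envelopes are correct and normalized", {
  expect_equal(isotope_envelope(elemental_composition(C = 1), 2),
               c(0.9893, 0.0107), tolerance = 0.0005)
  # 10-residue tryptic peptide vs exhaustive enumeration oracle
  comp <- composition_of_peptide("ACDEFGHMWK")
  env <- isotope_envelope(comp, 8)
  expect_lte(sum(env), 1)
  expect_true(all(env >= 0))
  expect_equal(env, envelope_oracle(comp, 8), tolerance = 1e-6)
  # offset 0 is the monoisotopic peak: largest for small molecules
  expect_equal(which.max(isotope_envelope(elemental_composition(C = 10, H = 20), 4)), 1)
})

test_that("envelope convolution is associative over composition addition", {
  a <- composition_of_peptide("PEPT", label = "none")
  b <- composition_of_peptide("IDEK", label = "none")
  n <- 9
  conv <- function(x, y) {
    out <- numeric(n)
    for (i in seq_along(x)) {
      jmax <- min(length(y), n - i + 1)
      if (jmax < 1) next
      out[i:(i + jmax - 1)] <- out[i:(i + jmax - 1)] + x[i] * y[seq_len(jmax)]
    }
    out
  }
  expect_equal(isotope_envelope(a + b, n),
               conv(isotope_envelope(a, n), isotope_envelope(b, n)),
               tolerance = 1e-9)
})

test_that("appending any residue strictly increases the labeled mass", {
  base <- monoisotopic_mass(composition_of_peptide("PEPTIDER"))
  for (res in names(.residue_masses)) {
    expect_gt(monoisotopic_mass(composition_of_peptide(paste0("PEPTIDER", res))),
              base)
  }
})

test_that("the 18 tags are isobaric and collapse into 9 channels", {
  tags <- tmtpro_tags()
  expect_equal(nrow(tags), 18)
  expect_lt(max(tags$total_heavy_mass) - min(tags$total_heavy_mass), 0.02)

  model <- build_channel_model(tags, resolvable_dm = 0.02)
  expect_equal(nrow(model), 9)
  expect_equal(model$channel, paste0("c", 1:9))
  expect_equal(model$nominal_offset, 0:8)
  expect_true(all(diff(model$exact_shift) > 0))
  expect_equal(sort(unlist(model$tags)), sort(tags$tag))

  # single tag is a single channel
  expect_equal(nrow(build_channel_model(tags[1, , drop = FALSE])), 1)

  # a 13C <-> 15N swap pair differs by 6.32 mDa and merges at 0.02 Da
  pair <- tags[tags$tag %in% c("132C", "133N"), ]
  expect_equal(abs(diff(pair$comp_shift)), 0.0063199, tolerance = 1e-4)
  expect_equal(nrow(build_channel_model(pair, resolvable_dm = 0.02)), 1)
  expect_equal(nrow(build_channel_model(pair, resolvable_dm = 0.005)), 2)

  # thresholds that merge distinct nominal masses break the 1 Da grid
  expect_error(build_channel_model(tags, resolvable_dm = 2), "1 Da")
})

test_that("channel model is invariant to tag input order", {
  tags <- tmtpro_tags()
  set.seed(1)
  shuffled <- tags[sample(nrow(tags)), ]
  expect_equal(build_channel_model(tags), build_channel_model(shuffled))
})

test_that("reporter ion masses reproduce the published series", {
  tags <- tmtpro_tags()
  expect_equal(tags$reporter_mz[tags$tag == "126"], 126.127726, tolerance = 1e-5)
  expect_equal(tags$reporter_mz[tags$tag == "127N"], 127.124761, tolerance = 1e-5)
  expect_equal(tags$reporter_mz[tags$tag == "127C"], 127.131081, tolerance = 1e-5)
  expect_equal(tags$reporter_mz[tags$tag == "135N"], 135.151600, tolerance = 1e-5)
})

test_that("impurity tables validate and sum to one per tag and region", {
  imp <- read_impurity_table()
  expect_setequal(names(imp), c("tag_name", "region", "offset", "fraction"))
  sums <- tapply(imp$fraction, paste(imp$tag_name, imp$region), sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  # off-diagonal impurities stay within the realistic 0-3% band
  expect_true(all(imp$fraction[imp$offset != 0] <= 0.03))
  bad <- imp
  bad$fraction[1] <- bad$fraction[1] + 0.5
  tf <- tempfile(fileext = ".tsv")
  readr::write_tsv(bad, tf)
  expect_error(read_impurity_table(tf), "sum to 1")
})
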