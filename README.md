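# tmtproc

Interference-free multiplexed proteome quantification from **TMTpro
complementary ions**, in R.

## Why complementary ions

Isobaric TMTpro labeling multiplexes up to 18 samples, but the conventional
readout — low-mass reporter ions in MS2 — suffers from coisolation
interference: every peptide co-selected in the precursor isolation window
sheds reporters at the same m/z, so measured ratios are compressed toward
the mixture average. The complementary ion (the balancer–peptide conjugate
left after the reporter region departs) is peptide-specific: coisolated
species form clusters at different m/z, making MS2 quantification from the
complement cluster essentially interference-free.

`tmtproc` implements this route end to end:

* **Tag chemistry** — isotopologue compositions of the 18 TMTpro labels
  (total +304.2071 Da, reporters 126.127726–135.151600), and their collapse
  into 9 distinguishable complement channels: tags whose balancers differ
  only by a ¹³C↔¹⁵N swap (Δm = 6.32 mDa) are unresolvable at practical
  Orbitrap transients and merge at the default 0.02 Da threshold.
* **Cluster prediction and extraction** — the complement cluster template
  for a PSM with precursor m/z *p* and charge *z* sits at
  `(z·p − loss)/z_c` with one peak per channel offset spaced by
  `1.00335/z_c`, where `loss` is the departing reporter cation plus CO
  under the default loss model and `z_c = z − 1`.
* **Impurity deconvolution** — observed cluster intensities **B** relate to
  channel abundances **x** through **A x = B**, where column *c* of **A**
  is channel *c*'s complement-region impurity vector convolved with the
  peptide's aggregated isotope envelope and shifted to its nominal offset.
  The overdetermined system is solved by QR decomposition; peptides pass
  the quantification filter at a total signal:FT-noise of 90 (9-plex) or
  10× the labeled channel count.
* **A synthetic acquisition simulator** — two-proteome interference samples
  (yeast-like design 0:1:5:10:1:10:5:1:0, human-like 1:1, mixed 1:10) with
  Poisson ion statistics, an FT noise floor, resolution-dependent centroid
  coalescence, coisolation, reporter-ion baselines, and a truth ledger, so
  every stage is testable without instrument data.
* **Time-course analysis** — razor peptide→protein assignment, anchor
  (mitochondrial-style) normalization, median protein roll-up, hierarchical
  k-means trajectory clustering with a two-pass reclustering schedule, and
  first/last fold-change summaries.

## Worked example

Simulate a 50-PSM yeast-design run with 30% coisolation, quantify it, and
compare the complement readout with the interference-prone reporter
baseline:

```r
library(tmtproc)

ch <- build_channel_model(tmtpro_tags())
ch
#> # A tibble: 9 × 6
#>   channel index nominal_offset exact_shift reporter_mz tags
#>   <chr>   <int>          <int>       <dbl>       <dbl> <list>
#> 1 c1          1              0        0           134. <chr [2]>
#> 2 c2          2              1        1.00        133. <chr [2]>
#> 3 c3          3              2        2.00        132. <chr [2]>
#> # i 6 more rows

cfg <- sim_config(n_peptides = c(yeast = 50, human = 0),
                  coisolation_prob = 0.3, noise_floor = 0, seed = 11)
sim <- simulate_interference_sample(cfg)
quant <- quantify_psms(sim$spectra, sim$psms)
dplyr::select(quant, peptide, c2, c4, c6, total_sn, quantified)
#> # A tibble: 50 × 6
#>   peptide              c2    c4    c6 total_sn quantified
#>   <chr>             <dbl> <dbl> <dbl>    <dbl> <lgl>
#> 1 AFRVKCSQCEARLHCTR 139.  1497. 1963.     4987 TRUE
#> 2 SQYKASDFQR        147.  1547. 1540.     4933 TRUE
#> 3 LCLCERVYVRFKMYCK   95.2 1583. 1436.     4810 TRUE
#> 4 TFTTMTRK          151.  1474. 1436.     4990 TRUE
#> # i 46 more rows

r <- quant$c4 / quant$c2
median(r[is.finite(r)])
#> [1] 10.24
rep_ratio <- vapply(seq_len(nrow(sim$spectra)), function(i) {
  x <- quantify_reporters(sim$spectra$peaks[[i]], sim$channels)
  x[["c4"]] / x[["c2"]]
}, numeric(1))
mean(rep_ratio)
#> [1] 7.46
```

Channels `c4` and `c2` were mixed at 10:1. The complement-cluster readout
recovers the design ratio (median 10.24 at 5000 Poisson ions per cluster)
while the reporter readout is compressed to 7.46 by the 1:1 coisolated
background — the central contrast the method exists to fix. Each PSM's
`total_sn` is its summed signal:FT-noise, gating the `quantified` flag.

Fitted objects follow broom conventions (`tidy()`, `glance()`) and have
`autoplot()` methods; a thin command-line front end
(`inst/cli/tmtproc`) exposes `simulate`, `quantify` and `timecourse`
subcommands over mzML/TSV files.

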