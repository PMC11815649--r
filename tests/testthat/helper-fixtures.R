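# Shared fixtures for the suite. Everything is generated in code.

noiseless_config <- function(n_yeast = 10, n_human = 0, ...) {
  sim_config(
    n_peptides = c(yeast = n_yeast, human = n_human),
    poisson = FALSE, noise_floor = 0, coisolation_prob = 0,
    ...
  )
}

channel_model_18 <- build_channel_model(tmtpro_tags())

# Truth matrix (scans x channels) aligned to a quant result.
truth_matrix <- function(sim, quant) {
  as.matrix(sim$truth[match(quant$scan, sim$truth$scan),
                      paste0("truth_c", 1:9)])
}

quant_matrix <- function(quant) as.matrix(quant[, paste0("c", 1:9)])

# A minimal two-channel model reusing real tag names so impurity lookups work.
toy_channels <- function() {
  tibble::tibble(
    channel = c("c1", "c2"), index = 1:2, nominal_offset = c(0L, 1L),
    exact_shift = c(0, 1.0033548),
    reporter_mz = c(134.154565, 133.151210),
    tags = list("134C", "133C")
  )
}

# Independent aggregated-envelope oracle: exhaustive enumeration of heavy-atom
# counts per element with dbinom/dmultinom (no polynomial convolution).
envelope_oracle <- function(comp, n_offsets) {
  pats <- list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99632, 0.00368),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9493, 0.0076, 0.0429, 0.0000, 0.0002)
  )
  per_element <- lapply(names(pats), function(el) {
    n <- unclass(comp)[[el]]
    pat <- pats[[el]]
    if (n == 0) return(1)
    k <- length(pat)
    max_off <- n_offsets - 1
    out <- numeric(max_off + 1)
    # enumerate counts of each isotope species across n atoms
    grid <- expand.grid(rep(list(0:min(n, max_off)), k - 1))
    for (r in seq_len(nrow(grid))) {
      counts_heavy <- as.numeric(grid[r, ])
      if (sum(counts_heavy) > n) next
      off <- sum(counts_heavy * seq_len(k - 1))
      if (off > max_off) next
      cnt <- c(n - sum(counts_heavy), counts_heavy)
      out[off + 1] <- out[off + 1] + stats::dmultinom(cnt, prob = pat)
    }
    out
  })
  env <- Reduce(function(a, b) {
    out <- numeric(n_offsets)
    for (i in seq_along(a)) {
      jmax <- min(length(b), n_offsets - i + 1)
      if (jmax < 1) next
      out[i:(i + jmax - 1)] <- out[i:(i + jmax - 1)] + a[i] * b[seq_len(jmax)]
    }
    out
  }, lapply(per_element, function(p) c(p, numeric(max(0, n_offsets - length(p))))[seq_len(n_offsets)]))
  env
}
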