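#' Build the impurity design matrix A
#'
#' Column `c` of the design matrix is the complement-region impurity vector
#' of channel `c` (averaged over its member tags, whose abundances are
#' indistinguishable within a channel) convolved with the peptide isotope
#' envelope and shifted to the channel's nominal offset. Rows are observed
#' cluster grid positions; signal convolved below `row_start` or beyond the
#' last row is dropped, so each column sums to at most 1 (the envelope mass
#' retained on the grid).
#'
#' @param envelope Peptide isotope envelope from [isotope_envelope()]. Its
#'   retained mass must be >= 0.999 (it is then renormalized to 1); otherwise
#'   recompute with more offsets.
#' @param channels Channel model from [build_channel_model()].
#' @param impurities Impurity table from [read_impurity_table()].
#' @param n_rows Number of grid rows (>= highest channel offset + 1 and >=
#'   channel count).
#' @param row_start First grid position covered by row 1 (default 0, the
#'   lowest channel; the simulator uses negative values to place signal the
#'   observation grid does not cover).
#' @return Numeric matrix (rows `n_rows`, columns = channels) with dimnames;
#'   attribute `row_positions` gives the nominal offset of each row.
#' @export
build_design_matrix <- function(envelope, channels,
                                impurities = read_impurity_table(),
                                n_rows = max(channels$nominal_offset) + 3,
                                row_start = 0) {
  if (n_rows < max(channels$nominal_offset) - row_start + 1) {
    abort("`n_rows` must cover the highest channel offset.")
  }
  if (n_rows < nrow(channels)) abort("`n_rows` must be >= the channel count.")
  imp <- .channel_impurities(channels, impurities)
  .design_from_vectors(envelope, channels, imp, n_rows, row_start)
}

# Design-matrix kernel on precomputed channel impurity vectors (avoids
# re-deriving them per PSM in the pipeline loops).
.design_from_vectors <- function(envelope, channels, imp, n_rows, row_start) {
  retained <- sum(envelope)
  if (retained < 0.999) {
    abort("Isotope envelope retains < 99.9% of its mass; recompute with more offsets.")
  }
  envelope <- envelope / retained
  A <- matrix(0, nrow = n_rows, ncol = nrow(channels),
              dimnames = list(paste0("r", row_start + seq_len(n_rows) - 1),
                              channels$channel))
  for (c_i in seq_len(nrow(channels))) {
    vec <- imp[[c_i]]
    off0 <- as.integer(names(vec)[1])
    conv <- .poly_mult(vec, envelope, length(vec) + length(envelope) - 1)
    rows <- channels$nominal_offset[c_i] + off0 + seq_along(conv) - 1 - row_start + 1
    keep <- rows >= 1 & rows <= n_rows
    A[rows[keep], c_i] <- A[rows[keep], c_i] + conv[keep]
  }
  attr(A, "row_positions") <- row_start + seq_len(n_rows) - 1
  A
}

# Lawson-Hanson active-set non-negative least squares.
.nnls <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  passive <- logical(n)
  x <- numeric(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0
  while (any(!passive) && max(w[!passive]) > tol && iter < 30 * n) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      s[passive] <- qr.solve(A[, passive, drop = FALSE], b)
      if (all(s[passive] > tol)) {
        x <- s
        break
      }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

#' Solve the overdetermined system A x = B for channel abundances
#'
#' Least-squares solution of the impurity system via QR (orthogonal)
#' decomposition. Negative components are clipped to zero by default, since
#' channel abundances are physical; full non-negative least squares or the
#' raw solution are available instead.
#'
#' @param A Design matrix from [build_design_matrix()].
#' @param B Observed cluster: either the tibble returned by
#'   [extract_cluster()] (intensity, noise and matched mask aligned to the
#'   grid) or a bare numeric vector of intensities.
#' @param nonneg Negative-value policy: `"clip"` (default), `"nnls"`
#'   (Lawson-Hanson), or `"none"`.
#' @return An object of class `channel_fit`: channel abundances plus fit
#'   diagnostics (residual norm, total signal-to-noise over matched peaks,
#'   number of matched peaks). Use [generics::tidy()] / [generics::glance()]
#'   to get tibbles.
#' @export
solve_channels <- function(A, B, nonneg = c("clip", "nnls", "none")) {
  nonneg <- match.arg(nonneg)
  if (is.data.frame(B)) {
    b <- B$intensity
    total_sn <- sum((B$intensity / B$noise)[B$matched])
    n_matched <- sum(B$matched)
  } else {
    b <- as.numeric(B)
    total_sn <- NA_real_
    n_matched <- NA_integer_
  }
  if (nrow(A) != length(b)) abort("rows(A) must equal length(B).")
  dec <- qr(A)
  if (dec$rank < ncol(A)) {
    dropped <- colnames(A)[dec$pivot[(dec$rank + 1):ncol(A)]]
    abort(paste0("Design matrix is rank deficient; collinear channel(s): ",
                 paste(dropped, collapse = ", ")))
  }
  raw <- as.numeric(qr.coef(dec, b))
  x <- switch(nonneg,
    clip = pmax(raw, 0),
    nnls = .nnls(A, b),
    none = raw
  )
  names(x) <- colnames(A)
  names(raw) <- colnames(A)
  structure(
    list(
      abundances = x,
      raw = raw,
      residual = sqrt(sum((A %*% x - b)^2)),
      total_sn = total_sn,
      n_matched = n_matched,
      nonneg = nonneg
    ),
    class = "channel_fit"
  )
}

#' @export
print.channel_fit <- function(x, ...) {
  cat("<channel_fit> ", length(x$abundances), " channels, residual ",
      format(x$residual, digits = 4), ", total S/N ",
      format(x$total_sn, digits = 4), "\n", sep = "")
  print(round(x$abundances, 3))
  invisible(x)
}

#' @rdname solve_channels
#' @param x A `channel_fit`.
#' @param ... Unused.
#' @export
tidy.channel_fit <- function(x, ...) {
  tibble(channel = names(x$abundances),
         abundance = unname(x$abundances),
         raw = unname(x$raw))
}

#' @rdname solve_channels
#' @export
glance.channel_fit <- function(x, ...) {
  tibble(residual = x$residual, total_sn = x$total_sn,
         n_matched = x$n_matched, nonneg = x$nonneg)
}

#' Quantification filter on total signal-to-noise
#'
#' A peptide is considered quantified when its summed signal-to-FT-noise over
#' matched cluster peaks reaches 90 for a full 9-plex, or 10 times the number
#' of labeled channels when fewer channels are labeled.
#'
#' @param x A `channel_fit` (its `total_sn` is used) or a numeric total S/N.
#' @param n_labeled_channels Number of labeled channels (>= 1; default 9).
#' @return Logical.
#' @examples
#' passes_quant_filter(90)
#' passes_quant_filter(89.9)
#' @export
passes_quant_filter <- function(x, n_labeled_channels = 9) {
  if (n_labeled_channels < 1) abort("`n_labeled_channels` must be >= 1.")
  sn <- if (inherits(x, "channel_fit")) x$total_sn else as.numeric(x)
  threshold <- if (n_labeled_channels == 9) 90 else 10 * n_labeled_channels
  sn >= threshold
}
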