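#' Daubechies-10 filter bank
#'
#' Decomposition low-pass filter for the orthonormal Daubechies wavelet with
#' 10 vanishing moments (20 taps).  The remaining three filters of the
#' orthogonal bank are derived by the usual quadrature-mirror relations.
#'
#' @return list with components `dec_lo`, `dec_hi`, `rec_lo`, `rec_hi`.
#' @keywords internal
db10_filters <- function() {
  rec_lo <- c(
    0.026670057900555554, 0.18817680007769148, 0.5272011889317256,
    0.6884590394536035, 0.2811723436605775, -0.24984642432731538,
    -0.19594627437737705, 0.12736934033579325, 0.09305736460357235,
    -0.07139414716639708, -0.029457536821875813, 0.033212674059341,
    0.0036065535669561697, -0.010733175483330575, 0.001395351747052901,
    0.001992405295185056, -0.0006858566949597116, -0.00011646685512928545,
    9.358867032006959e-05, -1.3264202894521244e-05)
  L <- length(rec_lo)
  dec_lo <- rev(rec_lo)
  dec_hi <- rec_lo * (-1)^seq_len(L)   # alternating flip: g[m] = (-1)^(m+1) h[L-1-m]
  rec_hi <- rev(dec_hi)
  list(dec_lo = dec_lo, dec_hi = dec_hi, rec_lo = rec_lo, rec_hi = rec_hi)
}

## circular convolution y[k] = sum_m f[m] x[(k + m - 1) mod N], k = 1..N
circ_filt <- function(x, f) {
  n <- length(x)
  L <- length(f)
  idx <- outer(seq_len(n) - 1L, seq_len(L) - 1L, "+") %% n + 1L
  as.numeric(matrix(x[idx], n, L) %*% f)
}

dwt_step <- function(x, filt) {
  n <- length(x)
  padded <- n %% 2L == 1L
  if (padded) x <- c(x, x[n])            # repeat last sample to even length
  lo <- circ_filt(x, filt$dec_lo)
  hi <- circ_filt(x, filt$dec_hi)
  keep <- seq(1L, length(x), by = 2L)
  list(approx = lo[keep], detail = hi[keep], len = n)
}

idwt_step <- function(approx, detail, len, filt) {
  n <- 2L * length(approx)
  up_a <- numeric(n); up_a[seq(1L, n, 2L)] <- approx
  up_d <- numeric(n); up_d[seq(1L, n, 2L)] <- detail
  ## synthesis is the adjoint of the analysis: correlate with the
  ## reconstruction filters (indices run backwards relative to circ_filt)
  x <- circ_filt_adj(up_a, filt$dec_lo) + circ_filt_adj(up_d, filt$dec_hi)
  x[seq_len(len)]
}

## adjoint of circ_filt: y[j] = sum_m f[m] x[(j - m) mod N]
circ_filt_adj <- function(x, f) {
  n <- length(x)
  L <- length(f)
  idx <- outer(seq_len(n) - 1L, -(seq_len(L) - 1L), "+") %% n + 1L
  as.numeric(matrix(x[idx], n, L) %*% f)
}

#' Multi-level discrete wavelet decomposition (db10, periodized)
#'
#' Pyramid decomposition of a 1-D signal with the db10 orthonormal filter
#' bank and periodic boundary handling.  Odd-length inputs at any level are
#' extended by repeating the final sample; the recorded per-level lengths
#' make the transform exactly invertible (see [dwt_reconstruct()]).
#'
#' Detail level 1 is the finest scale.  At sampling rate `r`, detail level
#' `j` covers approximately the band `[r/2^(j+1), r/2^j]` Hz.
#'
#' @param x numeric signal.
#' @param levels decomposition depth; reduced with a warning when the signal
#'   is too short to support it (at least one sample must remain per level).
#' @return object of class `gait_dwt`: list with `approx` (coarsest
#'   approximation), `details` (list, finest first), `lengths`, `levels`.
#' @export
dwt_decompose <- function(x, levels = 8L) {
  stopifnot(is.numeric(x), length(x) >= 2L)
  filt <- db10_filters()
  max_lev <- max(1L, floor(log2(length(x))) - 1L)
  if (levels > max_lev) {
    warning(sprintf("signal of length %d supports only %d DWT levels (requested %d)",
                    length(x), max_lev, levels))
    levels <- max_lev
  }
  details <- vector("list", levels)
  lengths <- integer(levels)
  cur <- x
  for (j in seq_len(levels)) {
    st <- dwt_step(cur, filt)
    details[[j]] <- st$detail
    lengths[j] <- st$len
    cur <- st$approx
  }
  structure(list(approx = cur, details = details, lengths = lengths,
                 levels = levels, n = length(x)),
            class = "gait_dwt")
}

#' Reconstruct a signal from selected DWT detail levels
#'
#' Inverse of [dwt_decompose()].  With `keep_levels = NULL` and
#' `keep_approx = TRUE` the original signal is recovered to machine
#' precision; otherwise all coefficients outside the kept detail levels
#' (and optionally the approximation) are zeroed first, yielding a
#' band-limited reconstruction.
#'
#' @param dec a `gait_dwt` object.
#' @param keep_levels integer vector of detail levels to keep (1 = finest),
#'   or NULL to keep all.
#' @param keep_approx keep the coarse approximation?
#' @return numeric signal of the original length.
#' @export
dwt_reconstruct <- function(dec, keep_levels = NULL, keep_approx = is.null(keep_levels)) {
  stopifnot(inherits(dec, "gait_dwt"))
  filt <- db10_filters()
  details <- dec$details
  if (!is.null(keep_levels)) {
    drop <- setdiff(seq_len(dec$levels), keep_levels)
    for (j in drop) details[[j]] <- numeric(length(details[[j]]))
  }
  cur <- if (keep_approx) dec$approx else numeric(length(dec$approx))
  for (j in rev(seq_len(dec$levels))) {
    cur <- idwt_step(cur, details[[j]], dec$lengths[j], filt)
  }
  cur
}

#' Per-sample energy of selected detail levels
#'
#' Squares the detail coefficients of the chosen levels, maps each back to
#' the sample positions it summarizes (coefficient k at level j covers
#' samples (k-1)*2^j + 1 .. k*2^j), and sums across levels.  Used by the
#' wavelet walk detector, which then smooths this energy envelope.
#'
#' @param dec a `gait_dwt` object.
#' @param levels detail levels to include.
#' @return numeric vector of length `dec$n`.
#' @export
dwt_detail_energy <- function(dec, levels) {
  stopifnot(inherits(dec, "gait_dwt"), all(levels >= 1L), all(levels <= dec$levels))
  energy <- numeric(dec$n)
  for (j in levels) {
    e <- dec$details[[j]]^2
    up <- rep(e, each = 2^j)[seq_len(dec$n)]
    if (length(up) < dec$n) up <- c(up, rep(up[length(up)], dec$n - length(up)))
    energy <- energy + up
  }
  energy
}
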